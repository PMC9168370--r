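## Single-level stationary (undecimated) 3-D wavelet transform.  The
## undecimated form keeps the array shape, so the original tumour mask
## applies unchanged to every sub-band.  Default basis Coiflet-1; any axis
## shorter than the filter support falls back to Haar (always the z axis of
## a 3-slice stack), which preserves the 8-band structure.

.WAVE_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  coif1 = c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
            0.852572020212255, 0.337897662457809, -0.072732619512854))

qmf_high <- function(lo) {
  n <- length(lo)
  rev(lo) * (-1)^(seq_len(n) - 1)
}

## periodic, phase-centred convolution along one axis (the output stays
## spatially aligned with the input so the original mask applies)
conv_axis_periodic <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  L <- dim(x)[1]
  xm <- matrix(x, nrow = L)
  out <- matrix(0, L, ncol(xm))
  # centre on the kernel's energy centroid (its group delay), so sub-bands
  # stay aligned with the mask even for asymmetric filters
  ctr <- round(sum((seq_along(kernel) - 1) * abs(kernel)) / sum(abs(kernel)))
  for (t in seq_along(kernel)) {
    idx <- ((seq_len(L) + t - 2L - ctr) %% L) + 1L
    out <- out + kernel[t] * xm[idx, , drop = FALSE]
  }
  aperm(array(out, dim(x)), order(perm))
}

#' Single-level stationary 3-D wavelet decomposition
#'
#' @param arr 3-D numeric array.
#' @param basis "coif1" (default) or "haar"; axes shorter than the filter
#'   fall back to Haar.
#' @return named list of 8 arrays (`LLL` ... `HHH`; letters are the
#'   low/high-pass choice along axes 1, 2, 3).
#' @export
swt3 <- function(arr, basis = "coif1") {
  stop_if_not(basis %in% names(.WAVE_FILTERS), "unknown wavelet basis")
  d <- dim(arr)
  bands <- stats::setNames(list(arr), "x")
  for (ax in 1:3) {
    lo <- .WAVE_FILTERS[[basis]]
    if (d[ax] < length(lo)) lo <- .WAVE_FILTERS[["haar"]]
    hi <- qmf_high(lo)
    nxt <- list()
    for (i in seq_along(bands)) {
      nm <- sub("^x", "", names(bands)[i])
      nxt[[paste0("x", nm, "L")]] <- conv_axis_periodic(bands[[i]], lo, ax)
      nxt[[paste0("x", nm, "H")]] <- conv_axis_periodic(bands[[i]], hi, ax)
    }
    bands <- nxt
  }
  names(bands) <- sub("^x", "", names(bands))
  bands[.WAVELET_BANDS]
}

#' Extract the full 851-feature handcrafted radiomics vector
#'
#' Concatenates, in catalogue order: 14 shape features of the mask stack,
#' 18 first-order and 75 texture features of the original image, and the 93
#' non-shape features recomputed on each of the 8 stationary-wavelet
#' sub-bands under the original mask.  Any non-finite value aborts with the
#' offending feature named.
#'
#' @param stack a `roi_stack` from [preprocess_roi()].
#' @param disc a [discretization_config()].
#' @param wavelet wavelet basis passed to [swt3()].
#' @return named numeric vector of length 851.
#' @export
extract_all <- function(stack, disc = discretization_config(),
                        wavelet = "coif1") {
  stopifnot(inherits(stack, "roi_stack"))
  masks <- stack$masks
  voxvol <- prod(stack$spacing)
  out <- numeric(0)
  sh <- extract_shape(masks, stack$spacing)
  names(sh) <- paste0("original_shape_", names(sh))
  fo <- extract_first_order(stack$slices[masks > 0], voxvol, disc$n_bins)
  names(fo) <- paste0("original_firstorder_", names(fo))
  tx <- texture_all_families(stack$slices, masks, disc)
  names(tx) <- paste0("original_", names(tx))
  out <- c(sh, fo, tx)
  for (band in swt3_named(stack$slices, wavelet)) {
    pre <- attr(band, "band_name")
    fo <- extract_first_order(band[masks > 0], voxvol, disc$n_bins)
    names(fo) <- paste0(pre, "_firstorder_", names(fo))
    tx <- texture_all_families(band, masks, disc)
    names(tx) <- paste0(pre, "_", names(tx))
    out <- c(out, fo, tx)
  }
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(utils::head(names(out)[bad], 5), collapse = ", "),
         call. = FALSE)
  out
}

swt3_named <- function(arr, basis) {
  b <- swt3(arr, basis)
  lapply(names(b), function(nm) {
    x <- b[[nm]]
    attr(x, "band_name") <- paste0("wavelet.", nm)
    x
  })
}

#' Extract a feature table for a list of ROI stacks
#'
#' @param stacks named list of `roi_stack` objects (names = subject ids).
#' @param disc a [discretization_config()].
#' @param wavelet wavelet basis.
#' @return numeric matrix, subjects x 851 named features.
#' @export
extract_feature_table <- function(stacks, disc = discretization_config(),
                                  wavelet = "coif1") {
  rows <- lapply(stacks, extract_all, disc = disc, wavelet = wavelet)
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(stacks)
  tab
}

#' Deterministic convolutional feature bank (external-feature stand-in)
#'
#' A pluggable numeric feature bank matching the shape of features exported
#' from pre-trained convolutional networks: `D` fixed random 5x5
#' convolution filters (seeded), valid convolution on each slice, ReLU
#' rectification, global max pooling, then the mean over the slices.  The
#' same table contract accepts user-supplied precomputed features via
#' [read_external_features()].
#'
#' @param stack a `roi_stack`.
#' @param D bank width, typically 512, 1536 or 2048.
#' @param seed filter seed; the same seed always yields the same bank.
#' @param prefix column-name prefix (e.g. the notional extractor name).
#' @return named numeric vector of length `D`.
#' @export
feature_bank <- function(stack, D = 2048L, seed = 1L, prefix = "bank") {
  stopifnot(inherits(stack, "roi_stack"))
  stop_if_not(D >= 1, "D must be positive")
  k <- 5L
  W <- with_seed(seed, matrix(stats::rnorm(k * k * D, sd = 1 / k), k * k, D))
  sl <- stack$slices
  n <- dim(sl)[3]
  nr <- dim(sl)[1]; nc <- dim(sl)[2]
  stop_if_not(nr >= k && nc >= k, "slice smaller than filter")
  pooled <- matrix(0, n, D)
  orow <- nr - k + 1L; ocol <- nc - k + 1L
  # im2col indices shared across slices
  base <- as.vector(outer(seq_len(orow), (seq_len(ocol) - 1L) * nr, `+`))
  patch <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * nr, `+`)) - 1L
  idx <- outer(base, patch, `+`)
  for (s in seq_len(n)) {
    X <- matrix(sl[, , s][idx], nrow(idx), ncol(idx))
    A <- pmax(X %*% W, 0)
    pooled[s, ] <- apply(A, 2, max)
  }
  stats::setNames(colMeans(pooled), sprintf("%s_f%04d", prefix, seq_len(D)))
}

#' Read precomputed external features from CSV
#'
#' The CSV must have a `subject_id` column followed by numeric feature
#' columns; rows are matched to `subject_ids` exactly.
#'
#' @param path CSV file path.
#' @param subject_ids required subject ids, in order.
#' @return numeric matrix subjects x features.
#' @export
read_external_features <- function(path, subject_ids) {
  df <- utils::read.csv(path, check.names = FALSE)
  stop_if_not("subject_id" %in% names(df),
              "external feature CSV needs a subject_id column")
  m <- match(subject_ids, df$subject_id)
  if (anyNA(m))
    stop("external feature CSV is missing subjects: ",
         paste(utils::head(subject_ids[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  x <- as.matrix(df[m, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- subject_ids
  stop_if_not(all(is.finite(x)), "external features contain non-finite values")
  x
}
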