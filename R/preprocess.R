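#' Preprocessing configuration
#'
#' Parameters of the image standardization chain applied between raw
#' volume+mask and the model-ready region-of-interest stack: intensity
#' resegmentation, adaptive windowing, Gaussian denoising, 0-255
#' normalization with histogram equalization, informative-slice selection
#' and fixed-size cropping.
#'
#' @param hu_range attenuation range (HU) retained by resegmentation.
#' @param denoise_sigma Gaussian denoising kernel SD in voxels (0 = off).
#' @param n_slices odd number of consecutive axial slices retained.
#' @param crop_size side length (pixels) of the square tumour crop; at the
#'   base 1 mm spacing one pixel is one mm.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_range = c(-1000, 400), denoise_sigma = 0.5,
                              n_slices = 3L, crop_size = 224L) {
  stop_if_not(hu_range[1] < hu_range[2], "hu_range must be increasing")
  stop_if_not(n_slices >= 1 && n_slices %% 2 == 1, "n_slices must be odd >= 1")
  stop_if_not(crop_size > 0, "crop_size must be positive")
  stop_if_not(denoise_sigma >= 0, "denoise_sigma must be >= 0")
  structure(list(hu_range = hu_range, out_range = c(0, 255),
                 denoise_sigma = denoise_sigma, n_slices = as.integer(n_slices),
                 crop_size = as.integer(crop_size)),
            class = "preprocess_config")
}

#' Intensity resegmentation of a tumour mask
#'
#' Restricts the mask to voxels whose attenuation lies inside `hu_range`,
#' excluding air, bone and other irrelevant content from the region of
#' interest.
#'
#' @param volume HU array.
#' @param mask 0/1 array on the same grid.
#' @param hu_range retained attenuation range (HU).
#' @return the restricted 0/1 mask (a subset of `mask`).
#' @export
resegment <- function(volume, mask, hu_range = c(-1000, 400)) {
  stop_if_not(identical(dim(volume), dim(mask)), "volume/mask grids differ")
  out <- mask * (volume >= hu_range[1] & volume <= hu_range[2])
  if (sum(out) == 0) stop("ROI eliminated by resegmentation", call. = FALSE)
  array(as.integer(out), dim(mask))
}

#' Adaptive intensity windowing around the tumour
#'
#' The window centre is the mean attenuation inside the mask and the window
#' width twice the inner 1st-99th percentile spread (floored at 1 HU);
#' intensities are clipped to the window.  Applying the window twice changes
#' nothing.
#'
#' @param volume HU array.
#' @param mask 0/1 array; must be nonempty.
#' @return list with clipped `volume` and the applied `window` (center, width).
#' @export
adaptive_window <- function(volume, mask) {
  vals <- volume[mask > 0]
  stop_if_not(length(vals) > 0, "adaptive_window: empty mask")
  ctr <- mean(vals)
  wid <- max(2 * (qtl(vals, 0.99) - qtl(vals, 0.01)), 1)
  list(volume = clip(volume, ctr - wid / 2, ctr + wid / 2),
       window = c(center = ctr, width = wid))
}

#' Gaussian denoising
#'
#' Separable Gaussian convolution with reflect boundary; `sigma = 0` is the
#' identity.  CT quantum noise is well modelled as additive Gaussian, which
#' this filter attenuates.
#'
#' @param image 2-D or 3-D numeric array.
#' @param sigma kernel SD in voxels.
#' @return filtered array of identical shape.
#' @export
denoise <- function(image, sigma = 0.5) {
  stop_if_not(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(image)
  gauss_smooth(image, sigma)
}

#' Rescale to 0-255 and equalize the histogram
#'
#' Linearly maps min to 0 and max to 255, then applies 256-bin histogram
#' equalization (cumulative-distribution remapping).  A constant image maps
#' to all zeros by convention.
#'
#' @param image numeric array.
#' @return array of the same shape with values in \[0, 255\].
#' @export
normalize_and_equalize <- function(image) {
  rng <- range(image)
  if (rng[1] == rng[2]) return(array(0, dim(image) %||% length(image)))
  x <- (image - rng[1]) / (rng[2] - rng[1]) * 255
  b <- pmin(floor(x), 255)                    # 256 bins, 0..255
  h <- tabulate(b + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  n <- length(x)
  lut <- round((cdf - cdf_min) / max(n - cdf_min, 1) * 255)
  out <- array(lut[b + 1L], dim(image) %||% length(image))
  out
}

#' Select the consecutive slices with maximal tumour area
#'
#' Returns the window of `n_slices` consecutive axial slice indices whose
#' total in-mask area is maximal; ties break toward the smaller index.  If
#' the mask spans fewer than `n_slices` slices, the window is centred on the
#' mask and empty-mask positions are later filled by duplicating the nearest
#' mask-bearing slice (a warning is raised when assembling the stack).
#'
#' @param mask 3-D 0/1 array.
#' @param n_slices odd window length.
#' @return integer vector of `n_slices` consecutive slice indices.
#' @export
select_informative_slices <- function(mask, n_slices = 3L) {
  areas <- apply(mask, 3, sum)
  stop_if_not(sum(areas) > 0, "select_informative_slices: empty mask")
  nz <- dim(mask)[3]
  occupied <- which(areas > 0)
  if (length(occupied) < n_slices) {
    k <- round(stats::median(occupied))
    half <- (n_slices - 1L) %/% 2L
    lo <- clip(k - half, 1L, max(1L, nz - n_slices + 1L))
    return(as.integer(seq(lo, length.out = min(n_slices, nz))))
  }
  if (nz < n_slices) return(seq_len(nz))
  win <- vapply(seq_len(nz - n_slices + 1L),
                function(i) sum(areas[i:(i + n_slices - 1L)]), numeric(1))
  i0 <- which.max(win)                        # which.max takes the first max
  as.integer(i0:(i0 + n_slices - 1L))
}

#' Crop a slice to a fixed tile centred on the tumour bounding box
#'
#' The tile is centred on the centre of the mask bounding box and
#' zero-padded where it extends past the image border, so a translation of
#' the tumour leaves the tile content unchanged.  If the tumour exceeds the
#' tile it is centre-cropped with a warning.
#'
#' @param slice 2-D numeric matrix.
#' @param mask_slice matching 0/1 matrix (defines the bounding box).
#' @param crop_size tile side length in pixels.
#' @param center optional precomputed (row, col) bounding-box centre; used to
#'   crop all slices of a stack consistently.
#' @return list with `tile`, `mask_tile` (both `crop_size` square) and the
#'   `center` used.
#' @export
crop_to_bbox <- function(slice, mask_slice, crop_size = 224L, center = NULL) {
  if (is.null(center)) {
    idx <- which(mask_slice > 0, arr.ind = TRUE)
    stop_if_not(nrow(idx) > 0, "crop_to_bbox: empty mask")
    center <- c(round((min(idx[, 1]) + max(idx[, 1])) / 2),
                round((min(idx[, 2]) + max(idx[, 2])) / 2))
    ext <- c(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
    if (any(ext > crop_size))
      warning("tumour exceeds crop size; centre-cropping", call. = FALSE)
  }
  half <- (crop_size - 1) / 2
  rows <- seq.int(floor(center[1] - half), length.out = crop_size)
  cols <- seq.int(floor(center[2] - half), length.out = crop_size)
  tile <- matrix(0, crop_size, crop_size)
  mtile <- matrix(0L, crop_size, crop_size)
  rok <- rows >= 1 & rows <= nrow(slice)
  cok <- cols >= 1 & cols <= ncol(slice)
  tile[rok, cok] <- slice[rows[rok], cols[cok]]
  mtile[rok, cok] <- mask_slice[rows[rok], cols[cok]]
  list(tile = tile, mask_tile = mtile, center = center)
}

#' Run the full preprocessing chain on one subject
#'
#' Fixed order: resegment, adaptive window, denoise, normalize + equalize,
#' informative-slice selection, bounding-box crop.  All intensity operations
#' precede slice selection so the retained slices share one transform; the
#' mask geometry is only changed by resegmentation.
#'
#' @param volume 3-D HU array.
#' @param mask 3-D 0/1 array on the same grid.
#' @param config a [preprocess_config()].
#' @param spacing voxel spacing (mm) carried through to feature extraction.
#' @return An object of class `roi_stack`: list with `slices` and `masks`
#'   (crop x crop x n_slices arrays), `slice_indices`, `window`, `spacing`.
#' @export
preprocess_roi <- function(volume, mask, config = preprocess_config(),
                           spacing = c(1, 1, 1)) {
  mask2 <- resegment(volume, mask, config$hu_range)
  aw <- adaptive_window(volume, mask2)
  vol <- denoise(aw$volume, config$denoise_sigma)
  vol <- normalize_and_equalize(vol)
  zi <- select_informative_slices(mask2, config$n_slices)
  # duplicate the nearest mask-bearing slice where the window overruns the mask
  areas <- apply(mask2, 3, sum)
  src <- zi
  if (any(areas[zi] == 0)) {
    warning("mask thinner than n_slices; duplicating boundary slices",
            call. = FALSE)
    occ <- which(areas > 0)
    src <- vapply(zi, function(k) occ[which.min(abs(occ - k))], integer(1))
  }
  um <- Reduce(`|`, lapply(src, function(k) mask2[, , k] > 0))
  idx <- which(um, arr.ind = TRUE)
  center <- c(round((min(idx[, 1]) + max(idx[, 1])) / 2),
              round((min(idx[, 2]) + max(idx[, 2])) / 2))
  ext <- c(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
  if (any(ext > config$crop_size))
    warning("tumour exceeds crop size; centre-cropping", call. = FALSE)
  n <- config$n_slices
  cs <- config$crop_size
  slices <- array(0, c(cs, cs, n))
  masks <- array(0L, c(cs, cs, n))
  for (j in seq_len(n)) {
    cr <- crop_to_bbox(vol[, , src[j]], mask2[, , src[j]], cs, center = center)
    slices[, , j] <- cr$tile
    masks[, , j] <- cr$mask_tile
  }
  structure(list(slices = slices, masks = masks,
                 slice_indices = as.integer(zi), window = aw$window,
                 spacing = as.numeric(spacing)),
            class = "roi_stack")
}

#' @export
print.roi_stack <- function(x, ...) {
  cat(sprintf("roi_stack: %d slices of %dx%d px, %d mask px, window %.1f +/- %.1f\n",
              dim(x$slices)[3], dim(x$slices)[1], dim(x$slices)[2],
              sum(x$masks), x$window["center"], x$window["width"] / 2))
  invisible(x)
}
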