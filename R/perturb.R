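#' Perturbation specification
#'
#' Levels of the three image perturbations used for robustness screening:
#' slice thickness `S` (mm, slab averaging of the base 1 mm acquisition),
#' in-plane rotation `R` (degrees) and segmentation `Seg` (target mask
#' area/volume ratio from morphological dilation or erosion).
#'
#' @param S slice thicknesses in mm.
#' @param R rotation angles in degrees.
#' @param Seg target mask volume ratios.
#' @return list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(S = c(1, 2, 3, 5), R = c(-30, -15, 15, 30),
                              Seg = c(0.8, 1.2)) {
  stop_if_not(length(S) > 0 && length(R) > 0 && length(Seg) > 0,
              "each perturbation kind needs at least one level")
  stop_if_not(all(Seg > 0), "Seg factors must be positive")
  structure(list(S = S, R = R, Seg = Seg), class = "perturbation_spec")
}

#' Slice-thickness perturbation by slab averaging
#'
#' Groups consecutive 1 mm axial slices into slabs of `t_mm`, averaging the
#' volume and taking a majority vote (>= 50 percent occupancy) for the mask.
#' Leftover slices that do not fill a slab are dropped.
#'
#' @param volume 3-D HU array at base spacing.
#' @param mask matching 0/1 array.
#' @param t_mm slab thickness; must be a multiple of the base z spacing.
#' @param base_mm base z spacing (mm).
#' @return list with `volume`, `mask` and updated `spacing`.
#' @export
perturb_thickness <- function(volume, mask, t_mm, base_mm = 1) {
  f <- t_mm / base_mm
  stop_if_not(abs(f - round(f)) < 1e-9 && f >= 1,
              "t_mm must be a positive multiple of the base spacing")
  f <- as.integer(round(f))
  if (f == 1L) return(list(volume = volume, mask = mask,
                           spacing = c(1, 1, base_mm)))
  nz <- dim(volume)[3] %/% f
  stop_if_not(nz >= 1, "thickness %s mm leaves no complete slab", t_mm)
  d <- dim(volume)
  vout <- array(0, c(d[1], d[2], nz))
  mout <- array(0L, c(d[1], d[2], nz))
  for (i in seq_len(nz)) {
    zz <- ((i - 1L) * f + 1L):(i * f)
    vout[, , i] <- apply(volume[, , zz, drop = FALSE], c(1, 2), mean)
    mout[, , i] <- (apply(mask[, , zz, drop = FALSE], c(1, 2), mean) >= 0.5) * 1L
  }
  list(volume = vout, mask = mout, spacing = c(1, 1, t_mm))
}

## Inverse-mapped rotation of a matrix about its centre.
## interp = "bilinear" (image) or "nearest" (mask); out-of-canvas pixels -> 0.
rotate_matrix <- function(m, theta_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- nrow(m); nc <- ncol(m)
  th <- theta_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - cr; dc <- g$c - cc
  # source coordinates: rotate backwards
  sr <- cos(th) * dr - sin(th) * dc + cr
  sc <- sin(th) * dr + cos(th) * dc + cc
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(nr * nc)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    out <- numeric(nr * nc)
    ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
    if (any(ok)) {
      i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
      i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
      out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
        m[i10] * fr[ok] * (1 - fc[ok]) +
        m[i01] * (1 - fr[ok]) * fc[ok] +
        m[i11] * fr[ok] * fc[ok]
    }
    # border pixels whose 2x2 neighbourhood is clipped: nearest fallback
    edge <- !ok & round(sr) >= 1 & round(sr) <= nr &
      round(sc) >= 1 & round(sc) <= nc
    if (any(edge)) out[edge] <- m[cbind(round(sr[edge]), round(sc[edge]))]
  }
  matrix(out, nr, nc)
}

#' In-plane rotation perturbation
#'
#' Rotates an axial slice and its mask about the tile centre, preserving the
#' canvas size.  The image uses bilinear interpolation, the mask
#' nearest-neighbour so it stays binary.
#'
#' @param slice 2-D numeric matrix.
#' @param mask matching 0/1 matrix.
#' @param theta rotation angle in degrees.
#' @return list with rotated `slice` and `mask`.
#' @export
perturb_rotation <- function(slice, mask, theta) {
  if (theta == 0) return(list(slice = slice, mask = mask))
  s2 <- rotate_matrix(slice, theta, "bilinear")
  m2 <- rotate_matrix(mask, theta, "nearest")
  if (sum(m2) == 0) stop("rotation emptied the mask", call. = FALSE)
  list(slice = s2, mask = matrix(as.integer(m2 > 0), nrow(mask), ncol(mask)))
}

## One morphological step with the unit ball (face-connected) element.
morph_step <- function(mask, grow = TRUE) {
  d <- dim(mask)
  acc <- mask
  for (ax in seq_along(d)) {
    for (s in c(-1L, 1L)) {
      shifted <- shift_array(mask, ax, s, fill = if (grow) 0L else 1L)
      acc <- if (grow) pmax(acc, shifted) else pmin(acc, shifted)
    }
  }
  array(as.integer(acc), d)
}

#' Segmentation perturbation by morphological dilation/erosion
#'
#' Iteratively dilates (`factor > 1`) or erodes (`factor < 1`) the mask with
#' a unit ball element, stopping at the iterate whose volume ratio to the
#' original is closest to `factor`.  If erosion would empty the mask, the
#' last nonempty iterate is returned with a warning.
#'
#' @param mask 0/1 array (2-D or 3-D), nonempty.
#' @param factor target volume ratio (> 0).
#' @return list with `mask` and `achieved_ratio`.
#' @export
perturb_segmentation <- function(mask, factor) {
  stop_if_not(factor > 0, "factor must be > 0")
  v0 <- sum(mask)
  stop_if_not(v0 > 0, "perturb_segmentation: empty mask")
  if (abs(factor - 1) < 1e-12)
    return(list(mask = mask, achieved_ratio = 1))
  grow <- factor > 1
  best <- mask; best_ratio <- 1
  cur <- mask
  repeat {
    nxt <- morph_step(cur, grow = grow)
    v <- sum(nxt)
    if (!grow && v == 0) {
      warning("erosion emptied the mask; returning last nonempty iterate",
              call. = FALSE)
      break
    }
    ratio <- v / v0
    if (abs(ratio - factor) < abs(best_ratio - factor)) {
      best <- nxt; best_ratio <- ratio
      cur <- nxt
    } else break
    if ((grow && ratio >= factor) || (!grow && ratio <= factor)) break
  }
  list(mask = best, achieved_ratio = best_ratio)
}

#' Build the perturbation replicate panel for one subject
#'
#' Produces, for each perturbation kind, the original plus one processed
#' replicate per level, every replicate run through the identical
#' preprocessing chain.  Thickness and segmentation act on the raw
#' volume/mask before preprocessing; rotation acts on the selected,
#' preprocessed axial slices (it is a 2-D in-plane perturbation).
#'
#' @param volume raw 3-D HU array.
#' @param mask raw 0/1 array.
#' @param config a [preprocess_config()].
#' @param spec a [perturbation_spec()].
#' @param spacing base voxel spacing (mm).
#' @return nested list `replicates[[kind]][[level]]` of `roi_stack`s, each
#'   kind also containing an `"original"` entry; plus an `achieved` vector
#'   of realized segmentation ratios.
#' @export
make_replicates <- function(volume, mask, config = preprocess_config(),
                            spec = perturbation_spec(), spacing = c(1, 1, 1)) {
  orig <- preprocess_roi(volume, mask, config, spacing = spacing)
  out <- list(S = list(original = orig), R = list(original = orig),
              Seg = list(original = orig))
  achieved <- c()
  for (t in spec$S) {
    p <- perturb_thickness(volume, mask, t, base_mm = spacing[3])
    out$S[[as.character(t)]] <-
      preprocess_roi(p$volume, p$mask, config, spacing = p$spacing)
  }
  for (th in spec$R) {
    st <- orig
    for (j in seq_len(dim(st$slices)[3])) {
      r <- perturb_rotation(st$slices[, , j], st$masks[, , j], th)
      st$slices[, , j] <- r$slice
      st$masks[, , j] <- r$mask
    }
    out$R[[as.character(th)]] <- st
  }
  for (f in spec$Seg) {
    p <- perturb_segmentation(mask, f)
    achieved[as.character(f)] <- p$achieved_ratio
    out$Seg[[as.character(f)]] <-
      preprocess_roi(volume, p$mask, config, spacing = spacing)
  }
  attr(out, "achieved_seg_ratio") <- achieved
  out
}
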