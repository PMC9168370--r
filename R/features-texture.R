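## Second-order texture features.  Matrices are built in 2-D per axial
## slice: GLCM and GLRLM over the four in-plane directions at distance 1
## (direction-averaged first, then slice-averaged); GLSZM, GLDM and NGTDM
## once per slice with 8-connected neighbourhoods.  Gray levels come from
## equal-width discretization of the pooled in-mask stack intensities.

.T_OFFSETS <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
.N_OFFSETS <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L),
                   c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))

## ---- GLCM -----------------------------------------------------------------

glcm_counts <- function(L, Ng, off) {
  B <- shift_matrix(L, -off[1], -off[2], fill = 0L)
  sel <- L > 0L & B > 0L
  if (!any(sel)) return(matrix(0, Ng, Ng))
  cnt <- tabulate((L[sel] - 1L) * Ng + B[sel], Ng * Ng)
  M <- matrix(cnt, Ng, Ng, byrow = TRUE)
  M + t(M)                                   # symmetric co-occurrences
}

glcm_features <- function(P) {
  Ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) { P <- matrix(0, Ng, Ng); P[1, 1] <- 1; tot <- 1 }
  P <- P / tot
  lv <- seq_len(Ng)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sigx <- sqrt(sum((lv - mux)^2 * px)); sigy <- sqrt(sum((lv - muy)^2 * py))
  psum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))        # k = 2..2Ng
  ks <- sort(unique(as.vector(i + j)))
  pdif <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))   # k = 0..Ng-1
  kd <- sort(unique(as.vector(abs(i - j))))
  da <- sum(kd * pdif)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + .EPS))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(P * i * j) - mux * muy) / (sigx * sigy) else 1
  # maximal correlation coefficient on the present gray levels
  pres <- which(px > 0)
  mcc <- if (length(pres) < 2) 1 else {
    Pp <- P[pres, pres, drop = FALSE]
    Pn <- sweep(Pp, 2, py[pres], `/`)
    Q <- sweep(Pp %*% t(Pn), 1, px[pres], `/`)
    e <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(clip(e[2], 0, 1))
  }
  c(Autocorrelation = sum(P * i * j),
    JointAverage = mux,
    ClusterProminence = sum(P * (i + j - mux - muy)^4),
    ClusterShade = sum(P * (i + j - mux - muy)^3),
    ClusterTendency = sum(P * (i + j - mux - muy)^2),
    Contrast = sum(P * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdif[pdif > 0] * log2(pdif[pdif > 0])),
    DifferenceVariance = sum((kd - da)^2 * pdif),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1, Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    SumSquares = sum(P * (i - mux)^2))
}

glcm_slice <- function(L, Ng) {
  rowMeans(vapply(.T_OFFSETS,
                  function(off) glcm_features(glcm_counts(L, Ng, off)),
                  numeric(24)))
}

## ---- GLRLM ----------------------------------------------------------------

## runs of positive levels in a vector where NA acts as a hard break
runs_of <- function(v) {
  r <- rle(v)
  keep <- !is.na(r$values) & r$values > 0
  cbind(level = r$values[keep], len = r$lengths[keep])
}

direction_vector <- function(L, off) {
  if (off[1] == 0L && off[2] == 1L) return(as.vector(rbind(t(L), NA)))
  if (off[1] == 1L && off[2] == 0L) return(as.vector(rbind(L, NA)))
  rr <- as.vector(row(L)); cc <- as.vector(col(L))
  key <- if (off[2] == 1L) cc - rr else cc + rr
  sp <- split(as.vector(L), key)
  unlist(lapply(sp, c, NA), use.names = FALSE)
}

glrlm_features <- function(cnt, Ng, Np) {
  Nr <- sum(cnt)
  if (Nr == 0) { cnt <- matrix(0, Ng, 1); cnt[1, 1] <- 1; Nr <- 1 }
  lv <- seq_len(Ng); rl <- seq_len(ncol(cnt))
  ri <- rowSums(cnt); rj <- colSums(cnt)
  p <- cnt / Nr
  mu_i <- sum(lv * rowSums(p)); mu_r <- sum(rl * colSums(p))
  c(ShortRunEmphasis = sum(t(cnt) / rl^2) / Nr,
    LongRunEmphasis = sum(t(cnt) * rl^2) / Nr,
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    RunLengthNonUniformity = sum(rj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    RunPercentage = Nr / Np,
    GrayLevelVariance = sum(p * (lv - mu_i)^2),
    RunVariance = sum(t(p) * (rl - mu_r)^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(cnt / lv^2) / Nr,
    HighGrayLevelRunEmphasis = sum(cnt * lv^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(t(cnt / lv^2) / rl^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(t(cnt * lv^2) / rl^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(t(cnt / lv^2) * rl^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(t(cnt * lv^2) * rl^2) / Nr)
}

glrlm_slice <- function(L, Ng) {
  Np <- sum(L > 0)
  feats <- vapply(.T_OFFSETS, function(off) {
    rn <- runs_of(direction_vector(L, off))
    if (nrow(rn) == 0) return(glrlm_features(matrix(0, Ng, 1), Ng, max(Np, 1)))
    mx <- max(rn[, "len"])
    cnt <- matrix(tabulate((rn[, "len"] - 1L) * Ng + rn[, "level"], Ng * mx),
                  Ng, mx)
    glrlm_features(cnt, Ng, Np)
  }, numeric(16))
  rowMeans(feats)
}

## ---- GLSZM ----------------------------------------------------------------

## connected zones of equal gray level (8-connectivity) via graph components
zones_of <- function(L) {
  idx <- which(L > 0L)
  m <- length(idx)
  if (m == 0) return(NULL)
  nr <- nrow(L); nc <- ncol(L)
  map <- integer(length(L)); map[idx] <- seq_len(m)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  e_from <- integer(0); e_to <- integer(0)
  for (off in .T_OFFSETS) {
    ok <- r + off[1] >= 1L & r + off[1] <= nr &
      cc + off[2] >= 1L & cc + off[2] <= nc
    nb <- idx[ok] + off[1] + off[2] * nr
    same <- L[nb] == L[idx[ok]] & L[nb] > 0L
    e_from <- c(e_from, map[idx[ok][same]])
    e_to <- c(e_to, map[nb[same]])
  }
  g <- igraph::make_empty_graph(m, directed = FALSE)
  if (length(e_from))
    g <- igraph::add_edges(g, as.vector(rbind(e_from, e_to)))
  comp <- igraph::components(g)
  first <- match(seq_len(comp$no), comp$membership)
  cbind(level = L[idx][first], size = comp$csize)
}

glszm_features <- function(zones, Ng, Np) {
  Nz <- nrow(zones)
  lvz <- zones[, "level"]; sz <- zones[, "size"]
  gl_cnt <- tabulate(lvz, Ng)
  sz_cnt <- tabulate(sz)
  p_lv <- gl_cnt / Nz
  mu_i <- sum(seq_len(Ng) * p_lv)
  mu_s <- mean(sz)
  pz <- rep(1 / Nz, Nz)
  c(SmallAreaEmphasis = mean(1 / sz^2),
    LargeAreaEmphasis = mean(sz^2),
    GrayLevelNonUniformity = sum(gl_cnt^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(gl_cnt^2) / Nz^2,
    SizeZoneNonUniformity = sum(sz_cnt^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(sz_cnt^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum(p_lv * (seq_len(Ng) - mu_i)^2),
    ZoneVariance = mean((sz - mu_s)^2),
    ZoneEntropy = {
      # joint (level, size) distribution
      key <- (sz - 1L) * Ng + lvz
      pj <- tabulate(key, Ng * max(sz)) / Nz
      -sum(pj[pj > 0] * log2(pj[pj > 0]))
    },
    LowGrayLevelZoneEmphasis = mean(1 / lvz^2),
    HighGrayLevelZoneEmphasis = mean(lvz^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (lvz^2 * sz^2)),
    SmallAreaHighGrayLevelEmphasis = mean(lvz^2 / sz^2),
    LargeAreaLowGrayLevelEmphasis = mean(sz^2 / lvz^2),
    LargeAreaHighGrayLevelEmphasis = mean(lvz^2 * sz^2))
}

glszm_slice <- function(L, Ng) {
  Np <- sum(L > 0)
  z <- zones_of(L)
  if (is.null(z)) z <- cbind(level = 1L, size = 1L)
  glszm_features(z, Ng, max(Np, 1))
}

## ---- GLDM -----------------------------------------------------------------

gldm_slice <- function(L, Ng) {
  inm <- L > 0L
  Np <- sum(inm)
  dep <- matrix(0L, nrow(L), ncol(L))
  for (off in .N_OFFSETS) {
    B <- shift_matrix(L, -off[1], -off[2], fill = 0L)
    dep <- dep + (inm & B == L & B > 0L)
  }
  d <- dep[inm] + 1L                          # centre voxel counts itself
  lv <- L[inm]
  Nd <- max(d)
  cnt <- matrix(tabulate((d - 1L) * Ng + lv, Ng * Nd), Ng, Nd)
  Nz <- sum(cnt)
  p <- cnt / Nz
  lvs <- seq_len(Ng); ds <- seq_len(Nd)
  ri <- rowSums(cnt); rj <- colSums(cnt)
  mu_i <- sum(lvs * rowSums(p)); mu_d <- sum(ds * colSums(p))
  c(SmallDependenceEmphasis = sum(t(cnt) / ds^2) / Nz,
    LargeDependenceEmphasis = sum(t(cnt) * ds^2) / Nz,
    GrayLevelNonUniformity = sum(ri^2) / Nz,
    DependenceNonUniformity = sum(rj^2) / Nz,
    DependenceNonUniformityNormalized = sum(rj^2) / Nz^2,
    GrayLevelVariance = sum(p * (lvs - mu_i)^2),
    DependenceVariance = sum(t(p) * (ds - mu_d)^2),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(cnt / lvs^2) / Nz,
    HighGrayLevelEmphasis = sum(cnt * lvs^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(t(cnt / lvs^2) / ds^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(t(cnt * lvs^2) / ds^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(t(cnt / lvs^2) * ds^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(t(cnt * lvs^2) * ds^2) / Nz)
}

## ---- NGTDM ----------------------------------------------------------------

ngtdm_slice <- function(L, Ng) {
  inm <- L > 0L
  nsum <- matrix(0, nrow(L), ncol(L))
  ncnt <- matrix(0L, nrow(L), ncol(L))
  for (off in .N_OFFSETS) {
    B <- shift_matrix(L, -off[1], -off[2], fill = 0L)
    nsum <- nsum + B * (B > 0L)
    ncnt <- ncnt + (B > 0L)
  }
  valid <- inm & ncnt > 0L
  Nvp <- sum(valid)
  if (Nvp == 0)
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  lv <- L[valid]
  A <- nsum[valid] / ncnt[valid]
  n_i <- tabulate(lv, Ng)
  agg <- rowsum(abs(lv - A), lv)              # sorted by level
  s_full <- numeric(Ng)
  s_full[as.integer(rownames(agg))] <- agg[, 1]
  p_i <- n_i / Nvp
  pres <- which(p_i > 0)
  Ngp <- length(pres)
  lvp <- pres
  pp <- p_i[pres]; sp <- s_full[pres]
  coarse_den <- sum(pp * sp)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(pp, pp) * outer(lvp, lvp, `-`)^2) / (Ngp * (Ngp - 1))) *
      (sum(sp) / Nvp)
  } else 0
  busy_den <- sum(abs(outer(lvp * pp, lvp * pp, `-`)))
  busyness <- if (busy_den > 0) sum(pp * sp) / busy_den else 0
  dif <- abs(outer(lvp, lvp, `-`))
  complexity <- sum(dif * (outer(pp * sp, pp * sp, `+`)) /
                    outer(pp, pp, `+`)) / Nvp
  s_tot <- sum(sp)
  strength <- if (s_tot > 0)
    sum(outer(pp, pp, `+`) * outer(lvp, lvp, `-`)^2) / s_tot else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

## ---- stack driver ---------------------------------------------------------

#' Texture features of one family for a slice stack
#'
#' Discretizes the pooled in-mask intensities with equal-width bins, builds
#' the requested texture matrices per axial slice and returns the
#' slice-averaged feature vector.
#'
#' @param slices crop x crop x n array of intensities.
#' @param masks matching 0/1 array.
#' @param family one of "glcm", "glrlm", "glszm", "gldm", "ngtdm".
#' @param disc a [discretization_config()].
#' @return named numeric feature vector for the family.
#' @export
extract_texture_family <- function(slices, masks,
                                   family = c("glcm", "glrlm", "glszm",
                                              "gldm", "ngtdm"),
                                   disc = discretization_config()) {
  family <- match.arg(family)
  lv <- level_stack(slices, masks, disc$n_bins)
  fn <- switch(family, glcm = glcm_slice, glrlm = glrlm_slice,
               glszm = glszm_slice, gldm = gldm_slice, ngtdm = ngtdm_slice)
  nfeat <- switch(family, glcm = 24L, glrlm = 16L, glszm = 16L,
                  gldm = 14L, ngtdm = 5L)
  vals <- vapply(seq_len(dim(lv$levels)[3]),
                 function(k) fn(lv$levels[, , k], lv$Ng), numeric(nfeat))
  rowMeans(vals)
}

## pooled discretization -> per-slice level matrices (0 outside mask)
level_stack <- function(slices, masks, n_bins) {
  vals <- slices[masks > 0]
  stop_if_not(length(vals) > 0, "texture: empty mask")
  lvl <- discretize_values(vals, n_bins)
  Ng <- max(lvl)
  L <- array(0L, dim(slices))
  L[masks > 0] <- lvl
  list(levels = L, Ng = Ng)
}

texture_all_families <- function(slices, masks, disc) {
  lv <- level_stack(slices, masks, disc$n_bins)
  nsl <- dim(lv$levels)[3]
  per_slice <- vapply(seq_len(nsl), function(k) {
    L <- lv$levels[, , k]
    c(glcm_slice(L, lv$Ng), glrlm_slice(L, lv$Ng), glszm_slice(L, lv$Ng),
      gldm_slice(L, lv$Ng), ngtdm_slice(L, lv$Ng))
  }, numeric(75))
  m <- rowMeans(per_slice)
  names(m) <- c(paste0("glcm_", .GLCM), paste0("glrlm_", .GLRLM),
                paste0("glszm_", .GLSZM), paste0("gldm_", .GLDM),
                paste0("ngtdm_", .NGTDM))
  m
}
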