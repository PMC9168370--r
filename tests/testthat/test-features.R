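test_that("feature catalogue has 851 unique names with the documented family sizes", {
  cat_ <- feature_catalogue()
  expect_equal(nrow(cat_), 851)
  expect_equal(anyDuplicated(cat_$name), 0)
  counts <- table(cat_$family[cat_$image == "original"])
  expect_equal(unname(counts[c("shape", "firstorder", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm")]),
               c(14, 18, 24, 16, 16, 14, 5), ignore_attr = TRUE)
  expect_equal(sum(cat_$image != "original"), 8 * 93)
})

test_that("first-order features match closed forms on tiny inputs", {
  f <- extract_first_order(rep(5, 12), voxel_volume = 2)
  expect_equal(unname(f["Mean"]), 5)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Energy"]), 12 * 25)
  expect_equal(unname(f["TotalEnergy"]), 2 * 12 * 25)
  expect_equal(unname(f["Uniformity"]), 1)
  f2 <- extract_first_order(c(1, 2, 3))
  expect_equal(unname(f2["Mean"]), 2)
  expect_equal(unname(f2["RootMeanSquared"]), sqrt(14 / 3))
  # symmetric sample has (near) zero skewness
  set.seed(1)
  v <- stats::rnorm(5000)
  f3 <- extract_first_order(c(v, -v))
  expect_lt(abs(f3["Skewness"]), 1e-10)
})

test_that("GLCM counts and features match hand enumeration", {
  # 2x2 checkerboard of levels {1,2}: horizontal pairs are all (1,2)/(2,1)
  L <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  P <- radstab:::glcm_counts(L, 2, c(0L, 1L))
  expect_equal(P / sum(P), matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- radstab:::glcm_features(P)
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["JointEntropy"]), 1)   # two cells at 0.5
  # random toy images against the pair-enumeration oracle
  set.seed(42)
  for (rep in 1:5) {
    L <- matrix(sample(0:4, 36, replace = TRUE), 6, 6)
    for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
      expect_equal(radstab:::glcm_counts(L, 4, off),
                   oracle_glcm_counts(L, 4, off))
    }
  }
})

test_that("GLRLM runs match hand enumeration and the textbook example", {
  # row [1,1,2,2]: two runs of length 2
  L <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  cnt <- oracle_glrlm_counts(L, 2, c(0L, 1L))
  expect_equal(cnt, matrix(c(0, 0, 1, 1), 2, 2))
  set.seed(7)
  for (rep in 1:5) {
    L <- matrix(sample(0:3, 30, replace = TRUE), 5, 6)
    st <- manual_stack(array(L, c(5, 6, 1)), array((L > 0) * 1L, c(5, 6, 1)))
    # compare family features computed from oracle counts vs the package
    got <- extract_texture_family(st$slices, st$masks, "glrlm",
                                  discretization_config(4))
    lv <- radstab:::level_stack(st$slices, st$masks, 4)
    want <- rowMeans(vapply(
      list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)),
      function(off) radstab:::glrlm_features(
        oracle_glrlm_counts(lv$levels[, , 1], lv$Ng, off), lv$Ng,
        sum(lv$levels > 0)),
      numeric(16)))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("GLSZM zones match recursive flood fill", {
  set.seed(11)
  for (rep in 1:5) {
    L <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    z_got <- radstab:::zones_of(L)
    z_want <- oracle_glszm_zones(L)
    # compare as multisets of (level, size)
    key <- function(z) sort(paste(z[, 1], z[, 2]))
    expect_equal(key(z_got), key(z_want))
  }
})

test_that("GLDM and NGTDM match loop oracles on toy images", {
  set.seed(13)
  for (rep in 1:5) {
    L <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    if (all(L == 0)) next
    st <- manual_stack(array(L, c(6, 6, 1)), array((L > 0) * 1L, c(6, 6, 1)))
    lv <- radstab:::level_stack(st$slices, st$masks, 4)
    Lq <- lv$levels[, , 1]
    # GLDM: dependence histogram identical
    o <- oracle_gldm_counts(Lq, lv$Ng)
    got <- extract_texture_family(st$slices, st$masks, "gldm",
                                  discretization_config(4))
    Nz <- sum(o)
    expect_equal(unname(got["SmallDependenceEmphasis"]),
                 sum(t(o) / seq_len(ncol(o))^2) / Nz)
    expect_equal(unname(got["LargeDependenceEmphasis"]),
                 sum(t(o) * seq_len(ncol(o))^2) / Nz)
    expect_equal(unname(got["GrayLevelNonUniformity"]),
                 sum(rowSums(o)^2) / Nz)
    # NGTDM: coarseness from the oracle n_i/s_i
    on <- oracle_ngtdm(Lq, lv$Ng)
    p_i <- on$n / on$Nvp
    cd <- sum(p_i * on$s)
    gotn <- extract_texture_family(st$slices, st$masks, "ngtdm",
                                   discretization_config(4))
    expect_equal(unname(gotn["Coarseness"]),
                 if (cd > 0) 1 / cd else 1e6)
  }
})

test_that("constant ROI yields degenerate texture conventions", {
  sl <- array(7, c(8, 8, 1))
  mk <- array(1L, c(8, 8, 1))
  g <- extract_texture_family(sl, mk, "glcm")
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["Correlation"]), 1)
  expect_equal(unname(g["MCC"]), 1)
})

test_that("texture features are invariant to additive intensity shift", {
  st <- small_stack(seed = 5)
  f1 <- extract_texture_family(st$slices, st$masks, "glcm")
  f2 <- extract_texture_family(st$slices + 40, st$masks, "glcm")
  expect_equal(f1, f2)
})

test_that("90-degree rotation leaves direction-averaged GLCM unchanged on a square ROI", {
  set.seed(3)
  L <- matrix(sample(1:4, 49, replace = TRUE), 7, 7)
  mk <- array(1L, c(7, 7, 1))
  st1 <- manual_stack(array(L, c(7, 7, 1)), mk)
  Lr <- t(L)[, rev(seq_len(7))]   # 90-degree rotation
  st2 <- manual_stack(array(Lr, c(7, 7, 1)), mk)
  f1 <- extract_texture_family(st1$slices, st1$masks, "glcm",
                               discretization_config(4))
  f2 <- extract_texture_family(st2$slices, st2$masks, "glcm",
                               discretization_config(4))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("doubling a constant ROI doubles energy and volume, keeps mean and entropy", {
  v1 <- rep(3, 50); v2 <- rep(3, 100)
  f1 <- extract_first_order(v1); f2 <- extract_first_order(v2)
  expect_equal(unname(f2["Energy"]), 2 * unname(f1["Energy"]))
  expect_equal(unname(f2["Mean"]), unname(f1["Mean"]))
  expect_equal(unname(f2["Entropy"]), unname(f1["Entropy"]))
  m1 <- array(0L, c(6, 6, 3)); m1[2:4, 2:4, 1:2] <- 1L
  m2 <- array(0L, c(6, 6, 3)); m2[2:4, 2:4, 1:2] <- 1L; m2[2:4, 2:4, 3] <- 1L
  s1 <- extract_shape(m1); s2 <- extract_shape(m1)
  expect_equal(unname(extract_shape(m2)["VoxelVolume"]),
               1.5 * unname(s1["VoxelVolume"]))
})

test_that("shape features: sphere is near-spherical, ellipse elongation is the axis ratio", {
  d <- c(24, 24, 24); ctr <- 12.5
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  m <- array(as.integer((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 64),
             d)
  sf <- extract_shape(m)
  expect_gt(sf["Sphericity"], 0.9)
  expect_lt(sf["Sphericity"], 1.1)
  expect_equal(unname(sf["VoxelVolume"]), sum(m))
  # 3:1 in-plane ellipse replicated over 3 slices: elongation ~ 1/3
  gg <- expand.grid(x = 1:61, y = 1:21)
  sl <- matrix(as.integer(((gg$x - 31) / 30)^2 + ((gg$y - 11) / 10)^2 <= 1),
               61, 21)
  m3 <- array(0L, c(61, 21, 3)); for (k in 1:3) m3[, , k] <- sl
  s3 <- extract_shape(m3)
  # PCA-of-coordinates oracle
  idx <- which(m3 > 0, arr.ind = TRUE)
  ev <- sort(eigen(stats::cov(idx) * (nrow(idx) - 1) / nrow(idx),
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(s3["Elongation"]), sqrt(ev[2] / ev[1]))
  expect_equal(unname(s3["Elongation"]), 1 / 3, tolerance = 0.05)
})

test_that("cuboid voxel volume is exact", {
  m <- array(0L, c(10, 9, 8)); m[2:5, 2:4, 2:3] <- 1L
  expect_equal(unname(extract_shape(m, c(1, 1, 1))["VoxelVolume"]), 4 * 3 * 2)
  expect_equal(unname(extract_shape(m, c(2, 1, 1))["VoxelVolume"]), 48)
})

test_that("extract_all returns 851 finite catalogue-ordered features, deterministically", {
  st <- small_stack(seed = 9)
  fv <- extract_all(st)
  expect_length(fv, 851)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_catalogue()$name)
  expect_identical(fv, extract_all(st))
})

test_that("wavelet decomposition: 8 bands, zero high-pass for constant input", {
  x <- array(5, c(8, 8, 3))
  b <- swt3(x, "haar")
  expect_named(b, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (nm in setdiff(names(b), "LLL")) expect_equal(max(abs(b[[nm]])), 0)
  expect_equal(b$LLL, array(5 * 2^(3 / 2), c(8, 8, 3)))
  # LLL of a smooth image tracks a Gaussian-smoothed image
  ph <- generate_phantom(phantom_spec(image_shape = c(36, 36, 28),
                                      tumor_diameter_mm = 18, noise_sd = 0,
                                      texture_amp = 30, texture_corr_len = 4,
                                      seed = 2))
  st <- preprocess_roi(ph$volume, ph$mask, preprocess_config(crop_size = 32))
  bl <- swt3(st$slices, "coif1")$LLL
  sm <- radstab:::gauss_smooth(st$slices, 1)
  expect_gt(stats::cor(bl[st$masks > 0], sm[st$masks > 0]), 0.9)
})

test_that("feature bank is deterministic, sized, and zero on zero input", {
  st <- small_stack(seed = 4)
  b1 <- feature_bank(st, D = 128, seed = 11, prefix = "VGG16")
  b2 <- feature_bank(st, D = 128, seed = 11, prefix = "VGG16")
  expect_identical(b1, b2)
  expect_length(b1, 128)
  z <- manual_stack(array(0, c(16, 16, 3)), array(1L, c(16, 16, 3)))
  expect_equal(unname(feature_bank(z, D = 16, seed = 1)), rep(0, 16))
})
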