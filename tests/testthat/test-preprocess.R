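test_that("resegmentation drops exactly the out-of-range voxels", {
  ph <- small_phantom(seed = 1, noise_sd = 0, texture_amp = 0)
  m1 <- resegment(ph$volume, ph$mask)
  expect_equal(m1, ph$mask)               # everything in (-1000, 400)
  vol <- ph$volume
  idx <- which(ph$mask > 0)
  drop <- idx[seq_len(round(0.1 * length(idx)))]
  vol[drop] <- -1200
  m2 <- resegment(vol, ph$mask)
  expect_equal(sum(m2), sum(ph$mask) - length(drop))
  vol[idx] <- 500
  expect_error(resegment(vol, ph$mask), "eliminated")
})

test_that("adaptive windowing is idempotent and centred on the tumour mean", {
  set.seed(2)
  vol <- array(stats::rnorm(40^3, 60, 10), c(40, 40, 40))
  mask <- array(0L, c(40, 40, 40)); mask[10:30, 10:30, 10:30] <- 1L
  w <- adaptive_window(vol, mask)
  vals <- vol[mask > 0]
  expect_equal(unname(w$window["center"]), mean(vals))
  expect_equal(unname(w$window["width"]),
               2 * (quantile(vals, .99, names = FALSE) -
                    quantile(vals, .01, names = FALSE)))
  w2 <- adaptive_window(w$volume, mask)
  expect_equal(w2$volume, adaptive_window(w2$volume, mask)$volume)
  # degenerate constant tumour: width floored at 1, output constant inside
  cvol <- array(7, c(10, 10, 10))
  cw <- adaptive_window(cvol, mask[1:10, 1:10, 1:10, drop = FALSE])
  expect_equal(unname(cw$window["width"]), 1)
  expect_equal(unique(as.vector(cw$volume)), 7)
})

test_that("normalization + equalization: 0-255 range, uniform histogram on a ramp", {
  expect_equal(unique(as.vector(normalize_and_equalize(array(3, c(4, 4))))), 0)
  set.seed(3)
  img <- matrix(stats::rnorm(400), 20, 20)
  out <- normalize_and_equalize(img)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # exact ramp: every gray level equally often -> equalization is identity
  ramp <- matrix(rep(0:255, each = 4), 32, 32)
  eq <- normalize_and_equalize(ramp)
  h <- tabulate(as.vector(eq) + 1, 256)
  expect_lte(diff(range(h)), 1)
})

test_that("denoising: identity at sigma 0, conserves constants, halves white-noise SD", {
  img <- matrix(stats::rnorm(900), 30, 30)
  expect_identical(denoise(img, 0), img)
  expect_equal(denoise(matrix(4, 20, 20), 2), matrix(4, 20, 20))
  set.seed(4)
  noise <- matrix(stats::rnorm(200 * 200, sd = 10), 200, 200)
  expect_lt(stats::sd(denoise(noise, 2)), 5)
})

test_that("informative-slice selection maximizes windowed area with stated tie-breaks", {
  mask <- array(0L, c(10, 10, 5))
  areas <- c(1, 5, 9, 5, 1)
  for (k in 1:5) mask[seq_len(areas[k]), 1, k] <- 1L
  expect_equal(select_informative_slices(mask, 3), 2:4)
  # spherical mask: window centred on the equator
  ph <- small_phantom(seed = 5, texture_amp = 0, noise_sd = 0)
  zi <- select_informative_slices(ph$mask, 3)
  equator <- which.max(apply(ph$mask, 3, sum))
  expect_true(equator %in% zi)
  # single-slice mask: padded window around it
  m1 <- array(0L, c(8, 8, 7)); m1[3:5, 3:5, 4] <- 1L
  expect_equal(select_informative_slices(m1, 3), 3:5)
  expect_error(select_informative_slices(array(0L, c(4, 4, 4)), 3), "empty")
})

test_that("cropping is exact-size, zero-padded and translation invariant", {
  sl <- matrix(stats::rnorm(60 * 60), 60, 60)
  mk <- matrix(0L, 60, 60); mk[10:20, 12:22] <- 1L
  cr <- crop_to_bbox(sl, mk, 24)
  expect_equal(dim(cr$tile), c(24, 24))
  expect_equal(sum(cr$mask_tile), sum(mk))
  # translate tumour and image content by (10, 10): identical tile
  sl2 <- matrix(0, 60, 60); mk2 <- matrix(0L, 60, 60)
  sl2[11:60, 11:60] <- sl[1:50, 1:50]
  mk2[11:60, 11:60] <- mk[1:50, 1:50]
  cr2 <- crop_to_bbox(sl2, mk2, 24)
  expect_equal(cr2$tile, cr$tile)
  # corner tumour: out-of-image area padded with zeros
  mk3 <- matrix(0L, 60, 60); mk3[1:4, 1:4] <- 1L
  cr3 <- crop_to_bbox(sl, mk3, 24)
  expect_equal(dim(cr3$tile), c(24, 24))
  # tile extends past the image corner; that margin is zero-padded
  expect_true(all(cr3$tile[1:10, 1:10] == 0))
  expect_gt(sum(cr3$mask_tile), 0)
})

test_that("the full chain is deterministic with in-range outputs and binary masks", {
  ph <- small_phantom(seed = 6)
  st1 <- preprocess_roi(ph$volume, ph$mask, preprocess_config(crop_size = 48))
  st2 <- preprocess_roi(ph$volume, ph$mask, preprocess_config(crop_size = 48))
  expect_identical(st1, st2)
  expect_true(all(st1$slices >= 0 & st1$slices <= 255))
  expect_true(all(st1$masks %in% c(0L, 1L)))
  expect_equal(dim(st1$slices), c(48, 48, 3))
  expect_equal(diff(st1$slice_indices), c(1, 1))
  expect_true(all(apply(st1$masks, 3, sum) > 0))
})
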