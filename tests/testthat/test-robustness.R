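clip_unit <- function(x) pmin(pmax(x, -1), 1)

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2)
  expect_equal(icc_agreement(m), oracle_icc(m), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:12, 1); k <- sample(2:5, 1)
    m <- matrix(stats::rnorm(n * k), n, k)
    expect_lt(abs(icc_agreement(m) - clip_unit(oracle_icc(m))), 1e-10)
  }
})

test_that("ICC conventions: identical columns give 1, i.i.d. noise gives ~0", {
  m <- matrix(rep(c(1, 5, 9, 2), 3), 4, 3)
  expect_equal(icc_agreement(m), 1)
  expect_equal(icc_agreement(matrix(3, 5, 4)), 1)   # zero variance convention
  set.seed(2)
  m2 <- matrix(stats::rnorm(50 * 3), 50, 3)
  expect_lt(abs(icc_agreement(m2)), 0.3)
})

test_that("ICC is invariant to a global constant but not to a one-column offset", {
  set.seed(4)
  base <- matrix(rep(stats::rnorm(8), 3), 8, 3)   # strong subject effect
  m <- base + matrix(stats::rnorm(24, sd = 0.1), 8, 3)
  expect_equal(icc_agreement(m + 100), icc_agreement(m), tolerance = 1e-12)
  shifted <- m; shifted[, 2] <- shifted[, 2] + 5
  expect_lt(icc_agreement(shifted), icc_agreement(m))
})

test_that("panels are balanced with the documented rater counts", {
  set.seed(6)
  mk_tab <- function() matrix(stats::rnorm(5 * 4), 5, 4,
                              dimnames = list(paste0("s", 1:5),
                                              paste0("f", 1:4)))
  tabs <- list(original = mk_tab(),
               S = list(`1` = mk_tab(), `2` = mk_tab(), `3` = mk_tab(),
                        `5` = mk_tab()),
               R = list(`-30` = mk_tab(), `-15` = mk_tab(), `15` = mk_tab(),
                        `30` = mk_tab()),
               Seg = list(`0.8` = mk_tab(), `1.2` = mk_tab()))
  panels <- build_panels(tabs)
  expect_equal(dim(panels$S)[2], 5)
  expect_equal(dim(panels$R)[2], 5)
  expect_equal(dim(panels$Seg)[2], 3)
  # dropping a subject in one replicate is rejected
  bad <- tabs; bad$S$`2` <- bad$S$`2`[-1, , drop = FALSE]
  expect_error(build_panels(bad), "unbalanced")
  # consistent subject permutation leaves all ICCs unchanged
  perm <- c(3, 1, 5, 2, 4)
  permuted <- list(original = tabs$original[perm, ],
                   S = lapply(tabs$S, function(t) t[perm, ]),
                   R = lapply(tabs$R, function(t) t[perm, ]),
                   Seg = lapply(tabs$Seg, function(t) t[perm, ]))
  r1 <- robustness_report(build_panels(tabs))
  r2 <- robustness_report(build_panels(permuted))
  expect_equal(r1$icc[, -1], r2$icc[, -1])
})

test_that("the all-kinds pass rule and percentage arithmetic are honoured", {
  icc_df <- data.frame(feature = c("a", "b", "c"),
                       ICC_S = c(0.9, 0.9, 0.99),
                       ICC_R = c(0.9, 0.84, 0.99),
                       ICC_Seg = c(0.9, 0.99, 0.80))
  rep_ <- structure(list(icc = icc_df), class = "robustness_report")
  expect_equal(robust_filter(rep_, 0.85), "a")
  expect_equal(robust_percent(718, 851), 84.37)
  expect_equal(robust_percent(199, 512), 38.87)
  # raising the cutoff never enlarges the passing set
  set.seed(8)
  icc_df2 <- data.frame(feature = paste0("f", 1:50),
                        ICC_S = runif(50), ICC_R = runif(50),
                        ICC_Seg = runif(50))
  rep2 <- structure(list(icc = icc_df2), class = "robustness_report")
  sizes <- vapply(c(0.1, 0.3, 0.5), function(ct)
    length(tryCatch(robust_filter(rep2, ct), error = function(e) character(0))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  all_fail <- structure(list(icc = data.frame(feature = "a", ICC_S = 0.1,
                                              ICC_R = 0.1, ICC_Seg = 0.1)),
                        class = "robustness_report")
  expect_error(robust_filter(all_fail, 0.85), "cutoff")
})

test_that("smoothed image content is more rotation-robust than high-pass content", {
  co <- tiny_cohort(n = 6, seed = 13)
  cfg <- preprocess_config(crop_size = 32)
  spec <- perturbation_spec(S = 1, R = c(-15, 15), Seg = 1)
  tabs <- replicate_feature_tables(co, cfg, spec)
  panels <- build_panels(list(original = tabs$original, R = tabs$R))
  icc_r <- vapply(seq_len(dim(panels$R)[3]),
                  function(f) icc_agreement(panels$R[, , f]), numeric(1))
  names(icc_r) <- dimnames(panels$R)[[3]]
  low <- icc_r[grep("^wavelet.LLL_firstorder", names(icc_r))]
  high <- icc_r[grep("^wavelet.HH[LH]_firstorder", names(icc_r))]
  expect_lt(stats::wilcox.test(low, high, alternative = "greater",
                               exact = FALSE)$p.value, 0.2)
  expect_gt(stats::median(low), stats::median(high))
})
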