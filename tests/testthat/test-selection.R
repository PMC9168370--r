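test_that("MAD filter drops exactly the zero-spread columns", {
  x <- cbind(const = rep(3, 4), spiky = c(1, 1, 1, 9), keep = 1:4)
  out <- mad_filter(x)
  expect_equal(colnames(out), "keep")
  expect_error(mad_filter(x[, 1, drop = FALSE]), "zero MAD")
})

test_that("univariate screen keeps ceil(fraction * p) t-ranked features", {
  pm <- planted_matrix(n = 30, p = 20, informative = 1, delta = 4)
  out <- univariate_top(pm$x, pm$y, 0.20)
  expect_equal(ncol(out), 4)                   # ceil(0.2 * 20)
  expect_true("f1" %in% colnames(out))
  expect_equal(ceiling(0.20 * 718), 144)
  # ranking matches the direct Welch formula on a small table
  set.seed(3)
  x <- matrix(stats::rnorm(10 * 20), 10, 20,
              dimnames = list(NULL, paste0("g", 1:20)))
  y <- rep(c(0, 1), 5)
  tvals <- apply(x, 2, function(v)
    abs(stats::t.test(v[y == 1], v[y == 0])$statistic))
  got <- radstab:::welch_t(x, y)
  expect_equal(unname(got), unname(tvals), tolerance = 1e-10)
})

test_that("score selectors rank a perfect separator first", {
  pm <- planted_matrix(n = 40, p = 15, informative = 0)
  x <- pm$x; y <- pm$y
  x[, 5] <- y                                   # identical to the label
  for (s in c("FSCR", "TSCR", "GINI", "CHSQ", "RELF")) {
    r <- score_filter(x, y, selector_spec(s))
    expect_equal(r$feature[1], "f5", info = s)
  }
  # GINI score of the perfect separator equals the parent impurity
  g <- radstab:::gini_score(x, y)
  p1 <- mean(y == 1)
  expect_equal(unname(g[5]), 1 - p1^2 - (1 - p1)^2)
})

test_that("CHSQ is calibrated against its null for label-independent features", {
  set.seed(10)
  x <- matrix(stats::rnorm(200 * 30), 200, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  y <- rep(c(0, 1), 100)
  s <- radstab:::chisq_score(x, y, 10)
  expect_lt(max(s), stats::qchisq(0.999, df = 9) * 1.5)
  expect_gt(mean(s), 4)   # E[chi2_9] = 9, loose lower check
})

test_that("ReliefF ranks interacting XOR features above noise", {
  set.seed(5)
  n <- 120
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(a, b))
  x <- cbind(xa = a + rnorm(n, sd = 0.05), xb = b + rnorm(n, sd = 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n))
  r <- score_filter(x, y, selector_spec("RELF"))
  expect_true(all(c("xa", "xb") %in% r$feature[1:2]))
})

test_that("plug-in MI matches closed forms and the table oracle", {
  # independent by construction: product table
  x <- rep(1:2, each = 50); y <- rep(rep(0:1, each = 25), 2)
  expect_equal(mutual_info(as.integer(x), y), 0, tolerance = 1e-12)
  # identical balanced binary variables: ln 2
  z <- rep(0:1, 50)
  expect_equal(mutual_info(as.integer(z), z), log(2), tolerance = 1e-12)
  # printed 2x2 table
  tab <- matrix(c(30, 10, 10, 30), 2, 2)
  xv <- rep(c(1L, 1L, 2L, 2L), times = c(30, 10, 10, 30))
  yv <- rep(c(0L, 1L, 0L, 1L), times = c(30, 10, 10, 30))
  expect_equal(mutual_info(xv, yv), oracle_mi_table(tab), tolerance = 1e-12)
})

test_that("every MI selector's first pick maximizes I(f;Y); duplicates are penalized", {
  pm <- planted_matrix(n = 60, p = 10, informative = 1, delta = 3)
  x <- pm$x; y <- pm$y
  x[, 10] <- x[, 1]                            # exact duplicate of the best
  colnames(x)[10] <- "dup"
  mi <- vapply(seq_len(ncol(x)), function(j)
    mutual_info(x[, j], y), numeric(1))
  top <- colnames(x)[which.max(mi)]
  for (s in c("MIM", "MIFS", "MRMR", "JMI", "CIFE", "CMIM", "ICAP", "DISR")) {
    r <- greedy_mi_select(x, y, selector_spec(s, K = 4))
    expect_equal(r$feature[1], top, info = s)
  }
  for (s in c("MIFS", "MRMR", "CIFE", "ICAP")) {
    r <- greedy_mi_select(x, y, selector_spec(s, K = 4))
    # the duplicate of an already selected feature is never added next
    expect_false(r$feature[2] == "dup", info = s)
  }
})

test_that("greedy MRMR equals per-step exhaustive criterion evaluation", {
  pm <- planted_matrix(n = 60, p = 6, informative = 2, delta = 1.5, seed = 9)
  x <- pm$x; y <- pm$y
  got <- greedy_mi_select(x, y, selector_spec("MRMR", K = 4))$feature
  # oracle: exhaustive argmax of I(f;Y) - mean_S I(f;s) at every step
  sel <- integer(0)
  for (step in 1:4) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    crit <- vapply(cand, function(j) {
      rel <- mutual_info(x[, j], y)
      if (!length(sel)) return(rel)
      red <- mean(vapply(sel, function(s)
        mutual_info(x[, j], radstab:::ef_bins(x[, s], 10)), numeric(1)))
      rel - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(crit)])
  }
  expect_equal(got, colnames(x)[sel])
})

test_that("selector rankings are invariant to feature column order", {
  pm <- planted_matrix(n = 50, p = 12, informative = 2, delta = 2, seed = 4)
  perm <- sample(ncol(pm$x))
  for (s in c("FSCR", "MRMR")) {
    r1 <- rank_features(pm$x, pm$y, selector_spec(s, K = 5))
    r2 <- rank_features(pm$x[, perm], pm$y, selector_spec(s, K = 5))
    expect_equal(r1$feature, r2$feature, info = s)
  }
  # CMIM can tie exactly on binned data; ties break by column order, so
  # order-invariance holds at the set level
  r1 <- rank_features(pm$x, pm$y, selector_spec("CMIM", K = 5))
  r2 <- rank_features(pm$x[, perm], pm$y, selector_spec("CMIM", K = 5))
  expect_setequal(r1$feature, r2$feature)
})

test_that("recursive feature addition keeps a perfect predictor and rejects copies", {
  set.seed(6)
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  x <- cbind(good = y + rnorm(n, sd = 0.05),
             copy = y + rnorm(n, sd = 0.05),
             noise = rnorm(n))
  r <- recursive_feature_addition(c("good", "copy", "noise"), x, y,
                                  classifier = "LogisticRegression",
                                  k = 5, seed = 2)
  expect_equal(r$features[1], "good")
  expect_false("copy" %in% r$features)
  # deterministic given (data, ranking, seed)
  r2 <- recursive_feature_addition(c("good", "copy", "noise"), x, y,
                                   classifier = "LogisticRegression",
                                   k = 5, seed = 2)
  expect_identical(r, r2)
})

test_that("all-noise RFA stays small with chance-level AUC", {
  set.seed(7)
  aucs <- vapply(1:10, function(i) {
    n <- 40
    y <- rep(c(0L, 1L), n / 2)
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("n", 1:8)))
    r <- recursive_feature_addition(colnames(x), x, y,
                                    classifier = "LogisticRegression",
                                    k = 5, seed = i)
    tail(c(0.5, r$trace), 1)
  }, numeric(1))
  expect_lt(mean(aucs), 0.75)
})

test_that("the cascade output is nested: selected within univariate within MAD", {
  pm <- planted_matrix(n = 50, p = 40, informative = 3, delta = 1.5, seed = 8)
  x <- cbind(pm$x, dead = rep(1, 50))
  out <- select_features(x, pm$y, selector_spec("MRMR", K = 5), rfa = FALSE)
  x1 <- mad_filter(x)
  x2 <- univariate_top(x1, pm$y, 0.20)
  expect_true(all(out$features %in% colnames(x2)))
  expect_true(all(colnames(x2) %in% colnames(x1)))
  expect_false("dead" %in% colnames(x1))
})

test_that("planted-feature recovery: MIM, MRMR and JMI find most planted features", {
  hits <- vapply(1:25, function(i) {
    pm <- planted_matrix(n = 100, p = 205, informative = 5, delta = 1.2,
                         seed = 100 + i)
    found <- vapply(c("MIM", "MRMR", "JMI"), function(s) {
      r <- greedy_mi_select(pm$x, pm$y, selector_spec(s, K = 10))
      sum(paste0("f", 1:5) %in% r$feature)
    }, numeric(1))
    found >= 3
  }, logical(3))
  expect_gte(mean(hits["MIM", ]), 0.8)
  expect_gte(mean(hits["MRMR", ]), 0.8)
  expect_gte(mean(hits["JMI", ]), 0.8)
})
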