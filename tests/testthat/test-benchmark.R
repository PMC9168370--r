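test_that("stratified folds partition subjects and keep both classes in training", {
  y <- rep(c(1L, 0L), c(28, 12))
  folds <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unlist(folds)), seq_along(y))
  for (f in folds) expect_equal(length(unique(y[-f])), 2)
  expect_identical(folds, stratified_folds(y, 10, seed = 3))
})

test_that("SMOTE emits convex combinations of minority neighbours", {
  set.seed(2)
  xm <- matrix(stats::rnorm(5 * 3), 5, 3)
  syn <- smote(xm, n_new = 5, k = 2, seed = 4)
  expect_equal(nrow(syn), 5)
  # each synthetic row must lie on a segment between two real rows:
  # check coordinate-wise betweenness against the best matching pair
  for (i in seq_len(nrow(syn))) {
    ok <- FALSE
    for (a in 1:5) for (b in 1:5) {
      if (a == b) next
      lo <- pmin(xm[a, ], xm[b, ]); hi <- pmax(xm[a, ], xm[b, ])
      if (all(syn[i, ] >= lo - 1e-12 & syn[i, ] <= hi + 1e-12)) ok <- TRUE
    }
    expect_true(ok)
  }
  # identical minority points produce identical synthetics
  xm2 <- rbind(c(1, 2), c(1, 2))
  expect_warning(syn2 <- smote(xm2, 3, k = 5, seed = 1), "reducing k")
  expect_true(all(syn2[, 1] == 1 & syn2[, 2] == 2))
  expect_error(smote(xm2[1, , drop = FALSE], 1), "at least 2")
})

test_that("AUC rank formulation equals exhaustive pair counting", {
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_rank(s, y), oracle_auc(s, y))
  }
})

test_that("RSD arithmetic: worked example, zero for constants, scale invariance", {
  expect_equal(rsd(c(0.8, 0.9, 1.0)), 100 * 0.1 / 0.9)
  expect_equal(round(rsd(c(0.8, 0.9, 1.0)), 2), 11.11)
  expect_equal(rsd(c(0.7, 0.7, 0.7)), 0)
  a <- c(0.6, 0.8, 0.9)
  expect_equal(rsd(a), rsd(0.5 * a))
  expect_error(rsd(c(-1, 1)), "positive")
})

test_that("a fully separable feature yields AUC 1 with zero RSD", {
  set.seed(1)
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(sep = ifelse(y == 1, 2, -2) + stats::rnorm(n, sd = 0.05),
             matrix(stats::rnorm(n * 5), n, 5))
  colnames(x) <- c("sep", paste0("n", 1:5))
  rec <- cv_evaluate(x, y, model_spec("Radiomics", "MIM", "NearestNeighbors"),
                     k = 5, seed = 2)
  expect_equal(rec$mean_auc, 1)
  expect_equal(rec$rsd, 0)
  expect_false(rec$failed)
})

test_that("permuted labels give chance-level benchmark AUC", {
  set.seed(11)
  aucs <- vapply(1:20, function(i) {
    n <- 100
    x <- matrix(stats::rnorm(n * 12), n, 12,
                dimnames = list(NULL, paste0("f", 1:12)))
    y <- sample(rep(c(1L, 0L), each = n / 2))   # label independent of x
    rec <- cv_evaluate(x, y, model_spec("Radiomics", "MIM",
                                        "LogisticRegression"),
                       k = 10, seed = i)
    rec$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("grid record counts follow the product rule with canonical names", {
  pm <- planted_matrix(n = 30, p = 12, informative = 1, delta = 2)
  sources <- list(Radiomics = pm$x, VGG16 = pm$x + 1)
  b <- run_grid(sources, pm$y, selectors = c("MIM", "GINI", "TSCR"),
                classifiers = c("NearestNeighbors", "LogisticRegression"),
                k = 5, seed = 2)
  expect_equal(nrow(b), 2 * 3 * 2)
  expect_true("Radiomics_GINI_NearestNeighbors" %in% b$name)
  expect_true(all(b$rsd >= 0 | is.na(b$rsd)))
  m <- benchmark_matrix(b, "Radiomics")
  expect_equal(dim(m), c(3, 2))
  # removing one classifier obeys the product rule
  b2 <- run_grid(sources, pm$y, selectors = c("MIM", "GINI", "TSCR"),
                 classifiers = "NearestNeighbors", k = 5, seed = 2)
  expect_equal(nrow(b2), 2 * 3 * 1)
})

test_that("best model maximizes AUC with RSD as tie-breaker", {
  df <- data.frame(name = c("a", "b", "c"),
                   extractor = "E", selector = c("S1", "S2", "S3"),
                   classifier = "C",
                   mean_auc = c(0.94, 0.94, 0.90),
                   rsd = c(0.86, 0.26, 0.10),
                   accuracy = 0.9, sensitivity = 0.9, specificity = 0.9,
                   precision = 0.9, f1 = 0.9, failed = FALSE)
  recs <- lapply(df$name, function(nm) list(name = nm))
  names(recs) <- df$name
  attr(df, "records") <- recs
  class(df) <- c("benchmark_table", "data.frame")
  expect_equal(best_model(df)$name, "b")
})

test_that("no leakage: mutating test-fold rows never changes train-fold selections", {
  pm <- planted_matrix(n = 40, p = 20, informative = 2, delta = 2, seed = 3)
  spec <- model_spec("Radiomics", "MRMR", "NearestNeighbors")
  r1 <- cv_evaluate(pm$x, pm$y, spec, k = 5, seed = 7)
  x2 <- pm$x
  folds <- stratified_folds(pm$y, 5, seed = 7)
  # replace fold 1's test rows with pure noise
  set.seed(99)
  x2[folds[[1]], ] <- matrix(stats::rnorm(length(folds[[1]]) * 20),
                             ncol = 20)
  r2 <- cv_evaluate(x2, pm$y, spec, k = 5, seed = 7)
  expect_identical(r1$selected_features[[1]], r2$selected_features[[1]])
})

test_that("SMOTE only ever interpolates training rows", {
  # train rows sit in [0, 1]^p, test rows far away at 100: any synthetic
  # point influenced by a test row would leave the training bounding box
  set.seed(8)
  x <- matrix(stats::runif(30 * 4), 30, 4)
  y <- rep(c(1L, 1L, 0L), 10)
  te <- which(y == 0)[1:3]
  x[te, ] <- 100
  tr <- setdiff(seq_len(30), te)
  bal <- radstab:::smote_balance(x[tr, ], y[tr], seed = 1)
  syn <- bal$x[-seq_along(tr), , drop = FALSE]
  expect_true(all(syn <= 1 + 1e-9))
})

test_that("response-code labelling reproduces the disease-control rate", {
  codes <- rep(c("CR", "PR", "SD", "PD"), times = c(1, 54, 17, 31))
  out <- label_outcomes(codes)
  expect_equal(sum(out$labels), 72)
  expect_equal(out$dcr, 69.9)
  expect_equal(label_outcomes(rep("PD", 5))$dcr, 0)
  expect_equal(label_outcomes(rep("CR", 5))$dcr, 100)
  expect_error(label_outcomes(c("CR", "XX")), "unknown")
})

test_that("every classifier returns usable probabilities on an easy problem", {
  set.seed(12)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(a = y * 3 + stats::rnorm(n), b = stats::rnorm(n),
             c = -2 * y + stats::rnorm(n))
  xte <- x[seq(1, n, 2), ]; yte <- y[seq(1, n, 2)]
  for (clf in CLASSIFIERS) {
    p <- suppressWarnings(
      fit_predict(clf, x, y, xte, seed = 5,
                  params = list(rf_ntree = 60L, xgb_nrounds = 20L,
                                mlp_size = 3L, ada_M = 10L)))
    expect_length(p, nrow(xte))
    expect_true(all(is.finite(p)), info = clf)
    expect_gt(auc_rank(p, yte), 0.8)
  }
})
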