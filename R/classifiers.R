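#' The twelve supported classifier names
#' @export
CLASSIFIERS <- c("NearestNeighbors", "SVC_linear", "SVC_RBF",
                 "GaussianProcess", "DecisionTree", "RandomForest", "MLP",
                 "AdaBoost", "NaiveBayes", "QDA", "XGBoost",
                 "LogisticRegression")

## k-nearest-neighbour class-1 probability (Euclidean, k = 5).
## Implemented directly so the probability of the positive class is exact
## (vote fraction), independent of which class wins.
knn_prob <- function(xtr, ytr, xte, k = 5L) {
  k <- min(k, nrow(xtr))
  pr <- numeric(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    d2 <- colSums((t(xtr) - xte[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    pr[i] <- mean(ytr[nn] == 1)
  }
  pr
}

## Discrete AdaBoost (SAMME) over depth-1 rpart stumps.
ada_fit <- function(x, y, M = 25L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- as.data.frame(x)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(M)) {
    fit <- rpart::rpart(factor(yy) ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != yy))
    err <- clip(err, 1e-10, 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas)
}

ada_prob <- function(model, xte) {
  df <- as.data.frame(xte)
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    f <- f + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))
}

#' Fit a classifier and predict class-1 probabilities
#'
#' Uniform interface over the twelve classifiers.  Implementations are
#' delegated to established toolkits (e1071, kernlab, rpart, randomForest,
#' nnet, MASS, xgboost, stats) with fixed default hyperparameters and
#' pinned seeds; the nearest-neighbour vote and AdaBoost stumps are
#' implemented in-package.
#'
#' @param name one of [CLASSIFIERS].
#' @param xtr,ytr training matrix and 0/1 labels.
#' @param xte test matrix.
#' @param seed seed pinned for stochastic learners.
#' @param params optional named list of per-classifier overrides
#'   (`knn_k`, `rf_ntree`, `xgb_nrounds`, `mlp_size`, `ada_M`).
#' @return numeric vector of class-1 probabilities for `xte` rows.
#' @export
fit_predict <- function(name, xtr, ytr, xte, seed = 1L, params = list()) {
  name <- match.arg(name, CLASSIFIERS)
  stop_if_not(length(unique(ytr)) == 2, "training fold lost a class")
  yf <- factor(ytr, levels = c(0, 1))
  dtr <- as.data.frame(xtr)
  dte <- as.data.frame(xte)
  with_seed(seed, switch(
    name,
    NearestNeighbors = knn_prob(xtr, ytr, xte, params$knn_k %||% 5L),
    SVC_linear = {
      fit <- e1071::svm(xtr, yf, kernel = "linear", probability = TRUE)
      attr(predict(fit, xte, probability = TRUE), "probabilities")[, "1"]
    },
    SVC_RBF = {
      fit <- e1071::svm(xtr, yf, kernel = "radial", probability = TRUE)
      attr(predict(fit, xte, probability = TRUE), "probabilities")[, "1"]
    },
    GaussianProcess = {
      # kernlab prints its sigma-estimation notice with cat(); silence it
      utils::capture.output(
        fit <- kernlab::gausspr(xtr, yf, type = "classification",
                                kernel = "rbfdot"))
      kernlab::predict(fit, xte, type = "probabilities")[, "1"]
    },
    DecisionTree = {
      fit <- rpart::rpart(y ~ ., data = cbind(dtr, y = yf), method = "class",
                          control = rpart::rpart.control(xval = 0))
      predict(fit, dte, type = "prob")[, "1"]
    },
    RandomForest = {
      fit <- randomForest::randomForest(xtr, yf,
                                        ntree = params$rf_ntree %||% 200L)
      predict(fit, xte, type = "prob")[, "1"]
    },
    MLP = {
      fit <- nnet::nnet(xtr, as.numeric(ytr == 1),
                        size = params$mlp_size %||% 5L, decay = 0.01,
                        maxit = params$mlp_maxit %||% 200L, trace = FALSE)
      as.vector(predict(fit, xte))
    },
    AdaBoost = ada_prob(ada_fit(xtr, ytr, params$ada_M %||% 25L), xte),
    NaiveBayes = {
      fit <- e1071::naiveBayes(xtr, yf)
      predict(fit, xte, type = "raw")[, "1"]
    },
    QDA = {
      fit <- MASS::qda(xtr, yf)
      predict(fit, xte)$posterior[, "1"]
    },
    XGBoost = {
      fit <- xgboost::xgboost(x = xtr, y = yf,
                              nrounds = params$xgb_nrounds %||% 50L,
                              max_depth = 3, learning_rate = 0.3,
                              verbosity = 0, nthreads = 1)
      as.vector(predict(fit, xte, type = "response"))
    },
    LogisticRegression = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(dtr, y = yf),
                                         family = stats::binomial()))
      suppressWarnings(as.vector(predict(fit, dte, type = "response")))
    }))
}
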