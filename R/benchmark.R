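#' Stratified k-fold assignment
#'
#' Shuffles subjects within each class (seeded) and deals them round-robin
#' into k folds, so every fold keeps the class mix as even as possible.
#'
#' @param y binary labels.
#' @param k folds.
#' @param seed shuffle seed.
#' @return list of k integer index vectors partitioning `seq_along(y)`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  stop_if_not(k >= 2, "need k >= 2 folds")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      for (i in seq_along(idx)) {
        fi <- (i - 1L) %% k + 1L
        folds[[fi]] <- c(folds[[fi]], idx[i])
      }
    }
  })
  folds
}

#' SMOTE synthetic minority rows
#'
#' For each required synthetic sample a seed minority row is chosen, one of
#' its k nearest minority neighbours (Euclidean) picked, and the new row
#' placed uniformly at random on the segment between the two.
#'
#' @param x_min minority-class rows (matrix).
#' @param n_new number of synthetic rows to emit.
#' @param k neighbours considered (reduced with a warning if too few rows).
#' @param seed RNG seed.
#' @return matrix of `n_new` synthetic rows.
#' @export
smote <- function(x_min, n_new, k = 5L, seed = 1L) {
  m <- nrow(x_min)
  stop_if_not(m >= 2, "SMOTE needs at least 2 minority rows")
  if (m <= k) {
    warning("SMOTE: reducing k to ", m - 1L, call. = FALSE)
    k <- m - 1L
  }
  if (n_new == 0) return(x_min[0, , drop = FALSE])
  D <- as.matrix(stats::dist(x_min))
  diag(D) <- Inf
  nn <- matrix(unlist(lapply(seq_len(m),
                             function(i) order(D[i, ])[seq_len(k)])),
               nrow = m, byrow = TRUE)
  with_seed(seed, {
    si <- sample(m, n_new, replace = TRUE)
    nj <- nn[cbind(si, sample(k, n_new, replace = TRUE))]
    lam <- stats::runif(n_new)
    x_min[si, , drop = FALSE] +
      lam * (x_min[nj, , drop = FALSE] - x_min[si, , drop = FALSE])
  })
}

## balance the training set to class parity with SMOTE
smote_balance <- function(x, y, k = 5L, seed = 1L) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(list(x = x, y = y))
  min_cls <- if (n1 < n0) 1 else 0
  need <- abs(n1 - n0)
  xs <- smote(x[y == min_cls, , drop = FALSE], need, k = k, seed = seed)
  list(x = rbind(x, xs), y = c(y, rep(min_cls, need)))
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' Midranks handle ties, so the value equals exhaustive positive/negative
#' pair counting with half-credit for tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\]; NA if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative standard deviation of cross-validated AUCs
#'
#' `RSD = (sd / mean) x 100` with the sample standard deviation; the
#' model-stability statistic used to separate equal-AUC models.
#'
#' @param aucs numeric vector of per-fold AUCs.
#' @return RSD percentage (scale-invariant, >= 0).
#' @export
rsd <- function(aucs) {
  m <- mean(aucs)
  stop_if_not(is.finite(m) && m > 0, "rsd: mean AUC must be positive")
  stats::sd(aucs) / m * 100
}

#' Model specification for the benchmark grid
#'
#' @param extractor feature-source name (e.g. "Radiomics", "Resnet50").
#' @param selector a [selector_spec()] or selector name.
#' @param classifier one of [CLASSIFIERS].
#' @return list of class `model_spec` with the canonical
#'   `<Extractor>_<Selector>_<Classifier>` name.
#' @export
model_spec <- function(extractor, selector, classifier) {
  if (is.character(selector)) selector <- selector_spec(selector)
  classifier <- match.arg(classifier, CLASSIFIERS)
  structure(list(extractor = extractor, selector = selector,
                 classifier = classifier,
                 name = paste(extractor, selector$name, classifier,
                              sep = "_")),
            class = "model_spec")
}

#' Cross-validated evaluation of one model
#'
#' Per fold: standardization fitted on the training split only, SMOTE class
#' balancing of the training split only, the selection cascade run on the
#' training split only, classifier fit and test-split scoring.  Reports the
#' ten per-fold AUCs (rank formulation), their mean and RSD, confusion
#' metrics at probability threshold 0.5 pooled over folds, the selected
#' features and the out-of-fold predictions.
#'
#' @param x subjects x features matrix (robust features, unstandardized).
#' @param y binary labels.
#' @param spec a [model_spec()].
#' @param k folds.
#' @param seed CV/SMOTE/classifier seed.
#' @param fraction univariate fraction in the cascade.
#' @param rfa run recursive feature addition inside each training fold.
#' @param params classifier parameter overrides (see [fit_predict()]).
#' @param selection_cache optional environment memoizing per-fold selections
#'   across classifiers of the same extractor/selector (identical results,
#'   shared work).
#' @return list of class `benchmark_record`.
#' @export
cv_evaluate <- function(x, y, spec, k = 10L, seed = 1L, fraction = 0.20,
                        rfa = FALSE, params = list(),
                        selection_cache = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  folds <- stratified_folds(y, k, seed)
  n <- length(y)
  oof <- rep(NA_real_, n)
  aucs <- rep(NA_real_, k)
  sel_feats <- list()
  failed <- FALSE
  for (fi in seq_len(k)) {
    te <- folds[[fi]]
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y[tr])) < 2) { failed <- TRUE; next }
    # a single-class test fold cannot yield an AUC; the fold still
    # contributes out-of-fold predictions and is skipped in the AUC mean
    xtr <- x[tr, , drop = FALSE]
    mu <- colMeans(xtr)
    sdv <- sqrt(pmax(colMeans(xtr^2) - mu^2, 0) *
                length(tr) / (length(tr) - 1))
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
    key <- sprintf("%s|%s|%d", spec$extractor, spec$selector$name, fi)
    feats <- if (!is.null(selection_cache) &&
                 !is.null(selection_cache[[key]])) {
      selection_cache[[key]]
    } else {
      bal <- smote_balance(xs[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, paste0("smote", fi)))
      # the MAD + univariate stages do not depend on the selector: share
      # them across the selector axis of a grid
      pkey <- sprintf("%s|prescreen|%d", spec$extractor, fi)
      pre <- if (!is.null(selection_cache) &&
                 !is.null(selection_cache[[pkey]])) {
        selection_cache[[pkey]]
      } else {
        pr <- tryCatch(prescreen_features(bal$x, bal$y, fraction),
                       error = function(e) NULL)
        if (!is.null(selection_cache) && !is.null(pr))
          selection_cache[[pkey]] <- pr
        pr
      }
      f <- if (is.null(pre)) NULL else tryCatch(
        select_features(bal$x, bal$y, spec$selector, fraction = fraction,
                        rfa = rfa, k = min(k, 5L),
                        seed = derive_seed(seed, paste0("rfa", fi)),
                        prescreened = pre)$features,
        error = function(e) NULL)
      if (!is.null(selection_cache) && !is.null(f))
        selection_cache[[key]] <- f
      f
    }
    if (is.null(feats) || !length(feats)) { failed <- TRUE; next }
    bal <- smote_balance(xs[tr, feats, drop = FALSE], y[tr],
                         seed = derive_seed(seed, paste0("smote", fi)))
    pr <- tryCatch(
      fit_predict(spec$classifier, bal$x, bal$y,
                  xs[te, feats, drop = FALSE],
                  seed = derive_seed(seed, paste0("clf", fi)),
                  params = params),
      error = function(e) NULL)
    if (is.null(pr)) { failed <- TRUE; next }
    oof[te] <- pr
    aucs[fi] <- auc_rank(pr, y[te])
    sel_feats[[fi]] <- feats
  }
  ok <- is.finite(aucs)
  mean_auc <- if (any(ok)) mean(aucs[ok]) else NA_real_
  rec <- list(name = spec$name, spec = spec, fold_aucs = aucs,
              mean_auc = mean_auc,
              rsd = if (sum(ok) >= 2 && isTRUE(mean_auc > 0))
                rsd(aucs[ok]) else NA_real_,
              selected_features = sel_feats,
              oof_prob = oof,
              oof_label = as.integer(oof >= 0.5),
              failed = failed,
              seed = seed)
  pred <- rec$oof_label
  okp <- !is.na(pred)
  tp <- sum(pred[okp] == 1 & y[okp] == 1)
  tn <- sum(pred[okp] == 0 & y[okp] == 0)
  fp <- sum(pred[okp] == 1 & y[okp] == 0)
  fn <- sum(pred[okp] == 0 & y[okp] == 1)
  rec$accuracy <- (tp + tn) / max(tp + tn + fp + fn, 1)
  rec$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  rec$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  rec$precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec$f1 <- if (is.finite(rec$precision) && is.finite(rec$sensitivity) &&
                (rec$precision + rec$sensitivity) > 0)
    2 * rec$precision * rec$sensitivity / (rec$precision + rec$sensitivity)
    else NA_real_
  class(rec) <- "benchmark_record"
  rec
}

#' @export
print.benchmark_record <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f RSD %.2f acc %.3f%s\n", x$name, x$mean_auc,
              x$rsd, x$accuracy, if (x$failed) " [failed folds]" else ""))
  invisible(x)
}

#' Run the extractor x selector x classifier benchmark grid
#'
#' One cross-validated record per combination.  Per-fold feature selections
#' are shared across classifiers of the same (extractor, selector) pair --
#' the cascade does not depend on the classifier unless recursive feature
#' addition is enabled, in which case caching is disabled automatically.
#'
#' @param sources named list of subjects x features matrices (one per
#'   extractor, e.g. `Radiomics`, `Resnet50`, ...).
#' @param y binary labels shared by all sources.
#' @param selectors character vector of selector names.
#' @param classifiers character vector of classifier names.
#' @param k,seed,fraction,rfa,params passed to [cv_evaluate()].
#' @param selector_params extra arguments for [selector_spec()].
#' @return data.frame of class `benchmark_table` (one row per model) with
#'   the full records in `attr(, "records")`.
#' @export
run_grid <- function(sources, y, selectors = SELECTORS,
                     classifiers = CLASSIFIERS, k = 10L, seed = 1L,
                     fraction = 0.20, rfa = FALSE, params = list(),
                     selector_params = list()) {
  stop_if_not(length(sources) >= 1 && length(selectors) >= 1 &&
              length(classifiers) >= 1, "empty grid axis")
  records <- list()
  for (src in names(sources)) {
    cache <- if (rfa) NULL else new.env(parent = emptyenv())
    for (sel in selectors) {
      sspec <- do.call(selector_spec, c(list(name = sel), selector_params))
      for (clf in classifiers) {
        ms <- model_spec(src, sspec, clf)
        rec <- cv_evaluate(sources[[src]], y, ms, k = k, seed = seed,
                           fraction = fraction, rfa = rfa, params = params,
                           selection_cache = cache)
        records[[ms$name]] <- rec
      }
    }
  }
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(name = r$name, extractor = r$spec$extractor,
               selector = r$spec$selector$name,
               classifier = r$spec$classifier, mean_auc = r$mean_auc,
               rsd = r$rsd, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               precision = r$precision, f1 = r$f1, failed = r$failed,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "records") <- records
  class(df) <- c("benchmark_table", "data.frame")
  df
}

#' Selector x classifier AUC (or RSD) matrix for one extractor
#'
#' @param bench a `benchmark_table`.
#' @param extractor extractor name.
#' @param metric "mean_auc" or "rsd".
#' @return selectors x classifiers numeric matrix.
#' @export
benchmark_matrix <- function(bench, extractor, metric = "mean_auc") {
  sub <- bench[bench$extractor == extractor, ]
  sels <- unique(sub$selector); clfs <- unique(sub$classifier)
  m <- matrix(NA_real_, length(sels), length(clfs),
              dimnames = list(sels, clfs))
  m[cbind(match(sub$selector, sels), match(sub$classifier, clfs))] <-
    sub[[metric]]
  m
}

#' Identify the optimal model of a benchmark table
#'
#' Maximum mean AUC; ties separated by lower RSD, then table order.
#'
#' @param bench a `benchmark_table`.
#' @param extractor optional extractor restriction.
#' @return the winning `benchmark_record`.
#' @export
best_model <- function(bench, extractor = NULL) {
  df <- if (is.null(extractor)) bench
        else bench[bench$extractor == extractor, ]
  df <- df[!df$failed & is.finite(df$mean_auc), ]
  stop_if_not(nrow(df) > 0, "no successful models")
  ord <- order(-df$mean_auc, df$rsd)
  attr(bench, "records")[[df$name[ord[1]]]]
}

#' Binary outcome labels and disease-control rate from response codes
#'
#' Complete response, partial response and stable disease count as disease
#' control (label 1); progressive disease as label 0.
#'
#' @param codes character vector of "CR", "PR", "SD", "PD".
#' @return list with `labels` (integer 0/1) and `dcr` (percentage, one
#'   decimal).
#' @export
label_outcomes <- function(codes) {
  bad <- setdiff(unique(codes), c("CR", "PR", "SD", "PD"))
  if (length(bad))
    stop("unknown response code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  labels <- as.integer(codes %in% c("CR", "PR", "SD"))
  list(labels = labels, dcr = round(100 * mean(labels), 1))
}
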