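#' Selector specification
#'
#' Names and tuning parameters of the thirteen filter feature selectors:
#' five score-based rankers (ReliefF RELF, Fisher score FSCR, Gini index
#' GINI, chi-square score CHSQ, t-test score TSCR) and eight greedy
#' mutual-information selectors from the conditional-likelihood framework
#' (MIM, MIFS, MRMR, JMI, CIFE, CMIM, ICAP, DISR).
#'
#' @param name selector name.
#' @param mi_bins equal-frequency bins used by the plug-in MI estimator.
#' @param relief_k neighbours per class for ReliefF.
#' @param K candidate budget: rankings are truncated to the top `K`.
#' @return list of class `selector_spec`.
#' @export
selector_spec <- function(name, mi_bins = 10L, relief_k = 10L, K = 30L) {
  name <- match.arg(name, SELECTORS)
  structure(list(name = name, mi_bins = as.integer(mi_bins),
                 relief_k = as.integer(relief_k), K = as.integer(K)),
            class = "selector_spec")
}

#' The thirteen supported selector names
#' @export
SELECTORS <- c("RELF", "FSCR", "GINI", "CHSQ", "JMI", "CIFE", "DISR", "MIM",
               "CMIM", "ICAP", "TSCR", "MRMR", "MIFS")

.MI_SELECTORS <- c("MIM", "MIFS", "MRMR", "JMI", "CIFE", "CMIM", "ICAP",
                   "DISR")

#' Drop features with zero median absolute deviation
#'
#' Removes features whose median absolute deviation about the median is
#' exactly zero (constant or majority-constant columns carry no usable
#' spread).
#'
#' @param x subjects x features matrix.
#' @return the filtered matrix.
#' @export
mad_filter <- function(x) {
  stop_if_not(ncol(x) > 0 && nrow(x) > 0, "empty feature table")
  keep <- apply(x, 2, function(v) stats::mad(v, constant = 1) > 0)
  if (!any(keep)) stop("all features have zero MAD", call. = FALSE)
  x[, keep, drop = FALSE]
}

## Welch t statistic per column (absolute value); degenerate columns -> 0.
welch_t <- function(x, y) {
  i1 <- y == 1; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(x[i1, , drop = FALSE]); m0 <- colMeans(x[i0, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[i0, , drop = FALSE], 2, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- abs(m1 - m0) / se
  t[!is.finite(t)] <- ifelse(abs(m1 - m0)[!is.finite(t)] > 0, 1e12, 0)
  t
}

#' Keep the top fraction of features by univariate separation
#'
#' Ranks features by the absolute Welch t statistic between the two classes
#' and keeps the top `ceiling(fraction * p)`.
#'
#' @param x subjects x features matrix.
#' @param y binary labels (0/1).
#' @param fraction fraction kept.
#' @return the reduced matrix (columns in original order).
#' @export
univariate_top <- function(x, y, fraction = 0.20) {
  stop_if_not(length(unique(y)) == 2, "univariate_top needs two classes")
  t <- welch_t(x, y)
  keep_n <- ceiling(fraction * ncol(x))
  ord <- order(t, decreasing = TRUE)
  keep <- sort(ord[seq_len(keep_n)])
  x[, keep, drop = FALSE]
}

## Equal-frequency binning to at most `bins` levels (ties collapse bins).
ef_bins <- function(v, bins = 10L) {
  br <- unique(qtl(v, seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(v)))
  findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Plug-in mutual information between a feature and a discrete target
#'
#' Continuous input is discretized to `bins` equal-frequency bins; the
#' plug-in estimate \eqn{I(X;Y) = \sum p(x,y) \log[p(x,y)/(p(x)p(y))]} is
#' returned in nats with the 0 log 0 = 0 convention.  With `z` given, the
#' conditional MI \eqn{I(X;Y|Z) = \sum_z p(z) I(X;Y|Z=z)} is returned.
#'
#' @param x numeric or integer vector.
#' @param y discrete vector.
#' @param z optional discrete conditioning vector.
#' @param bins equal-frequency bins for continuous `x`.
#' @return mutual information in nats (>= 0 up to estimation error).
#' @export
mutual_info <- function(x, y, z = NULL, bins = 10L) {
  xb <- if (is.integer(x) && length(unique(x)) <= bins) x else ef_bins(x, bins)
  if (is.null(z)) return(mi_disc(xb, y))
  zf <- as.integer(factor(z))
  out <- 0
  for (zz in unique(zf)) {
    w <- zf == zz
    out <- out + mean(w) * mi_disc(xb[w], y[w])
  }
  out
}

mi_disc <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  e <- outer(pa, pb)
  sel <- p > 0
  sum(p[sel] * log(p[sel] / e[sel]))
}

## ---- score-based rankers --------------------------------------------------

fisher_score <- function(x, y) {
  i1 <- y == 1; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  mu <- colMeans(x)
  m1 <- colMeans(x[i1, , drop = FALSE]); m0 <- colMeans(x[i0, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[i0, , drop = FALSE], 2, stats::var)
  num <- n1 * (m1 - mu)^2 + n0 * (m0 - mu)^2
  den <- n1 * v1 + n0 * v0
  s <- num / den
  s[!is.finite(s)] <- ifelse(num[!is.finite(s)] > 0, 1e12, 0)
  s
}

chisq_score <- function(x, y, bins = 10L) {
  yf <- factor(y)
  apply(x, 2, function(v) {
    b <- ef_bins(v, bins)
    if (length(unique(b)) < 2) return(0)
    O <- table(b, yf)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  })
}

gini_score <- function(x, y) {
  n <- length(y)
  p1 <- mean(y == 1)
  parent <- 1 - p1^2 - (1 - p1)^2
  apply(x, 2, function(v) {
    o <- order(v)
    vs <- v[o]; ys <- y[o] == 1
    cum1 <- cumsum(ys)
    nl <- seq_len(n - 1)
    valid <- which(diff(vs) > 0)            # thresholds at distinct midpoints
    if (!length(valid)) return(0)
    nl <- nl[valid]; c1 <- cum1[valid]
    pl <- c1 / nl; pr <- (sum(ys) - c1) / (n - nl)
    gl <- 1 - pl^2 - (1 - pl)^2
    gr <- 1 - pr^2 - (1 - pr)^2
    child <- (nl * gl + (n - nl) * gr) / n
    parent - min(child)
  })
}

relieff_score <- function(x, y, k = 10L) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xs <- sweep(x, 2, rng, `/`)
  D <- as.matrix(stats::dist(xs))
  diag(D) <- Inf
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_ <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_))
    if (kh == 0 || km == 0) next
    hits <- same[order(D[i, same])][seq_len(kh)]
    miss <- diff_[order(D[i, diff_])][seq_len(km)]
    dh <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))
    dm <- abs(sweep(xs[miss, , drop = FALSE], 2, xs[i, ]))
    w <- w - colMeans(dh) / n + colMeans(dm) / n
  }
  w
}

#' Rank features with a score-based filter selector
#'
#' Covers FSCR (Fisher score), TSCR (absolute Welch t), CHSQ (chi-square of
#' the binned feature x class contingency), GINI (impurity decrease of the
#' best threshold split) and RELF (ReliefF with range-normalized
#' differences and k nearest hits/misses).  Perfect separators receive a
#' large capped score and rank first.
#'
#' @param x subjects x features matrix (standardized).
#' @param y binary labels.
#' @param spec a [selector_spec()] with a score-based `name`.
#' @return object of class `ranked_features`: data.frame with `feature`,
#'   `score` in ranking order, truncated to `spec$K`.
#' @export
score_filter <- function(x, y, spec) {
  stopifnot(inherits(spec, "selector_spec"))
  s <- switch(spec$name,
              FSCR = fisher_score(x, y),
              TSCR = welch_t(x, y),
              CHSQ = chisq_score(x, y, spec$mi_bins),
              GINI = gini_score(x, y),
              RELF = relieff_score(x, y, spec$relief_k),
              stop("score_filter does not cover selector ", spec$name))
  s <- pmin(s, 1e12)
  ord <- order(s, decreasing = TRUE)         # stable: ties keep column order
  ord <- ord[seq_len(min(spec$K, length(ord)))]
  structure(data.frame(feature = colnames(x)[ord], score = s[ord],
                       row.names = NULL),
            class = c("ranked_features", "data.frame"),
            selector = spec$name)
}

## joint-count machinery for the greedy MI selectors -------------------------
## B: n x p matrix of bin indices (1..nb); y: 0/1; all-candidate MI terms
## against one already selected feature s are computed with vectorized
## column sums over indicator masks, so each greedy step is O(nb^2 * n * p).

mi_all_vs_y <- function(B, y, nb) {
  n <- nrow(B)
  G <- cbind(as.numeric(y == 0), as.numeric(y == 1))
  J <- array(0, c(ncol(B), nb, 2))
  for (b in seq_len(nb)) J[, b, ] <- crossprod(B == b, G)
  mi_from_joint(J / n)
}

## p x A x B joint probability array -> per-feature MI, fully vectorized
mi_from_joint <- function(pj) {
  d <- dim(pj); p <- d[1]
  pa <- matrix(rowSums(matrix(pj, p * d[2], d[3])), p, d[2])
  out <- numeric(p)
  for (b in seq_len(d[3])) {
    pjb <- matrix(pj[, , b], p, d[2])
    pbb <- rowSums(pjb)
    r <- pjb * log(pjb / (pa * pbb))
    r[pjb == 0] <- 0
    out <- out + rowSums(r)
  }
  out
}

## joint counts of every candidate with one discrete vector s (and y):
## p x nb x ns x 2 array from which I(f;s), I(f;s|Y), I(f;Y|s) derive
joint_with_s <- function(B, s, y, nb) {
  n <- nrow(B)
  ns <- max(s)
  G <- matrix(0, n, ns * 2L)
  G[cbind(seq_len(n), s + ns * (y == 1))] <- 1
  J <- array(0, c(ncol(B), nb, ns, 2))
  for (b in seq_len(nb)) {
    cnt <- crossprod(B == b, G)
    J[, b, , 1] <- cnt[, seq_len(ns)]
    J[, b, , 2] <- cnt[, ns + seq_len(ns)]
  }
  J / n
}

#' Greedy forward selection with a mutual-information criterion
#'
#' Implements the standard conditional-likelihood family: at each step the
#' candidate maximizing the criterion given the selected set S is added.
#' Criteria (I = plug-in MI, nats): MIM `I(f;Y)`; MIFS `I(f;Y) - sum_S
#' I(f;s)`; MRMR `I(f;Y) - mean_S I(f;s)`; JMI `I(f;Y) - mean_S [I(f;s) -
#' I(f;s|Y)]`; CIFE `I(f;Y) - sum_S [I(f;s) - I(f;s|Y)]`; CMIM `min_S
#' I(f;Y|s)`; ICAP `I(f;Y) - sum_S max(0, I(f;s) - I(f;s|Y))`; DISR `sum_S
#' I({f,s};Y) / H(f,s,Y)`.  The first pick of every criterion is
#' `argmax I(f;Y)`; ties break toward the earlier column.
#'
#' @param x subjects x features matrix.
#' @param y binary labels.
#' @param spec a [selector_spec()] with an MI-based `name`.
#' @param K number of features to select (defaults to `spec$K`).
#' @return a `ranked_features` data.frame in selection order with the
#'   criterion value at each step as `score`.
#' @export
greedy_mi_select <- function(x, y, spec, K = NULL) {
  stopifnot(inherits(spec, "selector_spec"))
  stop_if_not(spec$name %in% .MI_SELECTORS,
              "selector %s is not an MI criterion", spec$name)
  K <- K %||% spec$K
  p <- ncol(x)
  if (K > p) { K <- p }
  nb <- spec$mi_bins
  B <- apply(x, 2, ef_bins, bins = nb)
  rel <- mi_all_vs_y(B, y, nb)             # I(f;Y)
  n1 <- sum(y == 1) / length(y)
  hy <- -sum(c(n1, 1 - n1)[c(n1, 1 - n1) > 0] *
             log(c(n1, 1 - n1)[c(n1, 1 - n1) > 0]))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)                    # sum_S I(f;s)
  cond_sum <- numeric(p)                   # sum_S I(f;s|Y)
  icap_sum <- numeric(p)                   # sum_S max(0, I(f;s)-I(f;s|Y))
  cmim_min <- rep(Inf, p)                  # min_S I(f;Y|s)
  disr_sum <- numeric(p)                   # sum_S I({f,s};Y)/H(f,s,Y)
  for (step in seq_len(K)) {
    crit <- if (step == 1 || spec$name == "MIM") rel else {
      ns <- length(selected)
      switch(spec$name,
             MIFS = rel - red_sum,
             MRMR = rel - red_sum / ns,
             JMI = rel - (red_sum - cond_sum) / ns,
             CIFE = rel - (red_sum - cond_sum),
             CMIM = cmim_min,
             ICAP = rel - icap_sum,
             DISR = disr_sum)
    }
    crit[selected] <- -Inf
    pick <- which.max(crit)
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step == K || spec$name == "MIM") next
    # update only the running terms the criterion actually uses
    s_bin <- B[, pick]
    J <- joint_with_s(B, s_bin, y, nb)     # p x nb x ns x 2
    ns_lv <- dim(J)[3]
    p_fs <- J[, , , 1] + J[, , , 2]        # p x nb x ns
    if (ns_lv == 1) p_fs <- array(p_fs, c(p, nb, 1))
    need_red <- spec$name %in% c("MIFS", "MRMR", "JMI", "CIFE", "ICAP")
    need_cond <- spec$name %in% c("JMI", "CIFE", "ICAP")
    if (need_red) red_sum <- red_sum + (red <- mi_from_joint(p_fs))
    if (need_cond) {
      # I(f;s|Y) = sum_y p(y) I(f;s|Y=y)
      cond <- numeric(p)
      for (yy in 1:2) {
        py <- sum(J[1, , , yy])
        Jy <- J[, , , yy]
        if (ns_lv == 1) Jy <- array(Jy, c(p, nb, 1))
        if (py > 0) cond <- cond + py * mi_from_joint(Jy / py)
      }
      cond_sum <- cond_sum + cond
      if (spec$name == "ICAP") icap_sum <- icap_sum + pmax(0, red - cond)
    }
    if (spec$name == "CMIM") {
      fy_cond <- numeric(p)                # I(f;Y|s)
      for (ss in seq_len(ns_lv)) {
        ps <- sum(J[1, , ss, ])
        if (ps > 0) fy_cond <- fy_cond + ps * mi_from_joint(J[, , ss, ] / ps)
      }
      cmim_min <- pmin(cmim_min, fy_cond)
    }
    if (spec$name == "DISR") {
      # I({f,s};Y) / H(f,s,Y) with the (f,s) pair as one joint variable
      py2 <- c(sum(J[1, , , 1]), sum(J[1, , , 2]))
      hfsy <- numeric(p); ifs_y <- numeric(p)
      for (yy in 1:2) {
        Jy <- matrix(J[, , , yy], p, nb * ns_lv)
        E <- matrix(p_fs, p, nb * ns_lv) * py2[yy]
        r <- Jy * log(Jy / E)
        r[Jy == 0] <- 0
        ifs_y <- ifs_y + rowSums(r)
        h <- Jy * log(Jy)
        h[Jy == 0] <- 0
        hfsy <- hfsy - rowSums(h)
      }
      disr_sum <- disr_sum + ifelse(hfsy > 0, ifs_y / hfsy, 0)
    }
  }
  structure(data.frame(feature = colnames(x)[selected], score = scores,
                       row.names = NULL),
            class = c("ranked_features", "data.frame"),
            selector = spec$name)
}

#' Run the selector-independent prescreen stages
#'
#' MAD filter followed by the top-fraction univariate screen; returns the
#' surviving column names in original order.
#'
#' @inheritParams select_features
#' @return character vector of column names.
#' @export
prescreen_features <- function(x, y, fraction = 0.20) {
  colnames(univariate_top(mad_filter(x), y, fraction))
}

#' Rank features with any of the thirteen selectors
#'
#' Dispatches to [score_filter()] or [greedy_mi_select()].
#'
#' @inheritParams score_filter
#' @return a `ranked_features` data.frame.
#' @export
rank_features <- function(x, y, spec) {
  if (spec$name %in% .MI_SELECTORS) greedy_mi_select(x, y, spec)
  else score_filter(x, y, spec)
}

#' Recursive feature addition
#'
#' Walks the ranked list in order; each feature is tentatively added and
#' kept only if the mean stratified k-fold cross-validated AUC of the given
#' classifier improves by more than `tol`.  Folds are seeded, so the result
#' is deterministic given (data, ranking, seed).
#'
#' @param ranked a `ranked_features` data.frame (or character vector).
#' @param x subjects x features matrix.
#' @param y binary labels.
#' @param classifier classifier name from [CLASSIFIERS] used to score
#'   candidate subsets.
#' @param k folds.
#' @param seed fold/classifier seed.
#' @param tol minimum AUC improvement to keep a feature.
#' @return list with `features` (kept names) and `trace` (AUC after each
#'   accepted feature).
#' @export
recursive_feature_addition <- function(ranked, x, y,
                                       classifier = "LogisticRegression",
                                       k = 10L, seed = 1L, tol = 1e-4) {
  feats <- if (is.character(ranked)) ranked else ranked$feature
  stop_if_not(length(feats) > 0, "empty ranking")
  folds <- stratified_folds(y, k, seed)
  cv_auc <- function(cols) {
    xs <- x[, cols, drop = FALSE]
    aucs <- vapply(seq_along(folds), function(fi) {
      tr <- setdiff(seq_along(y), folds[[fi]])
      te <- folds[[fi]]
      pr <- tryCatch(
        fit_predict(classifier, xs[tr, , drop = FALSE], y[tr],
                    xs[te, , drop = FALSE], seed = seed),
        error = function(e) rep(0.5, length(te)))
      auc_rank(pr, y[te])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  kept <- character(0)
  best <- -Inf
  trace <- numeric(0)
  for (f in feats) {
    a <- cv_auc(c(kept, f))
    if (a > best + tol) {
      kept <- c(kept, f)
      best <- a
      trace <- c(trace, a)
    }
  }
  list(features = kept, trace = trace)
}

#' Run the full four-stage selection cascade
#'
#' MAD filter, top-fraction univariate screen, selector ranking, and
#' (optionally) recursive feature addition.  The output feature set is
#' always a subset of the univariate screen's output, which is a subset of
#' the MAD filter's output.
#'
#' @param x subjects x features matrix (standardized robust features).
#' @param y binary labels.
#' @param spec a [selector_spec()].
#' @param fraction univariate fraction kept.
#' @param rfa logical: run recursive feature addition after ranking.
#' @param classifier classifier used inside RFA.
#' @param k,seed CV folds and seed for RFA.
#' @param prescreened optional character vector of columns that already
#'   passed the MAD + univariate stages (they are selector-independent, so
#'   callers evaluating many selectors on the same data can compute them
#'   once via [prescreen_features()]).
#' @return list with `features`, `ranked`, and (if `rfa`) `trace`.
#' @export
select_features <- function(x, y, spec, fraction = 0.20, rfa = TRUE,
                            classifier = "LogisticRegression", k = 10L,
                            seed = 1L, prescreened = NULL) {
  x2 <- if (is.null(prescreened)) {
    univariate_top(mad_filter(x), y, fraction)
  } else {
    x[, prescreened, drop = FALSE]
  }
  ranked <- rank_features(x2, y, spec)
  if (!rfa)
    return(list(features = ranked$feature, ranked = ranked))
  r <- recursive_feature_addition(ranked, x2, y, classifier, k = k,
                                  seed = seed)
  feats <- if (length(r$features)) r$features else ranked$feature[1]
  list(features = feats, ranked = ranked, trace = r$trace)
}
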