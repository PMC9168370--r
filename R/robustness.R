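#' Two-way random, absolute-agreement, single-rater ICC(2,1)
#'
#' Computed from the two-way ANOVA mean squares of an n subjects x k raters
#' matrix: \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C -
#' MS_E))} where MS_R, MS_C and MS_E are the row (subject), column (rater)
#' and residual mean squares.  Absolute agreement penalizes systematic
#' rater offsets, unlike consistency forms.  The value is clipped to
#' \[-1, 1\]; a zero-variance matrix returns 1 by convention.
#'
#' @param m numeric matrix, subjects in rows, raters in columns.
#' @return ICC value in \[-1, 1\].
#' @export
icc_agreement <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stop_if_not(n >= 3 && k >= 2, "ICC needs n >= 3 subjects and k >= 2 raters")
  stop_if_not(all(is.finite(m)), "ICC input contains non-finite values")
  g <- mean(m)
  sst <- sum((m - g)^2)
  if (sst == 0) return(1)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) return(1)
  clip((msr - mse) / denom, -1, 1)
}

#' Assemble balanced ICC panels from replicate feature tables
#'
#' @param tables nested list: `original` = subjects x features matrix, plus
#'   one list per perturbation kind (`S`, `R`, `Seg`) of replicate matrices
#'   (one per level), all sharing subjects and feature columns.
#' @return list of class `icc_panel`: per kind, a 3-D array
#'   subjects x raters x features (rater 1 = original).
#' @export
build_panels <- function(tables) {
  stop_if_not(!is.null(tables$original), "tables$original is required")
  orig <- tables$original
  kinds <- intersect(c("S", "R", "Seg"), names(tables))
  stop_if_not(length(kinds) > 0, "no perturbation kinds supplied")
  panels <- list()
  for (kind in kinds) {
    reps <- tables[[kind]]
    for (nm in names(reps)) {
      r <- reps[[nm]]
      stop_if_not(identical(dim(r), dim(orig)) &&
                  identical(rownames(r), rownames(orig)) &&
                  identical(colnames(r), colnames(orig)),
                  "unbalanced replicate table %s/%s", kind, nm)
    }
    arr <- array(0, c(nrow(orig), length(reps) + 1L, ncol(orig)),
                 dimnames = list(rownames(orig),
                                 c("original", names(reps)),
                                 colnames(orig)))
    arr[, 1, ] <- orig
    for (i in seq_along(reps)) arr[, i + 1L, ] <- reps[[i]]
    panels[[kind]] <- arr
  }
  structure(panels, class = "icc_panel")
}

#' Score feature robustness across perturbation panels
#'
#' Computes ICC(2,1) per feature and perturbation kind, flags features
#' passing the cutoff for every kind, and summarizes each kind by the mean
#' and SD of its ICCs.
#'
#' @param panels an `icc_panel` from [build_panels()].
#' @param cutoff robustness threshold (pass means ICC >= cutoff for all
#'   kinds).
#' @return list of class `robustness_report`: `icc` (features x kinds
#'   data.frame with `pass`), `summary` (per kind mean, sd), `percent_robust`.
#' @export
robustness_report <- function(panels, cutoff = 0.85) {
  stopifnot(inherits(panels, "icc_panel"))
  kinds <- names(panels)
  features <- dimnames(panels[[1]])[[3]]
  icc <- sapply(kinds, function(kind) {
    arr <- panels[[kind]]
    vapply(seq_len(dim(arr)[3]), function(f) icc_agreement(arr[, , f]),
           numeric(1))
  })
  rownames(icc) <- features
  colnames(icc) <- paste0("ICC_", kinds)
  pass <- apply(icc >= cutoff, 1, all)
  df <- data.frame(feature = features, icc, pass = pass,
                   row.names = NULL, check.names = FALSE)
  structure(list(
    icc = df,
    summary = data.frame(kind = kinds,
                         mean = colMeans(icc),
                         sd = apply(icc, 2, stats::sd),
                         row.names = NULL),
    cutoff = cutoff,
    percent_robust = robust_percent(sum(pass), length(pass))),
    class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %d/%d features robust (%.2f%%) at ICC >= %.2f\n",
              sum(x$icc$pass), nrow(x$icc), x$percent_robust, x$cutoff))
  print(x$summary)
  invisible(x)
}

#' Percentage of robust features
#'
#' @param n_pass,n_total passing and total feature counts.
#' @return percentage rounded to two decimals (e.g. 718 of 851 gives 84.37).
#' @export
robust_percent <- function(n_pass, n_total) {
  stop_if_not(n_total > 0, "n_total must be positive")
  round(100 * n_pass / n_total, 2)
}

#' Names of features passing the robustness filter
#'
#' @param report a `robustness_report`.
#' @param cutoff threshold applied to every perturbation kind.
#' @return character vector of feature names in catalogue order.
#' @export
robust_filter <- function(report, cutoff = 0.85) {
  stopifnot(inherits(report, "robustness_report"))
  iccs <- as.matrix(report$icc[, grep("^ICC_", names(report$icc)),
                               drop = FALSE])
  keep <- apply(iccs >= cutoff, 1, all)
  if (!any(keep))
    stop("no features pass the robustness cutoff; consider relaxing it",
         call. = FALSE)
  report$icc$feature[keep]
}

#' Run the perturbation study for a cohort and build replicate tables
#'
#' For every subject builds the replicate panel ([make_replicates()]),
#' extracts the full feature vector for each replicate and assembles the
#' nested table structure consumed by [build_panels()].
#'
#' @param cohort a `phantom_cohort`.
#' @param config a [preprocess_config()].
#' @param spec a [perturbation_spec()].
#' @param disc a [discretization_config()].
#' @param wavelet wavelet basis.
#' @return nested list of feature tables (`original`, `S`, `R`, `Seg`).
#' @export
replicate_feature_tables <- function(cohort, config = preprocess_config(),
                                     spec = perturbation_spec(),
                                     disc = discretization_config(),
                                     wavelet = "coif1") {
  ids <- vapply(cohort$subjects, `[[`, character(1), "id")
  tabs <- list(original = NULL,
               S = stats::setNames(vector("list", length(spec$S)),
                                   as.character(spec$S)),
               R = stats::setNames(vector("list", length(spec$R)),
                                   as.character(spec$R)),
               Seg = stats::setNames(vector("list", length(spec$Seg)),
                                     as.character(spec$Seg)))
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    reps <- make_replicates(s$volume, s$mask, config, spec,
                            spacing = s$spacing)
    rows$original[[i]] <- extract_all(reps$S$original, disc, wavelet)
    for (kind in c("S", "R", "Seg"))
      for (lvl in setdiff(names(reps[[kind]]), "original"))
        rows[[paste(kind, lvl)]][[i]] <-
          extract_all(reps[[kind]][[lvl]], disc, wavelet)
  }
  bind <- function(lst) {
    m <- do.call(rbind, lst); rownames(m) <- ids; m
  }
  tabs$original <- bind(rows$original)
  for (kind in c("S", "R", "Seg"))
    for (lvl in names(tabs[[kind]]))
      tabs[[kind]][[lvl]] <- bind(rows[[paste(kind, lvl)]])
  tabs
}
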