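#' Default end-to-end pipeline configuration
#'
#' One configuration object drives the whole analysis: cohort generation,
#' preprocessing, perturbation, robustness screening, selection, the
#' benchmark grid and survival follow-through.  The global seed plus the
#' stage parameters fully determine every output; stage sub-seeds are
#' derived from the global seed by stable stage-name hashing, so enabling
#' or disabling one stage never shifts another stage's random stream.
#'
#' @param n cohort size.
#' @param seed global seed.
#' @param effect class-separation parameters (see [generate_cohort()]).
#' @param diameter_range,diameter_median cohort tumour size distribution.
#' @param crop_size preprocessing crop (pixels).
#' @param selectors,classifiers grid axes.
#' @param k cross-validation folds.
#' @param rfa run recursive feature addition inside training folds.
#' @param icc_cutoff robustness threshold.
#' @param stages character vector of enabled stages, a subset of
#'   `c("robustness", "benchmark", "survival")`.
#' @param params classifier parameter overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(n = 40, seed = 17L, effect = c(hu = 20, corr = 1.5),
                       diameter_range = c(10.4, 40),
                       diameter_median = 18,
                       crop_size = 32L,
                       selectors = c("GINI", "MRMR", "RELF"),
                       classifiers = c("NearestNeighbors", "RandomForest",
                                       "LogisticRegression"),
                       k = 10L, rfa = FALSE, icc_cutoff = 0.85,
                       stages = c("robustness", "benchmark", "survival"),
                       params = list()) {
  structure(list(n = n, seed = as.integer(seed), effect = effect,
                 diameter_range = diameter_range,
                 diameter_median = diameter_median,
                 crop_size = as.integer(crop_size), selectors = selectors,
                 classifiers = classifiers, k = as.integer(k), rfa = rfa,
                 icc_cutoff = icc_cutoff, stages = stages, params = params),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns problems instead of raising.
#'
#' @param config a [run_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (config$n < 4) add("n < 4: cannot stratify folds")
  if (config$n < 3) add("ICC needs at least 3 subjects")
  if (config$n < 2 * config$k)
    add(sprintf("k-fold = %d with n = %d leaves folds without both classes",
                config$k, config$n))
  bad_sel <- setdiff(config$selectors, SELECTORS)
  if (length(bad_sel))
    add(paste("unknown selector(s):", paste(bad_sel, collapse = ", ")))
  bad_clf <- setdiff(config$classifiers, CLASSIFIERS)
  if (length(bad_clf))
    add(paste("unknown classifier(s):", paste(bad_clf, collapse = ", ")))
  if (config$icc_cutoff < 0 || config$icc_cutoff > 1)
    add("icc_cutoff outside [0, 1]")
  bad_st <- setdiff(config$stages, c("robustness", "benchmark", "survival"))
  if (length(bad_st))
    add(paste("unknown stage(s):", paste(bad_st, collapse = ", ")))
  if (config$crop_size < 8) add("crop_size too small for texture analysis")
  problems
}

#' Run the full pipeline
#'
#' Generate, preprocess, perturb, extract, screen for robustness, select,
#' benchmark and follow through to survival, per the configuration.  When
#' the robustness stage is disabled, selection consumes the unfiltered
#' feature table (logged in the manifest).  If `out_dir` is given, the main
#' artifacts are written there (CSV/JSON) and hashed into the manifest.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `cohort`, `features`, `report`, `bench`, `best`,
#'   `survival` (as enabled) and a `manifest` of stage durations, warnings
#'   and output-file MD5 hashes.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  manifest <- list(stages = list(), warnings = character(0), files = list())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    out <- withCallingHandlers(expr, warning = function(w) {
      note(paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[stage]] <<-
      round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    out
  }
  res <- list()

  cohort <- timed("generate", generate_cohort(
    n = config$n, seed = derive_seed(config$seed, "cohort"),
    effect = config$effect, diameter_range = config$diameter_range,
    diameter_median = config$diameter_median))
  res$cohort <- cohort
  y <- cohort_labels(cohort)
  pp <- preprocess_config(crop_size = config$crop_size)

  if ("robustness" %in% config$stages) {
    tabs <- timed("perturb_extract", replicate_feature_tables(cohort, pp))
    report <- timed("robustness",
                    robustness_report(build_panels(tabs),
                                      cutoff = config$icc_cutoff))
    res$report <- report
    keep <- robust_filter(report, config$icc_cutoff)
    res$features <- tabs$original[, keep, drop = FALSE]
  } else {
    stacks <- timed("preprocess", {
      st <- lapply(cohort$subjects, function(s)
        preprocess_roi(s$volume, s$mask, pp, spacing = s$spacing))
      names(st) <- vapply(cohort$subjects, `[[`, character(1), "id")
      st
    })
    res$features <- timed("extract", extract_feature_table(stacks))
    note("robustness stage disabled: selection consumes the unfiltered table")
  }

  if ("benchmark" %in% config$stages) {
    res$bench <- timed("benchmark", run_grid(
      list(Radiomics = res$features), y,
      selectors = config$selectors, classifiers = config$classifiers,
      k = config$k, seed = derive_seed(config$seed, "bench"),
      rfa = config$rfa, params = config$params))
    res$best <- best_model(res$bench)
  }

  if ("survival" %in% config$stages && !is.null(res$best)) {
    res$survival <- timed("survival",
                          survival_analysis(res$best,
                                            cohort_clinical(cohort)))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(res$features, file.path(out_dir, "features.csv"))
    if (!is.null(res$report))
      write_robustness_report(res$report,
                              file.path(out_dir, "robustness.csv"),
                              file.path(out_dir, "robustness.json"))
    if (!is.null(res$bench))
      utils::write.csv(as.data.frame(res$bench),
                       file.path(out_dir, "bench.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    fls <- list.files(out_dir, full.names = TRUE)
    manifest$files <- as.list(tools::md5sum(fls))
  }
  res$manifest <- manifest
  res
}
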