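#' Write a phantom cohort to disk
#'
#' Volumes and masks as NIfTI (`<id>.nii.gz`, `<id>_mask.nii.gz`), the
#' clinical table as `clinical.csv` and the generation config as
#' `config.yaml`.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    img <- RNifti::asNifti(s$volume, pixdim = s$spacing)
    RNifti::writeNifti(img, file.path(dir, paste0(s$id, ".nii.gz")))
    msk <- RNifti::asNifti(s$mask, pixdim = s$spacing)
    RNifti::writeNifti(msk, file.path(dir, paste0(s$id, "_mask.nii.gz")))
  }
  utils::write.csv(cohort_clinical(cohort),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  yaml::write_yaml(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `phantom_cohort` (without generation specs).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  cfgf <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfgf)) yaml::read_yaml(cfgf) else list()
  subjects <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$subject_id[i]
    vol <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    msk <- RNifti::readNifti(file.path(dir, paste0(id, "_mask.nii.gz")))
    list(id = id, volume = array(as.numeric(vol), dim(vol)),
         mask = array(as.integer(msk), dim(msk)),
         spacing = RNifti::pixdim(vol)[1:3],
         label = clin$label[i], os_time = clin$os_time[i],
         os_event = clin$os_event[i])
  })
  structure(list(subjects = subjects, config = cfg),
            class = "phantom_cohort")
}

#' Write a processed ROI stack as NIfTI plus a JSON sidecar
#'
#' The slices and masks are written as `<prefix>.nii.gz` and
#' `<prefix>_mask.nii.gz`; the applied window and source slice indices go
#' to `<prefix>.json`.
#'
#' @param stack a `roi_stack`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_roi_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "roi_stack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(stack$slices, pixdim = stack$spacing),
                     paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(stack$masks, pixdim = stack$spacing),
                     paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(window = as.list(stack$window),
                            slice_indices = stack$slice_indices,
                            spacing = stack$spacing),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write a feature table as CSV
#'
#' @param x subjects x features matrix.
#' @param path output CSV (subject_id column + named feature columns).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a robustness report as CSV + JSON summary
#'
#' @param report a `robustness_report`.
#' @param csv_path per-feature ICC table destination.
#' @param json_path summary destination (`NULL` to skip).
#' @return `csv_path`, invisibly.
#' @export
write_robustness_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$icc, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(summary = report$summary,
                              cutoff = report$cutoff,
                              percent_robust = report$percent_robust),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(csv_path)
}

#' Plot a selector x classifier AUC or RSD heat map
#'
#' @param m matrix from [benchmark_matrix()].
#' @param main plot title.
#' @return invisibly, `m`.
#' @export
plot_benchmark_matrix <- function(m, main = "cross-validated AUC") {
  op <- graphics::par(mar = c(8, 8, 3, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
  invisible(m)
}

#' Plot Kaplan-Meier curves for the two predicted groups
#'
#' @param surv result of [survival_analysis()].
#' @param main plot title.
#' @return invisibly, `surv`.
#' @export
plot_km <- function(surv, main = "overall survival by predicted group") {
  cols <- c(`0` = "#D55E00", `1` = "#0072B2")
  xmax <- max(unlist(lapply(surv$km, function(k) k$time)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "months", ylab = "survival", main = main)
  for (g in names(surv$km)) {
    k <- surv$km[[g]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)),
                    col = cols[[g]], do.points = FALSE, lwd = 2)
  }
  graphics::legend("bottomleft",
                   legend = c("predicted progression", "predicted control"),
                   col = cols, lwd = 2, bty = "n")
  invisible(surv)
}
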