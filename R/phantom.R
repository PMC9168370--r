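#' Specification of a single synthetic tumour phantom
#'
#' Collects the geometric and intensity parameters of one CT-like tumour
#' phantom: a jittered ellipsoid of elevated attenuation embedded in a
#' liver-like background, with a correlated Gaussian random-field texture
#' inside the tumour and additive white Gaussian quantum noise everywhere.
#'
#' @param image_shape integer vector of 3 voxel counts (x, y, z).
#' @param voxel_size_mm numeric vector of 3 voxel spacings in mm; the base
#'   axial spacing is 1 mm so thickness resampling is pure slab averaging.
#' @param tumor_diameter_mm maximum tumour diameter in mm.
#' @param hu_background mean background attenuation in Hounsfield units
#'   (arterial-phase liver parenchyma is on the order of 60 HU).
#' @param hu_tumor_shift mean attenuation offset of the tumour interior
#'   relative to background (HU); class-dependent in cohorts.
#' @param texture_corr_len correlation length (voxels) of the Gaussian
#'   random-field texture inside the tumour; class-dependent in cohorts.
#' @param texture_amp standard deviation (HU) of the texture field.
#' @param noise_sd standard deviation (HU) of additive white Gaussian noise.
#' @param aspect relative ellipsoid semi-axes (rescaled so the longest
#'   equals 1, keeping `tumor_diameter_mm` the maximum extent).
#' @param jitter_amp RMS relative amplitude of the low-order
#'   spherical-harmonic boundary jitter (0 disables it).
#' @param seed integer seed making the phantom reproducible.
#' @param diameter_limits admissible diameter range in mm.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(image_shape = c(64L, 64L, 32L),
                         voxel_size_mm = c(1, 1, 1),
                         tumor_diameter_mm = 30,
                         hu_background = 60,
                         hu_tumor_shift = 35,
                         texture_corr_len = 2,
                         texture_amp = 30,
                         noise_sd = 10,
                         aspect = c(1, 1, 1),
                         jitter_amp = 0.1,
                         seed = 1L,
                         diameter_limits = c(10.40, 153.33)) {
  stop_if_not(length(image_shape) == 3 && all(image_shape >= 4),
              "image_shape must be 3 positive voxel counts")
  stop_if_not(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive spacings")
  stop_if_not(tumor_diameter_mm > 0, "tumor_diameter_mm must be positive")
  stop_if_not(tumor_diameter_mm >= diameter_limits[1] &&
              tumor_diameter_mm <= diameter_limits[2],
              "tumor diameter %.2f mm outside admissible range [%.2f, %.2f]",
              tumor_diameter_mm, diameter_limits[1], diameter_limits[2])
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(texture_amp >= 0, "texture_amp must be >= 0")
  aspect <- aspect / max(aspect)
  # radius in voxels along each axis, including jitter head-room
  r_vox <- tumor_diameter_mm / 2 * aspect / voxel_size_mm
  if (any(2 * r_vox * (1 + 2 * jitter_amp) + 2 > image_shape))
    stop("tumor does not fit inside the image volume", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tumor_diameter_mm = tumor_diameter_mm,
                 hu_background = hu_background,
                 hu_tumor_shift = hu_tumor_shift,
                 texture_corr_len = texture_corr_len,
                 texture_amp = texture_amp,
                 noise_sd = noise_sd,
                 aspect = aspect,
                 jitter_amp = jitter_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Low-order (l = 1..3) spherical-harmonic-style radial jitter evaluated at
## unit directions given as an n x 3 matrix; coefficients drawn from the
## current RNG stream; empirically normalized to unit RMS.
radial_jitter <- function(u) {
  a <- stats::rnorm(3)
  B <- matrix(stats::rnorm(9), 3, 3); B <- (B + t(B)) / 2
  diag(B) <- diag(B) - sum(diag(B)) / 3
  g <- stats::rnorm(3)
  f <- as.vector(u %*% a) +
    rowSums((u %*% B) * u) +
    as.vector((u^3 - 0.6 * u) %*% g)
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) return(rep(0, nrow(u)))
  f / s
}

#' Generate one tumour phantom volume and mask
#'
#' Renders the phantom described by a [phantom_spec()]: the tumour support is
#' an ellipsoid whose radius is modulated by low-order spherical-harmonic
#' jitter; the interior attenuation is background + tumour shift + a
#' correlated Gaussian random field; white Gaussian noise is added
#' everywhere and values are clipped to the CT-plausible range
#' \eqn{[-1024, 1400]} HU.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (3-D HU array), `mask` (3-D 0/1 integer array),
#'   and `spacing` (mm per axis).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$image_shape
    ctr <- (d + 1) / 2
    r_vox <- spec$tumor_diameter_mm / 2 * spec$aspect / spec$voxel_size_mm
    gx <- (seq_len(d[1]) - ctr[1]) / r_vox[1]
    gy <- (seq_len(d[2]) - ctr[2]) / r_vox[2]
    gz <- (seq_len(d[3]) - ctr[3]) / r_vox[3]
    ux <- array(gx, d)
    uy <- array(rep(gy, each = d[1]), d)
    uz <- array(rep(gz, each = d[1] * d[2]), d)
    s <- sqrt(ux^2 + uy^2 + uz^2)
    ssafe <- pmax(s, 1e-9)
    if (spec$jitter_amp > 0) {
      u <- cbind(as.vector(ux / ssafe), as.vector(uy / ssafe),
                 as.vector(uz / ssafe))
      jit <- spec$jitter_amp * radial_jitter(u)
    } else jit <- 0
    mask <- array(as.integer(as.vector(s) <= 1 + jit), d)
    stop_if_not(sum(mask) > 0, "degenerate phantom: empty tumour mask")

    vol <- array(spec$hu_background, d)
    if (spec$texture_amp > 0) {
      tex <- gauss_smooth(array(stats::rnorm(prod(d)), d),
                          spec$texture_corr_len)
      tex <- tex / max(stats::sd(tex), 1e-12)
      vol <- vol + (spec$hu_tumor_shift + spec$texture_amp * tex) * mask
    } else {
      vol <- vol + spec$hu_tumor_shift * mask
    }
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    list(volume = clip(vol, -1024, 1400), mask = mask,
         spacing = spec$voxel_size_mm)
  })
}

#' Generate a synthetic tumour-phantom cohort
#'
#' Draws per-subject phantom specifications with class-dependent intensity
#' shift and texture correlation length, renders the phantoms, and attaches
#' survival endpoints whose hazard depends on the class label.  Label 1 is
#' "disease control", label 0 "progressed disease"; exactly
#' `round(n * control_fraction)` subjects receive label 1.
#'
#' @param n number of subjects (>= 4 so folds can be stratified).
#' @param control_fraction fraction of label-1 subjects (0 < f < 1).
#' @param effect named numeric class-separation parameters: `hu` is the
#'   difference in mean tumour attenuation shift (HU) between classes,
#'   `corr` the difference in texture correlation length (voxels).  `effect
#'   = c(hu = 0, corr = 0)` makes the label independent of image content.
#' @param seed global integer seed; per-subject seeds are derived from it by
#'   counter offset so regeneration is bit-identical.
#' @param diameter_range admissible tumour diameter range (mm); defaults to
#'   the cohort the generator emulates.
#' @param diameter_median,diameter_sdlog log-normal diameter distribution
#'   parameters (median in mm), truncated to `diameter_range`.
#' @param base named numeric baseline: `hu_shift` mean attenuation shift,
#'   `corr` mean texture correlation length; class means are base +/- half
#'   the effect.
#' @param noise_sd,texture_amp shared intensity parameters (HU).
#' @param margin_voxels empty margin added around the tumour.
#' @param survival list of arguments forwarded to [generate_survival()]
#'   (`hr`, `median_ctrl`, `censor_rate`), or `NULL` to skip endpoints.
#' @return A `phantom_cohort`: list with `subjects` (each having `id`,
#'   `volume`, `mask`, `spacing`, `label`, `os_time`, `os_event`) and
#'   `config` echoing all generation parameters.
#' @export
generate_cohort <- function(n = 103,
                            control_fraction = 72 / 103,
                            effect = c(hu = 20, corr = 1.5),
                            seed = 1L,
                            diameter_range = c(10.40, 153.33),
                            diameter_median = 59.68,
                            diameter_sdlog = 0.45,
                            base = c(hu_shift = 35, corr = 2.25),
                            noise_sd = 10,
                            texture_amp = 30,
                            margin_voxels = 6L,
                            survival = list(hr = 2.49, median_ctrl = 18,
                                            censor_rate = 0.35)) {
  stop_if_not(n >= 4, "need at least 4 subjects to stratify folds")
  stop_if_not(control_fraction > 0 && control_fraction < 1,
              "control_fraction must be in (0, 1)")
  effect <- c(hu = unname(effect["hu"]) %||% 0,
              corr = unname(effect["corr"]) %||% 0)
  n1 <- round(n * control_fraction)
  stop_if_not(n1 >= 1 && n1 <= n - 1,
              "control_fraction leaves a class empty")
  labels <- with_seed(derive_seed(seed, "labels"),
                      sample(rep(c(1L, 0L), c(n1, n - n1))))
  # truncated log-normal diameters; median anchored inside the range
  dmed <- clip(diameter_median, diameter_range[1], diameter_range[2])
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, paste0("subject", i))
    pars <- with_seed(si, {
      repeat {
        dia <- stats::rlnorm(1, log(dmed), diameter_sdlog)
        if (dia >= diameter_range[1] && dia <= diameter_range[2]) break
      }
      list(dia = dia, aspect = stats::runif(3, 0.75, 1))
    })
    lab <- labels[i]
    hu_shift <- base[["hu_shift"]] + ifelse(lab == 1, +0.5, -0.5) * effect[["hu"]]
    corr <- max(0.5,
                base[["corr"]] + ifelse(lab == 1, -0.5, +0.5) * effect[["corr"]])
    r_vox <- pars$dia / 2
    shape <- as.integer(ceiling(2 * r_vox * 1.25) + 2 * margin_voxels)
    spec <- phantom_spec(image_shape = rep(shape, 3),
                         tumor_diameter_mm = pars$dia,
                         hu_tumor_shift = hu_shift,
                         texture_corr_len = corr,
                         texture_amp = texture_amp,
                         noise_sd = noise_sd,
                         aspect = pars$aspect,
                         seed = derive_seed(si, "render"),
                         diameter_limits = diameter_range)
    ph <- generate_phantom(spec)
    subjects[[i]] <- list(id = sprintf("S%03d", i), volume = ph$volume,
                          mask = ph$mask, spacing = ph$spacing,
                          label = lab, spec = spec)
  }
  if (!is.null(survival)) {
    sv <- generate_survival(labels,
                            hr = survival$hr %||% 2.49,
                            median_ctrl = survival$median_ctrl %||% 18,
                            censor_rate = survival$censor_rate %||% 0.35,
                            seed = derive_seed(seed, "survival"))
    for (i in seq_len(n)) {
      subjects[[i]]$os_time <- sv$os_time[i]
      subjects[[i]]$os_event <- sv$os_event[i]
    }
  }
  structure(list(subjects = subjects,
                 config = list(n = n, control_fraction = control_fraction,
                               effect = effect, seed = seed,
                               diameter_range = diameter_range,
                               diameter_median = diameter_median,
                               diameter_sdlog = diameter_sdlog, base = base,
                               noise_sd = noise_sd, texture_amp = texture_amp,
                               survival = survival)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf("phantom_cohort: %d subjects (%d control / %d progression)\n",
              length(x$subjects), sum(labs == 1), sum(labs == 0)))
  invisible(x)
}

#' Class labels of a cohort
#' @param cohort a `phantom_cohort`.
#' @return integer vector of 0/1 labels named by subject id.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) s$label, integer(1)) |>
    stats::setNames(vapply(cohort$subjects, function(s) s$id, character(1)))
}

#' Clinical table of a cohort
#' @param cohort a `phantom_cohort`.
#' @return data.frame with subject_id, label, os_time, os_event.
#' @export
cohort_clinical <- function(cohort) {
  data.frame(subject_id = vapply(cohort$subjects, `[[`, character(1), "id"),
             label = vapply(cohort$subjects, `[[`, integer(1), "label"),
             os_time = vapply(cohort$subjects,
                              function(s) s$os_time %||% NA_real_, numeric(1)),
             os_event = vapply(cohort$subjects,
                               function(s) as.numeric(s$os_event %||% NA),
                               numeric(1)),
             stringsAsFactors = FALSE)
}

#' Generate class-dependent exponential survival endpoints
#'
#' Event times are exponential with median `median_ctrl` months for label-1
#' (disease-control) subjects and hazard multiplied by `hr` for label-0
#' subjects.  A single administrative censoring horizon is solved
#' numerically so that the expected censoring fraction matches
#' `censor_rate`.
#'
#' @param labels integer 0/1 vector.
#' @param hr hazard ratio (> 0) of label-0 relative to label-1 subjects.
#' @param median_ctrl median survival (months) of label-1 subjects.
#' @param censor_rate target fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return list with `os_time` (months, > 0) and `os_event` (1 = death).
#' @export
generate_survival <- function(labels, hr = 2.49, median_ctrl = 18,
                              censor_rate = 0.35, seed = 1L) {
  stop_if_not(hr > 0, "hr must be > 0")
  stop_if_not(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  n <- length(labels)
  lam1 <- log(2) / median_ctrl
  rate <- lam1 * hr^(1 - labels)
  tt <- with_seed(seed, stats::rexp(n, rate))
  if (censor_rate > 0) {
    p1 <- mean(labels == 1)
    surv_mix <- function(C) p1 * exp(-lam1 * C) +
      (1 - p1) * exp(-lam1 * hr * C) - censor_rate
    C <- stats::uniroot(surv_mix, c(1e-6, 1e6))$root
    os_time <- pmin(tt, C)
    os_event <- as.integer(tt <= C)
  } else {
    os_time <- tt
    os_event <- rep(1L, n)
  }
  list(os_time = os_time, os_event = os_event)
}
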