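# Shared small fixtures, all generated in code.

small_phantom <- function(seed = 3, diameter = 18, noise_sd = 10,
                          texture_amp = 30) {
  sp <- phantom_spec(image_shape = c(36, 36, 28), tumor_diameter_mm = diameter,
                     noise_sd = noise_sd, texture_amp = texture_amp,
                     seed = seed)
  generate_phantom(sp)
}

small_stack <- function(seed = 3, crop = 32, ...) {
  ph <- small_phantom(seed = seed, ...)
  preprocess_roi(ph$volume, ph$mask, preprocess_config(crop_size = crop))
}

# a roi_stack built directly from explicit slice/mask arrays
manual_stack <- function(slices, masks, spacing = c(1, 1, 1)) {
  structure(list(slices = slices, masks = masks,
                 slice_indices = seq_len(dim(slices)[3]),
                 window = c(center = 0, width = 1), spacing = spacing),
            class = "roi_stack")
}

# tiny cohort for pipeline-level tests
tiny_cohort <- function(n = 10, seed = 7, effect = c(hu = 25, corr = 1.5)) {
  generate_cohort(n = n, seed = seed, effect = effect,
                  diameter_range = c(10.4, 16), diameter_median = 13,
                  texture_amp = 30)
}

# feature matrix with planted informative columns
planted_matrix <- function(n = 60, p = 40, informative = 2, delta = 2,
                           seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  for (j in seq_len(informative)) x[, j] <- x[, j] + delta * y
  list(x = x, y = y)
}
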