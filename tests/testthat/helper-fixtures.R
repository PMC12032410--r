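# Shared, lazily built fixtures. Everything is generated in code; the cache
# lives for one test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Noise-free validation cohort for measurement recovery (10 s at 500 Hz).
fix_cohort_noisefree <- function(n = 50) {
  memo(paste0("nf", n), function() {
    generate_cohort(n, noise_free(population_config()), seed = 29)
  })
}

# Desk-scale study cohort: n = 200 subjects, 4 s at 500 Hz, default
# (noisy) population, seed 17.
fix_cohort_desk <- function() {
  memo("desk200", function() {
    generate_cohort(200, population_config(), seed = 17, duration = 4)
  })
}

fix_split_desk <- function() {
  memo("desk_split", function() split_cohort(fix_cohort_desk(), seed = 17))
}

# Tiny architecture for fast training tests: 2 s signals, narrow channels.
tiny_generator_config <- function(input_leads = 1, n_samples = 1000) {
  generator_config(input_leads = input_leads, n_samples = n_samples,
                   down_channels = c(6, 8, 8, 10, 10, 12),
                   up_channels = c(12, 10, 10, 8, 6),
                   kernel = 9, strides = c(2, 2, 2, 5, 5, 5))
}

tiny_discriminator_config <- function(patch_samples = 400) {
  discriminator_config(patch_samples = patch_samples,
                       channels = c(6, 8, 8, 10, 10, 12, 12),
                       kernel = 5, stride = 2)
}

# Small cohort of short records for training mechanics tests.
fix_cohort_tiny <- function(n = 18, duration = 2) {
  memo(paste0("tiny", n, "_", duration), function() {
    generate_cohort(n, population_config(), seed = 5, duration = duration)
  })
}

# Random 12-lead signal (independent rows drawn iid, limb leads derived).
random_12lead <- function(n = 400, fs = 500) {
  s8 <- matrix(rnorm(8 * n, sd = 100), 8,
               dimnames = list(c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"), NULL))
  assemble_12_lead(ecg_signal(s8, fs))
}

# Long-format marker tibble from a records x leads matrix of one feature.
markers_from_matrix <- function(m, feature = "R") {
  tibble::tibble(
    id = rep(sprintf("rec_%03d", seq_len(nrow(m))), times = ncol(m)),
    lead = rep(colnames(m), each = nrow(m)),
    feature = feature,
    value = as.vector(m))
}
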