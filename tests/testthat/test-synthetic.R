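test_that("subject sampling is deterministic and respects the configuration", {
  cfg0 <- population_config(heart_rate_sd = 0, axis_sd_deg = 0, amp_cv = 0,
                            shared_sigma = 0, rr_jitter_range = c(10, 10),
                            noise_range = c(5, 5), wander_amp_range = c(30, 30),
                            wander_freq_range = c(0.25, 0.25))
  s1 <- withr::with_seed(1, sample_subject(cfg0))
  s2 <- withr::with_seed(99, sample_subject(cfg0))
  s2$id <- s1$id
  expect_equal(s1, s2)  # zero-variance population: identical subjects

  a <- withr::with_seed(7, sample_subject(population_config()))
  b <- withr::with_seed(7, sample_subject(population_config()))
  expect_equal(a, b)  # fixed seed reproduces the draw

  expect_error(population_config(heart_rate_range = c(120, 45)))
})

test_that("empirical heart-rate mean matches the configured distribution", {
  cfg <- population_config()
  hrs <- withr::with_seed(11, replicate(1000, sample_subject(cfg)$heart_rate))
  se <- cfg$heart_rate_sd / sqrt(1000)
  # truncation at (45, 120) barely moves the mean of Normal(70, 10)
  expect_lt(abs(mean(hrs) - cfg$heart_rate_mean), 3 * se + 0.2)
  expect_true(all(hrs > cfg$heart_rate_range[1] & hrs < cfg$heart_rate_range[2]))
})

test_that("zero wave amplitudes give a flat record with timing-based fiducials", {
  p <- subject_params(wave_amplitudes = matrix(0, 5, 3,
                        dimnames = list(c("P", "Q", "R", "S", "T"), NULL)),
                      st_level = c(0, 0, 0))
  r <- generate_record(p, duration = 4, fs = 500)
  expect_true(all(r$signal$samples == 0))
  expect_gt(nrow(r$fiducials), 0)
  expect_true(all(diff(t(as.matrix(r$fiducials[1, c("p_on", "p_peak", "qrs_on",
    "r_peak", "s_peak", "qrs_off", "st_mid", "t_on", "t_peak", "t_end")]))) > 0))
})

test_that("a lone R wave peaks at its configured time in every lead", {
  t0 <- 1.4  # seconds; beat onset 0.35 s + R center 1050 ms
  amp <- matrix(0, 5, 3, dimnames = list(c("P", "Q", "R", "S", "T"), NULL))
  amp["R", ] <- c(500, 400, 600)
  m <- dipole_model(waves = tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    center_ms = c(60, 168, (t0 - 0.35) * 1000, 1450, 1500),
    sigma_ms = c(20, 6, 12, 8, 45),
    ax = c(0, 0, 500, 0, 0), ay = c(0, 0, 400, 0, 0), az = c(0, 0, 600, 0, 0)))
  p <- subject_params(heart_rate = 35, wave_amplitudes = amp, st_level = c(0, 0, 0))
  r <- generate_record(p, model = m, duration = 2, fs = 500)
  proj_amp <- as.numeric(m$projection %*% amp["R", ])
  for (li in seq_along(lead_set()$independent)) {
    v <- r$signal$samples[lead_set()$independent[li], ]
    peak <- if (proj_amp[li] >= 0) which.max(v) else which.min(v)
    expect_lte(abs(peak - (round(t0 * 500) + 1)), 1)
  }
})

test_that("measured R amplitude matches the closed-form projection", {
  p <- subject_params(heart_rate = 65, axis_azimuth = 12, axis_elevation = -8,
                      global_scale = 1.3)
  r <- generate_record(p, duration = 10, fs = 500)
  rot <- ecgrecon:::axis_rotation(p$axis_azimuth, p$axis_elevation)
  closed <- p$global_scale * (r$model$projection %*% rot %*% p$wave_amplitudes["R", ])
  mk <- measure_signal(r$signal, leads = c("I", "V3"), detect_lead = "II")
  r_i <- mk$value[mk$lead == "I" & mk$feature == "R"]
  expect_lt(abs(r_i - closed["I", 1]) / closed["I", 1], 0.01)
  r_v3 <- mk$value[mk$lead == "V3" & mk$feature == "R"]
  expect_lt(abs(r_v3 - closed["V3", 1]) / closed["V3", 1], 0.03)
})

test_that("every record satisfies the limb-lead identities exactly", {
  co <- fix_cohort_tiny()
  for (r in co[1:5]) {
    s <- r$signal$samples
    expect_equal(s["III", ], s["II", ] - s["I", ], tolerance = 1e-14)
    expect_equal(s["aVR", ], -(s["I", ] + s["II", ]) / 2, tolerance = 1e-14)
    expect_equal(s["aVL", ], s["I", ] - s["II", ] / 2, tolerance = 1e-14)
    expect_equal(s["aVF", ], s["II", ] - s["I", ] / 2, tolerance = 1e-14)
  }
})

test_that("cohort generation is reproducible and records have the stated geometry", {
  c1 <- generate_cohort(5, seed = 101, duration = 4)
  c2 <- generate_cohort(5, seed = 101, duration = 4)
  expect_identical(cohort_manifest(c1), cohort_manifest(c2))
  expect_identical(c1[[3]]$signal$samples, c2[[3]]$signal$samples)
  expect_equal(n_samples(c1[[1]]$signal), 2000)
  expect_equal(c1[[1]]$signal$sampling_rate, 500)
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_record(subject_params(), duration = 1.0001, fs = 500),
               "integral")
  # default full-length geometry: 10 s at 500 Hz = 5000 samples
  r10 <- generate_record(subject_params(), duration = 10, fs = 500)
  expect_equal(n_samples(r10$signal), 5000)
})

test_that("cross-lead amplitude coupling stays weak (near-orthogonal lead)", {
  m <- dipole_model()
  draw_r2 <- function(cfg, n) {
    a <- withr::with_seed(303, t(replicate(n, {
      p <- sample_subject(cfg, m)
      rot <- ecgrecon:::axis_rotation(p$axis_azimuth, p$axis_elevation)
      ra <- p$global_scale * (m$projection %*% rot %*% p$wave_amplitudes["R", ])
      c(ra["I", 1], ra["V3", 1])
    })))
    cor(a[, 1], a[, 2])^2
  }
  cfg <- population_config()
  expect_lt(draw_r2(cfg, 500), cfg$r2_ceiling)
  # with the shared habitus factor switched off the leads decouple almost fully
  expect_lt(draw_r2(population_config(shared_sigma = 0), 300), 0.05)
})

test_that("the 80/10/10 split reproduces the published cohort sizes", {
  sp <- split_cohort(as.list(seq_len(9514)), seed = 4)
  expect_identical(lengths(sp, use.names = FALSE), c(7611L, 951L, 952L))
  sp10 <- split_cohort(as.list(1:10), seed = 1)
  expect_identical(lengths(sp10, use.names = FALSE), c(8L, 1L, 1L))
  for (n in c(3, 17, 100)) {
    sp_n <- split_cohort(as.list(seq_len(n)), seed = 2)
    expect_equal(sum(lengths(sp_n)), n)
    expect_setequal(unlist(sp_n), seq_len(n))
  }
  expect_error(split_cohort(as.list(1:2)), "at least 3")
  expect_error(split_cohort(as.list(1:10), fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("doubling global_scale doubles amplitudes and leaves intervals alone", {
  p1 <- withr::with_seed(8, sample_subject(noise_free(population_config())))
  p2 <- p1
  p2$global_scale <- 2 * p1$global_scale
  r1 <- generate_record(p1, duration = 6)
  r2 <- generate_record(p2, duration = 6)
  m1 <- expected_markers(r1, leads = c("I", "V1", "V3", "V6"))
  m2 <- expected_markers(r2, leads = c("I", "V1", "V3", "V6"))
  amp1 <- m1$value[!is.na(m1$lead)]
  amp2 <- m2$value[!is.na(m2$lead)]
  expect_equal(amp2, 2 * amp1, tolerance = 1e-10)
  expect_equal(m1$value[is.na(m1$lead)], m2$value[is.na(m2$lead)], tolerance = 1e-10)
})
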