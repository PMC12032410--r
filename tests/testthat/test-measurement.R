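match_beats <- function(fid, truth) {
  vapply(fid$r_peak, function(t) which.min(abs(truth$r_peak - t)), integer(1))
}

test_that("flat or empty signals raise a structured detection error", {
  z <- ecg_signal(matrix(0, 2, 3000, dimnames = list(c("I", "II"), NULL)), 500)
  expect_error(detect_r_peaks(z), "no beats")
  short <- ecg_signal(matrix(rnorm(200), 1, 200, dimnames = list("II", NULL)), 500)
  expect_error(detect_r_peaks(short), "2 s")
})

test_that("noise-free records are delineated to within samples of ground truth", {
  co <- fix_cohort_noisefree(50)
  for (r in co[1:6]) {
    rp <- detect_r_peaks(r$signal, "II")
    truth <- r$fiducials
    # every ground-truth beat recovered to +/- 1 sample
    det_t <- (rp - 1) / 500
    for (tt in truth$r_peak) expect_lte(min(abs(det_t - tt)), 1 / 500 + 1e-9)
    fid <- delineate(r$signal, rp, "II")
    m <- match_beats(fid, truth)
    for (cn in c("p_on", "qrs_on", "s_peak", "qrs_off", "t_on", "t_peak", "t_end")) {
      expect_lt(max(abs(fid[[cn]] - truth[[cn]][m])), 2.5 / 500)
    }
  }
})

test_that("beats at the record edge are flagged and skipped, not measured", {
  r <- fix_cohort_noisefree(50)[[1]]
  rp <- detect_r_peaks(r$signal, "II")
  # truncate so the first beat falls within the edge margin
  cut <- rp[1] - 30L
  s2 <- ecg_signal(r$signal$samples[, cut:n_samples(r$signal)], 500)
  rp2 <- detect_r_peaks(s2, "II")
  fid2 <- delineate(s2, rp2, "II")
  expect_gte(attr(fid2, "skipped_beats"), 1L)
  expect_lt(nrow(fid2), length(rp2))
  expect_gt(min(fid2$r_peak), 0.3)
})

test_that("delineation is equivariant under time shifts", {
  r <- fix_cohort_noisefree(50)[[2]]
  k <- 137L
  s1 <- r$signal
  s2 <- ecg_signal(s1$samples[, (k + 1):n_samples(s1)], 500)
  f1 <- delineate(s1, detect_r_peaks(s1, "II"), "II")
  f2 <- delineate(s2, detect_r_peaks(s2, "II"), "II")
  m <- match_beats(f2, dplyr::mutate(f1, r_peak = r_peak - k / 500))
  for (cn in c("p_on", "qrs_on", "r_peak", "qrs_off", "t_peak", "t_end")) {
    expect_equal(f2[[cn]], f1[[cn]][m] - k / 500, tolerance = 1e-8)
  }
})

test_that("amplitude markers scale linearly and intervals are scale-invariant", {
  r <- fix_cohort_noisefree(50)[[3]]
  rp <- detect_r_peaks(r$signal, "II")
  fid <- delineate(r$signal, rp, "II")
  m1 <- measure_markers(r$signal, fid, leads = c("V1", "V3"), id = "a")
  doubled <- ecg_signal(2 * r$signal$samples, 500)
  m2 <- measure_markers(doubled, fid, leads = c("V1", "V3"), id = "a")
  amp <- !is.na(m1$lead)
  expect_equal(m2$value[amp], 2 * m1$value[amp], tolerance = 1e-12)
  expect_equal(m2$value[!amp], m1$value[!amp])
})

test_that("a 60 bpm jitter-free subject measures RR = 1000 ms exactly", {
  p <- subject_params(heart_rate = 60)
  r <- generate_record(p, duration = 10, fs = 500)
  mk <- measure_signal(r$signal, leads = "V3", detect_lead = "II")
  expect_identical(mk$value[mk$feature == "RR"], 1000)
})

test_that("measured markers match the generator closed forms (sampled cohort)", {
  co <- fix_cohort_noisefree(50)
  for (r in co[1:5]) {
    mk <- measure_signal(r$signal, leads = c("I", "V1", "V3", "V6"), detect_lead = "II",
                         id = r$id)
    em <- expected_markers(r, leads = c("I", "V1", "V3", "V6"))
    j <- dplyr::inner_join(mk, em, by = c("id", "lead", "feature"),
                           suffix = c("_m", "_e"))
    amp <- j[!is.na(j$lead), ]
    # 2% relative, with a 10 uV absolute floor for near-zero markers
    expect_true(all(abs(amp$value_m - amp$value_e) <
                      pmax(0.02 * abs(amp$value_e), 10)))
    ints <- j[is.na(j$lead), ]
    expect_lt(max(abs(ints$value_m - ints$value_e)), 4)
  }
})

test_that("beat recall is perfect on the default-noise study cohort", {
  co <- fix_cohort_desk()
  worst <- 0
  for (r in co) {
    rp <- detect_r_peaks(r$signal, "II")
    det_t <- (rp - 1) / 500
    # a beat counts as recalled when a detection lands inside its
    # ground-truth QRS complex, within a 20 ms margin
    errs <- vapply(seq_len(nrow(r$fiducials)), function(b) {
      lo <- r$fiducials$qrs_on[b]; hi <- r$fiducials$qrs_off[b]
      d <- det_t[which.min(abs(det_t - (lo + hi) / 2))]
      max(0, lo - d, d - hi)
    }, numeric(1))
    worst <- max(worst, max(errs))
  }
  expect_lt(worst, 0.020)
})

test_that("marker tables round-trip through delimited text", {
  co <- fix_cohort_tiny()
  mk <- measure_cohort(co[1:3], leads = c("V1", "V3"), detect_lead = "II")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(mk, path)
  back <- read_marker_table(path)
  j <- dplyr::inner_join(mk, back, by = c("id", "lead", "feature"))
  expect_equal(nrow(j), nrow(mk))
  expect_equal(j$value.x, j$value.y, tolerance = 1e-9)
})

test_that("missing fiducial windows yield NA markers, never silent zeros", {
  r <- fix_cohort_noisefree(50)[[4]]
  fid <- r$fiducials[1, ]
  fid$t_end <- n_samples(r$signal) / 500 + 1  # beyond the record
  mk <- measure_markers(r$signal, fid, leads = "V3", id = "x")
  expect_true(all(is.na(mk$value[!is.na(mk$lead)])))
})
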