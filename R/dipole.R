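#' Dipole model of the normal 12-lead ECG
#'
#' The heart's net electrical activity is modelled as a time-varying 3D dipole
#' vector \eqn{D(t)}: each wave (P, Q, R, S, T) contributes a Gaussian bump per
#' spatial axis, and the ST segment contributes an explicit plateau between the
#' J point and T onset so that ST-level markers have nonzero targets. The
#' eight independent leads are fixed linear projections of \eqn{D(t)}
#' (a Dower-like geometry): leads I and II lie in the frontal plane (zero z
#' component) while the precordial rows rotate into the z axis, with V3 almost
#' orthogonal to lead I. The limb leads III, aVR, aVL, aVF are always derived
#' via [derive_limb_leads()], never simulated independently.
#'
#' Timing defaults (ms from beat onset) describe a normal adult beat; the T
#' wave is rate-adapted by scaling its latency and width from the J anchor by
#' \eqn{\sqrt{RR / 857}} so beats remain well formed across the supported
#' heart-rate range.
#'
#' @param waves Data frame with columns `wave`, `center_ms`, `sigma_ms`,
#'   `ax`, `ay`, `az` (baseline amplitude of the wave along each dipole axis,
#'   in \eqn{\mu V}). Row order must keep centers increasing P < Q < R < S < T.
#' @param st_level Length-3 numeric: ST plateau level per axis (\eqn{\mu V}).
#' @param projection 8 x 3 numeric matrix mapping the dipole to the
#'   independent leads (rows I, II, V1..V6); rows are normalised to unit
#'   length. Rows I and II must have zero z component.
#' @param fiducial_lead Lead used for ground-truth fiducial timing
#'   (default `"II"`).
#' @return A list of class `dipole_model`.
#' @export
dipole_model <- function(waves = NULL, st_level = c(20, 10, 60),
                         projection = NULL, fiducial_lead = "II") {
  if (is.null(waves)) {
    waves <- tibble::tibble(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(60, 168, 190, 218, 450),
      sigma_ms = c(20, 6, 12, 8, 45),
      ax = c(60, -100, 800, -300, 300),
      ay = c(40, -50, 1200, -200, 200),
      az = c(10, -40, 900, -1000, 500)
    )
  }
  waves <- tibble::as_tibble(waves)
  stopifnot(all(c("wave", "center_ms", "sigma_ms", "ax", "ay", "az") %in% names(waves)))
  if (is.unsorted(waves$center_ms, strictly = TRUE)) {
    stop("wave centers must be strictly increasing within a beat")
  }
  if (is.null(projection)) {
    projection <- rbind(
      I  = c(1.0, 0.0, 0.0),
      II = c(0.5, 0.866, 0.0),
      V1 = c(-0.5, 0.05, 0.86),
      V2 = c(-0.2, 0.10, 0.97),
      V3 = c(0.1, 0.10, 0.99),
      V4 = c(0.4, 0.20, 0.89),
      V5 = c(0.7, 0.20, 0.68),
      V6 = c(0.9, 0.10, 0.40)
    )
  }
  projection <- as.matrix(projection)
  stopifnot(nrow(projection) == 8L, ncol(projection) == 3L)
  if (is.null(rownames(projection))) rownames(projection) <- LEADS_INDEPENDENT
  projection <- projection / sqrt(rowSums(projection^2))
  if (any(abs(projection[c("I", "II"), 3]) > 1e-12)) {
    stop("projection rows I and II must lie in the frontal plane (zero z)")
  }
  structure(list(
    waves = waves,
    st_level = as.numeric(st_level),
    projection = projection,
    fiducial_lead = fiducial_lead,
    # ST plateau geometry (ms from beat onset): raised-cosine up-ramp after the
    # S wave, hold through the ST segment, down-ramp starting at T onset.
    st_ramp_up = c(240, 270),
    st_ramp_down_ms = 60,
    # reference RR (ms) for T-wave rate adaptation and its J-point anchor
    rr_ref_ms = 857,
    t_anchor_ms = 235
  ), class = "dipole_model")
}

# Fraction-of-peak threshold shared by the ground-truth fiducial conventions
# and the sample-domain delineator, and the persistence run length (ms) a
# signal must stay below threshold for an on/offset to be accepted.
FID_THRESHOLD_FRAC <- 0.05
FID_PERSIST_MS <- 8

#' Subject parameters for the dipole generator
#'
#' Bundles everything subject-specific: heart rate and RR jitter, electrical
#' axis rotation (azimuth about z, elevation about y), per-wave per-axis
#' amplitudes (already in \eqn{\mu V}, before rotation), ST plateau level, a
#' global habitus scale, and noise levels.
#'
#' @param heart_rate Beats per minute, in (30, 200).
#' @param rr_jitter_sd Per-beat RR jitter SD in ms.
#' @param axis_azimuth,axis_elevation Axis rotation in degrees.
#' @param wave_amplitudes Numeric matrix `n_waves x 3` (columns x, y, z) in
#'   \eqn{\mu V}; rows named after the model's waves.
#' @param st_level Length-3 ST plateau level per axis (\eqn{\mu V}).
#' @param global_scale Positive unitless scale applied to all amplitudes.
#' @param noise_sd Additive white noise SD per lead (\eqn{\mu V}).
#' @param baseline_wander_amp,baseline_wander_freq Sinusoidal baseline wander
#'   amplitude (\eqn{\mu V}) and frequency (Hz).
#' @param id Subject identifier.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(heart_rate = 70, rr_jitter_sd = 0,
                           axis_azimuth = 0, axis_elevation = 0,
                           wave_amplitudes = NULL, st_level = c(20, 10, 60),
                           global_scale = 1, noise_sd = 0,
                           baseline_wander_amp = 0, baseline_wander_freq = 0.25,
                           id = "subj_000") {
  if (heart_rate <= 30 || heart_rate >= 200) stop("heart_rate must be in (30, 200) bpm")
  if (global_scale <= 0) stop("global_scale must be positive")
  if (noise_sd < 0 || baseline_wander_amp < 0) stop("noise levels must be >= 0")
  if (is.null(wave_amplitudes)) {
    m <- dipole_model()
    wave_amplitudes <- as.matrix(m$waves[, c("ax", "ay", "az")])
    rownames(wave_amplitudes) <- m$waves$wave
  }
  structure(list(heart_rate = heart_rate, rr_jitter_sd = rr_jitter_sd,
                 axis_azimuth = axis_azimuth, axis_elevation = axis_elevation,
                 wave_amplitudes = as.matrix(wave_amplitudes),
                 st_level = as.numeric(st_level),
                 global_scale = global_scale, noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 id = id),
            class = "subject_params")
}

axis_rotation <- function(azimuth_deg, elevation_deg) {
  a <- azimuth_deg * pi / 180
  e <- elevation_deg * pi / 180
  rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  ry <- rbind(c(cos(e), 0, sin(e)), c(0, 1, 0), c(-sin(e), 0, cos(e)))
  rz %*% ry
}

# Per-beat onset times (s) covering [0, duration]; uses the current RNG for
# jitter. Beats start at 0.35 s (so the first beat clears the delineator's
# edge margin) and extend one beat past the end so partial waveforms at the
# record edge are still rendered.
beat_onsets <- function(params, duration) {
  rr_mean <- 60 / params$heart_rate
  onsets <- 0.35
  repeat {
    jit <- if (params$rr_jitter_sd > 0) stats::rnorm(1, 0, params$rr_jitter_sd / 1000) else 0
    rr <- max(0.3, rr_mean + jit)
    nxt <- onsets[length(onsets)] + rr
    onsets <- c(onsets, nxt)
    if (nxt > duration) break
  }
  onsets
}

# T-wave rate adaptation: scale latency from the J anchor and width by
# sqrt(RR / RR_ref).
t_timing <- function(model, rr_ms) {
  f <- sqrt(rr_ms / model$rr_ref_ms)
  tw <- model$waves[model$waves$wave == "T", ]
  list(center = model$t_anchor_ms + (tw$center_ms - model$t_anchor_ms) * f,
       sigma = tw$sigma_ms * f, f = f)
}

# Continuous noise-free waveform of the 8 independent leads, evaluated at
# arbitrary times (s). `onsets` are beat-start times (s). Returns a matrix
# 8 x length(times) in uV. This is the generator's closed form: fiducials,
# expected markers, and the sampled records all come from this one function.
analytic_waveform <- function(params, model, times, onsets) {
  rot <- axis_rotation(params$axis_azimuth, params$axis_elevation)
  amps <- params$global_scale * (rot %*% t(params$wave_amplitudes))  # 3 x nwaves
  st_vec <- params$global_scale * as.numeric(rot %*% params$st_level)
  lead_amp <- model$projection %*% amps                              # 8 x nwaves
  lead_st <- as.numeric(model$projection %*% st_vec)                 # 8
  out <- matrix(0, 8, length(times))
  n_on <- length(onsets)
  rr_ms <- c(diff(onsets), if (n_on > 1) diff(onsets)[n_on - 1] else model$rr_ref_ms / 1000) * 1000
  waves <- model$waves
  for (b in seq_len(n_on)) {
    tb <- (times - onsets[b]) * 1000  # ms within beat
    active <- which(tb > -50 & tb < rr_ms[b] + 250)
    if (!length(active)) next
    tb <- tb[active]
    tt <- t_timing(model, rr_ms[b])
    for (w in seq_len(nrow(waves))) {
      if (waves$wave[w] == "T") {
        centre <- tt$center; sigma <- tt$sigma
      } else {
        centre <- waves$center_ms[w]; sigma <- waves$sigma_ms[w]
      }
      bump <- exp(-((tb - centre)^2) / (2 * sigma^2))
      out[, active] <- out[, active] + outer(lead_amp[, w], bump)
    }
    # ST plateau: cosine up-ramp, hold, cosine down-ramp from T onset
    t_on <- tt$center - sqrt(2 * log(1 / FID_THRESHOLD_FRAC)) * tt$sigma
    ramp <- st_window(tb, model$st_ramp_up, t_on, model$st_ramp_down_ms * tt$f)
    if (any(ramp > 0)) out[, active] <- out[, active] + outer(lead_st, ramp)
  }
  rownames(out) <- rownames(model$projection)
  out
}

st_window <- function(tb, ramp_up, t_down_start, down_len) {
  w <- numeric(length(tb))
  up0 <- ramp_up[1]; up1 <- ramp_up[2]
  i <- tb > up0 & tb < up1
  w[i] <- 0.5 * (1 - cos(pi * (tb[i] - up0) / (up1 - up0)))
  i <- tb >= up1 & tb <= t_down_start
  w[i] <- 1
  i <- tb > t_down_start & tb < t_down_start + down_len
  w[i] <- 0.5 * (1 + cos(pi * (tb[i] - t_down_start) / down_len))
  w
}

# --- ground-truth fiducials -------------------------------------------------

# Earliest local maximum within `frac` of the window maximum; falls back to
# the plain argmax when no interior local maximum exists.
pick_r_peak <- function(vw, frac = 0.75) {
  n <- length(vw)
  if (n < 3L) return(which.max(vw))
  interior <- 2:(n - 1L)
  loc <- interior[vw[interior] >= vw[interior - 1L] & vw[interior] > vw[interior + 1L]]
  eligible <- loc[vw[loc] >= frac * max(vw)]
  if (!length(eligible)) which.max(vw) else min(eligible)
}

# Shared on/offset rule: scanning away from `from_idx`, accept the first index
# where |v| stays below `thr` for at least `persist` consecutive fine-grid
# steps. Returns the boundary index (last above-threshold sample + direction).
scan_offset <- function(v, from_idx, thr, step, persist_n) {
  idx <- from_idx
  n <- length(v)
  run <- 0L
  while (idx + step >= 1 && idx + step <= n) {
    idx <- idx + step
    if (abs(v[idx]) < thr) {
      run <- run + 1L
      if (run >= persist_n) return(idx - step * (persist_n - 1L))
    } else run <- 0L
  }
  NA_integer_
}

# Ground-truth fiducials for one beat, from the continuous model on a fine
# grid (dt_ms resolution). QRS landmarks use the designated lead; P- and
# T-wave landmarks use the root-mean-square composite of the 8 independent
# leads (robust to subjects whose rotation cancels those waves in any single
# lead). Times returned in seconds from record start; NULL when the beat
# extends beyond `duration`.
beat_fiducials <- function(params, model, onsets, beat, duration, dt_ms = 0.2) {
  onset <- onsets[beat]
  rr_ms <- if (beat < length(onsets)) (onsets[beat + 1] - onset) * 1000 else model$rr_ref_ms
  tt <- t_timing(model, rr_ms)
  t_end_max <- tt$center + 4 * tt$sigma
  grid_ms <- seq(0, min(t_end_max, rr_ms + 200), by = dt_ms)
  times <- onset + grid_ms / 1000
  if (max(times) > duration) return(NULL)
  wf <- analytic_waveform(params, model, times, onsets)
  vm <- sqrt(colMeans(wf^2))  # polarity-free composite of the 8 leads
  w <- model$waves
  persist_n <- max(2L, round(FID_PERSIST_MS / dt_ms))
  win <- function(lo, hi) which(grid_ms >= lo & grid_ms <= hi)

  ctr <- function(wave) w$center_ms[w$wave == wave]
  sg <- function(wave) w$sigma_ms[w$wave == wave]

  # R peak convention: earliest composite local maximum within 75% of the
  # QRS window maximum (robust to near-ties between the R and S deflections)
  i_r <- win(ctr("Q") - 3 * sg("Q"), ctr("S") + 3 * sg("S"))
  r_peak <- i_r[pick_r_peak(vm[i_r])]
  if (max(vm) < 1e-9) {
    # flat (zero-amplitude) waveform: fall back to nominal model timing
    kq <- sqrt(2 * log(1 / FID_THRESHOLD_FRAC))
    ms <- function(x) onset + x / 1000
    qrs_off_s <- ms(ctr("S") + kq * sg("S"))
    t_on_s <- ms(tt$center - kq * tt$sigma)
    return(tibble::tibble(
      beat = beat,
      p_on = ms(ctr("P") - kq * sg("P")), p_peak = ms(ctr("P")),
      qrs_on = ms(ctr("Q") - kq * sg("Q")), r_peak = ms(ctr("R")),
      s_peak = ms(ctr("S")), qrs_off = qrs_off_s,
      st_mid = (qrs_off_s + t_on_s) / 2,
      t_on = t_on_s, t_peak = ms(tt$center), t_end = ms(tt$center + 2 * tt$sigma)))
  }
  i_s <- win(grid_ms[r_peak] + 10, grid_ms[r_peak] + 60)
  s_peak <- i_s[which.max(vm[i_s])]
  i_p <- win(ctr("P") - 3 * sg("P"), ctr("P") + 3 * sg("P"))
  p_peak <- i_p[which.max(vm[i_p])]

  thr_qrs <- FID_THRESHOLD_FRAC * vm[r_peak]
  qrs_on <- scan_offset(vm, r_peak, thr_qrs, -1L, persist_n)
  qrs_off <- scan_offset(vm, s_peak, thr_qrs, +1L, persist_n)
  thr_p <- FID_THRESHOLD_FRAC * vm[p_peak]
  p_on <- scan_offset(vm, p_peak, thr_p, -1L, persist_n)

  i_t <- win(tt$center - 3 * tt$sigma, tt$center + 3.5 * tt$sigma)
  t_peak <- i_t[which.max(vm[i_t])]
  # tangent method: steepest point of the composite T downslope extrapolated
  # to baseline
  i_dn <- t_peak:max(i_t)
  dv <- diff(vm[i_dn]) / (dt_ms / 1000)
  m <- which.max(abs(dv))
  t_end_s <- times[i_dn[m]] + abs(vm[i_dn[m]]) / abs(dv[m])
  t_on_s <- times[t_peak] - sqrt(2 * log(1 / FID_THRESHOLD_FRAC)) *
    (t_end_s - times[t_peak]) / 2

  if (anyNA(c(qrs_on, qrs_off, p_on))) return(NULL)
  st_mid_s <- (times[qrs_off] + t_on_s) / 2
  tibble::tibble(
    beat = beat,
    p_on = times[p_on], p_peak = times[p_peak],
    qrs_on = times[qrs_on], r_peak = times[r_peak], s_peak = times[s_peak],
    qrs_off = times[qrs_off],
    st_mid = st_mid_s,
    t_on = t_on_s, t_peak = times[t_peak], t_end = t_end_s
  )
}
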