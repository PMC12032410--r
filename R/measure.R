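#' R-peak detection
#'
#' Pan-Tompkins-style detector: band-pass (5--25 Hz Butterworth, zero-phase),
#' differentiate, square, integrate over a 150 ms window, threshold at a
#' fraction of the integrated maximum with a 200 ms refractory period, then
#' refine each beat to the shared R-anchor convention on the landmark
#' composite. Detection runs on a single designated lead (default II).
#'
#' @param signal An [ecg_signal] of at least 2 s.
#' @param lead Lead to detect on.
#' @param composite_leads Leads forming the RMS composite used to place the
#'   R anchor (default: the 8 independent leads; evaluations exclude the
#'   input leads so real and reconstructed records are measured by the same
#'   information).
#' @return Integer vector of strictly increasing R-peak sample indices.
#' @export
detect_r_peaks <- function(signal, lead = "II",
                           composite_leads = LEADS_INDEPENDENT) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$sampling_rate
  x <- signal$samples[lead, ]
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  if (max(x) - min(x) < 1e-9) stop("no beats detected (flat signal)")
  bp <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf))^2
  w <- max(3L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * max(integ)
  if (thr <= 0) stop("no beats detected (flat signal)")
  above <- integ > thr
  if (!any(above)) stop("no beats detected")
  # local maxima of the integrated signal above threshold
  cand <- which(above & integ >= dplyr::lag(integ, default = 0) &
                  integ > dplyr::lead(integ, default = 0))
  # enforce refractory period, keeping the larger peak
  cand <- cand[order(-integ[cand])]
  keep <- integer(0)
  refr <- round(0.200 * fs)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # refine each candidate with the shared R-peak convention: earliest local
  # maximum of the (lightly smoothed) 8-lead RMS composite within 75% of the
  # window maximum, snapped to the exact composite maximum. Baselines are
  # estimated per candidate from the window just before it, so slow baseline
  # wander cannot tilt the R-vs-S comparison.
  has8 <- all(composite_leads %in% rownames(signal$samples)) &&
    length(composite_leads) > 1L
  M <- if (has8) signal$samples[composite_leads, , drop = FALSE] else NULL
  sm_w <- max(3L, round(0.010 * fs))
  half <- round(0.080 * fs)
  n <- length(x)
  r <- vapply(keep, function(i) {
    win <- max(1L, i - half):min(n, i + half)
    bwin <- max(1L, i - round(0.30 * fs)):max(1L, i - round(0.15 * fs))
    if (has8) {
      basev <- apply(M[, bwin, drop = FALSE], 1, stats::median)
      vref <- sqrt(colMeans((M[, win, drop = FALSE] - basev)^2))
    } else {
      vref <- abs(x[win] - stats::median(x[bwin]))
    }
    xs <- as.numeric(stats::filter(vref, rep(1 / sm_w, sm_w), sides = 2))
    xs[is.na(xs)] <- vref[is.na(xs)]
    # candidate maxima from the smoothed trace, heights judged on the raw
    # composite so smoothing does not tilt the 75% comparison
    nn <- length(xs)
    interior <- 2:(nn - 1L)
    loc <- interior[xs[interior] >= xs[interior - 1L] & xs[interior] > xs[interior + 1L]]
    if (!length(loc)) loc <- which.max(xs)
    ref <- vapply(loc, function(s) {
      fine <- max(1L, s - 3L):min(nn, s + 3L)
      fine[which.max(vref[fine])]
    }, integer(1))
    ref <- unique(ref)
    # parabolic interpolation of each peak height, so the 75% comparison
    # matches the continuous waveform rather than the sample grid
    h <- vapply(ref, function(p) {
      if (p <= 1L || p >= nn) return(vref[p])
      a <- (vref[p - 1L] + vref[p + 1L]) / 2 - vref[p]
      b <- (vref[p + 1L] - vref[p - 1L]) / 2
      if (a < 0) vref[p] - b^2 / (4 * a) else vref[p]
    }, numeric(1))
    win[min(ref[h >= 0.75 * max(h)])]
  }, integer(1))
  r <- sort(unique(r))
  r[c(TRUE, diff(r) >= refr)]
}

#' Delineate beats around detected R peaks
#'
#' Applies the package's fiducial conventions in the sample domain: QRS and P
#' on/offsets are the first points where the absolute baseline-corrected
#' signal stays below 5\% of the relevant peak amplitude for at least 8 ms;
#' the T peak is the largest post-J excursion; T end comes from the tangent
#' method (steepest downslope extrapolated to baseline); T onset is placed
#' symmetrically from the T peak; the ST midpoint is halfway between the J
#' point and T onset. Beats too close to the record edge are skipped and
#' counted in the `skipped_beats` attribute.
#'
#' @param signal An [ecg_signal].
#' @param r_peaks Integer R-peak sample indices (from [detect_r_peaks()]).
#' @param lead Lead to delineate on (same convention as detection).
#' @param composite_leads Leads forming the landmark RMS composite.
#' @return A tibble of per-beat fiducial times in seconds with columns
#'   matching the generator's ground truth (`p_on`, `p_peak`, `qrs_on`,
#'   `r_peak`, `s_peak`, `qrs_off`, `st_mid`, `t_on`, `t_peak`, `t_end`).
#' @export
delineate <- function(signal, r_peaks, lead = "II",
                      composite_leads = LEADS_INDEPENDENT) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$sampling_rate
  x <- signal$samples[lead, ]
  n <- length(x)
  smp <- function(sec) max(1L, round(sec * fs))
  persist_n <- max(2L, round(FID_PERSIST_MS / 1000 * fs))
  has8 <- all(composite_leads %in% rownames(signal$samples)) &&
    length(composite_leads) > 1L
  out <- vector("list", length(r_peaks))
  skipped <- 0L
  for (b in seq_along(r_peaks)) {
    iR <- r_peaks[b]
    if (iR - smp(0.30) < 1L || iR + smp(0.55) > n) {
      skipped <- skipped + 1L
      next
    }
    base_win <- (iR - smp(0.30)):(iR - smp(0.15))
    # T window scales with the local RR interval
    rr_s <- if (b < length(r_peaks)) (r_peaks[b + 1] - iR) / fs
            else if (b > 1) (iR - r_peaks[b - 1]) / fs else 0.857
    t_hi <- min(n, iR + smp(min(0.55, 0.75 * rr_s)))
    # all landmarks live on the baseline-corrected 8-lead RMS composite
    # (floor-subtracted so the white-noise floor does not bias thresholds)
    w_lo <- max(1L, iR - smp(0.30))
    if (has8) {
      basev <- apply(signal$samples[composite_leads, base_win, drop = FALSE],
                     1, stats::median)
      vm <- sqrt(colMeans((signal$samples[composite_leads, w_lo:t_hi,
                                          drop = FALSE] - basev)^2))
    } else {
      vm <- abs(signal$samples[lead, w_lo:t_hi] - stats::median(x[base_win]))
    }
    vm <- vm - min(vm)
    vmf <- function(idx) vm[idx - w_lo + 1L]
    thr_qrs <- FID_THRESHOLD_FRAC * vmf(iR)
    qrs_on <- scan_offset(vm, iR - w_lo + 1L, thr_qrs, -1L, persist_n)
    qrs_on <- if (is.na(qrs_on)) NA_integer_ else qrs_on + w_lo - 1L
    i_s <- (iR + smp(0.010)):(iR + smp(0.060))
    s_peak <- i_s[which.max(vmf(i_s))]
    qrs_off <- scan_offset(vm, s_peak - w_lo + 1L, thr_qrs, +1L, persist_n)
    qrs_off <- if (is.na(qrs_off)) NA_integer_ else qrs_off + w_lo - 1L
    if (anyNA(c(qrs_on, qrs_off)) || qrs_on < iR - smp(0.12)) {
      skipped <- skipped + 1L
      next
    }
    i_p <- max(w_lo, qrs_on - smp(0.15)):(qrs_on - smp(0.02))
    p_seg <- vmf(w_lo:max(i_p))
    p_seg <- p_seg - min(p_seg)
    p_peak <- i_p[which.max(vmf(i_p))]
    p_on <- scan_offset(p_seg, p_peak - w_lo + 1L,
                        FID_THRESHOLD_FRAC * p_seg[p_peak - w_lo + 1L],
                        -1L, persist_n)
    p_on <- if (is.na(p_on)) i_p[1] else p_on + w_lo - 1L
    i_t <- (qrs_off + smp(0.060)):t_hi
    vt <- vmf(i_t)
    vt <- vt - min(vt)
    sm <- stats::filter(vt, rep(1 / 3, 3), sides = 2)
    vt[!is.na(sm)] <- sm[!is.na(sm)]
    t_peak <- i_t[which.max(vt)]
    i_dn <- which(i_t >= t_peak)
    if (length(i_dn) < 3L) {
      skipped <- skipped + 1L
      next
    }
    dv <- diff(vt[i_dn])
    m <- which.max(abs(dv))
    t_end <- i_t[i_dn[m]] + abs(vt[i_dn[m]]) / abs(dv[m])
    t_on <- t_peak - sqrt(2 * log(1 / FID_THRESHOLD_FRAC)) * (t_end - t_peak) / 2
    st_mid_s <- ((qrs_off - 1) / fs + (t_on - 1) / fs) / 2
    out[[b]] <- tibble::tibble(
      beat = b,
      p_on = (p_on - 1) / fs, p_peak = (p_peak - 1) / fs,
      qrs_on = (qrs_on - 1) / fs, r_peak = (iR - 1) / fs,
      s_peak = (s_peak - 1) / fs, qrs_off = (qrs_off - 1) / fs,
      st_mid = st_mid_s,
      t_on = (t_on - 1) / fs, t_peak = (t_peak - 1) / fs,
      t_end = (t_end - 1) / fs
    )
  }
  fid <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  attr(fid, "skipped_beats") <- skipped
  fid
}

#' Measure amplitude and interval markers
#'
#' Computes the marker set the evaluation consumes, per lead: R, S, T and STM
#' amplitudes in \eqn{\mu V} relative to the PR-segment median baseline (R and
#' S reported as positive magnitudes, T signed), and the global intervals RR,
#' QT, PR and QRS duration in ms. Per-record values are medians across beats.
#' Markers whose measurement window is unavailable are returned as `NA`,
#' never silently zero. This function is deterministic.
#'
#' @param signal An [ecg_signal].
#' @param fiducials Per-beat fiducial tibble in seconds ([delineate()] output
#'   or a record's ground truth).
#' @param leads Leads for which amplitude markers are measured.
#' @param id Record identifier attached to the output.
#' @return A tibble with columns `id`, `lead`, `feature`, `value`; interval
#'   rows have `lead = NA`.
#' @export
measure_markers <- function(signal, fiducials, leads = c("V1", "V2", "V3", "V6"),
                            id = "record") {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$sampling_rate
  n <- n_samples(signal)
  leads <- intersect(leads, lead_names(signal))
  idx <- function(sec) pmin(n, pmax(1L, round(sec * fs) + 1L))
  amp <- vector("list", nrow(fiducials))
  for (b in seq_len(nrow(fiducials))) {
    f <- fiducials[b, ]
    pr_win <- idx(f$qrs_on - 0.045):idx(f$qrs_on - 0.005)
    qrs_win <- idx(f$qrs_on):idx(f$qrs_off)
    s_win <- idx(f$qrs_on):idx(f$qrs_off + 0.010)
    t_win <- idx(f$t_on - 0.020):idx(f$t_end)
    ok <- f$qrs_on - 0.045 >= 0 && f$t_end <= (n - 1) / fs
    amp[[b]] <- purrr::map_dfr(leads, function(ld) {
      v <- signal$samples[ld, ]
      base <- stats::median(v[pr_win])
      t_rel <- v[t_win] - base
      tibble::tibble(
        lead = ld,
        feature = c("R", "S", "T", "STM"),
        value = if (ok) c(max(v[qrs_win]) - base,
                          base - min(v[s_win]),
                          t_rel[which.max(abs(t_rel))],
                          v[idx(f$st_mid)] - base)
                else NA_real_
      )
    })
  }
  amp_tbl <- dplyr::bind_rows(amp) |>
    dplyr::group_by(.data$lead, .data$feature) |>
    dplyr::summarise(value = stats::median(.data$value, na.rm = TRUE), .groups = "drop")
  ints <- tibble::tibble(
    lead = NA_character_,
    feature = c("RR", "QT", "PR", "QRS"),
    value = c(if (nrow(fiducials) > 1) stats::median(diff(fiducials$r_peak)) * 1000 else NA_real_,
              stats::median(fiducials$t_end - fiducials$qrs_on) * 1000,
              stats::median(fiducials$qrs_on - fiducials$p_on) * 1000,
              stats::median(fiducials$qrs_off - fiducials$qrs_on) * 1000)
  )
  dplyr::bind_rows(amp_tbl, ints) |>
    dplyr::mutate(id = id, .before = 1)
}

#' Full measurement of one signal
#'
#' Convenience wrapper chaining [detect_r_peaks()], [delineate()] and
#' [measure_markers()].
#'
#' @inheritParams measure_markers
#' @inheritParams detect_r_peaks
#' @param detect_lead Lead used for detection and delineation.
#' @param composite_leads Leads forming the landmark RMS composite.
#' @return A marker tibble as from [measure_markers()].
#' @export
measure_signal <- function(signal, leads = c("V1", "V2", "V3", "V6"),
                           detect_lead = "II", id = "record",
                           composite_leads = LEADS_INDEPENDENT) {
  r <- detect_r_peaks(signal, lead = detect_lead, composite_leads = composite_leads)
  fid <- delineate(signal, r, lead = detect_lead, composite_leads = composite_leads)
  if (!nrow(fid)) stop("no measurable beats in record ", id)
  measure_markers(signal, fid, leads = leads, id = id)
}

#' Measure every record of a cohort (or list of signals)
#'
#' @param records An `ecg_cohort`, list of `ecg_record`, or named list of
#'   [ecg_signal] objects.
#' @inheritParams measure_signal
#' @return A long marker tibble with one row per record, lead and feature.
#'   Records in which no beat can be measured are dropped with a warning
#'   naming them.
#' @export
measure_cohort <- function(records, leads = c("V1", "V2", "V3", "V6"),
                           detect_lead = "II",
                           composite_leads = LEADS_INDEPENDENT) {
  purrr::imap_dfr(records, function(r, nm) {
    sig <- if (inherits(r, "ecg_record")) r$signal else r
    id <- if (inherits(r, "ecg_record")) r$id
          else if (is.character(nm)) nm else sprintf("rec_%05d", nm)
    tryCatch(
      measure_signal(sig, leads = leads, detect_lead = detect_lead, id = id,
                     composite_leads = composite_leads),
      error = function(e) {
        warning(sprintf("record %s not measurable: %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  })
}

#' Write / read a marker table as delimited text
#'
#' One row per record; amplitude columns are named `<feature>_<lead>` (in
#' \eqn{\mu V}) and interval columns `RR`, `QT`, `PR`, `QRS` (ms).
#'
#' @param markers Long marker tibble ([measure_cohort()] output).
#' @param path File path.
#' @return `write_marker_table()` returns `path` invisibly;
#'   `read_marker_table()` returns the long marker tibble.
#' @export
write_marker_table <- function(markers, path) {
  wide <- markers |>
    dplyr::mutate(col = ifelse(is.na(.data$lead), .data$feature,
                               paste0(.data$feature, "_", .data$lead))) |>
    dplyr::select("id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-"id", names_to = "col", values_to = "value") |>
    dplyr::mutate(
      lead = ifelse(grepl("_", .data$col), sub("^[^_]+_", "", .data$col), NA_character_),
      feature = sub("_.*$", "", .data$col)
    ) |>
    dplyr::select("id", "lead", "feature", "value")
}
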