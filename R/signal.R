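#' Multi-lead ECG signal container
#'
#' A light container for a multi-lead ECG: a numeric matrix of amplitudes in
#' microvolts (leads in rows, samples in columns), a sampling rate in Hz and an
#' ordered set of unique lead names. All amplitudes inside the package are in
#' \eqn{\mu V}; unit conversion happens only at file boundaries (see
#' [rescale_units()], [read_wfdb()]).
#'
#' @param samples Numeric matrix, `n_leads x n_samples`, amplitudes in
#'   \eqn{\mu V}.
#' @param sampling_rate Sampling frequency in Hz (positive scalar).
#' @param lead_names Character vector of unique lead labels, one per row of
#'   `samples`. Defaults to the rownames of `samples`.
#' @return An object of class `ecg_signal`.
#' @examples
#' sig <- ecg_signal(matrix(0, 2, 100, dimnames = list(c("I", "II"), NULL)), 500)
#' n_samples(sig)
#' @export
ecg_signal <- function(samples, sampling_rate, lead_names = rownames(samples)) {
  samples <- as.matrix(samples)
  if (is.null(lead_names)) {
    stop("`lead_names` must be supplied (or set as rownames of `samples`)")
  }
  lead_names <- as.character(lead_names)
  if (length(lead_names) != nrow(samples)) {
    stop(sprintf("%d lead names for %d signal rows", length(lead_names), nrow(samples)))
  }
  if (anyDuplicated(lead_names)) stop("lead names must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  storage.mode(samples) <- "double"
  rownames(samples) <- lead_names
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d leads x %d samples @ %g Hz (%.3g s), unit uV\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat("leads:", paste(rownames(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ecg_signal
#' @param x An `ecg_signal`.
#' @export
n_samples <- function(x) ncol(x$samples)

#' @rdname ecg_signal
#' @export
lead_names <- function(x) rownames(x$samples)

#' Standard lead sets
#'
#' The canonical 12-lead order used throughout the package is
#' I, II, III, aVR, aVL, aVF, V1--V6. Of these, 8 are linearly independent
#' (I, II, V1--V6) and 4 are exact linear combinations of leads I and II
#' (III, aVR, aVL, aVF). `lead_set()` describes an input configuration:
#' one-lead reconstruction measures lead I only; two-lead reconstruction
#' measures leads I and II.
#'
#' @param input_mode `"one_lead"` (input I) or `"two_lead"` (inputs I and II).
#' @return A list with elements `independent`, `derived`, `input`, `target`
#'   (the independent leads the model must reconstruct) and `input_mode`.
#' @examples
#' lead_set("one_lead")$target
#' @export
lead_set <- function(input_mode = c("one_lead", "two_lead")) {
  input_mode <- match.arg(input_mode)
  input <- if (input_mode == "one_lead") "I" else c("I", "II")
  list(independent = LEADS_INDEPENDENT,
       derived = LEADS_DERIVED,
       input = input,
       target = setdiff(LEADS_INDEPENDENT, input),
       input_mode = input_mode)
}

LEADS_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6")
LEADS_INDEPENDENT <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
LEADS_DERIVED <- c("III", "aVR", "aVL", "aVF")

#' Derive the redundant limb leads from leads I and II
#'
#' The six extremity leads contain only two degrees of freedom: Einthoven's
#' and Goldberger's relations give III, aVR, aVL and aVF exactly from leads I
#' and II:
#' \deqn{III = II - I,\quad aVR = -(I+II)/2,\quad aVL = I - II/2,\quad
#'       aVF = II - I/2.}
#'
#' @param lead_i,lead_ii Numeric vectors of equal length, amplitudes in
#'   \eqn{\mu V}.
#' @return A named list of four numeric vectors: `III`, `aVR`, `aVL`, `aVF`.
#' @examples
#' d <- derive_limb_leads(c(0, 100), c(50, 150))
#' d$III  # II - I
#' @export
derive_limb_leads <- function(lead_i, lead_ii) {
  if (length(lead_i) != length(lead_ii)) {
    stop(sprintf("lead I has %d samples but lead II has %d samples",
                 length(lead_i), length(lead_ii)))
  }
  list(III = lead_ii - lead_i,
       aVR = -(lead_i + lead_ii) / 2,
       aVL = lead_i - lead_ii / 2,
       aVF = lead_ii - lead_i / 2)
}

#' Assemble a full 12-lead ECG from the 8 independent leads
#'
#' Completes an 8-lead signal (I, II, V1--V6) to the canonical 12-lead set by
#' deriving III, aVR, aVL and aVF via [derive_limb_leads()]. Rows are returned
#' in canonical order I, II, III, aVR, aVL, aVF, V1--V6.
#'
#' @param independent An [ecg_signal] containing at least the 8 independent
#'   leads.
#' @return An [ecg_signal] with 12 leads.
#' @export
assemble_12_lead <- function(independent) {
  stopifnot(inherits(independent, "ecg_signal"))
  have <- rownames(independent$samples)
  missing <- setdiff(LEADS_INDEPENDENT, have)
  if (length(missing)) {
    stop("missing independent lead(s): ", paste(missing, collapse = ", "))
  }
  s <- independent$samples
  limb <- derive_limb_leads(s["I", ], s["II", ])
  out <- rbind(s[c("I", "II"), , drop = FALSE],
               do.call(rbind, limb),
               s[c("V1", "V2", "V3", "V4", "V5", "V6"), , drop = FALSE])
  ecg_signal(out[LEADS_12, , drop = FALSE], independent$sampling_rate)
}

#' Keep only the 8 independent leads
#'
#' Inverse of [assemble_12_lead()]: drops the four derived limb leads.
#'
#' @param signal An [ecg_signal] containing the independent leads.
#' @return An [ecg_signal] with the 8 independent leads in canonical order.
#' @export
independent_leads <- function(signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  missing <- setdiff(LEADS_INDEPENDENT, rownames(signal$samples))
  if (length(missing)) {
    stop("missing independent lead(s): ", paste(missing, collapse = ", "))
  }
  ecg_signal(signal$samples[LEADS_INDEPENDENT, , drop = FALSE],
             signal$sampling_rate)
}

#' Rescale signal amplitudes
#'
#' Multiplies all samples by a positive factor; used at file boundaries to
#' convert units (mV to the internal \eqn{\mu V} uses `factor = 1000`).
#'
#' @param signal An [ecg_signal].
#' @param factor Positive scalar.
#' @return The rescaled [ecg_signal].
#' @export
rescale_units <- function(signal, factor) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("`factor` must be a single positive number")
  }
  signal$samples <- signal$samples * factor
  signal
}

#' Tidy a signal into a long tibble
#'
#' @param signal An [ecg_signal].
#' @return A tibble with columns `lead`, `time_s`, `amplitude_uv`.
#' @export
signal_tbl <- function(signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- n_samples(signal)
  tibble::tibble(
    lead = rep(lead_names(signal), each = n),
    time_s = rep(seq_len(n) - 1, times = nrow(signal$samples)) / signal$sampling_rate,
    amplitude_uv = as.vector(t(signal$samples))
  )
}

#' Plot a multi-lead signal
#'
#' @param object An [ecg_signal].
#' @param leads Optional character vector of leads to show.
#' @param ... Unused.
#' @return A ggplot object, one facet per lead.
#' @export
autoplot.ecg_signal <- function(object, leads = NULL, ...) {
  dat <- signal_tbl(object)
  if (!is.null(leads)) dat <- dplyr::filter(dat, .data$lead %in% leads)
  dat$lead <- factor(dat$lead, levels = intersect(LEADS_12, unique(dat$lead)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$amplitude_uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)")
}
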