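#' Per-lead root mean squared reconstruction error
#'
#' RMSE between real and reconstructed signals over all samples of all
#' records, per lead, in \eqn{\mu V}.
#'
#' @param real,recon Named lists of [ecg_signal] (or records), aligned by id.
#' @param leads Leads to report.
#' @return A tibble with columns `lead`, `rmse_uv`, `n_records`.
#' @export
rmse_per_lead <- function(real, recon, leads = LEADS_INDEPENDENT) {
  real <- lapply(real, function(r) if (inherits(r, "ecg_record")) r$signal else r)
  ids_real <- names(real) %||% vapply(real, function(s) "", character(1))
  if (length(real) != length(recon)) {
    stop(sprintf("record sets differ: %d real vs %d reconstructed",
                 length(real), length(recon)))
  }
  acc <- matrix(0, length(leads), 2, dimnames = list(leads, c("ss", "n")))
  for (i in seq_along(real)) {
    sr <- real[[i]]$samples
    sc <- recon[[i]]$samples
    for (ld in intersect(leads, intersect(rownames(sr), rownames(sc)))) {
      d <- sr[ld, ] - sc[ld, ]
      acc[ld, "ss"] <- acc[ld, "ss"] + sum(d^2)
      acc[ld, "n"] <- acc[ld, "n"] + length(d)
    }
  }
  tibble::tibble(lead = leads,
                 rmse_uv = unname(sqrt(acc[, "ss"] / pmax(acc[, "n"], 1))),
                 n_records = length(real))
}

join_markers <- function(markers_real, markers_recon) {
  dplyr::inner_join(markers_real, markers_recon,
                    by = c("id", "lead", "feature"),
                    suffix = c("_real", "_recon"))
}

#' Percentiles of the reconstruction error
#'
#' Error is reconstructed minus real, per record; percentiles use linear
#' interpolation between closest order statistics (R quantile type 7). With
#' fewer than 20 records per cell the `unstable` flag is set.
#'
#' @param markers_real,markers_recon Long marker tibbles
#'   ([measure_cohort()] format).
#' @param levels Percentile levels in percent.
#' @return A tibble per feature x lead with one column per percentile.
#' @export
error_percentiles <- function(markers_real, markers_recon,
                              levels = c(5, 10, 90, 95)) {
  j <- join_markers(markers_real, markers_recon) |>
    dplyr::mutate(error = .data$value_recon - .data$value_real) |>
    dplyr::filter(is.finite(.data$error))
  j |>
    dplyr::group_by(.data$feature, .data$lead) |>
    dplyr::summarise(
      n = dplyr::n(),
      unstable = dplyr::n() < 20L,
      tibble::as_tibble_row(stats::setNames(
        as.list(stats::quantile(.data$error, levels / 100, type = 7)),
        paste0("p", levels))),
      .groups = "drop")
}

#' Compare marker means and variances between real and reconstructed ECGs
#'
#' Two-sided t-test on the means (paired by record by default, since the same
#' test records underlie both groups; set `paired = FALSE` for the unpaired
#' variant) and a two-sided F-test on the variance ratio, per feature x lead.
#' Cells where every paired difference is zero, or both variances vanish, are
#' flagged degenerate with no p-value.
#'
#' @inheritParams error_percentiles
#' @param paired Pair the t-test by record.
#' @return A tibble with means, SDs, `p_means`, `p_variance`, `var_ratio`
#'   (reconstructed over real) and a `degenerate` flag.
#' @export
compare_means_variances <- function(markers_real, markers_recon, paired = TRUE) {
  j <- join_markers(markers_real, markers_recon) |>
    dplyr::filter(is.finite(.data$value_real), is.finite(.data$value_recon))
  j |>
    dplyr::group_by(.data$feature, .data$lead) |>
    dplyr::summarise({
      x <- .data$value_real; y <- .data$value_recon
      deg_t <- if (paired) all(y - x == 0) else (sd(x) == 0 && sd(y) == 0)
      deg_f <- sd(x) == 0 && sd(y) == 0
      p_means <- if (deg_t) NA_real_ else {
        stats::t.test(y, x, paired = paired, var.equal = !paired)$p.value
      }
      p_var <- if (deg_f) NA_real_ else {
        if (sd(x) == 0 || sd(y) == 0) 0 else stats::var.test(y, x)$p.value
      }
      tibble::tibble(n = length(x),
                     mean_real = mean(x), sd_real = sd(x),
                     mean_recon = mean(y), sd_recon = sd(y),
                     var_ratio = ifelse(sd(x) > 0, stats::var(y) / stats::var(x), NA_real_),
                     p_means = p_means, p_variance = p_var,
                     degenerate = deg_t || deg_f)
    }, .groups = "drop")
}

#' Bland-Altman agreement of one marker
#'
#' Plots (and summarises) the reconstruction error, reconstructed minus real,
#' against the real value: mean difference, limits of agreement at
#' \eqn{\pm 1.96} SD of the differences, the squared Pearson correlation
#' between difference and real value, and the least-squares slope of
#' difference on real. Errors independent of the true amplitude give slope
#' and \eqn{R^2} near zero; a constant (population-mean) prediction gives
#' slope exactly \eqn{-1} and \eqn{R^2 = 1}, the regression-to-the-mean
#' extreme.
#'
#' @param real,recon Numeric vectors of one marker across records.
#' @return A one-row tibble: `n`, `mean_diff`, `loa_low`, `loa_high`,
#'   `r2_diff_vs_real`, `slope`, `degenerate`.
#' @export
bland_altman <- function(real, recon) {
  ok <- is.finite(real) & is.finite(recon)
  real <- real[ok]; recon <- recon[ok]
  d <- recon - real
  m <- mean(d); s <- sd(d)
  degenerate <- s == 0 || sd(real) == 0
  if (sd(real) == 0) {
    r2 <- 0; slope <- NA_real_
  } else if (s == 0) {
    r2 <- 0; slope <- 0
  } else {
    r2 <- cor(d, real)^2
    slope <- cov(d, real) / stats::var(real)
  }
  tibble::tibble(n = length(d), mean_diff = m,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 r2_diff_vs_real = r2, slope = slope, degenerate = degenerate)
}

#' Squared correlation between real and reconstructed markers
#'
#' Table-2-style calibration: per feature x lead, the squared Pearson
#' correlation between the real and reconstructed marker across records.
#'
#' @inheritParams error_percentiles
#' @return A tibble with `feature`, `lead`, `r2`, `n`.
#' @export
marker_r2 <- function(markers_real, markers_recon) {
  join_markers(markers_real, markers_recon) |>
    dplyr::filter(is.finite(.data$value_real), is.finite(.data$value_recon)) |>
    dplyr::group_by(.data$feature, .data$lead) |>
    dplyr::summarise(
      n = dplyr::n(),
      r2 = if (sd(.data$value_real) == 0 || sd(.data$value_recon) == 0) 0
           else cor(.data$value_real, .data$value_recon)^2,
      .groups = "drop")
}

#' Inter-lead marker correlation, real vs reconstructed
#'
#' For each precordial lead, the squared Pearson correlation between that
#' lead's marker and the lead-I marker across records, computed once with the
#' real precordial values and once with the reconstructed ones. The lead-I
#' marker is always taken from the real measurements (lead I is an input and
#' never reconstructed). A reconstruction that rebuilds each subject
#' faithfully leaves these correlations unchanged; one that leans on the
#' population mean plus the input lead inflates them. Records with missing
#' markers are dropped pairwise and counted.
#'
#' @inheritParams error_percentiles
#' @param feature Marker name (e.g. `"R"`).
#' @param leads Precordial leads to correlate against the reference.
#' @param ref_lead Reference lead (default `"I"`).
#' @return A tibble per lead: `r2_real`, `r2_recon`, `n`, and
#'   `recon_constant` flagging a zero-variance reconstructed marker (the
#'   degenerate mean-predictor extreme).
#' @export
interlead_correlation <- function(markers_real, markers_recon, feature = "R",
                                  leads = c("V1", "V2", "V3", "V6"),
                                  ref_lead = "I") {
  ftr <- feature
  ref <- markers_real |>
    dplyr::filter(.data$feature == ftr, .data$lead == ref_lead) |>
    dplyr::select("id", ref = "value")
  per_lead <- function(ld) {
    x_real <- markers_real |>
      dplyr::filter(.data$feature == ftr, .data$lead == ld) |>
      dplyr::select("id", real = "value")
    x_recon <- markers_recon |>
      dplyr::filter(.data$feature == ftr, .data$lead == ld) |>
      dplyr::select("id", recon = "value")
    d <- ref |>
      dplyr::inner_join(x_real, by = "id") |>
      dplyr::inner_join(x_recon, by = "id") |>
      dplyr::filter(is.finite(.data$ref), is.finite(.data$real), is.finite(.data$recon))
    const_recon <- sd(d$recon) == 0
    tibble::tibble(
      feature = ftr, lead = ld, n = nrow(d),
      r2_real = if (sd(d$real) == 0 || sd(d$ref) == 0) NA_real_ else cor(d$ref, d$real)^2,
      r2_recon = if (const_recon || sd(d$ref) == 0) NA_real_ else cor(d$ref, d$recon)^2,
      recon_constant = const_recon)
  }
  purrr::map_dfr(leads, per_lead)
}

#' Regression-to-the-mean verdict
#'
#' Flags a feature x lead cell when all three signatures hold
#' simultaneously: the reconstructed marker's variance is significantly below
#' the real one (variance ratio < 1 with two-sided F-test p < `alpha`), the
#' Bland-Altman slope of error on real value is negative, and the inter-lead
#' correlation with lead I is stronger in the reconstruction than in the real
#' data (a zero-variance reconstructed marker counts as the degenerate
#' extreme of both the slope and correlation signatures).
#'
#' @inheritParams error_percentiles
#' @param features Amplitude markers to assess.
#' @param leads Leads to assess.
#' @param alpha Significance level for the F-test.
#' @return A tibble per feature x lead with the three component flags and the
#'   combined `rtm` verdict.
#' @export
regression_to_mean_report <- function(markers_real, markers_recon,
                                      features = c("R", "S", "T", "STM"),
                                      leads = c("V1", "V2", "V3", "V6"),
                                      alpha = 0.05) {
  cmp <- compare_means_variances(markers_real, markers_recon)
  j <- join_markers(markers_real, markers_recon)
  purrr::map_dfr(features, function(ftr) {
    il <- interlead_correlation(markers_real, markers_recon, ftr, leads)
    purrr::map_dfr(leads, function(ld) {
      cc <- dplyr::filter(cmp, .data$feature == ftr, .data$lead == ld)
      dd <- dplyr::filter(j, .data$feature == ftr, .data$lead == ld)
      ba <- bland_altman(dd$value_real, dd$value_recon)
      ii <- dplyr::filter(il, .data$lead == ld)
      var_flag <- isTRUE(cc$var_ratio < 1 && is.finite(cc$p_variance) &&
                           cc$p_variance < alpha)
      slope_flag <- isTRUE(ba$slope < 0) ||
        (isTRUE(ii$recon_constant) && isTRUE(ba$slope <= 0))
      inter_flag <- isTRUE(ii$recon_constant) ||
        isTRUE(ii$r2_recon > ii$r2_real)
      tibble::tibble(feature = ftr, lead = ld,
                     var_ratio = cc$var_ratio, p_variance = cc$p_variance,
                     ba_slope = ba$slope, r2_real = ii$r2_real,
                     r2_recon = ii$r2_recon,
                     variance_shrunk = var_flag, negative_slope = slope_flag,
                     interlead_inflated = inter_flag,
                     rtm = var_flag && slope_flag && inter_flag)
    })
  })
}

#' Full evaluation of a reconstruction
#'
#' Runs the complete statistical battery on a set of real records and their
#' reconstructions: per-lead RMSE, marker measurement on both (identical
#' pipeline, delineating on the real input lead), error percentiles,
#' real-vs-reconstructed calibration \eqn{R^2}, mean/variance comparisons,
#' Bland-Altman agreement, inter-lead correlations and the composite
#' regression-to-the-mean verdict.
#'
#' @param real_records Test records (list of `ecg_record` or named 12-lead
#'   signals).
#' @param recon_signals Named list of reconstructed 12-lead signals
#'   ([reconstruct_cohort()] output).
#' @param input_mode Input configuration of the reconstruction; the input
#'   leads are excluded from the delineation composite so real and
#'   reconstructed records are measured from the same information.
#' @param leads Precordial leads evaluated (default the V1, V2, V3, V6
#'   subset).
#' @param features Amplitude markers evaluated.
#' @param detect_lead Lead used for beat detection on both real and
#'   reconstructed records.
#' @param alpha Significance level.
#' @return An object of class `ecg_evaluation` with elements `rmse`,
#'   `percentiles`, `r2`, `comparison`, `bland_altman`, `interlead`,
#'   `verdict`, `markers_real`, `markers_recon`.
#' @export
evaluate_reconstruction <- function(real_records, recon_signals,
                                    input_mode = c("one_lead", "two_lead"),
                                    leads = c("V1", "V2", "V3", "V6"),
                                    features = c("R", "S", "T", "STM"),
                                    detect_lead = "II", alpha = 0.05) {
  input_mode <- match.arg(input_mode)
  comp <- setdiff(LEADS_INDEPENDENT, lead_set(input_mode)$input)
  meas_leads <- union("I", leads)
  mk_real <- measure_cohort(real_records, leads = meas_leads,
                            detect_lead = detect_lead, composite_leads = comp)
  mk_recon <- measure_cohort(recon_signals, leads = meas_leads,
                             detect_lead = detect_lead, composite_leads = comp)
  real_sigs <- lapply(real_records, function(r) if (inherits(r, "ecg_record")) r$signal else r)
  names(real_sigs) <- vapply(seq_along(real_records), function(i) {
    r <- real_records[[i]]
    if (inherits(r, "ecg_record")) r$id else (names(real_records)[i] %||% as.character(i))
  }, character(1))
  j <- join_markers(mk_real, mk_recon)
  ba <- j |>
    dplyr::filter(.data$feature %in% features, .data$lead %in% leads) |>
    dplyr::group_by(.data$feature, .data$lead) |>
    dplyr::group_modify(~ bland_altman(.x$value_real, .x$value_recon)) |>
    dplyr::ungroup()
  il <- purrr::map_dfr(features, function(ftr) {
    interlead_correlation(mk_real, mk_recon, ftr, leads)
  })
  structure(list(
    rmse = rmse_per_lead(real_sigs, recon_signals),
    percentiles = error_percentiles(mk_real, mk_recon),
    r2 = marker_r2(mk_real, mk_recon),
    comparison = compare_means_variances(mk_real, mk_recon),
    bland_altman = ba,
    interlead = il,
    verdict = regression_to_mean_report(mk_real, mk_recon, features, leads, alpha),
    markers_real = mk_real, markers_recon = mk_recon,
    leads = leads, features = features, alpha = alpha),
    class = "ecg_evaluation")
}

#' @export
print.ecg_evaluation <- function(x, ...) {
  n_rtm <- sum(x$verdict$rtm)
  cat(sprintf("<ecg_evaluation> %d records; regression-to-the-mean flagged in %d/%d marker cells\n",
              x$rmse$n_records[1], n_rtm, nrow(x$verdict)))
  cat("RMSE (uV):", paste(sprintf("%s %.0f", x$rmse$lead, x$rmse$rmse_uv), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ecg_evaluation <- function(x, ...) x$verdict

#' @export
glance.ecg_evaluation <- function(x, ...) {
  tibble::tibble(
    n_records = x$rmse$n_records[1],
    mean_rmse_uv = mean(x$rmse$rmse_uv[x$rmse$lead %in% x$leads]),
    rtm_cells = sum(x$verdict$rtm), cells = nrow(x$verdict),
    median_var_ratio = stats::median(x$verdict$var_ratio, na.rm = TRUE),
    median_ba_slope = stats::median(x$verdict$ba_slope, na.rm = TRUE))
}

#' Write an evaluation report as delimited text
#'
#' Emits one TSV per table (RMSE, percentiles, calibration \eqn{R^2},
#' mean/variance comparison, Bland-Altman, inter-lead correlations, verdict)
#' plus a per-record marker file suitable for regenerating the figures.
#'
#' @param report An `ecg_evaluation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(rmse = report$rmse, percentiles = report$percentiles,
               r2 = report$r2, comparison = report$comparison,
               bland_altman = report$bland_altman,
               interlead = report$interlead, verdict = report$verdict)
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  fig <- join_markers(report$markers_real, report$markers_recon)
  readr::write_csv(fig, file.path(dir, "marker-pairs.csv"))
  invisible(dir)
}

#' Bland-Altman plot for one marker
#'
#' @param report An `ecg_evaluation`.
#' @param feature,lead Marker cell to plot.
#' @return A ggplot: error (reconstructed - real) against the real value,
#'   with mean difference and limits of agreement.
#' @export
plot_bland_altman <- function(report, feature = "R", lead = "V3") {
  ftr <- feature; ld <- lead
  d <- join_markers(report$markers_real, report$markers_recon) |>
    dplyr::filter(.data$feature == ftr, .data$lead == ld) |>
    dplyr::mutate(error = .data$value_recon - .data$value_real)
  ba <- dplyr::filter(report$bland_altman, .data$feature == ftr, .data$lead == ld)
  ggplot2::ggplot(d, ggplot2::aes(.data$value_real, .data$error)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$mean_diff, ba$loa_low, ba$loa_high),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::labs(x = sprintf("real %s amplitude in %s (uV)", ftr, ld),
                  y = "reconstruction error (uV)",
                  title = sprintf("%s(%s): slope %.2f, R2 %.2f", ftr, ld,
                                  ba$slope, ba$r2_diff_vs_real))
}

#' Inter-lead correlation plot for one marker
#'
#' @param report An `ecg_evaluation`.
#' @param feature Marker.
#' @param lead Precordial lead plotted against lead I.
#' @return A ggplot overlaying real and reconstructed marker scatter against
#'   the (real) lead-I marker.
#' @export
plot_interlead <- function(report, feature = "R", lead = "V3") {
  ftr <- feature; ld <- lead
  ref <- report$markers_real |>
    dplyr::filter(.data$feature == ftr, .data$lead == "I") |>
    dplyr::select("id", ref = "value")
  d <- dplyr::bind_rows(
    real = dplyr::filter(report$markers_real, .data$feature == ftr, .data$lead == ld),
    reconstructed = dplyr::filter(report$markers_recon, .data$feature == ftr, .data$lead == ld),
    .id = "source") |>
    dplyr::inner_join(ref, by = "id")
  il <- dplyr::filter(report$interlead, .data$feature == ftr, .data$lead == ld)
  ggplot2::ggplot(d, ggplot2::aes(.data$ref, .data$value, colour = .data$source)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("real %s amplitude in lead I (uV)", ftr),
                  y = sprintf("%s amplitude in %s (uV)", ftr, ld),
                  title = sprintf("%s(%s) vs lead I: R2 real %.2f, recon %.2f",
                                  ftr, ld, il$r2_real, il$r2_recon))
}
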