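#' ADC quantization
#'
#' Snaps amplitudes to the integer ADC grid used by the WFDB writer
#' (`gain` ADC units per \eqn{\mu V}; default 1, i.e. 1 \eqn{\mu V}
#' resolution, typical of digital resting ECGs). Writing a quantized signal
#' and reading it back is an exact round trip.
#'
#' @param signal An [ecg_signal].
#' @param gain ADC units per \eqn{\mu V}.
#' @return The quantized [ecg_signal].
#' @export
adc_quantize <- function(signal, gain = 1) {
  stopifnot(inherits(signal, "ecg_signal"), gain > 0)
  signal$samples <- round(signal$samples * gain) / gain
  signal
}

#' Write / read WFDB-compatible records
#'
#' Minimal WFDB support: a text header (`<record>.hea`) and a 16-bit
#' little-endian sample-interleaved signal file (`<record>.dat`, format 16).
#' Amplitudes are stored as `round(uV * gain)` ADC units with the per-signal
#' gain and unit recorded in the header; on read, stored units are converted
#' to the package-internal \eqn{\mu V} (a record stored in mV comes back
#' multiplied by 1000).
#'
#' @param signal An [ecg_signal].
#' @param record Record name (file stem).
#' @param dir Directory.
#' @param gain ADC units per \eqn{\mu V}.
#' @param units Unit string written to the header (`"uV"` or `"mV"`; the
#'   gain is interpreted as ADC units per that unit on read).
#' @return `write_wfdb()` returns the header path invisibly; `read_wfdb()`
#'   returns an [ecg_signal] in \eqn{\mu V}.
#' @export
write_wfdb <- function(signal, record, dir, gain = 1, units = "uV") {
  stopifnot(inherits(signal, "ecg_signal"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_sig <- nrow(signal$samples)
  n <- n_samples(signal)
  adc <- round(signal$samples * gain)
  if (any(abs(adc) > 32767)) stop("amplitude overflows 16-bit ADC range; lower `gain`")
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- paste0(record, ".dat")
  lines <- c(sprintf("%s %d %g %d", record, n_sig, signal$sampling_rate, n),
             sprintf("%s 16 %g(0)/%s 16 0 %d 0 0 %s",
                     dat, gain, units, as.integer(adc[, 1]),
                     rownames(signal$samples)))
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc[, seq_len(n)]), con, size = 2, endian = "little")
  invisible(hea)
}

#' @rdname write_wfdb
#' @param path Path to the `.hea` file (or the record stem).
#' @export
read_wfdb <- function(path) {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  if (!file.exists(path)) stop("unreadable header: ", path)
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(hd[2]); fs <- as.numeric(hd[3]); n <- as.integer(hd[4])
  sig_lines <- strsplit(trimws(lines[1 + seq_len(n_sig)]), "\\s+")
  dat_file <- sig_lines[[1]][1]
  spec <- vapply(sig_lines, `[`, character(1), 3)
  gain <- as.numeric(sub("\\(.*$", "", spec))
  units <- sub("^.*/", "", spec)
  leads <- vapply(sig_lines, function(x) x[length(x)], character(1))
  con <- file(file.path(dirname(path), dat_file), "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = n_sig * n, size = 2, endian = "little")
  m <- matrix(adc, nrow = n_sig)
  to_uv <- ifelse(tolower(units) == "mv", 1000, 1)
  phys <- (m / gain) * to_uv
  rownames(phys) <- leads
  ecg_signal(phys, fs)
}

#' Write a synthetic cohort as WFDB records plus delimited metadata
#'
#' Each record is ADC-quantized and written via [write_wfdb()]; the cohort
#' manifest (one row per record, labelled `normal`) and the ground-truth
#' fiducials (keyed by record id) are written as tab-separated text.
#'
#' @param cohort An `ecg_cohort`.
#' @param dir Output directory.
#' @param gain ADC units per \eqn{\mu V}.
#' @return `dir`, invisibly.
#' @export
write_wfdb_cohort <- function(cohort, dir, gain = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort) write_wfdb(r$signal, r$id, dir, gain = gain)
  man <- cohort_manifest(cohort)
  man$label <- "normal"
  readr::write_tsv(man, file.path(dir, "manifest.tsv"))
  fid <- purrr::map_dfr(cohort, function(r) {
    dplyr::mutate(r$fiducials, id = r$id, .before = 1)
  })
  readr::write_tsv(fid, file.path(dir, "fiducials.tsv"))
  invisible(dir)
}

#' Read a directory of WFDB records
#'
#' Loads every record listed in the directory's `manifest.tsv` (or every
#' `.hea` file when no manifest exists), optionally filtered on the manifest
#' `label` column. Records that fail the lead-count or sampling-rate checks
#' are skipped with a warning naming the reason; signals come back in
#' \eqn{\mu V}.
#'
#' @param dir Directory of `.hea`/`.dat` pairs.
#' @param label Keep only records with this manifest label (`NULL` keeps
#'   all).
#' @param expect_leads Required lead count (default 12; use `NULL` to skip).
#' @param expect_fs Required sampling rate in Hz (`NULL` to skip).
#' @return A named list of [ecg_signal].
#' @export
read_wfdb_cohort <- function(dir, label = "normal", expect_leads = 12,
                             expect_fs = 500) {
  man_path <- file.path(dir, "manifest.tsv")
  if (file.exists(man_path)) {
    man <- readr::read_tsv(man_path, show_col_types = FALSE)
    ids <- if (!is.null(label) && "label" %in% names(man)) {
      man$id[man$label == label]
    } else man$id
  } else {
    ids <- sub("\\.hea$", "", basename(Sys.glob(file.path(dir, "*.hea"))))
  }
  if (!length(ids)) {
    warning("no matching records in ", dir)
    return(stats::setNames(list(), character(0)))
  }
  out <- list()
  for (id in ids) {
    sig <- tryCatch(read_wfdb(file.path(dir, id)), error = function(e) e)
    reason <- NULL
    if (inherits(sig, "error")) {
      reason <- conditionMessage(sig)
    } else if (!is.null(expect_leads) && nrow(sig$samples) != expect_leads) {
      reason <- sprintf("has %d leads, expected %d", nrow(sig$samples), expect_leads)
    } else if (!is.null(expect_fs) && sig$sampling_rate != expect_fs) {
      reason <- sprintf("sampling rate %g Hz, expected %g", sig$sampling_rate, expect_fs)
    }
    if (is.null(reason)) out[[id]] <- sig
    else warning(sprintf("skipping %s: %s", id, reason))
  }
  out
}

#' Read ground-truth fiducials written by [write_wfdb_cohort()]
#'
#' @param dir Cohort directory.
#' @return A tibble of per-beat fiducial times keyed by record id.
#' @export
read_fiducials <- function(dir) {
  readr::read_tsv(file.path(dir, "fiducials.tsv"), show_col_types = FALSE)
}
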