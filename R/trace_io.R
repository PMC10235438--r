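#' Write a sweep series to a plain-text recording file
#'
#' The on-disk format is a `key: value` header block (sampling interval,
#' units, role, step protocol, metadata), a `---` separator, then one
#' tab-separated column of samples per sweep. Values are written with 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param series A [sweep_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(series, path) {
  stopifnot(inherits(series, "pk_sweeps"))
  tr1 <- series$sweeps[[1]]
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "patchkit-recording v1",
    paste0("dt: ", fmt(tr1$dt)),
    paste0("units: ", tr1$units),
    paste0("role: ", tr1$role),
    paste0("lowpass_cutoff: ",
      if (is.null(tr1$lowpass_cutoff)) "none" else fmt(tr1$lowpass_cutoff)),
    paste0("protocol_holding: ", fmt(series$protocol$holding)),
    paste0("protocol_step_onset: ", fmt(series$protocol$step_onset)),
    paste0("protocol_step_offset: ", fmt(series$protocol$step_offset)),
    paste0("protocol_step_levels: ",
      paste(fmt(series$protocol$step_levels), collapse = ",")))
  md <- series$metadata
  for (key in names(md)) {
    val <- md[[key]]
    sval <- if (is.character(val)) paste(val, collapse = ";") else fmt(val)
    if (is.logical(val)) sval <- as.character(val)
    hdr <- c(hdr, paste0("meta_", key, ": ", sval))
  }
  mat <- vapply(series$sweeps, `[[`, numeric(sweep_len(series)), "samples")
  mat <- matrix(sprintf("%.17g", mat), nrow = sweep_len(series))
  body <- do.call(paste, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]),
    list(sep = "\t")))
  writeLines(c(hdr, "---", body), path)
  invisible(path)
}

#' Read a plain-text recording file
#'
#' Parses the format written by [write_recording()]. Header fields `dt`,
#' `units`, `role` and the `protocol_*` entries are required; a missing
#' field raises a format error naming it, and data rows with unequal numbers
#' of sweeps raise a structural error.
#'
#' @param path Input file path.
#' @return A [sweep_series()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  sep <- match("---", lines)
  if (is.na(sep)) stop("format error: missing '---' separator", call. = FALSE)
  hdr_lines <- grep("^[A-Za-z_]+: ", lines[seq_len(sep - 1)], value = TRUE)
  keys <- sub(":.*$", "", hdr_lines)
  vals <- sub("^[A-Za-z_]+: ", "", hdr_lines)
  names(vals) <- keys
  need <- c("dt", "units", "role", "protocol_holding", "protocol_step_onset",
    "protocol_step_offset", "protocol_step_levels")
  missing <- setdiff(need, keys)
  if (length(missing)) {
    stop("format error: missing header field(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- lines[(sep + 1):length(lines)]
  body <- body[nzchar(body)]
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1L) {
    stop("structural error: sweeps have unequal lengths", call. = FALSE)
  }
  nswp <- nfield[1]
  vals_num <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  mat <- matrix(vals_num, ncol = nswp, byrow = TRUE)
  lowpass <- if (identical(vals[["lowpass_cutoff"]], "none")) NULL else
    as.numeric(vals[["lowpass_cutoff"]])
  metadata <- list()
  for (key in keys[startsWith(keys, "meta_")]) {
    raw <- vals[[key]]
    parsed <- if (raw %in% c("TRUE", "FALSE")) as.logical(raw) else
      suppressWarnings(as.numeric(raw))
    if (length(parsed) == 1 && is.na(parsed) && !raw %in% c("NA", "NaN")) {
      parsed <- strsplit(raw, ";", fixed = TRUE)[[1]]
    }
    metadata[[sub("^meta_", "", key)]] <- parsed
  }
  protocol <- step_protocol(
    holding = as.numeric(vals[["protocol_holding"]]),
    step_onset = as.numeric(vals[["protocol_step_onset"]]),
    step_offset = as.numeric(vals[["protocol_step_offset"]]),
    step_levels = as.numeric(strsplit(vals[["protocol_step_levels"]], ",")[[1]]))
  sweeps <- lapply(seq_len(nswp), function(j) {
    trace(mat[, j], dt = as.numeric(vals[["dt"]]), units = vals[["units"]],
      role = vals[["role"]], lowpass_cutoff = lowpass)
  })
  sweep_series(sweeps, protocol, metadata)
}

#' Apply liquid junction potential correction
#'
#' Shifts every voltage-valued quantity in the series by `-jp` millivolts:
#' the samples of voltage traces, or (for voltage-clamp families) the
#' command protocol levels. Current-valued samples are untouched. The series
#' is flagged `junction_corrected`; correcting twice is refused.
#'
#' @param series A [sweep_series()].
#' @param jp Junction potential in mV (default 10, potassium-gluconate
#'   internal vs. ACSF).
#' @return The corrected `pk_sweeps`.
#' @export
apply_junction_correction <- function(series, jp = 10) {
  stopifnot(inherits(series, "pk_sweeps"))
  if (isTRUE(series$metadata$junction_corrected)) {
    stop("series is already junction-corrected; refusing to correct twice",
      call. = FALSE)
  }
  role <- series$sweeps[[1]]$role
  if (role == "membrane_voltage") {
    series$sweeps <- lapply(series$sweeps, function(tr) {
      tr$samples <- tr$samples - jp
      tr
    })
  } else if (role == "membrane_current") {
    # voltage-clamp family: command levels are membrane potentials
    series$protocol$holding <- series$protocol$holding - jp
    series$protocol$step_levels <- series$protocol$step_levels - jp
  }
  series$metadata$junction_corrected <- TRUE
  series$metadata$junction_potential <- jp
  series
}

#' Quality-control gate for a recording
#'
#' Applies the access-resistance inclusion rule: recordings with pipette
#' access resistance above `ra_limit` fail QC; recordings without a recorded
#' access resistance fail as indeterminate.
#'
#' @param series A [sweep_series()] with `access_resistance` (MOhm) in its
#'   metadata.
#' @param ra_limit Maximum acceptable access resistance, MOhm (default 25).
#' @return A one-row tibble with `access_resistance`, `pass`, and a
#'   list-column `reasons` of failed-rule identifiers (empty iff `pass`).
#' @export
qc_recording <- function(series, ra_limit = 25) {
  stopifnot(inherits(series, "pk_sweeps"))
  ra <- series$metadata$access_resistance
  reasons <- character(0)
  if (is.null(ra) || !is.finite(ra)) {
    ra <- NA_real_
    reasons <- c(reasons, "indeterminate")
  } else if (ra > ra_limit) {
    reasons <- c(reasons, "access_resistance")
  }
  tibble(access_resistance = ra, pass = length(reasons) == 0L,
    reasons = list(reasons))
}
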