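#' ERP records
#'
#' An ERP record is one subject-visit-condition average: a channels x time
#' matrix in microvolts with a stimulus-locked time axis.
#'
#' @param data numeric matrix, channels x time, rows named by electrode label.
#' @param times_ms numeric vector of sample times in ms relative to stimulus
#'   onset; must be strictly increasing and uniformly spaced at
#'   `1000 / sampling_rate_hz`.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param subject_id,visit_id,condition record metadata.
#' @return An object of class `bna_erp`.
#' @export
erp_record <- function(data, times_ms, sampling_rate_hz,
                       subject_id, visit_id, condition) {
  data <- as.matrix(data)
  times_ms <- as.numeric(times_ms)
  if (ncol(data) != length(times_ms))
    bna_stop("bna_shape_mismatch", "data column count must equal length(times_ms)")
  check_uniform_times(times_ms, sampling_rate_hz)
  structure(list(data = data, times_ms = times_ms,
                 sampling_rate_hz = sampling_rate_hz,
                 subject_id = as.character(subject_id),
                 visit_id = as.character(visit_id),
                 condition = as.character(condition)),
            class = "bna_erp")
}

check_uniform_times <- function(times_ms, rate_hz, tol = 1e-4) {
  dt <- 1000 / rate_hz
  d <- diff(times_ms)
  if (length(d) && (any(d <= 0) || max(abs(d - dt)) > tol * dt))
    bna_stop("bna_nonuniform_times",
             sprintf("time axis must increase uniformly at %.6f ms", dt))
  invisible(times_ms)
}

#' @export
print.bna_erp <- function(x, ...) {
  cat(sprintf("<bna_erp> %s/%s/%s: %d ch x %d samples @ %g Hz, %g..%g ms\n",
              x$subject_id, x$visit_id, x$condition,
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Read / write ERP records as tab-separated text
#'
#' The format is diff-able plain text: `#key=value` metadata lines
#' (`subject`, `visit`, `condition`, `rate`), then a header row
#' `time_ms<TAB>label1<TAB>...`, then one row per sample.  Round-trips
#' preserve values to 6 significant digits.
#'
#' @param path file path.
#' @return `read_erp` returns a [erp_record()]; `write_erp` returns `path`
#'   invisibly.
#' @export
read_erp <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  for (key in c("subject", "visit", "condition", "rate"))
    if (is.null(meta[[key]]))
      bna_stop("bna_missing_metadata",
               sprintf("ERP file '%s' lacks a '#%s=' metadata line", path, key))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time_ms")
    bna_stop("bna_parse_error", "first header column must be 'time_ms'")
  labels <- header[-1]
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(cells) != length(header)))
    bna_stop("bna_parse_error", sprintf("ragged rows in ERP file '%s'", path))
  num <- matrix(as.numeric(unlist(cells)), ncol = length(header), byrow = TRUE)
  if (anyNA(num))
    bna_stop("bna_parse_error", sprintf("non-numeric value in ERP file '%s'", path))
  data <- t(num[, -1, drop = FALSE])
  rownames(data) <- labels
  erp_record(data, num[, 1], as.numeric(meta$rate),
             meta$subject, meta$visit, meta$condition)
}

#' @param rec a [erp_record()].
#' @rdname read_erp
#' @export
write_erp <- function(rec, path) {
  stopifnot(inherits(rec, "bna_erp"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#subject=%s", rec$subject_id),
               sprintf("#visit=%s", rec$visit_id),
               sprintf("#condition=%s", rec$condition),
               sprintf("#rate=%.10g", rec$sampling_rate_hz)), con)
  labels <- rownames(rec$data)
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_len(nrow(rec$data)))
  writeLines(paste(c("time_ms", labels), collapse = "\t"), con)
  # time axis at full precision (spacing must survive the round trip);
  # amplitudes at 6 significant digits
  rows <- vapply(seq_along(rec$times_ms), function(i)
    paste(c(sprintf("%.12g", rec$times_ms[i]),
            sprintf("%.6g", rec$data[, i])), collapse = "\t"), "")
  writeLines(rows, con)
  invisible(path)
}
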