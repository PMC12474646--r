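#' Construct a mitoPO2 trace
#'
#' A trace is one subject's 1-Hz mitoPO2 recording: integer sample times
#' starting at 0 with a constant 1-s step, and one finite mitoPO2 value
#' (mmHg) per sample.
#'
#' @param mitopo2 Numeric vector of mitoPO2 values (mmHg), all finite.
#' @param subject_id Character scalar identifying the subject.
#' @param sample_time Integer sample times in seconds; defaults to
#'   `0:(length(mitopo2) - 1)`.
#' @return An object of class `mito_trace`: a data frame with columns
#'   `sample_time` and `mitopo2` and attribute `subject_id`.
#' @export
mito_trace <- function(mitopo2, subject_id = "subject", sample_time = NULL) {
  mitopo2 <- as.numeric(mitopo2)
  if (length(mitopo2) < 1L) {
    stop("trace must contain at least one sample")
  }
  if (!all(is.finite(mitopo2))) {
    bad <- which(!is.finite(mitopo2))[1L]
    stop(sprintf("non-finite mitoPO2 value at row %d", bad))
  }
  if (is.null(sample_time)) {
    sample_time <- seq_along(mitopo2) - 1L
  }
  sample_time <- as.integer(sample_time)
  if (length(sample_time) != length(mitopo2)) {
    stop("sample_time and mitopo2 must have equal length")
  }
  if (length(sample_time) > 1L) {
    d <- diff(sample_time)
    if (any(d != 1L)) {
      bad <- which(d != 1L)[1L] + 1L
      stop(sprintf("non-uniform sampling: expected 1-s step at row %d", bad))
    }
  }
  out <- data.frame(sample_time = sample_time, mitopo2 = mitopo2)
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("mito_trace", "data.frame")
  out
}

#' @export
print.mito_trace <- function(x, ...) {
  cat(sprintf(
    "mitoPO2 trace '%s': %d samples (1 Hz), range %.1f-%.1f mmHg\n",
    attr(x, "subject_id"), nrow(x), min(x$mitopo2), max(x$mitopo2)
  ))
  invisible(x)
}

#' Construct a per-sample label sequence
#'
#' Each sample of a trace is classified as `"start"` (first sample of a
#' stop-flow decay), `"measurement"` (remaining decay samples) or `"na"`
#' (everything else). Matching is case-sensitive; the device literature's
#' "n/a" is encoded as the CSV-safe token `na`.
#'
#' @param labels Character vector with values in
#'   `c("start", "measurement", "na")`.
#' @param trace Optional `mito_trace` the labels annotate; if supplied the
#'   lengths must agree.
#' @return Character vector of class `mito_labels`.
#' @export
mito_labels <- function(labels, trace = NULL) {
  labels <- as.character(labels)
  bad <- which(!labels %in% LABEL_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown label '%s' at row %d (allowed: start, measurement, na)",
      labels[bad[1L]], bad[1L]
    ))
  }
  if (!is.null(trace) && length(labels) != nrow(trace)) {
    stop(sprintf(
      "label length %d does not match trace length %d",
      length(labels), nrow(trace)
    ))
  }
  structure(labels, class = "mito_labels")
}

#' @export
print.mito_labels <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = LABEL_LEVELS))
  cat(sprintf(
    "label sequence: %d samples (%d start, %d measurement, %d na)\n",
    length(x), tab[["start"]], tab[["measurement"]], tab[["na"]]
  ))
  invisible(x)
}

#' Read a mitoPO2 trace from CSV
#'
#' Reads the package's two-column trace dialect: a UTF-8 CSV with header
#' `sample_time_s,mitopo2_mmhg`, `.` decimal separator, one row per 1-Hz
#' sample.
#'
#' @param path Path to a `*.trace.csv` file.
#' @param subject_id Subject identifier; defaults to the filename stem
#'   (with a trailing `.trace` stripped).
#' @return A [mito_trace()].
#' @export
read_trace <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_time_s", "mitopo2_mmhg")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf(
      "expected header '%s' in %s", paste(need, collapse = ","), path
    ))
  }
  st <- suppressWarnings(as.numeric(df$sample_time_s))
  po <- suppressWarnings(as.numeric(df$mitopo2_mmhg))
  if (anyNA(st) || anyNA(po)) {
    bad <- which(is.na(st) | is.na(po))[1L]
    stop(sprintf("non-numeric cell at data row %d of %s", bad, path))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.trace$", "", sub("\\.[cC][sS][vV]$", "", basename(path)))
  }
  mito_trace(po, subject_id = subject_id, sample_time = st)
}

#' Write a mitoPO2 trace to CSV
#'
#' @param trace A [mito_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mito_trace"))
  df <- data.frame(
    sample_time_s = trace$sample_time,
    mitopo2_mmhg = sprintf("%.6f", trace$mitopo2)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label sequence from CSV
#'
#' Reads the `*.labels.csv` dialect (header `sample_time_s,label`) and
#' checks alignment against the trace the labels annotate.
#'
#' @param path Path to a labels CSV.
#' @param trace The [mito_trace()] the labels belong to.
#' @return A [mito_labels()] vector aligned to `trace`.
#' @export
read_labels <- function(path, trace) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_time_s", "label")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf(
      "expected header '%s' in %s", paste(need, collapse = ","), path
    ))
  }
  mito_labels(df$label, trace = trace)
}

#' Write a label sequence to CSV
#'
#' @param labels A [mito_labels()] vector.
#' @param trace The [mito_trace()] providing sample times.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, trace, path) {
  labels <- mito_labels(labels, trace = trace)
  df <- data.frame(sample_time_s = trace$sample_time, label = unclass(labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract measurement segments from a cleaned label sequence
#'
#' A measurement segment is one `start` sample together with the
#' immediately following run of `measurement` samples. Indices are 0-based
#' and inclusive at both ends, matching the trace's `sample_time`.
#'
#' @param labels A [mito_labels()] vector.
#' @param trace The annotated [mito_trace()].
#' @return A list of segments; each is a list with `start_index`,
#'   `end_index` (0-based, inclusive) and `mitopo2` (the trace slice).
#' @export
label_segments <- function(labels, trace) {
  labels <- mito_labels(labels, trace = trace)
  lab <- unclass(labels)
  starts <- which(lab == "start")
  segs <- list()
  for (s in starts) {
    e <- s
    while (e + 1L <= length(lab) && lab[e + 1L] == "measurement") e <- e + 1L
    segs[[length(segs) + 1L]] <- list(
      start_index = s - 1L,
      end_index = e - 1L,
      mitopo2 = trace$mitopo2[s:e]
    )
  }
  segs
}

#' Write per-subject mitoVO2 results to JSON
#'
#' @param subject_results A list of per-subject result lists, each with
#'   `subject_id`, `measurements` (list of per-segment entries carrying
#'   `start_index`, `end_index`, `params` (v0, p50, p0, z), `vmax_mmhg_per_s`
#'   and `converged`) and `mitovo2_mmhg_per_s` (subject mean Vmax over
#'   converged fits, or `NULL` when no measurement survived).
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_results <- function(subject_results, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
    error = function(e) stop(sprintf("cannot write results to %s: %s", path, conditionMessage(e)))
  )
  on.exit(close(con))
  jsonlite::write_json(
    subject_results, con,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a results JSON written by [write_results()]
#'
#' @param path Path to a `*.results.json` file.
#' @return The list of per-subject results.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("results file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = FALSE)
}
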