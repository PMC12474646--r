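#' Run the full two-step analysis on a directory of traces
#'
#' Step one labels each trace with the trained network and cleans the
#' labels with the rule engine; step two fits the oxygen disappearance
#' model to every surviving segment and averages Vmax per subject. The
#' run is deterministic given the checkpoint and the input files.
#'
#' @param input_dir Directory containing `*.trace.csv` files.
#' @param model A trained `mito_segmenter`, or a checkpoint path.
#' @param output_dir Optional directory for per-subject outputs: cleaned
#'   `<id>.labels.csv` and `<id>.results.json`, plus a cohort-level
#'   `results.json`.
#' @return Invisibly, a list with `results` (per-subject lists as written
#'   by [write_results()]) and `summary` (data frame: subject_id,
#'   n_segments, n_converged, mitovo2).
#' @export
run_pipeline <- function(input_dir, model, output_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "mito_segmenter"))
  files <- sort(list.files(input_dir, pattern = "\\.trace\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    warning(sprintf("no *.trace.csv files in %s", input_dir))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }

  results <- list()
  summary_rows <- list()
  for (f in files) {
    trace <- tryCatch(read_trace(f), error = function(e) {
      warning(sprintf("skipping unreadable trace %s: %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(trace)) next
    id <- attr(trace, "subject_id")
    raw <- predict_labels(model, trace)
    cleaned <- apply_rules(raw, trace)
    fitres <- fit_trace(trace, cleaned$labels)

    measurements <- lapply(seq_along(fitres$fits), function(i) {
      fit <- fitres$fits[[i]]
      seg <- fitres$segments[[i]]
      list(
        start_index = seg$start_index,
        end_index = seg$end_index,
        params = unclass(fit$params),
        vmax_mmhg_per_s = fit$vmax,
        converged = fit$converged
      )
    })
    res <- list(
      subject_id = id,
      measurements = measurements,
      mitovo2_mmhg_per_s = fitres$mitovo2
    )
    results[[id]] <- res
    summary_rows[[id]] <- data.frame(
      subject_id = id,
      n_segments = length(fitres$fits),
      n_converged = sum(vapply(fitres$fits, function(x) isTRUE(x$converged), TRUE)),
      mitovo2 = if (is.null(fitres$mitovo2)) NA_real_ else fitres$mitovo2
    )
    if (!is.null(output_dir)) {
      write_labels(cleaned$labels, trace,
                   file.path(output_dir, paste0(id, ".labels.csv")))
      write_results(list(res), file.path(output_dir, paste0(id, ".results.json")))
    }
  }
  summary <- if (length(summary_rows) > 0L) {
    do.call(rbind, c(summary_rows, make.row.names = FALSE))
  } else {
    data.frame(subject_id = character(0), n_segments = integer(0),
               n_converged = integer(0), mitovo2 = numeric(0))
  }
  if (!is.null(output_dir)) {
    write_results(unname(results), file.path(output_dir, "results.json"))
  }
  invisible(list(results = results, summary = summary))
}

#' Start indices of a label sequence
#'
#' @param labels A [mito_labels()] vector.
#' @return Sorted 0-based indices of `start` samples.
#' @export
start_indices <- function(labels) {
  which(unclass(mito_labels(labels)) == "start") - 1L
}
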