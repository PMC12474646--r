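# Deterministic rule engine turning raw per-sample network labels into
# valid measurement segments. Rules run in a fixed order: five label
# corrections (R1-R5), then quality-control steps (QC1-QC4), then a final
# consistency sweep. All indices in the log are 0-based.

.log_entry <- function(rule, indices, action) {
  data.frame(
    rule = rule,
    action = action,
    indices = I(list(as.integer(indices))),
    stringsAsFactors = FALSE
  )
}

# Maximal runs of a given label value; returns data.frame(start, end) 1-based.
.runs_of <- function(lab, value) {
  r <- rle(lab == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# End (1-based) of the strict segment: start + consecutive 'measurement'.
.strict_end <- function(lab, s) {
  e <- s
  n <- length(lab)
  while (e + 1L <= n && lab[e + 1L] == "measurement") e <- e + 1L
  e
}

# End of the loose segment: like .strict_end but bridging 'na' gaps that
# are followed by further 'measurement' samples before any other 'start'
# (those gaps are the ones the gap-filling rule will relabel).
.loose_end <- function(lab, s) {
  e <- .strict_end(lab, s)
  n <- length(lab)
  repeat {
    j <- e + 1L
    while (j <= n && lab[j] == "na") j <- j + 1L
    if (j <= n && j > e + 1L && lab[j] == "measurement") {
      e <- .strict_end(lab, j)
    } else {
      break
    }
  }
  e
}

#' Clean raw labels and extract valid measurement segments
#'
#' Applies the deterministic post-processing rules to a raw per-sample
#' label sequence, in order:
#'
#' * R1: runs of 1-2 `na` samples flanked by `measurement` on both sides
#'   become `measurement`.
#' * R2: a run of >= 10 consecutive `measurement` samples with no
#'   immediately preceding `start` has its first sample promoted to
#'   `start`.
#' * R3: when two `start` labels fall within 30 samples, the later one is
#'   discarded.
#' * R4: a measurement that begins at mitoPO2 <= 20 mmHg, or whose
#'   mitoPO2 never falls below 20 mmHg, is excluded entirely.
#' * R5: `na` samples between a `start` and its subsequent `measurement`
#'   run are relabeled `measurement`.
#' * QC1: each `start` is recentered to the highest mitoPO2 among the
#'   start sample and the following six samples (within the segment).
#' * QC2: a sharp rise (> 2 mmHg between consecutive samples) within the
#'   three samples after the start shifts the start past the rise, to the
#'   local maximum.
#' * QC3: a drop of more than 50 mmHg from the (re)defined start to the
#'   next sample invalidates the measurement.
#' * QC4: segments of 10 samples or fewer are removed (duration must
#'   exceed 10 s).
#'
#' A final sweep re-checks every surviving segment against the full set of
#' requirements (starts > 30 samples apart, start mitoPO2 > 20 mmHg, start
#' maximal in its 7-sample window, duration > 10 s, no sharp rise in the
#' first 3 s, minimum < 20 mmHg, first-step drop <= 50 mmHg) and clears
#' `measurement` labels that belong to no surviving segment, which makes
#' the engine idempotent.
#'
#' @param labels Raw [mito_labels()] aligned to `trace`.
#' @param trace The [mito_trace()] being annotated.
#' @return A list with `labels` (cleaned [mito_labels()]), `segments`
#'   (see [label_segments()]) and `log` (a data frame of rule
#'   applications: rule id, action, affected 0-based indices).
#' @export
apply_rules <- function(labels, trace) {
  lab <- unclass(mito_labels(labels, trace))
  p <- trace$mitopo2
  n <- length(lab)
  log <- list()
  note <- function(rule, idx, action) {
    log[[length(log) + 1L]] <<- .log_entry(rule, idx - 1L, action)
  }

  # R1: short na holes inside measurement runs
  for (r in seq_len(nrow(runs <- .runs_of(lab, "na")))) {
    s <- runs$start[r]; e <- runs$end[r]
    len <- e - s + 1L
    if (len <= 2L && s > 1L && e < n &&
        lab[s - 1L] == "measurement" && lab[e + 1L] == "measurement") {
      lab[s:e] <- "measurement"
      note("R1", s:e, "na hole filled with measurement")
    }
  }

  # R2: long measurement runs without a preceding start
  runs <- .runs_of(lab, "measurement")
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]
    if ((runs$end[r] - s + 1L) >= 10L && (s == 1L || lab[s - 1L] != "start")) {
      lab[s] <- "start"
      note("R2", s, "first of unheaded measurement run promoted to start")
    }
  }

  # R3: double starts within 30 samples
  starts <- which(lab == "start")
  if (length(starts) > 1L) {
    kept <- starts[1L]
    for (s in starts[-1L]) {
      if (s - kept <= 30L) {
        lab[s] <- "na"
        note("R3", s, "later start within 30 samples discarded")
      } else {
        kept <- s
      }
    }
  }

  # R4: segments starting at or below 20 mmHg, or never dropping below 20
  for (s in which(lab == "start")) {
    e <- .loose_end(lab, s)
    if (!(p[s] > 20) || !(min(p[s:e]) < 20)) {
      lab[s:e] <- "na"
      note("R4", s:e, if (p[s] > 20) {
        "measurement never below 20 mmHg excluded"
      } else {
        "measurement starting at <= 20 mmHg excluded"
      })
    }
  }

  # R5: na samples between a start and measurement labels that follow it
  # (holes anywhere inside the segment span, e.g. left by a discarded
  # double start) are relabeled measurement
  for (s in which(lab == "start")) {
    e <- .loose_end(lab, s)
    if (e > s) {
      idx <- (s + 1L):e
      gap <- idx[lab[idx] == "na"]
      if (length(gap) > 0L) {
        lab[gap] <- "measurement"
        note("R5", gap, "na inside segment span relabeled measurement")
      }
    }
  }

  # QC1: recenter each start on the local mitoPO2 maximum (7-sample window)
  for (s in which(lab == "start")) {
    e <- .strict_end(lab, s)
    w <- s:min(s + 6L, e)
    m <- w[which.max(p[w])]
    if (m != s) {
      lab[s:(m - 1L)] <- "na"
      lab[m] <- "start"
      note("QC1", c(s, m), "start recentered to 7-sample window maximum")
    }
  }

  # QC2: sharp rise (> 2 mmHg/sample) in the first 3 samples after a start
  for (s in which(lab == "start")) {
    repeat {
      e <- .strict_end(lab, s)
      if (e <= s) break
      ks <- s:min(s + 2L, e - 1L)
      rise <- ks[p[ks + 1L] - p[ks] > 2]
      if (length(rise) == 0L) break
      m <- rise[1L] + 1L
      while (m + 1L <= e && p[m + 1L] > p[m]) m <- m + 1L
      lab[s:(m - 1L)] <- "na"
      lab[m] <- "start"
      note("QC2", c(s, m), "start shifted past sharp rise")
      s <- m
    }
  }

  # QC3: first-step drop exceeding 50 mmHg is an artifact
  for (s in which(lab == "start")) {
    e <- .strict_end(lab, s)
    if (e > s && p[s] - p[s + 1L] > 50) {
      lab[s:e] <- "na"
      note("QC3", s:e, "first-step drop > 50 mmHg removed")
    }
  }

  # QC4: short segments
  for (s in which(lab == "start")) {
    e <- .strict_end(lab, s)
    if (e - s + 1L <= 10L) {
      lab[s:e] <- "na"
      note("QC4", s:e, "segment of <= 10 samples removed")
    }
  }

  # Final sweep: re-check every requirement after recentering/shifting and
  # clear orphaned measurement labels.
  kept <- -Inf
  for (s in which(lab == "start")) {
    e <- .strict_end(lab, s)
    w <- s:min(s + 6L, e)
    ks <- s:max(s, min(s + 2L, e - 1L)); ks <- ks[ks < e]
    ok <- (s - kept > 30L) &&
      (p[s] > 20) && (min(p[s:e]) < 20) && (e - s + 1L > 10L) &&
      (which.max(p[w]) == 1L) &&
      (length(ks) == 0L || all(p[ks + 1L] - p[ks] <= 2)) &&
      (p[s] - p[s + 1L] <= 50)
    if (!ok) {
      lab[s:e] <- "na"
      note("final", s:e, "segment failing re-checked requirements removed")
    } else {
      kept <- s
    }
  }
  runs <- .runs_of(lab, "measurement")
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]
    if (s == 1L || lab[s - 1L] != "start") {
      idx <- s:runs$end[r]
      lab[idx] <- "na"
      note("final", idx, "orphaned measurement labels cleared")
    }
  }

  clean <- mito_labels(lab, trace)
  list(
    labels = clean,
    segments = label_segments(clean, trace),
    log = if (length(log) > 0L) {
      do.call(rbind, log)
    } else {
      data.frame(rule = character(0), action = character(0),
                 indices = I(list()))
    }
  )
}
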