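#' Configuration for synthetic stop-flow cohorts
#'
#' Describes a cohort of simulated skin-oximetry sessions: continuous 1-Hz
#' mitoPO2 traces in which baseline plateaus alternate with stop-flow
#' decays (driven by the oxygen disappearance model) and exponential
#' reoxygenation recoveries. Defaults are chosen to produce physiologically
#' plausible sessions: baselines of a few tens of mmHg, per-subject mean
#' Vmax around 6-7 mmHg/s, and segments that satisfy the post-processing
#' quality requirements.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param measurements_per_subject Either a single count or a length-2
#'   range `c(lo, hi)` sampled per subject.
#' @param baseline_mean,baseline_sd Mean and SD (mmHg) of the Gaussian
#'   from which per-plateau baseline levels are drawn (truncated at 30).
#' @param noise_sd SD (mmHg) of i.i.d. Gaussian measurement noise added to
#'   every sample.
#' @param v0_range,p50_range,z_range Uniform sampling ranges for the
#'   kinetic parameters of each stop-flow decay (mmHg/s, mmHg, 1/s).
#' @param recovery_tau Time constant (s) of the exponential reoxygenation
#'   after each decay.
#' @param baseline_gap Range (s) of the uniform baseline plateau length
#'   between measurements; the default keeps consecutive starts well over
#'   30 s apart.
#' @param stop_level Early-release level (mmHg): with
#'   `hold_at_floor = FALSE` a stop-flow segment ends at the first sample
#'   below this level (but never before 10 s).
#' @param max_duration Stop-flow recording length (s); the device records
#'   each measurement for 120 s.
#' @param hold_at_floor If `TRUE` (default) compression is held for the
#'   full `max_duration`, so the trace sits at its consumption/influx
#'   floor until release, matching the device's 120-s recordings; if
#'   `FALSE` pressure is released once the trace crosses `stop_level`.
#' @param seed Integer seed; all subject-level randomness derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L,
                          measurements_per_subject = 8L,
                          baseline_mean = 60, baseline_sd = 10,
                          noise_sd = 1.5,
                          v0_range = c(4, 14),
                          p50_range = c(1, 6),
                          z_range = c(0.02, 0.15),
                          recovery_tau = 10,
                          baseline_gap = c(40, 90),
                          stop_level = 5,
                          max_duration = 120,
                          hold_at_floor = TRUE,
                          seed = 1L) {
  stopifnot(n_subjects >= 1L, all(measurements_per_subject >= 1L),
            noise_sd >= 0, recovery_tau > 0, stop_level > 0,
            max_duration > 0)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      measurements_per_subject = as.integer(measurements_per_subject),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd,
      v0_range = v0_range, p50_range = p50_range, z_range = z_range,
      recovery_tau = recovery_tau, baseline_gap = baseline_gap,
      stop_level = stop_level, max_duration = max_duration,
      hold_at_floor = isTRUE(hold_at_floor),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

.runif1 <- function(range) if (length(range) == 1L) range else runif(1, range[1L], range[2L])

.baseline_level <- function(config) {
  max(30, rnorm(1, config$baseline_mean, config$baseline_sd))
}

#' Generate one synthetic subject
#'
#' Builds a continuous session: an initial baseline plateau, then for each
#' measurement a stop-flow decay (RK4-integrated oxygen disappearance
#' model at 1 Hz, recorded for `max_duration` s under held compression, or
#' released early at `stop_level` when `hold_at_floor = FALSE`), an
#' exponential recovery toward the next baseline, and a new plateau. The first decay sample is labeled `start`, remaining
#' decay samples `measurement`, everything else `na`. White Gaussian noise
#' is added to the whole trace last.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Subject identifier.
#' @return A list with `trace` ([mito_trace()]), `labels`
#'   ([mito_labels()]), and `truth`: one entry per measurement with
#'   `params` ([kinetic_params()]), `start_index` (0-based) and
#'   `true_vmax = v0 * p0 / (p50 + p0)` (the analytic initial slope).
#' @export
generate_subject <- function(config, subject_seed, subject_id = "subject") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(subject_seed %% 2147483647))

  n_meas <- if (length(config$measurements_per_subject) > 1L) {
    sample(config$measurements_per_subject[1L]:config$measurements_per_subject[2L], 1L)
  } else {
    config$measurements_per_subject
  }

  values <- numeric(0)
  labels <- character(0)
  truth <- list()

  baseline <- .baseline_level(config)
  gap <- round(.runif1(config$baseline_gap))
  values <- c(values, rep(baseline, gap))
  labels <- c(labels, rep("na", gap))

  for (j in seq_len(n_meas)) {
    params <- kinetic_params(
      v0 = .runif1(config$v0_range),
      p50 = .runif1(config$p50_range),
      p0 = baseline,
      z = .runif1(config$z_range)
    )
    decay <- simulate_decay(params, duration = config$max_duration - 1, dt = 1)
    if (config$hold_at_floor) {
      p_dec <- decay$p
    } else {
      below <- which(decay$p < config$stop_level)
      cut <- if (length(below) > 0L) max(11L, below[1L]) else nrow(decay)
      p_dec <- decay$p[seq_len(min(cut, nrow(decay)))]
    }
    if (min(p_dec) >= 20) {
      warning(sprintf(
        "subject %s measurement %d never falls below 20 mmHg; it will be filtered downstream",
        subject_id, j
      ))
    }
    truth[[j]] <- list(
      params = params,
      start_index = length(values),   # 0-based: next appended sample
      true_vmax = params$v0 * params$p0 / (params$p50 + params$p0),
      # satisfies the downstream quality requirements by construction:
      # a decay whose minimum stays at/above 20 mmHg is filtered out later
      valid = min(p_dec) < 20 && params$p0 > 20 && length(p_dec) > 10L
    )
    values <- c(values, p_dec)
    labels <- c(labels, "start", rep("measurement", length(p_dec) - 1L))

    baseline <- .baseline_level(config)
    n_rec <- ceiling(5 * config$recovery_tau)
    rec <- baseline + (p_dec[length(p_dec)] - baseline) * exp(-(1:n_rec) / config$recovery_tau)
    gap <- round(.runif1(config$baseline_gap))
    values <- c(values, rec, rep(baseline, gap))
    labels <- c(labels, rep("na", n_rec + gap))
  }

  noisy <- values + rnorm(length(values), 0, config$noise_sd)
  list(
    trace = mito_trace(noisy, subject_id = subject_id),
    labels = mito_labels(labels),
    truth = truth,
    clean = values
  )
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()]; per-subject seeds are derived
#'   deterministically from `config$seed`.
#' @return A list of length `n_subjects`, each element as returned by
#'   [generate_subject()], named by subject id.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    id <- sprintf("S%03d", i)
    subject_seed <- (as.numeric(config$seed) + 77003 * i) %% 2147483647
    out[[i]] <- generate_subject(config, subject_seed, subject_id = id)
  }
  names(out) <- vapply(out, function(s) attr(s$trace, "subject_id"), "")
  out
}

#' Write a cohort to disk in the package's text formats
#'
#' Writes `<id>.trace.csv`, `<id>.labels.csv` and `<id>.truth.json` per
#' subject.
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subj in cohort) {
    id <- attr(subj$trace, "subject_id")
    write_trace(subj$trace, file.path(dir, paste0(id, ".trace.csv")))
    write_labels(subj$labels, subj$trace, file.path(dir, paste0(id, ".labels.csv")))
    truth <- lapply(subj$truth, function(tt) {
      list(
        params = unclass(tt$params),
        start_index = tt$start_index,
        true_vmax = tt$true_vmax
      )
    })
    jsonlite::write_json(truth, file.path(dir, paste0(id, ".truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Deterministic fixture exercising every label-cleaning rule
#'
#' Constructs a single noise-free trace with raw (pre-cleaning) labels
#' containing one instance of each pathology the rule engine handles:
#' short `na` holes inside a measurement run, a measurement run missing
#' its `start`, double starts within 30 samples, a decay starting below
#' 20 mmHg, a decay never reaching below 20 mmHg, a mislabeled gap after
#' a `start`, a start needing recentering to a later maximum, a sharp rise
#' just after a start, a > 50 mmHg first-step drop, and a too-short
#' segment.
#'
#' @return A list with `trace` and raw `labels`.
#' @export
adversarial_fixture <- function() {
  values <- numeric(0)
  labels <- character(0)
  add <- function(v, l) {
    values <<- c(values, v)
    labels <<- c(labels, l)
  }
  plateau <- function(n, level) add(rep(level, n), rep("na", n))
  # linear decay helper: from `from` by `step` for n samples (start incl.)
  decay <- function(from, step, n) seq(from, by = -step, length.out = n)

  plateau(40, 60)
  # (a) valid decay with a 2-sample na hole inside the measurement run
  d <- decay(60, 3.2, 16)                       # 60 .. 12
  add(d, c("start", rep("measurement", 6), "na", "na", rep("measurement", 7)))
  plateau(50, 62)
  # (b) measurement run with no start (12 samples): rescued by promotion
  d <- decay(62, 3.5, 14)                       # 62 .. 16.5
  add(d, c("na", "na", rep("measurement", 12)))
  plateau(50, 58)
  # (c) double start: second start 3 samples into the same decay
  d <- decay(58, 3.0, 15)                       # 58 .. 16
  add(d, c("start", "measurement", "measurement", "start",
           rep("measurement", 11)))
  plateau(50, 18)
  # (d) decay starting below 20 mmHg: excluded
  d <- decay(18, 1.0, 12)
  add(d, c("start", rep("measurement", 11)))
  plateau(50, 55)
  # (e) decay never reaching below 20 mmHg: excluded
  d <- decay(55, 2.0, 13)                       # 55 .. 31
  add(d, c("start", rep("measurement", 12)))
  plateau(50, 61)
  # (f) na gap between start and its measurement run
  d <- decay(61, 3.0, 15)                       # 61 .. 19
  add(d, c("start", "na", "na", rep("measurement", 12)))
  plateau(50, 57)
  # (g) start labeled 3 samples early on the plateau: recentered forward
  add(c(57, 57, 57), c("start", "measurement", "measurement"))
  d <- decay(59, 3.0, 15)                       # 59 (true peak) .. 17
  add(d, rep("measurement", 15))
  plateau(50, 56)
  # (h) sharp bounce right after the start (drop then > 2 mmHg rise):
  #     start shifted past the rise to the local maximum
  add(c(60, 52, 55), c("start", "measurement", "measurement"))
  d <- decay(52, 3.0, 12)                       # 52 .. 19
  add(d, rep("measurement", 12))
  plateau(50, 90)
  # (i) > 50 mmHg drop after the start: artifact, removed
  add(c(90, 30, 25, 20, 18, 15, 14, 13, 12, 11, 10, 9),
      c("start", rep("measurement", 11)))
  plateau(50, 59)
  # (j) too-short segment (6 samples): removed
  add(decay(59, 8.0, 6), c("start", rep("measurement", 5)))
  plateau(40, 60)

  list(
    trace = mito_trace(values, subject_id = "adversarial"),
    labels = mito_labels(labels)
  )
}
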