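#' Initial kinetic parameter guess for a measurement segment
#'
#' `v0` starts at the magnitude of the mean of the first three finite
#' differences of the segment (the initial decline slope after tissue
#' compression); `p0` at the mean mitoPO2 over the 10 samples preceding
#' the start (at least 3 required, otherwise the start value itself);
#' `p50` and `z` start at generic physiological values of 5 mmHg and
#' 0.01 1/s.
#'
#' @param segment A measurement segment (see [label_segments()]).
#' @param trace The [mito_trace()] the segment came from.
#' @return A [kinetic_params()] guess.
#' @export
initial_guess <- function(segment, trace) {
  y <- segment$mitopo2
  if (length(y) < 4L) stop("segment too short to estimate the initial slope (need >= 4 samples)")
  v0 <- abs(mean(diff(y[1:4])))
  s <- segment$start_index # 0-based
  pre <- trace$mitopo2[seq_len(s)] # samples 0 .. s-1
  pre <- tail(pre, 10L)
  p0 <- if (length(pre) >= 3L) mean(pre) else y[1L]
  kinetic_params(v0 = max(v0, 1e-3), p50 = 5, p0 = max(p0, 1e-3), z = 0.01)
}

.fit_bounds <- list(lower = c(0, 0.1, 0, 0), upper = c(100, 50, 150, 1))

.segment_residuals <- function(par, obs) {
  params <- kinetic_params(par[1L], par[2L], par[3L], par[4L])
  traj <- simulate_decay(params, duration = length(obs) - 1, dt = 1,
                         p_init = params$p0)
  traj$p - obs
}

#' Fit the oxygen disappearance model to one measurement segment
#'
#' Minimizes the sum of squared differences between the observed segment
#' and the RK4-integrated model trajectory (1-s step, started at `p0`)
#' over (v0, p50, p0, z) with bounded Levenberg-Marquardt least squares.
#' On non-convergence the fit is restarted up to 3 times from
#' deterministically jittered guesses. Vmax is the steepest slope of the
#' fitted curve, evaluated on a fine (0.01-s) integration grid.
#'
#' @param segment A measurement segment of >= 11 samples.
#' @param guess A [kinetic_params()] starting point, e.g. from
#'   [initial_guess()].
#' @return A list of class `fit_result`: `params`, `vmax` (mmHg/s, `NULL`
#'   when the optimizer failed), `rmse` (mmHg), `converged`, `n_points`.
#' @export
fit_segment <- function(segment, guess) {
  obs <- segment$mitopo2
  if (length(obs) < 11L) stop("segment must contain at least 11 samples")
  stopifnot(inherits(guess, "kinetic_params"))

  start0 <- unlist(guess[c("v0", "p50", "p0", "z")])
  # multistart against local minima: the plain guess, a sharp-knee start
  # (small p50), a shallow/plateau start (large p50, strong influx), and
  # two mixed perturbations
  jitters <- list(
    c(1, 1, 1, 1),
    c(1, 0.1, 1, 1),
    c(1, 10, 0.95, 10),
    c(0.5, 2, 1, 5),
    c(2, 0.5, 1.05, 0.2)
  )
  best <- NULL
  for (j in jitters) {
    start <- pmin(pmax(start0 * j, .fit_bounds$lower + 1e-6), .fit_bounds$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = .segment_residuals, obs = obs,
        lower = .fit_bounds$lower, upper = .fit_bounds$upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-8, ptol = 1e-8, maxiter = 400
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    converged <- fit$info %in% 1:4
    rss <- sum(fit$fvec^2)
    if (is.null(best) || (converged && !best$converged) ||
        (converged == best$converged && rss < best$rss)) {
      best <- list(fit = fit, converged = converged, rss = rss)
    }
    # an essentially interpolating fit cannot be improved meaningfully
    if (converged && sqrt(rss / length(obs)) < 0.01) break
  }

  if (is.null(best)) {
    return(structure(
      list(params = guess, vmax = NULL, rmse = NA_real_,
           converged = FALSE, n_points = length(obs)),
      class = "fit_result"
    ))
  }

  par <- best$fit$par
  params <- kinetic_params(par[1L], par[2L], par[3L], par[4L])
  rmse <- sqrt(mean(best$fit$fvec^2))
  converged <- best$converged
  vmax <- if (converged) {
    fine <- simulate_decay(params, duration = length(obs) - 1, dt = 0.01,
                           p_init = params$p0)
    vmax_of_curve(fine)
  } else {
    NULL
  }
  # sanity bound: a fitted initial slope far above the steepest observed
  # single-step drop indicates a divergent fit, not a measurement
  max_drop <- max(-diff(obs))
  if (!is.null(vmax) && max_drop > 0 && vmax > 1.5 * max_drop) {
    converged <- FALSE
    vmax <- NULL
  }
  structure(
    list(params = params, vmax = vmax, rmse = rmse,
         converged = converged, n_points = length(obs)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "segment fit (%d samples): Vmax = %s mmHg/s, rmse = %.3f mmHg, converged = %s\n",
    x$n_points,
    if (is.null(x$vmax)) "NA" else sprintf("%.3f", x$vmax),
    x$rmse, x$converged
  ))
  invisible(x)
}

#' Subject-level mitoVO2
#'
#' The arithmetic mean of Vmax over converged segment fits: a subject's
#' overall mitoVO2. Subjects with no valid measurement yield `NULL`.
#'
#' @param fit_results List of [fit_segment()] results (possibly empty).
#' @return Mean Vmax (mmHg/s) or `NULL`.
#' @export
subject_mitovo2 <- function(fit_results) {
  v <- unlist(lapply(fit_results, function(f) {
    if (isTRUE(f$converged) && !is.null(f$vmax)) f$vmax else NULL
  }))
  if (length(v) == 0L) NULL else mean(v)
}

#' Fit all segments of a cleaned, labeled trace
#'
#' @param trace A [mito_trace()].
#' @param labels Cleaned [mito_labels()] (after [apply_rules()]).
#' @return A list with `fits` (per-segment [fit_segment()] results),
#'   `segments`, and `mitovo2` (subject mean, `NULL` if no valid fit).
#' @export
fit_trace <- function(trace, labels) {
  segments <- label_segments(labels, trace)
  fits <- lapply(segments, function(seg) {
    fit_segment(seg, initial_guess(seg, trace))
  })
  list(fits = fits, segments = segments, mitovo2 = subject_mitovo2(fits))
}
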