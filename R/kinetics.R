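#' Kinetic parameters of the stop-flow oxygen disappearance model
#'
#' Under stop-flow, mitoPO2 declines through Michaelis-Menten oxygen
#' consumption while diffusive influx from surrounding tissue partially
#' replenishes it:
#'
#' \deqn{dP/dt = -\frac{V_0 \, P}{P_{50} + P} + Z (P_0 - P)}
#'
#' @param v0 Maximal consumption scale V0 (mmHg/s), the initial decline
#'   slope after tissue compression; `v0 >= 0`.
#' @param p50 MitoPO2 at half-maximal consumption (mmHg); `p50 > 0`.
#' @param p0 Mean mitoPO2 before compression (mmHg); `p0 >= 0`. Drives the
#'   diffusive influx term.
#' @param z Diffusive oxygen influx coefficient (1/s); `z >= 0`.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(v0, p50, p0, z) {
  stopifnot(is.numeric(v0), is.numeric(p50), is.numeric(p0), is.numeric(z))
  if (v0 < 0) stop("v0 must be >= 0")
  if (p50 <= 0) stop("p50 must be > 0")
  if (p0 < 0) stop("p0 must be >= 0")
  if (z < 0) stop("z must be >= 0")
  structure(
    list(v0 = as.numeric(v0), p50 = as.numeric(p50),
         p0 = as.numeric(p0), z = as.numeric(z)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic params: V0 = %.3f mmHg/s, P50 = %.3f mmHg, P0 = %.2f mmHg, Z = %.4f 1/s\n",
    x$v0, x$p50, x$p0, x$z
  ))
  invisible(x)
}

#' Instantaneous rate of mitoPO2 change under stop-flow
#'
#' Evaluates the oxygen disappearance model
#' `-(v0 * p) / (p50 + p) + z * (p0 - p)`.
#'
#' @param p MitoPO2 (mmHg), `p >= 0`; vectorised.
#' @param params A [kinetic_params()] object.
#' @return dP/dt in mmHg/s.
#' @export
dpdt <- function(p, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(p < 0)) stop("dpdt is defined for p >= 0 only")
  -(params$v0 * p) / (params$p50 + p) + params$z * (params$p0 - p)
}

# Vector field used inside the integrator: intermediate Runge-Kutta stages
# may transiently undershoot 0; consumption is evaluated on max(p, 0) so
# the model never produces oxygen from a negative tension.
.dpdt_raw <- function(p, v0, p50, p0, z) {
  pp <- pmax(p, 0)
  -(v0 * pp) / (p50 + pp) + z * (p0 - p)
}

#' Simulate a stop-flow mitoPO2 decay
#'
#' Integrates the oxygen disappearance model with the classic 4th-order
#' Runge-Kutta scheme and returns the trajectory on the requested output
#' grid (default 1 s, the device's sampling interval). Each output step
#' is internally subdivided so that the step stays well inside the
#' model's fastest local rate `v0/p50 + z`; stiff parameter corners
#' (small `p50`, large `v0`) are therefore integrated accurately on the
#' same 1-s grid.
#'
#' @param params A [kinetic_params()] object.
#' @param duration Total simulated time (s), `> 0`.
#' @param dt Step size (s), `0 < dt <= 1`.
#' @param p_init Initial mitoPO2 (mmHg); defaults to `params$p0`, the
#'   pre-compression mean.
#' @return A data frame with columns `t` (s) and `p` (mmHg) including
#'   `t = 0`; attribute `clipped` is `TRUE` if any state undershot 0 and
#'   was clipped to 0.
#' @export
simulate_decay <- function(params, duration, dt = 1, p_init = params$p0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (duration <= 0) stop("duration must be > 0")
  if (dt <= 0 || dt > 1) stop("dt must satisfy 0 < dt <= 1")
  if (p_init < 0) stop("p_init must be >= 0")
  n <- as.integer(ceiling(duration / dt - 1e-9))
  # fastest local rate of the vector field; keep h * rate <= 0.1 so the
  # 4th-order local error (~(h*rate)^5) stays negligible even when
  # v0/p50 makes the decay stiff on the 1-s sampling grid
  rate <- params$v0 / params$p50 + params$z
  m <- max(1L, min(10000L, as.integer(ceiling(dt * rate / 0.1))))
  res <- .rk4_decay(params$v0, params$p50, params$p0, params$z,
                    n, dt, m, p_init)
  if (res$diverged_at > 0L) {
    stop(sprintf("integration diverged at step %d (t = %.3f s)",
                 res$diverged_at, res$diverged_at * dt))
  }
  out <- data.frame(t = (0:n) * dt, p = res$p)
  attr(out, "clipped") <- res$clipped
  out
}

#' Maximal oxygen consumption of a decay curve
#'
#' The tangent at the steepest drop of the curve: the magnitude of the
#' most negative per-step slope, returned as a positive rate. For a model
#' trajectory started at the pre-compression level this occurs at the very
#' beginning of the decay.
#'
#' @param series A data frame with columns `t` and `p` (as returned by
#'   [simulate_decay()]), length >= 2.
#' @return Vmax in mmHg/s (`>= 0`). A series with no declining step
#'   returns 0 with a warning.
#' @export
vmax_of_curve <- function(series) {
  stopifnot(is.data.frame(series), all(c("t", "p") %in% names(series)))
  if (nrow(series) < 2L) stop("series must contain at least 2 points")
  slopes <- diff(series$p) / diff(series$t)
  m <- min(slopes)
  if (m >= 0) {
    if (m > 0) warning("series never declines; Vmax set to 0")
    return(0)
  }
  -m
}

#' Equilibrium mitoPO2 of the stop-flow model
#'
#' Solves `v0 * p / (p50 + p) = z * (p0 - p)` for the stable equilibrium
#' in closed form (positive root of the quadratic in p).
#'
#' @param params A [kinetic_params()] object.
#' @return Equilibrium mitoPO2 (mmHg); 0 when `z == 0`.
#' @export
equilibrium_po2 <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$z == 0) return(0)
  # z p^2 + (v0 + z p50 - z p0) p - z p50 p0 = 0
  b <- params$v0 + params$z * params$p50 - params$z * params$p0
  cc <- -params$z * params$p50 * params$p0
  (-b + sqrt(b^2 - 4 * params$z * cc)) / (2 * params$z)
}
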