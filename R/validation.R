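#' Match detected start points against a reference
#'
#' Start points are considered identical when they fall within `tol`
#' samples of each other. Points are paired one-to-one by an exact
#' assignment: maximum number of matches first, smallest total absolute
#' offset among ties (computed by dynamic programming over the two
#' sorted lists). Accuracies are reported at offsets 0, 1, 3 and 5
#' samples, with the reference count as denominator; test points
#' matching no reference are reported separately and not penalised.
#'
#' @param ref Sorted unique 0-based reference start indices.
#' @param test Sorted unique 0-based detected start indices.
#' @param tol Matching tolerance in samples.
#' @return A list of class `match_report`: `n_ref`, `n_test`, `matched`,
#'   `offsets` (named count vector over -tol..+tol, test minus reference),
#'   `unmatched_test`, and `acc0`, `acc1`, `acc3`, `acc5`.
#' @export
match_starts <- function(ref, test, tol = 5L) {
  ref <- as.integer(ref)
  test <- as.integer(test)
  if (is.unsorted(ref, strictly = TRUE)) stop("ref must be sorted and unique")
  if (is.unsorted(test, strictly = TRUE)) stop("test must be sorted and unique")

  # dynamic program over the two sorted lists: maximize matched pairs,
  # then minimize total |offset|. An optimal matching of two sorted
  # sequences under a window constraint can always be taken non-crossing,
  # so the DP over prefixes is exact.
  R <- length(ref)
  Tn <- length(test)
  n_m <- matrix(0L, R + 1L, Tn + 1L)        # matches
  cost <- matrix(0, R + 1L, Tn + 1L)        # total |offset|
  better <- function(n1, c1, n2, c2) n1 > n2 || (n1 == n2 && c1 < c2)
  for (i in seq_len(R)) {
    for (j in seq_len(Tn)) {
      bn <- n_m[i, j + 1L]; bc <- cost[i, j + 1L]        # skip ref i
      if (better(n_m[i + 1L, j], cost[i + 1L, j], bn, bc)) {
        bn <- n_m[i + 1L, j]; bc <- cost[i + 1L, j]      # skip test j
      }
      d <- abs(test[j] - ref[i])
      if (d <= tol &&
          better(n_m[i, j] + 1L, cost[i, j] + d, bn, bc)) {
        bn <- n_m[i, j] + 1L; bc <- cost[i, j] + d
      }
      n_m[i + 1L, j + 1L] <- bn
      cost[i + 1L, j + 1L] <- bc
    }
  }
  offsets <- integer(0)
  used_t <- logical(Tn)
  i <- R; j <- Tn
  while (i > 0L && j > 0L) {
    d <- abs(test[j] - ref[i])
    if (d <= tol &&
        n_m[i + 1L, j + 1L] == n_m[i, j] + 1L &&
        cost[i + 1L, j + 1L] == cost[i, j] + d) {
      offsets <- c(test[j] - ref[i], offsets)
      used_t[j] <- TRUE
      i <- i - 1L; j <- j - 1L
    } else if (n_m[i + 1L, j + 1L] == n_m[i, j + 1L] &&
               cost[i + 1L, j + 1L] == cost[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  hist <- table(factor(offsets, levels = -tol:tol))
  acc <- function(k) {
    if (length(ref) == 0L) return(NA_real_)
    sum(abs(offsets) <= k) / length(ref)
  }
  structure(
    list(
      n_ref = length(ref), n_test = length(test), matched = length(offsets),
      offsets = setNames(as.integer(hist), names(hist)),
      unmatched_test = sum(!used_t),
      acc0 = acc(0L), acc1 = acc(1L), acc3 = acc(3L), acc5 = acc(tol)
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "start matching: %d/%d reference points matched (acc0 %.3f, acc1 %.3f, acc3 %.3f, acc5 %.3f); %d extra detections\n",
    x$matched, x$n_ref, x$acc0, x$acc1, x$acc3, x$acc5, x$unmatched_test
  ))
  invisible(x)
}

#' Bland-Altman agreement between two methods
#'
#' Bias is the mean paired difference `x - y`; its 95% CI comes from the
#' paired t distribution; the limits of agreement are
#' `bias +/- 1.96 * sd(x - y)`.
#'
#' @param x,y Paired per-subject values (equal length, n >= 3).
#' @return A list of class `agreement_report`: `bias`, `bias_ci95`
#'   (length-2), `loa` (length-2), `sd_diff`, `n_subjects`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired subjects")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  ci <- if (s == 0) {
    c(bias, bias)
  } else {
    bias + qt(c(0.025, 0.975), df = n - 1L) * s / sqrt(n)
  }
  structure(
    list(
      bias = bias,
      bias_ci95 = ci,
      loa = c(bias - 1.96 * s, bias + 1.96 * s),
      sd_diff = s,
      n_subjects = n
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "agreement (n = %d): bias %.3f (95%% CI %.3f to %.3f), LoA %.3f to %.3f mmHg/s\n",
    x$n_subjects, x$bias, x$bias_ci95[1L], x$bias_ci95[2L],
    x$loa[1L], x$loa[2L]
  ))
  invisible(x)
}

#' Limits of agreement for repeated measurements per subject
#'
#' Extends the Bland-Altman limits to designs where each subject
#' contributes several (possibly unequal numbers of) replicate
#' differences. The variance of a single difference is decomposed by
#' one-way ANOVA into a between-subject component (heterogeneity of the
#' subject-level bias) and a within-subject component:
#'
#' \deqn{MSW = \sum_i \sum_j (d_{ij} - \bar d_i)^2 / \sum_i (m_i - 1)}
#' \deqn{MSB = \sum_i m_i (\bar d_i - \bar d)^2 / (k - 1)}
#' \deqn{n_0 = \left(\sum m_i - \sum m_i^2 / \sum m_i\right) / (k - 1)}
#' \deqn{\hat\sigma^2_b = \max(0, (MSB - MSW) / n_0), \quad
#'       \hat\sigma^2_d = \hat\sigma^2_b + MSW}
#'
#' where `m_i` is subject i's replicate count and `d-bar` is the overall
#' mean difference (the bias). The limits are
#' `bias +/- 1.96 * sigma_d`. With one replicate per subject throughout,
#' the within component cannot be estimated and the computation falls
#' back to [bland_altman()] on the single differences, with a warning.
#'
#' @param per_subject_diffs List (one element per subject, >= 3 subjects)
#'   of numeric vectors of replicate differences.
#' @return A list of class `agreement_report` (see [bland_altman()]) with
#'   additional fields `sigma2_between`, `sigma2_within`.
#' @export
extended_loa <- function(per_subject_diffs) {
  k <- length(per_subject_diffs)
  if (k < 3L) stop("need at least 3 subjects")
  m <- lengths(per_subject_diffs)
  if (any(m < 1L)) stop("every subject needs at least 1 replicate difference")
  if (all(m == 1L)) {
    warning("all subjects have a single replicate; falling back to plain Bland-Altman limits")
    d <- unlist(per_subject_diffs)
    out <- bland_altman(d, rep(0, k))
    out$sigma2_between <- NULL
    out$sigma2_within <- NULL
    return(out)
  }
  d <- unlist(per_subject_diffs)
  N <- sum(m)
  bias <- mean(d)
  means <- vapply(per_subject_diffs, mean, 0)
  ssw <- sum(vapply(seq_len(k), function(i) {
    sum((per_subject_diffs[[i]] - means[i])^2)
  }, 0))
  msw <- ssw / (N - k)
  msb <- sum(m * (means - bias)^2) / (k - 1L)
  n0 <- (N - sum(m^2) / N) / (k - 1L)
  sigma2_b <- max(0, (msb - msw) / n0)
  sigma2_d <- sigma2_b + msw
  s <- sqrt(sigma2_d)
  # bias CI: Var(mean of all differences) under the components model
  se <- sqrt(sigma2_b * sum(m^2) / N^2 + msw / N)
  ci <- bias + qt(c(0.025, 0.975), df = k - 1L) * se
  structure(
    list(
      bias = bias,
      bias_ci95 = ci,
      loa = c(bias - 1.96 * s, bias + 1.96 * s),
      sd_diff = s,
      n_subjects = k,
      sigma2_between = sigma2_b,
      sigma2_within = msw
    ),
    class = "agreement_report"
  )
}

#' Comparability decision for two methods
#'
#' Two methods are deemed comparable when the 95% CI of their bias lies
#' entirely within the predefined comparability range (default
#' +/- 0.3 mmHg/s, a non-inferiority-style margin). The interval check is
#' inclusive at the boundary.
#'
#' @param report An `agreement_report` from [bland_altman()] or
#'   [extended_loa()].
#' @param margin Comparability half-width (mmHg/s).
#' @return `TRUE` iff `bias_ci95` is contained in `[-margin, margin]`.
#' @export
comparability <- function(report, margin = 0.3) {
  stopifnot(inherits(report, "agreement_report"))
  report$bias_ci95[1L] >= -margin && report$bias_ci95[2L] <= margin
}
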