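# Exhaustive assignment oracle for start matching: maximum-cardinality
# one-to-one assignment within tolerance, minimizing total |offset| among
# ties. Feasible for <= 8 points.
oracle_match <- function(ref, test, tol = 5) {
  best <- list(n = -1, cost = Inf)
  k <- min(length(ref), length(test))
  assign_rec <- function(ri, used_t, pairs) {
    if (ri > length(ref)) {
      n <- nrow(pairs)
      cost <- if (n > 0) sum(abs(pairs$off)) else 0
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    # leave ref[ri] unmatched
    assign_rec(ri + 1, used_t, pairs)
    for (ti in seq_along(test)) {
      if (!used_t[ti] && abs(test[ti] - ref[ri]) <= tol) {
        u <- used_t; u[ti] <- TRUE
        assign_rec(ri + 1, u,
                   rbind(pairs, data.frame(r = ri, t = ti,
                                           off = test[ti] - ref[ri])))
      }
    }
  }
  assign_rec(1, logical(length(test)), data.frame(r = integer(0), t = integer(0), off = integer(0)))
  best
}

test_that("start matching reproduces the documented offset behaviour", {
  rep <- match_starts(100L, 105L)
  expect_equal(rep$matched, 1L)
  expect_equal(rep$offsets[["5"]], 1L)
  expect_equal(rep$acc5, 1)
  expect_equal(rep$acc3, 0)
  expect_equal(rep$acc0, 0)

  identical_rep <- match_starts(c(10L, 200L, 350L), c(10L, 200L, 350L))
  expect_equal(identical_rep$acc0, 1)
  expect_equal(identical_rep$matched, 3L)

  # the crossing case: the optimal assignment pairs 100-104 and 110-106
  rep2 <- match_starts(c(100L, 110L), c(104L, 106L))
  orc <- oracle_match(c(100, 110), c(104, 106))
  expect_equal(rep2$matched, orc$n)
  expect_equal(rep2$offsets[["4"]], 1L)
  expect_equal(rep2$offsets[["-4"]], 1L)

  expect_error(match_starts(c(5L, 3L), 4L), "sorted")
})

test_that("greedy matching attains the exhaustive optimum on random cases", {
  set.seed(88)
  for (i in 1:25) {
    ref <- sort(sample(0:40, sample(2:6, 1)))
    test <- sort(sample(0:40, sample(2:6, 1)))
    rep <- match_starts(ref, test)
    orc <- oracle_match(ref, test)
    expect_equal(rep$matched, orc$n, info = paste("case", i))
    # symmetry: swapping the roles negates offsets, count unchanged
    swapped <- match_starts(test, ref)
    expect_equal(swapped$matched, rep$matched)
    expect_equal(unname(swapped$offsets), unname(rev(rep$offsets)))
  }
})

test_that("match reports respect their structural invariants", {
  set.seed(99)
  for (i in 1:20) {
    ref <- sort(sample(0:60, sample(1:8, 1)))
    test <- sort(sample(0:60, sample(1:8, 1)))
    rep <- match_starts(ref, test)
    expect_lte(rep$matched, min(rep$n_ref, rep$n_test))
    expect_equal(sum(rep$offsets), rep$matched)
    accs <- c(rep$acc0, rep$acc1, rep$acc3, rep$acc5)
    expect_true(all(diff(accs) >= 0))
    expect_lte(rep$acc5, 1)
    expect_equal(rep$n_test - rep$matched, rep$unmatched_test)
  }
})

test_that("Bland-Altman reproduces hand-computed bias and limits", {
  # differences 1, -1, 1, -1: bias 0, sd = sqrt(4/3)
  x <- c(1, 0, 1, 0)
  y <- c(0, 1, 0, 1)
  rep <- bland_altman(x, y)
  expect_equal(rep$bias, 0)
  expect_equal(rep$sd_diff, sqrt(4 / 3))
  expect_equal(rep$loa, c(-1, 1) * 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  # CI matches the paired t-test
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(rep$bias_ci95, as.numeric(tt$conf.int), tolerance = 1e-12)

  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$bias, 0)
  expect_equal(same$loa, c(0, 0))

  const <- bland_altman(c(5, 6, 7) + 0.4, c(5, 6, 7))
  expect_equal(const$bias, 0.4)
  expect_equal(diff(const$loa), 0)

  expect_error(bland_altman(1:2, 1:2), "at least 3")
  expect_error(bland_altman(1:4, 1:3), "equal length")
})

test_that("the limits of agreement cover ~95% of normal differences", {
  set.seed(12)
  n <- 1e5
  x <- rnorm(n, 10, 2)
  y <- rnorm(n, 9.5, 2)
  rep <- bland_altman(x, y)
  d <- x - y
  cover <- mean(d >= rep$loa[1] & d <= rep$loa[2])
  expect_lt(abs(cover - 0.95), 0.005)
})

test_that("extended limits agree with ANOVA variance components (oracle)", {
  diffs <- list(
    c(1.0, 1.4),
    c(0.2, 0.5, 0.9),
    c(-0.3, 0.1, 0.6, 0.2, 0.4)
  )
  rep <- extended_loa(diffs)

  # independent oracle: one-way ANOVA mean squares via stats::aov
  d <- unlist(diffs)
  subj <- factor(rep(seq_along(diffs), lengths(diffs)))
  ms <- anova(aov(d ~ subj))
  msb <- ms$`Mean Sq`[1]
  msw <- ms$`Mean Sq`[2]
  m <- lengths(diffs)
  N <- sum(m)
  k <- length(m)
  n0 <- (N - sum(m^2) / N) / (k - 1)
  sigma2_d <- max(0, (msb - msw) / n0) + msw
  expect_equal(rep$sd_diff, sqrt(sigma2_d), tolerance = 1e-10)
  expect_equal(rep$bias, mean(d))
  expect_equal(rep$loa, mean(d) + c(-1, 1) * 1.96 * sqrt(sigma2_d),
               tolerance = 1e-10)
  expect_true(rep$bias >= rep$loa[1] && rep$bias <= rep$loa[2])
  expect_true(rep$bias >= rep$bias_ci95[1] && rep$bias <= rep$bias_ci95[2])
})

test_that("extended limits collapse to plain limits in degenerate designs", {
  # single replicate everywhere: plain Bland-Altman with a warning
  singles <- list(0.5, -0.2, 0.9, 0.1)
  expect_warning(rep <- extended_loa(singles), "single replicate")
  plain <- bland_altman(unlist(singles), rep(0, 4))
  expect_equal(rep$loa, plain$loa)
  expect_equal(rep$bias, plain$bias)

  # balanced design with zero within-subject variance: limits on the means
  means <- c(0.3, -0.4, 0.8, 0.05)
  balanced <- lapply(means, function(mu) rep(mu, 3))
  rep2 <- extended_loa(balanced)
  plain2 <- bland_altman(means, rep(0, 4))
  expect_equal(rep2$loa, plain2$loa, tolerance = 1e-10)
  expect_equal(rep2$bias_ci95, plain2$bias_ci95, tolerance = 1e-10)
})

test_that("comparability requires the bias CI inside the margin", {
  mk <- function(lo, hi) {
    structure(list(bias = (lo + hi) / 2, bias_ci95 = c(lo, hi),
                   loa = c(lo - 1, hi + 1), sd_diff = 1, n_subjects = 10L),
              class = "agreement_report")
  }
  expect_true(comparability(mk(-0.15, 0.27)))
  expect_false(comparability(mk(-0.4, 0.1)))
  expect_true(comparability(mk(-0.3, 0.3)))  # closed interval
  expect_false(comparability(mk(-0.31, 0.1)))
  expect_true(comparability(mk(-0.5, 0.5), margin = 0.6))
})
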