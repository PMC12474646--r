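# Small helper building a trace/label pair from explicit vectors.
pp_case <- function(values, labels) {
  tr <- mito_trace(values)
  list(trace = tr, labels = mito_labels(labels, tr))
}

test_that("short na holes inside a measurement run are filled", {
  # m m na m m plus enough context for the run to survive later rules
  v <- c(rep(60, 5), 58, seq(55, 10, by = -3), rep(40, 5))
  lab <- c(rep("na", 5), "start", rep("measurement", 3), "na", "na",
           rep("measurement", 11), rep("na", 5))
  case <- pp_case(v, lab)
  out <- apply_rules(case$labels, case$trace)
  expect_true("R1" %in% out$log$rule)
  expect_length(out$segments, 1L)
  expect_equal(out$segments[[1]]$start_index, 5L)
  expect_equal(out$segments[[1]]$end_index, 21L)
})

test_that("an unheaded run of >= 10 measurements gains a start", {
  v <- c(rep(60, 5), seq(58, by = -3.5, length.out = 13), rep(40, 8))
  lab <- c(rep("na", 5), rep("measurement", 13), rep("na", 8))
  case <- pp_case(v, lab)
  out <- apply_rules(case$labels, case$trace)
  expect_true("R2" %in% out$log$rule)
  expect_length(out$segments, 1L)
  expect_equal(out$segments[[1]]$start_index, 5L)
})

test_that("the later of two starts within 30 samples is discarded", {
  v <- c(rep(60, 100), seq(60, 3, by = -3), rep(50, 100))
  lab <- rep("na", length(v))
  lab[101] <- "start"
  lab[102:120] <- "measurement"
  lab[121] <- "start" # 20 samples after the first: discarded
  out <- apply_rules(mito_labels(lab), mito_trace(v))
  expect_true("R3" %in% out$log$rule)
  expect_length(out$segments, 1L)
  expect_equal(out$segments[[1]]$start_index, 100L)
})

test_that("measurements starting at <= 20 mmHg are excluded", {
  v <- c(rep(18, 10), seq(18, 2, by = -1), rep(15, 10))
  lab <- c(rep("na", 10), "start", rep("measurement", 16), rep("na", 10))
  out <- apply_rules(mito_labels(lab), mito_trace(v))
  expect_true("R4" %in% out$log$rule)
  expect_length(out$segments, 0L)
})

test_that("measurements never dropping below 20 mmHg are excluded", {
  v <- c(rep(60, 10), seq(60, 30, by = -2), rep(55, 10))
  lab <- c(rep("na", 10), "start", rep("measurement", 15), rep("na", 10))
  out <- apply_rules(mito_labels(lab), mito_trace(v))
  expect_true("R4" %in% out$log$rule)
  expect_length(out$segments, 0L)
})

test_that("a start is recentered on the highest mitoPO2 within 7 samples", {
  # start labeled 3 samples early; the true peak (58) is at index 43
  v <- c(rep(55, 40), 55, 55, 55, 58, seq(55, 13, by = -3), rep(45, 20))
  lab <- rep("na", length(v))
  lab[41] <- "start" # 0-based index 40
  lab[42:58] <- "measurement"
  out <- apply_rules(mito_labels(lab), mito_trace(v))
  expect_true("QC1" %in% out$log$rule)
  expect_length(out$segments, 1L)
  expect_equal(out$segments[[1]]$start_index, 43L)
})

test_that("a > 50 mmHg first-step drop invalidates the measurement", {
  v <- c(rep(80, 10), 80, 25, seq(24, 2, by = -2), rep(40, 10))
  lab <- c(rep("na", 10), "start", rep("measurement", 13), rep("na", 10))
  out <- apply_rules(mito_labels(lab), mito_trace(v))
  expect_true("QC3" %in% out$log$rule)
  expect_length(out$segments, 0L)
})

test_that("the adversarial fixture resolves to the hand-computed segments", {
  fx <- adversarial_fixture()
  out <- apply_rules(fx$labels, fx$trace)

  got <- vapply(out$segments, function(s) c(s$start_index, s$end_index), numeric(2))
  expect_equal(
    t(got),
    rbind(
      c(40L, 55L),    # na hole filled (R1)
      c(108L, 119L),  # start recovered by promotion (R2)
      c(170L, 184L),  # double start resolved (R3 + R5)
      c(360L, 374L),  # gap after start filled (R2/R3/R5 interplay)
      c(428L, 442L),  # start recentered onto the true peak (QC1)
      c(495L, 507L)   # start shifted past the bounce (QC2)
    ),
    ignore_attr = TRUE
  )
  # every rule fires exactly where designed
  expect_setequal(unique(out$log$rule),
                  c("R1", "R2", "R3", "R4", "R5", "QC1", "QC2", "QC3", "QC4"))
  expect_equal(sum(out$log$rule == "R4"), 2L) # low start + never below 20
  expect_equal(sum(out$log$rule == "QC3"), 1L)
  expect_equal(sum(out$log$rule == "QC4"), 1L)
  expect_equal(sum(out$log$rule == "QC1"), 1L)
  expect_equal(sum(out$log$rule == "QC2"), 1L)
})

test_that("the rule engine is idempotent", {
  fx <- adversarial_fixture()
  once <- apply_rules(fx$labels, fx$trace)
  twice <- apply_rules(once$labels, fx$trace)
  expect_identical(unclass(once$labels), unclass(twice$labels))
  expect_equal(nrow(twice$log), 0L)

  # also on noisy generated data with imperfect labels
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 2, seed = 71)))
  for (s in coh) {
    once <- apply_rules(s$labels, s$trace)
    twice <- apply_rules(once$labels, s$trace)
    expect_identical(unclass(once$labels), unclass(twice$labels))
  }
})

test_that("surviving segments satisfy every validity requirement", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n_subjects = 3, seed = 53)))
  for (s in coh) {
    out <- apply_rules(s$labels, s$trace)
    p <- s$trace$mitopo2
    starts <- vapply(out$segments, `[[`, 0L, "start_index") + 1L
    expect_true(all(diff(starts) > 30))
    for (seg in out$segments) {
      i0 <- seg$start_index + 1L
      i1 <- seg$end_index + 1L
      expect_gt(p[i0], 20)
      expect_lt(min(p[i0:i1]), 20)
      expect_gt(i1 - i0 + 1L, 10)
      w <- i0:min(i0 + 6L, i1)
      expect_equal(which.max(p[w]), 1L)
      ks <- i0:min(i0 + 2L, i1 - 1L)
      expect_true(all(p[ks + 1L] - p[ks] <= 2))
      expect_lte(p[i0] - p[i0 + 1L], 50)
    }
    # no measurement label outside a surviving segment
    lab <- unclass(out$labels)
    inside <- rep(FALSE, length(lab))
    for (seg in out$segments) inside[(seg$start_index + 1L):(seg$end_index + 1L)] <- TRUE
    expect_false(any(lab == "measurement" & !inside))
  }
})
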