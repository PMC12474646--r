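test_that("z-score normalization centers and scales per trace", {
  x <- normalize_trace(mito_trace(c(50, 60, 70)))
  expect_equal(mean(x), 0)
  expect_equal(sd(x), 1)
  expect_equal(x, c(-1, 0, 1) * (10 / sd(c(50, 60, 70))))
  # idempotent up to re-estimation
  expect_equal(normalize_trace(x), x, tolerance = 1e-12)
  expect_error(normalize_trace(mito_trace(rep(60, 10))), "zero variance")
})

test_that("window offsets follow the 250/10 overlap scheme", {
  # enumeration oracle: all o with o + 250 <= n, plus a clamped tail window
  oracle <- function(n, window = 250, step = 10) {
    off <- seq(0, n - window, by = step)
    off <- off[off + window <= n]
    if (max(off) < n - window) off <- c(off, n - window)
    off
  }
  for (n in c(250, 260, 505, 1000, 1003)) {
    tr <- mito_trace(sin(seq_len(n) / 5) * 10 + 60)
    ws <- make_windows(tr)
    expect_equal(ws$offsets, as.integer(oracle(n)), info = paste("n =", n))
  }
  # the documented cases: 260 samples -> offsets 0 and 10; 250 -> one window
  expect_equal(make_windows(mito_trace(rnorm(260, 60)))$offsets, c(0L, 10L))
  expect_length(make_windows(mito_trace(rnorm(250, 60)))$offsets, 1L)
})

test_that("short traces are tail-padded with masked na targets", {
  tr <- mito_trace(rnorm(100, 60))
  lab <- mito_labels(rep("na", 100))
  ws <- make_windows(tr, lab)
  expect_equal(dim(ws$x), c(250L, 1L))
  expect_equal(ws$x[101:250, 1], rep(ws$x[100, 1], 150))
  expect_equal(ws$y[101:250, 1], rep(0L, 150))
  expect_equal(ws$n_samples, 100L)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  H <- 4; Tn <- 8; B <- 3
  rmat <- function(r, c) matrix(rnorm(r * c, 0, 0.4), r, c)
  params <- list(
    Wxf = rmat(4 * H, 1), Whf = rmat(4 * H, H), bf = rnorm(4 * H, 0, 0.4),
    Wxb = rmat(4 * H, 1), Whb = rmat(4 * H, H), bb = rnorm(4 * H, 0, 0.4),
    Wy = rmat(3, 2 * H), by = rnorm(3, 0, 0.4)
  )
  X <- matrix(rnorm(Tn * B), Tn, B)
  Y <- matrix(sample(1:3, Tn * B, replace = TRUE), Tn, B)
  Y[1, 1] <- 0L # a masked sample
  lg <- mitovo2:::.bilstm_loss_grad(params, X, Y)
  num_grad <- function(nm, i, eps = 1e-6) {
    up <- params; dn <- params
    up[[nm]][i] <- up[[nm]][i] + eps
    dn[[nm]][i] <- dn[[nm]][i] - eps
    (mitovo2:::.bilstm_loss_grad(up, X, Y)$loss -
        mitovo2:::.bilstm_loss_grad(dn, X, Y)$loss) / (2 * eps)
  }
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(8, length(params[[nm]])))
    for (i in idx) {
      expect_equal(lg$grads[[nm]][i], num_grad(nm, i), tolerance = 1e-5,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("softmax outputs are proper per-sample distributions", {
  set.seed(3)
  H <- 4
  rmat <- function(r, c) matrix(rnorm(r * c, 0, 0.4), r, c)
  params <- list(
    Wxf = rmat(4 * H, 1), Whf = rmat(4 * H, H), bf = rnorm(4 * H),
    Wxb = rmat(4 * H, 1), Whb = rmat(4 * H, H), bb = rnorm(4 * H),
    Wy = rmat(3, 2 * H), by = rnorm(3)
  )
  P <- mitovo2:::.bilstm_probs(params, matrix(rnorm(40), 20, 2))
  expect_true(all(abs(apply(P, c(2, 3), sum) - 1) < 1e-6))
  expect_true(all(P >= 0))
})

test_that("hyperparameters outside the supported box are rejected", {
  expect_error(model_config(hidden_units = 40), "hidden_units")
  expect_error(model_config(initial_learn_rate = 2), "initial_learn_rate")
  expect_error(model_config(max_epochs = 0), "max_epochs")
  expect_error(model_config(max_epochs = 5), "max_epochs")
  expect_error(model_config(mini_batch_size = 10), "mini_batch_size")
  # the tuned defaults are inside the box
  cfg <- model_config()
  expect_equal(cfg$hidden_units, 55L)
  expect_equal(cfg$initial_learn_rate, 0.0137)
  expect_equal(cfg$max_epochs, 3L)
  expect_equal(cfg$mini_batch_size, 80L)
})

test_that("training and prediction are deterministic under a fixed seed", {
  coh <- tiny_cohort()
  cfg <- model_config(max_epochs = 2, seed = 99)
  m1 <- train_segmenter(coh, cfg)
  m2 <- train_segmenter(coh, cfg)
  expect_identical(m1$params, m2$params)
  probe <- coh[[1]]$trace
  expect_identical(unclass(predict_labels(m1, probe)),
                   unclass(predict_labels(m2, probe)))
  expect_identical(unclass(predict_labels(m1, probe)),
                   unclass(predict_labels(m1, probe)))
})

test_that("a model trained on only-na windows warns about degeneracy", {
  tr <- mito_trace(rnorm(300, 60))
  ws <- make_windows(tr, mito_labels(rep("na", 300)))
  expect_warning(train_segmenter(list(ws), model_config(max_epochs = 2, seed = 1)),
                 "only 'na'")
})

test_that("checkpoints round-trip through disk", {
  coh <- tiny_cohort()
  m <- train_segmenter(coh, model_config(max_epochs = 2, seed = 4))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m$params, m2$params)
  expect_error(load_model(withr::local_tempfile()), "not found")
})

test_that("random search stays inside the box and is reproducible", {
  coh <- tiny_cohort(n_subjects = 4, seed = 55)
  expect_error(tune_segmenter(coh, 0), "budget_trials")
  best1 <- tune_segmenter(coh, 2, seed = 10)
  best2 <- tune_segmenter(coh, 2, seed = 10)
  expect_equal(unclass(best1)[], unclass(best2)[])
  expect_true(best1$hidden_units >= 50 && best1$hidden_units <= 80)
  expect_true(best1$initial_learn_rate >= 0.001 && best1$initial_learn_rate <= 1)
  expect_true(best1$max_epochs %in% 2:4)
  expect_true(best1$mini_batch_size >= 60 && best1$mini_batch_size <= 100)
  expect_false(is.na(attr(best1, "validation_error")))
  single <- tune_segmenter(coh, 1, seed = 11)
  expect_equal(nrow(attr(single, "trials")), 1L)
})
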