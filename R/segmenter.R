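#' Segmenter network configuration
#'
#' Hyperparameters of the bidirectional LSTM point labeler. The permitted
#' box matches the hyperparameter search space (hidden units 50-80,
#' initial learning rate 0.001-1, 2-4 epochs, mini-batch 60-100); the
#' defaults are the tuned values used for the final network (55 hidden
#' units, learning rate 0.0137, 3 epochs, mini-batch 80).
#'
#' @param hidden_units LSTM cells per direction, in `[50, 80]`.
#' @param initial_learn_rate Adam learning rate, in `[0.001, 1]`.
#' @param max_epochs Training epochs, in `[2, 4]`.
#' @param mini_batch_size Windows per mini-batch, in `[60, 100]`.
#' @param seed Integer seed controlling weight initialisation and epoch
#'   shuffling; retraining with the same seed reproduces the weights.
#' @return A list of class `model_config`.
#' @export
model_config <- function(hidden_units = 55L, initial_learn_rate = 0.0137,
                         max_epochs = 3L, mini_batch_size = 80L, seed = 1L) {
  if (hidden_units < 50 || hidden_units > 80) {
    stop("hidden_units must be in [50, 80]")
  }
  if (initial_learn_rate < 0.001 || initial_learn_rate > 1) {
    stop("initial_learn_rate must be in [0.001, 1]")
  }
  if (max_epochs < 2 || max_epochs > 4) {
    stop("max_epochs must be in [2, 4]")
  }
  if (mini_batch_size < 60 || mini_batch_size > 100) {
    stop("mini_batch_size must be in [60, 100]")
  }
  structure(
    list(
      hidden_units = as.integer(hidden_units),
      initial_learn_rate = initial_learn_rate,
      max_epochs = as.integer(max_epochs),
      mini_batch_size = as.integer(mini_batch_size),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Z-score normalize a trace
#'
#' Centers to mean 0 and scales to (sample) standard deviation 1, per
#' trace: subjects differ in baseline level while the device is
#' relative-scale stable within a session.
#'
#' @param trace A [mito_trace()] or numeric vector of length >= 2.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
normalize_trace <- function(trace) {
  x <- if (inherits(trace, "mito_trace")) trace$mitopo2 else as.numeric(trace)
  if (length(x) < 2L) stop("normalization requires at least 2 samples")
  s <- sd(x)
  if (s == 0) stop("constant trace has zero variance; cannot z-score")
  (x - mean(x)) / s
}

.label_to_int <- function(labels) {
  match(unclass(labels), LABEL_LEVELS) # 1 = start, 2 = measurement, 3 = na
}

# Window offsets (0-based) covering a trace of length n: all full windows
# at the given stride, plus a final clamped window so the tail is covered.
.window_offsets <- function(n, window, step) {
  if (n <= window) return(0L)
  off <- seq(0L, n - window, by = step)
  if (off[length(off)] != n - window) off <- c(off, n - window)
  off
}

#' Slice a trace into overlapping training windows
#'
#' Cuts the z-score-normalized trace into fixed-length windows (default
#' 250 samples at stride 10, i.e. 240-sample overlap), each with
#' per-sample class targets. Traces shorter than the window are padded at
#' the tail with the last value and `na` targets; padded samples are
#' masked out of the loss.
#'
#' @param trace A [mito_trace()].
#' @param labels Aligned [mito_labels()] (or `NULL` for inference-only
#'   windows).
#' @param window Window length in samples.
#' @param step Stride between consecutive window offsets.
#' @return A list of class `window_set`: `x` (window x n matrix of
#'   normalized values), `y` (integer targets, 0 = padded), `offsets`
#'   (0-based), `trace_id`, `n_samples` (unpadded trace length).
#' @export
make_windows <- function(trace, labels = NULL, window = 250L, step = 10L) {
  stopifnot(inherits(trace, "mito_trace"))
  xn <- normalize_trace(trace)
  n <- length(xn)
  yi <- if (is.null(labels)) rep(3L, n) else .label_to_int(mito_labels(labels, trace))
  if (n < window) {
    xn <- c(xn, rep(xn[n], window - n))
    yi <- c(yi, rep(0L, window - n)) # padded: excluded from loss
  }
  off <- .window_offsets(max(n, window), window, step)
  x <- vapply(off, function(o) xn[(o + 1L):(o + window)], numeric(window))
  y <- vapply(off, function(o) yi[(o + 1L):(o + window)], integer(window))
  structure(
    list(
      x = matrix(x, nrow = window), y = matrix(y, nrow = window),
      offsets = as.integer(off),
      trace_id = attr(trace, "subject_id"), n_samples = n
    ),
    class = "window_set"
  )
}

# Concatenate window sets from several traces into one training pool.
.pool_windows <- function(window_sets) {
  list(
    x = do.call(cbind, lapply(window_sets, `[[`, "x")),
    y = do.call(cbind, lapply(window_sets, `[[`, "y"))
  )
}

# Weight initialisation: uniform(-1/sqrt(H), 1/sqrt(H)) as is conventional
# for LSTM layers, with the forget-gate bias raised to +1.
.nn_init <- function(hidden, seed) {
  set.seed(seed)
  H <- hidden
  k <- 1 / sqrt(H)
  rmat <- function(r, c) matrix(runif(r * c, -k, k), r, c)
  init_dir <- function() {
    b <- runif(4 * H, -k, k)
    b[(H + 1):(2 * H)] <- 1
    list(Wx = rmat(4 * H, 1), Wh = rmat(4 * H, H), b = b)
  }
  fwd <- init_dir()
  bwd <- init_dir()
  ko <- 1 / sqrt(2 * H)
  list(
    Wxf = fwd$Wx, Whf = fwd$Wh, bf = fwd$b,
    Wxb = bwd$Wx, Whb = bwd$Wh, bb = bwd$b,
    Wy = matrix(runif(3 * 2 * H, -ko, ko), 3, 2 * H),
    by = runif(3, -ko, ko)
  )
}

# One Adam step over the full parameter list.
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the bidirectional LSTM point labeler
#'
#' Trains a sequence-to-sequence classifier (univariate input, biLSTM with
#' `hidden_units` cells per direction, per-sample linear map to 3 scores,
#' softmax, cross-entropy loss, Adam) on windows cut from labeled traces.
#'
#' @param cohort Either a list of subjects (each with `trace` and `labels`,
#'   as produced by [generate_cohort()]) or a list of [make_windows()]
#'   window sets.
#' @param config A [model_config()].
#' @param window,step Window length and stride used to cut traces.
#' @return A model of class `mito_segmenter` carrying the trained weights,
#'   the configuration and the windowing/normalization convention.
#' @export
train_segmenter <- function(cohort, config = model_config(),
                            window = 250L, step = 10L) {
  stopifnot(inherits(config, "model_config"))
  wsets <- if (length(cohort) > 0 && inherits(cohort[[1L]], "window_set")) {
    cohort
  } else {
    lapply(cohort, function(s) make_windows(s$trace, s$labels, window, step))
  }
  if (length(wsets) == 0L) stop("empty training set")
  pool <- .pool_windows(wsets)
  nw <- ncol(pool$x)
  if (!any(pool$y %in% c(1L, 2L))) {
    warning("training targets contain only 'na'; classifier will be degenerate")
  }

  params <- .nn_init(config$hidden_units, config$seed)
  state <- list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  losses <- numeric(0)
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(nw)
    batch_starts <- seq(1L, nw, by = config$mini_batch_size)
    for (bs in batch_starts) {
      idx <- perm[bs:min(bs + config$mini_batch_size - 1L, nw)]
      res <- .bilstm_loss_grad(
        params,
        pool$x[, idx, drop = FALSE],
        pool$y[, idx, drop = FALSE]
      )
      upd <- .adam_step(params, res$grads, state, config$initial_learn_rate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, res$loss)
    }
  }

  structure(
    list(
      params = params,
      config = config,
      window = as.integer(window),
      step = as.integer(step),
      classes = LABEL_LEVELS,
      n_windows = nw,
      final_loss = losses[length(losses)],
      loss_history = losses
    ),
    class = "mito_segmenter"
  )
}

#' @export
print.mito_segmenter <- function(x, ...) {
  cat(sprintf(
    "biLSTM segmenter: %d hidden units/direction, trained on %d windows (final loss %.4f)\n",
    x$config$hidden_units, x$n_windows, x$final_loss
  ))
  invisible(x)
}

#' Per-sample class probabilities for a trace
#'
#' Runs the network on overlapping windows covering the whole trace and
#' averages class probabilities where windows overlap.
#'
#' @param model A trained `mito_segmenter`.
#' @param trace A [mito_trace()] of length >= 2.
#' @return A 3 x n matrix of class probabilities (rows: start,
#'   measurement, na), columns summing to 1.
#' @export
predict_probs <- function(model, trace) {
  stopifnot(inherits(model, "mito_segmenter"))
  if (nrow(trace) < 2L) stop("trace must contain at least 2 samples")
  ws <- make_windows(trace, labels = NULL, window = model$window, step = model$step)
  pr <- .bilstm_probs(model$params, ws$x) # 3 x n_windows x window
  n <- ws$n_samples
  acc <- matrix(0, 3, n)
  cnt <- numeric(n)
  for (w in seq_along(ws$offsets)) {
    o <- ws$offsets[w]
    span <- (o + 1L):min(o + model$window, n) # clip padding on short traces
    acc[, span] <- acc[, span] + pr[, w, seq_along(span)]
    cnt[span] <- cnt[span] + 1
  }
  sweep(acc, 2L, cnt, "/")
}

#' Label a trace with the trained network
#'
#' Per-sample argmax over the window-averaged class probabilities; a pure
#' function of the model weights and the trace.
#'
#' @param model A trained `mito_segmenter`.
#' @param trace A [mito_trace()].
#' @return A [mito_labels()] vector aligned to `trace`.
#' @export
predict_labels <- function(model, trace) {
  probs <- predict_probs(model, trace)
  mito_labels(LABEL_LEVELS[apply(probs, 2L, which.max)])
}

#' Save / load a trained segmenter checkpoint
#'
#' The checkpoint is a single RDS file containing weights, configuration
#' and the windowing/normalization convention.
#'
#' @param model A `mito_segmenter`.
#' @param path Checkpoint path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mito_segmenter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "mito_segmenter")) stop("not a segmenter checkpoint")
  model
}

#' Per-sample validation error of a model on labeled windows
#'
#' @param model A trained `mito_segmenter`.
#' @param subjects List of subjects with `trace` and `labels`.
#' @return Misclassification rate over all samples.
#' @export
classification_error <- function(model, subjects) {
  err <- 0L
  tot <- 0L
  for (s in subjects) {
    pred <- predict_labels(model, s$trace)
    err <- err + sum(unclass(pred) != unclass(s$labels))
    tot <- tot + length(pred)
  }
  err / tot
}

#' Reduced-budget hyperparameter search
#'
#' Seeded random search over the hyperparameter box (hidden units 50-80,
#' learning rate log-uniform on 0.001-1, epochs 2-4, mini-batch 60-100).
#' Subjects are split 80/10/10 into train/validation/test; each candidate
#' is trained on the training split and scored by per-sample
#' classification error on the validation split.
#'
#' @param cohort List of labeled subjects.
#' @param budget_trials Number of candidate configurations (>= 1).
#' @param seed Integer seed for the split and the candidate draws.
#' @return The best [model_config()] found, with attributes
#'   `validation_error` and `trials` (the search trace).
#' @export
tune_segmenter <- function(cohort, budget_trials, seed = 1L) {
  if (budget_trials < 1) stop("budget_trials must be >= 1")
  n <- length(cohort)
  if (n < 3L) stop("need at least 3 subjects for an 80/10/10 split")
  set.seed(seed)
  perm <- sample.int(n)
  n_val <- max(1L, round(0.1 * n))
  n_test <- max(1L, round(0.1 * n))
  val_idx <- perm[seq_len(n_val)]
  test_idx <- perm[n_val + seq_len(n_test)]
  train_idx <- setdiff(perm, c(val_idx, test_idx))

  draws <- data.frame(
    hidden_units = sample(50:80, budget_trials, replace = TRUE),
    initial_learn_rate = exp(runif(budget_trials, log(0.001), log(1))),
    max_epochs = sample(2:4, budget_trials, replace = TRUE),
    mini_batch_size = sample(60:100, budget_trials, replace = TRUE)
  )
  draws$validation_error <- NA_real_
  best <- NULL
  best_err <- Inf
  for (i in seq_len(budget_trials)) {
    cfg <- model_config(
      hidden_units = draws$hidden_units[i],
      initial_learn_rate = draws$initial_learn_rate[i],
      max_epochs = draws$max_epochs[i],
      mini_batch_size = draws$mini_batch_size[i],
      seed = seed + i
    )
    model <- train_segmenter(cohort[train_idx], cfg)
    err <- classification_error(model, cohort[val_idx])
    draws$validation_error[i] <- err
    if (err < best_err) {
      best_err <- err
      best <- cfg
    }
  }
  attr(best, "validation_error") <- best_err
  attr(best, "trials") <- draws
  best
}
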