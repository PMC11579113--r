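#' Configuration of the 3D convolutional brain-age regressor
#'
#' Four convolutional blocks (3D convolution with a 6^3 kernel, batch
#' normalization, ReLU, 2^3 max-pooling; dropout 0.2 on blocks 2-4), followed
#' by two dense layers producing the scalar brain-age estimate. Convolutions
#' use stride 1 with "same" padding so the pooling arithmetic holds at any
#' power-of-two input size. Training minimizes mean absolute error with Adam
#' and stops early after `patience` epochs without validation improvement.
#'
#' @param input_size voxels per axis of the input volume.
#' @param conv_filters filter counts of the four blocks
#'   (default `c(16, 32, 64, 128)`).
#' @param conv_kernel convolution kernel edge in voxels (default 6).
#' @param pool_kernel max-pool edge (default 2).
#' @param dropout dropout proportion on blocks 2-4, in `[0, 1)`.
#' @param dense_width units of the penultimate dense layer (default 128).
#' @param learning_rate Adam step size (default 1e-4).
#' @param patience early-stopping patience in epochs (default 20).
#' @param max_epochs hard cap on training epochs (default 200).
#' @param batch_size minibatch size (default 8).
#' @param seed integer seed controlling initialization, batching and dropout.
#' @return an object of class `vb_model_config`.
#' @export
model_config <- function(input_size = 32,
                         conv_filters = c(16, 32, 64, 128),
                         conv_kernel = 6,
                         pool_kernel = 2,
                         dropout = 0.2,
                         dense_width = 128,
                         learning_rate = 1e-4,
                         patience = 20,
                         max_epochs = 200,
                         batch_size = 8,
                         seed = 1) {
  if (length(conv_filters) != 4L) {
    stop("`conv_filters` must list four filter counts", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  s <- input_size
  for (b in 1:4) {
    kb <- min(pool_kernel, s)  # pooling saturates once the grid is that small
    if (s < 1 || s %% kb != 0) {
      stop(sprintf("input of %d voxels collapses below 1 voxel at block %d",
                   input_size, b), call. = FALSE)
    }
    s <- s %/% kb
  }
  structure(list(input_size = as.integer(input_size),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernel = as.integer(pool_kernel),
                 dropout = dropout,
                 dense_width = as.integer(dense_width),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "vb_model_config")
}

#' Build an untrained brain-age network
#'
#' Parameters are initialized deterministically under `config$seed` (He
#' initialization for convolution and hidden dense weights).
#'
#' @param config a [model_config()].
#' @return an object of class `ba_model`.
#' @examples
#' m <- build_model(model_config(input_size = 16, conv_filters = c(2, 2, 2, 2),
#'                               dense_width = 4))
#' n_parameters(m)
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "vb_model_config"))
  k <- config$conv_kernel
  pad_lo <- (k - 1L) %/% 2L
  layers <- list()
  in_ch <- 1L
  s <- config$input_size
  with_seed(derive_seed(config$seed, "init"), {
    for (b in 1:4) {
      out_ch <- config$conv_filters[b]
      K <- k^3 * in_ch
      w <- matrix(rnorm(K * out_ch, sd = sqrt(2 / K)), K, out_ch)
      layers[[length(layers) + 1L]] <-
        new_layer("conv", in_ch = in_ch, out_ch = out_ch, k = k,
                  pad_lo = pad_lo, w = w, b = numeric(out_ch))
      layers[[length(layers) + 1L]] <-
        new_layer("bn", ch = out_ch, gamma = rep(1, out_ch),
                  beta = numeric(out_ch), rmean = numeric(out_ch),
                  rvar = rep(1, out_ch))
      layers[[length(layers) + 1L]] <- new_layer("relu")
      kb <- min(config$pool_kernel, s)
      layers[[length(layers) + 1L]] <- new_layer("pool", k = kb)
      if (b >= 2 && config$dropout > 0) {
        layers[[length(layers) + 1L]] <- new_layer("dropout", p = config$dropout)
      }
      in_ch <- out_ch
      s <- s %/% kb
    }
    flat <- s^3 * in_ch
    layers[[length(layers) + 1L]] <- new_layer("flatten")
    layers[[length(layers) + 1L]] <-
      new_layer("dense", w = matrix(rnorm(flat * config$dense_width,
                                          sd = sqrt(2 / flat)),
                                    flat, config$dense_width),
                b = numeric(config$dense_width))
    layers[[length(layers) + 1L]] <- new_layer("relu")
    layers[[length(layers) + 1L]] <-
      new_layer("dense", w = matrix(rnorm(config$dense_width,
                                          sd = sqrt(1 / config$dense_width)),
                                    config$dense_width, 1L),
                b = numeric(1))
  })
  # GradCAM taps the final convolutional block's ReLU output (pre-pool).
  relu_idx <- which(vapply(layers, function(l) l$type == "relu", logical(1)))
  capture_layer <- relu_idx[4L]
  structure(list(layers = layers, config = config,
                 capture_layer = capture_layer,
                 age_center = 0, age_scale = 1,
                 history = NULL, variant = NULL, best_epoch = NA_integer_),
            class = "ba_model")
}

#' @export
print.ba_model <- function(x, ...) {
  cat(sprintf("<ba_model> input %d^3, filters %s, %d parameters%s\n",
              x$config$input_size,
              paste(x$config$conv_filters, collapse = "/"),
              n_parameters(x),
              if (!is.null(x$history)) {
                sprintf("; trained %d epochs (best %d)%s",
                        nrow(x$history), x$best_epoch,
                        if (!is.null(x$variant)) paste0(", variant ", x$variant)
                        else "")
              } else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `ba_model`.
#' @return integer count of trainable parameters (convolution and dense
#'   weights and biases, batch-norm scales and shifts).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    switch(ly$type,
           conv = length(ly$w) + length(ly$b),
           dense = length(ly$w) + length(ly$b),
           bn = length(ly$gamma) + length(ly$beta),
           0L)
  }, numeric(1)))
}

# Collect subject volumes into a (D,H,W,1,N) batch array.
as_input_batch <- function(x, input_size = NULL) {
  grids <- if (inherits(x, "vb_subject")) list(x$volume$data)
  else if (inherits(x, "vb_volume")) list(x$data)
  else if (is.array(x) && length(dim(x)) == 3L) list(x)
  else if (is.array(x) && length(dim(x)) == 5L) return(x)
  else if (is.list(x)) {
    lapply(x, function(e) {
      if (inherits(e, "vb_subject")) e$volume$data
      else if (inherits(e, "vb_volume")) e$data
      else if (is.array(e) && length(dim(e)) == 3L) e
      else stop("cannot interpret batch element as a volume", call. = FALSE)
    })
  } else stop("cannot interpret input as volume(s)", call. = FALSE)
  d <- dim(grids[[1]])
  if (!is.null(input_size) && any(d != input_size)) {
    stop(sprintf("volume shape %s does not match model input %d^3",
                 paste(d, collapse = "x"), input_size), call. = FALSE)
  }
  array(unlist(grids, use.names = FALSE), c(d, 1L, length(grids)))
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nm <- intersect(names(ly), c("w", "b", "gamma", "beta"))
    nm <- nm[vapply(nm, function(n) is.numeric(ly[[n]]), logical(1))]
    if (ly$type %in% c("conv", "dense")) nm <- c("w", "b")
    else if (ly$type == "bn") nm <- c("gamma", "beta")
    else return(NULL)
    st <- lapply(nm, function(n) list(m = ly[[n]] * 0, v = ly[[n]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, pgrads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    gr <- pgrads[[i]]
    if (is.null(gr)) next
    map <- c(w = "w", b = "b", gamma = "gamma", beta = "beta")
    for (n in names(gr)) {
      p <- map[[n]]
      st <- state[[i]][[p]]
      g <- gr[[n]]
      st$m <- 0.9 * st$m + 0.1 * g
      st$v <- 0.999 * st$v + 0.001 * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

snapshot_params <- function(layers) {
  lapply(layers, function(ly) ly[intersect(names(ly),
                                           c("w", "b", "gamma", "beta",
                                             "rmean", "rvar"))])
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (n in names(snap[[i]])) layers[[i]][[n]] <- snap[[i]][[n]]
  }
  layers
}

#' Train the brain-age regressor
#'
#' Minimizes mean absolute error (reported in years) with Adam. Targets are
#' internally standardized by the training cohort's age mean and standard
#' deviation so that the output layer starts near the cohort center; the
#' inverse transform is part of the model. Training stops when the validation
#' MAE has not improved for `patience` consecutive epochs, or at
#' `max_epochs`; the returned weights are those of the best validation epoch.
#'
#' @param model an untrained (or trained) `ba_model`.
#' @param train_subjects,val_subjects disjoint non-empty lists of
#'   `vb_subject`.
#' @param variant optional tag, e.g. `"ND"` or `"D"`.
#' @param verbose print one line per epoch.
#' @return the trained `ba_model` with `history` (data.frame of epoch,
#'   train_mae, val_mae), `best_epoch`, and the best-epoch weights.
#' @export
train_model <- function(model, train_subjects, val_subjects,
                        variant = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ba_model"))
  if (length(train_subjects) == 0L || length(val_subjects) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  tr_ids <- vapply(train_subjects, function(s) s$subject_id, character(1))
  va_ids <- vapply(val_subjects, function(s) s$subject_id, character(1))
  if (length(intersect(tr_ids, va_ids)) > 0L) {
    stop("training and validation sets overlap", call. = FALSE)
  }
  cfg <- model$config
  xtr <- as_input_batch(train_subjects, cfg$input_size)
  xva <- as_input_batch(val_subjects, cfg$input_size)
  age_tr <- vapply(train_subjects, function(s) s$age, numeric(1))
  age_va <- vapply(val_subjects, function(s) s$age, numeric(1))
  model$age_center <- mean(age_tr)
  model$age_scale <- if (sd(age_tr) > 0) sd(age_tr) else 1
  t_tr <- (age_tr - model$age_center) / model$age_scale

  n <- length(train_subjects)
  state <- adam_init(model$layers)
  best_val <- Inf
  best_epoch <- NA_integer_
  best_snap <- NULL
  wait <- 0L
  hist <- list()
  step <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch-", epoch)),
                     sample.int(n, n))
    starts <- seq(1L, n, by = cfg$batch_size)
    tr_abs <- 0
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
      xb <- xtr[, , , , idx, drop = FALSE]
      fw <- nn_forward(model, xb, training = TRUE,
                       dropout_seed = derive_seed(cfg$seed,
                                                  paste0("drop-", epoch, "-", bi)))
      model$layers <- fw$net$layers  # batch-norm running statistics
      resid <- fw$y - t_tr[idx]
      if (any(!is.finite(resid))) {
        stop(sprintf("non-finite loss at epoch %d batch %d", epoch, bi),
             call. = FALSE)
      }
      tr_abs <- tr_abs + sum(abs(resid))
      dy <- sign(resid) / length(idx)
      bw <- nn_backward(fw$net, fw$cache, dy, mode = "train")
      step <- step + 1L
      upd <- adam_step(model$layers, bw$pgrads, state,
                       cfg$learning_rate, step)
      model$layers <- upd$layers
      state <- upd$state
    }
    train_mae <- tr_abs / n * model$age_scale
    val_pred <- predict_ba(model, val_subjects)
    val_mae <- mean(abs(val_pred - age_va))
    if (!is.finite(val_mae)) stop("non-finite validation loss", call. = FALSE)
    hist[[epoch]] <- data.frame(epoch = epoch, train_mae = train_mae,
                                val_mae = val_mae)
    if (verbose) {
      message(sprintf("epoch %3d  train MAE %6.2f y  val MAE %6.2f y  wait %d",
                      epoch, train_mae, val_mae, wait))
    }
    if (val_mae < best_val - 1e-10) {
      best_val <- val_mae
      best_epoch <- epoch
      best_snap <- snapshot_params(model$layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$layers <- restore_params(model$layers, best_snap)
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  model$variant <- variant
  model$train_ids <- tr_ids
  model$val_ids <- va_ids
  model
}

#' Predict brain age
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch-norm using
#' running statistics).
#'
#' @param model a `ba_model`.
#' @param x a `vb_volume`, `vb_subject`, 3D array, or list of these.
#' @param chunk_size samples per forward pass (memory control).
#' @return numeric vector of estimated ages in years.
#' @export
predict_ba <- function(model, x, chunk_size = 16L) {
  xb <- as_input_batch(x, model$config$input_size)
  N <- dim(xb)[5]
  out <- numeric(N)
  for (s in seq(1L, N, by = chunk_size)) {
    idx <- s:min(s + chunk_size - 1L, N)
    fw <- nn_forward(model, xb[, , , , idx, drop = FALSE], training = FALSE,
                     need_param_grads = FALSE)
    out[idx] <- fw$y
  }
  model$age_center + model$age_scale * out
}

#' Mean absolute error of a model over subjects
#'
#' @param model a `ba_model`.
#' @param subjects non-empty list of `vb_subject`.
#' @return MAE in years.
#' @export
evaluate_mae <- function(model, subjects) {
  if (length(subjects) == 0L) stop("`subjects` must be non-empty", call. = FALSE)
  ages <- vapply(subjects, function(s) s$age, numeric(1))
  mean(abs(predict_ba(model, subjects) - ages))
}

#' Scalar model output and its input gradient
#'
#' Generics used by every attribution method, so that the methods can be
#' exercised against analytically tractable models (e.g. linear maps) as well
#' as the trained network. For `ba_model` the scalar is the estimated brain
#' age in years and evaluation mode is used throughout (deterministic).
#'
#' @param model the model.
#' @param x input batch: a `vb_volume`, 3D array, or `(D,H,W,1,N)` array.
#' @param ... passed to methods.
#' @return `predict_scalar()`: numeric vector, one scalar per sample.
#'   `input_gradient()`: array shaped like `x`, the gradient of each sample's
#'   scalar output with respect to its input voxels.
#' @export
predict_scalar <- function(model, x, ...) UseMethod("predict_scalar")

#' @export
predict_scalar.ba_model <- function(model, x, ...) {
  predict_ba(model, x)
}

#' @rdname predict_scalar
#' @param guided if `TRUE`, zero negative incoming backward signals at each
#'   ReLU (guided backpropagation) in addition to the ReLU's forward gating.
#' @export
input_gradient <- function(model, x, guided = FALSE, ...) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.ba_model <- function(model, x, guided = FALSE, ...) {
  xb <- as_input_batch(x, model$config$input_size)
  fw <- nn_forward(model, xb, training = FALSE, need_param_grads = FALSE)
  bw <- nn_backward(fw$net, fw$cache, rep(1, dim(xb)[5]),
                    mode = if (guided) "guided" else "input")
  g <- bw$gx * model$age_scale
  if (any(!is.finite(g))) stop("non-finite input gradient", call. = FALSE)
  dim(g) <- dim(xb)
  g
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, training history and target
#' scaling alongside the weights.
#'
#' @param model a `ba_model`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint()` returns the path invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ba_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ba_model"))
  m
}
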