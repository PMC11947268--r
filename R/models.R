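#' Classifier architecture specification
#'
#' Declares one of the four architectures with its hyperparameters. All
#' families end in a single sigmoid output unit (the positive class is MT,
#' the workload condition).
#'
#' * `eegnet` — compact convolutional network: shared temporal convolution
#'   (F1 = 8 filters, kernel 125), depthwise spatial filters (D = 2 per
#'   temporal filter), separable convolution (F2 = 16, kernel 16), average
#'   pooling 4 then 8, ELU activations, batch normalization, dropout 0.5.
#' * `bilstm` — one bidirectional LSTM layer with 64 units per direction on
#'   the raw channel sequence, dense 32, dropout 0.5, dense 1.
#' * `cnn1d` — four strided Conv1D blocks, filters (16, 32, 64, 128), kernel
#'   3, stride 2, 'same' padding, LeakyReLU (slope 0.3) in every block and
#'   batch normalization in blocks 1, 2 and 4; spatial dropout 0.25 before
#'   block 3 replaces its normalization; flatten, dense 64, dropout 0.5,
#'   dense 1. These block values were resolved so that the model's total
#'   parameter count (including normalization running statistics) is exactly
#'   165,649 for 26-channel and 176,689 for 256-channel input.
#' * `cnn1d_lstm` — the cnn1d convolutional front-end, its 16-step feature
#'   sequence passed (time-distributed flatten) to a bidirectional LSTM with
#'   32 units per direction, then dense 32, dropout 0.5, dense 1; totals
#'   77,777 / 88,817 parameters for 26 / 256 channels.
#'
#' @param family One of `"eegnet"`, `"bilstm"`, `"cnn1d"`, `"cnn1d_lstm"`.
#' @param ... Optional overrides of the family defaults listed above.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(family = c("eegnet", "bilstm", "cnn1d",
                                         "cnn1d_lstm"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    eegnet = list(F1 = 8, D = 2, F2 = 16, kernel = 125, sep_kernel = 16,
                  pool1 = 4, pool2 = 8, dropout = 0.5),
    bilstm = list(units = 64, dense = 32, dropout = 0.5),
    cnn1d = list(filters = c(16, 32, 64, 128), kernels = c(3, 3, 3, 3),
                 strides = c(2, 2, 2, 2), batchnorm = c(TRUE, TRUE, FALSE, TRUE),
                 leaky_slope = 0.3, spatial_dropout = 0.25,
                 dense = 64, dropout = 0.5),
    cnn1d_lstm = list(filters = c(16, 32, 64, 128), kernels = c(3, 3, 3, 3),
                      strides = c(2, 2, 2, 2),
                      batchnorm = c(TRUE, TRUE, FALSE, TRUE),
                      leaky_slope = 0.3, spatial_dropout = 0.25,
                      units = 32, dense = 32, dropout = 0.5)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown ", family, " option(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(family = family), defaults), class = "architecture_spec")
}

# Append the cnn1d convolutional front-end to a layer list.
cnn_front_end <- function(layers, spec, n_channels) {
  cin <- n_channels
  for (i in seq_along(spec$filters)) {
    if (i == 3) {
      layers <- c(layers, list(layer_dropout(spec$spatial_dropout,
                                             spatial = TRUE)))
    }
    layers <- c(layers, list(
      layer_conv1d(cin, spec$filters[i], spec$kernels[i], spec$strides[i],
                   "same")
    ))
    layers <- c(layers, list(layer_activation("leaky_relu",
                                              alpha = spec$leaky_slope)))
    if (spec$batchnorm[i]) layers <- c(layers, list(layer_batchnorm(spec$filters[i])))
    cin <- spec$filters[i]
  }
  layers
}

#' Build an (untrained) classifier
#'
#' Constructs the network for `spec` and input shape
#' `(n_channels, n_timesteps)`, initializes weights (Glorot uniform, seeded)
#' and computes the total parameter count. The count follows the
#' total-parameters convention of the common deep-learning frameworks:
#' weights + biases + normalization scale/shift + normalization running mean
#' and variance (4 entries per normalized feature).
#'
#' @param spec An [architecture_spec()].
#' @param n_channels Input channels (26 or 256 in the study; any value >= 1
#'   is accepted).
#' @param n_timesteps Samples per epoch (default 250).
#' @param seed Weight-initialization seed.
#' @return An `eegdecode_model`.
#' @export
build_model <- function(spec, n_channels, n_timesteps = 250, seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"))
  layers <- with_seed(seed, {
    switch(spec$family,
      bilstm = list(
        layer_bilstm(n_channels, spec$units),
        layer_dense(2 * spec$units, spec$dense),
        layer_activation("relu"),
        layer_dropout(spec$dropout),
        layer_dense(spec$dense, 1)
      ),
      cnn1d = {
        ls <- cnn_front_end(list(), spec, n_channels)
        Lout <- n_timesteps
        for (s in spec$strides) Lout <- ceiling(Lout / s)
        c(ls, list(
          layer_flatten(),
          layer_dense(Lout * spec$filters[length(spec$filters)], spec$dense),
          layer_activation("relu"),
          layer_dropout(spec$dropout),
          layer_dense(spec$dense, 1)
        ))
      },
      cnn1d_lstm = {
        ls <- cnn_front_end(list(), spec, n_channels)
        c(ls, list(
          layer_bilstm(spec$filters[length(spec$filters)], spec$units),
          layer_dense(2 * spec$units, spec$dense),
          layer_activation("relu"),
          layer_dropout(spec$dropout),
          layer_dense(spec$dense, 1)
        ))
      },
      eegnet = {
        T2 <- n_timesteps %/% spec$pool1
        T3 <- T2 %/% spec$pool2
        list(
          layer_temporal_conv(spec$F1, spec$kernel),
          layer_batchnorm(spec$F1),
          layer_depthwise_spatial(spec$F1, spec$D, n_channels),
          layer_batchnorm(spec$F1 * spec$D),
          layer_activation("elu"),
          layer_avgpool(spec$pool1),
          layer_dropout(spec$dropout),
          layer_separable_conv(spec$F1 * spec$D, spec$F2, spec$sep_kernel),
          layer_batchnorm(spec$F2),
          layer_activation("elu"),
          layer_avgpool(spec$pool2),
          layer_dropout(spec$dropout),
          layer_flatten(),
          layer_dense(spec$F2 * T3, 1)
        )
      }
    )
  })
  model <- structure(
    list(spec = spec, layers = layers, n_channels = n_channels,
         n_timesteps = n_timesteps, seed = seed, history = NULL,
         trained = FALSE),
    class = "eegdecode_model"
  )
  model$parameter_count <- count_parameters(model)
  model
}

#' Total parameter count of a model
#'
#' Counts every stored weight array plus, for each batch-normalization
#' layer, its two running statistics per feature (the "total params"
#' convention, making counts comparable across frameworks).
#'
#' @param model An `eegdecode_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    sum(vapply(ly$params, length, 0L)) + ly$extra_count
  }, 0))
}

#' @export
print.eegdecode_model <- function(x, ...) {
  cat(sprintf("<eegdecode_model> %s, input %d ch x %d steps, %s parameters%s\n",
              x$spec$family, x$n_channels, x$n_timesteps,
              format(x$parameter_count, big.mark = ","),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Epochs arrive as (n, C, T); the engine wants (C, T, n).
epochs_to_tensor <- function(es) aperm(es$epochs, c(2, 3, 1))

model_forward <- function(model, x, training = FALSE) {
  for (ly in model$layers) x <- ly$forward(x, training)
  x
}

model_backward <- function(model, dy) {
  for (ly in rev(model$layers)) dy <- ly$backward(dy)
  dy
}

#' Training configuration
#'
#' @param learning_rate Adam step size. The study uses 1e-3 for EEGNet and
#'   the BiLSTM and 1e-5 for the two CNN-based models.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience on validation loss; the best
#'   validation-loss weights are restored at the end.
#' @param seed Seed controlling shuffling and dropout.
#' @param standardize Whether [run_cv()] standardizes inputs with training
#'   statistics before fitting.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 100, patience = 10, seed = 1,
                         standardize = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, seed = seed,
                 standardize = standardize),
            class = "train_config")
}

#' Default learning rate per family
#'
#' 1e-3 for `eegnet`/`bilstm`, 1e-5 for `cnn1d`/`cnn1d_lstm`.
#' @param family Architecture family string.
#' @return Numeric learning rate.
#' @export
default_learning_rate <- function(family) {
  if (family %in% c("cnn1d", "cnn1d_lstm")) 1e-5 else 1e-3
}

bce_loss_and_grad <- function(z, y) {
  # numerically stable binary cross-entropy on logits
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- sigm(z)
  list(loss = loss, dz = (p - y) / length(y), p = p)
}

#' Train a classifier
#'
#' Mini-batch Adam on binary cross-entropy. Per-epoch training loss/accuracy
#' and validation loss/accuracy are recorded; training stops early when the
#' validation loss has not improved for `patience` epochs, and the weights of
#' the best validation epoch are restored. Deterministic for a fixed seed.
#'
#' @param model An untrained (or trained) `eegdecode_model`.
#' @param train Training `epoch_set` (both classes present).
#' @param val Validation `epoch_set`.
#' @param cfg A [train_config()].
#' @return The trained model with `$history` (data.frame).
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  d <- dim(train$epochs)
  if (d[2] != model$n_channels || d[3] != model$n_timesteps) {
    stop("epoch shape (", d[2], ", ", d[3], ") does not match model input (",
         model$n_channels, ", ", model$n_timesteps, ")")
  }
  if (length(unique(train$labels)) < 2) {
    stop("training set contains a single class")
  }
  x_train <- epochs_to_tensor(train)
  y_train <- train$labels
  x_val <- epochs_to_tensor(val)
  y_val <- val$labels
  n <- d[1]
  opt <- adam_new(model$layers, cfg$learning_rate)
  hist <- list()
  best_loss <- Inf
  best_snap <- NULL
  wait <- 0L

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1, n)]
        xb <- x_train[, , bi, drop = FALSE]
        yb <- y_train[bi]
        z <- model_forward(model, xb, training = TRUE)
        lg <- bce_loss_and_grad(as.numeric(z), yb)
        model_backward(model, matrix(lg$dz, 1))
        opt <- adam_step(opt, model$layers)
        ep_loss <- ep_loss + lg$loss * length(bi)
        ep_correct <- ep_correct + sum((lg$p >= 0.5) == (yb == 1))
      }
      ev <- evaluate_logits(model, x_val, y_val)
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                               accuracy = ep_correct / n,
                               val_loss = ev$loss, val_accuracy = ev$accuracy)
      if (ev$loss < best_loss - 1e-8) {
        best_loss <- ev$loss
        best_snap <- snapshot_params(model$layers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model$layers, best_snap)
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

# Forward in evaluation mode, in chunks to bound memory; returns loss/acc.
evaluate_logits <- function(model, x, y, chunk = 512L) {
  n <- dim(x)[3]
  z <- numeric(n)
  for (b0 in seq(1, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1, n)
    z[bi] <- as.numeric(model_forward(model, x[, , bi, drop = FALSE],
                                      training = FALSE))
  }
  p <- sigm(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, accuracy = mean((p >= 0.5) == (y == 1)), p = p)
}

#' Predict condition probabilities for epochs
#'
#' @param object A trained `eegdecode_model`.
#' @param epochs An `epoch_set` matching the model's input shape.
#' @param threshold Decision threshold; an epoch is labelled MT (1) when its
#'   probability is greater than or equal to the threshold.
#' @param ... Unused.
#' @return List with `probabilities` (P(MT)) and `labels` (0/1).
#' @export
predict.eegdecode_model <- function(object, epochs, threshold = 0.5, ...) {
  d <- dim(epochs$epochs)
  if (d[2] != object$n_channels || d[3] != object$n_timesteps) {
    stop("epoch shape (", d[2], ", ", d[3], ") does not match model input (",
         object$n_channels, ", ", object$n_timesteps, ")")
  }
  x <- epochs_to_tensor(epochs)
  n <- d[1]
  z <- numeric(n)
  for (b0 in seq(1, n, by = 512L)) {
    bi <- b0:min(b0 + 511L, n)
    z[bi] <- as.numeric(model_forward(object, x[, , bi, drop = FALSE],
                                      training = FALSE))
  }
  p <- sigm(z)
  list(probabilities = p, labels = as.integer(p >= threshold))
}
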