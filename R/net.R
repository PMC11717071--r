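#' Network hyperparameter configuration
#'
#' Hyperparameters of the recurrent calibration model. Defaults follow the
#' study's untuned two-layer BiLSTM-Attention setting (epochs 30, batch 16,
#' learning rate 0.01, hidden sizes 10/10, attention width 20, dense width
#' 20).
#'
#' @param lr Adam learning rate (> 0).
#' @param num_epochs training epochs (>= 0).
#' @param batch_size minibatch size (clamped to the training-set size).
#' @param hidden1,hidden2 per-direction hidden sizes of the two stacked
#'   recurrent layers.
#' @param dense width of the dense head.
#' @param attn_dim width of the additive-attention projection.
#' @param seed integer seed for parameter initialization and batch order.
#' @return An object of class `net_config`.
#' @export
net_config <- function(lr = 0.01, num_epochs = 30L, batch_size = 16L,
                       hidden1 = 10L, hidden2 = 10L, dense = 20L,
                       attn_dim = 20L, seed = 1L) {
  stopifnot(lr > 0, num_epochs >= 0, batch_size >= 1, hidden1 >= 1,
            hidden2 >= 1, dense >= 1, attn_dim >= 1)
  structure(list(lr = lr, num_epochs = as.integer(num_epochs),
                 batch_size = as.integer(batch_size),
                 hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(hidden2),
                 dense = as.integer(dense),
                 attn_dim = as.integer(attn_dim),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat("<net_config> lr=", format(x$lr, digits = 4),
      " epochs=", x$num_epochs, " batch=", x$batch_size,
      " hidden=", x$hidden1, "/", x$hidden2,
      " dense=", x$dense, " attn=", x$attn_dim, "\n", sep = "")
  invisible(x)
}

# Glorot-uniform initialization of all parameter matrices, deterministic
# given cfg$seed. Forget-gate biases start at 1 (standard LSTM practice).
.net_init_params <- function(cfg, bidirectional, attention) {
  h1 <- cfg$hidden1; h2 <- cfg$hidden2
  d2 <- if (bidirectional) 2L * h1 else h1
  m <- if (bidirectional) 2L * h2 else h2
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  lstm_b <- function(h) {
    b <- matrix(0, 1, 4 * h)
    b[1, (h + 1):(2 * h)] <- 1
    b
  }
  with_seed(cfg$seed, {
    par <- list(
      l1f_W = glorot(1, 4 * h1), l1f_U = glorot(h1, 4 * h1),
      l1f_b = lstm_b(h1),
      l2f_W = glorot(d2, 4 * h2), l2f_U = glorot(h2, 4 * h2),
      l2f_b = lstm_b(h2),
      m_Wf = glorot(h2, m), m_b = matrix(0, 1, m),
      a_W = glorot(m, cfg$attn_dim), a_b = matrix(0, 1, cfg$attn_dim),
      a_v = glorot(cfg$attn_dim, 1),
      d_W = glorot(m, cfg$dense), d_b = matrix(0, 1, cfg$dense),
      o_w = glorot(cfg$dense, 1), o_b = matrix(0, 1, 1))
    if (bidirectional) {
      par$l1b_W <- glorot(1, 4 * h1); par$l1b_U <- glorot(h1, 4 * h1)
      par$l1b_b <- lstm_b(h1)
      par$l2b_W <- glorot(d2, 4 * h2); par$l2b_U <- glorot(h2, 4 * h2)
      par$l2b_b <- lstm_b(h2)
      par$m_Wb <- glorot(h2, m)
    }
    par
  })
}

#' Build an untrained recurrent calibration model
#'
#' Constructs the parameter set of the sequence regressor: the spectrum's
#' bands, in increasing-wavelength order, form the input sequence (one
#' reflectance value per step). Two stacked recurrent layers encode the
#' sequence (bidirectionally unless disabled); the per-step directional
#' outputs are merged through a tanh-weighted combination; additive
#' attention scores every step, is normalized to a distribution and pools
#' the merged states into a context vector; a tanh dense layer and a linear
#' output produce the scalar prediction.
#'
#' @param cfg a [net_config()].
#' @param seq_len number of bands (sequence length) the model expects.
#' @param bidirectional include the backward recurrent stream
#'   (default `TRUE`).
#' @param attention use additive attention pooling; when `FALSE` the
#'   per-step states are pooled uniformly (default `TRUE`).
#' @return An object of class `bilstm_attention` (unfitted).
#' @export
build_model <- function(cfg, seq_len, bidirectional = TRUE,
                        attention = TRUE) {
  stopifnot(inherits(cfg, "net_config"), seq_len >= 1)
  structure(list(config = cfg, seq_len = as.integer(seq_len),
                 bidirectional = bidirectional, attention = attention,
                 parameters = .net_init_params(cfg, bidirectional, attention),
                 fitted = FALSE,
                 target_scaler = list(mean = 0, sd = 1),
                 history = NULL),
            class = "bilstm_attention")
}

.check_X <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$seq_len)
    stop("sequence length mismatch: model expects ", model$seq_len,
         " bands, got ", ncol(X))
  X
}

#' Train a recurrent calibration model
#'
#' Minimizes mean squared error on standardized targets with Adam
#' (minibatch gradient descent, shuffled batches each epoch). The target
#' mean/sd are learned from the training responses only and stored in the
#' model, so predictions return on the raw scale by default.
#'
#' @param model an unfitted (or fitted) `bilstm_attention` from
#'   [build_model()].
#' @param X_train numeric matrix, rows = spectra.
#' @param y_train numeric response (raw scale, e.g. g/100 g).
#' @param X_val,y_val optional validation set monitored per epoch.
#' @param verbose print the loss every few epochs.
#' @return The fitted model; `model$history` holds per-epoch `train_mse`
#'   and (when a validation set is given) `val_mse`, both on the
#'   standardized target scale.
#' @export
train <- function(model, X_train, y_train, X_val = NULL, y_val = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "bilstm_attention"))
  X <- .check_X(model, X_train)
  y <- as.numeric(y_train)
  stopifnot(length(y) == nrow(X))
  cfg <- model$config

  mu <- mean(y); sg <- sd(y)
  if (!is.finite(sg) || sg == 0) sg <- 1
  model$target_scaler <- list(mean = mu, sd = sg)
  yz <- (y - mu) / sg
  has_val <- !is.null(X_val)
  if (has_val) {
    Xv <- .check_X(model, X_val)
    yvz <- (as.numeric(y_val) - mu) / sg
  }

  if (cfg$num_epochs > 0) {
    res <- with_seed(cfg$seed + 1L,
      cpp_net_train(model$parameters, X, yz,
                    if (has_val) Xv else matrix(0, 0, model$seq_len),
                    if (has_val) yvz else numeric(0),
                    cfg$num_epochs, min(cfg$batch_size, nrow(X)), cfg$lr,
                    model$bidirectional, model$attention))
    model$parameters <- res$parameters
    hist_train <- res$train_mse
    hist_val <- if (has_val) res$val_mse else NULL
    if (verbose)
      cat("final train MSE ", format(hist_train[cfg$num_epochs],
                                     digits = 5),
          if (has_val) paste0("  val MSE ",
                              format(hist_val[cfg$num_epochs],
                                     digits = 5)),
          "\n", sep = "")
  } else {
    hist_train <- numeric(0)
    hist_val <- if (has_val) numeric(0) else NULL
  }
  model$fitted <- TRUE
  model$history <- if (has_val)
    data.frame(epoch = seq_len(cfg$num_epochs), train_mse = hist_train,
               val_mse = hist_val)
  else data.frame(epoch = seq_len(cfg$num_epochs), train_mse = hist_train)
  model
}

#' Fit a recurrent spectral calibration model
#'
#' One-call interface: builds the network for the band count of `x`, trains
#' it, and returns the fitted model. `model_type` picks the architecture
#' variants compared in the study: a plain unidirectional LSTM, a BiLSTM
#' with uniform pooling, or the BiLSTM with additive attention.
#'
#' @param x numeric matrix of (preprocessed, band-selected) spectra.
#' @param y numeric response vector (raw scale).
#' @param config a [net_config()].
#' @param model_type one of `"bilstm_attention"` (default), `"bilstm"`,
#'   `"lstm"`.
#' @param x_val,y_val optional validation data monitored during training.
#' @param verbose print progress.
#' @return A fitted `bilstm_attention` object.
#' @examples
#' \donttest{
#' X <- matrix(runif(200 * 10), 200, 10)
#' y <- rowMeans(X) * 10 + 20
#' m <- bilstm_attention(X, y, net_config(num_epochs = 5, seed = 1))
#' cor(predict(m, X), y)
#' }
#' @export
bilstm_attention <- function(x, y, config = net_config(),
                             model_type = c("bilstm_attention", "bilstm",
                                            "lstm"),
                             x_val = NULL, y_val = NULL, verbose = FALSE) {
  model_type <- match.arg(model_type)
  bidir <- model_type != "lstm"
  attn <- model_type == "bilstm_attention"
  model <- build_model(config, ncol(as.matrix(x)), bidirectional = bidir,
                       attention = attn)
  model$model_type <- model_type
  train(model, x, y, x_val, y_val, verbose = verbose)
}

#' Predict analyte values from a fitted model
#'
#' @param object a fitted `bilstm_attention` model.
#' @param newdata numeric matrix with the model's band count.
#' @param scale `"raw"` (de-standardized, g/100 g; default) or
#'   `"standardized"` (the training scale).
#' @param attention also return the per-step attention weights.
#' @param ... ignored.
#' @return Numeric vector of predictions, or (with `attention = TRUE`) a
#'   list with `pred` and the `n x seq_len` weight matrix.
#' @export
predict.bilstm_attention <- function(object, newdata,
                                     scale = c("raw", "standardized"),
                                     attention = FALSE, ...) {
  scale <- match.arg(scale)
  if (!object$fitted)
    stop("model is not fitted; call train() or bilstm_attention() first")
  X <- .check_X(object, newdata)
  out <- cpp_net_forward(object$parameters, X, object$bidirectional,
                         object$attention)
  pred <- out$pred
  if (scale == "raw")
    pred <- pred * object$target_scaler$sd + object$target_scaler$mean
  if (attention) list(pred = pred, attention = out$attention) else pred
}

#' Attention weights of an untrained or trained model on data
#'
#' @param model a `bilstm_attention` model (fitted or not).
#' @param X numeric matrix with the model's band count.
#' @return `n x seq_len` matrix; rows are non-negative and sum to one.
#' @export
attention_weights <- function(model, X) {
  stopifnot(inherits(model, "bilstm_attention"))
  X <- .check_X(model, X)
  cpp_net_forward(model$parameters, X, model$bidirectional,
                  model$attention)$attention
}

#' @export
print.bilstm_attention <- function(x, ...) {
  cat("<", if (is.null(x$model_type)) "bilstm_attention" else x$model_type,
      "> seq_len=", x$seq_len,
      if (!x$bidirectional) " (unidirectional)",
      if (!x$attention) " (uniform pooling)",
      if (x$fitted) " [fitted]" else " [unfitted]", "\n", sep = "")
  print(x$config)
  invisible(x)
}

#' @export
summary.bilstm_attention <- function(object, ...) {
  np <- sum(vapply(object$parameters, length, 1L))
  cat("Recurrent spectral calibration model\n")
  print(object)
  cat("  parameters: ", np, "\n", sep = "")
  if (!is.null(object$history)) {
    h <- object$history
    cat("  final train MSE (standardized): ",
        format(h$train_mse[nrow(h)], digits = 5), "\n", sep = "")
    if ("val_mse" %in% names(h))
      cat("  final val MSE (standardized): ",
          format(h$val_mse[nrow(h)], digits = 5), "\n", sep = "")
  }
  invisible(object)
}

#' @export
plot.bilstm_attention <- function(x, ...) {
  if (is.null(x$history) || nrow(x$history) == 0)
    stop("no training history to plot")
  h <- x$history
  ylim <- range(c(h$train_mse, h$val_mse), finite = TRUE)
  plot(h$epoch, h$train_mse, type = "l", xlab = "epoch",
       ylab = "MSE (standardized y)", ylim = ylim, ...)
  if ("val_mse" %in% names(h)) {
    graphics::lines(h$epoch, h$val_mse, col = 2)
    graphics::legend("topright", c("train", "validation"), col = 1:2,
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.bilstm_attention <- function(object, X, y, ...) {
  as.numeric(y) - predict(object, X)
}

#' @export
coef.bilstm_attention <- function(object, ...) object$parameters

#' Serialize a model to a JSON checkpoint
#'
#' Stores the configuration, architecture flags, target scaler and every
#' parameter matrix as plain JSON so checkpoints round-trip bit-exactly
#' through text.
#'
#' @param model a `bilstm_attention` model.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bilstm_attention"))
  obj <- list(config = unclass(model$config),
              seq_len = model$seq_len,
              bidirectional = model$bidirectional,
              attention = model$attention,
              model_type = model$model_type,
              fitted = model$fitted,
              target_scaler = model$target_scaler,
              parameters = lapply(model$parameters, function(p)
                list(dim = dim(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path file written by [save_model()].
#' @return A `bilstm_attention` model.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, obj$config)
  model <- build_model(cfg, obj$seq_len, obj$bidirectional, obj$attention)
  model$model_type <- obj$model_type
  model$fitted <- obj$fitted
  model$target_scaler <- as.list(obj$target_scaler)
  model$parameters <- lapply(obj$parameters, function(p)
    matrix(p$data, p$dim[1], p$dim[2]))
  model
}
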