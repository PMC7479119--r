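# Feed-forward Z-score regressor.
#
# Architecture: linear first hidden layer whose response carries an L2
# activity penalty and, during training only, additive Gaussian noise;
# ReLU hidden layers; linear scalar output. Trained with Adam on
# residue-level mean squared error, batching whole sequences. Implemented
# directly with BLAS matrix operations; the networks are small (tens of
# units per layer) and train in seconds to minutes on one CPU.

#' Network hyperparameters
#'
#' Defaults follow the reference architecture: hidden widths
#' (40, 10, 25, 40, 8) without evolutionary features or
#' (128, 80, 20, 15, 10) with them, Gaussian noise sd 0.1 after the first
#' hidden layer, learning rate 1e-4 (Adam), 100 epochs with batches of 50
#' sequences. The L2 activity-penalty coefficient on the first hidden layer
#' defaults to 1e-4.
#'
#' @param hidden_widths Integer vector of hidden-layer widths. Defaults per
#'   `evolution`.
#' @param evolution Selects the default widths when `hidden_widths` is NULL.
#' @param noise_sd Sd of Gaussian noise added after the first hidden layer
#'   during training.
#' @param l2_coeff Coefficient of the L2 activity penalty on the first hidden
#'   layer's response.
#' @param learning_rate Adam learning rate.
#' @param epochs Number of full passes over the training sequences.
#' @param batch_sequences Number of sequences per minibatch.
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   training noise.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(hidden_widths = NULL, evolution = FALSE,
                         noise_sd = 0.1, l2_coeff = 1e-4,
                         learning_rate = 1e-4, epochs = 100L,
                         batch_sequences = 50L, seed = 1L) {
  if (is.null(hidden_widths)) {
    hidden_widths <- if (evolution) c(128L, 80L, 20L, 15L, 10L) else
      c(40L, 10L, 25L, 40L, 8L)
  }
  stopifnot(length(hidden_widths) >= 2,
            all(hidden_widths >= 1), noise_sd >= 0, l2_coeff >= 0,
            learning_rate > 0, epochs >= 1, batch_sequences >= 1)
  structure(
    list(hidden_widths = as.integer(hidden_widths), noise_sd = noise_sd,
         l2_coeff = l2_coeff, learning_rate = learning_rate,
         epochs = as.integer(epochs),
         batch_sequences = as.integer(batch_sequences),
         seed = as.integer(seed)),
    class = "network_spec"
  )
}

# He initialization for the ReLU stack, Glorot for the linear first layer.
# The output layer starts at zero weights with its bias at the target mean,
# so that early training signal is not swamped by random initial predictions.
init_params <- function(n_features, hidden_widths, y_mean = 0) {
  dims <- c(n_features, hidden_widths, 1L)
  n_layers <- length(dims) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- dims[l]
    fan_out <- dims[l + 1L]
    sd_l <- if (l == 1L) sqrt(2 / (fan_in + fan_out)) else sqrt(2 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd_l),
                     fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  W[[n_layers]][] <- 0
  b[[n_layers]] <- y_mean
  list(W = W, b = b)
}

# forward pass; returns prediction vector and, when cache = TRUE, the
# activations needed for backpropagation
mlp_forward <- function(par, X, noise_sd = 0, cache = FALSE) {
  W <- par$W; b <- par$b
  n_layers <- length(W)
  A1 <- sweep(X %*% W[[1L]], 2L, b[[1L]], "+")
  if (noise_sd > 0) {
    A1 <- A1 + matrix(stats::rnorm(length(A1), sd = noise_sd),
                      nrow(A1), ncol(A1))
  }
  H <- vector("list", n_layers)  # post-activation of each hidden layer
  Z <- vector("list", n_layers)  # pre-activation of ReLU layers
  H[[1L]] <- A1
  h <- A1
  for (l in seq.int(2L, n_layers - 1L)) {
    z <- sweep(h %*% W[[l]], 2L, b[[l]], "+")
    h <- z * (z > 0)
    Z[[l]] <- z
    H[[l]] <- h
  }
  out <- drop(sweep(h %*% W[[n_layers]], 2L, b[[n_layers]], "+"))
  if (!cache) return(out)
  list(out = out, A1 = A1, H = H, Z = Z)
}

# gradients of MSE + l2_coeff * mean(A1^2) with respect to all parameters
mlp_backward <- function(par, X, y, fw, l2_coeff) {
  W <- par$W
  n_layers <- length(W)
  N <- length(y)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  d_out <- matrix(2 * (fw$out - y) / N, ncol = 1L)
  gW[[n_layers]] <- crossprod(fw$H[[n_layers - 1L]], d_out)
  gb[[n_layers]] <- colSums(d_out)
  dH <- d_out %*% t(W[[n_layers]])
  for (l in seq.int(n_layers - 1L, 2L)) {
    dZ <- dH * (fw$Z[[l]] > 0)
    gW[[l]] <- crossprod(fw$H[[l - 1L]], dZ)
    gb[[l]] <- colSums(dZ)
    dH <- dZ %*% t(W[[l]])
  }
  # first (linear) hidden layer: add the activity-penalty gradient
  dA1 <- dH + 2 * l2_coeff * fw$A1 / length(fw$A1)
  gW[[1L]] <- crossprod(X, dA1)
  gb[[1L]] <- colSums(dA1)
  list(W = gW, b = gb)
}

adam_state <- function(par) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(par$W), vW = zero_like(par$W),
       mb = zero_like(par$b), vb = zero_like(par$b), t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# assemble a residue-level design matrix and target vector from a list of
# per-sequence training examples, dropping residues without a target
stack_sequences <- function(seqs) {
  X <- do.call(rbind, lapply(seqs, `[[`, "X"))
  y <- unlist(lapply(seqs, `[[`, "y"), use.names = FALSE)
  keep <- !is.na(y)
  list(X = X[keep, , drop = FALSE], y = y[keep])
}

#' Train one Z-score regressor
#'
#' Trains the feed-forward network on normalized per-residue features by Adam
#' on residue-level mean squared error, batching whole sequences. Train and
#' test MSE are recorded after every epoch and the weights achieving the
#' lowest test MSE are returned. Fully reproducible given `spec$seed`.
#'
#' @param spec A [network_spec()].
#' @param train,test Lists of per-sequence examples, each a list with `X`
#'   (residues x features, already normalized) and `y` (per-residue observed
#'   Z, `NA` allowed and dropped).
#' @return An object of class `trained_model` with fields `par` (weights at
#'   the selected epoch), `spec`, `history` (per-epoch train/test MSE) and
#'   `selected_epoch`.
#' @export
train_model <- function(spec, train, test) {
  stopifnot(inherits(spec, "network_spec"),
            length(train) >= 1L, length(test) >= 1L)
  tr <- stack_sequences(train)
  te <- stack_sequences(test)
  if (length(tr$y) == 0L || length(te$y) == 0L) {
    stop("empty training or testing set after dropping missing Z-scores")
  }
  n_features <- ncol(tr$X)
  withr::with_seed(spec$seed, {
    par <- init_params(n_features, spec$hidden_widths, y_mean = mean(tr$y))
    state <- adam_state(par)
    history <- data.frame(epoch = seq_len(spec$epochs),
                          train_mse = NA_real_, test_mse = NA_real_)
    best <- list(mse = Inf, par = par, epoch = 0L)
    n_seq <- length(train)
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n_seq)
      batch_starts <- seq.int(1L, n_seq, by = spec$batch_sequences)
      for (s in batch_starts) {
        idx <- ord[seq.int(s, min(s + spec$batch_sequences - 1L, n_seq))]
        batch <- stack_sequences(train[idx])
        if (length(batch$y) == 0L) next
        fw <- mlp_forward(par, batch$X, noise_sd = spec$noise_sd,
                          cache = TRUE)
        if (!all(is.finite(fw$out))) {
          stop("non-finite loss at epoch ", epoch)
        }
        grad <- mlp_backward(par, batch$X, batch$y, fw, spec$l2_coeff)
        upd <- adam_step(par, grad, state, spec$learning_rate)
        par <- upd$par
        state <- upd$state
      }
      history$train_mse[epoch] <- mean((mlp_forward(par, tr$X) - tr$y)^2)
      history$test_mse[epoch] <- mean((mlp_forward(par, te$X) - te$y)^2)
      if (history$test_mse[epoch] < best$mse) {
        best <- list(mse = history$test_mse[epoch], par = par, epoch = epoch)
      }
    }
  })
  structure(
    list(par = best$par, spec = spec, history = history,
         selected_epoch = best$epoch, n_features = n_features),
    class = "trained_model"
  )
}

#' Predict per-residue Z-scores with one model
#'
#' Deterministic inference pass (training noise disabled).
#'
#' @param model A [train_model()] result.
#' @param features Numeric matrix of normalized features (residues x
#'   features) or a `feature_matrix`.
#' @return Numeric vector of predicted Z-scores, one per residue.
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  X <- if (inherits(features, "feature_matrix")) features$values else features
  if (ncol(X) != model$n_features) {
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         model$n_features)
  }
  mlp_forward(model$par, X)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$n_features, " features -> [",
      paste(x$spec$hidden_widths, collapse = ","),
      "] -> 1; selected epoch ", x$selected_epoch, " (test MSE ",
      format(x$history$test_mse[x$selected_epoch], digits = 4), ")\n",
      sep = "")
  invisible(x)
}
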