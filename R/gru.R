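#' Initialize GRU classifier parameters
#'
#' Builds the parameter set of a stacked GRU sequence classifier: per
#' layer, the input-to-hidden matrices `W_z`, `W_r`, `W_h`, the
#' hidden-to-hidden matrices `U_z`, `U_r`, `U_h`, and biases `b_z`,
#' `b_r`, `b_h`; plus a linear head mapping the final hidden state
#' (concatenated with the 13 clinical features when `fusion = TRUE`) to
#' the four class scores. Weights are drawn uniformly in
#' +/- 1/sqrt(hidden_size); biases start at zero.
#'
#' @param hidden_size Hidden units per layer.
#' @param num_layers Number of stacked GRU layers.
#' @param input_size Input dimension per time step (12 leads).
#' @param n_classes Number of output classes.
#' @param fusion Concatenate the clinical feature vector before the head?
#' @param n_features Length of the clinical feature vector.
#' @param seed Integer seed for the initialization draw.
#' @return A list of class `gru_params` with elements `layers` (list of
#'   per-layer parameter lists) and `head` (`W`, `b`).
#' @export
gru_init <- function(hidden_size, num_layers, input_size = 12, n_classes = 4,
                     fusion = FALSE, n_features = 13, seed = 1) {
  stopifnot(hidden_size >= 1, num_layers >= 1)
  s <- 1 / sqrt(hidden_size)
  with_local_seed(seed, {
    layers <- lapply(seq_len(num_layers), function(l) {
      i <- if (l == 1) input_size else hidden_size
      mk <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
      list(
        W_z = mk(hidden_size, i), U_z = mk(hidden_size, hidden_size),
        b_z = numeric(hidden_size),
        W_r = mk(hidden_size, i), U_r = mk(hidden_size, hidden_size),
        b_r = numeric(hidden_size),
        W_h = mk(hidden_size, i), U_h = mk(hidden_size, hidden_size),
        b_h = numeric(hidden_size)
      )
    })
    rep_dim <- hidden_size + if (fusion) n_features else 0
    head <- list(
      W = matrix(runif(n_classes * rep_dim, -s, s), n_classes, rep_dim),
      b = numeric(n_classes)
    )
    structure(
      list(layers = layers, head = head),
      class = "gru_params",
      hidden_size = hidden_size, num_layers = num_layers,
      input_size = input_size, n_classes = n_classes,
      fusion = fusion, n_features = n_features
    )
  })
}

#' One GRU cell update
#'
#' Reference single-step implementation of the gate equations: the update
#' gate `z` blends previous and candidate state, the reset gate `r`
#' controls how much past state enters the candidate, and
#' `h = (1 - z) * h_prev + z * h_tilde`.
#'
#' @param x_t Input vector at this time step.
#' @param h_prev Previous hidden state vector.
#' @param layer One layer's parameter list (as in [gru_init()]).
#' @return A list with gates `z`, `r`, candidate `h_tilde`, and new state `h`.
#' @export
gru_cell_step <- function(x_t, h_prev, layer) {
  if (length(x_t) != ncol(layer$W_z) || length(h_prev) != ncol(layer$U_z)) {
    abort("dimension mismatch between inputs and layer parameters")
  }
  sigmoid <- function(a) 1 / (1 + exp(-a))
  z <- sigmoid(drop(layer$W_z %*% x_t + layer$U_z %*% h_prev + layer$b_z))
  r <- sigmoid(drop(layer$W_r %*% x_t + layer$U_r %*% h_prev + layer$b_r))
  h_tilde <- tanh(drop(layer$W_h %*% x_t + layer$U_h %*% (r * h_prev) + layer$b_h))
  h <- (1 - z) * h_prev + z * h_tilde
  list(z = z, r = r, h_tilde = h_tilde, h = h)
}

#' Label-smoothed cross-entropy loss
#'
#' Target distribution `q_k = (1 - s) * 1[k = y] + s / K`; loss is
#' `-sum(q * log p)` with probabilities floored at 1e-12 so a zero
#' predicted probability yields a large finite loss rather than infinity.
#'
#' @param probs Predicted class probability vector.
#' @param label True class index (1-based) or a label in [ecg_classes].
#' @param smoothing Smoothing mass `s` in `[0, 1)`.
#' @return Scalar loss.
#' @export
smoothed_cross_entropy <- function(probs, label, smoothing = 0.2) {
  if (smoothing < 0 || smoothing >= 1) abort("smoothing must be in [0, 1)")
  k <- length(probs)
  y <- if (is.character(label) || is.factor(label)) {
    match(as.character(label), ecg_classes)
  } else {
    as.integer(label)
  }
  stopifnot(y >= 1, y <= k)
  q <- rep(smoothing / k, k)
  q[y] <- q[y] + 1 - smoothing
  -sum(q * log(pmax(probs, 1e-12)))
}

# Assemble a batch: list of 12 x d signal matrices -> cube array
# (input_size, batch, time), decimated by `stride`.
build_batch_array <- function(signals, stride = 1) {
  mats <- lapply(signals, function(s) s[, seq(1, ncol(s), by = stride), drop = FALSE])
  d <- ncol(mats[[1]])
  arr <- array(unlist(mats), dim = c(nrow(mats[[1]]), d, length(mats)))
  aperm(arr, c(1, 3, 2))
}

feature_matrix <- function(records, n_features = 13) {
  t(as.matrix(records[, ecg_feature_names, drop = FALSE]))
}

#' Forward pass of the GRU classifier
#'
#' Runs the stacked GRU over the signal (one time step per retained
#' sample, each step's input being the 12 per-lead samples), takes the
#' last layer's final hidden state, concatenates the clinical feature
#' vector when fusion is on, and applies the linear head and softmax.
#'
#' @param signal A 12 x d numeric matrix.
#' @param params A `gru_params` object.
#' @param features Numeric feature vector of length 13 (required when the
#'   parameters were built with `fusion = TRUE`; they should be on the
#'   normalized scale used in training).
#' @param stride Keep every `stride`-th sample (temporal decimation).
#' @return Class probability vector (sums to 1).
#' @export
gru_forward <- function(signal, params, features = NULL, stride = 1) {
  stopifnot(inherits(params, "gru_params"))
  if (nrow(signal) != attr(params, "input_size")) {
    abort(sprintf("signal must have %d channels", attr(params, "input_size")))
  }
  fusion <- attr(params, "fusion")
  if (fusion && is.null(features)) {
    abort("feature vector required: parameters were built with fusion = TRUE")
  }
  x <- build_batch_array(list(signal), stride)
  fmat <- if (fusion) matrix(features, ncol = 1) else matrix(0, 0, 1)
  res <- gru_batch_cpp(x, fmat, params$layers, params$head$W, params$head$b,
                       integer(0), 0, FALSE)
  p <- drop(res$probs)
  names(p) <- ecg_classes[seq_along(p)]
  p
}

# Batched probabilities for a record table. Returns n x K matrix.
gru_predict_probs <- function(params, records, stride = 1, chunk = 256) {
  check_ecg_tbl(records)
  fusion <- attr(params, "fusion")
  n <- nrow(records)
  out <- matrix(NA_real_, n, attr(params, "n_classes"))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    x <- build_batch_array(records$signal[idx], stride)
    fmat <- if (fusion) feature_matrix(records[idx, ]) else matrix(0, 0, length(idx))
    res <- gru_batch_cpp(x, fmat, params$layers, params$head$W, params$head$b,
                         integer(0), 0, FALSE)
    out[idx, ] <- t(res$probs)
  }
  colnames(out) <- ecg_classes[seq_len(ncol(out))]
  out
}

#' Training configuration for the GRU classifier
#'
#' Defaults follow the centralized training setup: Adam with learning
#' rate 0.001 and weight decay 1e-5, cross-entropy with label smoothing
#' 0.2. `stride` decimates the input sequence (keep every `stride`-th
#' sample) for desk-scale runs; 1 feeds every raw sample.
#'
#' @param learning_rate Optimizer step size.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param label_smoothing Smoothing mass of the loss.
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param stride Temporal decimation factor (integer >= 1).
#' @return A list of class `gru_train_config`.
#' @export
gru_train_config <- function(learning_rate = 0.001, weight_decay = 1e-5,
                             label_smoothing = 0.2, batch_size = 64,
                             optimizer = c("adam", "sgd"), stride = 1) {
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (label_smoothing < 0 || label_smoothing >= 1) {
    abort("label_smoothing must be in [0, 1)")
  }
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      label_smoothing = label_smoothing, batch_size = as.integer(batch_size),
      optimizer = match.arg(optimizer), stride = as.integer(stride)
    ),
    class = "gru_train_config"
  )
}
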