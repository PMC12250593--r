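#' Train the GRU classifier on a record table
#'
#' Minimizes the mean label-smoothed cross-entropy by mini-batch Adam (or
#' SGD). When a [dp_config()] is supplied, every batch gradient is first
#' clipped to the L2 bound and Gaussian noise is added before the
#' optimizer update (weight decay is applied after the mechanism, to the
#' privatized gradient). Training is deterministic given `seed` and the
#' input row order.
#'
#' @param train ECG record table to train on. When fusion parameters are
#'   used, the 13 feature columns should already be normalized (see
#'   [normalize_ecg_features()]).
#' @param params Initial `gru_params` (see [gru_init()]).
#' @param config A [gru_train_config()].
#' @param epochs Number of passes over the data; 0 returns `params`
#'   unchanged with an empty history.
#' @param validation Optional record table evaluated after each epoch.
#' @param dp Optional [dp_config()] enabling the gradient mechanism.
#' @param dp_round Optional list with `sigma` and `clip_norm` overriding
#'   the config values (used by the federated driver to apply a per-round
#'   schedule).
#' @param seed Integer seed controlling shuffling and noise.
#' @return An object of class `gru_fit` with elements `params`,
#'   `history` (tibble: epoch, train_loss, train_accuracy, and validation
#'   columns when supplied), `config`, and `dp`.
#' @export
train_gru <- function(train, params, config = gru_train_config(), epochs = 10,
                      validation = NULL, dp = NULL, dp_round = NULL, seed = 1) {
  check_ecg_tbl(train, "train")
  stopifnot(inherits(params, "gru_params"))
  if (nrow(train) == 0) abort("training set is empty")
  if (!is.null(dp)) stopifnot(inherits(dp, "dp_config"))

  fusion <- attr(params, "fusion")
  attrs <- attributes(params)
  theta <- flatten_params(unclass(params))
  y_all <- as.integer(as_label_factor(train$label))

  sigma <- clipn <- NULL
  if (!is.null(dp)) {
    sigma <- (dp_round %||% list(sigma = dp$noise_multiplier))$sigma
    clipn <- (dp_round %||% list(clip_norm = dp$clip_norm))$clip_norm %||% dp$clip_norm
  }

  opt <- config$optimizer
  m <- v <- numeric(length(theta))
  step <- 0L
  history <- vector("list", epochs)

  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(train))
      batch_starts <- seq(1, nrow(train), by = config$batch_size)
      ep_loss <- 0
      ep_correct <- 0L
      for (bs in batch_starts) {
        idx <- ord[bs:min(nrow(train), bs + config$batch_size - 1L)]
        x <- build_batch_array(train$signal[idx], config$stride)
        fmat <- if (fusion) feature_matrix(train[idx, ]) else matrix(0, 0, length(idx))
        pl <- unflatten_params(theta, unclass(params))
        res <- gru_batch_cpp(x, fmat, pl$layers, pl$head$W, pl$head$b,
                             y_all[idx], config$label_smoothing, TRUE)
        if (!is.finite(res$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        }
        g <- flatten_params(res$grads)
        if (!is.null(dp)) {
          g <- dp_transform_gradient(g, sigma, clipn, dp$noise_convention)
        }
        g <- g + config$weight_decay * theta
        step <- step + 1L
        if (opt == "adam") {
          m <- 0.9 * m + 0.1 * g
          v <- 0.999 * v + 0.001 * g^2
          mhat <- m / (1 - 0.9^step)
          vhat <- v / (1 - 0.999^step)
          theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
        } else {
          theta <- theta - config$learning_rate * g
        }
        ep_loss <- ep_loss + res$loss * length(idx)
        pred <- apply(res$probs, 2, which.max)
        ep_correct <- ep_correct + sum(pred == y_all[idx])
      }
      row <- tibble::tibble(
        epoch = ep,
        train_loss = ep_loss / nrow(train),
        train_accuracy = ep_correct / nrow(train)
      )
      if (!is.null(validation) && nrow(validation) > 0) {
        pl <- unflatten_params(theta, unclass(params))
        pl <- restore_params(pl, attrs)
        vp <- gru_predict_probs(pl, validation, stride = config$stride)
        vy <- as.integer(as_label_factor(validation$label))
        vloss <- mean(vapply(seq_len(nrow(vp)), function(i) {
          smoothed_cross_entropy(vp[i, ], vy[i], config$label_smoothing)
        }, numeric(1)))
        row$val_loss <- vloss
        row$val_accuracy <- mean(max.col(vp, ties.method = "first") == vy)
      }
      history[[ep]] <- row
    }
  })

  final <- restore_params(unflatten_params(theta, unclass(params)), attrs)
  structure(
    list(
      params = final,
      history = dplyr::bind_rows(history),
      config = config,
      dp = dp,
      epochs = epochs,
      seed = seed
    ),
    class = "gru_fit"
  )
}

restore_params <- function(p, attrs) {
  for (nm in setdiff(names(attrs), "names")) attr(p, nm) <- attrs[[nm]]
  p
}

#' @export
print.gru_fit <- function(x, ...) {
  cat(sprintf(
    "GRU classifier fit: hidden %d, %d layer(s), fusion %s, %d epoch(s)\n",
    attr(x$params, "hidden_size"), attr(x$params, "num_layers"),
    ifelse(attr(x$params, "fusion"), "on", "off"), x$epochs
  ))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(
      "final train loss %.4f, train accuracy %.3f\n",
      last$train_loss, last$train_accuracy
    ))
  }
  invisible(x)
}

#' Per-epoch training history of a GRU fit
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.gru_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a GRU fit
#' @param x A `gru_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the final-epoch loss and accuracy and
#'   the model dimensions.
#' @export
glance.gru_fit <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(train_loss = NA_real_, train_accuracy = NA_real_)
  tibble::tibble(
    epochs = x$epochs,
    hidden_size = attr(x$params, "hidden_size"),
    num_layers = attr(x$params, "num_layers"),
    fusion = attr(x$params, "fusion"),
    train_loss = last$train_loss,
    train_accuracy = last$train_accuracy,
    val_accuracy = if ("val_accuracy" %in% names(last)) last$val_accuracy else NA_real_
  )
}

#' Predict classes or probabilities from a GRU fit
#'
#' Ties at the probability argmax are broken toward the lowest class
#' index.
#'
#' @param object A `gru_fit`.
#' @param newdata ECG record table.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return A factor of predicted classes, or a tibble of per-class
#'   probabilities.
#' @export
predict.gru_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- gru_predict_probs(object$params, newdata, stride = object$config$stride)
  if (type == "prob") {
    return(tibble::as_tibble(as.data.frame(p)))
  }
  factor(ecg_classes[max.col(p, ties.method = "first")], levels = ecg_classes)
}

#' Learning-curve plot for a GRU fit
#' @param object A `gru_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy against epoch.
#' @export
autoplot.gru_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
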