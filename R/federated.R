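#' Client-side local training for one federated round
#'
#' Initializes the client model from the current global parameters and
#' runs `local_epochs` of (optionally differentially private) mini-batch
#' training on the client's own records. Only the resulting weights and
#' the client's sample count leave the call; the records themselves never
#' do.
#'
#' @param client_records The client's record table (nonempty).
#' @param global_params Current global `gru_params`.
#' @param local_epochs Local epochs `E_l`; 0 returns the global weights
#'   unchanged.
#' @param config A [gru_train_config()].
#' @param dp Optional [dp_config()].
#' @param dp_round Optional per-round `list(sigma, clip_norm)` from
#'   [dp_schedule_step()].
#' @param seed Integer seed.
#' @return A list with `weights` (a `gru_params`) and `n` (client size).
#' @export
local_train <- function(client_records, global_params, local_epochs,
                        config = gru_train_config(), dp = NULL,
                        dp_round = NULL, seed = 1) {
  check_ecg_tbl(client_records, "client_records")
  if (nrow(client_records) == 0) abort("client has no records")
  if (local_epochs == 0) {
    return(list(weights = global_params, n = nrow(client_records)))
  }
  fit <- train_gru(client_records, global_params, config = config,
                   epochs = local_epochs, dp = dp, dp_round = dp_round,
                   seed = seed)
  list(weights = fit$params, n = nrow(client_records),
       history = fit$history)
}

#' Size-weighted federated averaging
#'
#' Aggregates client parameter sets into
#' `theta_new = sum_i (N_i / sum_j N_j) * W_i`, array by array — the
#' exact weighted mean of every weight. The weight factors always sum
#' to 1.
#'
#' @param weights List of client parameter sets (`gru_params` or plain
#'   nested lists with identical structure).
#' @param sizes Client sample counts `N_i` (positive, same length).
#' @return The aggregated parameter set, with the attributes of the
#'   first client's parameters.
#' @export
fedavg_aggregate <- function(weights, sizes) {
  if (length(weights) == 0) abort("no client weights to aggregate")
  if (length(weights) != length(sizes)) abort("weights and sizes lengths differ")
  if (sum(sizes) <= 0) abort("total client size must be positive")
  flats <- lapply(weights, function(w) flatten_params(unclass(w)))
  len <- unique(vapply(flats, length, integer(1)))
  if (length(len) != 1) abort("client parameter schemas differ")
  w <- sizes / sum(sizes)
  agg <- Reduce(`+`, Map(`*`, flats, w))
  out <- unflatten_params(agg, unclass(weights[[1]]))
  restore_params(out, attributes(weights[[1]]))
}

#' Personalize a global model on one client
#'
#' Starts from the global weights and runs plain (non-private) local
#' fine-tuning on the client's records, producing the client's
#' personalized model.
#'
#' @inheritParams local_train
#' @param fine_tune_epochs Fine-tuning epochs; 0 returns the global
#'   parameters unchanged.
#' @return A `gru_params` object.
#' @export
personalize <- function(client_records, global_params, fine_tune_epochs,
                        config = gru_train_config(), seed = 1) {
  if (fine_tune_epochs == 0) {
    return(global_params)
  }
  fit <- train_gru(client_records, global_params, config = config,
                   epochs = fine_tune_epochs, seed = seed)
  fit$params
}

#' Run the full federated training loop
#'
#' For each of `rounds` global rounds: derive the round's DP schedule
#' values, run [local_train()] on every client (all clients participate
#' every round), aggregate with [fedavg_aggregate()], evaluate the global
#' model on the test split, and optionally fine-tune and evaluate a
#' personalized model per client. Per-round, per-client seeds are derived
#' deterministically from `seed` via [derive_seed()], so runs replay
#' bit-identically.
#'
#' When `local_test_fraction > 0`, that fraction of each client's records
#' (deterministically selected per client) is held out from local
#' training and used to measure per-client local-test accuracy of both
#' the global and the personalized model.
#'
#' @param split An `ecg_split` providing the global test set.
#' @param partition An `ecg_partition` of the training records.
#' @param params Initial global `gru_params`.
#' @param rounds Number of global rounds `E_g`.
#' @param local_epochs Local epochs per round `E_l`.
#' @param config A [gru_train_config()].
#' @param dp Optional [dp_config()]; omit for plain federated averaging.
#' @param personalize_epochs Fine-tuning epochs per client (0 disables
#'   personalization).
#' @param personalize_when `"round"` fine-tunes inside every round;
#'   `"final"` only after the last round.
#' @param local_test_fraction Per-client holdout fraction in `[0, 1)`.
#' @param eval_every Evaluate the global model every this many rounds.
#' @param seed Master integer seed.
#' @return An object of class `fl_fit`: `global_params`,
#'   `personalized` (list of per-client `gru_params`, when enabled),
#'   `history` (tibble: round, scope, client, loss, accuracy, sigma,
#'   clip_norm), `client_metrics` (per-client local-test accuracy of
#'   global vs personalized models, when measurable), plus the
#'   configuration used.
#' @export
run_federated <- function(split, partition, params, rounds = 10,
                          local_epochs = 1, config = gru_train_config(),
                          dp = NULL, personalize_epochs = 0,
                          personalize_when = c("round", "final"),
                          local_test_fraction = 0, eval_every = 1, seed = 1) {
  stopifnot(inherits(split, "ecg_split"), inherits(partition, "ecg_partition"))
  personalize_when <- match.arg(personalize_when)
  n_clients <- length(partition$clients)

  # per-client local holdout
  local_train_sets <- partition$clients
  local_test_sets <- vector("list", n_clients)
  if (local_test_fraction > 0) {
    for (i in seq_len(n_clients)) {
      ci <- partition$clients[[i]]
      n_hold <- max(1L, round(local_test_fraction * nrow(ci)))
      if (n_hold >= nrow(ci)) n_hold <- nrow(ci) - 1L
      hold <- with_local_seed(derive_seed(seed, 900, i),
                              sample.int(nrow(ci), n_hold))
      local_test_sets[[i]] <- ci[hold, , drop = FALSE]
      local_train_sets[[i]] <- ci[-hold, , drop = FALSE]
    }
  }
  sizes <- vapply(local_train_sets, nrow, integer(1))

  global <- params
  personalized <- vector("list", n_clients)
  history <- list()
  client_metrics <- list()

  for (t in seq_len(rounds)) {
    sched <- if (!is.null(dp)) dp_schedule_step(t, rounds, dp) else
      list(sigma = NA_real_, clip_norm = NA_real_)

    results <- lapply(seq_len(n_clients), function(i) {
      local_train(local_train_sets[[i]], global, local_epochs,
                  config = config, dp = dp,
                  dp_round = if (!is.null(dp)) sched else NULL,
                  seed = derive_seed(seed, t, i))
    })
    global <- fedavg_aggregate(
      lapply(results, `[[`, "weights"),
      vapply(results, `[[`, integer(1), "n")
    )

    if (t %% eval_every == 0 || t == rounds) {
      history[[length(history) + 1]] <- tibble::tibble(
        round = t, scope = "global", client = NA_integer_,
        loss = NA_real_,
        accuracy = local_accuracy(global, split$test, config$stride),
        sigma = sched$sigma, clip_norm = sched$clip_norm
      )
    }

    do_personalize <- personalize_epochs > 0 &&
      (personalize_when == "round" || t == rounds)
    if (do_personalize) {
      for (i in seq_len(n_clients)) {
        personalized[[i]] <- personalize(
          local_train_sets[[i]], global, personalize_epochs,
          config = config, seed = derive_seed(seed, t, i, 7)
        )
        if (!is.null(local_test_sets[[i]]) && nrow(local_test_sets[[i]]) > 0) {
          lt <- local_test_sets[[i]]
          acc_g <- local_accuracy(global, lt, config$stride)
          acc_p <- local_accuracy(personalized[[i]], lt, config$stride)
          client_metrics[[length(client_metrics) + 1]] <- tibble::tibble(
            round = t, client = i, n_local_test = nrow(lt),
            global_accuracy = acc_g, personalized_accuracy = acc_p
          )
          history[[length(history) + 1]] <- tibble::tibble(
            round = t, scope = "personalized", client = i,
            loss = NA_real_, accuracy = acc_p,
            sigma = sched$sigma, clip_norm = sched$clip_norm
          )
        }
      }
    }
  }

  structure(
    list(
      global_params = global,
      personalized = if (personalize_epochs > 0) personalized else NULL,
      history = dplyr::bind_rows(history),
      client_metrics = dplyr::bind_rows(client_metrics),
      sizes = sizes,
      rounds = rounds,
      local_epochs = local_epochs,
      config = config,
      dp = dp,
      seed = seed
    ),
    class = "fl_fit"
  )
}

local_accuracy <- function(params, records, stride) {
  p <- gru_predict_probs(params, records, stride = stride)
  mean(ecg_classes[max.col(p, ties.method = "first")] ==
         as.character(records$label))
}

#' @export
print.fl_fit <- function(x, ...) {
  cat(sprintf(
    "federated fit: %d round(s) x %d local epoch(s), %d client(s)%s\n",
    x$rounds, x$local_epochs, length(x$sizes),
    if (!is.null(x$dp)) sprintf(", DP (sigma %.3g, clip %.3g)",
                                x$dp$noise_multiplier, x$dp$clip_norm) else ""
  ))
  g <- x$history[x$history$scope == "global", ]
  if (nrow(g) > 0) {
    cat(sprintf("final global test accuracy %.3f\n", g$accuracy[nrow(g)]))
  }
  invisible(x)
}

#' Round-by-round history of a federated fit
#' @param x An `fl_fit`.
#' @param ... Unused.
#' @return Tibble of per-round global (and personalized) evaluations.
#' @export
tidy.fl_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a federated fit
#' @param x An `fl_fit`.
#' @param ... Unused.
#' @return One-row tibble with the final global accuracy and setup.
#' @export
glance.fl_fit <- function(x, ...) {
  g <- x$history[x$history$scope == "global", ]
  tibble::tibble(
    rounds = x$rounds,
    local_epochs = x$local_epochs,
    n_clients = length(x$sizes),
    dp = !is.null(x$dp),
    final_accuracy = if (nrow(g) > 0) g$accuracy[nrow(g)] else NA_real_
  )
}

#' Accuracy-vs-round plot of a federated fit
#' @param object An `fl_fit`.
#' @param ... Unused.
#' @return A ggplot of global test accuracy per round.
#' @export
autoplot.fl_fit <- function(object, ...) {
  h <- object$history[object$history$scope == "global", ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$round, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "global round", y = "global test accuracy")
}
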