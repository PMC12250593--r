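#' Stratified train / validation / test split
#'
#' Splits a record table by label so each split's class mix matches the
#' whole, with overall split sizes equal to the largest-remainder
#' rounding of `n * fractions` (75/10/15 by default). Deterministic per
#' seed.
#'
#' @param records ECG record table.
#' @param fractions Length-3 fractions (train, validation, test) summing
#'   to 1.
#' @param seed Integer seed for the shuffling.
#' @return A list of class `ecg_split` with elements `train`,
#'   `validation`, `test`.
#' @export
split_ecg <- function(records, fractions = c(0.75, 0.10, 0.15), seed = 1) {
  check_ecg_tbl(records)
  if (abs(sum(fractions) - 1) > 1e-9) abort("split fractions must sum to 1")
  if (length(fractions) != 3) abort("fractions must be length 3 (train, validation, test)")
  n <- nrow(records)
  if (n < 4) abort("need at least 4 records to split")

  targets <- largest_remainder(n, fractions)
  labels <- as_label_factor(records$label)
  classes <- levels(labels)

  # per-class largest-remainder apportionment, then a repair pass moving
  # single records between splits (within a class) until the overall split
  # sizes hit the targets; moves always pick the most over-represented cell
  nc <- table(labels)
  ideal <- outer(as.numeric(nc), fractions)
  alloc <- t(vapply(seq_along(classes),
                    function(i) largest_remainder(as.integer(nc[i]),
                                                  fractions),
                    integer(length(fractions))))
  for (step in seq_len(n)) {
    over <- which(colSums(alloc) > targets)
    under <- which(colSums(alloc) < targets)
    if (length(over) == 0) break
    j1 <- over[1]
    j2 <- under[1]
    # prefer the class most over-represented in the source split and most
    # under-represented in the destination split
    score <- (alloc[, j1] - ideal[, j1]) - (alloc[, j2] - ideal[, j2])
    score[alloc[, j1] == 0] <- -Inf
    i <- which.max(score)
    alloc[i, j1] <- alloc[i, j1] - 1L
    alloc[i, j2] <- alloc[i, j2] + 1L
  }

  assign_split <- with_local_seed(seed, {
    out <- integer(n)
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      idx <- idx[sample.int(length(idx))]
      sizes <- alloc[i, ]
      out[idx] <- rep(1:3, times = sizes)
    }
    out
  })
  structure(
    list(
      train = records[assign_split == 1, , drop = FALSE],
      validation = records[assign_split == 2, , drop = FALSE],
      test = records[assign_split == 3, , drop = FALSE]
    ),
    class = "ecg_split",
    fractions = fractions, seed = seed
  )
}

#' @export
print.ecg_split <- function(x, ...) {
  cat(sprintf(
    "ECG split: %d train / %d validation / %d test\n",
    nrow(x$train), nrow(x$validation), nrow(x$test)
  ))
  invisible(x)
}

#' Partition records across simulated clients
#'
#' Distributes a record table over `n_clients` simulated hospitals.
#' `"iid"` deals a shuffled copy round-robin, so client sizes differ by
#' at most one. `"dirichlet"` draws, independently per class, client
#' proportions from a symmetric Dirichlet(`alpha`) and allocates that
#' class's records accordingly (largest-remainder rounding): small
#' `alpha` gives strong label skew, large `alpha` approaches the global
#' mix. A client left empty receives one record from the largest client
#' so every client can train. With `n_clients = 1` the input is returned
#' as a single client unchanged (and in its original order).
#'
#' @param records ECG record table (typically the training split).
#' @param n_clients Number of clients (>= 1, at most `nrow(records)`).
#' @param strategy `"iid"` or `"dirichlet"`.
#' @param alpha Dirichlet concentration (label-skew strength).
#' @param seed Integer seed.
#' @return A list of class `ecg_partition` with elements `clients` (list
#'   of record tables), `sizes`, `strategy`, `alpha`.
#' @export
partition_clients <- function(records, n_clients = 4,
                              strategy = c("iid", "dirichlet"),
                              alpha = 0.5, seed = 1) {
  check_ecg_tbl(records)
  strategy <- match.arg(strategy)
  n <- nrow(records)
  if (n_clients < 1) abort("n_clients must be >= 1")
  if (n_clients > n) abort("more clients than records")

  clients <- if (n_clients == 1) {
    list(records)
  } else if (strategy == "iid") {
    with_local_seed(seed, {
      ord <- sample.int(n)
      cl <- rep_len(seq_len(n_clients), n)
      lapply(seq_len(n_clients), function(k) records[ord[cl == k], , drop = FALSE])
    })
  } else {
    with_local_seed(seed, {
      labels <- as_label_factor(records$label)
      assign_cl <- integer(n)
      for (cls in levels(labels)) {
        idx <- which(labels == cls)
        if (length(idx) == 0) next
        p <- rgamma(n_clients, shape = alpha)
        p <- p / sum(p)
        counts <- largest_remainder(length(idx), p)
        idx <- idx[sample.int(length(idx))]
        assign_cl[idx] <- rep(seq_len(n_clients), times = counts)
      }
      cl <- lapply(seq_len(n_clients), function(k) records[assign_cl == k, , drop = FALSE])
      # no client may be empty: borrow one record from the largest client
      repeat {
        sizes <- vapply(cl, nrow, integer(1))
        if (all(sizes > 0)) break
        from <- which.max(sizes)
        to <- which(sizes == 0)[1]
        cl[[to]] <- cl[[from]][1, , drop = FALSE]
        cl[[from]] <- cl[[from]][-1, , drop = FALSE]
      }
      cl
    })
  }
  structure(
    list(
      clients = clients,
      sizes = vapply(clients, nrow, integer(1)),
      strategy = strategy,
      alpha = if (strategy == "dirichlet") alpha else NA_real_
    ),
    class = "ecg_partition"
  )
}

#' @export
print.ecg_partition <- function(x, ...) {
  cat(sprintf(
    "ECG partition: %d client(s), strategy %s, sizes %s\n",
    length(x$clients), x$strategy, paste(x$sizes, collapse = "/")
  ))
  invisible(x)
}

#' Z-score the clinical features using training statistics
#'
#' Standardizes each of the 13 feature columns with the mean and standard
#' deviation of the *training* split only, applying the same transform to
#' the validation and test splits (and reusable at inference via the
#' returned `stats`). Features constant in training map to zero.
#'
#' @param split An `ecg_split` (or any list of record tables whose first
#'   element is the training set) from [split_ecg()].
#' @param stats Optional statistics tibble from an earlier call, applied
#'   as-is instead of recomputing.
#' @return The split with transformed feature columns and an added
#'   `stats` tibble (`feature`, `mean`, `sd`) as attribute and element.
#' @export
normalize_ecg_features <- function(split, stats = NULL) {
  stopifnot(inherits(split, "ecg_split"))
  if (nrow(split$train) == 0) abort("training split is empty")
  if (is.null(stats)) {
    mu <- vapply(split$train[ecg_feature_names], mean, numeric(1))
    sg <- vapply(split$train[ecg_feature_names], sd, numeric(1))
    sg[is.na(sg)] <- 0
    stats <- tibble::tibble(feature = ecg_feature_names, mean = mu, sd = sg)
  }
  apply_stats <- function(tbl) {
    for (i in seq_len(nrow(stats))) {
      f <- stats$feature[i]
      tbl[[f]] <- if (stats$sd[i] == 0) {
        rep(0, nrow(tbl))
      } else {
        (tbl[[f]] - stats$mean[i]) / stats$sd[i]
      }
    }
    tbl
  }
  out <- split
  for (nm in c("train", "validation", "test")) out[[nm]] <- apply_stats(out[[nm]])
  out$stats <- stats
  attr(out, "feature_stats") <- stats
  out
}

#' Write a record table to disk as CSV
#'
#' Stores one manifest CSV (`manifest.csv`: id, label, fs, demographics,
#' the 13 features, and the per-record signal path) plus one signal CSV
#' per record with 12 columns (one per lead) and one row per sample.
#' UTF-8, comma separator, `.` decimal mark. The clean reference signal
#' is not persisted.
#'
#' @param records ECG record table.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_ecg_records <- function(records, path) {
  check_ecg_tbl(records)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- records[, c("record_id", "label", "fs", "age", "sex",
                          setdiff(ecg_feature_names, c("age", "gender")))]
  manifest$signal_path <- paste0(records$record_id, ".csv")
  readr::write_csv(manifest, file.path(path, "manifest.csv"))
  purrr::walk2(records$signal, manifest$signal_path, function(sig, sp) {
    df <- as.data.frame(t(sig))
    names(df) <- ecg_lead_names
    readr::write_csv(df, file.path(path, sp))
  })
  invisible(path)
}

#' Read a record table written by [write_ecg_records()]
#'
#' Validates the channel count (exactly 12 leads) and the label tokens;
#' malformed records are reported by id.
#'
#' @param path Directory containing `manifest.csv` and the signal files.
#' @return An ECG record table. The `signal_clean` column is set equal to
#'   `signal` (the clean reference is not persisted).
#' @export
read_ecg_records <- function(path) {
  mf <- readr::read_csv(file.path(path, "manifest.csv"),
                        show_col_types = FALSE, progress = FALSE)
  labels <- as_label_factor(mf$label)
  signals <- purrr::map2(mf$signal_path, mf$record_id, function(sp, id) {
    df <- readr::read_csv(file.path(path, sp),
                          show_col_types = FALSE, progress = FALSE)
    if (ncol(df) != 12) {
      abort(sprintf(
        "record %s: expected 12 signal columns, found %d", id, ncol(df)
      ))
    }
    m <- t(as.matrix(df))
    rownames(m) <- ecg_lead_names
    m
  })
  tibble::tibble(
    record_id = mf$record_id,
    label = labels,
    fs = mf$fs,
    duration = vapply(signals, ncol, numeric(1)) / mf$fs,
    sex = mf$sex,
    age = mf$age,
    gender = as.numeric(mf$sex == "M"),
    !!!as.list(mf[setdiff(ecg_feature_names, c("age", "gender"))]),
    signal = signals,
    signal_clean = signals
  )
}
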