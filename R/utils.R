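# Internal helpers: seeded evaluation, parameter flattening, seed derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user RNG.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a downstream seed from a master seed
#'
#' Deterministic integer hash used to give every record, round, and client
#' its own reproducible stream. The result is always in `[0, 2^31 - 2]`.
#'
#' @param master Master integer seed.
#' @param ... Further integer indices (e.g. round, client).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 0
  m <- 2147483629 # large prime < 2^31
  for (v in idx) h <- (h * 1000003 + (v %% m)) %% m
  as.integer(h)
}

# Flatten a nested list of numeric arrays into one named numeric vector.
flatten_params <- function(p) {
  unlist(p, use.names = TRUE)
}

# Inverse of flatten_params given a structurally identical skeleton.
unflatten_params <- function(v, skeleton) {
  stopifnot(is.numeric(v))
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, fill)
      attributes(out) <- attributes(x)
      return(out)
    }
    n <- length(x)
    piece <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(piece) <- attributes(x)
    piece
  }
  out <- fill(skeleton)
  if (pos != length(v)) {
    abort("flat vector length does not match parameter skeleton")
  }
  out
}

# Largest-remainder rounding: integer counts summing to n, proportional to p.
largest_remainder <- function(n, p) {
  ideal <- n * p / sum(p)
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- ideal - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

check_ecg_tbl <- function(records, arg = "records") {
  if (!is.data.frame(records) || !all(c("record_id", "label", "fs", "signal") %in% names(records))) {
    abort(sprintf("`%s` must be an ECG record table (see generate_ecg_dataset())", arg))
  }
  invisible(records)
}

as_label_factor <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), ecg_classes)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown label token(s) %s; valid labels are %s",
      paste(sQuote(bad), collapse = ", "),
      paste(ecg_classes, collapse = ", ")
    ))
  }
  factor(label, levels = ecg_classes)
}
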