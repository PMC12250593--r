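# Independent oracles, coded directly from the defining formulas and kept
# free of the package's own computational paths.

# Scalar per-equation GRU forward: explicit time loop over gate equations.
oracle_gru_forward <- function(params, sig, feat = NULL, smoothing = NULL,
                               label = NULL) {
  L <- length(params$layers)
  H <- nrow(params$layers[[1]]$U_z)
  sigmoid <- function(a) 1 / (1 + exp(-a))
  h <- lapply(seq_len(L), function(l) rep(0, H))
  for (t in seq_len(ncol(sig))) {
    inp <- sig[, t]
    for (l in seq_len(L)) {
      la <- params$layers[[l]]
      z <- sigmoid(drop(la$W_z %*% inp + la$U_z %*% h[[l]] + la$b_z))
      r <- sigmoid(drop(la$W_r %*% inp + la$U_r %*% h[[l]] + la$b_r))
      ht <- tanh(drop(la$W_h %*% inp + la$U_h %*% (r * h[[l]]) + la$b_h))
      h[[l]] <- (1 - z) * h[[l]] + z * ht
      inp <- h[[l]]
    }
  }
  rep_vec <- c(h[[L]], feat)
  logit <- drop(params$head$W %*% rep_vec + params$head$b)
  p <- exp(logit - max(logit))
  p / sum(p)
}

# Textbook one-vs-rest metrics from a confusion matrix.
oracle_per_class <- function(cm) {
  tot <- sum(cm)
  k <- nrow(cm)
  out <- matrix(NA_real_, k, 4,
                dimnames = list(rownames(cm),
                                c("precision", "sensitivity",
                                  "specificity", "f1")))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- tot - tp - fp - fn
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    s <- if (tp + fn == 0) 0 else tp / (tp + fn)
    sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1 <- if (p + s == 0) 0 else 2 * p * s / (p + s)
    out[i, ] <- c(p, s, sp, f1)
  }
  out
}

oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) 0 else (po - pe) / (1 - pe)
}

oracle_mcc <- function(cm) {
  s <- sum(cm)
  cc <- sum(diag(cm))
  tk <- rowSums(cm)
  pk <- colSums(cm)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) 0 else (cc * s - sum(tk * pk)) / den
}

# Brute-force 1-D non-local means double loop.
oracle_nlm <- function(x, patch, search, h) {
  n <- length(x)
  pr <- patch %/% 2
  sr <- search %/% 2
  out <- numeric(n)
  clampi <- function(i) pmin(n, pmax(1, i))
  for (i in seq_len(n)) {
    js <- max(1, i - sr):min(n, i + sr)
    w <- vapply(js, function(j) {
      d2 <- mean((x[clampi(i + (-pr:pr))] - x[clampi(j + (-pr:pr))])^2)
      exp(-d2 / h^2)
    }, numeric(1))
    out[i] <- sum(w * x[js]) / sum(w)
  }
  out
}
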