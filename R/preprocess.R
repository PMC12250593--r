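#' Denoising pipeline configuration
#'
#' Parameters of the three-stage sequential pipeline applied per lead:
#' zero-phase Butterworth low-pass, LOESS baseline-wander removal, and
#' one-dimensional non-local means (NLM).
#'
#' @param cutoff_hz Low-pass cutoff in Hz. The default keeps the usual
#'   diagnostic ECG band (everything below 50 Hz).
#' @param order Butterworth order (applied forward and backward, so the
#'   effective magnitude response is squared).
#' @param loess_span LOESS span as a fraction of the record length used
#'   for the local degree-1 fits that estimate the baseline trend.
#' @param nlm_patch Patch length in samples (odd).
#' @param nlm_search Search window length in samples (odd).
#' @param nlm_h NLM smoothing strength; `NULL` estimates it per lead as
#'   0.7 x the noise SD from the median absolute deviation of the first
#'   difference.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cutoff_hz = 50, order = 4, loess_span = 0.15,
                          nlm_patch = 11, nlm_search = 101, nlm_h = NULL) {
  if (cutoff_hz <= 0) abort("cutoff_hz must be positive")
  if (order < 1) abort("order must be >= 1")
  if (loess_span <= 0 || loess_span > 1) abort("loess_span must be in (0, 1]")
  if (nlm_patch >= nlm_search) abort("nlm_patch must be smaller than nlm_search")
  structure(
    list(
      cutoff_hz = cutoff_hz, order = order, loess_span = loess_span,
      nlm_patch = as.integer(nlm_patch), nlm_search = as.integer(nlm_search),
      nlm_h = nlm_h
    ),
    class = "filter_config"
  )
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`cfg$order` digital Butterworth low-pass forward and
#' backward (`signal::filtfilt`), so the phase response is zero and QRS
#' peaks are not delayed; the magnitude response is applied twice.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param cfg A [filter_config()].
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, cfg = filter_config()) {
  if (cfg$cutoff_hz >= fs / 2) {
    abort(sprintf(
      "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
      cfg$cutoff_hz, fs / 2
    ))
  }
  if (length(x) <= 3 * cfg$order) abort("signal too short for the filter order")
  bf <- signal::butter(cfg$order, cfg$cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (zero initial conditions otherwise leak in)
  n <- length(x)
  pad <- min(n - 1, max(25 * cfg$order, 100))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  y[(pad + 1):(pad + n)]
}

#' Remove baseline wander by LOESS detrending
#'
#' Fits a locally weighted degree-1 regression of the signal on time over
#' a window of `loess_span` x record length and subtracts the fitted
#' trend. Robustness iterations downweight beat-scale deflections as
#' outliers, so constant offsets and sub-0.5 Hz drift are absorbed by the
#' trend while the P-QRS-T complexes pass through.
#'
#' @inheritParams butterworth_lowpass
#' @return Detrended signal, same length as `x`.
#' @export
loess_detrend <- function(x, fs, cfg = filter_config()) {
  n <- length(x)
  if (n < 10) abort("signal too short to detrend")
  if (cfg$loess_span * n < 4) {
    abort("loess_span too small: local fits are underdetermined")
  }
  # robust iterations keep the trend from chasing QRS deflections
  trend <- lowess(seq_len(n), x, f = cfg$loess_span, iter = 3)$y
  x - trend
}

#' One-dimensional non-local means denoising
#'
#' Each output sample is a weighted average of samples within the search
#' window whose surrounding patches resemble the target patch, with
#' weights `exp(-d2 / h^2)` (d2 = mean squared patch difference)
#' normalized to sum to one. With `nlm_h = NULL` the strength is
#' estimated as 0.7 x the noise SD (MAD of the first difference /
#' sqrt(2)); an estimated strength of zero returns the input unchanged.
#'
#' @inheritParams butterworth_lowpass
#' @return Denoised signal, same length as `x`.
#' @export
nlm_denoise <- function(x, cfg = filter_config()) {
  n <- length(x)
  if (cfg$nlm_patch < 1 || cfg$nlm_search >= n) {
    abort("degenerate NLM window sizes for this signal length")
  }
  h <- cfg$nlm_h
  if (is.null(h)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    h <- 0.7 * sigma
  }
  if (h <= 0) {
    return(x)
  }
  nlm_denoise_cpp(as.numeric(x), as.integer(cfg$nlm_patch),
                  as.integer(cfg$nlm_search), h)
}

#' Run the full denoising pipeline over a record table
#'
#' Applies, per lead and in this order: [butterworth_lowpass()],
#' [loess_detrend()], [nlm_denoise()]. Labels, features, and the retained
#' clean reference are unchanged; the stage order actually executed is
#' recorded in the `preprocessing` attribute of the returned table.
#'
#' @param records An ECG record table.
#' @param cfg A [filter_config()].
#' @return The record table with denoised `signal` matrices.
#' @export
preprocess_ecg <- function(records, cfg = filter_config()) {
  check_ecg_tbl(records)
  stages <- character(0)
  out <- records
  out$signal <- purrr::pmap(
    list(records$signal, records$fs),
    function(sig, fs) {
      t(apply(sig, 1, function(ch) {
        ch <- butterworth_lowpass(ch, fs, cfg)
        ch <- loess_detrend(ch, fs, cfg)
        nlm_denoise(ch, cfg)
      }))
    }
  )
  out$signal <- purrr::map2(out$signal, records$signal, function(s, orig) {
    rownames(s) <- rownames(orig)
    s
  })
  attr(out, "preprocessing") <- c("butterworth", "loess", "nlm")
  out
}
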