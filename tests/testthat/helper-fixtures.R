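# Shared fixtures: small clean datasets and tiny models, built in code.

tiny_dataset <- function(n = 16, seed = 42, fs = 100, duration = 2,
                         noise = noise_spec(0, 0, 0)) {
  generate_ecg_dataset(n, seed = seed, fs = fs, duration = duration,
                       noise = noise)
}

tiny_params <- function(hidden = 4, layers = 1, fusion = FALSE, seed = 9) {
  gru_init(hidden, layers, fusion = fusion, seed = seed)
}

flatten_params_for_test <- function(p) unlist(unclass(p), use.names = FALSE)

# Simple R-peak detector on a clean single-lead trace: local maxima above
# a fraction of the global maximum, separated by a refractory gap.
detect_beats <- function(x, fs, thresh = 0.5, refractory = 0.2) {
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[x[peaks] > thresh * max(x)]
  if (length(peaks) < 2) {
    return(peaks)
  }
  keep <- peaks[1]
  for (p in peaks[-1]) {
    if ((p - keep[length(keep)]) / fs > refractory) keep <- c(keep, p)
  }
  keep
}
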