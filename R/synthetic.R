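#' Contamination specification for synthetic ECGs
#'
#' Amplitudes of the three contamination sources added to a clean synthetic
#' record: mains interference at 50 Hz, slow baseline wander (drift
#' frequency drawn below 0.5 Hz), and white measurement noise. All values
#' are in millivolts; the defaults are moderate contamination relative to a
#' ~1 mV QRS complex. Use `noise_spec(0, 0, 0)` for clean records.
#'
#' @param powerline_amp Amplitude of the 50 Hz mains component (mV).
#' @param baseline_amp Amplitude of the baseline drift component (mV).
#' @param white_sigma Standard deviation of additive white noise (mV).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(powerline_amp = 0.05, baseline_amp = 0.2, white_sigma = 0.02) {
  if (any(c(powerline_amp, baseline_amp, white_sigma) < 0)) {
    abort("noise amplitudes must be nonnegative")
  }
  structure(
    list(
      powerline_amp = powerline_amp,
      baseline_amp = baseline_amp,
      white_sigma = white_sigma
    ),
    class = "noise_spec"
  )
}

# Per-lead projection of the scalar beat waveform onto the 12 leads.
# Signs and magnitudes loosely follow typical limb/precordial polarity;
# the generator makes no claim of vectorcardiographic fidelity.
lead_projection <- c(
  0.6, 1.0, 0.5, -0.8, 0.3, 0.7,
  -0.4, 0.9, 1.1, 1.2, 1.0, 0.8
)

# Ventricular-rate ranges (bpm) per rhythm class. Half-open [lo, hi).
class_rate_range <- list(
  SB   = c(40, 60),
  SR   = c(60, 100),
  AFIB = c(60, 160),
  GSVT = c(100, 200)
)

# RR-interval coefficient of variation: AFIB is irregular, the rest regular.
class_rr_cv <- c(SB = 0.03, SR = 0.03, AFIB = 0.20, GSVT = 0.03)

# Sum-of-Gaussian-bumps waveform for one beat train evaluated on grid `t`.
# Morphology: P bump before the R peak (absent in AFIB), a tall narrow QRS
# bump, and a broad T bump after it. All times in seconds, amplitudes mV.
beat_waveform <- function(t, beat_times, morph) {
  y <- numeric(length(t))
  for (tau in beat_times) {
    if (morph$p_amp > 0) {
      y <- y + morph$p_amp * exp(-((t - tau + morph$p_lag)^2) / (2 * morph$p_sigma^2))
    }
    y <- y + morph$qrs_amp * exp(-((t - tau)^2) / (2 * morph$qrs_sigma^2))
    y <- y + morph$t_amp * exp(-((t - tau - morph$t_lag)^2) / (2 * morph$t_sigma^2))
  }
  y
}

#' Generate one synthetic 12-lead ECG record
#'
#' Synthesizes a labeled record with class-dependent rhythm: the
#' ventricular rate is drawn uniformly in 40-60 bpm for SB, 60-100 for SR,
#' 60-160 for AFIB, and 100-200 for GSVT. AFIB records carry an irregular
#' RR train (coefficient of variation 0.2), no P wave, and a small
#' fibrillatory baseline oscillation; the other classes are regular
#' (CV 0.03) with a P wave. Beats are sums of Gaussian bumps (P, QRS, T)
#' projected onto 12 leads by a fixed amplitude vector. The 13 clinical
#' features are computed from the generated beat train itself
#' (`ventricular_rate` = 60 / mean RR, `qrs_count` = beats in the window,
#' interval features from the bump geometry), so the feature table is
#' consistent with the waveform by construction. Contamination (50 Hz
#' mains, sub-0.5 Hz drift, white noise) is added per `noise`; the clean
#' signal is retained in the `signal_clean` column.
#'
#' @param label Rhythm class, one of `"SB"`, `"AFIB"`, `"GSVT"`, `"SR"`.
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration Record length in seconds (> 0).
#' @param noise A [noise_spec()].
#' @param record_id Identifier string; derived from the seed when `NULL`.
#' @return A one-row tibble (an ECG record table) with columns
#'   `record_id`, `label`, `fs`, `duration`, `sex`, the 13 features of
#'   [ecg_feature_names], and list-columns `signal` / `signal_clean`
#'   holding 12 x (fs * duration) matrices in mV.
#' @examples
#' r <- generate_ecg_record("SB", seed = 1, fs = 100)
#' dim(r$signal[[1]])
#' @export
generate_ecg_record <- function(label, seed, fs = 500, duration = 10,
                                noise = noise_spec(), record_id = NULL) {
  label <- as.character(label)
  if (!label %in% ecg_classes) {
    abort(sprintf(
      "unknown label %s; valid labels are %s",
      sQuote(label), paste(ecg_classes, collapse = ", ")
    ))
  }
  if (duration <= 0) abort("duration must be positive")
  if (fs < 100) abort("fs must be at least 100 Hz")
  stopifnot(inherits(noise, "noise_spec"))

  with_local_seed(seed, {
    d <- round(fs * duration)
    t <- (seq_len(d) - 1) / fs

    rng <- class_rate_range[[label]]
    rate <- runif(1, rng[1], rng[2])
    mean_rr <- 60 / rate
    cv <- class_rr_cv[[label]]

    n_rr <- ceiling((duration + 2) / mean_rr) + 3
    rr <- rnorm(n_rr, mean_rr, cv * mean_rr)
    rr <- pmax(rr, 0.3 * mean_rr)
    rr <- rr * (mean_rr / mean(rr)) # exact mean RR -> rate is exact
    t0 <- runif(1, 0, mean_rr)
    beat_times <- t0 + cumsum(c(0, rr))
    beat_times <- beat_times[beat_times < duration + 0.5]

    morph <- list(
      p_amp = if (label == "AFIB") 0 else 0.15,
      p_lag = 0.16 * sqrt(mean_rr),
      p_sigma = 0.025,
      qrs_amp = runif(1, 0.9, 1.1),
      qrs_sigma = runif(1, 0.012, 0.018),
      t_amp = runif(1, 0.25, 0.35),
      t_lag = 0.25 * sqrt(mean_rr),
      t_sigma = runif(1, 0.05, 0.07)
    )

    base <- beat_waveform(t, beat_times, morph)
    if (label == "AFIB") {
      # fibrillatory f-waves: continuous small oscillation at 5.5-8 Hz
      f_fib <- runif(1, 5.5, 8)
      base <- base + 0.05 * sin(2 * pi * f_fib * t + runif(1, 0, 2 * pi))
    }
    # AC-coupled acquisition: recorded leads are zero-mean
    base <- base - mean(base)
    clean <- outer(lead_projection, base)
    rownames(clean) <- ecg_lead_names

    sig <- clean
    if (noise$powerline_amp > 0) {
      ph <- runif(12, 0, 2 * pi)
      pl <- vapply(ph, function(p) sin(2 * pi * 50 * t + p), numeric(d))
      sig <- sig + noise$powerline_amp * t(pl)
    }
    if (noise$baseline_amp > 0) {
      f_b <- runif(1, 0.15, 0.4)
      ph <- runif(12, 0, 2 * pi)
      bl <- vapply(ph, function(p) sin(2 * pi * f_b * t + p), numeric(d))
      sig <- sig + noise$baseline_amp * t(bl)
    }
    if (noise$white_sigma > 0) {
      sig <- sig + matrix(rnorm(12 * d, 0, noise$white_sigma), nrow = 12)
    }

    in_window <- beat_times[beat_times >= 0 & beat_times < duration]
    qrs_count <- length(in_window)
    tau1 <- if (qrs_count > 0) in_window[1] else beat_times[1]
    qt_s <- 3 * morph$qrs_sigma + morph$t_lag + 3 * morph$t_sigma

    sex <- if (runif(1) < 0.5) "M" else "F"
    age <- round(min(95, max(18, rnorm(1, 62, 15))))
    atrial <- if (label == "AFIB") runif(1, 300, 600) else rate

    feats <- c(
      age = age,
      gender = as.numeric(sex == "M"),
      ventricular_rate = rate,
      atrial_rate = atrial,
      qrs_duration = 1000 * 6 * morph$qrs_sigma,
      qt_interval = 1000 * qt_s,
      qt_corrected = 1000 * qt_s / sqrt(mean_rr),
      r_axis = rnorm(1, 60, 25),
      t_axis = rnorm(1, 45, 20),
      qrs_count = qrs_count,
      q_onset = max(0, round(fs * (tau1 - 3 * morph$qrs_sigma))),
      q_offset = max(0, round(fs * (tau1 + 3 * morph$qrs_sigma))),
      t_offset = max(0, round(fs * (tau1 + qt_s)))
    )

    id <- record_id %||% sprintf("rec_%s_%d", label, as.integer(seed))
    out <- tibble::tibble(
      record_id = id,
      label = factor(label, levels = ecg_classes),
      fs = fs,
      duration = duration,
      sex = sex,
      !!!as.list(feats),
      signal = list(sig),
      signal_clean = list(clean)
    )
    out
  })
}

#' Generate a labeled synthetic ECG dataset
#'
#' Draws exactly `n` records with per-class counts equal to the
#' largest-remainder rounding of `n * proportions`, in a label order
#' shuffled deterministically from `seed`. Each record's own seed is
#' derived from the master seed, so the full dataset is a pure function of
#' its arguments.
#'
#' @param n Number of records.
#' @param proportions Named or unnamed length-4 class fractions in the
#'   order SB, AFIB, GSVT, SR; must sum to 1.
#' @param seed Master integer seed.
#' @inheritParams generate_ecg_record
#' @return An ECG record table (tibble) with `n` rows.
#' @examples
#' ds <- generate_ecg_dataset(8, seed = 1, fs = 100)
#' table(ds$label)
#' @export
generate_ecg_dataset <- function(n, proportions = rep(0.25, 4), seed = 1,
                                 fs = 500, duration = 10, noise = noise_spec()) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("class proportions must sum to 1")
  }
  if (length(proportions) != length(ecg_classes)) {
    abort("proportions must have one entry per class (SB, AFIB, GSVT, SR)")
  }
  counts <- largest_remainder(n, proportions)
  labels <- rep(ecg_classes, counts)
  labels <- with_local_seed(derive_seed(seed, 0), sample(labels))
  recs <- purrr::imap(labels, function(lab, i) {
    generate_ecg_record(
      lab,
      seed = derive_seed(seed, i),
      fs = fs, duration = duration, noise = noise,
      record_id = sprintf("rec_%04d", i)
    )
  })
  dplyr::bind_rows(recs)
}

#' Plot the leads of one ECG record
#'
#' @param record A one-row ECG record table (or a row index into `data`).
#' @param leads Which leads to draw (names from [ecg_lead_names]).
#' @param clean Draw the retained clean signal instead of the contaminated one.
#' @return A ggplot object, leads stacked in facets.
#' @export
plot_ecg <- function(record, leads = c("II", "V2"), clean = FALSE) {
  check_ecg_tbl(record, "record")
  stopifnot(nrow(record) == 1)
  sig <- if (clean) record$signal_clean[[1]] else record$signal[[1]]
  keep <- intersect(leads, rownames(sig))
  df <- tibble::tibble(
    time = rep((seq_len(ncol(sig)) - 1) / record$fs, length(keep)),
    mv = as.vector(t(sig[keep, , drop = FALSE])),
    lead = factor(rep(keep, each = ncol(sig)), levels = keep)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead)) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (mV)",
      title = sprintf("%s (%s)", record$record_id, record$label)
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
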