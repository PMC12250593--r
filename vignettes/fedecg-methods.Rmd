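---
title: "Methods: privacy-preserving federated GRU classification of 12-lead ECGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving federated GRU classification of 12-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedecg)
```

## The problem

Hospitals hold 10-second, 12-lead ECG recordings labeled with one of four
merged rhythm classes — sinus bradycardia (SB), atrial fibrillation
(AFIB), the supraventricular-tachycardia group (GSVT), and sinus rhythm
(SR) — together with 13 routine clinical measurements per recording
(age, sex, ventricular and atrial rate, QRS duration, QT and corrected
QT, R and T axis, QRS count, and the Q-onset/Q-offset/T-offset landmark
indices). Records cannot leave the institution, so a single pooled
training set is not available. `fedecg` simulates the full pipeline on
one machine: synthetic data generation, denoising, sequence
classification, federated training with differentially private gradient
updates, per-client personalization, and diagnostic evaluation.

## The sequence model

The classifier is a stacked gated recurrent unit (GRU) network fed one
time step per retained signal sample; each step's input is the vector of
12 per-lead amplitudes. Per layer and time step, with $\sigma$ the
logistic function and $\odot$ elementwise multiplication:

$$
\begin{aligned}
z_t &= \sigma(W_z x_t + U_z h_{t-1} + b_z) \\
r_t &= \sigma(W_r x_t + U_r h_{t-1} + b_r) \\
\tilde h_t &= \tanh(W_h x_t + U_h (r_t \odot h_{t-1}) + b_h) \\
h_t &= (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t
\end{aligned}
$$

Note the convention in the last line: $z_t \to 1$ moves the state toward
the *candidate*, $z_t \to 0$ retains the previous state. Both
conventions appear in the literature (they differ by relabeling
$z \leftrightarrow 1-z$); `fedecg` uses the form above exactly as
written, and the tests pin the implementation to a scalar per-equation
oracle at $10^{-6}$.

The last layer's final hidden state is the sequence representation. With
*feature fusion* enabled, the 13 clinical features (z-scored with
training-split statistics) are concatenated to it before a single linear
layer and softmax produce the four class probabilities. Training
minimizes label-smoothed cross-entropy: with smoothing $s$ the target
distribution is $q_k = (1-s)\,\mathbf 1[k=y] + s/4$ and the loss
$-\sum_k q_k \log p_k$, probabilities floored at $10^{-12}$ so a zero
prediction is a large finite penalty rather than infinity. Defaults
follow the centralized setup: Adam, learning rate $10^{-3}$, weight
decay $10^{-5}$, smoothing $0.2$. Weight matrices initialize uniformly
in $\pm 1/\sqrt{\text{hidden}}$; biases at zero; batch size defaults
to 64. Forward and backward passes (truncated-nowhere BPTT over the full
sequence) are compiled C++ for speed; gradients are verified against
central finite differences in development.

Two preset geometries mirror the reference configurations: scenario 1
(hidden 64, 5 layers, no fusion) and scenario 2 (hidden 48, 5 layers,
fusion); scenarios 3 and 4 reuse the scenario-2 model federatedly.
A `stride` option decimates the input sequence (keep every k-th sample)
for desk-scale runs; it is a pure runtime/representation trade-off and
defaults to 1.

## Differential privacy mechanism

Privacy enters through the gradient: each mini-batch gradient is
flattened, clipped to an L2 bound $C$ as
$g \cdot \min(1,\, C/\lVert g \rVert_2)$, and perturbed with independent
Gaussian noise before the optimizer update. The clipping form follows
the standard DP-SGD construction (a printed variant that divides a
scalar "clipped" value by $C$ is dimensionally inconsistent and is not
used). Two noise conventions are supported because the literature uses
$\sigma$ both ways: `"multiplier"` (default) adds noise with standard
deviation $\sigma C$, reading $\sigma$ as a multiple of the clipping
norm; `"literal"` adds standard deviation $\sigma$ itself. When
$\sigma$ is not given it is calibrated as
$\sigma = C_{\mathrm{mech}} \cdot \text{Sensitivity} / \varepsilon$,
with both the mechanism constant and the sensitivity defaulting to the
clipping norm (the L2 sensitivity of a clipped gradient). A per-round
schedule hook either holds $(\sigma, C)$ constant or decays $\sigma$
linearly to a floor fraction (default 0.5) of its initial value over
the global rounds, with $C$ fixed, so $\sigma_t$ is non-increasing.

Clipping is applied to the per-batch gradient, matching the round
structure of the federated algorithm; a per-sample accounting view is
out of scope. **Limitation:** there is no formal $(\varepsilon,\delta)$
accountant — $\varepsilon$ influences training only through the
calibration formula above, so reported budgets are nominal, not
composition-tracked.

## Federated training and personalization

Each global round: every client (all participate every round) loads the
global weights, runs $E_l$ local epochs of (optionally DP) mini-batch
training on its own records, and returns only its final weights and
sample count. The server aggregates with size-weighted federated
averaging,
$\theta_{\text{new}} = \sum_i \frac{N_i}{\sum_j N_j}\, W_i$,
applied array by array; the weight factors sum to one by construction
and the aggregate is tested against a brute-force weighted mean at
$10^{-12}$. After aggregation the global model is evaluated on the held
global test split, and each client may fine-tune a personal copy
(plain, non-private local training) — either inside every round or once
after the last round. With one client, no noise and infinite clipping,
the whole loop reduces bit-for-bit to centralized training; this exact
reduction is enforced by a deterministic seed discipline in which every
(round, client) pair derives its RNG seed from the master seed by an
integer hash.

Client data layouts are produced by two partitioners: `iid` deals a
shuffled copy round-robin (sizes differ by at most one), and
`dirichlet` draws per-class client proportions from a symmetric
Dirichlet($\alpha$), the standard label-skew benchmark; $\alpha = 0.5$
gives strong heterogeneity, $\alpha \to \infty$ recovers the global
mix. The number of simulated hospitals defaults to 4 — a choice, since
no reference value exists. For personalization experiments a
per-client holdout fraction (0.25 in the tests) is split off before
local training so personalized and global models are compared on the
client's own label distribution.

## The synthetic generator

The generator emulates the *structure* of a 12-lead arrhythmia corpus,
not its physiology. Each record is a beat train of Gaussian bumps (P,
QRS, T) on a zero baseline, projected to 12 leads by a fixed amplitude
vector, sampled at `fs` (default 500 Hz) for `duration` seconds
(default 10 s):

* **Rates.** Ventricular rate is drawn uniformly per class: SB
  $[40,60)$, SR $[60,100)$, AFIB $[60,160)$, GSVT $[100,200)$ bpm. RR
  intervals are Gaussian with coefficient of variation 0.03 (regular
  rhythms) or 0.20 (AFIB), rescaled so the realized mean RR matches the
  drawn rate exactly.
* **AFIB signature.** No P bump, irregular RR, plus a small 5.5-8 Hz
  fibrillatory baseline oscillation; the atrial-rate feature is drawn
  in 300-600 bpm (fibrillatory), versus equal to the ventricular rate
  for the sinus-driven classes.
* **Features.** All 13 features are computed from the generated train
  itself (rate = 60/mean RR, QRS count = beats in the window, interval
  features from the bump geometry, QTc by Bazett), so waveform and
  table never disagree.
* **Leads.** Recorded leads are zero-mean, emulating AC-coupled
  acquisition front-ends; per-lead amplitudes come from one fixed
  projection vector. No vectorcardiographic fidelity is claimed.
* **Contamination.** Optional 50 Hz mains interference, sub-0.5 Hz
  baseline drift (frequency drawn in 0.15-0.4 Hz), and white noise,
  with default amplitudes 0.05 / 0.2 / 0.02 mV against a ~1 mV QRS —
  moderate contamination by clinical standards. The clean signal is
  retained alongside, which is what makes denoising measurable.

By construction a rate-threshold rule classifies the three non-AFIB
classes perfectly from the ventricular-rate feature, which guarantees
that learning-recovery tests *can* succeed; what the generator does
**not** contain — morphology pathologies, lead placement variation,
inter-patient covariance, class imbalance of a real registry — bounds
what passing tests show about real data: they validate the machinery,
not clinical performance.

## Denoising pipeline

Per lead, in this fixed order (the order is recorded on the output):

1. **Butterworth low-pass**, order 4 at 50 Hz, applied
   forward-backward for zero phase, with odd-reflection padding so the
   filter's startup transients do not leak into the record. The
   effective magnitude response is the squared analog response
   $1/(1+(f/f_c)^8)$ up to bilinear-transform warping, which makes the
   digital stopband slightly *stronger* than the analog form; the tests
   therefore compare gains within an absolute 0.01 of unit input.
2. **LOESS detrending**: a degree-1 locally weighted regression over a
   window of 15% of the record estimates the baseline and is
   subtracted. Robustness iterations downweight the spiky QRS
   deflections, so the trend follows drift rather than beats — this is
   what makes the stage approximately idempotent.
3. **1-D non-local means**: each sample becomes a weighted average of
   search-window samples whose patches resemble its own, weights
   $\exp(-d^2/h^2)$ normalized to one. Defaults: patch 11, search 101,
   $h = 0.7\,\hat\sigma$ with $\hat\sigma$ the noise SD estimated from
   the median absolute deviation of the first difference; $\hat\sigma
   = 0$ (an exactly clean signal) returns the input unchanged.

The 50 Hz cutoff equals the nominal mains frequency; whether "below
50 Hz" should include 50 Hz exactly is ambiguous, and the cutoff is
kept at 50 Hz as the diagnostic-band convention (the two-pass rolloff
attenuates the mains line by about half in amplitude; a dedicated notch
stage is deliberately not added).

## Evaluation

Predictions are the argmax of the forward probabilities, ties broken
toward the lowest class index. From the 4x4 confusion matrix (rows =
truth) the report computes one-vs-rest precision, sensitivity,
specificity and F1 per class, overall accuracy, Cohen's kappa
$(p_o-p_e)/(1-p_e)$, and the multiclass Matthews correlation
coefficient in the Gorodkin covariance form. Conventions for degenerate
cases: any 0/0 metric is 0 and raises a classed warning
(`fedecg_degenerate_metric`); kappa and MCC return 0 when their
denominators vanish. All metric paths are tested against independently
coded textbook formulas at $10^{-12}$.

## Numerical and experimental choices

* Probability floor $10^{-12}$ in the loss; softmax computed with the
  max-subtraction trick.
* Weight decay is added to the *privatized* gradient, so the DP
  mechanism sees exactly the loss gradient.
* Stratified splitting uses per-class largest-remainder apportionment
  plus a repair pass, giving exact overall 75/10/15 sizes and per-class
  deviations of at most one record.
* Desk-scale study conditions used by the test suite and the
  acceptance script: n = 400 noiseless records at 100 Hz, 4 balanced
  classes, the reduced scenario-2 model (hidden 16, 2 layers, fusion),
  sequence stride 5, batch size 6, and for FedAvg 4 IID clients with 10
  local epochs per round. Batch size and stride are free desk-scale
  choices made to give the fixed learning rate ($10^{-3}$) a sufficient
  optimizer-step budget inside the 30-epoch / 10-round windows;
  "reaches x% within N epochs/rounds" is always measured as the best
  per-epoch or per-round test evaluation inside the window.
* Remaining test errors in learning-recovery runs sit within a few bpm
  of the 60 and 100 bpm class boundaries, where uniformly drawn rates
  make adjacent classes arbitrarily close; a smooth classifier cannot
  resolve these boundary records without many more optimization steps.

## Known limitations

No privacy accountant (see above); a single-machine simulation of
clients with no transport layer, stragglers, or dropout; phenomenological
beat morphology; no class imbalance handling; the optional real-data
adapter is limited to the CSV layout written by `write_ecg_records()`.
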