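# fedecg

Privacy-preserving federated learning for four-class arrhythmia
classification from 10-second, 12-lead ECGs — simulated end to end on one
machine, in R.

Hospitals hold labeled ECG recordings (sinus bradycardia **SB**, atrial
fibrillation **AFIB**, the supraventricular-tachycardia group **GSVT**,
sinus rhythm **SR**, plus 13 routine clinical measurements per record)
that cannot be pooled. `fedecg` implements and evaluates the complete
pipeline for training a shared diagnostic model without moving records:

* **Synthetic 12-lead ECG generator** — class-dependent rhythm (rate
  ranges, RR irregularity and missing P waves for AFIB), a consistent
  13-feature clinical table computed from the generated beat train, and
  controllable contamination (50 Hz mains, baseline wander, white
  noise), with the clean reference retained.
* **Sequential denoising** — zero-phase order-4 Butterworth low-pass at
  50 Hz, robust LOESS baseline removal, 1-D non-local means.
* **GRU sequence classifier** (from scratch, C++ core) with optional
  fusion of the clinical features, trained with label-smoothed
  cross-entropy (Adam, lr 0.001, weight decay 1e-5, smoothing 0.2). The
  cell follows the standard gate equations; note the update-gate
  convention `h_t = (1 − z_t) ⊙ h_{t−1} + z_t ⊙ h̃_t`.
* **Differential privacy** — per-batch L2 gradient clipping
  `g · min(1, C/‖g‖₂)` plus Gaussian noise (std `σ·C` by default, or
  literal `σ`), calibration `σ = C·Sensitivity/ε`, and a per-round
  decay schedule. No formal (ε, δ) accountant is included.
* **Federated averaging** — size-weighted aggregation
  `θ_new = Σᵢ (Nᵢ/ΣⱼNⱼ)·Wᵢ` over all clients each round, IID or
  Dirichlet label-skew client partitioning, and per-client
  **personalization** by local fine-tuning of the aggregated model.
* **Diagnostics** — confusion matrix, per-class precision / sensitivity
  / specificity / F1, accuracy, Cohen's kappa, multiclass Matthews
  correlation (Gorodkin form), as tidy tibbles with `tidy()`,
  `glance()` and `autoplot()` methods.

## Worked example

Generate a clean, balanced dataset; split 75/10/15 with stratification;
z-score the clinical features on the training split; train the fusion
GRU; evaluate.

```r
library(fedecg)

ds <- generate_ecg_dataset(n = 400, seed = 2024, fs = 100,
                           noise = noise_spec(0, 0, 0))
ds[1:3, c("record_id", "label", "ventricular_rate", "atrial_rate", "qrs_count")]
#> 1 rec_0001  SB                53.4        53.4         9
#> 2 rec_0002  SB                48.4        48.4         8
#> 3 rec_0003  AFIB             116.        511.         20

sp <- split_ecg(ds, seed = 1) |> normalize_ecg_features()
#> ECG split: 300 train / 40 validation / 60 test

params <- gru_init(hidden_size = 16, num_layers = 2, fusion = TRUE, seed = 1)
fit <- train_gru(sp$train, params,
                 gru_train_config(batch_size = 6, stride = 5),
                 epochs = 30, validation = sp$validation, seed = 1)
#> GRU classifier fit: hidden 16, 2 layer(s), fusion on, 30 epoch(s)
#> final train loss 0.6879, train accuracy 0.970

report <- evaluate_model(fit, sp$test)
report
#> accuracy 0.9167 | kappa 0.8889 | MCC 0.8912
#>  class precision sensitivity specificity     f1
#>     SB    1.0000      1.0000      1.0000 1.0000
#>   AFIB    1.0000      0.8667      1.0000 0.9286
#>   GSVT    0.8571      0.8000      0.9556 0.8276
#>     SR    0.8333      1.0000      0.9333 0.9091
```

The model separates SB perfectly (its 40–60 bpm rate range and the
rate-derived features give a wide margin) and confuses only records
lying within a few bpm of the 60 / 100 bpm class boundaries; the kappa
and MCC near 0.89 say the agreement is far beyond chance.

The same data trained federatedly — 4 simulated hospitals, all
participating every round, size-weighted averaging:

```r
part <- partition_clients(sp$train, n_clients = 4, strategy = "iid", seed = 1)
#> ECG partition: 4 client(s), strategy iid, sizes 75/75/75/75
fl <- run_federated(sp, part, params, rounds = 10, local_epochs = 10,
                    config = gru_train_config(batch_size = 6, stride = 5),
                    seed = 1)
#> federated fit: 10 round(s) x 10 local epoch(s), 4 client(s)
#> final global test accuracy 0.900
```

Adding differential privacy is one argument:
`run_federated(..., dp = dp_config(clip_norm = 1, noise_multiplier = 0.5))`;
per-client personalized models come from `personalize_epochs > 0`. The
four reference setups (centralized raw / centralized + fusion / FedAvg /
FedAvg + DP + personalization) are packaged as `scenario_config(1:4)`
and `run_scenario()`, with a thin command-line front end in
`inst/scripts/fedecg-cli.R`. The methods vignette
(`vignettes/fedecg-methods.Rmd`) documents the model, the privacy
mechanism, the generator's assumptions, and every numerical convention.

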