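# finclick

Context-dependent echolocation click density in captive Yangtze finless
porpoises (*Neophocaena asiaeorientalis asiaeorientalis*).

Finless porpoises emit narrow-band high-frequency (NBHF) clicks peaking
between 87 and 145 kHz. In a captive facility the number of clicks
recorded per minute — the **click density** — shifts with social and
environmental context (separation of the group, training/feeding,
enrichment, noise events, visitors), which makes passive acoustic
monitoring a candidate welfare-assessment tool. `finclick` implements
that monitoring chain end-to-end, for bioacousticians and welfare
researchers who want a tested, fully synthetic-data-validated pipeline:

1. **Synthesize** ground-truthed recordings (Gaussian-enveloped click
   pulses in trains over broadband noise, optional pool-echo
   duplication) and minute-level count tables with known generative
   structure.
2. **Detect** clicks: Kaiser-window FIR high-pass (80 kHz cutoff) →
   STFT (window 512, noverlap 256, nfft 512) → per-frame RBF-SVM
   classification of 257-bin magnitude spectra → event merging with
   87–128 kHz peak acceptance → click trains (≥ 5 clicks, every
   inter-click interval ≤ 200 ms) and per-minute densities.
3. **Model** context effects with a Poisson GLMM: for minute *m* with
   *n<sub>m</sub>* animals present,

   log λ*<sub>m</sub>* = log *n<sub>m</sub>* + **x***<sub>m</sub>*′**β** +
   *u*<sub>date</sub> + *v*<sub>session</sub> + ε*<sub>m</sub>*,

   with the log group size as exposure offset, date/session random
   intercepts crossed with an observation-level intercept that absorbs
   overdispersion, VIF collinearity screening (enrichment split into
   four indicators), AIC model selection, Wald chi-squared tests per
   predictor, Holm-adjusted pairwise contrasts, and effects reported as
   percent changes 100·(e^β − 1).

## Worked example

Simulate a year-long study (~6000 observation minutes, 50 days × 4
sessions × 30 min) and recover the context effects:

```r
library(finclick)

sim <- generate_minute_counts(scenario_config(seed = 1))
des <- build_design(sim$minutes, sim$annotations)   # drops live-fish minutes
fit <- fit_poisson_glmm(des, random = c("date", "session", "observation"))
wald_test(fit)
#>          predictor     chi2 df         p percent_change
#> 1    n_individuals 1.04e+00  1  3.07e-01         -0.851
#> 2           season 3.60e+01  3  7.49e-08             NA
#> 3      time_of_day 2.69e-01  2  8.74e-01             NA
#> 4         training 3.73e+04  1  0.00e+00        314.143
#> 5         grouping 2.06e+04  1  0.00e+00        136.251
#> 6             toys 8.96e+03  1  0.00e+00        152.221
#> 7           humans 1.57e+02  1  4.82e-36        -11.832
#> 8  humans_and_toys 1.91e+04  1  0.00e+00        445.617
#> 9       new_object 1.70e+04  1  0.00e+00        498.482
#> 10   unusual_event 1.35e+03  4 1.22e-290             NA
#> 11        visitors 4.27e+03  2  0.00e+00             NA
```

Reading the table: separated animals click **+136%** more than the
intact group and training sessions run **+314%** above baseline — the
multipliers planted by the simulator (2.36 and 4.12) recovered on the
percent scale. `time_of_day` is correctly flat (the generator encodes no
diurnal effect), multi-level factors carry their full degrees of freedom
(season 3, unusual events 4, visitors 2), and `n_individuals` is the
*deviation from proportionality* with group size (≈ 0: density scales
with the number of animals, which the offset already encodes).

The detection side works the same way from a rendered recording:

```r
spectra <- generate_spectra_dataset(2000, click_fraction = 0.5, seed = 1)
model   <- train_classifier(augment_spectra(spectra, 3, 1, seed = 2), seed = 4)
clicks  <- generate_click_times(60, train_rate_per_min = 12, snr_db = c(15, 25))
rec     <- render_recording(clicks, 60)
events  <- detect_clicks(rec$clip, model)
click_density(events, 60)        # one row per complete minute
segment_trains(events)           # >= 5 clicks, ICI <= 200 ms
```

The numbered drivers under `analysis/` run these stages as a narrative
workflow (`01_simulate.R` → `04_context_model.R`), writing tables under
`results/`.

## Layout

- `R/` — package code: synthesis (`waveform.R`, `spectra.R`,
  `counts.R`), detection (`detector.R`, `classifier.R`), modelling
  (`design.R`, `glmm.R`), orchestration (`pipeline.R`), WAV I/O
  (`wav.R`).
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/click-density-methods.Rmd` — the full methods account:
  model assumptions, scenario defaults, numerical choices, limitations.
- `analysis/` — the staged workflow; `scripts/acceptance.R` — the
  reproduction script.
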