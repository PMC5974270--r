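# nocidecode

Decoding the intensity and onset of acute pain from simulated cortical LFP
and spike recordings.

## What this is for

In freely behaving rats, noxious laser stimulation of the hind paw evokes
event-related synchronization (ERS) — stimulus-locked power increases in
theta (4–8 Hz) and high-gamma (60–100 Hz) bands — in anterior cingulate
cortex (ACC) local field potentials, scaling with stimulus intensity
(non-noxious NS = 50 mW, low noxious LS = 150 mW, high noxious HS = 250 mW)
and amplified in the chronic-pain (CFA) state. `nocidecode` is for
computational neuroscientists who want a tested, reproducible implementation
of the population-decoding analysis built on those signals:

* **multitaper spectral estimation** with Slepian tapers (TW = 3,
  K = 2·TW − 1 = 5) and baseline-referenced band-power z-scores,
  `z_i = (P_i − mean(P_base)) / sd(P_base)`;
* **cumulative decoding features**: 50-ms spike-count bins and trailing 1-s
  LFP band-power windows, accumulated from laser onset over (0, 5] s
  (100 bins; dimension C…100·C for C units);
* **SVM decoding trajectories**: a polynomial-kernel classifier
  `y = Σ α_i K(x, x_i) + b`, stratified 5-fold cross-validation (each fold a
  20% test set) repeated over Monte-Carlo runs, reported as mean ± S.E.M.
  accuracy per time bin;
* **permutation chance levels**: mean accuracy over 500 label shuffles
  (≈ 50% for balanced classes);
* **threshold-fraction onset detection**: with dynamic range
  Δ = peak − chance, the decoded pain onset is the first crossing of
  `chance + f·Δ`, f = 1/e ≈ 0.37 (or ½), compared against paw-withdrawal
  latency.

No recordings from this paradigm are public, so the package ships a
seed-deterministic synthetic session generator (pink-noise LFP with
band-limited ERS, Poisson units with a 20–30% stimulus-modulated minority,
intensity-dependent withdrawal latencies truncated to (0, 5] s) that
reproduces the statistical structure the analysis assumes; every stage is
validated against it. See `vignettes/pain-decoding-methods.Rmd` for the
model details and design rationale.

## Worked example

```r
library(nocidecode)

cfg <- synth_config(seed = 1)                       # 1 kHz, 30 trials/class
ses <- preprocess_session(make_session(cfg, c("NS", "HS"), "naive", seed = 1))
ses
#> <pain_session> NS vs HS, naive condition
#>   60 trials (HS: 30, NS: 30), 8 channels at 1000 Hz, 8 units

z <- zscore_band_power(ses, "theta")
aggregate(z ~ intensity, data = z[, c("intensity", "z")],
          FUN = function(x) round(mean(x), 2))
#>   intensity    z
#> 1        HS 4.96
#> 2        NS 0.06

feats <- lfp_band_features(ses)                     # all-frequency, accumulated
ch <- chance_level(feats, n_shuffle = 100, seed = 3)
traj <- decode_trajectory(feats, n_mc = 10, bins = seq(4, 100, 4), seed = 2,
                          chance = ch)
traj
#> <decoding_trajectory> 25 bins over (0.00, 5.00] s, lfp_all
#>   peak accuracy 0.992 at 1.40 s, chance 0.500
ch
#> <chance_level> 0.4998 (SD 0.0727) from 100 shuffles at t = 5.00 s

onset_from_trajectory(traj)
#> <onset_estimate> onset 0.154 s (criterion f = 0.368, threshold 0.681)
#>   peak 0.992 at 1.40 s, chance 0.500, dynamic range 0.492
```

Reading the output: the high-noxious trials carry a strong theta ERS (mean
z ≈ 5) while non-noxious trials sit at baseline (z ≈ 0); the decoder
separates NS from HS essentially perfectly by ~1.4 s; label shuffling
confirms a ~50% chance level; and the accuracy curve crosses the 1/e
threshold of its dynamic range ~150 ms after laser onset — the decoded
onset of the pain signal, here well before the typical ~2 s withdrawal.
`run_pipeline(cfg, out_dir)` runs the full grid (2 conditions × 3 stimulus
pairs × 3 feature modalities) and writes tidy CSV tables plus a
checksummed run manifest.

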