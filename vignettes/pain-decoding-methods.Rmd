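---
title: "Methods: simulating and decoding acute pain signals from cortical LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding acute pain signals from cortical LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Acute pain in freely behaving rodents is conventionally read out from spinal
withdrawal behavior. Extracellular recordings from the anterior cingulate
cortex (ACC) offer a neural alternative: noxious laser stimulation of the
hind paw evokes event-related synchronization (ERS) — a stimulus-locked
increase of oscillatory power — in theta (4–8 Hz) and high-gamma (60–100 Hz)
bands of the local field potential (LFP), scaling with stimulus intensity. A
supervised classifier trained on accumulated LFP and spike features can then
decode which of two stimulus intensities was delivered, and the rise time of
its accuracy curve carries information about *when* the nociceptive signal
emerged.

`nocidecode` implements that analysis chain end to end, together with a
seed-deterministic synthetic session generator that reproduces the
statistical structure the analysis assumes. No public recordings exist for
this paradigm, so the generator is a first-class, tested component: it is the
ground truth against which every downstream stage is validated.

# The synthetic session generator

A *session* is a balanced, randomly interleaved sequence of trials for one
stimulus pair (NS–LS, NS–HS or LS–HS; NS/LS/HS = 50/150/250 mW laser
power), in one condition (naive or CFA-treated, the chronic inflammatory
pain model). Each trial spans $[-5, +5)$ s around laser onset on a half-open
sample grid (sample $k$ at $-5 + k/f_s$; 10,000 samples at the default
$f_s = 1$ kHz — the half-open convention avoids a duplicated boundary
sample).

**LFP model.** Each channel is $1/f^\alpha$ pink noise ($\alpha = 1$,
40 µV SD) built from a latent component shared across channels
(`channel_mix` = 0.6 of the variance) plus independent channel noise —
enough cross-channel structure for the first principal component to be
meaningful, without modeling tetrode geometry. During the stimulus epoch,
band-limited Gaussian noise is added to all channels with variance
$(g - 1)$ times the background power in that band, under a 50-ms
raised-cosine envelope, so that the band's power is multiplied by the
configured gain $g$ while the baseline $[-5, 0)$ s is untouched and $g = 1$
is an exact null. Default gains drive theta (1, 2.5, 4 for NS, LS, HS) and
high gamma (1, 2, 3.5), chosen so that NS–HS sessions decode strongly and
NS–LS sessions decode at an intermediate level, mirroring the qualitative
ordering observed in vivo.

**Stimulus epoch.** The stimulus lasts until paw withdrawal, or the full 5 s
when no withdrawal occurs (NS), so the ERS runs over
$[t_{\mathrm{on}}, \min(\text{latency}, 5)]$ s; `ers_onset_s` delays the
neural response relative to the laser (0 by default), which the
shift-equivariance tests exploit.

**Withdrawal latencies.** No latency distributions are published for this
paradigm, so latencies are gamma-distributed per intensity, truncated to
$(0, 5]$ by inverse-CDF sampling, with defaults centered near 3 s (LS;
shape 9, rate 3) and 2 s (HS; shape 8, rate 4) — plausible magnitudes with
HS reliably faster than LS. They are config-exposed placeholders, not
estimates.

**Spikes.** Each of the `n_units` (default 8) units is a homogeneous Poisson
process at 5 spikes/s. A fixed minority — `round(0.25 × n_units)`, round half
up, identities drawn once per session — multiplies its rate during the
stimulus epoch by $1 + (g_r - 1)\,d(I)$ with rate gain $g_r = 2$ and
intensity drive $d = 0, 0.6, 1$ for NS, LS, HS. The 20–30% modulated
fraction matches what is reported for pain-responsive ACC units; $g_r = 1$
is again an exact null.

**CFA.** Chronic pain is modeled as a single multiplicative factor (default
1.5) on the ERS *excess* $(g - 1)$ of noxious (LS, HS) trials. Multiplying
the excess rather than the gain keeps bands with $g = 1$ silent under CFA;
applying it to noxious trials only follows the observation that the
amplification is most pronounced for LS stimulation.

**Determinism.** Every stochastic element draws from a child seed derived
from the master seed (`derive_seed()`), so a session is byte-reproducible
and extending a Monte-Carlo loop never changes earlier draws.

# Preprocessing

Multi-channel LFP is reduced to one denoised trace per trial: per-channel
linear detrending (least squares), artifact-channel rejection, then
projection onto the first principal component of the channel covariance,
fitted per trial on the trial's own samples (trials are the decoding unit,
and no pooling rule across trials is assumed). The eigenvector sign is fixed
by non-negative correlation with the across-channel mean; a single surviving
channel passes through unchanged.

The artifact rule is ours (the step, not the statistic, is standard): a
channel is rejected when the absolute robust z-score of its log total power
— $(\log P - \mathrm{median})/(1.4826\,\mathrm{MAD})$ across channels —
exceeds 3. Log power makes the rule scale-invariant; the two-sided test also
catches dead channels; zero dispersion (all channels alike) keeps everything;
rejecting all channels is an error, not a silent empty result.

# Spectral estimation

Spectra are multitaper estimates: the trace is multiplied by $K$ orthonormal
Slepian (DPSS) tapers, the $K$ eigenspectra are averaged, trading a
controlled bandwidth $W = TW/(N/f_s)$ for reduced variance. Defaults
$TW = 3$, $K = 2\,TW - 1 = 5$. Tapers come from the standard symmetric
tridiagonal eigenproblem; above $N = 1536$ samples they are computed at a
1024-sample base length, spline-interpolated and re-orthonormalized by QR
(the approach MATLAB's `dpss` uses for large $N$), so the orthonormality
invariant holds exactly in both paths. No zero padding: the frequency grid
has resolution $f_s/N$.

Band powers sum the estimated power over the half-open intervals theta
$[4, 8)$, alpha $[8, 15)$, beta $[15, 30)$, low gamma $[30, 60)$, high gamma
$[60, 100)$ Hz, which tile $[4, 100)$ exactly once (the conventional closed
intervals share edges; half-open edges prevent double counting). Frequencies
of 1–3 Hz are excluded from decoding features as artifact-prone.

ERS is quantified per trial as a z-score of response-epoch band power
($[0, 5)$ s) against the across-trial distribution of baseline-epoch powers
($[-5, 0)$ s): $z_i = (P_i - \bar P_{\mathrm{base}})/s_{P_{\mathrm{base}}}$.
Cross-trial baseline dispersion is the standard ERS normalization and is
well-defined for single trials; within-trial dispersion would conflate
estimation noise with trial-to-trial state. Both epochs are half-open so the
onset sample belongs to the response. Spectrogram displays default to a
500-ms window stepped by 50 ms; the decoder uses its own windows (below).

# Decoding features

Two feature families, on a common 50-ms grid over $(0, 5]$ s (100 bins):

* **Spike counts**: per unit, counts in consecutive 50-ms bins, half-open
  $(\mathrm{start}, \mathrm{end}]$ (a spike at exactly 0 is baseline).
  Features accumulate: bin $k$ concatenates bins $1..k$ for all $C$ units,
  dimension $Ck$. Raw counts are used — no rate normalization.
* **LFP band powers**: at each step $t$, multitaper band power
  ($TW = 3, K = 5$) of the trailing 1-s window $[t-1, t)$ of the denoised
  trace, per band; all five bands concatenated per step form the
  "all frequency" set. For $t < 1$ s the trailing window reaches into the
  baseline — the price of keeping the LFP grid aligned with the spike bins
  from time 0, consistent with accuracy curves that rise within the first
  second. By default LFP features accumulate across steps exactly like the
  spike bins; a per-window (non-accumulated) mode is available and is what
  the scaled-down property tests use, since it reacts faster to localized
  power changes and is much cheaper at subsampled evaluation grids.

Both families obey the *prefix property* (features at bin $k$ are the
leading columns of bin $k+1$) and strict causality (bin $k$ uses no sample
at or beyond $k \cdot 50$ ms, verified by recomputation on truncated
traces). `combine_features()` concatenates families per step.

# The decoder and its chance level

The classifier is a polynomial-kernel SVM (libsvm via `e1071`),
$K(u, v) = (\gamma\, u \cdot v + c_0)^p$. The kernel family is fixed; the
degree is not published for this paradigm, so the common default $p = 3$ is
used ($C = 1$, $c_0 = 1$ so sub-degree terms are present — a homogeneous
odd-degree kernel cannot even represent XOR — and $\gamma = 1/d$ for
conditioning). Features are z-scaled with training-fold statistics only;
scaling is not mentioned in the source analyses but is necessary for kernel
conditioning and is toggleable.

Accuracy at each bin is stratified 5-fold cross-validation — each fold is a
20% test set, which reconciles the "80/20 split" and "5-fold CV"
descriptions — repeated over `n_mc` Monte-Carlo runs (100 at full scale)
with fresh fold draws; the same fold partition is reused across bins within
a run, which stabilizes the trajectory's shape. The trajectory reports mean
± S.E.M. over runs, its peak, and the earliest peak time on ties.

The chance level permutes the labels between classes, re-runs the
cross-validated decoding at the final bin, and averages over 500 shuffles.
For balanced classes it sits near 50%; imbalance pulls it toward the
majority rate, which is why it — not 0.5 — anchors the onset analysis.

# Onset estimation

With dynamic range $\Delta = \mathrm{peak} - \mathrm{chance}$, the decoded
onset is the first time, scanning forward from laser onset to the peak, at
which mean accuracy reaches $\mathrm{chance} + f\,\Delta$; $f = 1/e \approx
0.37$ by default (borrowed from receptive-field sizing), $f = 1/2$ as the
robustness alternative. The two agree on steep curves and separate on
shallow ones. Numerical choices: the crossing is linearly interpolated
between the straddling 50-ms bins (sub-bin resolution; a forward scan and
the backward-from-peak reading coincide for monotone curves); the curve is
anchored at $(0, \mathrm{chance})$; and an onset is only reported when
$\Delta$ exceeds a gate, by default $3\times$ the chance SD, to suppress
spurious crossings on null sessions. "Chance" in the threshold is the
permutation chance level, matching the dynamic-range definition. At reduced
Monte-Carlo counts the gate still admits a small false-positive rate; the
calibration tests therefore hold null sessions to the same 10% standard as
the accuracy calibration rather than to literal zero.

`compare_onset_withdrawal()` pairs decoded onsets with mean withdrawal
latencies: signed differences (median, IQR), Spearman correlation, and a
Mann–Whitney rank-sum comparison (the package's default two-group test
throughout; ties mid-ranked).

Decoded onset tracks the *start* of the neural response. It therefore
agrees with withdrawal latency when withdrawal promptly follows the neural
onset (fast-withdrawal regimes), and leads it when withdrawal is slow —
the generator makes both regimes reproducible.

# Problem sizes, verification scope, and limitations

The generator's defaults are the study conditions: 1 kHz, 8 channels,
30 trials/class, 8 units, 25% modulated. The test suite verifies the same
code paths at reduced sizes chosen once for tractability: 250 Hz sessions
with 4 channels/4 units and 15–30 trials per class, 2–4 Monte-Carlo runs,
evaluation grids of 10–50 bins, and 20-replicate calibration loops. The
headline chance-level check runs at full defaults (60 trials, 500 shuffles,
all-frequency accumulated features). Stochastic assertions are
Monte-Carlo-calibrated (3-SE bands, 10% calibration standards, ±0.15 s
shift-equivariance at high SNR) rather than exact.

What passing tests show — and what they do not: the synthetic model has
stationary pink-noise backgrounds, linear ERS scaling, Poisson spiking and
no line noise, movement artifacts, electrode drift, spike-sorting errors or
cross-frequency coupling. Results on synthetic sessions validate the
*machinery* (estimators, bookkeeping, calibration), not the in-vivo effect
sizes; real-data accuracies cannot be reproduced without the original
recordings. Spike-field coherence, phase features, three-way decoding and
coherence across regions are out of scope.

# Reproducing a run

```{r}
library(nocidecode)

cfg <- synth_config(seed = 1)
ses <- preprocess_session(make_session(cfg, c("NS", "HS"), "naive", seed = 1))
feats <- lfp_band_features(ses)
traj <- decode_trajectory(feats, n_mc = 20, seed = 2,
                          chance = chance_level(feats, n_shuffle = 100,
                                                seed = 3))
onset_from_trajectory(traj)

## full grid of conditions/pairs/modalities with CSV outputs + manifest:
run_pipeline(cfg, out_dir = "pipeline-out", n_mc = 20, n_shuffle = 100)
```
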