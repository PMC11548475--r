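---
title: "Validating a prototype EMG device by feature concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a prototype EMG device by feature concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgconcord)
```

## The problem

A laboratory-built surface EMG front end is only useful if the signals it
records carry the same information as those from a regulatory-approved
commercial system. `emgconcord` implements a statistical validation
methodology for exactly this situation: both devices record the same muscle
site simultaneously, the recording is cut into trial-aligned windows using
an analog trigger channel, a standard battery of 22 time-domain feature
indices is computed per window and device, and agreement is quantified
per feature and per subject with an inverted mean absolute percentage
error,

$$\mathrm{MAPE} = \frac{1}{n}\sum_{i=1}^{n}
  \frac{|y_i - \hat y_i|}{|y_i|}, \qquad
  \text{concordance} = 1 - \mathrm{MAPE},$$

where $y_i$ is the reference-device feature value in window $i$ and
$\hat y_i$ the prototype's. A concordance of 1 means the two devices yield
identical feature values; 0 means no similarity. The statistic is kept as a
fraction internally and multiplied by 100 only for display, so that
$1-\mathrm{MAPE}$ is coherent. The denominator uses $|y_i|$ because several
features (the log-difference indices) are legitimately negative, and a
signed denominator would flip error signs meaninglessly. Pairs with
$|y_i| < 10^{-8}$ are excluded (MAPE is undefined at zero) and the
exclusion count is reported rather than silently inflating the error.

## The experimental protocol being emulated

The target protocol records at 2 kHz while a participant performs 6
movement types, 10 repetitions each, 2 s per contraction with 5 s of rest
in between — 60 trials. Trial identity is encoded on a third analog channel
as a 5 ms rectangular pulse whose amplitude steps from 15 mV (movement 1)
to 40 mV (movement 6) in 5 mV increments.

Since real dual-device recordings are site-specific, the package ships a
first-class simulator of this protocol rather than data. The generative
model is:

* **Muscle source.** Surface EMG during an isometric-style contraction is
  well approximated by amplitude-modulated, band-limited Gaussian noise;
  the simulator band-limits white noise to 20–300 Hz and multiplies it by a
  trapezoidal envelope per trial (200 ms rise and fall, 2 s hold), with a
  resting baseline at 5% of the contraction amplitude. A reaction latency
  of 150 ± 50 ms (truncated at 0) separates each trigger from the envelope
  onset, emulating the delay with which participants start moving.
* **Reference device.** The source plus additive Gaussian noise
  (sd 0.02 in normalized source units).
* **Prototype device.** The source passed through a causal digital model
  of the prototype's analog chain — first-order high-pass at 20.7 Hz,
  first-order low-pass at 330 Hz, fourth-order 60 Hz notch, and a gain —
  plus stronger additive noise (sd 0.08; the prototype is by assumption
  the noisier instrument). The chain is applied single-pass, not
  forward–backward, because a physical analog front end is causal;
  zero-phase application would square the corner responses and misstate
  the passband gain.
* **Trigger channel.** Ideal rectangular pulses as described above.

All randomness flows from a single seeded generator recorded in the
session metadata; identical configurations are bit-reproducible.

What the simulator deliberately does *not* model: motor-unit physiology,
electrode–skin impedance, movement-specific spatial patterns (movement id
affects only the trigger label), ADC quantization, or baseline drift.
Passing tests on simulated sessions therefore demonstrate that the
*pipeline* is correct and sensitive to device noise — not that any
particular hardware meets a concordance threshold on real muscle.

## Pipeline stages and their parameters

1. **Preprocessing** (`preprocess_recording`): decimation from 2 kHz to
   500 Hz (zero-phase 64-tap FIR anti-alias filter cut at 0.8 of the
   target Nyquist, then every 4th sample), a fourth-order Butterworth
   band-pass 20–200 Hz applied forward–backward so event-relative timing
   is preserved, and peak normalization $y = x/\max|x|$ per full recording
   and channel (per-window normalization is available as an option). The
   trigger channel is never filtered or normalized. The stage order —
   decimate, filter, normalize — is fixed.
2. **Epoching** (`detect_triggers`, `extract_windows`): pulse detection
   runs on the *native* 2 kHz trigger channel, where a 5 ms pulse spans
   ~10 samples (after decimation it would span only 2–3). The onset
   threshold is half the smallest configured level; the pulse amplitude is
   the within-pulse median (robust to single corrupt samples); a 1 s
   refractory period suppresses duplicates. Amplitudes decode to movement
   ids by nearest level within a *closed* ±2 mV tolerance — half the 5 mV
   spacing minus a margin, which makes ties impossible; anything farther
   is reported as an unknown-level event and excluded, never defaulted.
   Onsets are mapped to the 500 Hz grid by integer division. Windows are
   3 s from the trigger onset: the instruction moment, the 2 s contraction
   with its reaction latency, and one further second.
3. **Features** (`feature_vector`): the 22 indices, in the fixed canonical
   order `FZC, EWL, EMAV, ASM, ASS, CARD, LDASDV, LDAMV, MYOP, VO, MMAV,
   MMAV2, IEMG, RMS, WA, LD, MAV, MAD, IQR, KURT, COV, SD`. The formulas
   follow the published EMG feature-extraction toolbox definitions this
   battery comes from, fixed in one file so any discrepancy can be patched
   in one place. Notable conventions, all unit-tested against an
   independent loop-based oracle:
   * thresholds (FZC, WA, CARD 0.01; MYOP 0.016) are in normalized
     (−1…1) units and configurable;
   * windows are 1-based in all weight boundaries (e.g. MMAV's central
     region is $0.25N \le i \le 0.75N$);
   * ASM/ASS take fractional powers of negative samples as principal
     complex roots and return the modulus of the complex sum, mirroring
     the naive numeric behaviour the toolbox relies on;
   * logarithms are guarded with $\varepsilon = 10^{-10}$;
   * KURT is the non-excess kurtosis (Gaussian ≈ 3) and is `NaN` with a
     warning on zero-variance windows; IQR uses linear-interpolation
     quantiles; SD uses the $N-1$ denominator; MAD is the mean absolute
     deviation about the mean.
4. **Concordance** (`concordance_matrix`): one $1-\mathrm{MAPE}$ cell per
   (feature, subject), pairing windows by trial index, reference as
   actual. Cells below 0 are kept (with a warning) unless `clip = TRUE`;
   marginal and overall means are taken over non-missing cells, and both
   marginal paths agree with the raw-cell mean to $10^{-12}$.
5. **Spectral diagnostics** (`compare_devices_spectral`): on a 6 s segment
   around a contraction (2 s before the onset to 2 s after the
   contraction), the zero-lag temporal correlation (equal, by
   construction, to the Pearson coefficient), the lag of the
   cross-correlation peak, and the peak of the normalized 2-D
   cross-correlation between Hann-tapered spectrograms (256-sample
   windows, 50% overlap at 500 Hz — about 2 Hz resolution), whose square
   is reported as explained variance. Spectrogram STFT parameters are
   configurable; the defaults are ordinary EMG practice.

## The COV caveat

The coefficient of variation divides by the window mean, and a band-passed
EMG window has essentially no DC component: its mean is a small random
number. COV is therefore a ratio of noise, and its MAPE across devices can
be arbitrarily large in either direction regardless of how well the
devices agree. The package computes COV exactly as defined, flags windows
with $|\bar x| < \sqrt\varepsilon$, and `concordance_matrix()` accepts
`exclude_features = "COV"` for aggregates. In the package's own
noise-sensitivity checks the monotonic degradation of concordance with
prototype noise is assessed with COV excluded, because with it included
the aggregate is dominated by this instability (observed per-feature means
≈ 0.95 for all indices except COV, which is large and negative); the
perfect-agreement limit is checked with all 22 features.

## What the checks compute

The test suite verifies, among other properties: 60 decoded trials and 60
windows per device on a default simulated session; exact label round-trip
from simulator schedule to decoded windows; the 22-feature vector against
an independently coded brute-force oracle at $10^{-9}$ relative tolerance;
hand-computed MAPE examples and the aggregation identities; filter
passband/stopband gains by sine fitting; Parseval's identity; and the
cross-correlation/Pearson equivalence at zero lag. Noise-sensitivity runs
simulate the full 60-trial protocol for 10 seeds at each prototype noise
level in $\{0, 0.05, 0.1, 0.2\}$ and require the seed-averaged overall
concordance to decrease strictly; the noiseless identity-channel
configuration (chain bypassed, unit gain, no noise on either channel) must
reach concordance 1 to within $10^{-3}$. These problem sizes — one
session per (seed, level), 18 subjects only in the worked pipeline example
— keep the checks quick while exercising the full protocol geometry.

## Known limitations

* MAPE-based concordance is scale-invariant under *joint* scaling but not
  robust to features crossing zero; the exclusion rule handles exact
  zeros, while near-zero actual values still inflate individual cells
  (COV being the extreme case).
* The simulator's movement types are statistically identical; it cannot
  exercise movement-specific spectral differences between devices.
* Trigger decoding assumes the configured level grid; drifting DAC
  amplitudes beyond ±2 mV are excluded rather than re-estimated.
* The analog-chain model captures spectral shaping only (bilinear-design
  IIR stand-ins at the measured corners), not saturation or slew effects.
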