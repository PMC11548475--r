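# emgconcord

Statistical validation of a prototype surface-EMG acquisition device
against a commercial reference system, from synchronized dual-device
recordings.

Research groups frequently build their own EMG conditioning circuits, but
rarely validate them rigorously against approved commercial equipment.
`emgconcord` implements a validation pipeline for the standard paired
design: both devices record the same muscle site simultaneously while the
participant performs a cued protocol (6 movement types × 10 repetitions,
2 s contraction / 5 s rest, acquired at 2 kHz), and trial identity is
encoded on an analog trigger channel as 5 ms pulses stepping from 15 mV to
40 mV in 5 mV increments.

The pipeline:

1. **Simulate or ingest** a synchronized session (`generate_session`,
   `read_recording`). The seeded simulator emulates the shared
   band-limited muscle source, the prototype's analog front end
   (high-pass 20.7 Hz, low-pass 330 Hz, fourth-order 60 Hz notch), its
   higher noise floor, and the amplitude-coded trigger channel.
2. **Preprocess** (`preprocess_recording`): decimate 2 kHz → 500 Hz,
   fourth-order Butterworth band-pass 20–200 Hz (zero-phase), normalize
   each channel to `y = x / max|x|`.
3. **Epoch** (`detect_triggers`, `extract_windows`): decode pulse
   amplitudes to movement ids (nearest level, closed ±2 mV tolerance) and
   cut one 3 s window per trial and device.
4. **Featurize** (`feature_vector`, `featurize_windows`): 22 canonical
   time-domain indices per window (FZC, EWL, EMAV, ASM, ASS, CARD,
   LDASDV, LDAMV, MYOP, VO, MMAV, MMAV2, IEMG, RMS, WA, LD, MAV, MAD,
   IQR, KURT, COV, SD).
5. **Quantify agreement** (`concordance_matrix`): for each feature *f*
   and subject *s*, with reference values *y* and prototype values *ŷ*
   paired by trial,

   ```
   MAPE = (1/n) Σ |y_i − ŷ_i| / |y_i|        concordance = 1 − MAPE
   ```

   giving a feature × subject concordance matrix (1 = identical devices),
   with per-feature, per-subject and overall means.
6. **Spectral diagnostics** (`compare_devices_spectral`): zero-lag
   temporal correlation and normalized 2-D spectrogram cross-correlation
   around a contraction, with explained variance r².

## Worked example

```r
library(emgconcord)
res <- run_pipeline(n_subjects = 3, seed = 1)   # simulated subjects
print(res$concordance)
#> concordance_matrix: 22 features x 3 subjects
#> overall mean (1 - MAPE): 0.8312 (83.1%)

round(res$concordance$per_feature_mean, 3)
#>    FZC    EWL   EMAV    ASM    ASS   CARD LDASDV  LDAMV   MYOP     VO   MMAV
#>  0.940  0.960  0.969  0.967  0.976  0.822  0.967  0.973  0.949  0.960  0.959
#>  MMAV2   IEMG    RMS     WA     LD    MAV    MAD    IQR   KURT    COV     SD
#>  0.960  0.959  0.960  0.960  0.909  0.959  0.959  0.944  0.967 -1.693  0.960

str(res$spectral)
#> $ temporal_r0        : num 0.881
#> $ temporal_peak_lag  : int 0
#> $ spectrogram_peak   : num 0.968
#> $ spectrogram_shift  : int [1:2] 0 0
#> $ explained_variance : num 0.937
```

Reading the output: most feature indices agree between the simulated
devices at concordance ≈ 0.95 under the default prototype noise; COV is
strongly negative because it divides by the near-zero mean of a
band-passed window and is documented as unstable (exclude it from
aggregates with `concordance_matrix(ft, exclude_features = "COV")`). The
devices correlate most at zero lag, and the spectrogram-domain correlation
exceeds the temporal one — the expected signature of two devices seeing
the same source through different noise and filtering.

A thin command-line wrapper lives in `inst/scripts/emg-pipeline.R`:

```sh
Rscript inst/scripts/emg-pipeline.R simulate --seed 1 --out session.csv
Rscript inst/scripts/emg-pipeline.R all --subjects 18 --seed 1 --out results/
```

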