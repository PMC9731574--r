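# spikefield

Analysis of simultaneously recorded spike trains and local field
potentials (LFP) from microwire bundle electrodes, built around the
question of how oscillations structure neural firing during memory
encoding: does spike timing lock to theta and gamma phase, at which
frequency, how do theta phase and gamma amplitude couple, and at what
latency do putative upstream and downstream units co-fire — each
contrasted between later-remembered ("hit") and later-forgotten ("miss")
trials.

The package implements the full pipeline:

* **Preprocessing** — zero-phase Butterworth low-pass (order 2, 300 Hz),
  spike interpolation (−2..+6 ms), line-noise template subtraction
  (least-squares sinusoid fit per epoch), anti-aliased epoching to
  −7..+7 s at 1 kHz, amplitude-based artifact rejection (z > 3 channels,
  z > 4 trials, 25-trial floor) and Gram–Schmidt local re-referencing
  against same-bundle neighbours.
* **Unit classification** — single vs multi units from ISI violations
  (> 1% below 3 ms) and the waveform-variability criterion
  c₂ = Σ s(t) / (m(t_j) − m(t_i)) over the rise window (MU if c₂ ≥ 3),
  plus normalized spike-density series
  z(t) = (sd(t) − μ_bl)/(σ_bl + 0.1).
* **Spike-field coupling** — Morlet phases (6 cycles, 2–40 Hz; 12 cycles,
  40–80 Hz on the differentiated LFP), Rayleigh + FDR screening (≥ 30
  spikes), pairwise phase consistency
  PPC = 2/(n(n−1)) Σ_{j<k} cos(θ_j − θ_k), a 10,000-draw trial-shuffle
  null for significant-pair counts, per-pair peak-frequency contrasts
  (threshold 0.005) and a selection-bias control (5000 screened shuffles).
* **Directionality** — phase slope index between spike density and distal
  LFP (5 Hz slope window, Welch cross-spectra, 100-shuffle z).
* **Theta-gamma coupling** — 18-bin modulation index
  MI = (log 18 − H)/log 18 at condition-matched PPC peak frequencies,
  200-shuffle z, eighth-harmonic and waveshape-asymmetry
  (AI = (T_asc − T_desc)/ω) controls.
* **Co-firing** — shuffle-normalized cross-correlograms of sender/receiver
  spike densities (25 ms kernel, 2000 trial shuffles), coincidence filter
  (mean z > 1 at any lag) and peak-lag condition contrast.
* **Synthetic sessions** — `session_design()` / `gen_session()` generate
  full sessions with non-stationary theta (3.5–9 Hz walks), theta-locked
  gamma bursts, von-Mises phase-locked spiking (hits 8 Hz theta / 70 Hz
  gamma; misses 5 Hz / 62 Hz) and lagged co-firing pairs (20 vs 60 ms),
  with the ground truth attached for recovery tests.

## Worked example

```r
library(spikefield)

ses <- gen_session(session_design(n_hits = 26, n_misses = 26, seed = 7))
cfg <- sfc_config(n_shuffles_pair_null = 20, n_draws_pair_null = 2000,
                  n_shuffles_psi = 40, n_shuffles_mi = 60,
                  n_shuffles_cofire = 200, seed = 3)
rep <- run_pipeline(ses, cfg, out_dir = "run1")

rep$sfc_contrast$low$peaks$mean_shift   # 2.6   (planted theta shift 8 - 5 = 3 Hz)
rep$sfc_contrast$high$peaks$mean_shift  # 6.33  (planted gamma shift 70 - 62 = 8 Hz)
mean(sapply(rep$psi, function(p) mean(p$hit$z[p$hit$freq %in% 7:9])))
                                        # 3.66  (hits: spikes lead the distal LFP)
mean(sapply(rep$cfc, function(r) r$dz)) # 54.6  (theta-gamma MI z, hit - miss)
rep$cofire$contrast$mean_diff           # -41.2 (hit co-firing ~40 ms earlier)
```

The recovered numbers match the planted ground truth: hits lock at faster
theta and gamma frequencies, the spike-providing unit leads the distal
LFP, theta-gamma coupling is hit-specific, and hit co-firing peaks ~40 ms
earlier (20 vs 60 ms).

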