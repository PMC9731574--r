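---
title: "Spike-field coupling, theta-gamma coupling and co-firing latency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-field coupling, theta-gamma coupling and co-firing latency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spikefield` analyses simultaneously recorded spike trains and local field
potentials (LFP) from microwire bundle electrodes, of the kind used in human
intracranial recordings during memory tasks. The pipeline asks three
questions about an encoding window (by default 2--3 s after cue onset):

1. **Spike-field coupling (SFC).** Are a unit's spikes phase-locked to the
   LFP, locally (same bundle) or distally (another bundle/region), and does
   the *frequency* of locking differ between later-remembered ("hit") and
   later-forgotten ("miss") trials?
2. **Cross-frequency coupling (CFC).** Is gamma amplitude locked to theta
   phase, and more so for hits?
3. **Co-firing latency.** Do putative upstream (distally theta-coupled) and
   downstream (locally gamma-coupled) units co-fire at shorter lags during
   hits?

A synthetic-session generator with exposed ground truth makes every stage
testable by parameter recovery; no patient data are required or included.

# The estimators

## Pairwise phase consistency

Spike-field coupling is quantified by the pairwise phase consistency

$$\mathrm{PPC} = \frac{2}{n(n-1)} \sum_{j<k} \cos(\theta_j - \theta_k),$$

the mean cosine of all pairwise differences of the LFP phases
$\theta_1,\dots,\theta_n$ at spike times. Unlike the mean resultant length,
its expectation does not depend on $n$, so hit/miss comparisons are not
biased by spike-count differences. It is computed through the exact
identity $\mathrm{PPC} = (|\sum_j e^{i\theta_j}|^2 - n)/(n(n-1))$, which the
test suite verifies against the $O(n^2)$ double loop to $10^{-12}$.

Phases come from Morlet wavelets: 6 cycles on a 2--40 Hz grid (1 Hz steps)
and 12 cycles on a 40--80 Hz grid (2 Hz steps). For the high band the first
temporal difference of the LFP (scaled by the sampling rate) is transformed
instead of the raw trace; this whitening counteracts the 1/f power
drop-off so gamma-band phase is not dominated by low-frequency leakage. The
wavelets are implemented as analytic Gaussian filters in the frequency
domain with $\sigma_f = f/n_{\mathrm{cycles}}$ and a gain of 1 at the
centre frequency (so a unit-amplitude sinusoid has envelope 1); the exact
amplitude normalization affects power scale only, never phase. Samples
within $3\sigma_t$ of an epoch edge are excluded by construction because
the analysis window sits far inside the 14 s epochs. A band-pass +
analytic-signal (Hilbert) variant with 4 Hz (low) / 8 Hz (high) pass-bands
provides a cross-method check; the two agree to ~0.1 rad on band-limited
signals.

## Screening and the pair-count null

Each unit x channel pair is screened with a Rayleigh test per frequency
(the Zar small-sample series for the p-value), Benjamini--Hochberg
corrected across the frequencies of the band; a pair with fewer than 30
spikes in the window is excluded. Whether the *number* of significant
pairs exceeds chance is assessed by re-running the identical screening on
shuffled spike/LFP trial pairings (100 per pair) and drawing 10,000
session-level samples of the significant-pair count, separately for local
and distal pairs.

## Peak frequencies and the selection-bias control

Condition PPC spectra are compared two ways: per-frequency paired t-tests
across pairs (FDR-corrected) and a per-pair peak-detection analysis (local
maxima above PPC 0.005 in *both* conditions; theta peaks searched in
3--13 Hz, gamma in 45--75 Hz; ties broken toward the lower frequency).
Because pairs are pre-selected by an all-trials screening, a control
re-computes pseudo-hit/pseudo-miss PPC on shuffled trial pairings that
survive the same screening, and z-transforms the real condition PPC
against that baseline. Two properties of this control are worth knowing,
both established by simulation in the test suite: (i) the corrected
spectra carry no spurious condition shift in *peak location* under trial
imbalance, which is what the peak analysis consumes; (ii) the corrected z
*magnitudes* still scale with each condition's spike count (the baseline's
SD shrinks with $n$), so raw z differences between conditions are not
themselves bias-free under imbalance.

## Phase slope index

Directionality between a spike-density signal (spikes convolved with a
25 ms Gaussian, 10 ms FWHM) and a distally coupled LFP uses the phase
slope index over a 5 Hz slope window,

$$\Psi(f) = \mathrm{Im} \sum_{f' \in W(f)} C^*(f')\, C(f' + \delta f),$$

with complex coherency $C$ estimated by Welch segmentation (500 ms
segments, 50% overlap, Hann taper) across trials in the window. The
cross-spectrum convention makes $\Psi > 0$ mean "spikes lead". Raw
$\Psi$ is z-normalized against 100 shuffles of the spike-trial assignment
per condition, preserving spike counts. A 60-spike floor applies (a
30-spike relaxed mode is available).

Two caveats are documented deliberately. First, narrow-band rhythms carry
little genuine phase-slope information (few independent cross-spectral
bins), so single-pair z values are noisy even when a true delay exists;
inference should pool pairs, as the condition-contrast function does.
Second, when the two signals are coherent at *zero* delay with
trial-unique phases, trial shuffling destroys all coherence and therefore
underestimates the variance of the paired estimate: z is overdispersed
(roughly 40% of |z| > 2 in simulations). With a common source shared
across trials the null is calibrated. Both behaviours are exercised in the
test suite.

## Modulation index and its controls

Theta-phase to gamma-amplitude coupling uses the 18-bin modulation index:
amplitudes are averaged in 18 uniform phase bins on $[-\pi,\pi)$
(left-closed bins), normalized to a distribution $P_j$, and
$\mathrm{MI} = (\log 18 - H)/\log 18$ with entropy $H$; empty bins
contribute $0\log 0 = 0$. Phase and amplitude series are concatenated
across a condition's trials (the alternative, averaging per-trial MI, needs
more data per trial than a 1 s window provides). The MI is z-normalized by
200 shuffles of the phase-trial assignment within condition, which removes
the trial-count bias of the raw MI; the shuffle-z is mean-zero under the
null even at 80/20 trial imbalance.

Channels enter the CFC analysis when their bundle is both locally
gamma-coupled and distally theta-coupled, and the MI is evaluated at each
condition's *own* PPC peak frequencies (theta restricted to 5--11 Hz,
gamma to 50--80 Hz) so the hit/miss frequency shift cannot masquerade as a
coupling difference.

Non-sinusoidal theta creates coupling to its own harmonics. Two controls
address this: the MI contrast repeated with gamma forced to the 8th theta
harmonic (9 Hz theta -> 72 Hz), and the waveshape asymmetry index
$AI = (T_{asc} - T_{desc})/\omega$ from peak/trough time stamps (band-pass
filtered extrema, each adjusted to the nearest broadband extremum within a
quarter cycle). One nuance discovered in testing: with 12-cycle wavelet
amplitudes ($\sigma_f \approx 5$--6 Hz at 64--70 Hz), a wavelet centred
*between* two theta harmonics captures both and can show a stronger
waveshape-born envelope beat than one centred exactly on the 8th harmonic,
so the harmonic control is interpreted through the *condition contrast*
(as in the group analysis), not through absolute MI magnitudes. The AI is
exact on clean waveforms (sinusoid 0, 75/25 ms sawtooth +0.5) but the
argmax-based extremum adjustment acquires a bias toward the shallower
flank as broadband noise grows (about -0.1 at 25% of signal amplitude);
recovery within +/-0.05 holds to roughly 10% noise.

## Co-firing cross-correlograms

Putative senders are units with significant distal low-frequency coupling
to a region; putative receivers are units locally gamma-coupled in that
same region. Spike trains are binned at 1 kHz in the window, convolved
with the 25 ms Gaussian kernel and cross-correlated per trial; the session
correlogram is the sum over trials, which equals the correlogram of the
concatenated trains minus negligible boundary terms. The null pairs sender
trial $i$ with receiver trial $\pi(i)$ for 2000 random permutations
(condition-wise, spike counts preserved); because the observed and
shuffled statistics are both sums over a precomputed trial x trial
cross-correlation tensor, the full shuffle distribution is exact and
cheap. Peak lags are the global z maximum in 0..+100 ms (ties toward 0);
the reverse-direction control searches -100..0 ms. Pairs are retained when
the condition-mean z exceeds 1 at any lag -- a deliberately permissive
rule (about half of fully independent pairs pass it); the latency
*contrast* across retained pairs carries the inference. Kernel widths of
15/25/35/45 ms leave the recovered lag difference stable within a few ms.

# The synthetic-session generator

`session_design()` fixes the ground truth; `gen_session()` realizes it
bit-identically from `(design, seed)`. The defaults encode the headline
study conditions:

* theta locking at **8 Hz (hits) vs 5 Hz (misses)**, gamma locking at
  **70 Hz (hits) vs 62 Hz (misses)**;
* theta-gamma coupling depth 0.6 for hits, 0 for misses (gamma envelope
  maximal at the theta trough);
* sender-to-receiver co-firing lags **20 ms (hits) vs 60 ms (misses)**,
  copy probability 0.35, 5 ms jitter;
* 30 hit and 20 miss trials per session, epochs -7..+7 s at 1 kHz, two
  4-wire bundles.

The oscillators are non-stationary: instantaneous frequency performs a
reflected mean-reverting Gaussian walk (relaxation time 1 s, innovation SD
0.05 Hz per sample for the default 3.5--9 Hz theta; the mean-reversion is
what keeps the long-run mean at the nominal 6 Hz rather than the range
midpoint). Spikes are a thinned inhomogeneous Poisson process with a
von-Mises gain, $\lambda(t) \propto \exp\{\kappa\cos(\phi(t)-\mu)\}$,
normalized so the expected rate is $\kappa$-independent; single-unit-like
trains get a 3 ms refractory period. Waveforms are drawn around a common
template with unit-specific variability so the SU/MU classifier has real
work to do.

Three generator choices deserve explanation:

* **Wire-to-wire phase offsets.** Each wire sees its bundle's oscillations
  with a fixed phase offset (offsets spread symmetrically over ~0.9 pi).
  Perfectly in-phase bundle rhythms would be annihilated by Gram-Schmidt
  re-referencing; phase-shifted copies leave a phase-locked residual, as
  real microwires do. A separate bundle-shared broadband component plays
  the role of volume conduction and *is* removed by re-referencing.
* **Sender lead.** The sender unit locks to the distal theta phase shifted
  30 ms into the future for hits (0 ms for misses), making the spike
  signal the upstream sender for the PSI analysis. The lead size is a
  generator choice (the source material reports the direction, not a
  latency); 30 ms gives a slope the 5 Hz PSI window resolves.
* **Noise.** White plus 1/f noise per wire. In pair-level gamma
  simulations the broadband noise is set at 2.5x the oscillation: with
  weaker noise the locked line's phase leaks across the whole high band
  (wavelet bandwidth grows with frequency) and PPC spectra plateau
  instead of peaking -- unrealistic and hostile to peak detection.

What the generator does *not* emulate: biophysical neuron dynamics, spike
waveform drift, behaviour-locked evoked components, electrode artifacts
(TTL transients), or inter-patient variability. Passing recovery tests
therefore demonstrates estimator correctness under the assumed statistical
structure, not performance on raw clinical recordings.

# Preprocessing

The order is fixed: order-2 Butterworth low-pass at 300 Hz (zero-phase,
`filtfilt`, chosen so phase estimates stay unbiased), linear interpolation
of the LFP from 2 ms before to 6 ms after each spike (overlapping windows
merged), least-squares sine/cosine template subtraction at the line
frequency per epoch (the line is stationary within an epoch; brain signals
are not, so the template spares physiological power at 50 Hz),
anti-aliased epoching to 14 s at 1 kHz, artifact rejection, and
Gram-Schmidt re-referencing against the mean of surviving same-bundle
neighbours ($x' = x - \frac{\langle x,r\rangle}{\langle r,r\rangle} r$ per
trial).

Artifact rejection applies four mean/SD z-score rules (channel RMSA across
channels at z > 3; per-channel trial RMSA and trial maximum amplitude
across trials at z > 4; a 25-trial floor per channel). Note an intrinsic
property of plain z-scores: a single outlier among $n$ items can reach at
most $z = (n-1)/\sqrt{n}$, so the channel rule needs $n > 10$ channels to
be able to fire at z > 3.

# Unit classification

Units are included with >= 50 spikes in either condition, a mean spike
count > 2 and a mean rate > 1 Hz in the 0--4 s encoding window (strict
inequalities as stated). Classification is multi-unit if more than 1% of
ISIs fall below 3 ms or if the waveform-variability criterion
$c_2 = \sum_{t_i}^{t_j} s(t) / (m(t_j)-m(t_i)) \ge 3$, where the rise
window runs from the maximum pre-peak curvature (second derivative,
searched from waveform start to peak -- the search region is unspecified
in the source procedure and this is the widest defensible choice) to the
waveform peak. Spike density uses a 250 ms Gaussian kernel
($\sigma$ = length/6, placing >= 99.7% of mass inside the stated support)
and the regularized baseline z-score $z(t) = (sd(t)-\mu_{bl})/(\sigma_{bl}
+ 0.1)$ with baseline -1000..-125 ms.

# Numerical and tie-break conventions

* Phase bins and wavelet grids are left-closed; phases wrap to
  $[-\pi,\pi)$.
* PPC/Rayleigh statistics use the exact resultant identities; Rayleigh
  p-values use the Zar series, floored at the smallest double.
* Peak detection breaks exact ties toward the lower frequency (PPC) or
  toward zero lag (co-firing).
* Zero-variance guards: normalization steps return 0 (with a warning)
  rather than NaN; shuffle z is NA where the shuffle SD is 0.
* All randomness flows through explicit seeds; per-stage child seeds are
  derived deterministically, and `gen_session()`/`run_pipeline()` reruns
  are bit-identical.

# Problem sizes used in tests and the acceptance script

Simulated problem sizes are chosen as the smallest that make each
recovery statistically decisive: 40 pairs for the frequency-shift
analyses (25 hit / 20 miss trials each), 24 pairs for the co-firing lag
contrast, 1000 simulations for screening type-I error, 60 s records for
PAC depth monotonicity, and one 52-trial session for the end-to-end
determinism check. Shuffle counts in illustrative runs are reduced from
the pinned defaults (which remain 100/200/2000/5000/10000 in
`sfc_config()`) where only a mean/SD of the null is needed; the defaults
themselves are never changed.

# Known limitations

* Statistical, not biophysical, synthesis (see above).
* Shuffle-z PSI is overdispersed for zero-delay coherent pairs with
  trial-unique phases; pool pairs before interpreting.
* The coincidence filter is permissive by design; it gates, but does not
  establish, co-firing.
* The AI extremum adjustment is noise-biased toward the shallower flank
  beyond ~10% broadband noise.
* TTL-artifact regression and spike clustering are out of scope; sessions
  are expected to arrive spike-sorted.
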