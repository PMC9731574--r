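# Synthetic-data generators. These emulate the statistical structure the
# analysis assumes -- non-stationary theta, theta-locked gamma bursts,
# von-Mises phase-locked spiking, lagged co-firing pairs -- with the hidden
# parameters exposed so every downstream estimator can be checked by
# parameter recovery.

#' Specification of a non-stationary oscillator
#'
#' Instantaneous frequency follows a reflected mean-reverting Gaussian walk
#' inside `freq_range`, so the oscillator drifts through the range while its
#' long-run mean stays at `mean_freq`.
#'
#' @param mean_freq mean instantaneous frequency (Hz).
#' @param freq_range length-2 numeric, lower/upper reflection bounds (Hz).
#' @param freq_walk_sd innovation SD of the frequency walk (Hz per sample).
#' @param amplitude oscillation amplitude (arbitrary units).
#' @param duration duration (s).
#' @param fs sampling rate (Hz); must exceed twice the upper frequency bound.
#' @return an `oscillator_spec` list.
#' @export
oscillator_spec <- function(mean_freq = 6, freq_range = c(3.5, 9),
                            freq_walk_sd = 0.05, amplitude = 1,
                            duration = 60, fs = 1000) {
  if (length(freq_range) != 2L || freq_range[1] >= freq_range[2]) {
    stopf("oscillator_spec: freq_range must be (lo, hi) with lo < hi")
  }
  if (mean_freq < freq_range[1] || mean_freq > freq_range[2]) {
    stopf("oscillator_spec: mean_freq must lie inside freq_range")
  }
  if (fs <= 2 * freq_range[2]) {
    stopf("oscillator_spec: fs = %g Hz too low; need fs > 2 x %g Hz",
          fs, freq_range[2])
  }
  if (freq_walk_sd < 0 || duration < 0) {
    stopf("oscillator_spec: freq_walk_sd and duration must be non-negative")
  }
  structure(list(mean_freq = mean_freq, freq_range = freq_range,
                 freq_walk_sd = freq_walk_sd, amplitude = amplitude,
                 duration = duration, fs = fs),
            class = "oscillator_spec")
}

#' Generate a non-stationary oscillation
#'
#' The instantaneous frequency performs a reflected mean-reverting random
#' walk (relaxation time 5 s) inside `spec$freq_range`; the signal is the
#' cosine of the integrated phase. With `freq_walk_sd = 0` the output is a
#' pure sinusoid at `mean_freq`.
#'
#' @param spec an [oscillator_spec()].
#' @param seed integer seed; the output is a deterministic function of
#'   `(spec, seed)`.
#' @return list with `samples`, wrapped `phase` (radians, trough at
#'   \eqn{\pm\pi}), instantaneous `freq` (Hz), time axis `t` and `fs`.
#' @export
gen_nonstationary_oscillator <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- round(spec$duration * spec$fs)
  if (n == 0L) {
    return(list(samples = numeric(0), phase = numeric(0), freq = numeric(0),
                t = numeric(0), fs = spec$fs, spec = spec))
  }
  with_seed(seed, {
    lo <- spec$freq_range[1]; hi <- spec$freq_range[2]
    alpha <- 1 / spec$fs  # mean reversion with ~1 s relaxation time
    eps <- stats::rnorm(n, 0, spec$freq_walk_sd)
    f <- numeric(n)
    cur <- spec$mean_freq
    for (i in seq_len(n)) {
      cur <- cur + alpha * (spec$mean_freq - cur) + eps[i]
      if (cur < lo) cur <- lo + (lo - cur)
      if (cur > hi) cur <- hi - (cur - hi)
      # a huge innovation could overshoot the reflected range; clamp
      if (cur < lo) cur <- lo else if (cur > hi) cur <- hi
      f[i] <- cur
    }
    phase0 <- stats::runif(1, -pi, pi)
    phase <- phase0 + cumsum(2 * pi * f / spec$fs)
    list(samples = spec$amplitude * cos(phase),
         phase = wrap_phase(phase),
         freq = f,
         t = (seq_len(n) - 1) / spec$fs,
         fs = spec$fs,
         spec = spec)
  })
}

#' Specification of von-Mises phase locking of a spike train
#'
#' @param target which oscillation the unit locks to (`"theta"` or
#'   `"gamma"`); informational, used by [gen_session()].
#' @param preferred_phase preferred firing phase (radians in \eqn{[-\pi,\pi)};
#'   \eqn{-\pi} is the trough of a cosine oscillator).
#' @param kappa von-Mises concentration (>= 0); 0 gives phase-independent
#'   Poisson firing.
#' @param base_rate mean firing rate (Hz).
#' @param refractory absolute refractory period (s); spikes closer than this
#'   are pruned. Set 0 to disable (used for multi-unit-like trains).
#' @return a `locking_spec` list.
#' @export
locking_spec <- function(target = c("theta", "gamma"), preferred_phase = -pi,
                         kappa = 2, base_rate = 10, refractory = 0.003) {
  target <- match.arg(target)
  if (kappa < 0) stopf("locking_spec: kappa must be >= 0")
  if (base_rate < 0) stopf("locking_spec: base_rate must be >= 0")
  structure(list(target = target,
                 preferred_phase = wrap_phase(preferred_phase),
                 kappa = kappa, base_rate = base_rate,
                 refractory = refractory),
            class = "locking_spec")
}

#' Generate spikes phase-locked to an oscillation
#'
#' Thinned inhomogeneous Poisson process whose rate is modulated by a
#' von-Mises gain on the supplied phase series,
#' \eqn{\lambda(t) = r_0 \exp\{\kappa \cos(\phi(t) - \mu)\} / I_0(\kappa)},
#' so the expected spike count is `base_rate * duration` for any
#' `kappa` (the gain has unit mean over a uniform phase).
#'
#' @param phase numeric vector of instantaneous phase (radians) sampled at
#'   `fs`; typically the `phase` element of
#'   [gen_nonstationary_oscillator()].
#' @param spec a [locking_spec()].
#' @param fs sampling rate of `phase` (Hz).
#' @param seed integer seed.
#' @return sorted numeric vector of spike times (s) in `[0, duration)`.
#' @export
gen_locked_spikes <- function(phase, spec, fs, seed = NULL) {
  stopifnot(inherits(spec, "locking_spec"))
  n <- length(phase)
  if (n == 0L) {
    # zero-duration input: an empty train, not an error, when explicitly
    # asked for 0 samples would be ambiguous -- require explicit phase
    stopf("gen_locked_spikes: empty phase series")
  }
  duration <- n / fs
  with_seed(seed, {
    # exp(kappa)/I0(kappa) computed with the scaled Bessel to avoid overflow
    i0s <- besselI(spec$kappa, 0, expon.scaled = TRUE)  # I0(k) * exp(-k)
    lambda_max <- spec$base_rate / i0s
    n_cand <- stats::rpois(1, lambda_max * duration)
    if (n_cand == 0L) return(numeric(0))
    tt <- sort(stats::runif(n_cand, 0, duration))
    idx <- pmin(pmax(round(tt * fs) + 1, 1), n)  # nearest sample: no half-sample lag bias
    accept_p <- exp(spec$kappa * (cos(phase[idx] - spec$preferred_phase) - 1))
    keep <- stats::runif(n_cand) < accept_p
    out <- tt[keep]
    if (spec$refractory > 0 && length(out) > 1L) {
      keep2 <- c(TRUE, diff(out) >= spec$refractory)
      # iterative pruning so surviving ISIs all respect the refractory period
      while (any(!keep2)) {
        out <- out[keep2]
        if (length(out) < 2L) break
        keep2 <- c(TRUE, diff(out) >= spec$refractory)
      }
    }
    out
  })
}

#' Specification of theta-gamma phase-amplitude coupling
#'
#' @param theta_freq theta frequency (Hz).
#' @param gamma_freq gamma frequency (Hz); must exceed `theta_freq`.
#' @param coupling_depth modulation depth in `[0, 1]`; 0 gives a constant
#'   gamma envelope.
#' @param gamma_phase_of_max theta phase (radians) at which the gamma
#'   envelope is maximal.
#' @return a `pac_spec` list.
#' @export
pac_spec <- function(theta_freq = 8, gamma_freq = 70, coupling_depth = 0.5,
                     gamma_phase_of_max = -pi) {
  if (gamma_freq <= theta_freq) {
    stopf("pac_spec: gamma_freq must exceed theta_freq")
  }
  if (coupling_depth < 0 || coupling_depth > 1) {
    stopf("pac_spec: coupling_depth must be in [0, 1]")
  }
  structure(list(theta_freq = theta_freq, gamma_freq = gamma_freq,
                 coupling_depth = coupling_depth,
                 gamma_phase_of_max = wrap_phase(gamma_phase_of_max)),
            class = "pac_spec")
}

#' Generate an LFP with theta-phase-modulated gamma amplitude
#'
#' The signal is
#' \eqn{a_\theta \cos\phi_\theta + a_\gamma [1 + d \cos(\phi_\theta -
#' \phi_{max})] \cos\phi_\gamma + \epsilon}, i.e. a theta oscillation plus a
#' gamma oscillation whose envelope is a cosine function of theta phase with
#' depth `d`, plus white noise.
#'
#' @param spec a [pac_spec()].
#' @param duration duration (s).
#' @param fs sampling rate (Hz).
#' @param noise_sd white-noise SD.
#' @param theta_amp,gamma_amp component amplitudes.
#' @param theta_phase0,gamma_phase0 initial phases (radians); randomize
#'   across trials to make trial-shuffle nulls meaningful.
#' @param seed integer seed.
#' @return list with `lfp`, `theta_phase`, `gamma_phase`, ground-truth
#'   `gamma_env`, `t` and `fs`.
#' @export
gen_pac_lfp <- function(spec, duration, fs, noise_sd = 0, theta_amp = 1,
                        gamma_amp = 0.5, theta_phase0 = 0, gamma_phase0 = 0,
                        seed = NULL) {
  stopifnot(inherits(spec, "pac_spec"))
  if (fs <= 2 * spec$gamma_freq) {
    stopf("gen_pac_lfp: fs = %g too low for gamma at %g Hz",
          fs, spec$gamma_freq)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  th_ph <- theta_phase0 + 2 * pi * spec$theta_freq * t
  ga_ph <- gamma_phase0 + 2 * pi * spec$gamma_freq * t
  env <- 1 + spec$coupling_depth * cos(th_ph - spec$gamma_phase_of_max)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else numeric(n)
  list(lfp = theta_amp * cos(th_ph) + gamma_amp * env * cos(ga_ph) + noise,
       theta_phase = wrap_phase(th_ph), gamma_phase = wrap_phase(ga_ph),
       gamma_env = env, t = t, fs = fs, spec = spec)
}

#' Specification of a lagged co-firing relationship
#'
#' @param lag latency from a sender spike to its induced receiver spike (ms);
#'   may be negative for the reverse-direction control.
#' @param jitter_sd Gaussian jitter of the induced spike (ms).
#' @param copy_prob probability that a sender spike induces a receiver spike.
#' @return a `cofire_spec` list.
#' @export
cofire_spec <- function(lag = 20, jitter_sd = 2, copy_prob = 0.5) {
  if (copy_prob < 0 || copy_prob > 1) {
    stopf("cofire_spec: copy_prob must be in [0, 1]")
  }
  if (jitter_sd < 0) stopf("cofire_spec: jitter_sd must be >= 0")
  structure(list(lag = lag, jitter_sd = jitter_sd, copy_prob = copy_prob),
            class = "cofire_spec")
}

#' Generate a receiver spike train co-firing with a sender
#'
#' Each sender spike is copied with probability `copy_prob`, shifted by
#' `lag` ms plus Gaussian jitter; independent background spikes at
#' `background_rate` are superimposed.
#'
#' @param sender numeric vector of sender spike times (s); must be non-empty.
#' @param spec a [cofire_spec()].
#' @param duration duration of the record (s); induced spikes outside
#'   `[0, duration)` are dropped.
#' @param background_rate rate of the independent background Poisson
#'   component (Hz).
#' @param seed integer seed.
#' @return sorted numeric vector of receiver spike times (s).
#' @export
gen_cofiring_pair <- function(sender, spec, duration,
                              background_rate = 2, seed = NULL) {
  stopifnot(inherits(spec, "cofire_spec"))
  if (length(sender) == 0L) stopf("gen_cofiring_pair: empty sender train")
  with_seed(seed, {
    copied <- sender[stats::runif(length(sender)) < spec$copy_prob]
    induced <- copied + spec$lag / 1000 +
      stats::rnorm(length(copied), 0, spec$jitter_sd / 1000)
    n_bg <- stats::rpois(1, background_rate * duration)
    bg <- stats::runif(n_bg, 0, duration)
    out <- sort(c(induced, bg))
    out[out >= 0 & out < duration]
  })
}
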