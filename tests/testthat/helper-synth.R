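# Shared fixtures, generated in code. Sessions and pair-level simulations
# are cached per test run because several test files reuse them.

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = the_cache)) {
    assign(key, force(expr), envir = the_cache)
  }
  get(key, envir = the_cache)
}

# Small default synthetic session (the headline hit/miss scenario).
small_session <- function() {
  cached("small_session", gen_session(
    session_design(n_hits = 26, n_misses = 26, seed = 7)))
}

# Phases of a spike train locked to an oscillation, looked up on the grid.
phases_at <- function(osc, spikes, fs = 1000) {
  idx <- pmin(pmax(round(spikes * fs) + 1, 1), length(osc$phase))
  osc$phase[idx]
}

# Circular distance.
circ_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# Simulate one spike-LFP pair with condition-dependent locking frequency.
# Short 3 s trials with the analysis window in the middle second, so the
# wavelet padding fits. Returns spikes, lfp matrix, time axis and labels.
sim_locked_pair <- function(freq_hit, freq_miss, n_hit = 25, n_miss = 20,
                            kappa = 1.5, rate = 25, band_halfwidth = 1.5,
                            noise_sd = 0.5, seed = 1, fs = 1000,
                            duration = 3) {
  labels <- factor(rep(c("hit", "miss"), c(n_hit, n_miss)),
                   levels = c("hit", "miss"))
  set.seed(seed * 31 + 5)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  lfp <- matrix(0, length(labels), length(t))
  spikes <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    f0 <- if (labels[i] == "hit") freq_hit else freq_miss
    o <- gen_nonstationary_oscillator(oscillator_spec(
      mean_freq = f0, freq_range = c(f0 - band_halfwidth, f0 + band_halfwidth),
      freq_walk_sd = 0.02, duration = duration, fs = fs),
      seed = seed * 10000 + i)
    lfp[i, ] <- o$samples + noise_sd * stats::rnorm(length(t))
    spikes[[i]] <- gen_locked_spikes(o$phase,
      locking_spec(kappa = kappa, base_rate = rate, refractory = 0),
      fs, seed = seed * 20011 + i)
  }
  list(spikes = spikes, lfp = lfp, t = t, labels = labels, fs = fs)
}

# Sawtooth wave with given rise fraction (period `T` seconds).
sawtooth <- function(t, rise = 0.075, T = 0.1) {
  ph <- t %% T
  ifelse(ph < rise, -1 + 2 * ph / rise, 1 - 2 * (ph - rise) / (T - rise))
}
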