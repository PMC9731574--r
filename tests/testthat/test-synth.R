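# Synthetic-data generators: determinism, ground-truth properties and the
# degenerate cases.

test_that("oscillator keeps frequency in range with mean near target", {
  spec <- oscillator_spec(mean_freq = 6, freq_range = c(3.5, 9),
                          duration = 60, fs = 1000)
  o <- gen_nonstationary_oscillator(spec, seed = 3)
  expect_true(all(o$freq >= 3.5 & o$freq <= 9))
  expect_lt(abs(mean(o$freq) - 6), 0.3)
  # instantaneous frequency from the analytic phase agrees with the
  # generator's own frequency series
  a <- Arg(spikefield:::analytic_signal(o$samples))
  instf <- spikefield:::wrap_phase(diff(a)) * 1000 / (2 * pi)
  expect_lt(abs(mean(instf) - mean(o$freq)), 0.1)
})

test_that("zero walk SD gives a pure sinusoid at the mean frequency", {
  o <- gen_nonstationary_oscillator(
    oscillator_spec(freq_walk_sd = 0, duration = 10), seed = 2)
  P <- Mod(stats::fft(o$samples))^2
  peak_hz <- (which.max(P[1:5000]) - 1) / 10
  expect_equal(peak_hz, 6)
  expect_equal(diff(range(o$freq)), 0)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- oscillator_spec(duration = 5)
  expect_identical(gen_nonstationary_oscillator(spec, seed = 11),
                   gen_nonstationary_oscillator(spec, seed = 11))
  o <- gen_nonstationary_oscillator(spec, seed = 11)
  ls <- locking_spec(kappa = 3, base_rate = 10)
  expect_identical(gen_locked_spikes(o$phase, ls, 1000, seed = 4),
                   gen_locked_spikes(o$phase, ls, 1000, seed = 4))
  cs <- cofire_spec(lag = 20)
  snd <- sort(runif(50, 0, 5))
  expect_identical(gen_cofiring_pair(snd, cs, 5, seed = 9),
                   gen_cofiring_pair(snd, cs, 5, seed = 9))
  d <- session_design(n_hits = 3, n_misses = 3, seed = 5)
  expect_identical(gen_session(d), gen_session(d))
})

test_that("oscillator rejects too-low sampling rates", {
  expect_error(oscillator_spec(fs = 15), "too low")
})

test_that("locked spikes concentrate at the preferred phase", {
  o <- gen_nonstationary_oscillator(oscillator_spec(duration = 100), seed = 8)
  sp <- gen_locked_spikes(o$phase,
    locking_spec(kappa = 5, preferred_phase = -pi, base_rate = 10,
                 refractory = 0), 1000, seed = 2)
  # expected count ~ base_rate x duration
  expect_lt(abs(length(sp) - 1000), 3 * sqrt(1000))
  ph <- phases_at(o, sp)
  expect_lt(circ_dist(circ_mean(ph), -pi), 0.15)
})

test_that("kappa = 0 reproduces phase-independent Poisson firing", {
  o <- gen_nonstationary_oscillator(oscillator_spec(duration = 60), seed = 1)
  # Rayleigh test should reject at ~alpha rate only; 300 replicates
  p <- vapply(1:300, function(s) {
    sp <- gen_locked_spikes(o$phase,
      locking_spec(kappa = 0, base_rate = 3, refractory = 0), 1000, seed = s)
    rayleigh_test(phases_at(o, sp))$p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.094)
})

test_that("deviation scale shrinks as 1/sqrt(kappa) toward the point limit", {
  o <- gen_nonstationary_oscillator(oscillator_spec(duration = 80), seed = 6)
  dev_sd <- vapply(c(50, 500), function(k) {
    sp <- gen_locked_spikes(o$phase,
      locking_spec(kappa = k, preferred_phase = 1, base_rate = 6,
                   refractory = 0), 1000, seed = k)
    sd(spikefield:::wrap_phase(phases_at(o, sp) - 1))
  }, numeric(1))
  expect_lt(abs(dev_sd[1] - 1 / sqrt(50)), 0.05)
  expect_lt(abs(dev_sd[2] - 1 / sqrt(500)), 0.02)
  expect_lt(dev_sd[2], dev_sd[1] / 2)
  sp <- gen_locked_spikes(o$phase,
    locking_spec(kappa = 500, preferred_phase = 1, base_rate = 6,
                 refractory = 0), 1000, seed = 12)
  expect_lt(max(circ_dist(phases_at(o, sp), 1)), 3.5 / sqrt(500))
})

test_that("empty or zero-duration phase input is handled", {
  expect_error(gen_locked_spikes(numeric(0), locking_spec(), 1000),
               "empty")
  o <- gen_nonstationary_oscillator(oscillator_spec(duration = 0), seed = 1)
  expect_length(o$samples, 0)
})

test_that("PAC envelope follows the closed form and depth is monotone", {
  g <- gen_pac_lfp(pac_spec(8, 70, 0.5), 10, 1000, noise_sd = 0,
                   theta_amp = 0, gamma_amp = 1)
  env <- Mod(spikefield:::analytic_signal(g$lfp))
  i <- 1000:9000  # away from edges
  expect_lt(max(abs(env[i] - g$gamma_env[i])), 1e-6)

  # 18-bin profile unimodal with max in the bin of gamma_phase_of_max
  g1 <- gen_pac_lfp(pac_spec(8, 70, 1, gamma_phase_of_max = 0.5), 60, 1000,
                    noise_sd = 0.5, seed = 4)
  am <- Mod(morlet_tfr(c(0, diff(g1$lfp)) * 1000, 1000, 70, 12))
  prof <- modulation_index(g1$theta_phase, as.vector(am))
  expect_equal(which.max(prof$A),
               floor((0.5 + pi) / (2 * pi / 18)) + 1)

  mi <- vapply(seq(0, 1, 0.2), function(d) {
    g <- gen_pac_lfp(pac_spec(8, 70, d), 60, 1000, noise_sd = 1, seed = 11)
    th <- Arg(morlet_tfr(g$lfp, 1000, 8, 6))
    amp <- Mod(morlet_tfr(c(0, diff(g$lfp)) * 1000, 1000, 70, 12))
    modulation_index(as.vector(th), as.vector(amp))$mi
  }, numeric(1))
  expect_gt(cor(seq(0, 1, 0.2), mi, method = "spearman"), 0.95)
  expect_lt(mi[1], 0.01)  # depth 0: no coupling by construction
  expect_error(pac_spec(8, 70, 1.2), "coupling_depth")
  expect_error(pac_spec(70, 8), "gamma_freq")
})

test_that("co-firing pair places the cross-correlogram mode at the lag", {
  set.seed(3)
  snd <- sort(runif(600, 0, 60))
  mode_at <- function(lag) {
    rec <- gen_cofiring_pair(snd, cofire_spec(lag, jitter_sd = 2,
                                              copy_prob = 0.5),
                             60, background_rate = 1, seed = 5)
    dd <- outer(rec, snd, `-`) * 1000
    h <- hist(dd[abs(dd) <= 100], breaks = seq(-100.5, 100.5, 1),
              plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  expect_lt(abs(mode_at(20) - 20), 1.5)
  expect_lt(abs(mode_at(-30) + 30), 1.5)
  expect_error(gen_cofiring_pair(numeric(0), cofire_spec(), 10), "empty")
})

test_that("session carries the designed structure and degenerate designs work", {
  ses <- small_session()
  expect_s3_class(ses, "sfc_session")
  expect_equal(dim(ses$lfp), c(52, 14001, 8))
  expect_equal(length(ses$t), 14001)
  expect_setequal(names(ses$units), c("sender", "receiver", "background"))
  # all-hit session remains valid
  d0 <- session_design(n_hits = 3, n_misses = 0, seed = 2)
  s0 <- gen_session(d0)
  expect_equal(sum(s0$labels == "miss"), 0)
  expect_silent(spikefield:::validate_session(s0))
})

test_that("session round-trips through the plain-text serialization", {
  ses <- gen_session(session_design(n_hits = 2, n_misses = 2, seed = 13))
  dir <- tempfile("ses")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$lfp, ses$lfp, tolerance = 1e-12)
  expect_equal(back$labels, ses$labels)
  expect_equal(back$channels$bundle, ses$channels$bundle)
  for (u in names(ses$units)) {
    expect_equal(back$units[[u]]$spikes, ses$units[[u]]$spikes,
                 tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})
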