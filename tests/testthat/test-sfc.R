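# Spike-field coupling: PPC estimator, Rayleigh/FDR screening, pair-count
# null, condition contrasts, peak detection and the selection-bias control.

test_that("PPC equals the O(n^2) brute force and its closed forms", {
  brute <- function(th) {
    n <- length(th); s <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) s <- s + cos(th[j] - th[k])
    2 * s / (n * (n - 1))
  }
  set.seed(77)
  for (n in c(5, 50, 200)) {
    th <- runif(n, -pi, pi)
    expect_lt(abs(ppc(th) - brute(th)), 1e-12)
  }
  expect_equal(ppc(rep(2.1, 12)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  expect_error(ppc(0.3), "at least 2")
  # expectation ~ 0 for uniform phases
  m <- mean(replicate(400, ppc(runif(50, -pi, pi))))
  expect_lt(abs(m), 0.01)
})

test_that("PPC is invariant under global phase rotation", {
  set.seed(3)
  th <- runif(80, -pi, pi)
  for (rot in c(0.5, -2, pi)) {
    expect_lt(abs(ppc(th) - ppc(spikefield:::wrap_phase(th + rot))), 1e-12)
  }
})

test_that("rayleigh test matches its analytic small-sample behavior", {
  # concentrated sample: tiny p; uniform grid: p ~ 1
  expect_lt(rayleigh_test(rnorm(100, 1, 0.1))$p, 1e-10)
  grid <- seq(-pi, pi - 2 * pi / 64, length.out = 64)
  expect_gt(rayleigh_test(grid)$p, 0.99)
  r <- rayleigh_test(c(0.2, 0.4, 1.2, -0.3, 0.8))
  expect_equal(r$z, 5 * r$Rbar^2)
})

test_that("screening flags planted locking and controls type-I error", {
  pair <- sim_locked_pair(8, 8, kappa = 2, rate = 25, seed = 21)
  wp <- wavelet_phase(pair$lfp, pair$t, pair$fs, frequency_grid("low"),
                      window = c(1, 2))
  ps <- spike_phase_set(pair$spikes, wp, pair$labels)
  scr <- rayleigh_fdr_screen(ps)
  expect_true(scr$significant)
  sig_f <- scr$table$freq[scr$table$p_fdr < 0.05]
  expect_true(any(abs(sig_f - 8) <= 2))

  # type-I error of the Rayleigh+FDR screen on uniform phases, 1000 sims
  set.seed(55)
  nf <- 39
  hits <- vapply(1:1000, function(s) {
    th <- matrix(runif(50 * nf, -pi, pi), 50, nf)
    p <- spikefield:::rayleigh_p_cols(th)
    any(p.adjust(p, "BH") < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.055)
})

test_that("pairs below 30 spikes are excluded, not errored", {
  pair <- sim_locked_pair(8, 8, rate = 1, n_hit = 5, n_miss = 5, seed = 3)
  wp <- wavelet_phase(pair$lfp, pair$t, pair$fs, frequency_grid("low"),
                      window = c(1, 2))
  ps <- spike_phase_set(pair$spikes, wp, pair$labels)
  scr <- rayleigh_fdr_screen(ps)
  expect_true(scr$excluded)
  expect_false(scr$significant)
})

test_that("peak detection honors the 0.005 threshold and low-frequency ties", {
  freqs <- 40 + 2 * (0:20)
  v <- rep(0.001, 21)
  expect_null(find_ppc_peak(freqs, v, c(45, 75)))
  v[8] <- 0.2; v[14] <- 0.2  # exact tie: lower frequency wins
  pk <- find_ppc_peak(freqs, v, c(45, 75))
  expect_equal(pk$freq, freqs[8])
  v2 <- rep(0.001, 21); v2[12] <- 0.05
  expect_equal(find_ppc_peak(freqs, v2, c(45, 75))$freq, freqs[12])
  expect_null(find_ppc_peak(freqs, v2, c(45, 60)))  # peak outside band
})

test_that("gamma frequency shift is recovered across synthetic pairs", {
  res <- lapply(1:12, function(i) {
    pair <- sim_locked_pair(70, 62, n_hit = 20, n_miss = 16, kappa = 1.2,
                            rate = 30, band_halfwidth = 2.5, seed = 500 + i)
    wp <- wavelet_phase(pair$lfp, pair$t, pair$fs, frequency_grid("high"),
                        window = c(1, 2))
    ppc_spectrum(spike_phase_set(pair$spikes, wp, pair$labels))
  })
  shift <- peak_frequency_shift(res, band = c(45, 75))
  expect_gte(shift$n_used, 8)
  expect_gt(shift$mean_shift, 3)
  expect_lt(shift$test$p.value, 0.05)
  contrast <- condition_contrast(res)
  # hits carry more PPC than misses around 70 Hz
  i70 <- which(contrast$freq == 70)
  expect_gt(contrast$diff[i70], 0)
})

test_that("no planted shift yields no significant contrast in most runs", {
  res <- lapply(1:8, function(i) {
    pair <- sim_locked_pair(8, 8, n_hit = 15, n_miss = 15, kappa = 1.5,
                            rate = 25, seed = 900 + i)
    wp <- wavelet_phase(pair$lfp, pair$t, pair$fs, frequency_grid("low"),
                        window = c(1, 2))
    ppc_spectrum(spike_phase_set(pair$spikes, wp, pair$labels))
  })
  shift <- peak_frequency_shift(res, band = c(3, 13))
  expect_gt(shift$test$p.value, 0.05)
  expect_lt(abs(shift$mean_shift), 1.5)
})

test_that("session-level screening finds planted couplings and a calibrated null", {
  ses <- small_session()
  scr_l <- sfc_screen(ses, band = "low", n_shuffles = 25, n_draws = 2000,
                      seed = 5)
  p <- scr_l$pairs
  # sender unit distally theta-coupled to every bundle-2 wire
  sender_distal <- p$unit_id == "sender" & p$locality == "distal"
  expect_true(all(p$significant[sender_distal]))
  # distal significant count beats its shuffle null
  expect_lt(scr_l$null$distal$p, 0.01)

  scr_h <- sfc_screen(ses, band = "high", n_shuffles = 25, n_draws = 2000,
                      seed = 6)
  ph <- scr_h$pairs
  rec_local <- ph$unit_id == "receiver" & ph$locality != "distal"
  expect_true(all(ph$significant[rec_local]))
  expect_lt(scr_h$null$local$p, 0.01)
  # the unlocked background unit is not locally gamma-coupled
  bg_local <- ph$unit_id == "background" & ph$locality != "distal"
  expect_false(any(ph$significant[bg_local]))
  # same-wire and different-wire local couplings show consistent profiles
  keys <- which(rec_local)
  sw <- keys[ph$locality[keys] == "same_wire"]
  lb <- keys[ph$locality[keys] == "local_bundle"]
  if (length(sw) && length(lb)) {
    a <- scr_h$spectra[[sw[1]]]$ppc_all
    b <- rowMeans(sapply(lb, function(k) scr_h$spectra[[k]]$ppc_all))
    expect_gt(cor(a, b), 0.8)
  }
})

test_that("null session shows no excess of significant pairs", {
  # a session with no phase locking anywhere: observed counts fall inside
  # the shuffle null's 95% interval
  d <- session_design(n_hits = 14, n_misses = 12, theta_kappa = 0,
                      gamma_kappa = 0, copy_prob = 0, pac_depth = c(hit = 0,
                      miss = 0), seed = 23)
  ses <- gen_session(d)
  scr <- sfc_screen(ses, band = "low", n_shuffles = 40, n_draws = 4000,
                    seed = 9)
  for (loc in c("local", "distal")) {
    nl <- scr$null[[loc]]
    expect_gte(nl$observed, 0)
    expect_lte(nl$observed, quantile(nl$counts, 0.975) + 1)
  }
})

test_that("selection-bias control centres a spurious contrast at zero", {
  # unbalanced 80/20 trials, identical locking in both conditions
  pair <- sim_locked_pair(7, 7, n_hit = 32, n_miss = 8, kappa = 1.5,
                          rate = 25, seed = 71)
  wp <- wavelet_phase(pair$lfp, pair$t, pair$fs, frequency_grid("low"),
                      window = c(1, 2))
  sbc <- selection_bias_control(pair$spikes, wp, pair$labels,
                                n_shuffles = 300, seed = 8)
  expect_gte(sbc$n_kept, 50)
  # no true condition difference: the corrected spectra agree on where the
  # coupling sits (z-weighted centroid; the spectra plateau over the
  # wavelet bandwidth so the argmax is unstable)
  sel <- sbc$z$freq >= 3 & sbc$z$freq <= 13
  centroid <- function(z) {
    z <- pmax(z, 0); sum(sbc$z$freq[sel] * z[sel]) / sum(z[sel])
  }
  expect_lt(abs(centroid(sbc$z$z_hit) - centroid(sbc$z$z_miss)), 1)
  expect_lt(abs(centroid(sbc$z$z_hit) - 7.5), 1.5)

  # a genuine condition difference survives the correction
  pair2 <- sim_locked_pair(8, 5, n_hit = 28, n_miss = 12, kappa = 1.8,
                           rate = 25, seed = 72)
  wp2 <- wavelet_phase(pair2$lfp, pair2$t, pair2$fs, frequency_grid("low"),
                       window = c(1, 2))
  sbc2 <- selection_bias_control(pair2$spikes, wp2, pair2$labels,
                                 n_shuffles = 300, seed = 9)
  i8 <- which(sbc2$z$freq == 8)
  i5 <- which(sbc2$z$freq == 5)
  expect_gt(sbc2$z$z_hit[i8], sbc2$z$z_miss[i8])
  expect_gt(sbc2$z$z_miss[i5], sbc2$z$z_hit[i5])

  # no coupling at all: almost no shuffles survive, warning path
  pair3 <- sim_locked_pair(7, 7, n_hit = 20, n_miss = 20, kappa = 0,
                           rate = 20, seed = 73)
  wp3 <- wavelet_phase(pair3$lfp, pair3$t, pair3$fs, frequency_grid("low"),
                       window = c(1, 2))
  expect_warning(
    sbc3 <- selection_bias_control(pair3$spikes, wp3, pair3$labels,
                                   n_shuffles = 100, seed = 10),
    "kept")
  expect_true(sbc3$wide_ci)
})
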