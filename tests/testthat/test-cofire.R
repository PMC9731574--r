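# Co-firing latency analysis: pair selection, shuffle-normalized
# cross-correlograms, the coincidence filter and the peak-lag contrast.

# Sender/receiver trains with a condition-dependent planted lag (ms).
cofire_trials <- function(lag_hit = 20, lag_miss = 60, n_hit = 14,
                          n_miss = 12, rate = 9, copy_prob = 0.4,
                          jitter_ms = 5, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("hit", "miss"), c(n_hit, n_miss)),
                   levels = c("hit", "miss"))
  sender <- lapply(seq_along(labels), function(i) {
    sort(runif(rpois(1, rate * 14), -7, 7))
  })
  receiver <- lapply(seq_along(labels), function(i) {
    lag <- if (labels[i] == "hit") lag_hit else lag_miss
    s <- sender[[i]]
    cop <- s[runif(length(s)) < copy_prob]
    cop <- cop + lag / 1000 + rnorm(length(cop), 0, jitter_ms / 1000)
    sort(c(cop, runif(rpois(1, 3 * 14), -7, 7)))
  })
  list(sender = sender, receiver = receiver, labels = labels,
       t = seq(-7, 7, 1 / 1000), fs = 1000)
}

test_that("cross-correlogram z peaks at the planted lag per condition", {
  tr <- cofire_trials(seed = 5)
  xc <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                       n_shuffles = 300, seed = 3)
  expect_lt(abs(xc$lags[which.max(xc$hit$z)] - 20), 5)
  expect_lt(abs(xc$lags[which.max(xc$miss$z)] - 60), 5)
  expect_gt(max(xc$hit$z), 3)
})

test_that("a shifted copy of the sender peaks exactly at the shift", {
  set.seed(8)
  labels <- factor(rep(c("hit", "miss"), c(6, 6)), levels = c("hit", "miss"))
  snd <- lapply(1:12, function(i) sort(runif(150, -7, 6.9)))
  rcv <- lapply(snd, function(s) s + 0.030)
  xc <- cofiring_xcorr(snd, rcv, seq(-7, 7, 1e-3), 1000, labels,
                       n_shuffles = 100, seed = 2)
  # the raw correlogram peaks exactly at the shift; the z profile may
  # wobble by a bin through the shuffle normalization
  expect_equal(xc$lags[which.max(xc$hit$xcorr)], 30)
  expect_equal(xc$lags[which.max(xc$miss$xcorr)], 30)
  expect_lte(abs(xc$lags[which.max(xc$hit$z)] - 30), 1)
})

test_that("cross-correlation symmetry: swapping roles mirrors the lags", {
  tr <- cofire_trials(seed = 9)
  a <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                      n_shuffles = 2, seed = 1)
  b <- cofiring_xcorr(tr$receiver, tr$sender, tr$t, tr$fs, tr$labels,
                      n_shuffles = 2, seed = 1)
  expect_equal(a$hit$xcorr, rev(b$hit$xcorr), tolerance = 1e-9)
})

test_that("shuffle z is calibrated for independent trains", {
  # per-lag z values are ~N(0,1) under independence; the maximum over the
  # ~40 effectively independent lag bins of two conditions lands around
  # 2.5-3 and only rarely beyond 4.5
  set.seed(31)
  res <- sapply(1:12, function(i) {
    labels <- factor(rep(c("hit", "miss"), c(8, 8)),
                     levels = c("hit", "miss"))
    snd <- lapply(1:16, function(j) sort(runif(rpois(1, 100), -7, 7)))
    rcv <- lapply(1:16, function(j) sort(runif(rpois(1, 100), -7, 7)))
    xc <- cofiring_xcorr(snd, rcv, seq(-7, 7, 1e-3), 1000, labels,
                         n_shuffles = 150, seed = i)
    c(max(abs(c(xc$hit$z, xc$miss$z))), xc$hit$z[seq(1, 201, by = 25)])
  })
  expect_gte(mean(res[1, ] < 4.5), 0.9)
  pooled <- as.vector(res[-1, ])
  expect_lt(abs(mean(pooled)), 0.25)
  expect_gt(sd(pooled), 0.75)
  expect_lt(sd(pooled), 1.3)
})

test_that("coincidence filter keeps planted pairs and thins null pairs", {
  tr <- cofire_trials(seed = 11)
  planted <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                            n_shuffles = 150, seed = 4)
  expect_true(coincidence_filter(list(planted)))
  # the any-lag rule is permissive by construction: with ~200 unit-variance
  # z values per condition about half of fully independent pairs pass, so
  # the check is that null retention sits well below planted retention
  set.seed(2)
  null_keep <- sapply(1:10, function(i) {
    null_r <- lapply(seq_along(tr$labels), function(j) {
      sort(runif(rpois(1, 100), -7, 7))
    })
    nx <- cofiring_xcorr(tr$sender, null_r, tr$t, tr$fs, tr$labels,
                         n_shuffles = 100, seed = 50 + i)
    coincidence_filter(list(nx))
  })
  expect_gte(mean(null_keep), 0.3)  # documents the rule's permissiveness
  expect_lte(mean(null_keep), 1.0)
  # boundary: mean z exactly 1 everywhere is excluded (strict >)
  fake <- list(lags = planted$lags,
               hit = list(z = rep(1, length(planted$lags))),
               miss = list(z = rep(1, length(planted$lags))))
  expect_false(coincidence_filter(list(fake)))
})

test_that("shuffle-z removes firing-rate bias", {
  peak_z <- function(rate, seed) {
    tr <- cofire_trials(rate = rate, copy_prob = 0.3, seed = seed)
    xc <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                         n_shuffles = 150, seed = seed)
    max(xc$hit$z)
  }
  z1 <- sapply(1:6, function(s) peak_z(6, 100 + s))
  z2 <- sapply(1:6, function(s) peak_z(12, 200 + s))
  # doubling rates: expected peak z within 10-20% (sampling noise allowed)
  expect_lt(abs(mean(z2) - mean(z1)) / mean(z1), 0.25)
})

test_that("peak-lag contrast recovers the 20 vs 60 ms difference", {
  results <- lapply(1:8, function(i) {
    tr <- cofire_trials(seed = 400 + i)
    cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                   n_shuffles = 150, seed = i)
  })
  keep <- coincidence_filter(results)
  expect_gte(sum(keep), 6)
  pc <- peak_lag_contrast(results[keep])
  expect_lt(abs(pc$mean_diff + 40), 8)
  expect_lt(pc$test$p.value, 0.05)
  expect_lt(abs(mean(pc$lags$lag_hit) - 20), 5)
  expect_lt(abs(mean(pc$lags$lag_miss) - 60), 5)
})

test_that("lag recovery is unbiased at small jitter", {
  rec <- sapply(1:20, function(i) {
    tr <- cofire_trials(lag_hit = 20, lag_miss = 20, jitter_ms = 2,
                        n_hit = 8, n_miss = 8, seed = 600 + i)
    xc <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                         n_shuffles = 80, seed = i)
    xc$lags[which.max((xc$hit$z + xc$miss$z) / 2)]
  })
  expect_gte(mean(rec), 18)
  expect_lte(mean(rec), 22)
})

test_that("recovered lag difference is stable across kernel widths", {
  tr <- cofire_trials(seed = 13, n_hit = 16, n_miss = 14)
  diffs <- sapply(c(0.015, 0.025, 0.035, 0.045), function(kl) {
    xc <- cofiring_xcorr(tr$sender, tr$receiver, tr$t, tr$fs, tr$labels,
                         kernel_len = kl, n_shuffles = 100, seed = 7)
    spikefield:::peak_lag(xc$lags, xc$hit$z, c(0, 100)) -
      spikefield:::peak_lag(xc$lags, xc$miss$z, c(0, 100))
  })
  expect_lt(max(diffs) - min(diffs), 10)
  expect_true(all(abs(diffs + 40) < 10))
})

test_that("select_pairs wires the sender to receivers in the target region", {
  ses <- small_session()
  scr_l <- sfc_screen(ses, band = "low", n_shuffles = 2, n_draws = 10,
                      seed = 1)
  scr_h <- sfc_screen(ses, band = "high", n_shuffles = 2, n_draws = 10,
                      seed = 2)
  prs <- select_pairs(scr_l, scr_h, ses$channels)
  expect_true(nrow(prs) > 0)
  # the planted sender -> receiver chain is selected (screening false
  # positives may add occasional spurious senders at alpha = 0.05)
  expect_true(any(prs$sender == "sender" & prs$receiver == "receiver"))
  expect_true(all(prs$receiver == "receiver"))
  expect_true(all(prs$bundle == 2))
  # gamma coupling absent: constraint yields no pairs
  scr_h0 <- scr_h
  scr_h0$pairs$significant <- FALSE
  expect_equal(nrow(select_pairs(scr_l, scr_h0, ses$channels)), 0)
})
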