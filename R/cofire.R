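# Co-firing latency analysis: selection of putative sender/receiver unit
# pairs from the spike-field coupling results, shuffle-normalized
# cross-correlograms of Gaussian-convolved spike trains, the coincidence
# filter, and the peak-lag condition contrast.

#' Select putative sender/receiver unit pairs
#'
#' A sender is a unit with significant *distal* low-frequency coupling to
#' some LFP channel; the receiver is a unit that is *locally* gamma-coupled
#' to a channel of that same bundle (region). Pairing a distally
#' theta-coupled upstream unit with the locally gamma-entrained unit of the
#' target region operationalizes the sender -> receiver hypothesis.
#'
#' @param screen_low an [sfc_screen()] result for the low band.
#' @param screen_high an [sfc_screen()] result for the high band.
#' @param channels the session's channel table (channel, bundle).
#' @return data.frame of pairs: sender, receiver, bundle (target region),
#'   sender_channel, receiver_channel. Zero rows when no pair qualifies.
#' @export
select_pairs <- function(screen_low, screen_high, channels) {
  pl <- screen_low$pairs; ph <- screen_high$pairs
  bundle_of <- function(ch) channels$bundle[match(ch, channels$channel)]
  senders <- pl[pl$significant & !pl$excluded & pl$locality == "distal", ,
                drop = FALSE]
  receivers <- ph[ph$significant & !ph$excluded &
                    ph$locality %in% c("local_bundle", "same_wire"), ,
                  drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(senders))) {
    target_bundle <- bundle_of(senders$channel[i])
    for (j in seq_len(nrow(receivers))) {
      if (bundle_of(receivers$channel[j]) == target_bundle &&
          receivers$unit_id[j] != senders$unit_id[i]) {
        out[[length(out) + 1L]] <- data.frame(
          sender = senders$unit_id[i], receiver = receivers$unit_id[j],
          bundle = target_bundle,
          sender_channel = senders$channel[i],
          receiver_channel = receivers$channel[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sender = character(0), receiver = character(0),
                      bundle = integer(0), sender_channel = integer(0),
                      receiver_channel = integer(0)))
  }
  unique(do.call(rbind, out))
}

# Per-trial cross-correlation tensor machinery. For spike-density matrices
# S, R (trials x time), the cross-correlogram at lag k is
# sum_t s(t) r(t + k). The observed correlogram pairs trial i with trial i;
# a shuffle pairs sender trial i with receiver trial perm(i). Both are sums
# of rows of the trial-pair tensor, computed once via FFT.
xcorr_tensor <- function(S, R, fs, max_lag) {
  n_tr <- nrow(S); n <- ncol(S)
  L <- next_pow2(2 * n)
  lags <- -max_lag:max_lag
  FS <- stats::mvfft(t(cbind(S, matrix(0, n_tr, L - n))))
  FR <- stats::mvfft(t(cbind(R, matrix(0, n_tr, L - n))))
  # tensor[(i-1)*n_tr + j, ] = xcorr(sender trial i, receiver trial j);
  # cc[k+1, j] = sum_t s_i(t) r_j(t+k) circularly, exact because of the
  # zero padding; lag -m sits at index L-m+1
  tens <- matrix(0, n_tr * n_tr, length(lags))
  idx <- c((L - max_lag + 1):L, 1:(max_lag + 1))  # lags -max..max in order
  for (i in seq_len(n_tr)) {
    cc <- Re(stats::mvfft(Conj(FS[, i]) * FR, inverse = TRUE)) / L
    tens[(i - 1) * n_tr + seq_len(n_tr), ] <- t(cc[idx, , drop = FALSE])
  }
  list(tensor = tens, lags = lags / fs * 1000, n_tr = n_tr)
}

#' Shuffle-normalized cross-correlogram of a unit pair
#'
#' Spike trains are binned on the analysis window, convolved with a
#' Gaussian kernel (default 25 ms support, ~10 ms FWHM) and
#' cross-correlated per trial; the session correlogram is the sum over
#' trials. The null pairs sender trials with `n_shuffles` random
#' permutations of receiver trials (condition-wise, spike counts
#' preserved), and the observed correlogram is z-transformed by the
#' shuffle mean and SD per lag. Positive lags mean the receiver fires
#' after the sender.
#'
#' @param sender,receiver lists of per-trial spike times (s).
#' @param t epoch time axis (s).
#' @param fs sampling rate (Hz).
#' @param labels trial condition factor (`hit`/`miss`); the correlogram is
#'   computed per condition.
#' @param window analysis window (s), default `c(2, 3)`.
#' @param kernel_len Gaussian kernel support (s), default 0.025
#'   (sigma = 10 ms / 2.355).
#' @param max_lag_ms maximum lag (ms), default 100.
#' @param n_shuffles receiver-trial shuffles, default 2000.
#' @param seed integer seed.
#' @return a `cofire_xcorr` list: `lags` (ms) and per condition `z`,
#'   `xcorr` (raw) and spike counts.
#' @export
cofiring_xcorr <- function(sender, receiver, t, fs, labels,
                           window = c(2, 3), kernel_len = 0.025,
                           max_lag_ms = 100, n_shuffles = 2000,
                           seed = NULL) {
  win <- t >= window[1] & t < window[2]
  k <- gauss_kernel(kernel_len, fs, sigma = 0.010 / 2.355)
  binm <- function(sp) {
    t(vapply(sp, function(s) bin_spikes(s, t, fs), numeric(length(t))))
  }
  S_all <- conv_rows_same(binm(sender), k)[, win, drop = FALSE]
  R_all <- conv_rows_same(binm(receiver), k)[, win, drop = FALSE]
  max_lag <- round(max_lag_ms / 1000 * fs)
  out <- list(lags = (-max_lag:max_lag) / fs * 1000)
  with_seed(seed, {
    for (lev in levels(labels)) {
      ix <- which(labels == lev)
      n_sp_s <- sum(vapply(sender[ix], function(s) sum(s >= window[1] & s < window[2]), numeric(1)))
      n_sp_r <- sum(vapply(receiver[ix], function(s) sum(s >= window[1] & s < window[2]), numeric(1)))
      if (length(ix) < 2L || n_sp_s == 0 || n_sp_r == 0) {
        out[[lev]] <- list(z = NULL, xcorr = NULL, excluded = TRUE,
                           n_spikes_sender = n_sp_s,
                           n_spikes_receiver = n_sp_r)
        next
      }
      tx <- xcorr_tensor(S_all[ix, , drop = FALSE], R_all[ix, , drop = FALSE],
                         fs, max_lag)
      n_tr <- tx$n_tr
      diag_rows <- (seq_len(n_tr) - 1) * n_tr + seq_len(n_tr)
      obs <- colSums(tx$tensor[diag_rows, , drop = FALSE])
      null <- matrix(0, n_shuffles, length(out$lags))
      for (s in seq_len(n_shuffles)) {
        pm <- sample.int(n_tr)
        rows <- (seq_len(n_tr) - 1) * n_tr + pm
        null[s, ] <- colSums(tx$tensor[rows, , drop = FALSE])
      }
      mu <- colMeans(null); sdv <- apply(null, 2, stats::sd)
      z <- (obs - mu) / sdv
      z[sdv == 0] <- 0
      out[[lev]] <- list(z = z, xcorr = obs, excluded = FALSE,
                         n_spikes_sender = n_sp_s, n_spikes_receiver = n_sp_r)
    }
    structure(out, class = "cofire_xcorr")
  })
}

#' Coincidence filter for co-firing pairs
#'
#' Keeps pairs whose mean z over conditions exceeds 1 at any lag (strict),
#' ensuring that only pairs with meaningful co-firing enter the latency
#' contrast.
#'
#' @param results list of [cofiring_xcorr()] results.
#' @return logical vector, one per pair.
#' @export
coincidence_filter <- function(results) {
  vapply(results, function(r) {
    if (is.null(r$hit$z) || is.null(r$miss$z)) return(FALSE)
    any((r$hit$z + r$miss$z) / 2 > 1)
  }, logical(1))
}

# Peak of z(lag) restricted to a lag range; global maximum, ties toward 0.
peak_lag <- function(lags, z, range_ms) {
  sel <- which(lags >= range_ms[1] & lags <= range_ms[2])
  if (!length(sel)) return(NA_real_)
  v <- z[sel]
  best <- which(v == max(v))
  if (length(best) > 1L) best <- best[which.min(abs(lags[sel][best]))]
  lags[sel][best]
}

#' Peak-lag condition contrast across retained pairs
#'
#' Peak z lag per condition in the forward direction (0..`max_ms`,
#' sender -> receiver) and, as the reverse-direction control, over negative
#' lags, with a paired t-test of hit versus miss peak lags across pairs.
#'
#' @param results list of [cofiring_xcorr()] results (already filtered by
#'   [coincidence_filter()]).
#' @param max_ms peak search bound (ms), default 100.
#' @return list with per-pair `lags` data.frame, the forward `test`,
#'   reverse `test_reverse`, and mean lag difference (hit - miss, ms).
#' @export
peak_lag_contrast <- function(results, max_ms = 100) {
  if (length(results) < 2L) {
    stopf("peak_lag_contrast: need >= 2 retained pairs")
  }
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      pair = i,
      lag_hit = peak_lag(r$lags, r$hit$z, c(0, max_ms)),
      lag_miss = peak_lag(r$lags, r$miss$z, c(0, max_ms)),
      lag_hit_rev = peak_lag(r$lags, r$hit$z, c(-max_ms, 0)),
      lag_miss_rev = peak_lag(r$lags, r$miss$z, c(-max_ms, 0)))
  })
  lags <- do.call(rbind, rows)
  ok <- stats::complete.cases(lags[, c("lag_hit", "lag_miss")])
  test <- if (sum(ok) >= 2 && stats::sd(lags$lag_hit[ok] - lags$lag_miss[ok]) > 0) {
    stats::t.test(lags$lag_hit[ok], lags$lag_miss[ok], paired = TRUE)
  } else NULL
  okr <- stats::complete.cases(lags[, c("lag_hit_rev", "lag_miss_rev")])
  test_rev <- if (sum(okr) >= 2 &&
                  stats::sd(lags$lag_hit_rev[okr] - lags$lag_miss_rev[okr]) > 0) {
    stats::t.test(lags$lag_hit_rev[okr], lags$lag_miss_rev[okr],
                  paired = TRUE)
  } else NULL
  list(lags = lags, test = test, test_reverse = test_rev,
       mean_diff = mean(lags$lag_hit[ok] - lags$lag_miss[ok]),
       n_used = sum(ok))
}
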