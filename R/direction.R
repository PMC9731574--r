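# Phase-slope-index directionality between a spike-density signal and a
# distally coupled LFP, with shuffle z-normalization.

# Welch-style segmented cross/auto spectra for matched trial matrices.
# Returns complex coherency C(f) averaged over segments and trials, with
# the convention S_xy = X * Conj(Y): a positive phase slope of C means x
# leads y.
segmented_coherency <- function(x, y, fs, seg_len = 0.5, overlap = 0.5) {
  stopifnot(all(dim(x) == dim(y)))
  n <- ncol(x)
  nseg <- round(seg_len * fs)
  if (nseg > n) stopf("segmented_coherency: segment longer than window")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  freqs <- (0:(nseg - 1)) * fs / nseg
  keep <- seq_len(floor(nseg / 2) + 1)
  Sxy <- complex(length(keep)); Sxx <- numeric(length(keep))
  Syy <- numeric(length(keep))
  for (tr in seq_len(nrow(x))) {
    for (s0 in starts) {
      ix <- s0:(s0 + nseg - 1)
      X <- stats::fft((x[tr, ix] - mean(x[tr, ix])) * taper)[keep]
      Y <- stats::fft((y[tr, ix] - mean(y[tr, ix])) * taper)[keep]
      Sxy <- Sxy + X * Conj(Y)
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
    }
  }
  C <- Sxy / sqrt(Sxx * Syy)
  list(freq = freqs[keep], coherency = C, df = fs / nseg)
}

# Raw PSI from a coherency spectrum: Im(sum over the slope window of
# C*(f') C(f' + df)).
psi_from_coherency <- function(co, freqs_out, bandwidth = 5) {
  f <- co$freq; C <- co$coherency; df <- co$df
  vapply(freqs_out, function(f0) {
    sel <- which(f >= f0 - bandwidth / 2 & f <= f0 + bandwidth / 2)
    sel <- sel[sel + 1 <= length(f) & f[sel + 1] <= f0 + bandwidth / 2]
    if (!length(sel)) return(NA_real_)
    sum(Im(Conj(C[sel]) * C[sel + 1]))
  }, numeric(1))
}

#' Phase slope index between spike density and LFP
#'
#' The spike train is convolved with a short Gaussian kernel (25 ms
#' support) into a density signal; complex coherency with the LFP is
#' estimated by Welch segmentation (500 ms segments, 50% overlap, Hann
#' taper) across trials inside the analysis window, and the PSI
#' \deqn{\Psi(f) = \mathrm{Im}\sum_{f' \in W(f)} C^*(f')\,C(f'+\delta f)}
#' is computed over a 5 Hz slope window. Positive \eqn{\Psi} means the
#' spike-providing signal leads (is the sender). The raw PSI is
#' z-normalized against `n_shuffles` random spike-trial reassignments,
#' which removes spike-count and spectral-estimation bias.
#'
#' @param spikes list of per-trial spike times (s relative to cue).
#' @param lfp matrix trials x time of the LFP channel (full epoch).
#' @param t epoch time axis (s).
#' @param fs sampling rate (Hz).
#' @param window analysis window (s), default `c(2, 3)`.
#' @param freqs_out output frequencies (Hz), default 2-13 Hz (theta range).
#' @param bandwidth slope-window width (Hz), default 5.
#' @param kernel_len spike-density kernel support (s), default 0.025
#'   (sigma = 10 ms FWHM / 2.355).
#' @param seg_len,overlap Welch segmentation parameters.
#' @param n_shuffles shuffles for the z baseline, default 100.
#' @param min_spikes minimum spikes in the window, default 60 (set 30 for
#'   the relaxed mode).
#' @param seed integer seed.
#' @return a `psi_spectrum` data.frame: freq, psi, z, plus attributes
#'   `n_spikes` and `excluded`.
#' @export
psi <- function(spikes, lfp, t, fs, window = c(2, 3),
                freqs_out = 2:13, bandwidth = 5, kernel_len = 0.025,
                seg_len = 0.5, overlap = 0.5, n_shuffles = 100,
                min_spikes = 60, seed = NULL) {
  win <- t >= window[1] & t < window[2]
  n_tr <- length(spikes)
  stopifnot(nrow(lfp) == n_tr)
  n_sp <- sum(vapply(spikes, function(s) {
    sum(s >= window[1] & s < window[2])
  }, numeric(1)))
  if (n_sp < min_spikes) {
    out <- data.frame(freq = freqs_out, psi = NA_real_, z = NA_real_)
    attr(out, "n_spikes") <- n_sp; attr(out, "excluded") <- TRUE
    class(out) <- c("psi_spectrum", "data.frame")
    return(out)
  }
  k <- gauss_kernel(kernel_len, fs, sigma = 0.010 / 2.355)
  bin <- t(vapply(spikes, function(s) bin_spikes(s, t, fs), numeric(length(t))))
  dens <- conv_rows_same(bin, k)[, win, drop = FALSE]
  L <- lfp[, win, drop = FALSE]
  co <- segmented_coherency(dens, L, fs, seg_len, overlap)
  raw <- psi_from_coherency(co, freqs_out, bandwidth)
  with_seed(seed, {
    null <- matrix(NA_real_, n_shuffles, length(freqs_out))
    for (s in seq_len(n_shuffles)) {
      pm <- sample.int(n_tr)
      co_s <- segmented_coherency(dens[pm, , drop = FALSE], L, fs,
                                  seg_len, overlap)
      null[s, ] <- psi_from_coherency(co_s, freqs_out, bandwidth)
    }
    mu <- colMeans(null); sdv <- apply(null, 2, stats::sd)
    z <- (raw - mu) / sdv
    z[sdv == 0] <- NA_real_
    out <- data.frame(freq = freqs_out, psi = raw, z = z)
    attr(out, "n_spikes") <- n_sp; attr(out, "excluded") <- FALSE
    class(out) <- c("psi_spectrum", "data.frame")
    out
  })
}

#' Condition-wise PSI with shuffle z-normalization
#'
#' Runs [psi()] separately for hit and miss trials (shuffling within
#' condition, preserving each condition's spike counts).
#'
#' @inheritParams psi
#' @param labels trial condition factor.
#' @return list with `hit` and `miss` `psi_spectrum`s.
#' @export
psi_by_condition <- function(spikes, lfp, t, fs, labels, ...) {
  out <- lapply(c(hit = "hit", miss = "miss"), function(lev) {
    ix <- which(labels == lev)
    psi(spikes[ix], lfp[ix, , drop = FALSE], t, fs, ...)
  })
  out
}

#' Across-pairs PSI condition contrast
#'
#' Per frequency: paired t-test of hit versus miss z-normalized PSI across
#' pairs (FDR-corrected), plus per-condition one-sample tests against zero.
#'
#' @param z_hit,z_miss matrices pairs x freq of z-normalized PSI.
#' @param freqs frequencies (Hz).
#' @param alpha FDR level.
#' @return data.frame per frequency with the contrast and against-zero
#'   statistics.
#' @export
psi_condition_contrast <- function(z_hit, z_miss, freqs, alpha = 0.05) {
  z_hit <- as.matrix(z_hit); z_miss <- as.matrix(z_miss)
  if (nrow(z_hit) < 5) {
    warning("psi_condition_contrast: fewer than 5 pairs; tests unstable")
  }
  one_sided_p <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || stats::sd(v) == 0) return(NA_real_)
    stats::t.test(v)$p.value
  }
  res <- lapply(seq_along(freqs), function(i) {
    h <- z_hit[, i]; m <- z_miss[, i]
    ok <- !is.na(h) & !is.na(m)
    p <- if (sum(ok) >= 2 && stats::sd(h[ok] - m[ok]) > 0) {
      stats::t.test(h[ok], m[ok], paired = TRUE)$p.value
    } else NA_real_
    data.frame(freq = freqs[i], mean_z_hit = mean(h, na.rm = TRUE),
               mean_z_miss = mean(m, na.rm = TRUE),
               diff = mean(h[ok] - m[ok]),
               p = p, p_hit_vs0 = one_sided_p(h), p_miss_vs0 = one_sided_p(m))
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}
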