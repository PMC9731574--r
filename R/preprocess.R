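# LFP preprocessing: low-pass filtering, spike interpolation, line-noise
# template subtraction, epoching/downsampling, amplitude-based artifact
# rejection and Gram-Schmidt local re-referencing.
#
# The pipeline order is fixed: lowpass -> spike interpolation -> line noise
# -> epoch/downsample -> artifact rejection -> re-referencing.

#' Construct a continuous raw LFP container
#'
#' @param samples numeric matrix, time x channels (microvolt).
#' @param fs sampling rate (Hz).
#' @param spike_markers list (one element per channel) of sample indices at
#'   which spikes were detected; used by [interpolate_spikes()].
#' @param bundle_of integer/character vector mapping each channel to its
#'   microwire bundle.
#' @return an `sfc_raw` object.
#' @export
raw_lfp <- function(samples, fs, spike_markers = NULL, bundle_of = NULL) {
  samples <- as.matrix(samples)
  n_ch <- ncol(samples)
  spike_markers <- spike_markers %||% rep(list(integer(0)), n_ch)
  if (length(spike_markers) != n_ch) {
    stopf("raw_lfp: spike_markers must have one entry per channel")
  }
  for (m in spike_markers) {
    if (length(m) && (min(m) < 1 || max(m) > nrow(samples))) {
      stopf("raw_lfp: spike markers out of bounds")
    }
  }
  structure(list(samples = samples, fs = fs,
                 spike_markers = spike_markers,
                 bundle_of = bundle_of %||% rep(1L, n_ch)),
            class = "sfc_raw")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-2 Butterworth low-pass (default cutoff 300 Hz) applied
#' forward-backward (`filtfilt`), so the filter introduces no phase shift --
#' a requirement for unbiased phase estimation downstream.
#'
#' @param raw an [raw_lfp()] object.
#' @param cutoff cutoff frequency (Hz).
#' @param order filter order (before the forward-backward doubling).
#' @return the filtered `sfc_raw`.
#' @export
lowpass_filter <- function(raw, cutoff = 300, order = 2) {
  stopifnot(inherits(raw, "sfc_raw"))
  if (raw$fs <= 2 * cutoff) {
    stopf("lowpass_filter: fs = %g Hz must exceed 2 x cutoff (%g Hz)",
          raw$fs, cutoff)
  }
  bf <- signal::butter(order, cutoff / (raw$fs / 2), type = "low")
  for (ch in seq_len(ncol(raw$samples))) {
    raw$samples[, ch] <- signal::filtfilt(bf, raw$samples[, ch])
  }
  raw
}

# Merge overlapping intervals given as a 2-column matrix (start, end).
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + 1) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Interpolate the LFP across spike times
#'
#' Replaces the window from `pre_ms` before to `post_ms` after each spike
#' marker by linear interpolation between the window's boundary samples,
#' removing spike leakage into the LFP. Overlapping windows are merged;
#' windows clipped by the record edge are filled with the surviving boundary
#' value.
#'
#' @param raw an [raw_lfp()] with `spike_markers`.
#' @param pre_ms,post_ms window (ms) around each marker, default -2/+6 ms.
#' @return the interpolated `sfc_raw`.
#' @export
interpolate_spikes <- function(raw, pre_ms = 2, post_ms = 6) {
  stopifnot(inherits(raw, "sfc_raw"))
  n <- nrow(raw$samples)
  pre <- round(pre_ms / 1000 * raw$fs)
  post <- round(post_ms / 1000 * raw$fs)
  for (ch in seq_len(ncol(raw$samples))) {
    mk <- raw$spike_markers[[ch]]
    if (!length(mk)) next
    iv <- merge_intervals(cbind(pmax(mk - pre, 1), pmin(mk + post, n)))
    x <- raw$samples[, ch]
    for (i in seq_len(nrow(iv))) {
      a <- iv[i, 1]; b <- iv[i, 2]
      left <- if (a > 1) x[a - 1] else NA_real_
      right <- if (b < n) x[b + 1] else NA_real_
      if (is.na(left)) left <- right
      if (is.na(right)) right <- left
      if (is.na(left)) next  # whole record inside one interval
      x[a:b] <- left + (right - left) * seq_len(b - a + 1) / (b - a + 2)
    }
    raw$samples[, ch] <- x
  }
  raw
}

# Least-squares sine + cosine fit at `freq`, subtracted per column of `x`.
subtract_sinusoid <- function(x, fs, freq) {
  n <- nrow(x)
  tt <- (seq_len(n) - 1) / fs
  X <- cbind(sin(2 * pi * freq * tt), cos(2 * pi * freq * tt))
  beta <- solve(crossprod(X), crossprod(X, x))
  x - X %*% beta
}

#' Remove line noise by template subtraction
#'
#' Fits amplitude and phase of a sinusoid at the line frequency per channel
#' (and per epoch, for epoched input) by least squares and subtracts it.
#' Because the line component is stationary within an epoch while brain
#' signals are not, the fit removes the line while leaving physiological
#' activity at the line frequency largely intact -- unlike a band-stop
#' filter.
#'
#' @param x an `sfc_raw` or `sfc_epochs` object.
#' @param line_freq line frequency (Hz), default 50.
#' @return object of the same class with the line component removed.
#' @export
remove_line_noise <- function(x, line_freq = 50) {
  if (inherits(x, "sfc_raw")) {
    x$samples <- subtract_sinusoid(x$samples, x$fs, line_freq)
    return(x)
  }
  if (inherits(x, "sfc_epochs")) {
    for (tr in seq_len(dim(x$lfp)[1])) {
      x$lfp[tr, , ] <- subtract_sinusoid(
        matrix(x$lfp[tr, , ], ncol = dim(x$lfp)[3]), x$fs, line_freq)
    }
    return(x)
  }
  stopf("remove_line_noise: expected sfc_raw or sfc_epochs")
}

#' Cut continuous LFP into cue-centred epochs and downsample to 1 kHz
#'
#' Extracts 14 s epochs (-7..+7 s around each cue) after anti-alias
#' filtering (zero-phase Butterworth, order 4, cutoff 0.4 x target rate) and
#' resamples onto the 1 kHz grid by index lookup. Cues whose epoch exceeds
#' the record are dropped and logged.
#'
#' @param raw an [raw_lfp()].
#' @param cue_times cue times (s, relative to record start).
#' @param fs_out target rate (Hz), default 1000.
#' @param pre,post epoch extent (s) before/after cue.
#' @return an `sfc_epochs` object with `lfp` (trials x time x channels),
#'   time axis `t`, keep-masks and a rejection `log`.
#' @export
epoch_and_downsample <- function(raw, cue_times, fs_out = 1000,
                                 pre = 7, post = 7) {
  stopifnot(inherits(raw, "sfc_raw"))
  if (raw$fs < fs_out) stopf("epoch_and_downsample: fs below target rate")
  x <- raw$samples
  if (raw$fs > fs_out) {
    bf <- signal::butter(4, (0.4 * fs_out) / (raw$fs / 2), type = "low")
    for (ch in seq_len(ncol(x))) x[, ch] <- signal::filtfilt(bf, x[, ch])
  }
  t_rel <- seq(-pre, post, by = 1 / fs_out)
  n_t <- length(t_rel)
  dur <- nrow(x) / raw$fs
  keep <- (cue_times - pre) >= 0 & (cue_times + post) <= dur - 1 / raw$fs
  log <- data.frame(trial = which(!keep), channel = NA_integer_,
                    rule = "epoch_out_of_bounds", z = NA_real_)
  cues <- cue_times[keep]
  lfp <- array(0, dim = c(length(cues), n_t, ncol(x)))
  for (i in seq_along(cues)) {
    idx <- round((cues[i] + t_rel) * raw$fs) + 1
    idx <- pmin(pmax(idx, 1), nrow(x))
    lfp[i, , ] <- x[idx, ]
  }
  structure(list(lfp = lfp, t = t_rel, fs = fs_out,
                 bundle_of = raw$bundle_of,
                 keep_trial = matrix(TRUE, length(cues), ncol(x)),
                 keep_channel = rep(TRUE, ncol(x)),
                 log = log),
            class = "sfc_epochs")
}

#' Build an epochs container from an already-epoched array
#'
#' @param lfp array trials x time x channels.
#' @param t time axis (s, relative to cue).
#' @param fs sampling rate (Hz).
#' @param bundle_of channel -> bundle map.
#' @return an `sfc_epochs` object.
#' @export
as_epochs <- function(lfp, t, fs, bundle_of = NULL) {
  stopifnot(length(dim(lfp)) == 3L, dim(lfp)[2] == length(t))
  structure(list(lfp = lfp, t = t, fs = fs,
                 bundle_of = bundle_of %||% rep(1L, dim(lfp)[3]),
                 keep_trial = matrix(TRUE, dim(lfp)[1], dim(lfp)[3]),
                 keep_channel = rep(TRUE, dim(lfp)[3]),
                 log = data.frame(trial = integer(0), channel = integer(0),
                                  rule = character(0), z = numeric(0))),
            class = "sfc_epochs")
}

#' Amplitude-based artifact rejection
#'
#' Four sequential rules on the window of interest:
#' channels whose root-mean-square amplitude (RMSA, averaged over trials)
#' is an outlier across channels (z > `z_channel`) are dropped; per channel,
#' trials whose RMSA is an outlier across trials (z > `z_trial`) are
#' dropped; trials whose maximum raw amplitude is an outlier across trials
#' (z > `z_amp`) are dropped; channels left with fewer than `min_trials`
#' trials are dropped entirely. All rejections are logged.
#'
#' @param epochs an `sfc_epochs` object.
#' @param window window of interest (s), default `c(-0.5, 5)`.
#' @param z_channel,z_trial,z_amp rejection thresholds.
#' @param min_trials minimum surviving trials per channel.
#' @return the `sfc_epochs` with updated keep-masks and log.
#' @export
reject_artifacts <- function(epochs, window = c(-0.5, 5), z_channel = 3,
                             z_trial = 4, z_amp = 4, min_trials = 25) {
  stopifnot(inherits(epochs, "sfc_epochs"))
  win <- epochs$t >= window[1] & epochs$t <= window[2]
  n_tr <- dim(epochs$lfp)[1]; n_ch <- dim(epochs$lfp)[3]
  rmsa <- matrix(0, n_tr, n_ch)  # per trial x channel
  amax <- matrix(0, n_tr, n_ch)
  for (ch in seq_len(n_ch)) {
    seg <- matrix(epochs$lfp[, win, ch], nrow = n_tr)
    rmsa[, ch] <- sqrt(rowMeans(seg^2))
    amax[, ch] <- apply(abs(seg), 1, max)
  }
  log <- epochs$log

  # rule 1: channel-level RMSA z-scored across channels
  ch_rmsa <- colMeans(rmsa)
  zc <- (ch_rmsa - mean(ch_rmsa)) / stats::sd(ch_rmsa)
  bad_ch <- which(zc > z_channel)
  epochs$keep_channel[bad_ch] <- FALSE
  epochs$keep_trial[, bad_ch] <- FALSE
  if (length(bad_ch)) {
    log <- rbind(log, data.frame(trial = NA_integer_, channel = bad_ch,
                                 rule = "channel_rmsa", z = zc[bad_ch]))
  }

  for (ch in which(epochs$keep_channel)) {
    # rule 2: trial-level mean RMSA across trials
    z2 <- (rmsa[, ch] - mean(rmsa[, ch])) / stats::sd(rmsa[, ch])
    # rule 3: trial-level max raw amplitude across trials
    z3 <- (amax[, ch] - mean(amax[, ch])) / stats::sd(amax[, ch])
    bad2 <- which(z2 > z_trial & epochs$keep_trial[, ch])
    if (length(bad2)) {
      epochs$keep_trial[bad2, ch] <- FALSE
      log <- rbind(log, data.frame(trial = bad2, channel = ch,
                                   rule = "trial_rmsa", z = z2[bad2]))
    }
    bad3 <- which(z3 > z_amp & epochs$keep_trial[, ch])
    if (length(bad3)) {
      epochs$keep_trial[bad3, ch] <- FALSE
      log <- rbind(log, data.frame(trial = bad3, channel = ch,
                                   rule = "trial_maxamp", z = z3[bad3]))
    }
    # rule 4: minimum remaining trials
    if (sum(epochs$keep_trial[, ch]) < min_trials) {
      epochs$keep_channel[ch] <- FALSE
      epochs$keep_trial[, ch] <- FALSE
      log <- rbind(log, data.frame(trial = NA_integer_, channel = ch,
                                   rule = "min_trials", z = NA_real_))
    }
  }
  if (!any(epochs$keep_channel)) {
    stopf("reject_artifacts: all channels rejected")
  }
  epochs$log <- log
  epochs
}

#' Gram-Schmidt local re-referencing
#'
#' For each channel x, the mean r of its surviving same-bundle neighbours is
#' computed per trial and the projection of x onto r is subtracted:
#' \eqn{x' = x - \frac{\langle x, r\rangle}{\langle r, r\rangle} r}. The
#' output is orthogonal to the neighbour mean, removing signal components
#' shared across the bundle (such as volume conduction) without blindly
#' injecting the reference's noise. Channels without surviving neighbours
#' are dropped and logged.
#'
#' @param epochs an `sfc_epochs` object (after [reject_artifacts()]).
#' @return the re-referenced `sfc_epochs`.
#' @export
gram_schmidt_rereference <- function(epochs) {
  stopifnot(inherits(epochs, "sfc_epochs"))
  n_tr <- dim(epochs$lfp)[1]
  out <- epochs$lfp
  bundles <- epochs$bundle_of
  for (ch in which(epochs$keep_channel)) {
    nb <- which(bundles == bundles[ch] & epochs$keep_channel)
    nb <- setdiff(nb, ch)
    if (!length(nb)) {
      epochs$keep_channel[ch] <- FALSE
      epochs$keep_trial[, ch] <- FALSE
      epochs$log <- rbind(epochs$log,
                          data.frame(trial = NA_integer_, channel = ch,
                                     rule = "no_reference_neighbor",
                                     z = NA_real_))
      next
    }
    for (tr in seq_len(n_tr)) {
      x <- epochs$lfp[tr, , ch]
      r <- if (length(nb) == 1L) epochs$lfp[tr, , nb] else
        rowMeans(matrix(epochs$lfp[tr, , nb], ncol = length(nb)))
      rr <- sum(r * r)
      out[tr, , ch] <- if (rr > 0) x - (sum(x * r) / rr) * r else x
    }
  }
  epochs$lfp <- out
  epochs
}
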