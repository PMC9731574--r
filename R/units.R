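# Unit-level operations: inclusion gating, single-/multi-unit
# classification from waveform variability and inter-spike intervals, and
# normalized spike-density time series.

#' Fraction of inter-spike intervals violating the refractory period
#'
#' ISIs are computed within trials (never across trial boundaries).
#'
#' @param spikes list of per-trial spike-time vectors (s).
#' @param threshold_ms refractory threshold (ms), default 3.
#' @return fraction of ISIs below `threshold_ms` (0 when fewer than 2
#'   spikes exist in every trial).
#' @export
isi_violation_rate <- function(spikes, threshold_ms = 3) {
  isis <- unlist(lapply(spikes, function(s) if (length(s) > 1) diff(sort(s))))
  if (!length(isis)) return(0)
  mean(isis < threshold_ms / 1000)
}

#' Unit inclusion rule
#'
#' A unit enters the analysis only if it fired at least `min_spikes` spikes
#' in hits or in misses, with a mean per-trial spike count above 2 and a
#' mean firing rate above 1 Hz, all evaluated in the encoding window
#' (0-4 s). All inequalities are strict except the spike-count floor
#' (>= 50).
#'
#' @param spikes list of per-trial spike-time vectors (s relative to cue).
#' @param labels factor of trial conditions (`hit`/`miss`).
#' @param window encoding window (s), default `c(0, 4)`.
#' @param min_spikes minimum spikes in either condition, default 50.
#' @return logical.
#' @export
unit_inclusion <- function(spikes, labels, window = c(0, 4),
                           min_spikes = 50) {
  if (is.null(labels) || length(labels) != length(spikes)) {
    stopf("unit_inclusion: labels must match the number of trials")
  }
  counts <- vapply(spikes, function(s) {
    sum(s >= window[1] & s <= window[2])
  }, numeric(1))
  n_hit <- sum(counts[labels == "hit"])
  n_miss <- sum(counts[labels == "miss"])
  mean_count <- mean(counts)
  mean_rate <- mean_count / diff(window)
  (n_hit >= min_spikes || n_miss >= min_spikes) &&
    mean_count > 2 && mean_rate > 1
}

#' Rise window of a mean spike waveform
#'
#' The end of the rise is the waveform peak; the start is the sample of
#' maximum curvature (second derivative) in the region preceding the peak.
#'
#' @param m numeric vector, the across-spike mean waveform.
#' @return list with integer sample indices `t_i` (rise start) and `t_j`
#'   (peak).
#' @export
rise_window <- function(m) {
  n <- length(m)
  if (n < 5L) stopf("rise_window: waveform too short")
  if (max(m) - min(m) <= 0) stopf("rise_window: flat waveform, no peak")
  t_j <- which.max(m)
  if (t_j <= 3L || t_j == n) {
    stopf("rise_window: no detectable interior peak (monotone waveform?)")
  }
  # discrete second derivative on the pre-peak region
  idx <- 2:(t_j - 1)
  curv <- m[idx + 1] - 2 * m[idx] + m[idx - 1]
  t_i <- idx[which.max(curv)]
  list(t_i = t_i, t_j = t_j)
}

#' Waveform-variability criterion c2
#'
#' The across-spike standard deviation summed over the rise window, divided
#' by the spike height:
#' \deqn{c_2 = \frac{\sum_{t = t_i}^{t_j} s(t)}{m(t_j) - m(t_i)}}
#' where s(t) is the per-sample SD across spikes and m the mean waveform.
#' Low values indicate a homogeneous waveshape, i.e. a putative single
#' unit. c2 is invariant under global amplitude rescaling.
#'
#' @param waveforms numeric matrix, spikes x samples.
#' @param rise list `(t_i, t_j)` from [rise_window()]; computed from the
#'   mean waveform when missing.
#' @return c2 (dimensionless, >= 0).
#' @export
waveform_variability_c2 <- function(waveforms, rise = NULL) {
  if (nrow(waveforms) < 2L) stopf("waveform_variability_c2: need >= 2 spikes")
  m <- colMeans(waveforms)
  rise <- rise %||% rise_window(m)
  height <- m[rise$t_j] - m[rise$t_i]
  if (height <= 0) stopf("waveform_variability_c2: invalid rise window")
  s <- apply(waveforms[, rise$t_i:rise$t_j, drop = FALSE], 2, stats::sd)
  sum(s) / height
}

#' Classify a unit as single unit (SU) or multi unit (MU)
#'
#' MU if more than 1% of ISIs violate the 3 ms refractory period or if the
#' waveform-variability criterion c2 is 3 or larger; SU otherwise (c2
#' strictly below 3, violations at most 1%).
#'
#' @param isi_rate ISI violation rate in `[0, 1]`.
#' @param c2 waveform-variability criterion.
#' @return `"SU"` or `"MU"`.
#' @export
classify_unit <- function(isi_rate, c2) {
  if (isi_rate < 0 || isi_rate > 1 || c2 < 0) {
    stopf("classify_unit: invalid inputs")
  }
  if (isi_rate > 0.01 || c2 >= 3) "MU" else "SU"
}

#' Classification table for a session's units
#'
#' Runs [isi_violation_rate()], [waveform_variability_c2()],
#' [classify_unit()] and [unit_inclusion()] over all units of a session.
#'
#' @param session an `sfc_session`.
#' @return data.frame: unit_id, n_spikes, isi_violation_rate, c2, label,
#'   included.
#' @export
unit_table <- function(session) {
  validate_session(session)
  rows <- lapply(session$units, function(u) {
    c2 <- tryCatch(waveform_variability_c2(u$waveforms),
                   error = function(e) NA_real_)
    isi <- isi_violation_rate(u$spikes)
    data.frame(unit_id = u$unit_id,
               n_spikes = sum(lengths(u$spikes)),
               isi_violation_rate = isi,
               c2 = c2,
               label = if (is.na(c2)) "rejected" else classify_unit(isi, c2),
               included = unit_inclusion(u$spikes, session$labels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized spike-density time series
#'
#' Per-trial binary spike series convolved with a Gaussian kernel
#' (`kernel_len` support, sigma = support/6) and converted to rate (Hz).
#' The condition-average density is z-normalized against the pre-cue
#' baseline with a regularized SD:
#' \deqn{z(t) = \frac{sd(t) - \mu_{bl}}{\sigma_{bl} + \lambda}}
#' where the baseline statistics are taken over the baseline window of the
#' condition average and \eqn{\lambda} (default 0.1) keeps z finite for
#' silent baselines.
#'
#' @param spikes list of per-trial spike times (s relative to cue).
#' @param t epoch time axis (s), e.g. `seq(-7, 7, by = 1/1000)`.
#' @param fs sampling rate (Hz).
#' @param labels optional trial condition factor; when given, `z` is a
#'   matrix with one column per condition.
#' @param kernel_len Gaussian kernel support (s), default 0.25.
#' @param lambda regularization constant, default 0.1.
#' @param baseline baseline window (s), default `c(-1, -0.125)` (the upper
#'   edge is half the kernel length before the cue).
#' @return list with per-trial densities `sd_trial` (Hz), condition/overall
#'   averages `sd`, normalized `z`, and the baseline statistics.
#' @export
spike_density <- function(spikes, t, fs, labels = NULL, kernel_len = 0.25,
                          lambda = 0.1, baseline = c(-1, -0.125)) {
  bl <- t >= baseline[1] & t <= baseline[2]
  if (!any(bl)) stopf("spike_density: baseline window outside epoch")
  k <- gauss_kernel(kernel_len, fs)
  bin <- t(vapply(spikes, function(s) bin_spikes(s, t, fs), numeric(length(t))))
  dens <- conv_rows_same(bin, k)
  groups <- if (is.null(labels)) {
    list(all = seq_along(spikes))
  } else {
    split(seq_along(spikes), labels)
  }
  sd_avg <- sapply(groups, function(ix) {
    if (!length(ix)) rep(NA_real_, length(t))
    else colMeans(dens[ix, , drop = FALSE])
  })
  mu_bl <- apply(sd_avg, 2, function(v) mean(v[bl]))
  sigma_bl <- apply(sd_avg, 2, function(v) stats::sd(v[bl]))
  z <- sweep(sweep(sd_avg, 2, mu_bl, `-`), 2, sigma_bl + lambda, `/`)
  list(t = t, sd_trial = dens, sd = sd_avg, z = z,
       mu_bl = mu_bl, sigma_bl = sigma_bl, lambda = lambda)
}

#' Power spectrum of a spike train's density
#'
#' Spike series are convolved with a short Gaussian kernel (25 ms support),
#' restricted to the analysis window, Hann-tapered and Fourier transformed
#' per trial; power is averaged over trials and smoothed over +/- `smooth_hz`
#' Hz. Used to probe for oscillatory rhythmicity in the spiking itself.
#'
#' @param spikes list of per-trial spike times (s relative to cue).
#' @param t epoch time axis (s).
#' @param fs sampling rate (Hz).
#' @param window analysis window (s), default `c(2, 3)`.
#' @param kernel_len density kernel support (s), default 0.025.
#' @param smooth_hz half-width of the spectral smoothing (Hz), default 2.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
spike_train_spectrum <- function(spikes, t, fs, window = c(2, 3),
                                 kernel_len = 0.025, smooth_hz = 2) {
  win <- t >= window[1] & t < window[2]
  if (!any(win)) stopf("spike_train_spectrum: window outside epoch")
  k <- gauss_kernel(kernel_len, fs)
  bin <- t(vapply(spikes, function(s) bin_spikes(s, t, fs), numeric(length(t))))
  dens <- conv_rows_same(bin, k)[, win, drop = FALSE]
  n <- ncol(dens)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  freq <- (0:(n - 1)) * fs / n
  keep <- freq <= fs / 2
  pow <- rep(0, sum(keep))
  for (i in seq_len(nrow(dens))) {
    x <- dens[i, ]
    x <- (x - mean(x)) * taper
    P <- Mod(stats::fft(x))^2 / n
    pow <- pow + P[keep]
  }
  pow <- pow / nrow(dens)
  # +/- smooth_hz moving average across frequency bins
  df <- fs / n
  half <- round(smooth_hz / df)
  sm <- vapply(seq_along(pow), function(i) {
    mean(pow[max(1, i - half):min(length(pow), i + half)])
  }, numeric(1))
  data.frame(freq = freq[keep], power = sm)
}
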