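# Phase and power estimation: Morlet wavelets (frequency-domain
# implementation), band-pass + analytic-signal phase, power normalization,
# 1/f correction and inter-trial phase consistency.

#' Standard frequency grids
#'
#' The low band covers 2-40 Hz in 1 Hz steps with 6-cycle wavelets; the
#' high band covers 40-80 Hz in 2 Hz steps with 12-cycle wavelets, and the
#' first temporal derivative of the LFP is transformed instead of the raw
#' signal (whitening that counteracts the 1/f power drop-off).
#'
#' @param band `"low"` or `"high"`.
#' @return list with `freqs`, `cycles` and `derivative`.
#' @export
frequency_grid <- function(band = c("low", "high")) {
  band <- match.arg(band)
  if (band == "low") {
    list(band = "low", freqs = 2:40, cycles = 6, derivative = FALSE)
  } else {
    list(band = "high", freqs = seq(40, 80, by = 2), cycles = 12,
         derivative = TRUE)
  }
}

#' Morlet wavelet transform of a single time series
#'
#' Implemented as analytic Gaussian filters in the frequency domain: at
#' each centre frequency f the spectrum is multiplied by
#' \eqn{2\exp\{-(f'-f)^2 / (2\sigma_f^2)\}} over positive frequencies with
#' \eqn{\sigma_f = f / n_{cycles}} (equivalently \eqn{\sigma_t =
#' n_{cycles}/(2\pi f)} in time). The factor 2 makes the coefficient
#' envelope of a unit-amplitude sinusoid equal 1.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param freqs centre frequencies (Hz); must stay below Nyquist.
#' @param n_cycles wavelet width in cycles.
#' @return complex matrix `length(x)` x `length(freqs)`, with attribute
#'   `edge`: per-frequency number of samples at each end inside one
#'   3-sigma_t edge region (flagged invalid for phase use).
#' @export
morlet_tfr <- function(x, fs, freqs, n_cycles) {
  n <- length(x)
  if (any(freqs >= fs / 2)) {
    stopf("morlet_tfr: frequencies above Nyquist (%g Hz)", fs / 2)
  }
  if (any(freqs <= 0)) stopf("morlet_tfr: frequencies must be positive")
  sigma_t <- n_cycles / (2 * pi * freqs)
  L <- next_pow2(n + ceiling(6 * max(sigma_t) * fs))
  X <- stats::fft(c(x, numeric(L - n)))
  fgrid <- (0:(L - 1)) * fs / L
  pos <- fgrid <= fs / 2
  out <- matrix(0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    sigma_f <- freqs[j] / n_cycles
    H <- numeric(L)
    H[pos] <- 2 * exp(-(fgrid[pos] - freqs[j])^2 / (2 * sigma_f^2))
    out[, j] <- (stats::fft(X * H, inverse = TRUE) / L)[seq_len(n)]
  }
  attr(out, "edge") <- ceiling(3 * sigma_t * fs)
  attr(out, "freqs") <- freqs
  out
}

#' Wavelet phase/power stack for epoched data, restricted to a window
#'
#' Computes Morlet coefficients for every trial of one channel on the
#' analysis window plus symmetric padding (3 wavelet sigma_t at the lowest
#' frequency, clipped to the epoch), returning only the window samples so
#' edge artifacts never enter the analysis.
#'
#' @param x matrix trials x time (one channel).
#' @param t epoch time axis (s).
#' @param fs sampling rate (Hz).
#' @param grid a [frequency_grid()] (or compatible list). When
#'   `grid$derivative` is TRUE the first difference scaled by `fs` is
#'   transformed instead of the raw signal.
#' @param window analysis window (s), default `c(2, 3)`.
#' @return list with complex `coef` (trials x window-time x freq),
#'   `freqs`, window time axis `t`, and `fs`.
#' @export
wavelet_phase <- function(x, t, fs, grid, window = c(2, 3)) {
  stopifnot(is.matrix(x), ncol(x) == length(t))
  sigma_max <- grid$cycles / (2 * pi * min(grid$freqs))
  pad <- 3 * sigma_max
  lo <- max(t[1], window[1] - pad)
  hi <- min(t[length(t)], window[2] + pad)
  seg <- which(t >= lo & t <= hi)
  win_in_seg <- which(t[seg] >= window[1] & t[seg] < window[2])
  n_tr <- nrow(x)
  coef <- array(0i, dim = c(n_tr, length(win_in_seg), length(grid$freqs)))
  for (tr in seq_len(n_tr)) {
    s <- x[tr, seg]
    if (isTRUE(grid$derivative)) s <- c(0, diff(s)) * fs
    cf <- morlet_tfr(s, fs, grid$freqs, grid$cycles)
    coef[tr, , ] <- cf[win_in_seg, ]
  }
  list(coef = coef, freqs = grid$freqs, t = t[seg][win_in_seg], fs = fs,
       band = grid$band %||% NA_character_)
}

#' Band-pass + analytic-signal (Hilbert) phase
#'
#' Zero-phase Butterworth band-pass of the stated bandwidth around the
#' centre frequency, followed by the analytic signal. The alternative to
#' wavelet phase used to check robustness against non-stationarity: the
#' wide pass-band (4 Hz low / 8 Hz high) leaves room for instantaneous
#' frequency to fluctuate.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param center centre frequency (Hz).
#' @param bandwidth full pass-band width (Hz): 4 for the low range, 8 for
#'   the high range.
#' @param order Butterworth order, default 2.
#' @return complex vector (envelope x exp(i phase)); zero input yields
#'   zero coefficients (undefined phase).
#' @export
hilbert_phase <- function(x, fs, center, bandwidth = 4, order = 2) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0 || hi >= fs / 2) {
    stopf("hilbert_phase: band [%g, %g] crosses 0 or Nyquist", lo, hi)
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  analytic_signal(xf)
}

#' Trial-level power normalization
#'
#' Power per trial (already averaged over the time window of interest) is
#' z-scored across trials per frequency using the median and SD; trials
#' whose maximum |z| over frequencies exceeds `z_out` are dropped as
#' outliers, and condition means are returned. Zero-variance frequencies
#' yield z = 0 by convention (with a warning).
#'
#' @param power numeric matrix trials x frequencies of time-averaged power.
#' @param labels optional trial condition factor.
#' @param z_out outlier threshold on |z|, default 2.5.
#' @return list with `z` (trials x freq), logical `kept`, and `condition`
#'   (matrix freq x condition of means over kept trials).
#' @export
normalize_power <- function(power, labels = NULL, z_out = 2.5) {
  power <- as.matrix(power)
  med <- apply(power, 2, stats::median)
  sdv <- apply(power, 2, stats::sd)
  zerovar <- sdv == 0
  if (any(zerovar)) {
    warning("normalize_power: zero-variance frequencies set to z = 0")
    sdv[zerovar] <- 1
  }
  z <- sweep(sweep(power, 2, med, `-`), 2, sdv, `/`)
  z[, zerovar] <- 0
  kept <- apply(abs(z), 1, max) <= z_out
  if (!any(kept)) stopf("normalize_power: all trials flagged as outliers")
  groups <- if (is.null(labels)) list(all = seq_len(nrow(power)))
            else split(seq_len(nrow(power)), labels)
  cond <- sapply(groups, function(ix) {
    ix <- ix[kept[ix]]
    if (!length(ix)) rep(NA_real_, ncol(power))
    else colMeans(z[ix, , drop = FALSE])
  })
  list(z = z, kept = kept, condition = cond)
}

#' 1/f correction of a power spectrum
#'
#' Fits a line to the log-log spectrum, subtracts it, back-transforms to
#' linear space, optionally centres the frequency axis at a peak frequency,
#' and z-normalizes across the spectrum. Isolates narrow-band bumps from
#' the broadband background.
#'
#' @param freq frequencies (Hz), >= 5 points.
#' @param power positive power values.
#' @param peak_freq optional centring frequency (Hz).
#' @return data.frame with `freq`, `rel_freq` (freq - peak), `corrected`
#'   (z-normalized residual power) and `residual_log` (log-space residual).
#' @export
one_over_f_correct <- function(freq, power, peak_freq = NULL) {
  if (length(freq) < 5L) stopf("one_over_f_correct: need >= 5 frequencies")
  if (any(power <= 0)) stopf("one_over_f_correct: power must be positive")
  lf <- log10(freq); lp <- log10(power)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  resid_log <- lp - cbind(1, lf) %*% fit$coefficients
  lin <- 10^resid_log
  z <- (lin - mean(lin)) / stats::sd(lin)
  data.frame(freq = freq,
             rel_freq = if (is.null(peak_freq)) freq else freq - peak_freq,
             corrected = as.vector(z),
             residual_log = as.vector(resid_log))
}

#' Inter-trial phase consistency (PPC across trials)
#'
#' Pairwise phase consistency computed across trials at each time-frequency
#' point, per condition: the across-trials analogue of spike-field PPC,
#' quantifying stimulus-locked phase alignment.
#'
#' @param coef complex array trials x time x freq (e.g. from
#'   [wavelet_phase()]).
#' @param labels optional trial condition factor; >= 2 trials required per
#'   condition.
#' @return array time x freq (x condition when `labels` given).
#' @export
itpc <- function(coef, labels = NULL) {
  stopifnot(length(dim(coef)) == 3L)
  groups <- if (is.null(labels)) list(all = seq_len(dim(coef)[1]))
            else split(seq_len(dim(coef)[1]), labels)
  nt <- dim(coef)[2]; nf <- dim(coef)[3]
  out <- array(NA_real_, dim = c(nt, nf, length(groups)),
               dimnames = list(NULL, NULL, names(groups)))
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    if (length(ix) < 2L) stopf("itpc: need >= 2 trials per condition")
    ph <- coef[ix, , , drop = FALSE]
    u <- ph / Mod(ph)
    u[Mod(ph) == 0] <- 0
    n <- length(ix)
    S2 <- Mod(apply(u, c(2, 3), sum))^2
    out[, , g] <- (S2 - n) / (n * (n - 1))
  }
  if (is.null(labels)) out[, , 1] else out
}
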