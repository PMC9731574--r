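# Spike-field coupling: phase extraction at spike times, Rayleigh + FDR
# screening, PPC spectra per condition, shuffle-based pair-count null,
# condition contrasts, peak-frequency analysis and the selection-bias
# control.

#' Phases of an LFP at a unit's spike times
#'
#' Extracts, for every spike inside the analysis window, the LFP phase at
#' every frequency of a wavelet (or Hilbert) stack.
#'
#' @param spikes list of per-trial spike times (s relative to cue).
#' @param wp a [wavelet_phase()] result for the LFP channel (same trials).
#' @param labels optional trial condition factor.
#' @return an `spike_phase_set`: `phases` (spikes x freq), `freqs`,
#'   per-spike `trial` and `cond`, per-spike sample index `it`, and spike
#'   counts per condition.
#' @export
spike_phase_set <- function(spikes, wp, labels = NULL) {
  n_tr <- dim(wp$coef)[1]
  if (length(spikes) != n_tr) {
    stopf("spike_phase_set: %d spike trials vs %d LFP trials",
          length(spikes), n_tr)
  }
  n_t <- dim(wp$coef)[2]
  tr_idx <- integer(0); it_idx <- integer(0)
  for (tr in seq_len(n_tr)) {
    s <- spikes[[tr]]
    s <- s[s >= wp$t[1] & s <= wp$t[n_t]]
    it <- time_to_index(s, wp$t[1], wp$fs, n_t)
    it <- it[!is.na(it)]
    tr_idx <- c(tr_idx, rep(tr, length(it)))
    it_idx <- c(it_idx, it)
  }
  nf <- length(wp$freqs)
  ph <- matrix(NA_real_, length(tr_idx), nf)
  if (length(tr_idx)) {
    flat <- Arg(wp$coef)
    base <- tr_idx + (it_idx - 1) * n_tr
    offs <- (seq_len(nf) - 1) * n_tr * n_t
    ph <- matrix(flat[outer(base, offs, `+`)], length(tr_idx), nf)
  }
  cond <- if (is.null(labels)) factor(rep("all", length(tr_idx)))
          else factor(as.character(labels)[tr_idx], levels = levels(labels))
  structure(list(phases = ph, freqs = wp$freqs, trial = tr_idx, it = it_idx,
                 cond = cond, n = length(tr_idx),
                 n_cond = table(cond)),
            class = "spike_phase_set")
}

#' Rayleigh screening with FDR correction across frequencies
#'
#' Rayleigh test of circular uniformity at every frequency,
#' Benjamini-Hochberg corrected across the frequencies of the band; the
#' spike-LFP pair is flagged significant if any corrected p falls below
#' `alpha`. Pairs with fewer than `min_spikes` spikes are excluded (flagged,
#' not an error).
#'
#' @param pset a [spike_phase_set()].
#' @param alpha FDR level, default 0.05.
#' @param min_spikes minimum spike count, default 30.
#' @return list with per-frequency `table` (freq, Rbar, z, p, p_fdr),
#'   `significant`, `excluded`, and `n`.
#' @export
rayleigh_fdr_screen <- function(pset, alpha = 0.05, min_spikes = 30) {
  stopifnot(inherits(pset, "spike_phase_set"))
  if (pset$n < min_spikes) {
    return(list(table = NULL, significant = FALSE, excluded = TRUE,
                n = pset$n))
  }
  n <- pset$n
  C <- colSums(cos(pset$phases)); S <- colSums(sin(pset$phases))
  Rbar <- sqrt(C^2 + S^2) / n
  z <- n * Rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p_fdr <- stats::p.adjust(p, method = "BH")
  list(table = data.frame(freq = pset$freqs, Rbar = Rbar, z = z, p = p,
                          p_fdr = p_fdr),
       significant = any(p_fdr < alpha), excluded = FALSE, n = n)
}

#' PPC spectrum per condition
#'
#' @param pset a [spike_phase_set()] built with trial labels.
#' @param min_spikes minimum spikes per condition for that condition's
#'   spectrum (conditions below the floor yield NA), default 2 -- callers
#'   enforce the 30-spike analysis threshold.
#' @return data.frame: freq, ppc_all and one `ppc_<cond>` column per
#'   condition.
#' @export
ppc_spectrum <- function(pset, min_spikes = 2) {
  stopifnot(inherits(pset, "spike_phase_set"))
  out <- data.frame(freq = pset$freqs)
  out$ppc_all <- if (pset$n >= 2) ppc_cols(pset$phases) else NA_real_
  for (lev in levels(pset$cond)) {
    ix <- pset$cond == lev
    out[[paste0("ppc_", lev)]] <- if (sum(ix) >= max(2, min_spikes)) {
      ppc_cols(pset$phases[ix, , drop = FALSE])
    } else NA_real_
  }
  out
}

#' Detect the peak of a PPC spectrum in a band
#'
#' Local maxima inside the band are located; the largest one above
#' `threshold` wins, ties broken toward the lower frequency.
#'
#' @param freqs frequencies (Hz).
#' @param values PPC values.
#' @param band search band (Hz), e.g. `c(3, 13)` for theta or `c(45, 75)`
#'   for gamma.
#' @param threshold minimum peak PPC, default 0.005.
#' @return list `(freq, value)` or `NULL` when no qualifying peak exists.
#' @export
find_ppc_peak <- function(freqs, values, band, threshold = 0.005) {
  if (all(is.na(values))) return(NULL)
  # peaks are local maxima of the full spectrum (so a band-edge frequency
  # can still qualify), restricted to the search band afterwards
  pk <- pracma::findpeaks(values)
  if (is.null(pk)) return(NULL)
  fpk <- freqs[pk[, 2]]
  keep <- pk[, 1] > threshold & fpk >= band[1] & fpk <= band[2]
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(NULL)
  best <- which(pk[, 1] == max(pk[, 1]))
  if (length(best) > 1L) best <- best[which.min(pk[best, 2])]
  list(freq = freqs[pk[best, 2]], value = pk[best, 1])
}

#' Per-pair peak-frequency shift between conditions
#'
#' For each pair, the PPC peak frequency is extracted per condition inside
#' the band (peaks must exceed the PPC threshold in *both* conditions,
#' otherwise the pair is excluded), and the across-pairs paired t-test of
#' hit versus miss peak frequencies is returned.
#'
#' @param spectra list of per-pair [ppc_spectrum()] data.frames (with
#'   `ppc_hit`/`ppc_miss` columns).
#' @param band peak search band (Hz).
#' @param threshold PPC peak threshold, default 0.005.
#' @return list with per-pair `peaks` (peak_hit, peak_miss), the paired
#'   `test` (htest or NULL), `mean_shift` (hit - miss, Hz) and `n_used`.
#' @export
peak_frequency_shift <- function(spectra, band, threshold = 0.005) {
  peaks <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    ph <- find_ppc_peak(sp$freq, sp$ppc_hit, band, threshold)
    pm <- find_ppc_peak(sp$freq, sp$ppc_miss, band, threshold)
    data.frame(pair = i,
               peak_hit = if (is.null(ph)) NA_real_ else ph$freq,
               peak_miss = if (is.null(pm)) NA_real_ else pm$freq,
               ppc_peak_hit = if (is.null(ph)) NA_real_ else ph$value,
               ppc_peak_miss = if (is.null(pm)) NA_real_ else pm$value)
  }))
  ok <- stats::complete.cases(peaks[, c("peak_hit", "peak_miss")])
  test <- NULL
  if (sum(ok) >= 2 &&
      stats::sd(peaks$peak_hit[ok] - peaks$peak_miss[ok]) > 0) {
    test <- stats::t.test(peaks$peak_hit[ok], peaks$peak_miss[ok],
                          paired = TRUE)
  }
  list(peaks = peaks, test = test,
       mean_shift = mean(peaks$peak_hit[ok] - peaks$peak_miss[ok]),
       n_used = sum(ok))
}

#' Across-pairs condition contrast of PPC spectra
#'
#' Per frequency, a paired t-test of hit versus miss PPC across pairs,
#' FDR-corrected across frequencies.
#'
#' @param spectra list of per-pair [ppc_spectrum()] data.frames.
#' @param alpha FDR level, default 0.05.
#' @return data.frame: freq, mean_hit, mean_miss, diff, t, p, p_fdr,
#'   significant; pairs with NA in either condition are dropped per test.
#' @export
condition_contrast <- function(spectra, alpha = 0.05) {
  freqs <- spectra[[1]]$freq
  H <- sapply(spectra, function(s) s$ppc_hit)
  M <- sapply(spectra, function(s) s$ppc_miss)
  H <- matrix(H, nrow = length(freqs)); M <- matrix(M, nrow = length(freqs))
  res <- lapply(seq_along(freqs), function(i) {
    h <- H[i, ]; m <- M[i, ]
    ok <- !is.na(h) & !is.na(m)
    if (sum(ok) < 2 || stats::sd(h[ok] - m[ok]) == 0) {
      return(data.frame(freq = freqs[i], mean_hit = mean(h, na.rm = TRUE),
                        mean_miss = mean(m, na.rm = TRUE),
                        diff = NA_real_, t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(h[ok], m[ok], paired = TRUE)
    data.frame(freq = freqs[i], mean_hit = mean(h[ok]),
               mean_miss = mean(m[ok]), diff = mean(h[ok] - m[ok]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out
}

# --- session-level screening ----------------------------------------------

# Closure-based fast phase lookup for one channel stack: given a trial
# permutation, returns the spikes x freq phase matrix of (spike trial i,
# LFP trial perm[i]).
phase_lookup <- function(wp, tr_idx, it_idx) {
  flat <- Arg(wp$coef)
  n_tr <- dim(wp$coef)[1]; n_t <- dim(wp$coef)[2]; nf <- length(wp$freqs)
  base <- (it_idx - 1) * n_tr
  offs <- (seq_len(nf) - 1) * n_tr * n_t
  base_mat <- outer(base, offs, `+`)
  function(perm) {
    matrix(flat[base_mat + perm[tr_idx]], length(tr_idx), nf)
  }
}

#' Screen all spike-LFP pairs of a session
#'
#' For every unit x channel pair: wavelet phases at spike times in the
#' analysis window, Rayleigh + FDR screening, condition PPC spectra, and a
#' trial-shuffle null for the *count* of significant pairs. The null is
#' built by re-running the identical screening on `n_shuffles` random
#' spike/LFP trial pairings per pair (condition trial counts unchanged) and
#' then drawing `n_draws` session-level samples of the significant-pair
#' count, separately for local (same-bundle) and distal pairs.
#'
#' @param session an `sfc_session` (cleaned).
#' @param band `"low"` (2-40 Hz) or `"high"` (40-80 Hz; LFP derivative).
#' @param window analysis window (s), default `c(2, 3)`.
#' @param min_spikes screening spike floor, default 30.
#' @param alpha FDR level, default 0.05.
#' @param n_shuffles trial shuffles per pair, default 100.
#' @param n_draws samples of the pair-count null, default 10000.
#' @param keep_channel optional logical mask of channels to use.
#' @param seed integer seed for the shuffles.
#' @return an `sfc_screen` list: `pairs` table, per-pair `spectra`,
#'   per-pair `phase_sets`, and `null` (distributions and p-values for the
#'   local / distal significant-pair counts).
#' @export
sfc_screen <- function(session, band = c("high", "low"), window = c(2, 3),
                       min_spikes = 30, alpha = 0.05, n_shuffles = 100,
                       n_draws = 10000, keep_channel = NULL, seed = NULL) {
  validate_session(session)
  band <- match.arg(band)
  grid <- frequency_grid(band)
  n_tr <- dim(session$lfp)[1]
  channels <- session$channels
  use_ch <- keep_channel %||% rep(TRUE, nrow(channels))

  pair_rows <- list(); spectra <- list(); phase_sets <- list()
  shuffle_sig <- list()
  with_seed(seed, {
    perms <- replicate(n_shuffles, sample.int(n_tr), simplify = FALSE)
    for (ch in channels$channel[use_ch]) {
      wp <- wavelet_phase(matrix(session$lfp[, , ch], nrow = n_tr),
                          session$t, session$fs, grid, window)
      for (u in session$units) {
        pset <- spike_phase_set(u$spikes, wp, session$labels)
        key <- paste(u$unit_id, ch, sep = "|")
        scr <- rayleigh_fdr_screen(pset, alpha, min_spikes)
        same_bundle <- u$bundle == channels$bundle[channels$channel == ch]
        locality <- if (!same_bundle) "distal"
                    else if (u$channel == ch) "same_wire" else "local_bundle"
        sp <- ppc_spectrum(pset, min_spikes = 2)
        pair_rows[[key]] <- data.frame(
          unit_id = u$unit_id, channel = ch,
          locality = locality,
          local = same_bundle,
          n_spikes = pset$n,
          n_hit = as.integer(pset$n_cond["hit"] %||% 0L),
          n_miss = as.integer(pset$n_cond["miss"] %||% 0L),
          excluded = scr$excluded,
          p_fdr_min = if (scr$excluded) NA_real_ else min(scr$table$p_fdr),
          significant = scr$significant)
        spectra[[key]] <- sp
        phase_sets[[key]] <- pset
        # shuffle screening for the pair-count null
        if (!scr$excluded) {
          lk <- phase_lookup(wp, pset$trial, pset$it)
          shuffle_sig[[key]] <- vapply(perms, function(pm) {
            ph <- lk(pm)
            p <- rayleigh_p_cols(ph)
            any(stats::p.adjust(p, "BH") < alpha)
          }, logical(1))
        } else {
          shuffle_sig[[key]] <- rep(FALSE, n_shuffles)
        }
      }
    }
    pairs <- do.call(rbind, pair_rows)
    rownames(pairs) <- NULL

    null_for <- function(sel) {
      if (!any(sel)) {
        return(list(observed = 0L, counts = integer(n_draws), p = 1))
      }
      sig_mat <- do.call(rbind, shuffle_sig[which(sel)])
      draws <- matrix(sample.int(n_shuffles, sum(sel) * n_draws,
                                 replace = TRUE), nrow = sum(sel))
      counts <- colSums(matrix(
        sig_mat[cbind(rep(seq_len(sum(sel)), n_draws), as.vector(draws))],
        nrow = sum(sel)))
      obs <- sum(pairs$significant[sel])
      list(observed = obs, counts = counts,
           p = (1 + sum(counts >= obs)) / (n_draws + 1))
    }
    null <- list(local = null_for(pairs$local & !pairs$excluded),
                 distal = null_for(!pairs$local & !pairs$excluded))

    structure(list(pairs = pairs, spectra = spectra,
                   phase_sets = phase_sets, null = null, band = band,
                   freqs = grid$freqs, window = window, alpha = alpha),
              class = "sfc_screen")
  })
}

#' Selection-bias control for condition PPC
#'
#' Re-runs the screening-then-PPC procedure on shuffled spike/LFP trial
#' pairings (hit/miss trial counts unchanged): shuffles whose all-trials
#' Rayleigh survives FDR are kept, their pseudo-hit / pseudo-miss PPC
#' spectra form the bias baseline, and the real condition PPC is
#' z-transformed against that baseline. Because the pseudo-conditions
#' inherit the same trial imbalance and the same selection step as the real
#' analysis, the z-values are free of the screening selection bias.
#'
#' @param spikes list of per-trial spike times (s).
#' @param wp a [wavelet_phase()] stack of the LFP channel.
#' @param labels trial condition factor.
#' @param n_shuffles number of shuffles, default 5000.
#' @param alpha FDR level of the screening step.
#' @param min_kept below this number of surviving shuffles a warning is
#'   issued and `wide_ci` is flagged, default 50.
#' @param seed integer seed.
#' @return list with `z` (data.frame freq, z_hit, z_miss), the real
#'   spectra, `n_kept` and `wide_ci`.
#' @export
selection_bias_control <- function(spikes, wp, labels, n_shuffles = 5000,
                                   alpha = 0.05, min_kept = 50,
                                   seed = NULL) {
  pset <- spike_phase_set(spikes, wp, labels)
  if (pset$n < 2) stopf("selection_bias_control: too few spikes")
  real <- ppc_spectrum(pset)
  n_tr <- dim(wp$coef)[1]
  lk <- phase_lookup(wp, pset$trial, pset$it)
  hit_ix <- pset$cond == "hit"; miss_ix <- pset$cond == "miss"
  nf <- length(pset$freqs)
  with_seed(seed, {
    acc_h <- matrix(NA_real_, n_shuffles, nf)
    acc_m <- matrix(NA_real_, n_shuffles, nf)
    kept <- 0L
    for (s in seq_len(n_shuffles)) {
      ph <- lk(sample.int(n_tr))
      p <- rayleigh_p_cols(ph)
      if (any(stats::p.adjust(p, "BH") < alpha)) {
        kept <- kept + 1L
        if (sum(hit_ix) >= 2) {
          acc_h[kept, ] <- ppc_cols(ph[hit_ix, , drop = FALSE])
        }
        if (sum(miss_ix) >= 2) {
          acc_m[kept, ] <- ppc_cols(ph[miss_ix, , drop = FALSE])
        }
      }
    }
    wide_ci <- kept < min_kept
    if (wide_ci) {
      warning(sprintf(
        "selection_bias_control: only %d of %d shuffles kept; z baseline noisy",
        kept, n_shuffles))
    }
    zfun <- function(real_v, acc) {
      if (kept < 2) return(rep(NA_real_, nf))
      mu <- colMeans(acc[seq_len(kept), , drop = FALSE], na.rm = TRUE)
      sdv <- apply(acc[seq_len(kept), , drop = FALSE], 2, stats::sd,
                   na.rm = TRUE)
      (real_v - mu) / sdv
    }
    list(z = data.frame(freq = pset$freqs,
                        z_hit = zfun(real$ppc_hit, acc_h),
                        z_miss = zfun(real$ppc_miss, acc_m)),
         real = real, n_kept = kept, wide_ci = wide_ci)
  })
}
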