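# Session container and the full synthetic-session generator.
#
# A session bundles everything one recording contributes to the pipeline:
# epoched LFP (trials x time x channels, -7..+7 s around cue at 1 kHz),
# per-unit spike trains and waveforms, hit/miss trial labels and channel ->
# microwire-bundle metadata. Synthetic sessions additionally carry the
# generator's hidden parameters (`ground_truth`) for recovery tests.

#' Design of a synthetic session
#'
#' Defines the condition-dependent ground truth of a synthetic session: the
#' theta/gamma frequencies spikes lock to, phase-amplitude coupling depth and
#' the sender-to-receiver co-firing lag, for hits and misses separately. The
#' defaults are the headline scenario the analysis is meant to recover:
#' hits lock at faster theta (8 Hz) and gamma (70 Hz) than misses (5 Hz,
#' 62 Hz), theta-gamma coupling is present for hits only, and co-firing lags
#' are 20 ms for hits versus 60 ms for misses.
#'
#' @param n_hits,n_misses number of hit / miss trials.
#' @param n_bundles number of microwire bundles (regions). The first bundle
#'   houses the sender unit, the second the receiver unit and the LFP both
#'   units couple to.
#' @param wires_per_bundle microwires per bundle.
#' @param theta_freq,gamma_freq named numeric `c(hit=, miss=)` locking
#'   frequencies (Hz).
#' @param pac_depth named numeric `c(hit=, miss=)` theta-gamma coupling
#'   depth in `[0, 1]`.
#' @param cofire_lag named numeric `c(hit=, miss=)` sender-to-receiver lag
#'   (ms).
#' @param sender_lead_ms named numeric `c(hit=, miss=)`: how far the sender
#'   unit's spikes lead the distal theta LFP (ms); a positive lead makes
#'   the spike signal the upstream sender for the phase-slope-index
#'   analysis.
#' @param cofire_jitter_sd jitter of induced receiver spikes (ms).
#' @param copy_prob probability a sender spike induces a receiver spike.
#' @param theta_kappa,gamma_kappa von-Mises concentration of the sender's
#'   theta locking and the receiver's gamma locking.
#' @param sender_rate,receiver_rate,background_rate unit firing rates (Hz).
#' @param noise_sd_white,noise_sd_pink per-wire noise SDs (white and 1/f).
#' @param gamma_amp gamma amplitude relative to theta (theta amplitude 1).
#' @param seed integer seed; regeneration from `(design, seed)` is
#'   bit-identical.
#' @return a `session_design` list.
#' @export
session_design <- function(n_hits = 30, n_misses = 20,
                           n_bundles = 2, wires_per_bundle = 4,
                           theta_freq = c(hit = 8, miss = 5),
                           gamma_freq = c(hit = 70, miss = 62),
                           pac_depth = c(hit = 0.6, miss = 0),
                           cofire_lag = c(hit = 20, miss = 60),
                           sender_lead_ms = c(hit = 30, miss = 0),
                           cofire_jitter_sd = 5,
                           copy_prob = 0.35,
                           theta_kappa = 2, gamma_kappa = 1.5,
                           sender_rate = 10, receiver_rate = 10,
                           background_rate = 12,
                           noise_sd_white = 0.5, noise_sd_pink = 0.5,
                           gamma_amp = 0.5,
                           seed = 1L) {
  for (nm in c("theta_freq", "gamma_freq", "pac_depth", "cofire_lag")) {
    v <- get(nm)
    if (!all(c("hit", "miss") %in% names(v))) {
      stopf("session_design: %s needs named entries 'hit' and 'miss'", nm)
    }
  }
  if (n_hits < 0 || n_misses < 0 || n_hits + n_misses == 0) {
    stopf("session_design: need at least one trial")
  }
  if (n_bundles < 2) stopf("session_design: need >= 2 bundles")
  structure(as.list(environment()), class = "session_design")
}

# 1/f (pink) noise of length n with unit SD, shaped in the frequency domain.
pink_noise <- function(n, fs) {
  if (n == 0L) return(numeric(0))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)    # symmetric (two-sided) frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Biphasic-looking mean waveform template on `n` samples: Gaussian bump.
wave_template <- function(n = 48, amp = 80, peak = 18, sigma = 3) {
  s <- seq_len(n)
  amp * exp(-(s - peak)^2 / (2 * sigma^2))
}

#' Generate a synthetic session
#'
#' Builds a full session from a [session_design()]: per bundle and trial a
#' non-stationary theta oscillation (condition-dependent mean frequency) and
#' a gamma oscillation whose envelope is locked to theta phase
#' (condition-dependent depth), mixed onto each microwire with wire-specific
#' gains plus white and 1/f noise; a "sender" unit in bundle 1 whose spikes
#' lock to the *distal* theta phase of bundle 2; a "receiver" unit in bundle
#' 2 locked to its local gamma phase, which additionally repeats sender
#' spikes at the condition's co-firing lag; and an unlocked multi-unit-like
#' background train. Spike waveforms are drawn around a common template with
#' unit-specific variability so the single-/multi-unit classifier has
#' something to do.
#'
#' @param design a [session_design()].
#' @return an `sfc_session` object: `lfp` (trials x time x channels), time
#'   axis `t` (-7..7 s at `fs` = 1000 Hz), `channels`, `units`, `labels`
#'   and `ground_truth`.
#' @export
gen_session <- function(design) {
  stopifnot(inherits(design, "session_design"))
  d <- design
  fs <- 1000
  t <- seq(-7, 7, by = 1 / fs)
  n_t <- length(t)
  n_trials <- d$n_hits + d$n_misses
  n_ch <- d$n_bundles * d$wires_per_bundle
  channels <- data.frame(
    channel = seq_len(n_ch),
    bundle = rep(seq_len(d$n_bundles), each = d$wires_per_bundle),
    wire = rep(seq_len(d$wires_per_bundle), d$n_bundles)
  )
  labels <- factor(rep(c("hit", "miss"), c(d$n_hits, d$n_misses)),
                   levels = c("hit", "miss"))

  with_seed(d$seed, {
    # fixed per-wire mixing gains and phase offsets. The offsets matter:
    # perfectly in-phase bundle oscillations would be annihilated by the
    # Gram-Schmidt re-referencing, whereas real wires see the rhythm with
    # wire-to-wire phase shifts, so a phase-shifted residual survives local
    # re-referencing (spread offsets symmetrically over ~0.9 pi)
    gain_theta <- stats::runif(n_ch, 0.8, 1.2)
    gain_gamma <- stats::runif(n_ch, 0.8, 1.2)
    W <- d$wires_per_bundle
    phase_off <- rep(((seq_len(W) - (W + 1) / 2) / W) * 1.2 * pi,
                     d$n_bundles)

    lfp <- array(0, dim = c(n_trials, n_t, n_ch))
    theta_phase <- array(0, dim = c(n_trials, n_t, d$n_bundles))
    gamma_phase <- array(0, dim = c(n_trials, n_t, d$n_bundles))

    for (tr in seq_len(n_trials)) {
      cond <- as.character(labels[tr])
      fth <- d$theta_freq[[cond]]
      fga <- d$gamma_freq[[cond]]
      depth <- d$pac_depth[[cond]]
      for (b in seq_len(d$n_bundles)) {
        th <- gen_nonstationary_oscillator(oscillator_spec(
          mean_freq = fth, freq_range = c(max(fth - 2, 0.5), fth + 2),
          freq_walk_sd = 0.04, duration = n_t / fs, fs = fs))
        ga <- gen_nonstationary_oscillator(oscillator_spec(
          mean_freq = fga, freq_range = c(fga - 3, fga + 3),
          freq_walk_sd = 0.05, duration = n_t / fs, fs = fs))
        th_phase <- th$phase[seq_len(n_t)]
        ga_phase <- ga$phase[seq_len(n_t)]
        env <- 1 + depth * cos(th_phase - (-pi))  # gamma max at theta trough
        theta_phase[tr, , b] <- th_phase
        gamma_phase[tr, , b] <- ga_phase
        shared_bb <- pink_noise(n_t, fs)  # volume-conducted broadband
        wires <- which(channels$bundle == b)
        for (w in wires) {
          lfp[tr, , w] <- gain_theta[w] * cos(th_phase + phase_off[w]) +
            d$gamma_amp * gain_gamma[w] * env *
              cos(ga_phase + phase_off[w]) +
            d$noise_sd_pink * shared_bb +
            d$noise_sd_white * stats::rnorm(n_t) +
            0.5 * d$noise_sd_pink * pink_noise(n_t, fs)
        }
      }
    }

    # --- units ------------------------------------------------------------
    sender_ch <- channels$channel[channels$bundle == 1][1]
    receiver_ch <- channels$channel[channels$bundle == 2][1]
    bg_ch <- channels$channel[channels$bundle == 1][2]

    spikes_from_phase <- function(phase_b, spec) {
      lapply(seq_len(n_trials), function(tr) {
        gen_locked_spikes(phase_b[tr, ], spec, fs) - 7
      })
    }

    sender_spec <- locking_spec("theta", preferred_phase = -pi,
                                kappa = d$theta_kappa,
                                base_rate = d$sender_rate)
    # the sender locks to the distal theta phase shifted into the future by
    # the condition's lead, so its spikes precede the LFP phase they lock to
    sender_spikes <- lapply(seq_len(n_trials), function(tr) {
      cond <- as.character(labels[tr])
      lead <- round(d$sender_lead_ms[[cond]] / 1000 * fs)
      ph <- theta_phase[tr, , 2]
      if (lead > 0) ph <- c(ph[(lead + 1):n_t], rep(ph[n_t], lead))
      gen_locked_spikes(ph, sender_spec, fs) - 7
    })

    receiver_spec <- locking_spec("gamma", preferred_phase = -pi,
                                  kappa = d$gamma_kappa,
                                  base_rate = d$receiver_rate)
    receiver_base <- spikes_from_phase(gamma_phase[, , 2, drop = FALSE][, , 1],
                                       receiver_spec)
    receiver_spikes <- lapply(seq_len(n_trials), function(tr) {
      cond <- as.character(labels[tr])
      s <- sender_spikes[[tr]]
      copied <- s[stats::runif(length(s)) < d$copy_prob]
      induced <- copied + d$cofire_lag[[cond]] / 1000 +
        stats::rnorm(length(copied), 0, d$cofire_jitter_sd / 1000)
      out <- sort(c(receiver_base[[tr]], induced))
      out <- out[out >= -7 & out <= 7]
      if (length(out) > 1L) out <- out[c(TRUE, diff(out) >= 0.003)]
      out
    })

    bg_spec <- locking_spec("theta", kappa = 0, base_rate = d$background_rate,
                            refractory = 0)
    bg_spikes <- spikes_from_phase(theta_phase[, , 1, drop = FALSE][, , 1],
                                   bg_spec)

    make_unit <- function(id, ch, spikes, wf_noise, gt) {
      n_sp <- sum(lengths(spikes))
      tmpl <- wave_template()
      wf <- matrix(stats::rnorm(max(n_sp, 2) * length(tmpl), 0, wf_noise),
                   ncol = length(tmpl), byrow = TRUE)
      wf <- sweep(wf, 2, tmpl, `+`)
      list(unit_id = id, channel = ch,
           bundle = channels$bundle[channels$channel == ch],
           spikes = spikes, waveforms = wf, fs_wave = 32000, ground_truth = gt)
    }

    units <- list(
      make_unit("sender", sender_ch, sender_spikes, wf_noise = 4,
                gt = list(role = "sender", spec = sender_spec,
                          target_bundle = 2, label = "SU")),
      make_unit("receiver", receiver_ch, receiver_spikes, wf_noise = 4,
                gt = list(role = "receiver", spec = receiver_spec,
                          target_bundle = 2, label = "SU",
                          cofire_lag = d$cofire_lag,
                          cofire_jitter_sd = d$cofire_jitter_sd,
                          copy_prob = d$copy_prob)),
      make_unit("background", bg_ch, bg_spikes, wf_noise = 25,
                gt = list(role = "background", spec = bg_spec,
                          target_bundle = 1, label = "MU"))
    )
    names(units) <- vapply(units, `[[`, "", "unit_id")

    structure(list(lfp = lfp, t = t, fs = fs, channels = channels,
                   units = units, labels = labels,
                   ground_truth = list(design = d,
                                       theta_phase = theta_phase,
                                       gamma_phase = gamma_phase),
                   seed = d$seed),
              class = "sfc_session")
  })
}

#' @export
print.sfc_session <- function(x, ...) {
  cat(sprintf(
    "<sfc_session> %d trials (%d hits / %d misses), %d channels in %d bundles, %d units\n",
    dim(x$lfp)[1], sum(x$labels == "hit"), sum(x$labels == "miss"),
    dim(x$lfp)[3], length(unique(x$channels$bundle)), length(x$units)))
  cat(sprintf("  epoch %.1f..%.1f s @ %d Hz; seed %s\n",
              min(x$t), max(x$t), x$fs, format(x$seed)))
  invisible(x)
}

validate_session <- function(session) {
  if (!inherits(session, "sfc_session")) stopf("not an sfc_session")
  dm <- dim(session$lfp)
  if (is.null(dm) || length(dm) != 3L || any(dm == 0L)) {
    stopf("session has empty LFP array")
  }
  if (dm[1] != length(session$labels)) {
    stopf("label count does not match trial count")
  }
  if (dm[3] != nrow(session$channels)) {
    stopf("channel metadata does not match LFP channels")
  }
  for (u in session$units) {
    if (!u$channel %in% session$channels$channel) {
      stopf("unit %s references unknown channel %s", u$unit_id, u$channel)
    }
    if (length(u$spikes) != dm[1]) {
      stopf("unit %s has %d spike trials, session has %d",
            u$unit_id, length(u$spikes), dm[1])
    }
  }
  invisible(TRUE)
}

#' Write / read a session as plain-text files
#'
#' Serializes a session to a directory of CSV and JSON files: `meta.json`
#' (sampling rate, time axis, seed, JSON-encoded design), `labels.csv`,
#' `channels.csv`, `lfp.csv` (long format: trial, channel, sample, value)
#' and per-unit spike/waveform CSVs. Intended for small sessions and
#' interchange; large sessions are cheaper to regenerate from
#' `(design, seed)`.
#'
#' @param session an `sfc_session`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "units"), showWarnings = FALSE)
  meta <- list(fs = session$fs, t0 = session$t[1], n_t = length(session$t),
               seed = session$seed,
               design = session$ground_truth$design[
                 setdiff(names(session$ground_truth$design), character(0))])
  class(meta$design) <- NULL
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(trial = seq_along(session$labels),
                              label = as.character(session$labels)),
                   file.path(path, "labels.csv"), row.names = FALSE)
  utils::write.csv(session$channels, file.path(path, "channels.csv"),
                   row.names = FALSE)
  dm <- dim(session$lfp)
  long <- data.frame(
    trial = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    sample = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    channel = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    value = as.vector(session$lfp))
  utils::write.csv(long, file.path(path, "lfp.csv"), row.names = FALSE)
  for (u in session$units) {
    sp <- data.frame(
      trial = rep(seq_along(u$spikes), lengths(u$spikes)),
      time = unlist(u$spikes) %||% numeric(0))
    utils::write.csv(sp,
      file.path(path, "units", paste0(u$unit_id, "_spikes.csv")),
      row.names = FALSE)
    utils::write.csv(as.data.frame(u$waveforms),
      file.path(path, "units", paste0(u$unit_id, "_waveforms.csv")),
      row.names = FALSE)
    jsonlite::write_json(
      list(unit_id = u$unit_id, channel = u$channel, bundle = u$bundle,
           fs_wave = u$fs_wave),
      file.path(path, "units", paste0(u$unit_id, "_meta.json")),
      auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(path, "labels.csv"))
  channels <- utils::read.csv(file.path(path, "channels.csv"))
  long <- utils::read.csv(file.path(path, "lfp.csv"))
  n_trials <- max(long$trial); n_t <- max(long$sample); n_ch <- max(long$channel)
  lfp <- array(long$value[order(long$channel, long$sample, long$trial)],
               dim = c(n_trials, n_t, n_ch))
  unit_meta <- list.files(file.path(path, "units"), pattern = "_meta\\.json$",
                          full.names = TRUE)
  units <- lapply(unit_meta, function(f) {
    um <- jsonlite::read_json(f, simplifyVector = TRUE)
    sp <- utils::read.csv(sub("_meta\\.json$", "_spikes.csv", f))
    wf <- as.matrix(utils::read.csv(sub("_meta\\.json$", "_waveforms.csv", f)))
    dimnames(wf) <- NULL
    spikes <- lapply(seq_len(n_trials), function(tr) sp$time[sp$trial == tr])
    list(unit_id = um$unit_id, channel = um$channel, bundle = um$bundle,
         spikes = spikes, waveforms = wf, fs_wave = um$fs_wave,
         ground_truth = NULL)
  })
  names(units) <- vapply(units, `[[`, "", "unit_id")
  t <- meta$t0 + (seq_len(meta$n_t) - 1) / meta$fs
  structure(list(lfp = lfp, t = t, fs = meta$fs, channels = channels,
                 units = units,
                 labels = factor(labels$label, levels = c("hit", "miss")),
                 ground_truth = list(design = meta$design),
                 seed = meta$seed),
            class = "sfc_session")
}
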