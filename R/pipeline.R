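# End-to-end orchestration: behavioral labelling and chance arithmetic,
# the pinned default configuration, and the staged pipeline runner.

#' Label encoding trials by later recall outcome
#'
#' A trial counts as a hit only when *both* associates were later selected
#' correctly; partial recall and full forgetting are pooled into the miss
#' category.
#'
#' @param first_correct,second_correct logical vectors: was the
#'   first/second selected associate correct? Trials where the patient
#'   reported remembering nothing should be passed as `FALSE`/`FALSE`.
#' @return factor with levels `hit`, `miss`, plus attribute `outcome`
#'   (`both_correct`, `one_correct`, `none_correct`).
#' @export
label_trials <- function(first_correct, second_correct) {
  stopifnot(length(first_correct) == length(second_correct))
  n_ok <- as.integer(first_correct) + as.integer(second_correct)
  outcome <- c("none_correct", "one_correct", "both_correct")[n_ok + 1]
  lab <- factor(ifelse(n_ok == 2, "hit", "miss"), levels = c("hit", "miss"))
  attr(lab, "outcome") <- outcome
  lab
}

#' Chance probabilities of the cued-recall selection
#'
#' Two targets are selected sequentially from a panel of four images (two
#' targets, two foils) without replacement: the first pick is correct with
#' probability 2/4, the second with 1/3 given the first, so
#' \eqn{p_{both} = 1/6}; by symmetry \eqn{p_{none} = 1/6} and
#' \eqn{p_{one} = 2/3}. A miss is anything but a full hit:
#' \eqn{p_{miss} = 5/6}.
#'
#' @return named list of probabilities `p_both`, `p_one`, `p_none`,
#'   `p_miss` (fractions in `[0, 1]`).
#' @export
chance_probabilities <- function() {
  p_both <- (2 / 4) * (1 / 3)
  p_none <- (2 / 4) * (1 / 3)
  list(p_both = p_both,
       p_one = 1 - p_both - p_none,
       p_none = p_none,
       p_miss = 1 - p_both)
}

#' Convert an oscillatory phase lag to a firing latency
#'
#' Two neurons locked to a common oscillation at frequency f with a
#' constant phase lag \eqn{\Delta\phi} fire \eqn{\Delta\phi / (2\pi f)}
#' seconds apart; the same angular lag means a shorter latency at a faster
#' frequency. E.g. a quarter-cycle lag corresponds to 31.25 ms at 8 Hz but
#' 62.5 ms at 4 Hz.
#'
#' @param lag_rad phase lag (radians).
#' @param freq oscillation frequency (Hz).
#' @return latency in seconds.
#' @export
phase_lag_latency <- function(lag_rad, freq) {
  if (any(freq <= 0)) stopf("phase_lag_latency: freq must be positive")
  lag_rad / (2 * pi * freq)
}

#' Default analysis configuration
#'
#' All stage parameters with their standard values: 2-3 s window of
#' interest, 6/12-cycle wavelet grids, 30/60-spike minimums, 18 phase
#' bins, shuffle counts 100 (pair null, PSI), 200 (MI), 2000 (co-firing),
#' 5000 (selection bias), 10000 pair-count draws, PPC peak threshold
#' 0.005, coincidence threshold 1.0 and FDR level 0.05. Override any field
#' through `...`.
#'
#' @param ... named overrides.
#' @return a `run_config` list.
#' @export
sfc_config <- function(...) {
  cfg <- list(
    window = c(2, 3),
    low_freqs = 2:40, low_cycles = 6,
    high_freqs = seq(40, 80, by = 2), high_cycles = 12,
    min_spikes_sfc = 30, min_spikes_psi = 60,
    n_bins = 18,
    n_shuffles_pair_null = 100, n_shuffles_psi = 100,
    n_shuffles_mi = 200, n_shuffles_cofire = 2000,
    n_shuffles_selection = 5000, n_draws_pair_null = 10000,
    ppc_peak_threshold = 0.005, coincidence_threshold = 1.0,
    fdr_alpha = 0.05,
    theta_peak_band = c(3, 13), gamma_peak_band = c(45, 75),
    cfc_theta_band = c(5, 11), cfc_gamma_band = c(50, 80),
    kernel_cofire = 0.025, max_lag_ms = 100,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("sfc_config: unknown fields: %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_table <- function(x, out_dir, name) {
  if (!is.null(out_dir) && !is.null(x)) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(x)
}

#' Run the full analysis pipeline on a session
#'
#' Executes preprocessing (line-noise removal, artifact rejection,
#' Gram-Schmidt re-referencing), unit classification, low- and high-band
#' spike-field screening with pair-count nulls, PPC condition contrasts
#' and peak-frequency shifts, PSI directionality for distal theta pairs,
#' peak-matched theta-gamma coupling for overlap channels, and the
#' co-firing latency analysis for sender/receiver pairs. Stage failures
#' are caught; completed results are returned together with a failure
#' manifest. With `out_dir` set, all result tables are persisted as CSV.
#'
#' @param session an `sfc_session`.
#' @param config a [sfc_config()].
#' @param out_dir optional output directory for CSV tables and the run
#'   manifest.
#' @return an `sfc_report` list with one element per stage plus
#'   `failures`.
#' @export
run_pipeline <- function(session, config = sfc_config(), out_dir = NULL) {
  validate_session(session)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- list(config = config, failures = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      report$failures[[name]] <<- conditionMessage(e)
      NULL
    })
    report[[name]] <<- res
    res
  }

  # --- preprocess ---------------------------------------------------------
  pre <- run_stage("preprocess", {
    ep <- as_epochs(session$lfp, session$t, session$fs,
                    bundle_of = session$channels$bundle)
    ep <- remove_line_noise(ep)
    ep <- reject_artifacts(ep, min_trials = min(25, dim(ep$lfp)[1]))
    ep <- gram_schmidt_rereference(ep)
    ep
  })
  if (is.null(pre)) {
    report$failures$preprocess <- report$failures$preprocess %||% "failed"
    return(structure(report, class = "sfc_report"))
  }
  clean <- session
  clean$lfp <- pre$lfp
  write_table(pre$log, out_dir, "rejection_log")

  # --- units --------------------------------------------------------------
  units_tab <- run_stage("units", unit_table(clean))
  write_table(units_tab, out_dir, "units")
  if (!is.null(units_tab)) {
    keep_units <- units_tab$unit_id[units_tab$included &
                                      units_tab$label != "rejected"]
    clean$units <- clean$units[names(clean$units) %in% keep_units]
  }

  # --- spike-field coupling ----------------------------------------------
  keep_ch <- pre$keep_channel
  scr_low <- run_stage("sfc_low", sfc_screen(
    clean, band = "low", window = config$window,
    min_spikes = config$min_spikes_sfc, alpha = config$fdr_alpha,
    n_shuffles = config$n_shuffles_pair_null,
    n_draws = config$n_draws_pair_null, keep_channel = keep_ch,
    seed = child_seed(config$seed, 1)))
  scr_high <- run_stage("sfc_high", sfc_screen(
    clean, band = "high", window = config$window,
    min_spikes = config$min_spikes_sfc, alpha = config$fdr_alpha,
    n_shuffles = config$n_shuffles_pair_null,
    n_draws = config$n_draws_pair_null, keep_channel = keep_ch,
    seed = child_seed(config$seed, 2)))

  contrasts <- run_stage("sfc_contrast", {
    out <- list()
    for (scr in list(scr_low, scr_high)) {
      if (is.null(scr)) next
      sel <- scr$pairs$significant & !scr$pairs$excluded &
        scr$pairs$n_hit >= config$min_spikes_sfc &
        scr$pairs$n_miss >= config$min_spikes_sfc
      if (!any(sel)) next
      keys <- which(sel)
      spectra <- scr$spectra[keys]
      band <- if (scr$band == "low") config$theta_peak_band
              else config$gamma_peak_band
      out[[scr$band]] <- list(
        contrast = if (sum(sel) >= 2) condition_contrast(spectra) else NULL,
        peaks = peak_frequency_shift(spectra, band,
                                     config$ppc_peak_threshold),
        pairs = scr$pairs[keys, , drop = FALSE])
    }
    out
  })
  for (b in names(contrasts)) {
    write_table(contrasts[[b]]$contrast, out_dir, paste0("ppc_contrast_", b))
    write_table(contrasts[[b]]$peaks$peaks, out_dir, paste0("ppc_peaks_", b))
  }
  if (!is.null(scr_low)) write_table(scr_low$pairs, out_dir, "sfc_pairs_low")
  if (!is.null(scr_high)) write_table(scr_high$pairs, out_dir, "sfc_pairs_high")

  # --- directionality (PSI) ----------------------------------------------
  psi_res <- run_stage("psi", {
    if (is.null(scr_low)) stopf("low-band screening unavailable")
    sel <- scr_low$pairs$significant & !scr_low$pairs$excluded &
      scr_low$pairs$locality == "distal"
    rows <- which(sel)
    res <- list()
    for (i in rows) {
      u <- clean$units[[scr_low$pairs$unit_id[i]]]
      ch <- scr_low$pairs$channel[i]
      res[[paste(u$unit_id, ch, sep = "|")]] <- psi_by_condition(
        u$spikes, matrix(clean$lfp[, , ch], nrow = dim(clean$lfp)[1]),
        clean$t, clean$fs, clean$labels, window = config$window,
        n_shuffles = config$n_shuffles_psi,
        min_spikes = config$min_spikes_psi,
        seed = child_seed(config$seed, 10 + i))
    }
    res
  })
  if (length(psi_res)) {
    psi_tab <- do.call(rbind, lapply(names(psi_res), function(k) {
      data.frame(pair = k, freq = psi_res[[k]]$hit$freq,
                 psi_hit = psi_res[[k]]$hit$psi, z_hit = psi_res[[k]]$hit$z,
                 psi_miss = psi_res[[k]]$miss$psi,
                 z_miss = psi_res[[k]]$miss$z)
    }))
    write_table(psi_tab, out_dir, "psi")
  }

  # --- theta-gamma coupling ----------------------------------------------
  cfc_res <- run_stage("cfc", {
    if (is.null(scr_low) || is.null(scr_high) || is.null(contrasts)) {
      stopf("screening unavailable")
    }
    # overlap rule: bundles that have a distally theta-coupled LFP and a
    # locally gamma-coupled LFP
    pl <- scr_low$pairs; ph <- scr_high$pairs
    bundle_of <- function(ch) {
      clean$channels$bundle[match(ch, clean$channels$channel)]
    }
    theta_b <- unique(bundle_of(pl$channel[pl$significant & !pl$excluded &
                                             pl$locality == "distal"]))
    gamma_b <- unique(bundle_of(ph$channel[ph$significant & !ph$excluded &
                                             ph$locality != "distal"]))
    overlap <- intersect(theta_b, gamma_b)
    res <- list()
    for (b in overlap) {
      chans <- clean$channels$channel[clean$channels$bundle == b & keep_ch]
      for (ch in chans) {
        # condition-specific peaks from this channel's own PPC spectra
        kl <- which(pl$channel == ch & pl$significant & !pl$excluded &
                      pl$locality == "distal")
        kh <- which(ph$channel == ch & ph$significant & !ph$excluded &
                      ph$locality != "distal")
        if (!length(kl) || !length(kh)) next
        spl <- scr_low$spectra[[kl[1]]]; sph <- scr_high$spectra[[kh[1]]]
        tp <- c(hit = NA_real_, miss = NA_real_)
        gp <- c(hit = NA_real_, miss = NA_real_)
        for (lev in c("hit", "miss")) {
          pk_t <- find_ppc_peak(spl$freq, spl[[paste0("ppc_", lev)]],
                                config$cfc_theta_band,
                                config$ppc_peak_threshold)
          pk_g <- find_ppc_peak(sph$freq, sph[[paste0("ppc_", lev)]],
                                config$cfc_gamma_band,
                                config$ppc_peak_threshold)
          if (!is.null(pk_t)) tp[lev] <- pk_t$freq
          if (!is.null(pk_g)) gp[lev] <- pk_g$freq
        }
        cm <- peak_matched_cfc(
          matrix(clean$lfp[, , ch], nrow = dim(clean$lfp)[1]),
          clean$t, clean$fs, clean$labels, tp, gp,
          window = config$window, n_bins = config$n_bins,
          n_shuffles = config$n_shuffles_mi,
          seed = child_seed(config$seed, 100 + ch))
        if (!is.null(cm)) res[[as.character(ch)]] <- cm
      }
    }
    res
  })
  if (length(cfc_res)) {
    cfc_tab <- do.call(rbind, lapply(names(cfc_res), function(k) {
      r <- cfc_res[[k]]
      data.frame(channel = k, theta_peak_hit = r$theta_peak[["hit"]],
                 theta_peak_miss = r$theta_peak[["miss"]],
                 gamma_peak_hit = r$gamma_peak[["hit"]],
                 gamma_peak_miss = r$gamma_peak[["miss"]],
                 mi_hit = r$hit$mi, z_hit = r$hit$z,
                 mi_miss = r$miss$mi, z_miss = r$miss$z)
    }))
    write_table(cfc_tab, out_dir, "cfc")
    if (nrow(cfc_tab) >= 2) {
      report$cfc_test <- tryCatch(
        cfc_condition_test(cfc_tab$z_hit, cfc_tab$z_miss),
        error = function(e) NULL)
    }
  }

  # --- co-firing ----------------------------------------------------------
  cofire_res <- run_stage("cofire", {
    if (is.null(scr_low) || is.null(scr_high)) stopf("screening unavailable")
    prs <- select_pairs(scr_low, scr_high, clean$channels)
    if (!nrow(prs)) return(list(pairs = prs, results = list()))
    results <- lapply(seq_len(nrow(prs)), function(i) {
      cofiring_xcorr(clean$units[[prs$sender[i]]]$spikes,
                     clean$units[[prs$receiver[i]]]$spikes,
                     clean$t, clean$fs, clean$labels,
                     window = config$window,
                     kernel_len = config$kernel_cofire,
                     max_lag_ms = config$max_lag_ms,
                     n_shuffles = config$n_shuffles_cofire,
                     seed = child_seed(config$seed, 1000 + i))
    })
    kept <- coincidence_filter(results)
    contrast <- if (sum(kept) >= 2) {
      peak_lag_contrast(results[kept], max_ms = config$max_lag_ms)
    } else NULL
    list(pairs = prs, kept = kept, results = results, contrast = contrast)
  })
  if (!is.null(cofire_res)) {
    write_table(cofire_res$pairs, out_dir, "cofire_pairs")
    if (!is.null(cofire_res$contrast)) {
      write_table(cofire_res$contrast$lags, out_dir, "cofire_lags")
    }
  }

  if (!is.null(out_dir)) {
    manifest <- list(seed = config$seed,
                     failures = report$failures,
                     stages = names(report))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(report, class = "sfc_report")
}

#' @export
print.sfc_report <- function(x, ...) {
  cat("<sfc_report>\n")
  stages <- setdiff(names(x), c("config", "failures"))
  for (s in stages) {
    status <- if (is.null(x[[s]])) "FAILED" else "ok"
    cat(sprintf("  %-12s %s\n", s, status))
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (n in names(x$failures)) cat(sprintf("  %s: %s\n", n, x$failures[[n]]))
  }
  invisible(x)
}
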