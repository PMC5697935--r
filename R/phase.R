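#' Theta-band instantaneous phase of an LFP trace
#'
#' Zero-phase (forward-backward) 4th-order Butterworth bandpass to 5-15 Hz,
#' then the analytic-signal phase via the Hilbert transform. Phase convention:
#' 0 at the oscillation peak (cosine convention), advancing through +pi/2 at
#' the falling zero-crossing. Edges are padded by reflection before
#' filtering.
#'
#' @param samples LFP sample vector.
#' @param fs Sampling rate (Hz); must be at least 4x the band's upper edge.
#' @param band Passband (Hz), default `c(5, 15)`.
#' @param t0 Time of the first sample (s).
#' @return A `phase_series`: `phase` (radians in (-pi, pi]), `amplitude`
#'   (envelope), `band`, `fs`, `t0`.
#' @export
bandpass_phase <- function(samples, fs, band = c(5, 15), t0 = 0) {
  if (band[2] >= fs / 2) {
    abort("band extends beyond Nyquist", class = "thetasync_phase_error")
  }
  if (fs < 4 * band[2]) {
    abort("sampling rate must be >= 4x the band's upper edge",
          class = "thetasync_phase_error")
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  np <- min(length(samples) - 1, round(3 * fs / band[1]))
  padded <- c(rev(samples[seq_len(np) + 1]), samples,
              rev(samples[length(samples) - seq_len(np)]))
  filt <- signal::filtfilt(bf, padded)
  filt <- filt[np + seq_along(samples)]
  an <- analytic_signal(filt)
  structure(
    list(phase = Arg(an), amplitude = Mod(an), band = band, fs = fs, t0 = t0),
    class = "phase_series"
  )
}

# Analytic signal via the frequency-domain Hilbert transform. Input is
# reflection-padded to a highly composite length so the FFT stays fast for
# arbitrary recording lengths.
analytic_signal <- function(x) {
  n0 <- length(x)
  n_fft <- stats::nextn(n0)
  if (n_fft > n0) {
    pad <- n_fft - n0
    x <- c(x, rev(x[n0 - seq_len(pad) + 1]))
  }
  out <- analytic_signal_exact(x)
  out[seq_len(n0)]
}

analytic_signal_exact <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase of each peri-event spike
#'
#' Assigns every spike inside the peri-event window the instantaneous phase
#' of the reference LFP at `spike_time + lag`, interpolating between samples
#' on the unit circle. Spikes whose lagged time leaves the analysis window
#' (or the recording) are dropped; the number dropped is reported as an
#' attribute.
#'
#' @param spike_times Spike times (s).
#' @param phase A `phase_series` from [bandpass_phase()].
#' @param trials Optional trial table; when given, only spikes within
#'   `align + window` of some trial are used.
#' @param align,window Peri-event selection (default action, `c(-2, 2)` s).
#' @param lag Time shift (s) applied to spike times before phase lookup
#'   (|lag| <= 0.1 s); negative lag pairs spikes with earlier LFP phase.
#' @param lag_window Window (s) the lagged time must stay inside (defaults to
#'   `window`); the lag profile passes the full window here while selecting
#'   spikes from a lag-invariant core.
#' @return Numeric vector of phase angles in (-pi, pi]; attribute
#'   `"n_dropped"` counts boundary-dropped spikes.
#' @export
spike_phases <- function(spike_times, phase, trials = NULL, align = "action",
                         window = c(-2, 2), lag = 0, lag_window = window) {
  if (abs(lag) > 0.1 + 1e-9) {
    abort("lag must be within +/-0.1 s", class = "thetasync_phase_error")
  }
  st <- spike_times
  n0 <- length(st)
  if (!is.null(trials)) {
    ev <- switch(align,
      cue = trials$cue_time, action = trials$action_time,
      reward = trials$reward_time
    )
    keep <- rep(FALSE, length(st))
    lagged_ok <- rep(FALSE, length(st))
    for (e in ev) {
      inw <- st >= e + window[1] & st < e + window[2]
      keep <- keep | inw
      lagged_ok <- lagged_ok |
        (inw & st + lag >= e + lag_window[1] & st + lag < e + lag_window[2])
    }
    st <- st[keep & lagged_ok]
    n0 <- sum(keep)
  }
  tt <- st + lag
  idx <- (tt - phase$t0) * phase$fs + 1
  ok <- idx >= 1 & idx <= length(phase$phase)
  idx <- idx[ok]
  i0 <- floor(idx)
  i1 <- pmin(i0 + 1, length(phase$phase))
  w <- idx - i0
  z <- (1 - w) * exp(1i * phase$phase[i0]) + w * exp(1i * phase$phase[i1])
  out <- Arg(z)
  attr(out, "n_dropped") <- n0 - length(out)
  out
}

#' Mean resultant length of phase angles
#'
#' `MRL = |1/N sum_n exp(i Phi_n)|`: 0 for uniformly spread phases, 1 for
#' perfect phase locking.
#'
#' @param phases Phase angles (radians).
#' @return MRL in `[0, 1]`.
#' @export
mrl <- function(phases) {
  if (length(phases) == 0) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Spike-count-controlled phase-locking value
#'
#' Because the MRL is biased by spike count, the PLV is the MRL averaged over
#' `n_iter` iterations, each computed from `n_resample` spikes drawn without
#' replacement. Units with `n <= n_resample` spikes are excluded (flagged,
#' never silently computed on fewer spikes).
#'
#' @param phases Spike phase angles.
#' @param n_iter Resampling iterations (1000).
#' @param n_resample Spikes per iteration (100).
#' @param seed Optional seed for the resampling stream.
#' @return List: `plv`, `mrl_raw` (all spikes), `preferred_phase` (circular
#'   mean), `n_spikes`, `excluded` flag.
#' @export
plv <- function(phases, n_iter = 1000, n_resample = 100, seed = NULL) {
  n <- length(phases)
  if (n <= n_resample) {
    return(list(plv = NA_real_, mrl_raw = mrl(phases),
                preferred_phase = Arg(mean(exp(1i * phases))),
                n_spikes = n, excluded = TRUE))
  }
  z <- exp(1i * phases)
  run <- function() {
    mean(vapply(seq_len(n_iter), function(i) {
      Mod(mean(z[sample.int(n, n_resample)]))
    }, numeric(1)))
  }
  val <- if (is.null(seed)) run() else with_seed(seed, run())
  list(plv = val, mrl_raw = Mod(mean(z)),
       preferred_phase = Arg(mean(z)), n_spikes = n, excluded = FALSE)
}

#' Rayleigh test of circular uniformity
#'
#' `z = n R^2` with `R` the mean resultant length; the p-value uses the
#' standard small-sample-corrected approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - n^2 R^2)) - (1 + 2n))`.
#'
#' @param phases Phase angles (>= 10).
#' @return List `z`, `p`, `n`; `NA` with a flag below 10 spikes.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 10) {
    return(list(z = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  }
  R <- mrl(phases)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n^2 * R^2)) - (1 + 2 * n))
  list(z = z, p = min(p, 1), n = n, flagged = FALSE)
}

#' Time-lagged phase-locking profile
#'
#' Recomputes the PLV with spike times shifted relative to the LFP by each
#' lag from -100 to +100 ms in 4 ms steps (51 lags). The peak lag is the
#' argmax PLV; ties break toward the lag nearest zero, then toward the
#' negative lag. A negative peak lag means spikes align best with preceding
#' LFP phase — the oscillation leads the spikes.
#'
#' @param spike_times Spike times of one unit (s).
#' @param phase A `phase_series`.
#' @param trials Trial table for peri-event selection.
#' @param align,window Peri-event selection.
#' @param lags Lag grid (s).
#' @param n_iter,n_resample,seed PLV resampling controls.
#' @return List: `profile` tibble (lag_ms, plv, n_spikes), `peak_lag_ms`.
#' @export
lagged_plv_profile <- function(spike_times, phase, trials, align = "action",
                               window = c(-2, 2),
                               lags = seq(-0.1, 0.1, by = 0.004),
                               n_iter = 1000, n_resample = 100, seed = NULL) {
  # shrink the selection window by the largest |lag| so the same spike set
  # enters every lag; lag-dependent boundary dropping would otherwise tilt
  # the profile (removing unlocked edge spikes inflates MRL with |lag|)
  core <- window + c(max(abs(lags)), -max(abs(lags)))
  vals <- vapply(seq_along(lags), function(i) {
    ph <- spike_phases(spike_times, phase, trials, align, core,
                       lag = lags[i], lag_window = window)
    pv <- plv(ph, n_iter, n_resample,
              seed = if (is.null(seed)) NULL else seed + i)
    c(pv$plv, length(ph))
  }, numeric(2))
  profile <- tibble::tibble(
    lag_ms = lags * 1000, plv = vals[1, ], n_spikes = as.integer(vals[2, ])
  )
  pk <- which(profile$plv == max(profile$plv, na.rm = TRUE))
  if (length(pk) > 1) {
    pk <- pk[order(abs(profile$lag_ms[pk]), profile$lag_ms[pk])][1]
  }
  list(profile = profile, peak_lag_ms = profile$lag_ms[pk])
}

#' Blockwise spike-field phase-locking analysis of a session
#'
#' For each unit of `spike_region` and each block (shock-excluded trials):
#' extracts peri-action spike phases against the `lfp_region` theta phase,
#' applies the spike-count inclusion rule (more than `min_spikes` peri-action
#' spikes in every block), and computes the resampled PLV, raw MRL, preferred
#' phase, and Rayleigh statistics.
#'
#' @param session An `ephys_session`.
#' @param spike_region Region whose units are analyzed.
#' @param lfp_region Region providing the phase reference (local or
#'   cross-regional).
#' @param band Theta band (Hz).
#' @param align,window Peri-event epoch.
#' @param min_spikes Inclusion threshold per block (100).
#' @param n_iter,n_resample PLV resampling controls.
#' @param seed Base seed; substreams are keyed by (unit, block, lfp region).
#' @return Tibble: unit_id, block, plv, mrl_raw, preferred_phase, rayleigh_z,
#'   rayleigh_p, n_spikes, included.
#' @export
phase_locking_analysis <- function(session, spike_region, lfp_region,
                                   band = c(5, 15), align = "action",
                                   window = c(-2, 2), min_spikes = 100,
                                   n_iter = 1000, n_resample = 100,
                                   seed = 1L) {
  trials <- exclude_shock_trials(session$trials)
  li <- which(session$lfp$region == lfp_region)
  if (length(li) != 1) {
    abort(sprintf("no %s LFP channel in session", lfp_region),
          class = "thetasync_phase_error")
  }
  ps <- bandpass_phase(session$lfp$samples[[li]], session$lfp$fs[li], band,
                       session$lfp$t0[li])
  units <- dplyr::filter(session$units, .data$region == !!spike_region)
  blocks <- sort(unique(trials$block))
  rows <- list()
  for (u in seq_len(nrow(units))) {
    ph_by_block <- lapply(blocks, function(b) {
      spike_phases(units$spike_times[[u]], ps,
                   trials[trials$block == b, ], align, window)
    })
    included <- all(vapply(ph_by_block, length, integer(1)) > min_spikes)
    for (bi in seq_along(blocks)) {
      ph <- ph_by_block[[bi]]
      pv <- if (included) {
        plv(ph, n_iter, n_resample,
            seed = derive_seed(seed, paste(units$unit_id[u], blocks[bi],
                                           lfp_region)))
      } else {
        list(plv = NA_real_, mrl_raw = mrl(ph),
             preferred_phase = if (length(ph)) Arg(mean(exp(1i * ph)))
               else NA_real_,
             n_spikes = length(ph), excluded = TRUE)
      }
      ray <- rayleigh_test(ph)
      rows[[length(rows) + 1]] <- tibble::tibble(
        unit_id = units$unit_id[u], lfp_region = lfp_region,
        block = blocks[bi], plv = pv$plv, mrl_raw = pv$mrl_raw,
        preferred_phase = pv$preferred_phase,
        rayleigh_z = ray$z, rayleigh_p = ray$p,
        n_spikes = pv$n_spikes, included = included
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Blockwise PLV comparison across units
#'
#' Paired Wilcoxon signed-rank tests of per-unit PLVs between blocks, plus
#' per-block mean PLV and the proportion of Rayleigh-significant units.
#'
#' @param results Tibble from [phase_locking_analysis()] (included units).
#' @param alpha Rayleigh significance level for the proportions (0.05).
#' @return List: `per_block` tibble (block, mean_plv, n, prop_locked) and
#'   `pairwise` tibble (block_a, block_b, p, n_pairs); pairwise p is `NA`
#'   (flagged) below 6 paired units, and the comparison is skipped with a
#'   message when only one block is present.
#' @export
blockwise_plv_comparison <- function(results, alpha = 0.05) {
  res <- dplyr::filter(results, .data$included)
  per_block <- dplyr::summarise(
    dplyr::group_by(res, .data$block),
    mean_plv = mean(.data$plv, na.rm = TRUE),
    n = dplyr::n(),
    prop_locked = mean(.data$rayleigh_p < alpha, na.rm = TRUE),
    .groups = "drop"
  )
  blocks <- sort(unique(res$block))
  if (length(blocks) < 2) {
    message("only one block present; blockwise comparison skipped")
    return(list(per_block = per_block, pairwise = NULL))
  }
  wide <- tidyr::pivot_wider(res[, c("unit_id", "block", "plv")],
                             names_from = "block", values_from = "plv")
  pairs <- utils::combn(blocks, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    a <- wide[[as.character(pr[1])]]
    b <- wide[[as.character(pr[2])]]
    ok <- complete.cases(a, b)
    p <- if (sum(ok) < 6) NA_real_ else {
      wilcox.test(a[ok], b[ok], paired = TRUE)$p.value
    }
    tibble::tibble(block_a = pr[1], block_b = pr[2], p = p,
                   n_pairs = sum(ok))
  })
  list(per_block = per_block, pairwise = dplyr::bind_rows(pw))
}
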