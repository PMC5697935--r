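#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth product
#' `nw` via the standard symmetric tridiagonal eigenproblem. Tapers are
#' normalized to unit energy, ordered by spectral concentration, and
#' sign-fixed so each taper's mean (odd orders: initial slope) is positive.
#' Results are cached per `(n, nw, k)`.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product (default 5; with `k = 2 nw - 1 = 9`
#'   tapers the half-bandwidth is `nw / (n dt)` Hz).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 5, k = 2 * nw - 1) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .thetasync_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t_ <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  off <- t_[-1] * (n - t_[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if ((j %% 2 == 1 && sum(tap[, j]) < 0) ||
        (j %% 2 == 0 && sum(t_ * tap[, j]) < 0)) {
      tap[, j] <- -tap[, j]
    }
  }
  .thetasync_cache[[key]] <- tap
  tap
}

.thetasync_cache <- new.env(parent = emptyenv())

# Multitaper auto/cross spectra of aligned trial segments.
# Returns list of arrays: freqs, and for each requested pair the
# taper+trial-pooled spectra per window.
mt_segments <- function(x, fs, t0, events, centers, win_len, nw, k, nfft,
                        fmax) {
  n_win <- round(win_len * fs)
  tap <- dpss_tapers(n_win, nw, k)
  freqs <- (0:(nfft - 1)) * fs / nfft
  sel <- which(freqs > 0 & freqs <= fmax)
  list(tap = tap, sel = sel, freqs = freqs[sel], n_win = n_win)
}

# Extract one detrended segment of length n_win centered at time tc.
segment_at <- function(x, fs, t0, tc, n_win) {
  i0 <- round((tc - t0) * fs) - n_win %/% 2 + 1
  if (i0 < 1 || i0 + n_win - 1 > length(x)) return(NULL)
  seg <- x[i0:(i0 + n_win - 1)]
  tt <- seq_len(n_win)
  seg - (lm.fit(cbind(1, tt), seg)$fitted.values)
}

#' Multitaper spectrogram of trial-aligned LFP
#'
#' Fourier transforms the LFP in a 500 ms window moving in 50 ms steps across
#' the peri-event epoch, with `k = 9` Slepian tapers (time-bandwidth product
#' `nw = 5`, half-bandwidth 10 Hz at 500 ms), averaging power over tapers and
#' trials. Power is scaled as a one-sided density (`|X|^2 / (fs * K)`, summed
#' over tapers) on a 1 Hz frequency grid by zero-padding to `fs` points.
#'
#' @param samples LFP sample vector.
#' @param fs Sampling rate (Hz).
#' @param trials Trial table (shock trials excluded upstream).
#' @param align Event to align to (`"cue"`, `"action"`, `"reward"`,
#'   `"baseline"`).
#' @param window Peri-event window (s).
#' @param t0 Time of the first sample (s).
#' @param win_len,step Moving-window length and step (s).
#' @param nw,k Taper parameters.
#' @param fmax Highest analysis frequency (Hz, <= 125).
#' @return A `spectrogram`: `power` (window x frequency, trial-averaged),
#'   `per_trial` (trial x frequency, window-averaged; used for baseline
#'   normalization), `freqs`, `window_centers`, `tapers`, `normalized`.
#' @export
multitaper_spectrogram <- function(samples, fs, trials, align = "action",
                                   window = c(-2, 2), t0 = 0, win_len = 0.5,
                                   step = 0.05, nw = 5, k = 9, fmax = 125) {
  if (fs < 2 * fmax) {
    abort("sampling rate too low for requested frequency band",
          class = "thetasync_spectrum_error")
  }
  ev <- switch(align,
    cue = trials$cue_time, action = trials$action_time,
    reward = trials$reward_time, baseline = trials$cue_time - 1.5
  )
  nfft <- round(fs)
  mt <- mt_segments(samples, fs, t0, ev, NULL, win_len, nw, k, nfft, fmax)
  centers <- seq(window[1] + win_len / 2, window[2] - win_len / 2, by = step)
  n_tr <- length(ev)
  pow <- matrix(0, length(centers), length(mt$sel))
  per_trial <- matrix(0, n_tr, length(mt$sel))
  n_used <- 0
  for (tr in seq_len(n_tr)) {
    tr_pow <- matrix(0, length(centers), length(mt$sel))
    ok <- TRUE
    for (wi in seq_along(centers)) {
      seg <- segment_at(samples, fs, t0, ev[tr] + centers[wi], mt$n_win)
      if (is.null(seg)) { ok <- FALSE; break }
      X <- stats::mvfft(rbind(seg * mt$tap,
                              matrix(0, nfft - mt$n_win, ncol(mt$tap))))
      tr_pow[wi, ] <- rowMeans(abs(X[mt$sel, , drop = FALSE])^2) * 2 / fs
    }
    if (!ok) next
    pow <- pow + tr_pow
    per_trial[tr, ] <- colMeans(tr_pow)
    n_used <- n_used + 1
  }
  if (n_used == 0) {
    abort("no trial had the full peri-event window inside the recording",
          class = "thetasync_spectrum_error")
  }
  structure(
    list(power = pow / n_used, per_trial = per_trial, freqs = mt$freqs,
         window_centers = centers, tapers = k, normalized = FALSE,
         n_trials = n_used),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram>%s %d windows x %d freqs (%g-%g Hz), %d tapers, %d trials\n",
              if (x$normalized) " z-scored," else "",
              length(x$window_centers), length(x$freqs),
              min(x$freqs), max(x$freqs), x$tapers, x$n_trials))
  invisible(x)
}

#' Baseline z-score normalization of a spectrogram
#'
#' Standardizes power at each (window, frequency) by the across-trial mean
#' and standard deviation of the baseline power at that frequency.
#'
#' @param spec A `spectrogram` over the epoch of interest.
#' @param baseline_spec A `spectrogram` over the pre-cue baseline epoch with
#'   the same frequency grid.
#' @return The z-scored `spectrogram` (`normalized = TRUE`); frequencies with
#'   zero baseline SD get `NA` and are reported via attribute
#'   `"flagged_freqs"`.
#' @export
normalize_spectrogram <- function(spec, baseline_spec) {
  stopifnot(identical(spec$freqs, baseline_spec$freqs))
  m <- colMeans(baseline_spec$per_trial)
  s <- apply(baseline_spec$per_trial, 2, sd)
  bad <- which(!is.finite(s) | s == 0)
  s[bad] <- NA_real_
  spec$power <- sweep(sweep(spec$power, 2, m), 2, s, "/")
  if (length(bad)) {
    warn(sprintf("zero baseline SD at %d frequency bin(s); z undefined there",
                 length(bad)))
  }
  spec$normalized <- TRUE
  attr(spec, "flagged_freqs") <- spec$freqs[bad]
  spec
}

#' Magnitude-squared coherence between two trial-aligned LFP channels
#'
#' Multitaper cross- and auto-spectra pooled over tapers and trials in each
#' moving window: `C_xy(f) = |S_xy(f)|^2 / (S_x(f) S_y(f))`, bounded in
#' `[0, 1]`.
#'
#' @param x,y LFP sample vectors (simultaneously recorded, equal `fs`).
#' @inheritParams multitaper_spectrogram
#' @return List: `coherence` (window x frequency), `freqs`,
#'   `window_centers`, `n_trials`.
#' @export
msc_coherence <- function(x, y, fs, trials, align = "action",
                          window = c(-2, 2), t0 = 0, win_len = 0.5,
                          step = 0.05, nw = 5, k = 9, fmax = 125) {
  stopifnot(length(x) == length(y))
  ev <- switch(align,
    cue = trials$cue_time, action = trials$action_time,
    reward = trials$reward_time, baseline = trials$cue_time - 1.5
  )
  if (length(ev) * k < 2) {
    abort("need >= 2 effective samples (tapers x trials) for coherence",
          class = "thetasync_spectrum_error")
  }
  nfft <- round(fs)
  mt <- mt_segments(x, fs, t0, ev, NULL, win_len, nw, k, nfft, fmax)
  centers <- seq(window[1] + win_len / 2, window[2] - win_len / 2, by = step)
  nf <- length(mt$sel)
  sxx <- matrix(0, length(centers), nf)
  syy <- matrix(0, length(centers), nf)
  sxy <- matrix(0 + 0i, length(centers), nf)
  n_used <- 0
  pad <- matrix(0, nfft - mt$n_win, ncol(mt$tap))
  for (tr in seq_along(ev)) {
    segs <- lapply(centers, function(ctr) {
      list(x = segment_at(x, fs, t0, ev[tr] + ctr, mt$n_win),
           y = segment_at(y, fs, t0, ev[tr] + ctr, mt$n_win))
    })
    if (any(vapply(segs, function(s) is.null(s$x) || is.null(s$y),
                   logical(1)))) next
    for (wi in seq_along(centers)) {
      X <- stats::mvfft(rbind(segs[[wi]]$x * mt$tap, pad))[mt$sel, ,
                                                           drop = FALSE]
      Y <- stats::mvfft(rbind(segs[[wi]]$y * mt$tap, pad))[mt$sel, ,
                                                           drop = FALSE]
      sxx[wi, ] <- sxx[wi, ] + rowSums(abs(X)^2)
      syy[wi, ] <- syy[wi, ] + rowSums(abs(Y)^2)
      sxy[wi, ] <- sxy[wi, ] + rowSums(X * Conj(Y))
    }
    n_used <- n_used + 1
  }
  if (n_used == 0) {
    abort("no trial had the full peri-event window inside the recording",
          class = "thetasync_spectrum_error")
  }
  list(coherence = abs(sxy)^2 / (sxx * syy), freqs = mt$freqs,
       window_centers = centers, n_trials = n_used)
}
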