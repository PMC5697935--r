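#' Bivariate vector autoregression fit with AIC order selection
#'
#' Least-squares VAR fit of a channel pair pooled across trial segments. Each
#' segment is demeaned and linearly detrended before stacking lagged
#' regressors. Model order is the AIC argmin over `1..order_max`
#' (`log det(Sigma) + 2 p q^2 / N`).
#'
#' @param x,y Equal-length numeric matrices (samples x segments) or vectors
#'   (a single segment) for the two channels.
#' @param order_max Largest candidate order (default 20).
#' @param order Fix the order instead of searching (used by the permutation
#'   bound for speed).
#' @return A `var_fit`: `A` (2 x 2 x p coefficient array), `Sigma` (2 x 2
#'   residual covariance), `order`, `aic` table, `n_obs`.
#' @export
fit_var <- function(x, y, order_max = 20, order = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)))
  n <- nrow(x)
  if (n <= 3 * order_max) {
    abort("segments too short for requested order_max; use a shorter order",
          class = "thetasync_var_error")
  }
  detr <- function(m) {
    tt <- cbind(1, seq_len(nrow(m)))
    m - tt %*% qr.coef(qr(tt), m)
  }
  x <- detr(x)
  y <- detr(y)
  if (max(abs(x - y)) < 1e-12 * max(abs(x), 1)) {
    abort("channels are identical; VAR regressors singular",
          class = "thetasync_var_error")
  }
  build <- function(p) {
    resp <- NULL
    design <- NULL
    for (s in seq_len(ncol(x))) {
      idx <- (p + 1):n
      r <- cbind(x[idx, s], y[idx, s])
      d <- matrix(0, length(idx), 2 * p)
      for (j in seq_len(p)) {
        d[, 2 * j - 1] <- x[idx - j, s]
        d[, 2 * j] <- y[idx - j, s]
      }
      resp <- rbind(resp, r)
      design <- rbind(design, d)
    }
    list(resp = resp, design = design)
  }
  fit_order <- function(p) {
    bd <- build(p)
    qrd <- qr(bd$design)
    if (qrd$rank < ncol(bd$design)) {
      abort("near-singular regressor matrix; use a shorter order",
            class = "thetasync_var_error")
    }
    B <- qr.coef(qrd, bd$resp)            # (2p) x 2
    res <- bd$resp - bd$design %*% B
    N <- nrow(bd$resp)
    Sigma <- crossprod(res) / (N - 2 * p)
    aic <- log(det(Sigma)) + 2 * p * 4 / N
    A <- array(0, dim = c(2, 2, p))
    for (j in seq_len(p)) {
      # row i of A_j: coefficients of channel i on lag-j regressors
      A[1, , j] <- B[c(2 * j - 1, 2 * j), 1]
      A[2, , j] <- B[c(2 * j - 1, 2 * j), 2]
    }
    list(A = A, Sigma = Sigma, order = p, aic = aic, n_obs = N)
  }
  if (!is.null(order)) {
    out <- fit_order(order)
    out$aic_table <- NULL
    class(out) <- "var_fit"
    return(out)
  }
  fits <- lapply(seq_len(order_max), fit_order)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  best$aic_table <- tibble::tibble(order = seq_len(order_max), aic = aics)
  class(best) <- "var_fit"
  best
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> bivariate VAR(%d), %d observations, det(Sigma)=%.4g\n",
              x$order, x$n_obs, det(x$Sigma)))
  invisible(x)
}

#' Spectral Granger causality from a fitted bivariate VAR
#'
#' Builds the transfer function `H(f) = (I - sum_j A_j e^{-2 pi i f j / fs})^-1`
#' and the spectral matrix `S(f) = H Sigma H*`, then the Geweke spectral
#' measure in both directions, e.g. channel 1 to channel 2:
#' `I_{1->2}(f) = -ln(1 - (Sigma_11 - Sigma_12^2 / Sigma_22) |H_21(f)|^2 / S_22(f))`.
#' Integrated over (0, Nyquist) this matches the time-domain Granger
#' causality. Frequencies where the VAR characteristic matrix is numerically
#' singular are flagged and excluded (`NA`).
#'
#' @param var A `var_fit`.
#' @param freqs Frequency grid (Hz).
#' @param fs Sampling rate of the fitted series (Hz).
#' @return A `gc_result` tibble: `freq`, `gc_xy` (1 -> 2), `gc_yx` (2 -> 1).
#' @export
spectral_gc <- function(var, freqs, fs) {
  p <- var$order
  S_ <- var$Sigma
  out <- vapply(freqs, function(f) {
    Af <- diag(2) + 0i
    for (j in seq_len(p)) {
      Af <- Af - var$A[, , j] * exp(-2i * pi * f * j / fs)
    }
    dt <- Af[1, 1] * Af[2, 2] - Af[1, 2] * Af[2, 1]
    if (Mod(dt) < 1e-12) return(c(NA_real_, NA_real_))
    H <- solve(Af)
    Sf <- H %*% S_ %*% Conj(t(H))
    s11 <- Re(Sf[1, 1]); s22 <- Re(Sf[2, 2])
    c(
      -log(pmax(1 - (S_[1, 1] - S_[1, 2]^2 / S_[2, 2]) * abs(H[2, 1])^2 / s22,
                .Machine$double.eps)),
      -log(pmax(1 - (S_[2, 2] - S_[1, 2]^2 / S_[1, 1]) * abs(H[1, 2])^2 / s11,
                .Machine$double.eps))
    )
  }, numeric(2))
  res <- tibble::tibble(freq = freqs, gc_xy = out[1, ], gc_yx = out[2, ])
  class(res) <- c("gc_result", class(res))
  res
}

#' Permutation upper confidence bound for spectral Granger causality
#'
#' Builds a surrogate GC distribution by randomly permuting the pairing of
#' whole trial segments of one channel relative to the other (preserving each
#' segment's autocorrelation while destroying the cross-channel temporal
#' relation), refitting the VAR at the observed order, and recomputing the
#' spectral GC. The per-frequency bound is the `1 - alpha` quantile of the
#' surrogate values, pooled over both directions.
#'
#' @param x,y Samples x segments matrices (>= 2 segments).
#' @param freqs Frequency grid (Hz).
#' @param fs Sampling rate (Hz).
#' @param n_perm Number of permutations (>= 20; at least `1/alpha`
#'   recommended).
#' @param alpha Significance level (0.001 by default).
#' @param order VAR order for the surrogate fits (defaults to the observed
#'   AIC order).
#' @param order_max Passed to [fit_var()] when `order` is `NULL`.
#' @param seed Optional seed.
#' @return Tibble: `freq`, `bound`.
#' @export
gc_permutation_bound <- function(x, y, freqs, fs, n_perm = 1000,
                                 alpha = 0.001, order = NULL,
                                 order_max = 20, seed = NULL) {
  if (n_perm < 20) {
    abort("n_perm must be >= 20", class = "thetasync_gc_error")
  }
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) < 2) {
    abort("permutation bound needs >= 2 trial segments",
          class = "thetasync_gc_error")
  }
  if (is.null(order)) {
    order <- fit_var(x, y, order_max = order_max)$order
  }
  run <- function() {
    surr <- array(NA_real_, dim = c(n_perm, length(freqs), 2))
    for (s in seq_len(n_perm)) {
      perm <- sample(ncol(y))
      vf <- fit_var(x, y[, perm, drop = FALSE], order = order)
      gc <- spectral_gc(vf, freqs, fs)
      surr[s, , 1] <- gc$gc_xy
      surr[s, , 2] <- gc$gc_yx
    }
    surr
  }
  surr <- if (is.null(seed)) run() else with_seed(seed, run())
  if (alpha >= 1) {
    bound <- apply(surr, 2, min, na.rm = TRUE)
  } else {
    bound <- vapply(seq_along(freqs), function(fi) {
      quantile(c(surr[, fi, 1], surr[, fi, 2]), 1 - alpha, na.rm = TRUE,
               names = FALSE)
    }, numeric(1))
  }
  tibble::tibble(freq = freqs, bound = bound)
}

#' Peri-action LFP segments of a session region pair
#'
#' Cuts the two regions' LFP into aligned peri-action segments on
#' shock-excluded trials, optionally decimating to a lower rate for VAR
#' fitting.
#'
#' @param session An `ephys_session` with both LFP channels.
#' @param window Peri-action window (s), default `c(-2, 2)`.
#' @param decimate Integer decimation factor (default 5: 1000 -> 200 Hz),
#'   applied after an anti-alias low-pass.
#' @return List: `x` (VTA), `y` (mPFC) samples x segments matrices, `fs`.
#' @export
lfp_segments <- function(session, window = c(-2, 2), decimate = 5L) {
  trials <- exclude_shock_trials(session$trials)
  lfp <- session$lfp
  get_chan <- function(region) {
    i <- which(lfp$region == region)
    if (length(i) != 1) abort(sprintf("no %s LFP channel", region),
                              class = "thetasync_gc_error")
    list(s = lfp$samples[[i]], fs = lfp$fs[i], t0 = lfp$t0[i])
  }
  vta <- get_chan("VTA")
  mpfc <- get_chan("mPFC")
  stopifnot(vta$fs == mpfc$fs)
  fs <- vta$fs
  xs <- vta$s
  ys <- mpfc$s
  if (decimate > 1) {
    bf <- signal::butter(4, 0.8 / decimate, type = "low")
    xs <- signal::filtfilt(bf, xs)
    ys <- signal::filtfilt(bf, ys)
    keep <- seq(1, length(xs), by = decimate)
    xs <- xs[keep]
    ys <- ys[keep]
    fs <- fs / decimate
  }
  n_seg <- round(diff(window) * fs)
  segs_x <- segs_y <- NULL
  for (tr in seq_len(nrow(trials))) {
    i0 <- round((trials$action_time[tr] + window[1] - vta$t0) * fs) + 1
    if (i0 < 1 || i0 + n_seg - 1 > length(xs)) next
    segs_x <- cbind(segs_x, xs[i0:(i0 + n_seg - 1)])
    segs_y <- cbind(segs_y, ys[i0:(i0 + n_seg - 1)])
  }
  list(x = segs_x, y = segs_y, fs = fs, trials = trials)
}

#' Blockwise VTA/mPFC spectral Granger causality of a session
#'
#' Fits the bivariate VAR on peri-action LFP segments per block and returns
#' the spectral GC in both directions with the theta-band (5-15 Hz) means.
#'
#' @inheritParams lfp_segments
#' @param freqs Frequency grid (Hz), default 1-50 Hz.
#' @param order_max AIC search cap.
#' @param theta_band Band (Hz) summarized by in-band means.
#' @return Tibble: block, freq, gc curves, plus per-block theta-band summary
#'   attached as attribute `"theta_summary"`.
#' @export
granger_blockwise <- function(session, window = c(-2, 2), decimate = 5L,
                              freqs = 1:50, order_max = 20,
                              theta_band = c(5, 15)) {
  segs <- lfp_segments(session, window, decimate)
  blocks <- segs$trials$block
  rows <- list()
  summ <- list()
  for (b in sort(unique(blocks))) {
    i <- which(blocks == b)
    vf <- fit_var(segs$x[, i, drop = FALSE], segs$y[, i, drop = FALSE],
                  order_max = order_max)
    gc <- spectral_gc(vf, freqs, segs$fs)
    rows[[length(rows) + 1]] <- dplyr::mutate(gc, block = b,
                                              .before = "freq")
    inb <- gc$freq >= theta_band[1] & gc$freq <= theta_band[2]
    summ[[length(summ) + 1]] <- tibble::tibble(
      block = b,
      gc_vta_to_mpfc = mean(gc$gc_xy[inb], na.rm = TRUE),
      gc_mpfc_to_vta = mean(gc$gc_yx[inb], na.rm = TRUE),
      order = vf$order
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "theta_summary") <- dplyr::bind_rows(summ)
  out
}
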