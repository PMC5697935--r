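#' Bias-corrected percent explained variance (omega PEV)
#'
#' One-way effect-size statistic for how much of the across-trial variance in
#' a spike count is explained by block (punishment contingency):
#' `(SS_blocks - df_blocks * MS_error) / (SS_total + MS_error)`. Unbiased under
#' the null (expected value zero when block means are equal); equals 1 when
#' within-block variance is zero and block means differ. Defined as 0 when
#' `SS_total + MS_error = 0` (all counts identical).
#'
#' @param x Numeric vector of per-trial spike counts in one time bin.
#' @param blocks Block label per trial (2+ blocks with 2+ trials each).
#' @return The omega PEV value (scalar, at most 1).
#' @export
compute_wpev <- function(x, blocks) {
  blocks <- as.factor(blocks)
  if (nlevels(blocks) < 2 || any(table(blocks) < 2)) {
    abort("compute_wpev needs >= 2 blocks with >= 2 trials each",
          class = "thetasync_wpev_error")
  }
  as.numeric(wpev_trace(matrix(x, ncol = 1), blocks))
}

#' @rdname compute_wpev
#' @param counts Trials x bins spike-count matrix: the omega PEV is computed
#'   down each column, giving the time-resolved trace.
#' @export
wpev_trace <- function(counts, blocks) {
  blocks <- as.factor(blocks)
  n <- nrow(counts)
  g <- nlevels(blocks)
  ng <- as.numeric(table(blocks))
  tot <- colSums(counts)
  ss_t <- colSums(counts^2) - tot^2 / n
  gs <- rowsum(counts, blocks, reorder = TRUE)
  ss_b <- colSums(gs^2 / ng) - tot^2 / n
  ms_e <- (ss_t - ss_b) / (n - g)
  denom <- ss_t + ms_e
  out <- (ss_b - (g - 1) * ms_e) / denom
  out[abs(denom) < 1e-12] <- 0
  out
}

#' Trial-shuffled surrogate pointwise and global omega PEV bands
#'
#' Block labels are permuted across trials (jointly for all bins of a trial,
#' preserving within-trial temporal correlation) `n_shuffles` times and the
#' omega PEV trace recomputed per shuffle. Starting at the surrogate
#' distribution's mean and stepping up by one-hundredth of its standard
#' deviation, the pointwise band at each bin is the lowest level exceeded by
#' strictly fewer than `alpha` of surrogates at that bin, and the global band
#' is the lowest level such that strictly fewer than `alpha` of surrogate
#' traces exceed it in any bin (family-wise control across time bins). The
#' search is capped at `max(surrogates) + SD`.
#'
#' @param counts Trials x bins spike-count matrix for one unit.
#' @param blocks Block label per trial.
#' @param n_shuffles Number of label shuffles (>= 100; 1000 by default).
#' @param alpha Significance level (0.01 by default).
#' @param seed Optional seed for the shuffle stream.
#' @return List with `pointwise` (per-bin), `global` (scalar), the surrogate
#'   `mean`, `sd`, `step`, and bookkeeping fields.
#' @export
surrogate_bands <- function(counts, blocks, n_shuffles = 1000, alpha = 0.01,
                            seed = NULL) {
  if (n_shuffles < 100) {
    abort("n_shuffles must be >= 100", class = "thetasync_band_error")
  }
  blocks <- as.factor(blocks)
  if (nrow(counts) < nlevels(blocks) * 2) {
    abort("too few trials relative to blocks after exclusion",
          class = "thetasync_band_error")
  }
  run <- function() {
    surr <- matrix(0, n_shuffles, ncol(counts))
    for (s in seq_len(n_shuffles)) {
      surr[s, ] <- wpev_trace(counts, sample(blocks))
    }
    surr
  }
  surr <- if (is.null(seed)) run() else with_seed(seed, run())

  m <- mean(surr)
  sdv <- sd(as.vector(surr))
  step <- sdv / 100
  n <- nrow(surr)
  # strictly fewer than alpha of the surrogates may exceed the band
  a <- max(0, ceiling(alpha * n) - 1)
  # smallest stepped level L = m + k*step (k >= 0) with #{v > L} <= a:
  # equivalently L >= the (a+1)-th largest value.
  stepped_level <- function(v) {
    crit <- sort(v, decreasing = TRUE)[a + 1]
    if (!is.finite(crit) || step == 0) return(m)
    lvl <- m + step * max(0, ceiling((crit - m) / step - 1e-9))
    min(lvl, max(v) + sdv)
  }
  pointwise <- apply(surr, 2, stepped_level)
  global <- stepped_level(apply(surr, 1, max))
  list(pointwise = pointwise, global = global, mean = m, sd = sdv,
       step = step, n_shuffles = n_shuffles, alpha = alpha)
}

#' Classify a unit as punishment-encoding from its omega PEV trace
#'
#' A unit encodes the action-punishment contingency if its omega PEV curve
#' crosses the global surrogate band in at least one time bin.
#'
#' @param wpev Omega PEV trace (per bin).
#' @param bands Output of [surrogate_bands()] (or a scalar global band).
#' @param unit_id Optional unit label.
#' @param centers Optional bin centers (s) carried into the result.
#' @return An `encoding_result`: unit_id, wpev, pointwise/global bands,
#'   `encoder` flag, `crossing_bins`, surrogate bookkeeping.
#' @export
classify_encoder <- function(wpev, bands, unit_id = NA_character_,
                             centers = NULL) {
  if (is.numeric(bands) && length(bands) == 1) {
    bands <- list(pointwise = rep(bands, length(wpev)), global = bands,
                  n_shuffles = NA_integer_, alpha = NA_real_)
  }
  crossing <- which(wpev > bands$global)
  structure(
    list(unit_id = unit_id, wpev = wpev, pointwise_band = bands$pointwise,
         global_band = bands$global, encoder = length(crossing) > 0,
         crossing_bins = crossing, centers = centers,
         n_surrogates = bands$n_shuffles, alpha = bands$alpha),
    class = "encoding_result"
  )
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf("<encoding_result> unit %s: %s (global band %.4f, %d/%d bins above)\n",
              x$unit_id, if (x$encoder) "ENCODER" else "non-encoder",
              x$global_band, length(x$crossing_bins), length(x$wpev)))
  invisible(x)
}

#' @rdname classify_encoder
#' @param x An `encoding_result`.
#' @param ... Unused.
#' @export
tidy.encoding_result <- function(x, ...) {
  tibble::tibble(
    unit_id = x$unit_id,
    bin = seq_along(x$wpev),
    time = x$centers %||% rep(NA_real_, length(x$wpev)),
    wpev = x$wpev,
    pointwise_band = x$pointwise_band,
    global_band = x$global_band,
    crossing = seq_along(x$wpev) %in% x$crossing_bins
  )
}

#' Standardized regression coefficient of spike counts on block index
#'
#' Ordinary least squares of counts on the block index (1, 2, 3 for shock
#' probabilities 0, 0.06, 0.1), with the coefficient standardized by
#' `beta * Sx / Sy` — in simple regression this equals the Pearson
#' correlation. The sign gives the direction of punishment modulation
#' (excitatory or inhibitory).
#'
#' @param counts Per-trial counts: a vector (one bin or a pooled epoch) or a
#'   trials x bins matrix (per-bin SRCs plus a pooled summary).
#' @param blocks Block label per trial (3+ trials).
#' @return An `src_result` list: `src` per bin, `summary_src` (SRC of counts
#'   pooled over the epoch), `sign` (`"excitatory"`/`"inhibitory"`), and a
#'   `flagged` marker for zero-variance inputs.
#' @export
src_direction <- function(counts, blocks) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  if (nrow(counts) < 3) {
    abort("src_direction needs >= 3 trials", class = "thetasync_src_error")
  }
  x <- as.numeric(blocks)
  src_one <- function(y) {
    sy <- sd(y)
    if (!is.finite(sy) || sy == 0) return(0)
    beta <- cov(y, x) / var(x)
    beta * sd(x) / sy
  }
  per_bin <- apply(counts, 2, src_one)
  pooled <- rowSums(counts)
  summary_src <- src_one(pooled)
  structure(
    list(src = per_bin, summary_src = summary_src,
         sign = if (summary_src >= 0) "excitatory" else "inhibitory",
         flagged = sd(pooled) == 0),
    class = "src_result"
  )
}

#' Baseline (inter-trial interval) firing-rate modulation across blocks
#'
#' Kruskal-Wallis test across blocks on spike counts in the 2 s baseline
#' window beginning 2.5 s before each cue; the direction of modulation is the
#' sign of the block-index SRC on the same counts.
#'
#' @param spike_times Spike time vector of one unit.
#' @param trials Trial table (shock trials excluded upstream).
#' @param alpha Significance level (0.05).
#' @return List: `modulated`, `p`, `direction`, and the per-trial counts.
#' @export
baseline_block_modulation <- function(spike_times, trials, alpha = 0.05) {
  if (any(table(trials$block) == 0)) {
    abort("empty block in baseline modulation test",
          class = "thetasync_baseline_error")
  }
  starts <- trials$cue_time - 2.5
  counts <- vapply(starts, function(s) {
    sum(spike_times >= s & spike_times < s + 2)
  }, numeric(1))
  if (sd(counts) == 0) {
    return(list(modulated = FALSE, p = 1, direction = "none",
                counts = counts))
  }
  kw <- kruskal.test(counts, as.factor(trials$block))
  dir <- src_direction(counts, trials$block)$sign
  list(modulated = kw$p.value < alpha, p = kw$p.value, direction = dir,
       counts = counts)
}

#' Correlation between peri-action firing rate and response time
#'
#' Pearson correlation of per-trial peri-action spike counts with the
#' log-transformed response time, two-sided.
#'
#' @param counts Per-trial peri-action counts (>= 10 trials).
#' @param rts Per-trial response times (s), log-transformed internally.
#' @return List `r`, `p`, `flagged` (zero-variance input).
#' @export
rate_rt_correlation <- function(counts, rts) {
  if (length(counts) < 10) {
    abort("rate_rt_correlation needs >= 10 trials",
          class = "thetasync_corr_error")
  }
  if (sd(counts) == 0 || sd(rts) == 0) {
    return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
  }
  ct <- cor.test(counts, log(rts))
  list(r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

#' Per-unit punishment-encoding analysis of a session
#'
#' For every unit: bins peri-event counts (200 ms window, 50 ms steps by
#' default) on shock-excluded trials, computes the omega PEV trace, builds
#' trial-shuffled pointwise/global bands, flags encoders, and summarizes the
#' response direction (SRC) and the firing-rate/response-time correlation over
#' the peri-event epoch.
#'
#' @param session An `ephys_session`.
#' @param align,window,bin_width,bin_step Peri-event binning geometry.
#' @param epoch Sub-epoch (s, relative to the event) pooled for the SRC
#'   summary and RT correlation.
#' @param n_shuffles,alpha Surrogate band parameters.
#' @param seed Seed for surrogate shuffles; each unit gets a reproducible
#'   substream keyed by its unit_id.
#' @return Tibble with one row per unit: encoder flag, crossing bins, max
#'   omega PEV, global band, summary SRC and direction, baseline modulation,
#'   RT correlation, and the `encoding_result` as a list-column.
#' @export
encode_units <- function(session, align = "action", window = c(-1, 1),
                         bin_width = 0.2, bin_step = 0.05,
                         epoch = c(-0.5, 0.5), n_shuffles = 1000,
                         alpha = 0.01, seed = 1L) {
  trials <- exclude_shock_trials(session$trials)
  tens <- bin_peri_event(session$units, trials, align = align,
                         window = window, bin_width = bin_width,
                         bin_step = bin_step)
  in_epoch <- tens$centers >= epoch[1] & tens$centers <= epoch[2]
  rows <- purrr::map(seq_along(tens$unit_id), function(u) {
    counts <- tens$counts[u, , ]
    wpev <- wpev_trace(counts, trials$block)
    bands <- surrogate_bands(counts, trials$block, n_shuffles = n_shuffles,
                             alpha = alpha,
                             seed = derive_seed(seed, tens$unit_id[u]))
    res <- classify_encoder(wpev, bands, unit_id = tens$unit_id[u],
                            centers = tens$centers)
    pooled <- rowSums(counts[, in_epoch, drop = FALSE])
    src_res <- src_direction(counts[, in_epoch, drop = FALSE], trials$block)
    bm <- baseline_block_modulation(session$units$spike_times[[u]], trials)
    rc <- rate_rt_correlation(pooled, trials$rt)
    tibble::tibble(
      unit_id = tens$unit_id[u],
      region = session$units$region[u],
      encoder = res$encoder,
      n_crossing = length(res$crossing_bins),
      max_wpev = max(wpev),
      global_band = bands$global,
      src = src_res$summary_src,
      direction = src_res$sign,
      baseline_modulated = bm$modulated,
      baseline_p = bm$p,
      baseline_direction = bm$direction,
      rt_r = rc$r,
      rt_p = rc$p,
      result = list(res)
    )
  })
  dplyr::bind_rows(rows)
}
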