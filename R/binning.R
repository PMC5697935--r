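#' Bin spikes into a peri-event unit x trial x bin tensor
#'
#' Counts spikes in half-open bins `[event + start_b, event + start_b +
#' bin_width)` tiled across `window` with step `bin_step` (overlapping bins
#' allowed, e.g. the 200 ms window stepping by 50 ms used by the encoding
#' statistic). Shock trials should be excluded before binning (see
#' [exclude_shock_trials()]); binning uses the trials it is given.
#'
#' @param units Unit table of an `ephys_session` (or a session, in which case
#'   its units and, unless supplied, its trials are used).
#' @param trials Trial table; every trial must carry the alignment event.
#' @param align One of `"cue"`, `"action"`, `"reward"`, `"baseline"`. The
#'   baseline alignment anchors bins at the start of the 2 s baseline window
#'   beginning 2.5 s before cue onset (its natural window is `c(0, 2)`).
#' @param window Two-element window (s) relative to the event, half-open bins.
#' @param bin_width,bin_step Bin geometry in seconds.
#' @return A `peri_event_tensor`: list with `counts` (unit x trial x bin
#'   array), `unit_id`, `trial_id`, `block`, bin geometry, `centers`, and a
#'   `values` field naming what the array holds (`"counts"`).
#' @export
bin_peri_event <- function(units, trials = NULL, align = "action",
                           window = c(-2, 2), bin_width = 0.05,
                           bin_step = bin_width) {
  if (inherits(units, "ephys_session")) {
    if (is.null(trials)) trials <- units$trials
    units <- units$units
  }
  align <- match.arg(align, c("cue", "action", "reward", "baseline"))
  ev <- switch(align,
    cue = trials$cue_time,
    action = trials$action_time,
    reward = trials$reward_time,
    baseline = trials$cue_time - 2.5
  )
  if (anyNA(ev)) {
    abort(sprintf("alignment event '%s' missing on trial %s", align,
                  paste(trials$trial_id[is.na(ev)], collapse = ", ")),
          class = "thetasync_binning_error")
  }
  starts <- bin_starts(window, bin_width, bin_step)
  n_u <- nrow(units)
  n_t <- length(ev)
  n_b <- length(starts)
  counts <- array(0, dim = c(n_u, n_t, n_b))
  for (u in seq_len(n_u)) {
    st <- units$spike_times[[u]]
    for (tr in seq_len(n_t)) {
      rel <- st[st >= ev[tr] + window[1] & st < ev[tr] + window[2] + bin_width]
      rel <- rel - ev[tr]
      if (length(rel)) {
        counts[u, tr, ] <- vapply(
          starts, function(s) sum(rel >= s & rel < s + bin_width), numeric(1)
        )
      }
    }
  }
  structure(
    list(counts = counts, unit_id = units$unit_id,
         trial_id = trials$trial_id, block = trials$block,
         align = align, window = window,
         bin_width = bin_width, bin_step = bin_step,
         centers = starts + bin_width / 2, values = "counts"),
    class = "peri_event_tensor"
  )
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  cat(sprintf(
    "<peri_event_tensor> %d units x %d trials x %d bins (%s), align=%s, window=[%g, %g] s, bin %g s step %g s\n",
    dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3], x$values,
    x$align, x$window[1], x$window[2], x$bin_width, x$bin_step
  ))
  invisible(x)
}

#' Convert counts to firing rates and smooth across bins
#'
#' Divides counts by the bin width and applies a centered boxcar across
#' `n_smooth` bins (default five, matching the 5 x 50 ms smoothing of the
#' trial-averaged rate analysis). The boxcar is truncated and renormalized at
#' the epoch edges.
#'
#' @param tensor A `peri_event_tensor` of counts.
#' @param n_smooth Boxcar length in bins; 1 disables smoothing.
#' @return The tensor with `values = "rates"`.
#' @export
tensor_to_rates <- function(tensor, n_smooth = 5) {
  x <- tensor$counts / tensor$bin_width
  if (n_smooth > 1) {
    n_b <- dim(x)[3]
    half <- (n_smooth - 1) %/% 2
    sm <- array(0, dim = dim(x))
    for (b in seq_len(n_b)) {
      lo <- max(1, b - half)
      hi <- min(n_b, b + half)
      sm[, , b] <- apply(x[, , lo:hi, drop = FALSE], c(1, 2), mean)
    }
    x <- sm
  }
  tensor$counts <- x
  tensor$values <- "rates"
  tensor
}

#' Z-score a peri-event tensor against its baseline epoch
#'
#' Each unit's rates are standardized by the mean and standard deviation of
#' its baseline firing rate, pooled over baseline bins and trials. Units with
#' zero baseline variance are flagged and their z-scores set to `NA` so they
#' drop out of downstream averages.
#'
#' @param tensor A `peri_event_tensor` (converted to rates if still counts).
#' @param baseline A `peri_event_tensor` over the baseline epoch for the same
#'   units (see `align = "baseline"` in [bin_peri_event()]).
#' @return The tensor with `values = "zscores"` and an attribute
#'   `flagged_units` listing zero-variance units.
#' @export
zscore_to_baseline <- function(tensor, baseline) {
  if (tensor$values == "counts") tensor <- tensor_to_rates(tensor, 1)
  if (baseline$values == "counts") baseline <- tensor_to_rates(baseline, 1)
  stopifnot(identical(tensor$unit_id, baseline$unit_id))
  if (dim(baseline$counts)[2] < 2) {
    abort("baseline needs at least 2 trials", class = "thetasync_baseline_error")
  }
  flagged <- character(0)
  for (u in seq_along(tensor$unit_id)) {
    base_u <- baseline$counts[u, , ]
    m <- mean(base_u)
    s <- sd(as.vector(base_u))
    if (!is.finite(s) || s == 0) {
      flagged <- c(flagged, tensor$unit_id[u])
      tensor$counts[u, , ] <- NA_real_
    } else {
      tensor$counts[u, , ] <- (tensor$counts[u, , ] - m) / s
    }
  }
  if (length(flagged)) {
    warn(sprintf("zero baseline variance; z undefined for unit %s",
                 paste(flagged, collapse = ", ")))
  }
  tensor$values <- "zscores"
  attr(tensor, "flagged_units") <- flagged
  tensor
}
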