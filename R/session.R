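#' Trial-structured electrophysiology session container
#'
#' An `ephys_session` bundles the three data streams recorded in one behavioral
#' session: a trial/event table, per-unit spike trains, and per-region LFP
#' traces, plus provenance metadata (seed, generator config when synthetic).
#'
#' @param trials Tibble with one row per trial: `trial_id`, `block` (integer in
#'   1..3), `cue_time`, `action_time`, `reward_time` (seconds from session
#'   start), `shock_flag` (logical), `rt`, `immobile_rt`, `reward_rt` (seconds).
#' @param units Tibble with one row per single unit: `unit_id`, `region`
#'   (`"mPFC"` or `"VTA"`), `waveform_width` (ms), `spike_times` (list-column of
#'   strictly increasing numeric vectors, seconds). A `baseline_rate` column
#'   (Hz) is computed from the inter-trial baseline windows if absent.
#' @param lfp Tibble with one row per recorded region: `region`, `fs` (Hz),
#'   `t0` (seconds), `samples` (list-column of numeric vectors, microvolts).
#' @param meta Named list of session metadata; `duration` (s) is computed from
#'   the data if not supplied. A `seed` entry records provenance for synthetic
#'   sessions.
#' @param validate Validate all invariants (strict by default); set to `FALSE`
#'   only for deliberately malformed test inputs.
#'
#' @return An object of class `ephys_session`.
#' @export
ephys_session <- function(trials, units, lfp = NULL, meta = list(),
                          validate = TRUE) {
  trials <- tibble::as_tibble(trials)
  units <- tibble::as_tibble(units)
  if (!"rt" %in% names(trials)) {
    trials$rt <- trials$action_time - trials$cue_time
  }
  if (!"immobile_rt" %in% names(trials)) trials$immobile_rt <- 0
  if (!"reward_rt" %in% names(trials)) trials$reward_rt <- NA_real_
  if (is.null(meta$duration)) {
    dur <- max(trials$reward_time) + 5
    if (!is.null(lfp) && nrow(lfp) > 0) {
      dur <- max(dur, max(purrr::map2_dbl(
        lfp$samples, seq_len(nrow(lfp)),
        function(s, i) lfp$t0[i] + length(s) / lfp$fs[i]
      )))
    }
    meta$duration <- dur
  }
  if (!"baseline_rate" %in% names(units)) {
    units$baseline_rate <- purrr::map_dbl(
      units$spike_times, compute_baseline_rate, trials = trials
    )
  }
  out <- structure(
    list(trials = trials, units = units, lfp = lfp, meta = meta),
    class = "ephys_session"
  )
  if (validate) validate_session(out)
  out
}

#' @export
print.ephys_session <- function(x, ...) {
  n_reg <- table(x$units$region)
  cat("<ephys_session>\n")
  cat(sprintf("  trials: %d in %d blocks (%d shock)\n",
              nrow(x$trials), length(unique(x$trials$block)),
              sum(x$trials$shock_flag)))
  cat(sprintf("  units : %s\n",
              paste(sprintf("%s=%d", names(n_reg), n_reg), collapse = ", ")))
  if (!is.null(x$lfp)) {
    cat(sprintf("  lfp   : %s @ %s Hz\n",
                paste(x$lfp$region, collapse = ", "),
                paste(unique(x$lfp$fs), collapse = "/")))
  }
  cat(sprintf("  duration: %.1f s; seed: %s\n", x$meta$duration,
              x$meta$seed %||% "NA"))
  invisible(x)
}

# Mean firing rate (Hz) over the pre-cue baseline windows of all trials.
# Baseline epoch: 2 s window beginning 2.5 s before cue onset.
compute_baseline_rate <- function(spike_times, trials,
                                  baseline_offset = -2.5, baseline_len = 2) {
  starts <- trials$cue_time + baseline_offset
  starts <- pmax(starts, 0)
  n <- sum(vapply(starts, function(s) {
    sum(spike_times >= s & spike_times < s + baseline_len)
  }, numeric(1)))
  n / (length(starts) * baseline_len)
}

#' Validate an ephys_session against its structural invariants
#'
#' Checks event ordering (cue < action < reward per trial), consistency of the
#' derived `rt` column, shock flags confined to blocks 2-3, `immobile_rt <= rt`,
#' sorted non-negative spike times inside the session span, positive waveform
#' widths, and LFP sampling rates high enough for a 125 Hz analysis ceiling.
#'
#' @param session An `ephys_session`.
#' @return The session, invisibly; aborts with the offending trial/unit id on
#'   violation.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  bad <- which(!(tr$cue_time < tr$action_time & tr$action_time < tr$reward_time))
  if (length(bad)) {
    abort(sprintf("event order violated (cue < action < reward) on trial %s",
                  paste(tr$trial_id[bad], collapse = ", ")),
          class = "thetasync_validation_error")
  }
  bad <- which(abs(tr$rt - (tr$action_time - tr$cue_time)) > 1e-9)
  if (length(bad)) {
    abort(sprintf("rt != action_time - cue_time on trial %s",
                  paste(tr$trial_id[bad], collapse = ", ")),
          class = "thetasync_validation_error")
  }
  bad <- which(tr$shock_flag & tr$block == 1L)
  if (length(bad)) {
    abort(sprintf("shock_flag set in block 1 on trial %s",
                  paste(tr$trial_id[bad], collapse = ", ")),
          class = "thetasync_validation_error")
  }
  bad <- which(tr$immobile_rt > tr$rt + 1e-9)
  if (length(bad)) {
    abort(sprintf("immobile_rt exceeds rt on trial %s",
                  paste(tr$trial_id[bad], collapse = ", ")),
          class = "thetasync_validation_error")
  }
  tpb <- session$meta$trials_per_block
  if (!is.null(tpb)) {
    sizes <- table(tr$block)
    if (any(sizes != tpb)) {
      abort(sprintf("block sizes %s do not equal configured trials_per_block %d",
                    paste(sizes, collapse = "/"), tpb),
            class = "thetasync_validation_error")
    }
  }
  un <- session$units
  for (i in seq_len(nrow(un))) {
    st <- un$spike_times[[i]]
    if (length(st) && (is.unsorted(st, strictly = FALSE) || st[1] < 0 ||
                       st[length(st)] > session$meta$duration + 1e-6)) {
      abort(sprintf("spike times of unit %s unsorted or outside session span",
                    un$unit_id[i]),
            class = "thetasync_validation_error")
    }
  }
  if (any(un$waveform_width <= 0)) {
    abort("waveform_width must be positive",
          class = "thetasync_validation_error")
  }
  if (!is.null(session$lfp) && any(session$lfp$fs < 250)) {
    abort("LFP sampling rate below 250 Hz cannot support the 125 Hz ceiling",
          class = "thetasync_validation_error")
  }
  invisible(session)
}

#' Drop trials on which a foot shock was delivered
#'
#' Shock-delivery trials (three in block 2 and five in block 3 under the
#' default task contingencies) are contaminated by electrical artifact and are
#' excluded from every neural analysis. Row order of the remaining trials is
#' preserved.
#'
#' @param trials A trial table (tibble) with a `shock_flag` column, or an
#'   `ephys_session` (its trial table is used).
#' @return The trial table with all flagged trials removed.
#' @export
exclude_shock_trials <- function(trials) {
  if (inherits(trials, "ephys_session")) trials <- trials$trials
  out <- dplyr::filter(trials, !.data$shock_flag)
  empty <- setdiff(unique(trials$block), unique(out$block))
  if (length(empty)) {
    warn(sprintf("block %s has no trials left after shock exclusion",
                 paste(empty, collapse = ", ")))
  }
  out
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `trials.tsv` (trial table), `spikes.tsv` (long table: unit_id,
#' region, waveform_width, spike_time), `lfp.tsv` (long table: region, sample
#' value, in recording order), and `session.json` (per-region fs/t0, duration,
#' seed and generator config). Full double precision is retained.
#'
#' @param session An `ephys_session`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    })
    df
  }
  data.table::fwrite(fmt(session$trials), file.path(path, "trials.tsv"),
                     sep = "\t")
  spikes_long <- tidyr::unnest(
    dplyr::select(session$units, "unit_id", "region", "waveform_width",
                  "spike_times"),
    "spike_times"
  )
  names(spikes_long)[names(spikes_long) == "spike_times"] <- "spike_time"
  data.table::fwrite(fmt(spikes_long), file.path(path, "spikes.tsv"),
                     sep = "\t")
  meta <- session$meta
  if (!is.null(session$lfp)) {
    lfp_long <- tidyr::unnest(dplyr::select(session$lfp, "region", "samples"),
                              "samples")
    names(lfp_long)[names(lfp_long) == "samples"] <- "sample"
    data.table::fwrite(fmt(lfp_long), file.path(path, "lfp.tsv"), sep = "\t")
    meta$lfp_channels <- purrr::pmap(
      session$lfp[, c("region", "fs", "t0")], list
    )
  }
  meta$unit_meta <- purrr::pmap(
    session$units[, c("unit_id", "region", "waveform_width")], list
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from a directory written by [write_session()]
#'
#' Derived fields (`rt`, per-unit baseline rates) are recomputed; an `rt`
#' column inconsistent with `action_time - cue_time` fails validation.
#'
#' @param path Session directory.
#' @param validate Run [validate_session()] after loading (default `TRUE`).
#' @return An `ephys_session`.
#' @export
read_session <- function(path, validate = TRUE) {
  need <- c("trials.tsv", "spikes.tsv", "session.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("session file missing: %s", file.path(path, f)),
            class = "thetasync_load_error")
    }
  }
  trials <- tibble::as_tibble(data.table::fread(
    file.path(path, "trials.tsv"), sep = "\t"
  ))
  trials$shock_flag <- as.logical(trials$shock_flag)
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = FALSE)
  unit_meta <- dplyr::bind_rows(lapply(meta$unit_meta, tibble::as_tibble))
  spikes_long <- tibble::as_tibble(data.table::fread(
    file.path(path, "spikes.tsv"), sep = "\t"
  ))
  by_unit <- split(spikes_long$spike_time, spikes_long$unit_id)
  units <- unit_meta
  units$spike_times <- lapply(units$unit_id, function(u) {
    sort(by_unit[[as.character(u)]] %||% numeric(0))
  })
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.tsv")) &&
      !is.null(meta$lfp_channels)) {
    lfp_long <- data.table::fread(file.path(path, "lfp.tsv"), sep = "\t")
    chans <- dplyr::bind_rows(lapply(meta$lfp_channels, tibble::as_tibble))
    chans$samples <- lapply(chans$region, function(r) {
      lfp_long$sample[lfp_long$region == r]
    })
    lfp <- chans
  }
  keep <- c("duration", "seed", "trials_per_block", "config", "synthetic")
  meta_out <- meta[intersect(names(meta), keep)]
  if ("rt" %in% names(trials)) {
    off <- which(abs(trials$rt - (trials$action_time - trials$cue_time)) > 1e-9)
    if (length(off)) {
      warn(sprintf("stored rt mismatches action - cue on trial %s; recomputed",
                   paste(trials$trial_id[off], collapse = ", ")))
    }
  }
  trials$rt <- trials$action_time - trials$cue_time
  ephys_session(trials, units, lfp, meta_out, validate = validate)
}
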