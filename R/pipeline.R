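#' Descriptive behavioral summary of a trial table
#'
#' Per-block mean and variance of response time, immobile RT, and reward
#' retrieval latency, plus the RT profile by trial lag (distance) from the
#' previous shock.
#'
#' @param trials Trial table.
#' @param max_lag Largest shock lag summarized.
#' @return List: `per_block` tibble and `shock_lag` tibble (lag, mean_rt, n).
#' @export
behavioral_summary <- function(trials, max_lag = 10) {
  per_block <- dplyr::summarise(
    dplyr::group_by(trials, .data$block),
    mean_rt = mean(.data$rt), var_rt = var(.data$rt),
    mean_immobile_rt = mean(.data$immobile_rt),
    mean_reward_rt = mean(.data$reward_rt),
    n = dplyr::n(), n_shock = sum(.data$shock_flag),
    .groups = "drop"
  )
  lag_since_shock <- rep(NA_integer_, nrow(trials))
  last_shock <- NA_integer_
  ord <- order(trials$cue_time)
  for (i in ord) {
    if (!is.na(last_shock)) lag_since_shock[i] <- i - last_shock
    if (trials$shock_flag[i]) last_shock <- i
  }
  ok <- !is.na(lag_since_shock) & lag_since_shock <= max_lag
  shock_lag <- if (any(ok)) {
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(lag = lag_since_shock[ok], rt = trials$rt[ok]),
        .data$lag
      ),
      mean_rt = mean(.data$rt), n = dplyr::n(), .groups = "drop"
    )
  } else {
    tibble::tibble(lag = integer(0), mean_rt = numeric(0), n = integer(0))
  }
  list(per_block = per_block, shock_lag = shock_lag)
}

#' Run the full analysis pipeline on a session
#'
#' Executes shock-trial exclusion, per-unit punishment-encoding analysis, VTA
#' cell classification, population GPFA trajectory/RT correlation, blockwise
#' theta power and coherence, spectral Granger causality, and spike-field
#' phase locking, and returns a machine-readable summary. Stages that need
#' LFP are skipped (with a note in the summary) when the session has none.
#'
#' @param session An `ephys_session` (or a path readable by
#'   [read_session()]).
#' @param out_dir Optional directory; when given, stage tables are written as
#'   TSV and the summary as JSON.
#' @param n_shuffles,alpha_encoding Encoding-band parameters.
#' @param gpfa_region Region for the population trajectory stage (needs 10+
#'   units).
#' @param gpfa_p GPFA dimensionality (5).
#' @param n_iter_plv PLV resampling iterations.
#' @param theta_band Theta band (Hz).
#' @param seed Base seed for all surrogate/resampling streams.
#' @param stages Character vector choosing stages; default all.
#' @return List of stage results plus `summary` (named list of headline
#'   numbers) and `provenance` (seed, parameters, included trials).
#' @export
run_all <- function(session, out_dir = NULL, n_shuffles = 1000,
                    alpha_encoding = 0.01, gpfa_region = "mPFC", gpfa_p = 5,
                    n_iter_plv = 1000, theta_band = c(5, 15), seed = 1L,
                    stages = c("behavior", "encoding", "cells", "gpfa",
                               "spectra", "granger", "phase")) {
  if (is.character(session)) session <- read_session(session)
  trials <- exclude_shock_trials(session$trials)
  out <- list(provenance = list(
    seed = seed, n_shuffles = n_shuffles, alpha_encoding = alpha_encoding,
    theta_band = theta_band, included_trials = trials$trial_id
  ))
  summary <- list()

  if ("behavior" %in% stages) {
    out$behavior <- behavioral_summary(session$trials)
    summary$mean_rt_by_block <- out$behavior$per_block$mean_rt
  }
  if ("encoding" %in% stages) {
    out$encoding <- encode_units(session, n_shuffles = n_shuffles,
                                 alpha = alpha_encoding, seed = seed)
    enc <- out$encoding
    summary$prop_encoders_by_region <- vapply(
      split(enc$encoder, enc$region), mean, numeric(1)
    )
  }
  if ("cells" %in% stages && any(session$units$region == "VTA")) {
    out$cells <- classify_vta_units(session)
    summary$n_putative_da <- sum(out$cells$label == "putative_DA")
    if (!is.null(out$encoding)) {
      lbl <- out$cells$label[match(out$encoding$unit_id, out$cells$unit_id)]
      grp <- ifelse(out$encoding$region == "mPFC", "mPFC", lbl)
      summary$prop_encoders_by_class <- vapply(
        split(out$encoding$encoder, grp), mean, numeric(1)
      )
    }
  }
  if ("gpfa" %in% stages &&
      sum(session$units$region == gpfa_region) >= 10) {
    out$gpfa <- population_trajectories(session, gpfa_region, p = gpfa_p,
                                        max_iter = 100, tol = 1e-6)
    summary$trajectory_rt_r <- out$gpfa$correlation$r_total
    summary$trajectory_rt_p <- out$gpfa$correlation$p_total
  }
  has_lfp <- !is.null(session$lfp) && nrow(session$lfp) == 2
  if ("spectra" %in% stages && has_lfp) {
    theta_z <- numeric(0)
    for (b in sort(unique(trials$block))) {
      trb <- trials[trials$block == b, ]
      iv <- which(session$lfp$region == "VTA")
      spec <- multitaper_spectrogram(session$lfp$samples[[iv]],
                                     session$lfp$fs[iv], trb,
                                     align = "action", window = c(-2, 2),
                                     t0 = session$lfp$t0[iv])
      base <- multitaper_spectrogram(session$lfp$samples[[iv]],
                                     session$lfp$fs[iv], trb,
                                     align = "baseline", window = c(-1, 1),
                                     t0 = session$lfp$t0[iv])
      z <- normalize_spectrogram(spec, base)
      inb <- z$freqs >= theta_band[1] & z$freqs <= theta_band[2]
      pre <- z$window_centers >= -1 & z$window_centers <= 0
      theta_z <- c(theta_z, mean(z$power[pre, inb], na.rm = TRUE))
    }
    out$theta_power_z <- theta_z
    summary$vta_theta_z_by_block <- theta_z
  }
  if ("granger" %in% stages && has_lfp) {
    out$granger <- granger_blockwise(session, theta_band = theta_band)
    ts <- attr(out$granger, "theta_summary")
    summary$gc_theta_vta_to_mpfc <- ts$gc_vta_to_mpfc
    summary$gc_theta_mpfc_to_vta <- ts$gc_mpfc_to_vta
  }
  if ("phase" %in% stages && has_lfp) {
    out$phase <- dplyr::bind_rows(
      phase_locking_analysis(session, "mPFC", "VTA", band = theta_band,
                             n_iter = n_iter_plv, seed = seed),
      phase_locking_analysis(session, "VTA", "VTA", band = theta_band,
                             n_iter = n_iter_plv, seed = seed)
    )
    cmp <- blockwise_plv_comparison(out$phase)
    out$plv_comparison <- cmp
    summary$mean_plv_by_block <- cmp$per_block$mean_plv
  }
  out$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$encoding)) {
      data.table::fwrite(
        dplyr::select(out$encoding, -"result"),
        file.path(out_dir, "encoding_results.tsv"), sep = "\t"
      )
    }
    if (!is.null(out$cells)) {
      data.table::fwrite(out$cells, file.path(out_dir, "vta_classes.tsv"),
                         sep = "\t")
    }
    if (!is.null(out$phase)) {
      data.table::fwrite(out$phase, file.path(out_dir, "plv_results.tsv"),
                         sep = "\t")
    }
    jsonlite::write_json(
      c(summary, list(provenance = out$provenance)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}
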