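#' auROC reward-response profile of a unit
#'
#' For each 100 ms bin from 0.5 s before to 1 s after reward delivery (15
#' bins), computes the area under the ROC curve comparing the across-trial
#' distribution of firing rates in that bin against the across-trial
#' distribution of baseline firing rates. Computed via the Mann-Whitney
#' identity with ties counted 0.5; 0.5 means no discrimination from baseline,
#' 1 means every trial's rate exceeds every baseline rate.
#'
#' @param spike_times Spike times (s) of one unit.
#' @param trials Trial table (shock trials excluded upstream; >= 10 trials).
#' @param window Epoch around reward (s), default `c(-0.5, 1)`.
#' @param bin_width Bin width (s), default 0.1.
#' @return Numeric vector of per-bin auROC values in `[0, 1]`.
#' @export
auroc_profile <- function(spike_times, trials, window = c(-0.5, 1),
                          bin_width = 0.1) {
  if (nrow(trials) < 10) {
    abort("auroc_profile needs >= 10 trials", class = "thetasync_auroc_error")
  }
  base_starts <- trials$cue_time - 2.5
  baseline <- vapply(base_starts, function(s) {
    sum(spike_times >= s & spike_times < s + 2) / 2
  }, numeric(1))
  if (length(baseline) == 0) {
    abort("empty baseline", class = "thetasync_auroc_error")
  }
  starts <- bin_starts(window, bin_width, bin_width)
  vapply(starts, function(s) {
    rates <- vapply(trials$reward_time + s, function(t0) {
      sum(spike_times >= t0 & spike_times < t0 + bin_width) / bin_width
    }, numeric(1))
    auroc(rates, baseline)
  }, numeric(1))
}

# Two-component Gaussian mixture with the covariance structure chosen by
# BIC, fitted both from mclust's model-based hierarchical initialization and
# from EM restarts seeded by k-means (20 restarts); the solution with the
# best BIC wins. Small samples make single-initialization EM land in poor
# local optima often enough to matter.
fit_gmm2 <- function(scores, model_names, seed) {
  n <- nrow(scores)
  cands <- list()
  mc <- tryCatch(
    mclust::Mclust(scores, G = 2, modelNames = model_names,
                   prior = mclust::priorControl(), verbose = FALSE),
    error = function(e) NULL
  )
  if (!is.null(mc)) {
    cands[[length(cands) + 1]] <- list(
      classification = mc$classification, bic = mc$bic,
      modelName = mc$modelName, fit = mc
    )
  }
  km <- with_seed(seed, stats::kmeans(scores, 2, nstart = 20))
  z0 <- mclust::unmap(km$cluster)
  for (mn in model_names) {
    f <- tryCatch(
      mclust::me(data = scores, modelName = mn, z = z0,
                 prior = mclust::priorControl()),
      error = function(e) NULL
    )
    if (is.null(f) || !is.finite(f$loglik)) next
    df <- mclust::nMclustParams(mn, ncol(scores), 2) + 2 - 1
    cands[[length(cands) + 1]] <- list(
      classification = mclust::map(f$z), bic = 2 * f$loglik - df * log(n),
      modelName = mn, fit = f
    )
  }
  if (!length(cands)) return(NULL)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "bic"))]]
}

# auROC of `pos` vs `neg` distributions: P(pos > neg) + 0.5 P(pos == neg),
# via mid-ranks (Mann-Whitney identity).
auroc <- function(pos, neg) {
  n1 <- length(pos)
  n2 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' PCA + Gaussian-mixture clustering of auROC reward-response profiles
#'
#' Column-mean-centers the units x bins auROC matrix, decomposes it by SVD,
#' maps units into the space of the top principal components, and fits a
#' 2-component Gaussian mixture by EM, selecting the covariance structure
#' (spherical to full) by BIC with a conjugate prior for regularization —
#' an unconstrained full covariance is under-determined at the unit counts
#' a single session yields. The cluster whose mean
#' profile shows phasic post-reward elevation — the larger mean auROC within
#' 0-300 ms after reward — is labeled `Type1` (the putative-DA reward
#' signature); the other is `Type2`. Labels are anchored by this criterion,
#' not by mixture-component index.
#'
#' @param profiles Units x bins auROC matrix (rownames = unit ids); bins
#'   assumed to span `window` with `bin_width` spacing.
#' @param n_pc Number of principal components retained (3).
#' @param window,bin_width Geometry of the profile bins, used to locate the
#'   0-300 ms post-reward bins for the Type1 anchor.
#' @param model_names Candidate mclust covariance structures, chosen by BIC.
#' @param seed Seed for the k-means-seeded EM restarts.
#' @return List: `cluster` (factor `Type1`/`Type2` per unit), `pc_scores`,
#'   `loadings`, `center`, `cluster_means` (mean auROC profile per cluster),
#'   `degenerate` flag, and the fitted mclust model.
#' @export
pca_cluster <- function(profiles, n_pc = 3, window = c(-0.5, 1),
                        bin_width = 0.1,
                        model_names = c("EII", "VII", "EEE", "VVV"),
                        seed = 1L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 4) {
    abort("pca_cluster needs at least 2x more units than mixture components",
          class = "thetasync_cluster_error")
  }
  ctr <- colMeans(profiles)
  xc <- sweep(profiles, 2, ctr)
  if (all(abs(xc) < 1e-12)) {
    return(list(cluster = factor(rep("Type1", nrow(profiles)),
                                 levels = c("Type1", "Type2")),
                pc_scores = matrix(0, nrow(profiles), n_pc),
                loadings = NULL, center = ctr, cluster_means = NULL,
                degenerate = TRUE, model = NULL))
  }
  sv <- svd(xc)
  n_pc <- min(n_pc, sum(sv$d > 1e-10))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  rownames(scores) <- rownames(profiles)
  fit <- fit_gmm2(scores, model_names, seed)
  if (is.null(fit)) {
    abort("Gaussian mixture EM failed to converge in all restarts",
          class = "thetasync_cluster_error")
  }
  comp <- fit$classification
  centers <- bin_starts(window, bin_width, bin_width) + bin_width / 2
  phasic <- centers > 0 & centers <= 0.3
  mean_prof <- rbind(colMeans(profiles[comp == 1, , drop = FALSE]),
                     colMeans(profiles[comp == 2, , drop = FALSE]))
  type1_comp <- which.max(rowMeans(mean_prof[, phasic, drop = FALSE]))
  cluster <- factor(ifelse(comp == type1_comp, "Type1", "Type2"),
                    levels = c("Type1", "Type2"))
  list(cluster = cluster, pc_scores = scores,
       loadings = sv$v[, seq_len(n_pc), drop = FALSE], center = ctr,
       cluster_means = rbind(Type1 = mean_prof[type1_comp, ],
                             Type2 = mean_prof[3 - type1_comp, ]),
       degenerate = FALSE, model = fit)
}

#' Dual-criterion putative dopamine classification of a VTA unit
#'
#' A VTA unit is putative DA iff (1) its mean baseline firing rate is slower
#' than 12 Hz AND its waveform width is greater than 1.2 ms (both strict), and
#' (2) its reward-response cluster is `Type1` (phasic excitation to reward).
#' Units meeting either or neither criterion are putative non-DA.
#'
#' @param baseline_rate Baseline firing rate(s), Hz.
#' @param waveform_width Waveform width(s), ms.
#' @param cluster Cluster label(s), `"Type1"`/`"Type2"`.
#' @return Character vector: `"putative_DA"` or `"putative_nonDA"`.
#' @export
classify_vta_unit <- function(baseline_rate, waveform_width, cluster) {
  if (anyNA(baseline_rate) || anyNA(waveform_width) || anyNA(cluster)) {
    abort("missing metadata in classify_vta_unit",
          class = "thetasync_classify_error")
  }
  ifelse(baseline_rate < 12 & waveform_width > 1.2 & cluster == "Type1",
         "putative_DA", "putative_nonDA")
}

#' Classify all VTA units of a session
#'
#' Runs [auroc_profile()] for every VTA unit on shock-excluded trials,
#' clusters the profiles with [pca_cluster()], and applies the dual-criterion
#' rule of [classify_vta_unit()]. mPFC units are never classified; units with
#' baseline rates above 20 Hz are flagged as metadata only.
#'
#' @param session An `ephys_session` with VTA units.
#' @param ... Passed to [pca_cluster()].
#' @return Tibble: unit_id, baseline_rate, waveform_width, cluster, label,
#'   fast_spiking flag; the `pca_cluster()` output is attached as attribute
#'   `"clustering"`.
#' @export
classify_vta_units <- function(session, ...) {
  trials <- exclude_shock_trials(session$trials)
  vta <- dplyr::filter(session$units, .data$region == "VTA")
  if (nrow(vta) == 0) {
    abort("no VTA units in session", class = "thetasync_classify_error")
  }
  profs <- t(vapply(vta$spike_times, auroc_profile, numeric(15),
                    trials = trials))
  rownames(profs) <- vta$unit_id
  cl <- pca_cluster(profs, ...)
  out <- tibble::tibble(
    unit_id = vta$unit_id,
    baseline_rate = vta$baseline_rate,
    waveform_width = vta$waveform_width,
    cluster = as.character(cl$cluster),
    label = classify_vta_unit(vta$baseline_rate, vta$waveform_width,
                              cl$cluster),
    fast_spiking = vta$baseline_rate > 20
  )
  attr(out, "clustering") <- cl
  out
}
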