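#' Gaussian-process factor analysis (GPFA) of a neural population
#'
#' Fits the linear-Gaussian latent model `y_t | x_t ~ N(C x_t + d, R)` with
#' `R` diagonal, where each latent dimension follows an independent
#' Gaussian-process prior over time bins with a squared-exponential kernel
#' `K_i(t, s) = (1 - s_n) exp(-(t - s)^2 / (2 tau_i^2)) + s_n [t == s]`
#' (unit prior variance for identifiability, small innovation floor `s_n`).
#' Parameters are fitted by EM: the E-step is the closed-form joint-Gaussian
#' posterior over all latents and time bins; the M-step updates `C`, `d`, `R`
#' in closed form and each GP timescale `tau_i` by maximizing its expected
#' complete-data term numerically. Observations should be square-rooted spike
#' counts.
#'
#' @param y Numeric array, units x bins x trials, of square-rooted spike
#'   counts (use [population_counts()] to build it from a session).
#' @param p Latent dimensionality (must be < number of units).
#' @param bin_width Bin width in seconds (used for the timescale grid).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param tau_init Initial GP timescale (s).
#' @param gp_noise Innovation floor `s_n` on the GP kernel diagonal.
#' @param update_tau Update timescales in the M-step (default `TRUE`).
#' @return A `gpfa_model`: `C`, `d`, `R` (diagonal as vector), `tau`,
#'   `loglik` trace, dimensions, convergence flag.
#' @export
gpfa_fit <- function(y, p, bin_width = 0.02, max_iter = 200, tol = 1e-8,
                     tau_init = 0.1, gp_noise = 1e-3, update_tau = TRUE) {
  dims <- dim(y)
  q <- dims[1]; T_ <- dims[2]; n_tr <- dims[3]
  if (q <= p) abort("need more units than latent dimensions (q > p)",
                    class = "thetasync_gpfa_error")

  # init by PCA on time-pooled observations
  ym <- matrix(y, nrow = q)            # q x (T*n_tr)
  d <- rowMeans(ym)
  yc <- ym - d
  sv <- svd(yc, nu = p, nv = 0)
  C <- sv$u %*% diag(sv$d[seq_len(p)] / sqrt(ncol(ym)), p)
  R <- pmax(apply(yc, 1, function(r) mean(r^2)) -
              rowSums(C^2), 1e-3)
  tau <- rep(tau_init, p)
  tgrid <- (seq_len(T_) - 1) * bin_width

  make_K <- function(tau_i) {
    D2 <- outer(tgrid, tgrid, function(a, b) (a - b)^2)
    (1 - gp_noise) * exp(-D2 / (2 * tau_i^2)) + gp_noise * diag(T_)
  }

  loglik_trace <- numeric(0)
  idx_t <- function(t) (seq_len(p) - 1L) * T_ + t   # latent-major indices

  for (iter in seq_len(max_iter)) {
    ## ---- E-step ----
    Ks <- lapply(tau, make_K)
    Kbar_inv <- matrix(0, p * T_, p * T_)
    logdet_K <- 0
    for (i in seq_len(p)) {
      ch <- chol(Ks[[i]])
      logdet_K <- logdet_K + 2 * sum(log(diag(ch)))
      rng <- ((i - 1) * T_ + 1):(i * T_)
      Kbar_inv[rng, rng] <- chol2inv(ch)
    }
    CtRi <- t(C / R)                       # p x q (rows of C scaled by 1/R)
    CtRiC <- CtRi %*% C                    # p x p
    prec <- Kbar_inv + kronecker(CtRiC, diag(T_))
    prec <- (prec + t(prec)) / 2
    ch_prec <- chol(prec)
    Sigma <- chol2inv(ch_prec)             # posterior covariance (shared)

    # posterior means for all trials: B[, tr] latent-major
    Mu <- matrix(0, p * T_, n_tr)
    for (tr in seq_len(n_tr)) {
      Bt <- CtRi %*% (y[, , tr] - d)       # p x T
      Mu[, tr] <- Sigma %*% as.vector(t(Bt))
    }

    ## ---- log-likelihood of the current model ----
    # ll = sum_tr [ -0.5 (qT log 2pi + logdet(Sbar) + e' Sbar^{-1} e) ]
    # using det/inv identities with the posterior precision:
    # logdet(Sbar) = logdet(K) + logdet(prec) + sum(T*log R)
    # e' Sbar^{-1} e = e'R^{-1}e - b' Sigma b   (b = Cbar'R^{-1}e)
    logdet_S <- logdet_K + 2 * sum(log(diag(ch_prec))) + T_ * sum(log(R))
    quad <- 0
    for (tr in seq_len(n_tr)) {
      e <- y[, , tr] - d
      b <- as.vector(t(CtRi %*% e))
      quad <- quad + sum(e^2 / R) - sum(b * (Sigma %*% b))
    }
    ll <- -0.5 * (n_tr * (q * T_ * log(2 * pi) + logdet_S) + quad)
    loglik_trace <- c(loglik_trace, ll)
    if (iter > 1) {
      dl <- ll - loglik_trace[iter - 1]
      if (abs(dl) < tol * abs(ll)) break
    }

    ## ---- M-step ----
    Sxx <- matrix(0, p, p)
    Sx <- numeric(p)
    Sxy <- matrix(0, q, p)
    Sy <- numeric(q)
    Syy <- numeric(q)
    # cross-time second moments per latent pair, summed over t (for C update)
    # E[x_t x_t'] = Sigma[idx_t, idx_t] + mu_t mu_t'
    Sig_tt <- array(0, dim = c(p, p, T_))
    for (t in seq_len(T_)) Sig_tt[, , t] <- Sigma[idx_t(t), idx_t(t)]
    sum_Sig_tt <- apply(Sig_tt, c(1, 2), sum)
    for (tr in seq_len(n_tr)) {
      Mu_t <- matrix(Mu[, tr], nrow = T_)  # T x p (latent-major unstack)
      Sxx <- Sxx + crossprod(Mu_t)
      Sx <- Sx + colSums(Mu_t)
      Sxy <- Sxy + y[, , tr] %*% Mu_t
      Sy <- Sy + rowSums(y[, , tr])
      Syy <- Syy + rowSums(y[, , tr]^2)
    }
    Sxx <- Sxx + n_tr * sum_Sig_tt
    N <- n_tr * T_
    G <- rbind(cbind(Sxx, Sx), c(Sx, N))
    Cd <- cbind(Sxy, Sy) %*% solve(G)
    C <- Cd[, seq_len(p), drop = FALSE]
    d <- Cd[, p + 1]
    R <- pmax((Syy - rowSums(Cd * cbind(Sxy, Sy))) / N, 1e-6)

    if (update_tau) {
      for (i in seq_len(p)) {
        rng <- ((i - 1) * T_ + 1):(i * T_)
        Ei <- n_tr * Sigma[rng, rng] +
          tcrossprod_rows(Mu, rng)
        nll <- function(log_tau) {
          K <- make_K(exp(log_tau))
          ch <- chol(K)
          n_tr * sum(log(diag(ch))) +
            0.5 * sum(chol2inv(ch) * Ei)
        }
        opt <- optimise(nll, interval = log(c(bin_width / 2, 2)))
        tau[i] <- exp(opt$minimum)
      }
    }
  }

  structure(
    list(C = C, d = d, R = R, tau = tau, gp_noise = gp_noise,
         bin_width = bin_width, p = p, q = q, T = T_,
         n_trials = n_tr, loglik = loglik_trace,
         converged = length(loglik_trace) < max_iter),
    class = "gpfa_model"
  )
}

# sum over trials of Mu[rng, tr] %*% t(Mu[rng, tr])
tcrossprod_rows <- function(Mu, rng) {
  M <- Mu[rng, , drop = FALSE]
  tcrossprod(M)
}

#' @export
print.gpfa_model <- function(x, ...) {
  cat(sprintf(
    "<gpfa_model> q=%d units, p=%d latents, T=%d bins (%g s), %d trials\n",
    x$q, x$p, x$T, x$bin_width, x$n_trials))
  cat(sprintf("  loglik %.2f after %d EM iterations (%sconverged)\n",
              tail(x$loglik, 1), length(x$loglik),
              if (x$converged) "" else "not "))
  cat(sprintf("  timescales: %s ms\n",
              paste(round(x$tau * 1000), collapse = ", ")))
  invisible(x)
}

#' @rdname gpfa_fit
#' @param x A `gpfa_model`.
#' @param ... Unused.
#' @export
tidy.gpfa_model <- function(x, ...) {
  tibble::tibble(
    latent = seq_len(x$p),
    timescale = x$tau,
    loading_norm = sqrt(colSums(x$C^2))
  )
}

#' @rdname gpfa_fit
#' @export
glance.gpfa_model <- function(x, ...) {
  tibble::tibble(
    q = x$q, p = x$p, n_bins = x$T, n_trials = x$n_trials,
    loglik = tail(x$loglik, 1), n_iter = length(x$loglik),
    converged = x$converged
  )
}

#' Posterior latent trajectories under a fitted GPFA model
#'
#' @param model A `gpfa_model`.
#' @param y Units x bins x trials array of square-rooted counts.
#' @return Array p x bins x trials of posterior means `E[x | y]`.
#' @export
gpfa_trajectories <- function(model, y) {
  q <- model$q; T_ <- model$T; p <- model$p
  stopifnot(dim(y)[1] == q, dim(y)[2] == T_)
  n_tr <- dim(y)[3]
  tgrid <- (seq_len(T_) - 1) * model$bin_width
  D2 <- outer(tgrid, tgrid, function(a, b) (a - b)^2)
  Kbar_inv <- matrix(0, p * T_, p * T_)
  for (i in seq_len(p)) {
    K <- (1 - model$gp_noise) * exp(-D2 / (2 * model$tau[i]^2)) +
      model$gp_noise * diag(T_)
    rng <- ((i - 1) * T_ + 1):(i * T_)
    Kbar_inv[rng, rng] <- chol2inv(chol(K))
  }
  CtRi <- t(model$C / model$R)
  prec <- Kbar_inv + kronecker(CtRi %*% model$C, diag(T_))
  prec <- (prec + t(prec)) / 2
  Sigma <- chol2inv(chol(prec))
  out <- array(0, dim = c(p, T_, n_tr))
  for (tr in seq_len(n_tr)) {
    Bt <- CtRi %*% (y[, , tr] - model$d)
    mu <- Sigma %*% as.vector(t(Bt))
    out[, , tr] <- t(matrix(mu, nrow = T_))
  }
  out
}

#' Marginal log-likelihood of data under a fitted GPFA model
#'
#' @param model A `gpfa_model`.
#' @param y Units x bins x trials array.
#' @return Total log-likelihood over trials.
#' @export
gpfa_loglik <- function(model, y) {
  q <- model$q; T_ <- model$T; p <- model$p
  n_tr <- dim(y)[3]
  tgrid <- (seq_len(T_) - 1) * model$bin_width
  D2 <- outer(tgrid, tgrid, function(a, b) (a - b)^2)
  Kbar_inv <- matrix(0, p * T_, p * T_)
  logdet_K <- 0
  for (i in seq_len(p)) {
    K <- (1 - model$gp_noise) * exp(-D2 / (2 * model$tau[i]^2)) +
      model$gp_noise * diag(T_)
    ch <- chol(K)
    logdet_K <- logdet_K + 2 * sum(log(diag(ch)))
    rng <- ((i - 1) * T_ + 1):(i * T_)
    Kbar_inv[rng, rng] <- chol2inv(ch)
  }
  CtRi <- t(model$C / model$R)
  prec <- Kbar_inv + kronecker(CtRi %*% model$C, diag(T_))
  prec <- (prec + t(prec)) / 2
  ch_prec <- chol(prec)
  Sigma <- chol2inv(ch_prec)
  logdet_S <- logdet_K + 2 * sum(log(diag(ch_prec))) +
    T_ * sum(log(model$R))
  ll <- 0
  for (tr in seq_len(n_tr)) {
    e <- y[, , tr] - model$d
    b <- as.vector(t(CtRi %*% e))
    quad <- sum(e^2 / model$R) - sum(b * (Sigma %*% b))
    ll <- ll - 0.5 * (q * T_ * log(2 * pi) + logdet_S + quad)
  }
  ll
}

#' Cross-validated choice of the GPFA latent dimensionality
#'
#' Splits trials into folds, fits each candidate dimensionality on the
#' training trials, and evaluates the held-out marginal log-likelihood. The
#' returned `p_star` follows the plateau (1-SE) rule: the smallest candidate
#' whose mean held-out log-likelihood is within one standard error of the
#' maximum.
#'
#' @param y Units x bins x trials array of square-rooted counts.
#' @param candidates Candidate dimensionalities.
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed for the trial shuffle into folds.
#' @param ... Passed to [gpfa_fit()].
#' @return List: `p_star`, `cv` tibble (candidate, fold, loglik), and the
#'   per-candidate mean/SE table.
#' @export
select_dimensionality <- function(y, candidates, folds = 4, seed = 1L, ...) {
  n_tr <- dim(y)[3]
  if (folds < 2) abort("need >= 2 folds", class = "thetasync_gpfa_error")
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n_tr)))
  if (min(table(fold_id)) < max(candidates)) {
    abort("a fold has fewer trials than the largest candidate p",
          class = "thetasync_gpfa_error")
  }
  if (length(candidates) == 1) {
    return(list(p_star = candidates, cv = NULL, summary = NULL))
  }
  rows <- list()
  for (p in candidates) {
    for (f in seq_len(folds)) {
      train <- y[, , fold_id != f, drop = FALSE]
      test <- y[, , fold_id == f, drop = FALSE]
      fit <- gpfa_fit(train, p, ...)
      ll <- gpfa_loglik(fit, test) / dim(test)[3]
      rows[[length(rows) + 1]] <- tibble::tibble(p = p, fold = f, loglik = ll)
    }
  }
  cv <- dplyr::bind_rows(rows)
  summ <- dplyr::summarise(
    dplyr::group_by(cv, .data$p),
    mean_ll = mean(.data$loglik),
    se_ll = sd(.data$loglik) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  best <- summ[which.max(summ$mean_ll), ]
  ok <- summ$mean_ll >= best$mean_ll - best$se_ll
  p_star <- min(summ$p[ok])
  list(p_star = p_star, cv = cv, summary = summ)
}

#' Orthonormalize a GPFA model and its latent trajectories
#'
#' SVD of the loading matrix `C = U S V'`; the orthonormal basis is `U` and
#' latents are re-expressed as `S V' x`, so the reconstruction `C x` equals
#' `U (S V' x)` exactly and the orthonormalized space supports Euclidean
#' ('PCA-like') geometry.
#'
#' @param model A `gpfa_model`.
#' @param trajectories p x bins x trials array from [gpfa_trajectories()].
#' @param blocks Optional per-trial block labels carried into the result.
#' @param trial_id Optional per-trial ids.
#' @return A `trajectory_set`: `latents` (orthonormalized, p x bins x
#'   trials), `basis` (q x p, orthonormal columns), `blocks`, `trial_id`,
#'   `bin_width`.
#' @export
orthonormalize <- function(model, trajectories, blocks = NULL,
                           trial_id = NULL) {
  sv <- svd(model$C)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (r < model$p) {
    warn(sprintf("loading matrix rank-deficient (rank %d < p = %d); reduced basis",
                 r, model$p))
  }
  TM <- diag(sv$d[seq_len(r)], r) %*% t(sv$v[, seq_len(r), drop = FALSE])
  n_tr <- dim(trajectories)[3]
  out <- array(0, dim = c(r, dim(trajectories)[2], n_tr))
  for (tr in seq_len(n_tr)) {
    out[, , tr] <- TM %*% trajectories[, , tr]
  }
  structure(
    list(latents = out, basis = sv$u[, seq_len(r), drop = FALSE],
         blocks = blocks, trial_id = trial_id, bin_width = model$bin_width),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d orthonormalized dims x %d bins x %d trials\n",
              dim(x$latents)[1], dim(x$latents)[2], dim(x$latents)[3]))
  invisible(x)
}

#' Trajectory-deviation vs response-time correlation
#'
#' Per-trial neural deviation is the mean over time bins of the Euclidean
#' distance (in the orthonormalized latent space, all dimensions) between the
#' trial's trajectory and the mean trajectory of block-1 trials. Behavioral
#' deviation is `log(RT) - mean(log RT of block 1)`. Pearson correlations with
#' two-sided p-values are reported for all trials pooled and within each
#' block.
#'
#' @param trajset A `trajectory_set` with `blocks` set.
#' @param trials Trial table for the same included trials (same order).
#' @return List: `deviation` tibble (trial_id, block, neural_dev,
#'   behav_dev), `r_total`, `p_total`, and a `per_block` tibble.
#' @export
trajectory_rt_correlation <- function(trajset, trials) {
  stopifnot(dim(trajset$latents)[3] == nrow(trials))
  blocks <- trajset$blocks %||% trials$block
  b1 <- which(blocks == min(blocks))
  mean_traj <- apply(trajset$latents[, , b1, drop = FALSE], c(1, 2), mean)
  n_tr <- dim(trajset$latents)[3]
  neural_dev <- vapply(seq_len(n_tr), function(tr) {
    diff <- trajset$latents[, , tr] - mean_traj
    mean(sqrt(colSums(diff^2)))
  }, numeric(1))
  lrt <- log(trials$rt)
  behav_dev <- lrt - mean(lrt[b1])
  ct <- cor.test(neural_dev, behav_dev)
  per_block <- lapply(sort(unique(blocks)), function(b) {
    i <- which(blocks == b)
    if (length(i) < 3) {
      return(tibble::tibble(block = b, r = NA_real_, p = NA_real_,
                            n = length(i), flagged = TRUE))
    }
    cb <- cor.test(neural_dev[i], behav_dev[i])
    tibble::tibble(block = b, r = unname(cb$estimate), p = cb$p.value,
                   n = length(i), flagged = FALSE)
  })
  list(
    deviation = tibble::tibble(
      trial_id = trajset$trial_id %||% trials$trial_id,
      block = blocks, neural_dev = neural_dev, behav_dev = behav_dev
    ),
    r_total = unname(ct$estimate), p_total = ct$p.value,
    per_block = dplyr::bind_rows(per_block)
  )
}

#' Square-rooted spike-count array for a population
#'
#' Bins a region's simultaneously recorded units over the peri-action window
#' (20 ms non-overlapping bins by default) on shock-excluded trials and
#' square-root transforms the counts.
#'
#' @param session An `ephys_session`.
#' @param region `"mPFC"` or `"VTA"`.
#' @param window Peri-action window (s), default `c(-0.5, 0.5)`.
#' @param bin_width GPFA bin width (s), default 0.02.
#' @return List: `y` (units x bins x trials of sqrt counts), `trials` (the
#'   included trial table), `unit_id`.
#' @export
population_counts <- function(session, region, window = c(-0.5, 0.5),
                              bin_width = 0.02) {
  trials <- exclude_shock_trials(session$trials)
  units <- dplyr::filter(session$units, .data$region == !!region)
  if (nrow(units) < 10) {
    warn(sprintf("population has %d units; populations of 10+ are expected",
                 nrow(units)))
  }
  tens <- bin_peri_event(units, trials, align = "action", window = window,
                         bin_width = bin_width, bin_step = bin_width)
  y <- sqrt(aperm(tens$counts, c(1, 3, 2)))
  list(y = y, trials = trials, unit_id = units$unit_id,
       bin_width = bin_width, window = window)
}

#' End-to-end population trajectory analysis of one region
#'
#' Builds square-rooted population counts, fits GPFA at dimensionality `p`
#' (5 by default, for cross-population comparability), extracts and
#' orthonormalizes single-trial trajectories, and computes the
#' trajectory-deviation/RT correlation.
#'
#' @inheritParams population_counts
#' @param p Latent dimensionality.
#' @param ... Passed to [gpfa_fit()].
#' @return List: `model`, `trajectories` (a `trajectory_set`), `correlation`
#'   (from [trajectory_rt_correlation()]), `trials`.
#' @export
population_trajectories <- function(session, region, p = 5,
                                    window = c(-0.5, 0.5), bin_width = 0.02,
                                    ...) {
  pc <- population_counts(session, region, window, bin_width)
  model <- gpfa_fit(pc$y, p, bin_width = bin_width, ...)
  lat <- gpfa_trajectories(model, pc$y)
  trajset <- orthonormalize(model, lat, blocks = pc$trials$block,
                            trial_id = pc$trials$trial_id)
  corr <- trajectory_rt_correlation(trajset, pc$trials)
  list(model = model, trajectories = trajset, correlation = corr,
       trials = pc$trials)
}
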