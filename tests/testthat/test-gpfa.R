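test_that("EM log-likelihood is non-decreasing and matches a direct evaluation", {
  set.seed(2)
  q <- 3; T_ <- 4; ntr <- 6
  y <- array(rnorm(q * T_ * ntr, 2), c(q, T_, ntr))
  fit <- gpfa_fit(y, 2, bin_width = 0.02, max_iter = 15, tol = 0,
                  update_tau = FALSE)
  expect_true(all(diff(fit$loglik) > -1e-6 * abs(fit$loglik[-1])))
  # direct marginal likelihood from the explicit joint covariance
  tg <- (seq_len(T_) - 1) * fit$bin_width
  D2 <- outer(tg, tg, "-")^2
  Sb <- matrix(0, q * T_, q * T_)
  for (l in 1:2) {
    Kl <- (1 - fit$gp_noise) * exp(-D2 / (2 * fit$tau[l]^2)) +
      fit$gp_noise * diag(T_)
    Sb <- Sb + kronecker(Kl, tcrossprod(fit$C[, l]))
  }
  Sb <- Sb + kronecker(diag(T_), diag(fit$R, q))
  ll <- 0
  for (tr in seq_len(ntr)) {
    e <- as.vector(y[, , tr] - fit$d)
    ll <- ll - 0.5 * (q * T_ * log(2 * pi) +
                        as.numeric(determinant(Sb)$modulus) +
                        drop(t(e) %*% solve(Sb, e)))
  }
  expect_equal(gpfa_loglik(fit, y), ll, tolerance = 1e-8)
})

test_that("GPFA recovers the loading subspace and timescales of a known model", {
  dat <- gpfa_truth_data()
  fit <- gpfa_fit(dat$y, 2, bin_width = dat$bin_width, max_iter = 80,
                  tol = 1e-7)
  ang <- principal_angles(dat$C, fit$C)
  expect_true(all(ang < 15))
  expect_equal(sort(fit$tau), sort(dat$tau), tolerance = 0.35)
  expect_true(all(diff(fit$loglik) > -1e-6 * abs(fit$loglik[-1])))
  expect_error(gpfa_fit(dat$y, 12), class = "thetasync_gpfa_error")
})

test_that("posterior latents approach GP-smoothed observations in the low-noise full-rank limit", {
  set.seed(3)
  q <- 4; T_ <- 30; ntr <- 3
  tg <- (seq_len(T_) - 1) * 0.02
  K <- 0.999 * exp(-outer(tg, tg, "-")^2 / (2 * 0.1^2)) + 1e-3 * diag(T_)
  ch <- chol(K)
  y <- array(0, c(q, T_, ntr))
  for (tr in seq_len(ntr)) {
    y[, , tr] <- t(ch) %*% matrix(rnorm(T_ * q), T_) |> t()
  }
  model <- structure(
    list(C = diag(q), d = rep(0, q), R = rep(1e-8, q), tau = rep(0.1, q),
         gp_noise = 1e-3, bin_width = 0.02, p = q, q = q, T = T_,
         n_trials = ntr, loglik = NA, converged = TRUE),
    class = "gpfa_model"
  )
  lat <- gpfa_trajectories(model, y)
  expect_equal(lat[, , 1], y[, , 1], tolerance = 0.02)
})

test_that("cross-validated dimensionality selection finds the true p and degrades on noise", {
  dat <- gpfa_truth_data()
  sel <- select_dimensionality(dat$y[, , 1:60], 1:3, folds = 3, seed = 2,
                               max_iter = 50, tol = 1e-6)
  expect_equal(sel$p_star, 2)
  # held-out likelihood of the true p beats underfitting decisively
  s1 <- sel$summary$mean_ll[sel$summary$p == 1]
  s2 <- sel$summary$mean_ll[sel$summary$p == 2]
  expect_gt(s2, s1)
  # pure white noise: smallest candidate wins
  set.seed(4)
  yn <- array(rnorm(12 * 50 * 24), c(12, 50, 24))
  seln <- select_dimensionality(yn, 1:2, folds = 2, seed = 2,
                                max_iter = 25, tol = 1e-5)
  expect_equal(seln$p_star, 1)
  # single candidate short-circuits
  expect_equal(select_dimensionality(yn, 3, folds = 2)$p_star, 3)
})

test_that("orthonormalization preserves the reconstruction exactly", {
  dat <- gpfa_truth_data()
  fit <- gpfa_fit(dat$y[, , 1:30], 2, bin_width = dat$bin_width,
                  max_iter = 30, tol = 1e-6)
  lat <- gpfa_trajectories(fit, dat$y[, , 1:30])
  ts <- orthonormalize(fit, lat)
  expect_equal(crossprod(ts$basis), diag(2), tolerance = 1e-10)
  for (tr in c(1, 7)) {
    expect_equal(fit$C %*% lat[, , tr], ts$basis %*% ts$latents[, , tr],
                 tolerance = 1e-10)
  }
  # C = diag(2, 3): basis identity up to sign/order, latents scaled
  model <- fit
  model$C <- rbind(diag(c(2, 3)), matrix(0, 10, 2))
  lat2 <- array(rnorm(2 * 50 * 3), c(2, 50, 3))
  ts2 <- orthonormalize(model, lat2)
  # largest singular value first: dimension 1 is the tripled latent
  expect_equal(abs(ts2$basis[2, 1]), 1, tolerance = 1e-12)
  expect_equal(ts2$latents[1, , 1], sign(ts2$basis[2, 1]) * 3 * lat2[2, , 1],
               tolerance = 1e-12)
})

test_that("trajectory deviation has the stated geometry and rotation invariance", {
  lat <- array(0, c(3, 10, 4))
  lat[, , 2] <- 1 / sqrt(3)   # unit distance from origin at every bin
  blocks <- c(1, 2, 2, 1)
  ts <- structure(list(latents = lat, basis = diag(3), blocks = blocks,
                       trial_id = 1:4, bin_width = 0.02),
                  class = "trajectory_set")
  trials <- tibble::tibble(trial_id = 1:4, block = blocks, rt = c(1, 2, 2, 1))
  corr <- trajectory_rt_correlation(ts, trials)
  # block-1 trials sit on the block-1 mean -> deviation 0
  expect_equal(corr$deviation$neural_dev[c(1, 4)], c(0, 0))
  expect_equal(corr$deviation$neural_dev[2], 1)
  # rotation invariance of the deviation
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lat_r <- lat
  for (tr in 1:4) lat_r[, , tr] <- Q %*% lat[, , tr]
  ts_r <- ts
  ts_r$latents <- lat_r
  corr_r <- trajectory_rt_correlation(ts_r, trials)
  expect_equal(corr_r$deviation$neural_dev, corr$deviation$neural_dev,
               tolerance = 1e-10)
})

test_that("trajectory-RT correlation is positive iff the latent coupling is on", {
  s <- spikes_session()
  res <- population_trajectories(s, "mPFC", p = 5, max_iter = 60,
                                 tol = 1e-6)
  expect_gt(res$correlation$r_total, 0)
  expect_lt(res$correlation$p_total, 0.01)
  s0 <- no_shock_spikes_session()
  res0 <- population_trajectories(s0, "mPFC", p = 5, max_iter = 60,
                                  tol = 1e-6)
  expect_gt(res0$correlation$p_total, 0.05)
  expect_lt(abs(res0$correlation$r_total), 0.2)
})
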