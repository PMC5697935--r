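test_that("bandpass phase follows the cosine convention with the right slope", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)
  ps <- bandpass_phase(cos(2 * pi * 10 * tt), fs)
  # unwrapped phase advances at 2 pi f rad/s
  dp <- ((diff(ps$phase) + pi) %% (2 * pi)) - pi
  expect_equal(mean(dp[2000:28000]) * fs, 2 * pi * 10, tolerance = 1e-3)
  # phase 0 at the waveform peak
  peaks <- (10:200) * 0.1
  ph <- spike_phases(peaks, ps)
  expect_lt(max(abs(ph)), 0.02)
  expect_error(bandpass_phase(tt, fs, band = c(5, 600)),
               class = "thetasync_phase_error")
  expect_error(bandpass_phase(tt, 50, band = c(5, 15)),
               class = "thetasync_phase_error")
})

test_that("the 5-15 Hz filter attenuates out-of-band tones by over 20 dB", {
  fs <- 1000
  tt <- seq(0, 30, by = 1 / fs)
  gain_db <- vapply(c(2.5, 10, 30), function(f0) {
    ps <- bandpass_phase(cos(2 * pi * f0 * tt), fs)
    20 * log10(mean(ps$amplitude[5000:25000]))
  }, numeric(1))
  expect_lt(gain_db[1], -20)
  expect_lt(gain_db[3], -20)
  expect_gt(gain_db[2], -1)
})

test_that("spike phase lookup interpolates, lags, and respects periodicity", {
  fs <- 1000
  tt <- seq(0, 60, by = 1 / fs)
  ps <- bandpass_phase(cos(2 * pi * 10 * tt), fs)
  expect_length(spike_phases(numeric(0), ps), 0)
  st <- (1:300) * 0.123
  p0 <- spike_phases(st, ps, lag = 0)
  p1 <- spike_phases(st, ps, lag = 0.1)  # one full 10 Hz cycle
  expect_lt(max(abs(Arg(exp(1i * (p0 - p1))))), 1e-3)
  expect_error(spike_phases(st, ps, lag = 0.2),
               class = "thetasync_phase_error")
  # boundary-dropped spikes are counted
  trials <- toy_trials(3)
  ph <- spike_phases(trials$action_time[1] + c(-1.999, 0, 1.5), ps, trials,
                     window = c(-2, 2), lag = -0.05)
  expect_equal(attr(ph, "n_dropped"), 1)
})

test_that("MRL and PLV reach their documented extremes", {
  expect_equal(mrl(rep(0.7, 500)), 1)
  expect_equal(mrl(2 * pi * (0:99) / 100), 0, tolerance = 1e-12)
  expect_equal(mrl(c(0, pi / 2)), sqrt(2) / 2)
  pv <- plv(rep(1.1, 400), n_iter = 50, seed = 1)
  expect_equal(pv$plv, 1)
  expect_equal(pv$preferred_phase, 1.1)
  # count <= resample size: excluded, never silently computed
  ex <- plv(runif(80, -pi, pi), n_resample = 100)
  expect_true(ex$excluded)
  expect_true(is.na(ex$plv))
})

test_that("resampled PLV matches the von Mises Bessel-ratio at kappa = 1", {
  set.seed(11)
  # inverse-cdf-free von Mises sampling via rejection (Best-Fisher)
  rvm <- function(n, kappa) {
    out <- numeric(0)
    while (length(out) < n) {
      z <- runif(n, -pi, pi)
      keep <- runif(n) < exp(kappa * (cos(z) - 1))
      out <- c(out, z[keep])
    }
    out[seq_len(n)]
  }
  phases <- rvm(4000, 1)
  pv <- plv(phases, n_iter = 400, n_resample = 100, seed = 2)
  bessel_ratio <- besselI(1, 1) / besselI(1, 0)   # ~0.4464
  # 100-spike MRL is slightly inflated relative to the asymptotic ratio
  expect_equal(pv$plv, bessel_ratio, tolerance = 0.05)
})

test_that("PLV resampling equalizes units with different spike counts", {
  set.seed(12)
  rvm <- function(n, kappa) {
    out <- numeric(0)
    while (length(out) < n) {
      z <- runif(n, -pi, pi)
      keep <- runif(n) < exp(kappa * (cos(z) - 1))
      out <- c(out, z[keep])
    }
    out[seq_len(n)]
  }
  small <- plv(rvm(150, 1.5), n_iter = 500, seed = 3)
  big <- plv(rvm(3000, 1.5), n_iter = 500, seed = 4)
  expect_lt(abs(small$plv - big$plv), 0.05)
})

test_that("Rayleigh statistics follow the stated formulas", {
  uni <- rayleigh_test(2 * pi * (0:99) / 100)
  expect_equal(uni$z, 0, tolerance = 1e-12)
  expect_equal(uni$p, 1, tolerance = 1e-6)
  # n = 100, R = 0.3 -> z = 9, p ~ 1.05e-4 under the approximation
  n <- 100; R <- 0.3
  p_expected <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n^2 * R^2)) - (1 + 2 * n))
  # build a phase set with that exact R: two opposed groups plus aligned rest
  expect_equal(p_expected, 1.047292e-4, tolerance = 1e-6)
  expect_lt(p_expected, 0.001)
  ident <- rayleigh_test(rep(0.3, 100))
  expect_equal(ident$z, 100)
  expect_lt(ident$p, 1e-10)
  expect_true(rayleigh_test(runif(5))$flagged)
})

test_that("lagged phase locking recovers a programmed oscillation lead", {
  # bursts with per-trial frequency jitter; spikes coupled to the phase
  # 20 ms before the spike => profile peaks near -20 ms
  set.seed(42)
  fs <- 1000
  n_tr <- 150
  lead <- 0.02
  acts <- 5 + (0:(n_tr - 1)) * 8 + runif(n_tr)
  dur <- max(acts) + 5
  fk <- 8 + 2 * rnorm(n_tr)
  phk <- runif(n_tr, -pi, pi)
  pe <- function(t) {
    idx <- findInterval(t, acts)
    k0 <- pmin(pmax(idx, 1), n_tr)
    k1 <- pmin(k0 + 1, n_tr)
    k <- ifelse(abs(t - acts[k1]) < abs(t - acts[k0]), k1, k0)
    dt <- t - acts[k]
    list(phase = 2 * pi * fk[k] * dt + phk[k],
         env = ifelse(abs(dt) < 0.5, cos(pi * dt)^2, 0))
  }
  kappa <- 2.5
  Lam <- 17 * exp(kappa) / besselI(kappa, 0)
  nc <- rpois(1, Lam * dur)
  tc <- sort(runif(nc, 0, dur))
  k0 <- pmin(pmax(findInterval(tc, acts), 1), n_tr)
  lam <- 5 + 12 * exp(-(tc - acts[k0])^2 / (2 * 0.08^2))
  pp <- pe(tc - lead)
  kap <- kappa * pp$env
  lam <- lam * exp(kap * cos(pp$phase)) / besselI(kap, 0)
  st <- tc[runif(nc) < lam / Lam]
  grid <- (0:(dur * fs - 1)) / fs
  pg <- pe(grid)
  lfp <- 20 * pg$env * cos(pg$phase) + rnorm(length(grid), sd = 5)
  trials <- toy_trials(n_tr)
  trials$cue_time <- acts - 2
  trials$action_time <- acts
  trials$reward_time <- acts + 1
  ps <- bandpass_phase(lfp, fs)
  lp <- lagged_plv_profile(st, ps, trials, window = c(-0.5, 0.5),
                           n_iter = 500, seed = 2)
  expect_lte(abs(lp$peak_lag_ms - (-20)), 8 + 1e-9)
  # zero-delay coupling peaks at zero lag
  pp0 <- pe(tc)
  kap0 <- kappa * pp0$env
  lam0 <- (5 + 12 * exp(-(tc - acts[k0])^2 / (2 * 0.08^2))) *
    exp(kap0 * cos(pp0$phase)) / besselI(kap0, 0)
  st0 <- tc[runif(nc) < lam0 / Lam]
  lp0 <- lagged_plv_profile(st0, ps, trials, window = c(-0.5, 0.5),
                            n_iter = 500, seed = 3)
  expect_lte(abs(lp0$peak_lag_ms), 4 + 1e-9)
  # uniform spikes: flat profile within resampling noise
  stu <- sort(runif(3000, 0, dur))
  lpu <- lagged_plv_profile(stu, ps, trials, window = c(-0.5, 0.5),
                            n_iter = 200, seed = 4)
  expect_lt(max(lpu$profile$plv) - min(lpu$profile$plv), 0.08)
})

test_that("blockwise comparisons detect the programmed kappa decline and skip degenerate input", {
  s <- default_session()
  truth <- ground_truth(s)
  pl <- phase_locking_analysis(s, "VTA", "VTA", n_iter = 300, seed = 1)
  da <- truth$units$unit_id[truth$units$da]
  cmp <- blockwise_plv_comparison(pl[pl$unit_id %in% da, ])
  b13 <- cmp$pairwise[cmp$pairwise$block_a == 1 & cmp$pairwise$block_b == 3, ]
  m <- cmp$per_block$mean_plv
  expect_gt(m[1], m[3])
  expect_lt(b13$p, 0.05)
  expect_message(blockwise_plv_comparison(pl[pl$block == 1, ]),
                 "one block")
})

test_that("cross-regional phase locking reflects a purely bottom-up coupling topology", {
  # only mPFC spikes are coupled (to VTA theta); VTA units are uncoupled
  tpl <- default_unit_templates(n_mpfc = 8, n_vta_da = 4, n_vta_nonda = 4)
  tpl$kappa[tpl$region == "VTA"] <- 0
  tpl$kappa[tpl$region == "mPFC"] <- 2
  cfg <- session_config(seed = 6, trials_per_block = 25, units = tpl,
                        kappa_block_gain = c(1, 1, 1))
  s <- generate_session(cfg)
  xm <- phase_locking_analysis(s, "mPFC", "VTA", n_iter = 200, seed = 1)
  xv <- phase_locking_analysis(s, "VTA", "mPFC", n_iter = 200, seed = 1)
  plv_m <- mean(xm$plv[xm$included], na.rm = TRUE)
  plv_v <- mean(xv$plv[xv$included], na.rm = TRUE)
  expect_gt(plv_m, plv_v)
})
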