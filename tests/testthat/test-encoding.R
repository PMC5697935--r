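test_that("omega PEV matches hand-computed one-way ANOVA tables", {
  # perfectly separated blocks, zero within-block variance: SS_B = 16,
  # MS_E = 0, SS_T = 16 -> 1
  expect_equal(compute_wpev(c(0, 0, 2, 2, 4, 4), c(1, 1, 2, 2, 3, 3)), 1)
  # identical blocks {1,3}: SS_B = 0, SS_T = 6, MS_E = 2 -> -4/8
  expect_equal(compute_wpev(c(1, 3, 1, 3, 1, 3), c(1, 1, 2, 2, 3, 3)), -0.5)
  # all counts equal: defined 0
  expect_equal(compute_wpev(rep(2, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(compute_wpev(c(1, 2, 3), c(1, 2, 3)),
               class = "thetasync_wpev_error")
})

test_that("omega PEV agrees with aov-based omega squared on random draws", {
  set.seed(4)
  blocks <- rep(1:3, each = 15)
  for (i in 1:5) {
    x <- rpois(45, 3) + rep(c(0, i / 2, i), each = 15)
    fit <- summary(stats::aov(x ~ factor(blocks)))[[1]]
    ss_b <- fit["factor(blocks)", "Sum Sq"]
    ms_e <- fit["Residuals", "Mean Sq"]
    ss_t <- ss_b + fit["Residuals", "Sum Sq"]
    expect_equal(compute_wpev(x, blocks),
                 (ss_b - 2 * ms_e) / (ss_t + ms_e), tolerance = 1e-12)
  }
})

test_that("omega PEV is at most 1 and invariant to block relabeling", {
  set.seed(9)
  blocks <- rep(1:3, each = 10)
  for (i in 1:20) {
    x <- matrix(rpois(30 * 4, 2), 30)
    w1 <- thetasync:::wpev_trace(x, blocks)
    expect_true(all(w1 <= 1 + 1e-12))
    perm <- sample(3)
    w2 <- thetasync:::wpev_trace(x, perm[blocks])
    expect_equal(w1, w2, tolerance = 1e-12)
  }
})

test_that("peri-event binning counts spikes in half-open bins", {
  trials <- toy_trials(1)
  ev <- trials$action_time[1]
  units <- tibble::tibble(
    unit_id = c("a", "b"), region = "mPFC", waveform_width = 1,
    spike_times = list(ev + c(0.01, 0.06), numeric(0)),
    baseline_rate = c(1, 0)
  )
  tens <- bin_peri_event(units, trials, align = "action",
                         window = c(0, 0.2), bin_width = 0.05)
  expect_equal(tens$counts[1, 1, ], c(1, 1, 0, 0))
  expect_equal(tens$counts[2, 1, ], rep(0, 4))
  # boundary spike at exactly a bin edge belongs to the upper bin
  units$spike_times[[2]] <- ev + 0.05
  tens2 <- bin_peri_event(units, trials, align = "action",
                          window = c(0, 0.2), bin_width = 0.05)
  expect_equal(tens2$counts[2, 1, ], c(0, 1, 0, 0))
  trials_na <- trials
  trials_na$reward_time[1] <- NA
  expect_error(bin_peri_event(units, trials_na, align = "reward"),
               "trial 1", class = "thetasync_binning_error")
})

test_that("five-bin boxcar smoothing averages with edge renormalization", {
  trials <- toy_trials(1)
  ev <- trials$action_time[1]
  units <- tibble::tibble(
    unit_id = "a", region = "mPFC", waveform_width = 1,
    spike_times = list(ev + rep(0.45, 5)), baseline_rate = 1
  )
  # counts per 0.2s bin over [0,1): c(0, 0, 5, 0, 0)
  tens <- bin_peri_event(units, trials, align = "action",
                         window = c(0, 1), bin_width = 0.2)
  expect_equal(tens$counts[1, 1, ], c(0, 0, 5, 0, 0))
  sm <- tensor_to_rates(tens, n_smooth = 5)
  # rates = counts / 0.2; center bin boxcar mean = 5/5 / 0.2 = 5
  expect_equal(sm$counts[1, 1, 3], 5)
  # edge bin: truncated 3-bin mean = (0 + 0 + 25) / 3
  expect_equal(sm$counts[1, 1, 1], 25 / 3)
})

test_that("baseline z-scoring has the stated arithmetic and flags zero variance", {
  tens <- structure(
    list(counts = array(8, c(2, 4, 3)), unit_id = c("a", "b"),
         trial_id = 1:4, block = rep(1, 4), align = "action",
         window = c(0, 3), bin_width = 1, bin_step = 1,
         centers = c(0.5, 1.5, 2.5), values = "rates"),
    class = "peri_event_tensor"
  )
  base <- tens
  base$counts <- array(rep(c(2, 6), 12), c(2, 4, 3))  # mean 4, sd ~2 per unit
  base$counts[1, , ] <- matrix(rep(c(2, 6, 2, 6), 3), 4)
  base$counts[2, , ] <- 3
  expect_warning(z <- zscore_to_baseline(tens, base), "unit b")
  sd1 <- sd(base$counts[1, , ])
  expect_equal(z$counts[1, 1, 1], (8 - 4) / sd1)
  expect_true(all(is.na(z$counts[2, , ])))
  expect_equal(attr(z, "flagged_units"), "b")
  # rate equal to baseline mean -> z = 0
  tens0 <- tens
  tens0$counts[1, , ] <- 4
  z0 <- suppressWarnings(zscore_to_baseline(tens0, base))
  expect_equal(z0$counts[1, , ], array(0, c(4, 3)), ignore_attr = TRUE)
})

test_that("surrogate bands honor their degenerate and ordering properties", {
  blocks <- rep(1:3, each = 10)
  # all-zero counts -> all surrogate traces zero -> bands at 0
  bands0 <- surrogate_bands(matrix(0, 30, 4), blocks, n_shuffles = 100,
                            seed = 1)
  expect_equal(bands0$global, 0)
  expect_equal(bands0$pointwise, rep(0, 4))
  # one bin: global band equals the pointwise band
  set.seed(2)
  b1 <- surrogate_bands(matrix(rpois(30, 3), 30, 1), blocks,
                        n_shuffles = 300, seed = 3)
  expect_equal(b1$global, b1$pointwise)
  # multiple bins: global >= pointwise everywhere
  bm <- surrogate_bands(matrix(rpois(30 * 8, 3), 30), blocks,
                        n_shuffles = 300, seed = 4)
  expect_true(all(bm$global >= bm$pointwise - 1e-12))
  expect_error(surrogate_bands(matrix(0, 30, 2), blocks, n_shuffles = 50),
               class = "thetasync_band_error")
})

test_that("encoder classification is driven by global-band crossings", {
  res <- classify_encoder(c(0.1, 0.2, 0.1), 0.3, unit_id = "u")
  expect_false(res$encoder)
  expect_length(res$crossing_bins, 0)
  res2 <- classify_encoder(c(0.1, 0.5, 0.6, 0.2), 0.3)
  expect_true(res2$encoder)
  expect_equal(res2$crossing_bins, c(2L, 3L))
  td <- tidy(res2)
  expect_equal(td$crossing, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("standardized regression coefficient equals the Pearson correlation", {
  blocks <- rep(1:3, each = 8)
  # exact linear counts -> src = 1; constant -> 0
  expect_equal(src_direction(2 * blocks, blocks)$summary_src, 1,
               tolerance = 1e-12)
  expect_equal(src_direction(rep(3, 24), blocks)$summary_src, 0)
  set.seed(6)
  for (i in 1:10) {
    x <- rpois(24, 4)
    expect_equal(src_direction(x, blocks)$summary_src,
                 suppressWarnings(cor(x, as.numeric(blocks))),
                 tolerance = 1e-12)
  }
  r <- src_direction(-1 * blocks, blocks)
  expect_identical(r$sign, "inhibitory")
  expect_true(abs(r$summary_src) <= 1 + 1e-12)
})

test_that("baseline modulation test recovers a programmed shift and calibrates under the null", {
  trials <- toy_trials(60, spacing = 12)
  trials$block <- rep(1:3, each = 20)
  set.seed(3)
  # null: homogeneous Poisson baseline spikes
  mk_spikes <- function(rates) {
    unlist(lapply(seq_len(nrow(trials)), function(i) {
      t0 <- trials$cue_time[i] - 2.5
      sort(t0 + runif(rpois(1, 2 * rates[i]), 0, 2))
    }))
  }
  null_rej <- vapply(1:40, function(i) {
    baseline_block_modulation(mk_spikes(rep(4, 60)), trials)$modulated
  }, logical(1))
  expect_lte(mean(null_rej), 0.15)  # nominal 0.05 within MC error
  # programmed +50% block-3 shift
  shift <- baseline_block_modulation(
    mk_spikes(c(rep(4, 40), rep(6, 20))), trials
  )
  expect_true(shift$modulated)
  expect_identical(shift$direction, "excitatory")
  # constant spike train: no rejection
  flat <- baseline_block_modulation(numeric(0), trials)
  expect_false(flat$modulated)
  expect_equal(flat$p, 1)
})

test_that("firing-rate/RT correlation handles exact and degenerate inputs", {
  rts <- exp(seq(0.1, 1.2, length.out = 12))
  expect_equal(abs(rate_rt_correlation(3 + 2 * log(rts), rts)$r), 1,
               tolerance = 1e-10)
  flagged <- rate_rt_correlation(rep(2, 12), rts)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$r))
  expect_error(rate_rt_correlation(1:5, rts[1:5]),
               class = "thetasync_corr_error")
})

test_that("encoder recovery is high at strong gain and detection grows with effect size", {
  s <- strong_gain_session()
  truth <- ground_truth(s)
  enc <- encode_units(s, n_shuffles = 400, seed = 11)
  tr <- truth$units$encoder[match(enc$unit_id, truth$units$unit_id)]
  sens <- mean(enc$encoder[tr])
  spec <- mean(!enc$encoder[!tr])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # detected encoders at strong up-gain carry positive SRC
  expect_true(mean(enc$src[tr & enc$encoder] > 0) > 0.9)
  # max omega PEV of true encoders exceeds that of nulls on average
  expect_gt(mean(enc$max_wpev[tr]), mean(enc$max_wpev[!tr]))
})
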