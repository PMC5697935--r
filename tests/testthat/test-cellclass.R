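test_that("auROC equals exhaustive pair enumeration with half-credit ties", {
  # event {0,1} vs baseline {1,2}: 0 wins, 1 tie of 4 pairs -> 0.125
  expect_equal(thetasync:::auroc(c(0, 1), c(1, 2)), 0.125)
  expect_equal(thetasync:::auroc(c(5, 6), c(1, 2)), 1)
  expect_equal(thetasync:::auroc(c(1, 2), c(1, 2)), 0.5)
  set.seed(2)
  for (i in 1:10) {
    pos <- rpois(12, 4)
    neg <- rpois(9, 4)
    brute <- mean(outer(pos, neg, function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(thetasync:::auroc(pos, neg), brute, tolerance = 1e-12)
  }
})

test_that("auROC is invariant to strictly monotone rate transforms", {
  set.seed(5)
  pos <- rpois(15, 6)
  neg <- rpois(15, 4)
  a0 <- thetasync:::auroc(pos, neg)
  expect_equal(thetasync:::auroc(exp(pos / 3), exp(neg / 3)), a0)
  expect_equal(thetasync:::auroc(log1p(pos), log1p(neg)), a0)
})

test_that("auROC reward profiles have 15 bins and detect programmed responses", {
  s <- default_session()
  trials <- exclude_shock_trials(s$trials)
  truth <- ground_truth(s)
  prof_da <- auroc_profile(
    s$units$spike_times[[match("d01", s$units$unit_id)]], trials
  )
  expect_length(prof_da, 15)
  expect_true(all(prof_da >= 0 & prof_da <= 1))
  centers <- seq(-0.45, 1.05, by = 0.1)[1:15]
  phasic <- centers > 0 & centers <= 0.3
  # DA-like template: phasic excitation right after reward (the bump decays
  # within the 300 ms window, so the mean over the three bins sits below the
  # peak bin)
  expect_gt(mean(prof_da[phasic]), 0.65)
  expect_gt(max(prof_da[phasic]), 0.8)
  # suppressed non-DA template: below-baseline discrimination after reward
  prof_sup <- auroc_profile(
    s$units$spike_times[[match("n05", s$units$unit_id)]], trials
  )
  expect_lt(mean(prof_sup[centers > 0.1 & centers <= 0.6]), 0.4)
})

test_that("PCA + GMM clustering separates two synthetic profile families", {
  set.seed(7)
  centers <- seq(-0.45, 1.05, by = 0.1)[1:15]
  phasic_tpl <- 0.5 + 0.4 * exp(-(centers - 0.15)^2 / (2 * 0.08^2))
  # late, slowly building sustained response: low in the 0-300 ms window
  sustained_tpl <- 0.5 + 0.25 * pmax(pmin((centers - 0.1) / 0.5, 1), 0)
  n1 <- 14; n2 <- 12
  profs <- rbind(
    t(replicate(n1, pmin(phasic_tpl + rnorm(15, 0, 0.03), 1))),
    t(replicate(n2, pmin(sustained_tpl + rnorm(15, 0, 0.03), 1)))
  )
  rownames(profs) <- sprintf("u%02d", seq_len(n1 + n2))
  cl <- pca_cluster(profs)
  truth_lbl <- rep(c("Type1", "Type2"), c(n1, n2))
  agreement <- mean(as.character(cl$cluster) == truth_lbl)
  expect_gte(agreement, 0.95)
  expect_false(cl$degenerate)
  # PCA reconstruction identity at full rank
  full <- svd(sweep(profs, 2, colMeans(profs)))
  recon <- full$u %*% diag(full$d) %*% t(full$v) +
    matrix(colMeans(profs), nrow(profs), 15, byrow = TRUE)
  expect_equal(recon, profs, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Type1 is anchored by the phasic post-reward criterion, not component index", {
  # swapping the row order of the input families must not change which
  # profile shape is called Type1
  set.seed(8)
  centers <- seq(-0.45, 1.05, by = 0.1)[1:15]
  phasic_tpl <- 0.5 + 0.4 * exp(-(centers - 0.15)^2 / (2 * 0.08^2))
  flat_tpl <- rep(0.5, 15)
  profs <- rbind(
    t(replicate(10, phasic_tpl + rnorm(15, 0, 0.02))),
    t(replicate(10, flat_tpl + rnorm(15, 0, 0.02)))
  )
  cl_a <- pca_cluster(profs)
  cl_b <- pca_cluster(profs[rev(seq_len(20)), ])
  expect_equal(as.character(cl_a$cluster)[1:10], rep("Type1", 10))
  expect_equal(as.character(cl_b$cluster)[11:20], rep("Type1", 10))
})

test_that("degenerate identical profiles raise the flag", {
  profs <- matrix(0.5, 10, 15)
  cl <- pca_cluster(profs)
  expect_true(cl$degenerate)
  expect_error(pca_cluster(profs[1:3, ]),
               class = "thetasync_cluster_error")
})

test_that("the dual DA criterion applies strict 12 Hz / 1.2 ms boundaries", {
  expect_identical(classify_vta_unit(5, 1.5, "Type1"), "putative_DA")
  expect_identical(classify_vta_unit(15, 1.5, "Type1"), "putative_nonDA")
  expect_identical(classify_vta_unit(5, 1.5, "Type2"), "putative_nonDA")
  # boundary values are excluded (strict inequalities)
  expect_identical(classify_vta_unit(12, 1.5, "Type1"), "putative_nonDA")
  expect_identical(classify_vta_unit(5, 1.2, "Type1"), "putative_nonDA")
  expect_identical(classify_vta_unit(11.999, 1.201, "Type1"), "putative_DA")
  expect_error(classify_vta_unit(NA, 1.5, "Type1"),
               class = "thetasync_classify_error")
})

test_that("session-level VTA classification recovers the template classes", {
  s <- pooled_vta_session()
  truth <- ground_truth(s)
  cls <- classify_vta_units(s)
  expect_equal(nrow(cls), sum(s$units$region == "VTA"))
  tr_da <- truth$units$da[match(cls$unit_id, truth$units$unit_id)]
  agreement <- mean((cls$label == "putative_DA") == tr_da)
  expect_gte(agreement, 0.95)
  expect_false(any(cls$fast_spiking & cls$baseline_rate <= 20))
})
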