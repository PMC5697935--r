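# Shared fixtures: sessions are expensive to generate, so they are built
# lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# full default session (all effects on), with LFP
default_session <- function() {
  fixture("default", function() generate_session(session_config(seed = 3)))
}

# default task structure, spikes only (fast)
spikes_session <- function() {
  fixture("spikes_only", function() {
    generate_session(session_config(seed = 5), lfp = FALSE)
  })
}

# no-shock control session (all block effects off), with LFP
null_session <- function() {
  fixture("null", function() generate_session(no_shock_config(seed = 5)))
}

no_shock_spikes_session <- function() {
  fixture("null_spikes", function() {
    generate_session(no_shock_config(seed = 5), lfp = FALSE)
  })
}

# compact session for I/O and plumbing tests
small_session <- function() {
  fixture("small", function() {
    cfg <- session_config(
      seed = 21, trials_per_block = 10, lfp_fs = 500,
      units = default_unit_templates(n_mpfc = 4, n_vta_da = 2,
                                     n_vta_nonda = 2)
    )
    generate_session(cfg)
  })
}

# cohort of 30 mPFC-style units, 30% encoders at strong block gain, no
# phase coupling: the encoder-recovery study condition
strong_gain_session <- function() {
  fixture("strong_gain", function() {
    n <- 30L
    tpl <- default_unit_templates(n_mpfc = n, n_vta_da = 0L,
                                  n_vta_nonda = 0L)
    n_enc <- round(0.3 * n)
    tpl$block_gain <- c(rep(list(c(1, 1.8, 2.6)), n_enc),
                        rep(list(c(1, 1, 1)), n - n_enc))
    tpl$baseline_block_gain <- rep(list(c(1, 1, 1)), n)
    tpl$amp_action <- 8
    tpl$amp_cue <- 3
    tpl$amp_reward <- 3
    tpl$kappa <- 0
    cfg <- session_config(units = tpl, kappa_block_gain = c(1, 1, 1),
                          seed = 42)
    generate_session(cfg, lfp = FALSE)
  })
}

# VTA cohort at the pooled across-session scale used for cell
# classification (a single session's ~13 VTA units under-determine the
# mixture)
pooled_vta_session <- function() {
  fixture("pooled_vta", function() {
    cfg <- session_config(
      seed = 9,
      units = default_unit_templates(n_mpfc = 2, n_vta_da = 24,
                                     n_vta_nonda = 24)
    )
    generate_session(cfg, lfp = FALSE)
  })
}

# data simulated from a known GPFA model (q=12, p=2)
gpfa_truth_data <- function(ntr = 100) {
  fixture(paste0("gpfa_", ntr), function() {
    set.seed(1)
    q <- 12; p <- 2; T_ <- 50; bw <- 0.02
    tg <- (seq_len(T_) - 1) * bw
    Kf <- function(tau) {
      0.999 * exp(-outer(tg, tg, "-")^2 / (2 * tau^2)) + 1e-3 * diag(T_)
    }
    C <- matrix(rnorm(q * p), q, p) * 0.8
    d <- runif(q, 1, 3)
    R <- runif(q, 0.05, 0.2)
    y <- array(0, c(q, T_, ntr))
    ch <- list(chol(Kf(0.08)), chol(Kf(0.15)))
    for (tr in seq_len(ntr)) {
      x <- rbind(as.vector(t(ch[[1]]) %*% rnorm(T_)),
                 as.vector(t(ch[[2]]) %*% rnorm(T_)))
      y[, , tr] <- C %*% x + d + matrix(rnorm(q * T_, 0, sqrt(R)), q, T_)
    }
    list(y = y, C = C, d = d, R = R, tau = c(0.08, 0.15), bin_width = bw)
  })
}

# trial table of evenly spaced one-block events for signal-level tests
toy_trials <- function(n = 5, spacing = 10, first = 10) {
  acts <- first + (seq_len(n) - 1) * spacing
  tibble::tibble(
    trial_id = seq_len(n), block = 1L,
    cue_time = acts - 2, action_time = acts, reward_time = acts + 1,
    shock_flag = FALSE, rt = 2, immobile_rt = 0.5, reward_rt = 1
  )
}

principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  acos(pmin(svd(crossprod(qa, qb))$d, 1)) * 180 / pi
}
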