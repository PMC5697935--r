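#' Configuration for the synthetic session generator
#'
#' Defines the statistical structure of a generated session: a 3-block x
#' 50-trial instrumental task with action-punishment contingencies
#' (0, 0.06, 0.1), block-modulated lognormal response times, event-locked
#' Gaussian firing-rate bumps with block-dependent gain, pink-noise LFP with an
#' action-locked theta burst whose amplitude declines over blocks, a delayed
#' scaled copy of the VTA theta component in the mPFC trace (VTA-to-mPFC
#' direction), and von Mises spike-phase coupling injected by thinning.
#'
#' @param n_blocks,trials_per_block Task block structure (3 x 50 by default).
#' @param shock_contingency Per-block probability that an action is followed by
#'   foot shock; the realized shock count per block is
#'   `round(contingency * trials_per_block)` (0/3/5 at defaults).
#' @param rt_meanlog,rt_sdlog Per-block lognormal response-time parameters;
#'   defaults make both the mean and the trial-to-trial variance rise with
#'   risk.
#' @param reward_rt_meanlog,reward_rt_sdlog Reward-retrieval latency lognormal
#'   parameters (block-independent).
#' @param iti_range Uniform range (s) of the reward-to-next-cue interval; must
#'   leave room for the 2 s baseline window beginning 2.5 s before each cue.
#' @param units Unit template table, see [default_unit_templates()].
#' @param lfp_fs LFP sampling rate in Hz (stored-rate decision; well above the
#'   250 Hz floor needed for a 125 Hz analysis ceiling).
#' @param pink_noise_sd 1/f background noise standard deviation (microvolts).
#' @param theta_freq_range Session theta-burst frequency is drawn uniformly
#'   from this range (Hz), inside the 5-15 Hz analysis band.
#' @param theta_freq_jitter SD (Hz) of the per-trial jitter around the session
#'   theta frequency. Real theta fluctuates cycle to cycle; a pure fixed-
#'   frequency burst would make time-lagged phase locking periodic in the lag
#'   (aliased peaks one cycle away), which the jitter removes.
#' @param theta_amplitude Peak theta burst amplitude in block 1 (microvolts).
#' @param theta_block_gain Per-block multiplier on the theta burst amplitude
#'   (declining with risk by default).
#' @param theta_burst_dur Hann envelope duration (s) of the burst, centered on
#'   the action.
#' @param coupling_delay,coupling_gain Delay (s) and gain of the copy of the
#'   VTA theta component embedded in the mPFC trace.
#' @param kappa_block_gain Per-block multiplier on each unit's von Mises
#'   phase-coupling concentration.
#' @param latent_rt_gain,latent_rate_gain Gain of the shared per-trial latent
#'   (half-normal, block-scaled by `latent_block_scale`) on log response time
#'   and on population event-response amplitude. Set both to 0 to switch the
#'   latent-trajectory/RT coupling off.
#' @param latent_block_scale Per-block scale of the latent. The default is
#'   block-homogeneous so that units without block gain have identical rate
#'   distributions in every block (their encoder truth is false); block-scaled
#'   values make behavioral variability grow with risk at the cost of making
#'   the latent itself a block signal.
#' @param seed Session seed; all randomness derives from it.
#'
#' @return A `session_config` list.
#' @export
session_config <- function(n_blocks = 3L,
                           trials_per_block = 50L,
                           shock_contingency = c(0, 0.06, 0.1),
                           rt_meanlog = log(c(0.8, 1.4, 2.2)),
                           rt_sdlog = c(0.25, 0.35, 0.45),
                           reward_rt_meanlog = log(1.0),
                           reward_rt_sdlog = 0.15,
                           iti_range = c(6, 8),
                           units = default_unit_templates(),
                           lfp_fs = 1000,
                           pink_noise_sd = 15,
                           theta_freq_range = c(6, 10),
                           theta_freq_jitter = 2,
                           theta_amplitude = 20,
                           theta_block_gain = c(1, 0.65, 0.35),
                           theta_burst_dur = 1,
                           coupling_delay = 0.02,
                           coupling_gain = 0.8,
                           kappa_block_gain = c(1, 0.75, 0.5),
                           latent_rt_gain = 0.25,
                           latent_rate_gain = 0.35,
                           latent_block_scale = c(1, 1, 1),
                           seed = 1L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    shock_contingency = shock_contingency,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    reward_rt_meanlog = reward_rt_meanlog, reward_rt_sdlog = reward_rt_sdlog,
    iti_range = iti_range, units = tibble::as_tibble(units),
    lfp_fs = lfp_fs, pink_noise_sd = pink_noise_sd,
    theta_freq_range = theta_freq_range,
    theta_freq_jitter = theta_freq_jitter, theta_amplitude = theta_amplitude,
    theta_block_gain = theta_block_gain, theta_burst_dur = theta_burst_dur,
    coupling_delay = coupling_delay, coupling_gain = coupling_gain,
    kappa_block_gain = kappa_block_gain,
    latent_rt_gain = latent_rt_gain, latent_rate_gain = latent_rate_gain,
    latent_block_scale = latent_block_scale,
    seed = as.integer(seed)
  )
  if (any(cfg$shock_contingency < 0 | cfg$shock_contingency > 1)) {
    abort("shock_contingency must lie in [0, 1]",
          class = "thetasync_config_error")
  }
  if (length(cfg$shock_contingency) != cfg$n_blocks) {
    abort("shock_contingency must have one entry per block",
          class = "thetasync_config_error")
  }
  if (any(cfg$units$kappa < 0)) {
    abort("phase-coupling kappa must be non-negative",
          class = "thetasync_config_error")
  }
  if (any(cfg$units$baseline_rate <= 0)) {
    abort("baseline rates must be positive", class = "thetasync_config_error")
  }
  structure(cfg, class = "session_config")
}

#' Default per-unit generator templates
#'
#' A deterministic roster of unit templates: mPFC regular-firing units with
#' diffuse event responses (a mix of up- and down-gain punishment encoders and
#' baseline-modulated units), VTA putative-DA-like units (slow, broad
#' waveforms, sharp phasic bumps at every event, strongly theta phase-coupled
#' with declining concentration over blocks), and VTA non-DA-like units
#' (faster, narrow waveforms, sustained excited or suppressed reward
#' responses, weak phase coupling). Every unit's phase reference is the VTA
#' theta component (bottom-up coupling) with a 20 ms oscillation lead.
#'
#' @param n_mpfc,n_vta_da,n_vta_nonda Unit counts per group.
#' @param encoder_gain Block-gain vector of an up-modulated encoder; the
#'   down-modulated variant is its reciprocal profile.
#' @param osc_lead Oscillation lead time (s): spikes are coupled to the theta
#'   phase this long before the spike, so lagged phase locking peaks at the
#'   negative of this value.
#' @return Tibble of unit templates consumed by [generate_session()].
#' @export
default_unit_templates <- function(n_mpfc = 16L, n_vta_da = 7L,
                                   n_vta_nonda = 6L,
                                   encoder_gain = c(1, 1.5, 2),
                                   osc_lead = 0.02) {
  down_gain <- rev(encoder_gain) / encoder_gain[3]
  flat <- c(1, 1, 1)
  mk <- function(id, region, class, baseline, width, amps, lat, rw,
                 gain, base_gain, kappa, pref) {
    tibble::tibble(
      unit_id = id, region = region, class = class,
      baseline_rate = baseline, waveform_width = width,
      amp_cue = amps[1], amp_action = amps[2], amp_reward = amps[3],
      resp_latency = lat, resp_width = rw,
      block_gain = list(gain), baseline_block_gain = list(base_gain),
      kappa = kappa, pref_phase = pref, phase_ref = "VTA",
      osc_lead = osc_lead
    )
  }
  rows <- list()
  for (i in seq_len(n_mpfc)) {
    enc <- i <= ceiling(n_mpfc / 2)
    gain <- if (!enc) flat else if (i %% 2 == 1) encoder_gain else down_gain
    # baseline modulation co-directional with the event gain where both exist
    base_gain <- if (i %in% c(1, 3, 9)) c(1, 1.15, 1.3)
      else if (i %in% c(4, 10)) c(1, 0.9, 0.8) else flat
    rows[[length(rows) + 1]] <- mk(
      sprintf("m%02d", i), "mPFC", "mPFC",
      baseline = 3 + 6 * (i - 1) / max(1, n_mpfc - 1),
      width = 0.8 + 0.4 * (i %% 5) / 4,
      amps = c(3, 6, 3), lat = 0.05, rw = 0.25,
      gain = gain, base_gain = base_gain,
      kappa = if (i <= ceiling(0.6 * n_mpfc)) 1.5 else 0.3,
      pref = pi / 4
    )
  }
  for (i in seq_len(n_vta_da)) {
    enc <- i <= ceiling(0.7 * n_vta_da)
    rows[[length(rows) + 1]] <- mk(
      sprintf("d%02d", i), "VTA", "DA",
      baseline = 4 + 2 * (i - 1) / max(1, n_vta_da - 1),
      width = 1.4 + 0.4 * (i - 1) / max(1, n_vta_da - 1),
      amps = c(10, 12, 18), lat = 0.06, rw = 0.08,
      gain = if (enc) c(1, 1.4, 1.8) else flat, base_gain = flat,
      kappa = 2.5, pref = 0
    )
  }
  for (i in seq_len(n_vta_nonda)) {
    suppressed <- i > ceiling(n_vta_nonda / 2)
    rows[[length(rows) + 1]] <- mk(
      sprintf("n%02d", i), "VTA", "nonDA",
      baseline = 9 + 6 * (i - 1) / max(1, n_vta_nonda - 1),
      width = 0.7 + 0.4 * (i - 1) / max(1, n_vta_nonda - 1),
      amps = c(2, 4, if (suppressed) -6 else 5), lat = 0.1, rw = 0.4,
      gain = if (i %% 2 == 0) c(1, 1.3, 1.6) else flat,
      base_gain = if (i == 1) c(1, 1.25, 1.5) else flat,
      kappa = 0.6, pref = pi / 2
    )
  }
  dplyr::bind_rows(rows)
}

# 1/f-amplitude (pink) noise by spectral shaping of seeded white phases.
# Shaped at the next highly-composite length (fast FFT) and truncated.
pink_noise <- function(n, sd_target) {
  n_fft <- stats::nextn(n)
  if (n_fft > n) {
    return(pink_noise_exact(n_fft, sd_target)[seq_len(n)])
  }
  pink_noise_exact(n, sd_target)
}

pink_noise_exact <- function(n, sd_target) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x * sd_target / sd(x)
}

# Hann envelope of total width `dur` centered at 0; zero outside.
hann_env <- function(dt, dur) {
  ifelse(abs(dt) < dur / 2, cos(pi * dt / dur)^2, 0)
}

#' Generate a synthetic session
#'
#' Draws the trial table (event chain cue -> action -> reward with per-block
#' lognormal RTs and pseudo-randomly flagged shock trials), spike trains from
#' inhomogeneous Poisson rates (baseline x per-block offset + event-locked
#' Gaussian bumps with per-block gain and a shared per-trial latent
#' modulation), and a VTA/mPFC LFP pair (pink noise + action-locked theta
#' burst; the mPFC trace embeds a delayed, scaled copy of the VTA theta
#' component). Spike-phase coupling is injected by von Mises thinning against
#' the burst phase of the unit's reference region, evaluated `osc_lead`
#' seconds before the spike.
#'
#' Ground truth (encoder flags, DA labels, kappas, coupling delay, theta
#' frequency, the latent series) is stored in the session metadata and
#' retrieved with [ground_truth()].
#'
#' @param config A [session_config()].
#' @param lfp Generate the LFP pair (set `FALSE` for spike-only sessions,
#'   which is much faster when only trial/spike analyses are needed).
#' @return An `ephys_session`.
#' @export
generate_session <- function(config = session_config(), lfp = TRUE) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, generate_session_impl(config, lfp))
}

generate_session_impl <- function(cfg, with_lfp) {
  nb <- cfg$n_blocks
  tpb <- cfg$trials_per_block
  n_tr <- nb * tpb
  block <- rep(seq_len(nb), each = tpb)

  # shared per-trial latent: half-normal, block-scaled
  latent <- abs(rnorm(n_tr)) * cfg$latent_block_scale[block]

  # trial event chain
  rt <- exp(cfg$rt_meanlog[block] + cfg$rt_sdlog[block] * rnorm(n_tr) +
              cfg$latent_rt_gain * latent)
  reward_rt <- rlnorm(n_tr, cfg$reward_rt_meanlog, cfg$reward_rt_sdlog)
  iti <- runif(n_tr, cfg$iti_range[1], cfg$iti_range[2])
  block_timeout <- ifelse(seq_len(n_tr) %% tpb == 1 & seq_len(n_tr) > 1, 20, 0)
  cue <- numeric(n_tr)
  t_now <- 5  # leaves room for the baseline window before the first cue
  for (i in seq_len(n_tr)) {
    t_now <- t_now + block_timeout[i]
    cue[i] <- t_now
    t_now <- t_now + rt[i] + reward_rt[i] + iti[i]
  }
  action <- cue + rt
  reward <- action + reward_rt

  shock_flag <- rep(FALSE, n_tr)
  for (b in seq_len(nb)) {
    n_shock <- round(cfg$shock_contingency[b] * tpb)
    if (n_shock > 0) {
      idx <- which(block == b)
      shock_flag[sample(idx, n_shock)] <- TRUE
    }
  }

  trials <- tibble::tibble(
    trial_id = seq_len(n_tr), block = block,
    cue_time = cue, action_time = action, reward_time = reward,
    shock_flag = shock_flag, rt = rt,
    immobile_rt = rt * runif(n_tr, 0.2, 0.6),
    reward_rt = reward_rt
  )

  duration <- max(reward) + 5
  theta_freq <- runif(1, cfg$theta_freq_range[1], cfg$theta_freq_range[2])
  freq_tr <- pmin(pmax(theta_freq + cfg$theta_freq_jitter * rnorm(n_tr), 5.2),
                  14.5)
  burst_phase <- runif(n_tr, -pi, pi)

  # analytic theta burst phase/envelope of the VTA component at times t
  theta_phase_env <- function(t) {
    idx <- findInterval(t, action)
    k0 <- pmin(pmax(idx, 1L), n_tr)
    k1 <- pmin(k0 + 1L, n_tr)
    pick <- abs(t - action[k1]) < abs(t - action[k0])
    k <- ifelse(pick, k1, k0)
    dt <- t - action[k]
    list(
      phase = 2 * pi * freq_tr[k] * dt + burst_phase[k],
      env = hann_env(dt, cfg$theta_burst_dur),
      trial = k
    )
  }

  # spikes: thinning of a homogeneous Poisson majorant
  units <- cfg$units
  spike_trains <- vector("list", nrow(units))
  max_latent_gain <- 1 + cfg$latent_rate_gain * max(latent)
  for (u in seq_len(nrow(units))) {
    un <- units[u, ]
    bg <- un$block_gain[[1]]
    bb <- un$baseline_block_gain[[1]]
    amps <- c(cue = un$amp_cue, action = un$amp_action, reward = un$amp_reward)
    lam_max <- un$baseline_rate * max(bb) +
      sum(pmax(amps, 0)) * max(bg) * max_latent_gain + 1
    # von Mises phase modulation is rate-preserving (normalized by its
    # Bessel mean), so the majorant grows by the density's peak factor
    kap_u <- un$kappa * max(cfg$kappa_block_gain)
    vm_factor <- if (kap_u > 0) exp(kap_u) / besselI(kap_u, 0) else 1
    Lam <- lam_max * vm_factor
    n_cand <- rpois(1, Lam * duration)
    tc <- sort(runif(n_cand, 0, duration))

    blk_of <- block[pmin(pmax(findInterval(tc, cue - 4.5), 1L), n_tr)]
    lam <- un$baseline_rate * bb[blk_of]
    ev_times <- list(cue = cue, action = action, reward = reward)
    for (ev in names(ev_times)) {
      if (amps[[ev]] == 0) next
      et <- ev_times[[ev]] + un$resp_latency
      idx <- findInterval(tc, et)
      for (j in 0:1) {
        k <- pmin(pmax(idx + j, 1L), n_tr)
        dt <- tc - et[k]
        contrib <- amps[[ev]] * bg[block[k]] *
          (1 + cfg$latent_rate_gain * latent[k]) *
          exp(-dt^2 / (2 * un$resp_width^2))
        if (j == 1) contrib[idx + 1 > n_tr] <- 0
        if (j == 0) contrib[idx < 1] <- 0
        lam <- lam + contrib
      }
    }
    lam <- pmax(lam, 0)
    if (un$kappa > 0 && n_cand > 0) {
      ref_shift <- if (un$phase_ref == "mPFC") cfg$coupling_delay else 0
      pe <- theta_phase_env(tc - un$osc_lead - ref_shift)
      kap <- un$kappa * cfg$kappa_block_gain[block[pe$trial]] * pe$env
      lam <- lam * exp(kap * cos(pe$phase - un$pref_phase)) / besselI(kap, 0)
    }
    spike_trains[[u]] <- tc[runif(n_cand) < lam / Lam]
  }

  unit_tbl <- tibble::tibble(
    unit_id = units$unit_id, region = units$region,
    waveform_width = units$waveform_width,
    spike_times = spike_trains
  )

  lfp_tbl <- NULL
  if (with_lfp) {
    fs <- cfg$lfp_fs
    n_samp <- ceiling(duration * fs)
    tt <- (seq_len(n_samp) - 1) / fs
    pe <- theta_phase_env(tt)
    theta_vta <- cfg$theta_amplitude *
      cfg$theta_block_gain[block[pe$trial]] * pe$env * cos(pe$phase)
    vta <- pink_noise(n_samp, cfg$pink_noise_sd) + theta_vta
    d_samp <- round(cfg$coupling_delay * fs)
    theta_del <- c(rep(0, d_samp), theta_vta[seq_len(n_samp - d_samp)])
    mpfc <- pink_noise(n_samp, cfg$pink_noise_sd) +
      cfg$coupling_gain * theta_del
    lfp_tbl <- tibble::tibble(
      region = c("VTA", "mPFC"), fs = fs, t0 = 0,
      samples = list(vta, mpfc)
    )
  }

  truth <- list(
    units = tibble::tibble(
      unit_id = units$unit_id,
      region = units$region,
      class = units$class,
      # any block-dependent rate (event gain or baseline offset) makes the
      # unit's peri-event counts block-discriminable, hence an encoder
      encoder = vapply(units$block_gain,
                       function(g) diff(range(g)) > 0, logical(1)) |
        vapply(units$baseline_block_gain,
               function(g) diff(range(g)) > 0, logical(1)),
      baseline_modulated = vapply(units$baseline_block_gain,
                                  function(g) diff(range(g)) > 0, logical(1)),
      da = units$class == "DA",
      kappa = units$kappa,
      pref_phase = units$pref_phase,
      osc_lead = units$osc_lead
    ),
    coupling_delay = cfg$coupling_delay,
    coupling_direction = "VTA->mPFC",
    theta_freq = theta_freq,
    latent = latent,
    latent_coupled = cfg$latent_rt_gain != 0 && cfg$latent_rate_gain != 0
  )

  ephys_session(
    trials, unit_tbl, lfp_tbl,
    meta = list(duration = duration, seed = cfg$seed,
                trials_per_block = tpb, synthetic = TRUE,
                config = cfg[setdiff(names(cfg), "units")], truth = truth)
  )
}

#' No-shock control configuration
#'
#' The control condition: the same block/trial structure with every
#' punishment-dependent effect switched off — zero shock contingency in all
#' blocks, block-constant response-time distribution, flat event-response and
#' baseline block gains for every unit, block-constant theta amplitude and
#' phase-coupling concentration, and no latent trajectory/RT coupling. Under
#' this configuration every blockwise detection across the pipeline is a
#' false positive, so detection rates calibrate against their nominal alpha.
#'
#' @param seed Session seed.
#' @param ... Further overrides passed to [session_config()].
#' @return A `session_config`.
#' @export
no_shock_config <- function(seed = 1L, ...) {
  units <- default_unit_templates()
  flat <- list(c(1, 1, 1))
  units$block_gain <- rep(flat, nrow(units))
  units$baseline_block_gain <- rep(flat, nrow(units))
  session_config(
    shock_contingency = c(0, 0, 0),
    rt_meanlog = rep(log(0.8), 3), rt_sdlog = rep(0.25, 3),
    units = units,
    theta_block_gain = c(1, 1, 1),
    kappa_block_gain = c(1, 1, 1),
    latent_rt_gain = 0, latent_rate_gain = 0,
    seed = seed, ...
  )
}

#' Ground truth of a synthetic session
#'
#' @param session An `ephys_session` produced by [generate_session()].
#' @return List with per-unit truth (encoder status, DA labels, kappa,
#'   preferred phase, oscillation lead), the coupling delay/direction, theta
#'   frequency, and the per-trial latent series.
#' @export
ground_truth <- function(session) {
  if (is.null(session$meta$truth)) {
    abort("session carries no ground truth (not generated by this package)",
          class = "thetasync_unsupported_error")
  }
  session$meta$truth
}
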