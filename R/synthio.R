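# Synthetic survey generator with known ground truth: vessel counts,
# activity-state sequences from context-specific transition matrices,
# state-dependent theodolite tracks, dB-scale noise series and whistle
# contours whose characteristics depend on noise and group context.

#' Default context-specific transition matrices
#'
#' Four 5x5 row-stochastic matrices over the activity states, one per vessel
#' context. The Low matrix is doubly stochastic (uniform stationary budget),
#' Decreasing equals Low (no effect), High inflates foraging persistence and
#' drains socialising/resting into travelling, and Increasing inflates
#' travelling persistence and reduces socialising persistence — the effect
#' directions reported for vessel-exposed dolphin groups.
#'
#' @return Named list of matrices keyed by vessel context.
#' @export
default_context_matrices <- function() {
  s <- activity_states
  low <- matrix(0.13, 5, 5, dimnames = list(s, s))
  diag(low) <- 0.48
  high <- rbind(
    foraging    = c(0.70, 0.075, 0.075, 0.075, 0.075),
    milling     = c(0.20, 0.40, 0.05, 0.05, 0.30),
    resting     = c(0.10, 0.15, 0.25, 0.10, 0.40),
    socialising = c(0.15, 0.15, 0.10, 0.20, 0.40),
    travelling  = c(0.15, 0.12, 0.05, 0.13, 0.55)
  )
  dimnames(high) <- list(s, s)
  inc <- low
  inc["travelling", ] <- c(0.10, 0.10, 0.05, 0.10, 0.65)
  inc["socialising", ] <- c(0.10, 0.20, 0.10, 0.25, 0.35)
  list(Low = low, High = high, Increasing = inc, Decreasing = low)
}

#' Default effects linking whistle latent parameters to covariates
#'
#' Each element gives the additive effect, on the latent (log or logit)
#' scale, of broadband noise (per dB above the base level), activity state,
#' group size (linear, per animal) and calf presence on one contour-shaping
#' parameter. Signs follow the reported directions: duration, minimum
#' frequency, modulation (extrema) and harmonics decline with rising noise
#' while frequency range widens.
#'
#' @return Named list of effect lists.
#' @export
default_whistle_effects <- function() {
  st <- function(...) stats::setNames(c(...), activity_states)
  list(
    log_duration = list(nl = -0.012, state = st(-0.15, -0.10, 0, -0.10, 0.25),
                        gsize = 0.05, calf = 0),
    log_fmin = list(nl = -0.008, state = st(-0.10, 0, 0, -0.10, 0.05),
                    gsize = 0, calf = -0.08),
    log_delta = list(nl = 0.010, state = st(0.20, -0.15, 0, 0.20, -0.10),
                     gsize = 0.06, calf = 0.15),
    log_cycles = list(nl = -0.020, state = st(-0.30, -0.30, 0, -0.20, 0.40),
                      gsize = 0.10, calf = 0.10),
    logit_harmonics = list(nl = -0.080, state = st(-0.30, 0.60, 0, -0.30, 0),
                           gsize = 0, calf = 0)
  )
}

#' Zeroed whistle effects (null generator)
#'
#' All covariate effects set to zero; whistle characteristics are then
#' independent of noise, activity, group size and calf presence. Used for
#' null-calibration checks.
#' @return Named list of effect lists, same shape as
#'   [default_whistle_effects()].
#' @export
null_whistle_effects <- function() {
  eff <- default_whistle_effects()
  lapply(eff, function(e) {
    list(nl = 0, state = e$state * 0, gsize = 0, calf = 0)
  })
}

#' Configuration of the synthetic survey generator
#'
#' Bundles all ground-truth parameters. Defaults describe an urban-estuary
#' survey: Poisson vessel counts with epoch-switching rates tuned so the
#' empirical median per 5-min sample is 3 (the operational density cutoff),
#' five activity states driven by context-specific transition matrices,
#' state-dependent lognormal movement speeds, an ambient broadband level
#' around 110 dB re 1 uPa, and group sizes 1-5 with mean 2.4.
#'
#' @param seed Integer RNG seed; fixed seed and config give byte-identical
#'   output.
#' @param n_samples Number of 5-min intervals to simulate.
#' @param vessel_rate_low,vessel_rate_high Poisson means (vessels per 5 min)
#'   in low- and high-traffic epochs.
#' @param epoch_mean_low,epoch_mean_high Mean epoch lengths in samples for
#'   the two-state semi-Markov traffic process.
#' @param context_matrices Named list of four 5x5 row-stochastic matrices
#'   keyed by vessel context.
#' @param state_speed_means Named mean ground speeds (m/s) per activity
#'   state.
#' @param state_speed_cv Coefficient of variation of the per-sample lognormal
#'   speed draw.
#' @param whistle_effects Effect structure as in
#'   [default_whistle_effects()].
#' @param whistle_rate Expected whistles per 5-min sample.
#' @param noise_base_db Centre of the broadband noise series, dB re 1 uPa.
#' @param noise_walk_sd_db Per-second standard deviation of the reflected
#'   random walk of the noise series, dB.
#' @param noise_range_db Half-width of the reflecting band around the base
#'   level, dB.
#' @param group_size_probs Probabilities of group sizes 1..5 (default mean
#'   2.4).
#' @param calf_prob Probability a sighting block includes a calf.
#' @param gap_prob Probability any 5-min sample is missing from the record
#'   (breaks transition chains).
#' @param cutoff Vessel-density cutoff used when deriving contexts.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_samples = 1000L,
                         vessel_rate_low = 2.8,
                         vessel_rate_high = 7,
                         epoch_mean_low = 12,
                         epoch_mean_high = 4,
                         context_matrices = default_context_matrices(),
                         state_speed_means = c(foraging = 0.8, milling = 0.6,
                                               resting = 0.3, socialising = 0.7,
                                               travelling = 1.7),
                         state_speed_cv = 0.35,
                         whistle_effects = default_whistle_effects(),
                         whistle_rate = 0.35,
                         noise_base_db = 110,
                         noise_walk_sd_db = 0.5,
                         noise_range_db = 12,
                         group_size_probs = c(0.25, 0.35, 0.20, 0.12, 0.08),
                         calf_prob = 0.41,
                         gap_prob = 0.04,
                         cutoff = 3) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (vessel_rate_low <= 0 || vessel_rate_high <= 0) {
    stop("vessel rates must be strictly positive", call. = FALSE)
  }
  if (any(state_speed_means <= 0)) {
    stop("state speed means must be strictly positive", call. = FALSE)
  }
  stopifnot(setequal(names(context_matrices), vessel_contexts))
  for (cx in names(context_matrices)) {
    M <- context_matrices[[cx]]
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12)) {
      stop("context matrix '", cx, "' rows must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  stopifnot(length(group_size_probs) == 5,
            abs(sum(group_size_probs) - 1) < 1e-8)
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         vessel_rate_low = vessel_rate_low, vessel_rate_high = vessel_rate_high,
         epoch_mean_low = epoch_mean_low, epoch_mean_high = epoch_mean_high,
         context_matrices = context_matrices,
         state_speed_means = state_speed_means, state_speed_cv = state_speed_cv,
         whistle_effects = whistle_effects, whistle_rate = whistle_rate,
         noise_base_db = noise_base_db, noise_walk_sd_db = noise_walk_sd_db,
         noise_range_db = noise_range_db,
         group_size_probs = group_size_probs, calf_prob = calf_prob,
         gap_prob = gap_prob, cutoff = cutoff),
    class = "synth_config"
  )
}

.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Simulate per-5-min vessel counts
#'
#' Two-state semi-Markov traffic process: epochs of geometric length (means
#' `epoch_mean_low`/`epoch_mean_high` samples) alternate between low and high
#' Poisson rates. With the default rates the empirical median count is 3 and
#' runs of heavy traffic occur, so all four vessel contexts arise.
#'
#' @param config A [synth_config()].
#' @param n Number of samples (defaults to `config$n_samples`).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return Integer vector of non-negative counts.
#' @export
simulate_vessel_counts <- function(config, n = config$n_samples,
                                   seed = config$seed) {
  .maybe_seed(seed)
  counts <- integer(0)
  high <- stats::runif(1) < config$epoch_mean_high /
    (config$epoch_mean_low + config$epoch_mean_high)
  while (length(counts) < n) {
    mean_len <- if (high) config$epoch_mean_high else config$epoch_mean_low
    len <- 1L + stats::rgeom(1, 1 / mean_len)
    rate <- if (high) config$vessel_rate_high else config$vessel_rate_low
    counts <- c(counts, stats::rpois(len, rate))
    high <- !high
  }
  counts[seq_len(n)]
}

#' Simulate an activity-state sequence driven by vessel context
#'
#' The state at step t+1 is drawn from row `state(t)` of the transition
#' matrix for the context of the step, where the context is classified from
#' the vessel counts of samples t and t+1 with the same rule the analysis
#' uses ([classify_context()]).
#'
#' @param counts Integer vessel-count series (one per sample).
#' @param config A [synth_config()].
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return Character vector of activity states, same length as `counts`.
#' @export
simulate_behaviour_sequence <- function(counts, config, seed = config$seed) {
  .maybe_seed(seed)
  n <- length(counts)
  ctx <- as.character(classify_context(counts[-n], counts[-1], config$cutoff))
  states <- character(n)
  states[1] <- sample(activity_states, 1)
  for (t in seq_len(n - 1)) {
    P <- config$context_matrices[[ctx[t]]]
    row <- P[states[t], ]
    states[t + 1] <- sample(activity_states, 1, prob = row)
  }
  states
}

#' Simulate theodolite fixes for a sequence of 5-min samples
#'
#' Each sample gets a straight-line track segment at a constant ground speed
#' drawn lognormally with the activity state's configured mean and CV; at
#' least two fixes are placed on a 5-s grid inside the window, and positions
#' are converted to horizontal/vertical theodolite angles by inverting the
#' station geometry. Tracks whose positions would approach the horizon
#' (range beyond 4.8 km, where the depression angle vanishes) are rejected
#' and resampled.
#'
#' @param samples Data frame with `sample_start`, `group_id` and
#'   `activity_state`.
#' @param config A [synth_config()].
#' @param station A [station_geometry()] with positive effective height.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return List with `fixes` (timestamp, target_id, target_kind,
#'   horizontal_angle, vertical_angle) and `truth` (per-sample true speed,
#'   m/s).
#' @export
simulate_track <- function(samples, config, station, seed = config$seed) {
  stopifnot(inherits(station, "station_geometry"))
  if (station$effective_height <= 0) stop("station height must be positive")
  .maybe_seed(seed)
  cv <- config$state_speed_cv
  sdlog <- sqrt(log(1 + cv^2))
  n <- nrow(samples)
  fix_list <- vector("list", n)
  true_speed <- numeric(n)
  for (k in seq_len(n)) {
    m <- config$state_speed_means[[samples$activity_state[k]]]
    meanlog <- log(m) - sdlog^2 / 2
    sp <- stats::rlnorm(1, meanlog, sdlog)
    true_speed[k] <- sp
    n_fix <- 2L + stats::rpois(1, 3)
    times <- samples$sample_start[k] +
      sort(sample(seq(5, 295, by = 5), min(n_fix, 59)))
    repeat {
      r0 <- stats::runif(1, 400, 2200)
      th <- stats::runif(1, 0, 2 * pi)
      head <- stats::runif(1, 0, 2 * pi)
      x <- r0 * sin(th) + sp * (times - times[1]) * sin(head)
      y <- r0 * cos(th) + sp * (times - times[1]) * cos(head)
      rng <- sqrt(x^2 + y^2)
      if (all(rng < 4800) && all(rng > 20)) break
    }
    pos <- data.frame(timestamp = times, x_east = x, y_north = y)
    ang <- position_to_fix(pos, station)
    # one track burst per sample: groups are re-acquired after dives, so
    # fixes are continuous within a 5-min sample but not across samples
    fix_list[[k]] <- data.frame(
      timestamp = ang$timestamp,
      target_id = sprintf("%s-%06d", samples$group_id[k],
                          samples$sample_start[k]),
      target_kind = "dolphin_group",
      horizontal_angle = ang$horizontal_angle,
      vertical_angle = ang$vertical_angle
    )
  }
  list(fixes = do.call(rbind, fix_list),
       truth = data.frame(sample_start = samples$sample_start,
                          true_speed = true_speed))
}

#' Simulate a broadband/octave-band noise series
#'
#' A reflected Gaussian random walk (1-s steps) around `noise_base_db`
#' bounded within `noise_range_db`, plus twelve octave-band levels generated
#' as the broadband level shifted by a declining spectral shape with
#' band-specific autocorrelated wobble — deliberately highly collinear, as
#' measured octave bands are.
#'
#' @param config A [synth_config()].
#' @param t_end End time in seconds (series covers `0:t_end`).
#' @param dt Time step of the series, seconds (default 1).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return Data frame with `time`, `nl_bb` and `obl_<centre>` columns for
#'   centres 16 Hz to 32 kHz.
#' @export
simulate_noise_series <- function(config, t_end = config$n_samples * 300,
                                  dt = 1, seed = config$seed) {
  .maybe_seed(seed)
  times <- seq(0, t_end, by = dt)
  nt <- length(times)
  steps <- stats::rnorm(nt - 1, 0, config$noise_walk_sd_db * sqrt(dt))
  x <- cumsum(c(stats::runif(1, -2, 2), steps))
  # reflect into [-range, range]
  rng <- config$noise_range_db
  x <- abs((x + rng) %% (4 * rng) - 2 * rng) - rng
  nl <- config$noise_base_db + x
  centres <- 15.625 * 2^(0:11)
  offsets <- -3 - 1.2 * (0:11)
  out <- data.frame(time = times, nl_bb = nl)
  for (k in seq_along(centres)) {
    wob <- as.numeric(stats::filter(stats::rnorm(nt, 0, 0.4), 0.95,
                                    method = "recursive"))
    out[[paste0("obl_", round(centres[k]))]] <- nl + offsets[k] + wob
  }
  out
}

# values of a regularly sampled, sorted time series in [t0, t1)
.window_vals <- function(times, values, t0, t1) {
  i0 <- findInterval(t0 - 1e-9, times) + 1L
  i1 <- findInterval(t1 - 1e-9, times)
  if (i1 < i0) return(values[0])
  values[i0:i1]
}

# group sizes 1..5 with configured probabilities (default mean 2.4)
.draw_group_size <- function(n, probs) {
  sample(1:5, n, replace = TRUE, prob = probs)
}

.contour_dt <- 0.01  # 10-ms contour sampling

# build one contour from latent parameters; returns data.frame(time, frequency)
.make_contour <- function(start_time, duration, fmin, delta, ncyc, shape,
                          break_gap = 0) {
  tt <- seq(0, duration, by = .contour_dt)
  if (length(tt) < 3) tt <- seq(0, duration, length.out = 3)
  u <- tt / max(tt)
  f <- if (shape == "saddle") {
    g <- ifelse(u < 0.4, u / 0.4 * 0.5, ifelse(u <= 0.6, 0.5, 0.5 + (u - 0.6) / 0.4 * 0.5))
    fmin + delta * g
  } else if (ncyc >= 1) {
    fmin + (delta / 2) * (1 - cos(2 * pi * ncyc * u))
  } else if (shape == "down") {
    fmin + delta * (1 - u)
  } else {
    fmin + delta * u
  }
  f <- pmax(f, 100)  # clip: frequencies must stay positive
  ct <- data.frame(time = start_time + tt, frequency = f)
  if (break_gap > 0 && nrow(ct) > 12) {
    mid <- ct$time[1] + duration / 2
    ct <- ct[ct$time < mid | ct$time >= mid + break_gap, ]
  }
  ct
}

#' Simulate whistles, contours and the accompanying noise series
#'
#' Whistle occurrence is Poisson per 5-min sample. Each whistle's latent
#' contour parameters (log duration, log minimum frequency, log frequency
#' range, log modulation cycles, harmonics log-odds) receive additive
#' covariate effects — broadband noise in the 2 s before the whistle (dB
#' about the base level), activity state, group size and calf presence —
#' with the configured signs, plus lognormal/Poisson/Bernoulli noise.
#' Contours are sampled at 10-ms resolution from parametric families
#' (linear sweeps, raised-cosine modulation, stepped "saddle" contours);
#' a small fraction carry a >50-ms gap (a break). Frequencies that an
#' extreme effect would push below zero are clipped at 100 Hz with a
#' warning.
#'
#' @param samples Data frame with `sample_start`, `activity_state`,
#'   `group_size`, `calf_present`.
#' @param config A [synth_config()].
#' @param noise Optional noise series from [simulate_noise_series()];
#'   generated if `NULL`.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return List with `whistles` (whistle_id, start_time, harmonics, plus the
#'   generating covariates as `true_*` columns), `contours` (whistle_id,
#'   time, frequency) and `noise`.
#' @export
simulate_whistles <- function(samples, config, noise = NULL,
                              seed = config$seed) {
  .maybe_seed(seed)
  if (is.null(noise)) {
    noise <- simulate_noise_series(config,
                                   t_end = max(samples$sample_start) + 300,
                                   seed = NULL)
  }
  eff <- config$whistle_effects
  base_db <- config$noise_base_db
  wl <- list(); cl <- list()
  wid <- 0L
  clipped <- FALSE
  for (k in seq_len(nrow(samples))) {
    nw <- stats::rpois(1, config$whistle_rate)
    if (nw == 0) next
    st <- samples$activity_state[k]
    gs <- samples$group_size[k]
    calf <- as.integer(samples$calf_present[k])
    for (w in seq_len(nw)) {
      wid <- wid + 1L
      t0 <- samples$sample_start[k] + stats::runif(1, 3, 295)
      nl <- mean(.window_vals(noise$time, noise$nl_bb, t0 - 2, t0))
      lp <- function(e) e$nl * (nl - base_db) + e$state[[st]] +
        e$gsize * gs + e$calf * calf
      dur <- stats::rlnorm(1, log(0.4) + lp(eff$log_duration), 0.25)
      dur <- min(max(dur, 0.08), 2.5)
      fmin <- stats::rlnorm(1, log(5000) + lp(eff$log_fmin), 0.20)
      delta <- stats::rlnorm(1, log(4000) + lp(eff$log_delta), 0.25)
      ncyc <- stats::rpois(1, exp(log(1.0) + lp(eff$log_cycles)))
      harm <- stats::rbinom(1, 1, stats::plogis(0 + lp(eff$logit_harmonics)))
      shape <- if (ncyc >= 1) "mod" else sample(c("up", "down", "saddle"), 1,
                                                prob = c(0.55, 0.35, 0.10))
      brk <- stats::runif(1) < 0.06
      if (fmin < 100) clipped <- TRUE
      ct <- .make_contour(t0, dur, fmin, delta, ncyc, shape,
                          break_gap = if (brk) 0.08 else 0)
      ct$whistle_id <- wid
      cl[[wid]] <- ct
      wl[[wid]] <- data.frame(
        whistle_id = wid, start_time = t0, harmonics = harm,
        true_nl = nl, true_state = st, true_group_size = gs,
        true_calf = calf, true_duration = dur, true_fmin = fmin,
        true_delta = delta, true_cycles = ncyc, true_shape = shape,
        true_break = brk
      )
    }
  }
  if (clipped) warning("some contour frequencies clipped at 100 Hz")
  whistles <- if (length(wl)) do.call(rbind, wl) else
    data.frame(whistle_id = integer(), start_time = numeric(),
               harmonics = integer())
  contours <- if (length(cl)) do.call(rbind, cl)[, c("whistle_id", "time", "frequency")] else
    data.frame(whistle_id = integer(), time = numeric(), frequency = numeric())
  list(whistles = whistles, contours = contours, noise = noise)
}

#' Simulate a complete synthetic survey
#'
#' Chains all generators: vessel counts, context-driven activity sequence,
#' sighting gaps, per-block group size and calf presence, theodolite fixes,
#' noise series and whistles. The returned `truth` element carries the
#' generating parameters for recovery tests.
#'
#' @param config A [synth_config()].
#' @param station A [station_geometry()]; default is a 32-m vantage point.
#' @param whistles Logical; generate the acoustic side (noise + whistles).
#' @return List with `samples`, `fixes`, `noise`, `whistles`, `contours`,
#'   `track_truth` and `truth` (the config).
#' @export
simulate_survey <- function(config, station = station_geometry(32),
                            whistles = TRUE) {
  set.seed(config$seed)
  n <- config$n_samples
  counts <- simulate_vessel_counts(config, seed = NULL)
  states <- simulate_behaviour_sequence(counts, config, seed = NULL)
  keep <- stats::runif(n) > config$gap_prob
  samples <- data.frame(
    sample_start = (seq_len(n) - 1) * 300,
    group_id = "g1",
    activity_state = states,
    vessel_count = counts
  )[keep, ]
  # group size and calf presence are constant within a sighting block
  block <- cumsum(c(1, diff(samples$sample_start) != 300))
  nb <- max(block)
  gs_block <- .draw_group_size(nb, config$group_size_probs)
  calf_block <- stats::runif(nb) < config$calf_prob
  samples$group_size <- gs_block[block]
  samples$calf_present <- calf_block[block]
  samples$obs_time <- samples$sample_start + 150
  trk <- simulate_track(samples, config, station, seed = NULL)
  out <- list(samples = samples, fixes = trk$fixes, track_truth = trk$truth,
              truth = config)
  if (whistles) {
    wh <- simulate_whistles(samples, config, seed = NULL)
    out$noise <- wh$noise
    out$whistles <- wh$whistles
    out$contours <- wh$contours
  }
  out
}
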