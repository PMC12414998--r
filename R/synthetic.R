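# Ground-truth synthetic data for every pipeline stage. All draws flow
# from a single master seed through named substreams so stages regenerate
# independently and bit-identically.

substream <- function(seed, k) as.integer((seed %% 1000000L) * 1000L + k)

#' Configuration of the synthetic experiment
#'
#' Defaults mirror the study conditions: 14 subjects, 8 blocks of 100
#' trials (alternating native/novel cue blocks; 50 flattened and 50 shaped
#' per block), four source positions (FU 45, FD 135, BU 225, BD 270 degrees
#' polar), a group drift-rate advantage of 0.36 1/s for the matching
#' accumulator, and an EEG-to-drift link slope of -0.017 1/(microvolt s).
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks,trials_per_block Block structure (cue alternates by
#'   block).
#' @param group_mean Named group-level means: `A`, `B`, `t0` (s), `v0`
#'   (baseline drift 1/s), `delta` (match-mismatch drift contrast, 1/s).
#' @param group_sd Named between-subject SDs on the transformed scale
#'   (log for `A`, `B`, `t0`; raw for `v0`, `delta`).
#' @param beta_eeg EEG-amplitude drift slope, 1/(microvolt s).
#' @param amp_mean Named condition means of the single-trial cluster
#'   amplitude (microvolts) for `native_flattened`, `native_shaped`,
#'   `novel_flattened`, `novel_shaped`; defaults carry the sign pattern of
#'   the N1 contrast (native: flattened more negative; novel: reversed).
#' @param amp_sd Single-trial amplitude SD (microvolts).
#' @param erp Named list for the epoch generator: `n_channels`,
#'   `effect_channels` (indices; `NULL` picks channel 1 and its four
#'   nearest neighbours, a spatially compact patch), `effect_window` (s),
#'   `effect_uv`
#'   (microvolts), `noise_sd` (microvolts), `spatial_decay` (m),
#'   `trials_per_condition`, `fs` (Hz), `tmin`, `tmax` (s).
#' @param localization Named list: `gain`, `bias_lat`, `bias_pol`
#'   (degrees), `scatter_lat`, `scatter_pol` (degrees),
#'   `confusion_rate` in `[0, 1]`, `confusion_center` (degrees polar).
#' @param seed Master seed recorded with the config.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_subjects = 14,
    n_blocks = 8, trials_per_block = 100,
    group_mean = c(A = 0.5, B = 1.0, t0 = 0.25, v0 = 2.5, delta = 0.36),
    group_sd = c(A = 0.2, B = 0.2, t0 = 0.15, v0 = 0.3, delta = 0.15),
    beta_eeg = -0.017,
    amp_mean = c(native_flattened = -2, native_shaped = 0,
                 novel_flattened = 0, novel_shaped = -2),
    amp_sd = 10,
    erp = list(n_channels = 32, effect_channels = NULL,
               effect_window = c(0.08, 0.17), effect_uv = 0.5,
               noise_sd = 1, spatial_decay = 0.04,
               trials_per_condition = 30, fs = 100,
               tmin = -0.1, tmax = 1.5),
    localization = list(gain = 1, bias_lat = 0, bias_pol = 0,
                        scatter_lat = 8, scatter_pol = 20,
                        confusion_rate = 0.1, confusion_center = 180),
    seed = 1L) {
  stopifnot(all(group_sd >= 0), amp_sd > 0,
            localization$confusion_rate >= 0,
            localization$confusion_rate <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Draw per-subject LBA parameters from the group distributions
#'
#' `A`, `B`, `t0` vary lognormally around the group means; the baseline
#' drift `v0` and match contrast `delta` vary normally.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Data frame, one row per subject, with the realized `A`, `B`,
#'   `t0`, `v0`, `delta`.
#' @export
gen_subject_params <- function(config, seed = config$seed) {
  set.seed(substream(seed, 1L))
  n <- config$n_subjects
  gm <- config$group_mean; gs <- config$group_sd
  data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    A  = exp(log(gm["A"])  + stats::rnorm(n, 0, gs["A"])),
    B  = exp(log(gm["B"])  + stats::rnorm(n, 0, gs["B"])),
    t0 = exp(log(gm["t0"]) + stats::rnorm(n, 0, gs["t0"])),
    v0 = gm["v0"] + stats::rnorm(n, 0, gs["v0"]),
    delta = gm["delta"] + stats::rnorm(n, 0, gs["delta"]),
    row.names = NULL
  )
}

# the balanced factorial trial frame for one subject
design_cells <- function(config) {
  n_blocks <- config$n_blocks
  tpb <- config$trials_per_block
  blocks <- lapply(seq_len(n_blocks), function(b) {
    cue <- if (b %% 2 == 1) "native" else "novel"
    half <- tpb / 2
    pos <- rep(c("FU", "FD", "BU", "BD"), length.out = half)
    data.frame(block = b, cue = cue,
               direction = rep(c("flattened", "shaped"), each = half),
               position = c(pos, pos))
  })
  tab <- do.call(rbind, blocks)
  tab$vertical <- ifelse(tab$position %in% c("FU", "BU"), "up", "down")
  tab$horizontal <- ifelse(tab$position %in% c("FU", "FD"), "front", "back")
  tab
}

#' Generate single-trial EEG cluster amplitudes for a trial frame
#'
#' Amplitude = condition mean (by cue x direction, following the N1 sign
#' pattern) + Gaussian noise. Generated before behaviour so the LBA drifts
#' can include the `beta_eeg * amplitude` term, making amplitudes and
#' behaviour dependent exactly as the joint model assumes.
#'
#' @param trial_frame Data frame with `cue` and `direction` columns.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Numeric vector of amplitudes (microvolts).
#' @export
gen_eeg_amplitudes <- function(trial_frame, config, seed = config$seed) {
  set.seed(substream(seed, 2L))
  key <- paste(trial_frame$cue, trial_frame$direction, sep = "_")
  mu <- config$amp_mean[key]
  stopifnot(!any(is.na(mu)))
  as.numeric(mu + stats::rnorm(nrow(trial_frame), 0, config$amp_sd))
}

#' Simulate the behavioural trial table from the hierarchical LBA
#'
#' For every subject and trial, the looming/receding accumulator drift
#' means are `v0 +/- delta/2` (the matching accumulator gets the boost:
#' looming for flattened, receding for shaped stimuli) plus
#' `beta_eeg * amplitude` on both accumulators; choices and RTs come from
#' [simulate_lba()].
#'
#' @param subject_params Data frame from [gen_subject_params()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Trial table with columns `subject`, `block`, `trial`, `cue`,
#'   `direction`, `position`, `vertical`, `horizontal`, `eeg_amp`,
#'   `choice` ("looming"/"receding"), `rt` (s).
#' @export
gen_behavior <- function(subject_params, config, seed = config$seed) {
  cells <- design_cells(config)
  out <- vector("list", nrow(subject_params))
  for (i in seq_len(nrow(subject_params))) {
    sp <- subject_params[i, ]
    tab <- cells
    tab$subject <- sp$subject
    tab$trial <- seq_len(nrow(tab))
    tab$eeg_amp <- gen_eeg_amplitudes(tab, config,
                                      seed = substream(seed, 100L + i))
    match_loom <- tab$direction == "flattened"
    v_loom <- sp$v0 + ifelse(match_loom,  sp$delta / 2, -sp$delta / 2) +
      config$beta_eeg * tab$eeg_amp
    v_rec  <- sp$v0 + ifelse(match_loom, -sp$delta / 2,  sp$delta / 2) +
      config$beta_eeg * tab$eeg_amp
    pars <- lba_params(A = sp$A, B = sp$B, t0 = sp$t0, v = c(1, 1), sv = 1)
    sim <- simulate_lba(nrow(tab), pars, seed = substream(seed, 200L + i),
                        v_trial = cbind(v_loom, v_rec))
    tab$choice <- c("looming", "receding")[sim$choice]
    tab$rt <- sim$rt
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

# synthetic hemispheric cap: Fibonacci points on the upper half sphere
synthetic_cap_layout <- function(n_channels, radius = 0.09) {
  i <- seq_len(n_channels)
  z <- (i - 0.5) / n_channels          # upper hemisphere heights
  phi <- i * pi * (3 - sqrt(5))        # golden-angle azimuths
  r <- sqrt(pmax(1 - z^2, 0))
  channel_layout(sprintf("E%03d", i),
                 radius * cbind(r * cos(phi), r * sin(phi), z))
}

#' Generate epoched multichannel ERP data with a known effect
#'
#' Per subject, condition and trial: spatially correlated Gaussian noise
#' (exponentially decaying correlation with channel distance) plus a
#' condition-dependent deflection of `effect_uv` microvolts inside the
#' effect window on the effect channels. The deflection follows the N1
#' contrast pattern: negative for native flattened and novel shaped,
#' absent for native shaped and novel flattened. Time axis
#' `[tmin, tmax]` at `fs` Hz.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param n_subjects,effect_uv Optional overrides of the config.
#' @return An [erp_epochs()] object with conditions `native_flattened`,
#'   `native_shaped`, `novel_flattened`, `novel_shaped`.
#' @export
gen_erp_epochs <- function(config, seed = config$seed,
                           n_subjects = config$n_subjects,
                           effect_uv = config$erp$effect_uv) {
  e <- config$erp
  set.seed(substream(seed, 3L))
  layout <- synthetic_cap_layout(e$n_channels)
  times <- seq(e$tmin, e$tmax, by = 1 / e$fs)
  nt <- length(times)
  D <- as.matrix(stats::dist(layout$positions))
  if (is.null(e$effect_channels))
    e$effect_channels <- order(D[1, ])[1:5]  # compact patch around ch 1
  L <- chol(exp(-D / e$spatial_decay) + diag(1e-8, e$n_channels))
  win <- times >= e$effect_window[1] & times <= e$effect_window[2]
  eff_sign <- c(native_flattened = -1, native_shaped = 0,
                novel_flattened = 0, novel_shaped = -1)
  data <- list()
  for (s in seq_len(n_subjects)) {
    sdat <- list()
    for (cond in names(eff_sign)) {
      a <- array(0, c(e$n_channels, nt, e$trials_per_condition))
      for (tr in seq_len(e$trials_per_condition)) {
        noise <- t(L) %*% matrix(stats::rnorm(e$n_channels * nt,
                                              0, e$noise_sd),
                                 e$n_channels, nt)
        a[, , tr] <- noise
      }
      a[e$effect_channels, win, ] <-
        a[e$effect_channels, win, ] + eff_sign[cond] * effect_uv
      sdat[[cond]] <- a
    }
    data[[sprintf("S%02d", s)]] <- sdat
  }
  erp_epochs(data, times, layout)
}

#' Generate localization responses from a gain/bias/scatter model
#'
#' Responses are `gain * target + bias + scatter` per dimension, with a
#' configurable probability of quadrant confusion: the polar response is
#' redrawn near the confusion centre (default 180 degrees, the rear of the
#' horizontal plane, reproducing the rear response bias seen with
#' non-native cues). Lateral responses are clipped to `[-90, 90]`, polar
#' responses wrapped into `[-90, 270)`.
#'
#' @param targets Data frame with `target_lat`, `target_pol` (degrees).
#' @param model Named list as in [synthetic_config()]'s `localization`.
#' @param seed Integer seed.
#' @return Data frame: the targets plus `resp_lat`, `resp_pol`,
#'   `confused` (logical).
#' @export
gen_localization_responses <- function(targets,
                                       model = synthetic_config()$localization,
                                       seed = 1L) {
  set.seed(substream(seed, 4L))
  n <- nrow(targets)
  stopifnot(n >= 1)
  resp_lat <- model$gain * targets$target_lat + model$bias_lat +
    stats::rnorm(n, 0, model$scatter_lat)
  resp_pol <- model$gain * targets$target_pol + model$bias_pol +
    stats::rnorm(n, 0, model$scatter_pol)
  confused <- stats::runif(n) < model$confusion_rate
  if (any(confused))
    resp_pol[confused] <- model$confusion_center +
      stats::rnorm(sum(confused), 0, model$scatter_pol)
  data.frame(targets,
             resp_lat = pmin(pmax(resp_lat, -90), 90),
             resp_pol = wrap_polar(resp_pol),
             confused = confused)
}

#' Generate the full synthetic bundle
#'
#' Runs every generator from one master seed (named substreams per stage),
#' returning behaviour, per-trial EEG amplitudes (inside the behaviour
#' table), epoched ERP data, localization responses and the ground-truth
#' parameter record. Regeneration from the same `(config, seed)` is
#' bit-identical.
#'
#' @param config A [synthetic_config()].
#' @param seed Master seed (defaults to the config's).
#' @return List of class `synthetic_bundle`: `behavior`, `epochs`,
#'   `localization`, `subject_params`, `config`, `seed`.
#' @export
simulate_bundle <- function(config = synthetic_config(),
                            seed = config$seed) {
  sp <- gen_subject_params(config, seed)
  behavior <- gen_behavior(sp, config, seed)
  epochs <- gen_erp_epochs(config, seed)
  grid <- expand.grid(target_lat = seq(-60, 60, by = 30),
                      target_pol = seq(-30, 210, by = 30))
  loc <- gen_localization_responses(grid, config$localization, seed)
  structure(list(behavior = behavior, epochs = epochs, localization = loc,
                 subject_params = sp, config = config, seed = seed),
            class = "synthetic_bundle")
}
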