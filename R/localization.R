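#' Wrap polar angles into the interaural convention [-90, 270)
#'
#' @param x Polar angle(s) in degrees.
#' @return Angles wrapped modulo 360 into `[-90, 270)`.
#' @export
wrap_polar <- function(x) ((x + 90) %% 360) - 90

#' Absolute circular polar error, wrapped into [0, 180]
#'
#' Difference in polar angle between target and response on the 360-degree
#' polar circle (below -90, front 0, above 90, back 180), symmetric in its
#' arguments and invariant to adding 360 to either angle.
#'
#' @param target,response Polar angles in degrees (vectorized).
#' @return Error(s) in degrees, in `[0, 180]`.
#' @export
polar_error <- function(target, response) {
  d <- (response - target) %% 360
  pmin(d, 360 - d)
}

#' Score localization trials into the three error measures
#'
#' Computes the lateral error (mean absolute lateral difference, no
#' wrapping: the lateral range is `[-90, 90]`), the quadrant error rate
#' (percentage of trials whose polar error exceeds `local_threshold`) and
#' the local polar error (mean polar error over the remaining, local
#' trials).
#'
#' @param trials Data frame with columns `target_lat`, `target_pol`,
#'   `resp_lat`, `resp_pol` (degrees).
#' @param local_threshold Polar-error cutoff in degrees separating local
#'   from quadrant errors (default 90).
#' @return List of class `error_summary`: `lateral_error`,
#'   `local_polar_error` (NA with a warning if every trial is a quadrant
#'   error), `quadrant_error_rate` (percent), `n_trials`, `n_local_trials`.
#' @export
score_trials <- function(trials, local_threshold = 90) {
  stopifnot(nrow(trials) >= 1L)
  pe <- polar_error(trials$target_pol, trials$resp_pol)
  local <- pe <= local_threshold
  n <- nrow(trials)
  lpe <- if (any(local)) mean(pe[local]) else {
    warning("all trials are quadrant errors; local polar error undefined")
    NA_real_
  }
  structure(list(
    lateral_error = mean(abs(trials$target_lat - trials$resp_lat)),
    local_polar_error = lpe,
    quadrant_error_rate = 100 * sum(!local) / n,
    n_trials = n,
    n_local_trials = sum(local)
  ), class = "error_summary")
}

#' Score localization trials per participant, then average
#'
#' Matches repeated-measures use: each participant is scored with
#' [score_trials()] and the error measures are averaged across
#' participants. Set `pool = TRUE` for plain pooling over all trials.
#'
#' @param trials Data frame as in [score_trials()] plus a `participant`
#'   column (ignored when pooling).
#' @inheritParams score_trials
#' @param pool Pool all trials instead of participant-wise averaging.
#' @return `error_summary` of (averaged) measures.
#' @export
score_by_participant <- function(trials, local_threshold = 90, pool = FALSE) {
  if (pool || is.null(trials$participant))
    return(score_trials(trials, local_threshold))
  per <- lapply(split(trials, trials$participant),
                score_trials, local_threshold = local_threshold)
  structure(list(
    lateral_error = mean(vapply(per, `[[`, 0, "lateral_error")),
    local_polar_error = mean(vapply(per, `[[`, 0, "local_polar_error")),
    quadrant_error_rate = mean(vapply(per, `[[`, 0, "quadrant_error_rate")),
    n_trials = sum(vapply(per, `[[`, 0, "n_trials")),
    n_local_trials = sum(vapply(per, `[[`, 0, "n_local_trials"))
  ), class = "error_summary")
}

#' Uniform response sampler over a target range
#'
#' Returns a sampler closure drawing responses uniformly over the given
#' lateral interval and polar interval (the "equal response distribution
#' inside the target range" used for the chance-level virtual experiment).
#'
#' @param lat_range Length-2 lateral range in degrees.
#' @param pol_range Length-2 polar range in degrees (interaural convention).
#' @return `function(n)` returning a data frame with `resp_lat`, `resp_pol`.
#' @export
uniform_response_sampler <- function(lat_range = c(-90, 90),
                                     pol_range = c(-90, 270)) {
  force(lat_range); force(pol_range)
  function(n) data.frame(
    resp_lat = stats::runif(n, lat_range[1], lat_range[2]),
    resp_pol = wrap_polar(stats::runif(n, pol_range[1], pol_range[2]))
  )
}

#' Chance-level reference by virtual localization experiment
#'
#' Simulates `n_sim` replicates of the experiment with the actual target
#' locations (resampled with replacement) and fully randomized responses
#' drawn from `sampler`, scores each replicate with [score_trials()], and
#' averages. When an observed `error_summary` is supplied, the
#' observed/chance ratios are attached (1 = chance, 0 = error-free).
#'
#' @param targets Data frame with `target_lat`, `target_pol` (degrees).
#' @param sampler Response sampler `function(n)` as returned by
#'   [uniform_response_sampler()], or any closure with that contract.
#' @param n_sim Number of simulated replicates.
#' @param seed Integer seed.
#' @param observed Optional observed `error_summary` for normalization.
#' @param n_trials Trials per simulated replicate (default: number of
#'   targets).
#' @return List of class `chance_reference` with chance-level
#'   `lateral_error`, `local_polar_error`, `quadrant_error_rate`,
#'   Monte-Carlo SEs, and (optionally) `ratios`.
#' @export
chance_simulation <- function(targets, sampler = uniform_response_sampler(),
                              n_sim = 100, seed = 1L, observed = NULL,
                              n_trials = nrow(targets)) {
  stopifnot(nrow(targets) >= 1L, n_sim >= 1L)
  set.seed(seed)
  sims <- vapply(seq_len(n_sim), function(i) {
    idx <- sample.int(nrow(targets), n_trials, replace = TRUE)
    resp <- sampler(n_trials)
    s <- score_trials(data.frame(target_lat = targets$target_lat[idx],
                                 target_pol = targets$target_pol[idx],
                                 resp_lat = resp$resp_lat,
                                 resp_pol = resp$resp_pol))
    c(s$lateral_error, s$local_polar_error, s$quadrant_error_rate)
  }, numeric(3))
  chance <- rowMeans(sims)
  se <- apply(sims, 1, stats::sd) / sqrt(n_sim)
  out <- list(lateral_error = chance[1], local_polar_error = chance[2],
              quadrant_error_rate = chance[3],
              se = stats::setNames(se, c("lateral_error", "local_polar_error",
                                         "quadrant_error_rate")),
              n_sim = n_sim, n_trials = n_trials)
  if (!is.null(observed)) {
    out$ratios <- c(
      lateral_error = observed$lateral_error / chance[1],
      local_polar_error = observed$local_polar_error / chance[2],
      quadrant_error_rate = observed$quadrant_error_rate / chance[3])
  }
  structure(out, class = "chance_reference")
}
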