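#' Single-accumulator first-passage density and distribution
#'
#' Closed-form density/CDF of the time at which one linear ballistic
#' accumulator (start point uniform on `[0, A]`, deterministic within-trial
#' slope drawn once per trial from a normal with mean `v` and SD `sv`)
#' reaches threshold `b`. With `posdrift = TRUE` (default) the drift is
#' truncated to positive values, so the passage time is proper (CDF limit
#' 1) and defective densities over a race normalize.
#'
#' @param t Time(s) since accumulation onset, seconds (decision time, i.e.
#'   already excluding non-decision time).
#' @param A Start-point range (evidence units), `A >= 0`.
#' @param b Threshold (evidence units), `b >= A`, `b > 0`.
#' @param v Drift-rate mean (evidence units / s).
#' @param sv Drift-rate SD (evidence units / s), `sv >= 0`.
#' @param posdrift Truncate the drift distribution at zero.
#' @return Numeric vector of densities (`dlba_node`) or probabilities
#'   (`plba_node`).
#' @export
dlba_node <- function(t, A, b, v, sv = 1, posdrift = TRUE) {
  check_node_params(A, b, v, sv)
  out <- numeric(length(t))
  pos <- t > 0
  t <- t[pos]
  denom <- if (posdrift) stats::pnorm(v / max(sv, 1e-10)) else 1
  if (sv == 0) {
    # deterministic drift: passage time uniform on [(b - A)/v, b/v]
    f <- if (A > 0 && v > 0) ifelse(t >= (b - A) / v & t <= b / v, v / A, 0)
         else rep(0, length(t))
    out[pos] <- f
    return(out)
  }
  if (A == 0) {
    out[pos] <- b / (sv * t^2) * stats::dnorm((b / t - v) / sv) / denom
    return(out)
  }
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  f <- (-v * stats::pnorm(z1) + sv * stats::dnorm(z1) +
         v * stats::pnorm(z2) - sv * stats::dnorm(z2)) / A
  out[pos] <- pmax(f, 0) / denom
  out
}

#' @rdname dlba_node
#' @export
plba_node <- function(t, A, b, v, sv = 1, posdrift = TRUE) {
  check_node_params(A, b, v, sv)
  out <- numeric(length(t))
  pos <- t > 0
  t <- t[pos]
  denom <- if (posdrift) stats::pnorm(v / max(sv, 1e-10)) else 1
  if (sv == 0) {
    p <- if (v > 0) {
      if (A > 0) pmin(pmax((t * v - (b - A)) / A, 0), 1)
      else as.numeric(t >= b / v)
    } else rep(0, length(t))
    out[pos] <- p
    return(out)
  }
  if (A == 0) {
    out[pos] <- stats::pnorm((v - b / t) / sv) / denom
    return(out)
  }
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  p <- 1 + (b - A - t * v) / A * stats::pnorm(z1) -
           (b - t * v) / A * stats::pnorm(z2) +
           t * sv / A * (stats::dnorm(z1) - stats::dnorm(z2))
  # negative-drift trials never finish, so the raw F already excludes that
  # mass; conditioning on positive drift just rescales
  if (posdrift) p <- p / denom
  out[pos] <- pmin(pmax(p, 0), 1)
  out
}

check_node_params <- function(A, b, v, sv) {
  if (!is.finite(A) || A < 0) stop("A must be finite and >= 0")
  if (!is.finite(b) || b <= 0 || b < A) stop("b must be positive and >= A")
  if (!is.finite(v)) stop("v must be finite")
  if (!is.finite(sv) || sv < 0) stop("sv must be finite and >= 0")
  invisible(TRUE)
}

#' LBA parameter set for a race between accumulators
#'
#' @param A Start-point range, `A >= 0`.
#' @param B Threshold offset above the start-point range; threshold
#'   `b = A + B`, `B > 0`.
#' @param t0 Non-decision time in seconds, `t0 >= 0`.
#' @param v Vector of drift-rate means, one per accumulator.
#' @param sv Drift-rate SDs (scalar recycled, default 1; the first
#'   accumulator class is conventionally fixed to 1 for identifiability).
#' @return List of class `lba_params`.
#' @export
lba_params <- function(A, B, t0, v, sv = 1) {
  stopifnot(A >= 0, B > 0, t0 >= 0, length(v) >= 2)
  sv <- rep(sv, length.out = length(v))
  structure(list(A = A, B = B, b = A + B, t0 = t0, v = v, sv = sv),
            class = "lba_params")
}

#' Defective density of (choice, RT) under the LBA race
#'
#' `f_winner(rt - t0) * prod_losers(1 - F_loser(rt - t0))`; integrates to 1
#' summed over choices under the positive-truncated drift convention.
#'
#' @param rt Response time(s), seconds.
#' @param choice Integer index of the winning accumulator (recycled).
#' @param params An [lba_params()] object.
#' @param log Return log density.
#' @param posdrift Truncate drifts at zero.
#' @return Density values; `rt <= t0` yields 0 (`-Inf` on the log scale).
#' @export
defective_density <- function(rt, choice, params, log = FALSE,
                              posdrift = TRUE) {
  stopifnot(inherits(params, "lba_params"))
  choice <- rep(as.integer(choice), length.out = length(rt))
  t <- rt - params$t0
  n_acc <- length(params$v)
  dens <- rep(0, length(rt))
  ok <- t > 0
  if (any(ok)) {
    val <- rep(1, sum(ok))
    tt <- t[ok]
    ch <- choice[ok]
    for (a in seq_len(n_acc)) {
      f <- dlba_node(tt, params$A, params$b, params$v[a], params$sv[a],
                     posdrift)
      F <- plba_node(tt, params$A, params$b, params$v[a], params$sv[a],
                     posdrift)
      val <- val * ifelse(ch == a, f, 1 - F)
    }
    dens[ok] <- val
  }
  if (log) base::log(dens) else dens
}

#' Simulate choices and response times from the LBA race
#'
#' @param n Number of trials.
#' @param params An [lba_params()] object; alternatively supply `v` as a
#'   matrix `n x n_acc` of per-trial drift means via `v_trial`.
#' @param seed Integer seed.
#' @param v_trial Optional `n x n_acc` matrix of per-trial drift means
#'   overriding `params$v`.
#' @param posdrift Truncate drifts at zero.
#' @return Data frame with `choice` (accumulator index) and `rt` (s).
#' @export
simulate_lba <- function(n, params, seed = NULL, v_trial = NULL,
                         posdrift = TRUE) {
  stopifnot(inherits(params, "lba_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_acc <- length(params$v)
  vmat <- if (is.null(v_trial)) matrix(params$v, n, n_acc, byrow = TRUE)
          else { stopifnot(ncol(v_trial) == n_acc, nrow(v_trial) == n); v_trial }
  times <- matrix(NA_real_, n, n_acc)
  for (a in seq_len(n_acc)) {
    k <- stats::runif(n, 0, params$A)
    sv <- params$sv[a]
    d <- if (sv == 0) vmat[, a] else if (posdrift) {
      u <- stats::runif(n, stats::pnorm(-vmat[, a] / sv), 1)
      vmat[, a] + sv * stats::qnorm(pmin(u, 1 - 1e-16))
    } else vmat[, a] + sv * stats::rnorm(n)
    ti <- (params$b - k) / d
    ti[d <= 0] <- Inf
    times[, a] <- ti
  }
  choice <- max.col(-times, ties.method = "first")
  data.frame(choice = choice,
             rt = params$t0 + times[cbind(seq_len(n), choice)])
}

#' Build the LBA drift-rate design from a trial table
#'
#' Expands each trial into one row per accumulator (looming, receding),
#' derives the latent stimulus-response `match` factor (an accumulator
#' matches when it is the looming accumulator for a flattened stimulus or
#' the receding accumulator for a shaped stimulus), and evaluates the
#' drift formula (e.g.
#' `~ match * direction * cue + vertical * horizontal + eeg`) into a design
#' matrix. The `eeg` term maps to the `eeg_amp` column, z-scored within
#' subject when `standardize_eeg` is `TRUE`.
#'
#' @param trials Data frame with factor columns `direction`
#'   (flattened/shaped), `cue` (native/novel), `vertical` (up/down),
#'   `horizontal` (front/back), optional `eeg_amp`, optional `subject`.
#' @param formula Right-hand-side formula over `match`, `direction`, `cue`,
#'   `vertical`, `horizontal` and `eeg`.
#' @param standardize_eeg Z-score `eeg_amp` within subject before use.
#' @return List of class `lba_design`: `X` (2n x p design matrix, rows
#'   trial-major with accumulator fastest: looming then receding),
#'   `formula`, `acc_names`, `xlevels`, `eeg_sd` (per-subject SDs used for
#'   standardization), `n_trials`.
#' @export
build_design <- function(trials, formula = ~ match * direction * cue +
                           vertical * horizontal + eeg,
                         standardize_eeg = TRUE) {
  acc_names <- c("looming", "receding")
  n <- nrow(trials)
  vars <- all.vars(formula)
  use_eeg <- "eeg" %in% vars
  eeg_sd <- NULL
  eeg <- NULL
  if (use_eeg) {
    if (is.null(trials$eeg_amp))
      stop("formula contains `eeg` but trials have no eeg_amp column")
    eeg <- trials$eeg_amp
    if (standardize_eeg) {
      sub <- if (is.null(trials$subject)) rep(1L, n) else trials$subject
      eeg_sd <- tapply(trials$eeg_amp, sub, stats::sd)
      mu <- stats::ave(trials$eeg_amp, sub, FUN = mean)
      sdv <- stats::ave(trials$eeg_amp, sub, FUN = stats::sd)
      eeg <- (trials$eeg_amp - mu) / ifelse(sdv > 0, sdv, 1)
    }
  }
  long <- data.frame(
    acc = factor(rep(acc_names, n), levels = acc_names),
    direction = rep(factor(trials$direction,
                           levels = c("flattened", "shaped")), each = 2),
    cue = rep(factor(trials$cue, levels = c("native", "novel")), each = 2),
    vertical = rep(factor(trials$vertical, levels = c("up", "down")),
                   each = 2),
    horizontal = rep(factor(trials$horizontal, levels = c("front", "back")),
                     each = 2)
  )
  long$match <- factor(ifelse(
    (long$acc == "looming" & long$direction == "flattened") |
    (long$acc == "receding" & long$direction == "shaped"),
    "match", "mismatch"), levels = c("match", "mismatch"))
  if (use_eeg) long$eeg <- rep(eeg, each = 2)
  keep <- intersect(c("match", "direction", "cue", "vertical", "horizontal",
                      "eeg"), vars)
  mf <- stats::model.frame(formula, long)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  structure(list(X = X, formula = formula, acc_names = acc_names,
                 xlevels = lapply(long[intersect(keep, names(long))],
                                  function(x) if (is.factor(x)) levels(x)),
                 eeg_sd = eeg_sd, n_trials = n,
                 standardize_eeg = standardize_eeg),
            class = "lba_design")
}

#' Log-likelihood of a trial table under an LBA design
#'
#' Sum of log defective densities with per-accumulator drift means
#' `v = X beta` from the design.
#'
#' @param trials Data frame with `choice` ("looming"/"receding" or 1/2) and
#'   `rt` columns matching the design's trial order.
#' @param design An [lba_design()][build_design()].
#' @param pars Named list/vector with `A`, `B`, `t0` and `beta` (drift
#'   coefficients, length `ncol(design$X)`).
#' @param posdrift Truncate drifts at zero.
#' @return Scalar log-likelihood (`-Inf` if any `rt <= t0`); attribute
#'   `n_invalid` counts rt values at or below `t0`.
#' @export
lba_loglik <- function(trials, design, pars, posdrift = TRUE) {
  v <- as.vector(design$X %*% pars$beta)
  loglik_core(trials_rt = trials$rt,
              winner = choice_index(trials$choice),
              v = v, A = pars$A, b = pars$A + pars$B, t0 = pars$t0,
              sv = 1, posdrift = posdrift)
}

choice_index <- function(choice) {
  if (is.numeric(choice)) return(as.integer(choice))
  match(as.character(choice), c("looming", "receding"))
}

# v: length 2n vector (looming, receding per trial); winner in {1,2}
loglik_core <- function(trials_rt, winner, v, A, b, t0, sv = 1,
                        posdrift = TRUE) {
  n <- length(trials_rt)
  t <- trials_rt - t0
  bad <- sum(t <= 0)
  if (bad > 0) {
    out <- -Inf
    attr(out, "n_invalid") <- bad
    return(out)
  }
  tt <- rep(t, each = 2)
  f <- dlba_node_vec(tt, A, b, v, sv, posdrift)
  F <- plba_node_vec(tt, A, b, v, sv, posdrift)
  wrow <- 2 * seq_len(n) - 2 + winner
  lrow <- 2 * seq_len(n) - 2 + (3L - winner)
  # floor guards against underflow of extreme (but valid) samples
  ll <- sum(log(pmax(f[wrow], 1e-300))) +
        sum(log(pmax(1 - F[lrow], 1e-300)))
  attr(ll, "n_invalid") <- 0L
  ll
}

# vectorized over heterogeneous drift means v (same A, b, sv)
dlba_node_vec <- function(t, A, b, v, sv, posdrift = TRUE) {
  denom <- if (posdrift) stats::pnorm(v / sv) else 1
  if (A == 0) return(b / (sv * t^2) * stats::dnorm((b / t - v) / sv) / denom)
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  f <- (-v * stats::pnorm(z1) + sv * stats::dnorm(z1) +
         v * stats::pnorm(z2) - sv * stats::dnorm(z2)) / A
  pmax(f, 0) / denom
}

plba_node_vec <- function(t, A, b, v, sv, posdrift = TRUE) {
  denom <- if (posdrift) stats::pnorm(v / sv) else 1
  if (A == 0) return(stats::pnorm((v - b / t) / sv) / denom)
  z1 <- (b - A - t * v) / (t * sv)
  z2 <- (b - t * v) / (t * sv)
  p <- 1 + (b - A - t * v) / A * stats::pnorm(z1) -
           (b - t * v) / A * stats::pnorm(z2) +
           t * sv / A * (stats::dnorm(z1) - stats::dnorm(z2))
  if (posdrift) p <- p / denom
  pmin(pmax(p, 0), 1)
}

#' Bayes factor approximation from a BIC difference
#'
#' `BF = exp((bic_null - bic_alt) / 2)` with posterior model probability
#' `BF / (1 + BF)` (equal prior odds).
#'
#' @param bic_null,bic_alt BIC of the null (simpler) and alternative model.
#' @return List with `bf` and `posterior_prob` (probability of the
#'   alternative).
#' @export
bf_from_bic <- function(bic_null, bic_alt) {
  stopifnot(is.finite(bic_null), is.finite(bic_alt))
  bf <- exp((bic_null - bic_alt) / 2)
  list(bf = bf, posterior_prob = bf / (1 + bf))
}
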