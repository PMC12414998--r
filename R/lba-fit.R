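# Hierarchical Bayesian estimation of the LBA by adaptive
# Metropolis-within-Gibbs: per-subject random-walk Metropolis blocks over
# the transformed parameter vector (log A, log B, log t0, drift
# coefficients), conjugate Gibbs updates of the group means and variances.

#' Default priors for the hierarchical LBA
#'
#' Normal priors on group means (transformed scale: `log A`, `log B`,
#' `log t0`, raw drift coefficients) and inverse-gamma priors on group
#' variances (weakly informative; prior variance mean around 0.25).
#'
#' @param p Number of drift coefficients.
#' @param mu_mean Prior means for `(log A, log B, log t0)` followed by the
#'   drift coefficients (recycled zeros by default for the coefficients).
#' @param mu_sd Prior SD of every group mean.
#' @param sigma_shape,sigma_rate Inverse-gamma shape/rate for group
#'   variances.
#' @return List of class `lba_priors`.
#' @export
lba_priors <- function(p, mu_mean = NULL, mu_sd = 2,
                       sigma_shape = 3, sigma_rate = 0.5) {
  P <- 3 + p
  if (is.null(mu_mean))
    mu_mean <- c(log(0.5), log(1), log(0.3), 2, rep(0, p - 1))
  stopifnot(length(mu_mean) == P)
  structure(list(mu_mean = mu_mean, mu_sd = rep(mu_sd, length.out = P),
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate, P = P),
            class = "lba_priors")
}

subject_loglik <- function(theta, sub) {
  A <- exp(theta[1]); B <- exp(theta[2]); t0 <- exp(theta[3])
  beta <- theta[-(1:3)]
  v <- as.vector(sub$X %*% beta)
  as.numeric(loglik_core(sub$rt, sub$winner, v, A, A + B, t0))
}

#' Fit the hierarchical LBA by MCMC
#'
#' Subject-level parameters `theta_s = (log A, log B, log t0, beta)` are
#' drawn from `N(mu, diag(sigma^2))`; group means and variances get
#' conjugate Gibbs updates; subject blocks are updated by adaptive
#' random-walk Metropolis (step size tuned toward ~25% acceptance during
#' burn-in). A Gelman-Rubin convergence report over the group-level chains
#' is attached and a warning is raised if any split-Rhat exceeds 1.1.
#'
#' @param trials Data frame with columns `subject`, `choice`, `rt` plus the
#'   factor columns required by `formula` (see [build_design()]).
#' @param formula Drift-rate formula.
#' @param priors An [lba_priors()] (defaults constructed from the design).
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Kept iterations per chain.
#' @param n_burn Burn-in iterations per chain (adaptation happens here).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param standardize_eeg Passed to [build_design()].
#' @param prior_only Ignore the data likelihood (samples the prior
#'   predictive of the hierarchy; used to check prior contraction).
#' @param verbose Print progress.
#' @return Object of class `lba_posterior` with elements `mu`
#'   (iter x chain x P array of group means), `sigma` (group SDs, same
#'   shape), `subject` (iter x chain x S x P subject draws), `loglik`
#'   (iter x chain total data log-likelihood), `param_names`, `design`,
#'   `subjects`, `rhat`, `acceptance`, `priors`.
#' @export
fit_lba_hier <- function(trials, formula = ~ match * direction * cue +
                           vertical * horizontal + eeg,
                         priors = NULL, n_chains = 3, n_iter = 500,
                         n_burn = 300, seed = 1L, standardize_eeg = TRUE,
                         prior_only = FALSE, verbose = FALSE) {
  stopifnot(n_chains >= 2, !is.null(trials$subject))
  subjects <- unique(trials$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  design <- build_design(trials, formula, standardize_eeg = standardize_eeg)
  p <- ncol(design$X)
  P <- 3 + p
  if (is.null(priors)) priors <- lba_priors(p)
  stopifnot(priors$P == P)
  param_names <- c("logA", "logB", "logt0", colnames(design$X))

  # per-subject data blocks (design rows 2i-1, 2i belong to trial i)
  subs <- lapply(subjects, function(s) {
    idx <- which(trials$subject == s)
    rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
    list(X = design$X[rows, , drop = FALSE],
         rt = trials$rt[idx],
         winner = choice_index(trials$choice[idx]))
  })
  S <- length(subs)
  sll <- if (prior_only) function(theta, sub) 0
         else subject_loglik

  run_chain <- function(chain) {
    set.seed(seed + chain)
    mu <- priors$mu_mean
    sig2 <- rep(0.1, P)
    theta <- matrix(rep(mu, each = S), S, P, byrow = FALSE) +
      matrix(stats::rnorm(S * P, 0, 0.05), S, P)
    ll_s <- vapply(seq_len(S), function(s) sll(theta[s, ], subs[[s]]),
                   0)
    # fall back to prior means if a random start is degenerate
    for (s in which(!is.finite(ll_s))) {
      theta[s, ] <- mu
      ll_s[s] <- sll(mu, subs[[s]])
    }
    step <- rep(0.08, S)
    acc <- integer(S)
    tries <- integer(S)
    keep_mu <- matrix(NA_real_, n_iter, P)
    keep_sig <- matrix(NA_real_, n_iter, P)
    keep_theta <- array(NA_real_, c(n_iter, S, P))
    keep_ll <- numeric(n_iter)
    total <- n_burn + n_iter
    for (it in seq_len(total)) {
      # subject blocks: joint random-walk Metropolis (exact Gibbs draw from
      # the hierarchy when there is no data likelihood)
      if (prior_only) {
        # the posterior equals the prior: draw it ancestrally (i.i.d.)
        mu <- stats::rnorm(P, priors$mu_mean, priors$mu_sd)
        sig2 <- 1 / stats::rgamma(P, priors$sigma_shape, priors$sigma_rate)
        theta <- matrix(stats::rnorm(S * P, rep(mu, each = S),
                                     rep(sqrt(sig2), each = S)), S, P)
        ll_s[] <- 0
        acc <- acc + 1L; tries <- tries + 1L
      } else for (s in seq_len(S)) {
        prop <- theta[s, ] + stats::rnorm(P, 0, step[s] * sqrt(sig2 + 0.01))
        ll_p <- sll(prop, subs[[s]])
        lp_old <- sum(stats::dnorm(theta[s, ], mu, sqrt(sig2), log = TRUE))
        lp_new <- sum(stats::dnorm(prop, mu, sqrt(sig2), log = TRUE))
        if (is.finite(ll_p) &&
            log(stats::runif(1)) < (ll_p + lp_new) - (ll_s[s] + lp_old)) {
          theta[s, ] <- prop
          ll_s[s] <- ll_p
          acc[s] <- acc[s] + 1L
        }
        tries[s] <- tries[s] + 1L
      }
      # adapt proposal scale during burn-in
      if (it <= n_burn && it %% 25 == 0) {
        rate <- acc / pmax(tries, 1)
        step <- step * exp(0.6 * (rate - 0.25))
        acc[] <- 0L; tries[] <- 0L
      }
      # group means: conjugate normal update
      prec <- S / sig2 + 1 / priors$mu_sd^2
      mean_post <- (colSums(theta) / sig2 + priors$mu_mean / priors$mu_sd^2) /
        prec
      mu <- stats::rnorm(P, mean_post, sqrt(1 / prec))
      # group variances: conjugate inverse-gamma update
      ssq <- colSums((theta - matrix(mu, S, P, byrow = TRUE))^2)
      sig2 <- 1 / stats::rgamma(P, priors$sigma_shape + S / 2,
                                priors$sigma_rate + ssq / 2)
      if (it > n_burn) {
        k <- it - n_burn
        keep_mu[k, ] <- mu
        keep_sig[k, ] <- sqrt(sig2)
        keep_theta[k, , ] <- theta
        keep_ll[k] <- sum(ll_s)
      }
    }
    if (verbose) message("chain ", chain, " done")
    list(mu = keep_mu, sigma = keep_sig, theta = keep_theta, ll = keep_ll,
         acc_rate = mean(acc / pmax(tries, 1)))
  }

  chains <- lapply(seq_len(n_chains), run_chain)
  mu <- array(NA_real_, c(n_iter, n_chains, P),
              dimnames = list(NULL, NULL, param_names))
  sigma <- mu
  subj <- array(NA_real_, c(n_iter, n_chains, S, P))
  ll <- matrix(NA_real_, n_iter, n_chains)
  for (c in seq_len(n_chains)) {
    mu[, c, ] <- chains[[c]]$mu
    sigma[, c, ] <- chains[[c]]$sigma
    subj[, c, , ] <- chains[[c]]$theta
    ll[, c] <- chains[[c]]$ll
  }
  post <- structure(list(mu = mu, sigma = sigma, subject = subj, loglik = ll,
                         param_names = param_names, design = design,
                         subjects = subjects, priors = priors,
                         subs_data = subs,
                         acceptance = vapply(chains, `[[`, 0, "acc_rate")),
                    class = "lba_posterior")
  post$rhat <- gelman_rubin(post)
  if (any(post$rhat > 1.1, na.rm = TRUE))
    warning("chains may not have converged: max split-Rhat = ",
            round(max(post$rhat, na.rm = TRUE), 3))
  post
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' factor is computed over the split chains. Constant chains return 1.
#'
#' @param x An `lba_posterior` (monitors the group means and SDs) or a
#'   3-D array `(iteration, chain, parameter)`.
#' @return Named vector of split-Rhat values (>= 1 up to Monte-Carlo noise).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "lba_posterior")) {
    arr <- array(c(x$mu, x$sigma), c(dim(x$mu)[1], dim(x$mu)[2],
                                     2 * dim(x$mu)[3]))
    dimnames(arr) <- list(NULL, NULL,
                          c(paste0("mu_", x$param_names),
                            paste0("sigma_", x$param_names)))
    x <- arr
  }
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[2] < 2L) stop("need at least 2 chains")
  n <- dim(x)[1]
  if (n < 10L) stop("need at least 10 samples per chain")
  half <- floor(n / 2)
  apply(x, 3, function(ch) {
    splits <- cbind(ch[seq_len(half), , drop = FALSE],
                    ch[(n - half + 1):n, , drop = FALSE])
    m <- ncol(splits)
    means <- colMeans(splits)
    vars <- apply(splits, 2, stats::var)
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  })
}

#' Bayesian Predictive Information Criterion
#'
#' `BPIC = Dbar + 2 * pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(theta_bar)` the effective number of parameters
#' (deviance evaluated at the posterior mean of the subject-level
#' parameters). Lower is better.
#'
#' @param posterior An `lba_posterior`.
#' @return List with `bpic`, `dbar`, `dhat`, `pd`.
#' @export
bpic <- function(posterior) {
  stopifnot(inherits(posterior, "lba_posterior"))
  if (is.null(posterior$loglik)) stop("posterior carries no log-likelihoods")
  dbar <- mean(-2 * posterior$loglik)
  theta_bar <- apply(posterior$subject, c(3, 4), mean)  # S x P
  ll_hat <- sum(vapply(seq_len(nrow(theta_bar)), function(s)
    subject_loglik(theta_bar[s, ], posterior$subs_data[[s]]), 0))
  dhat <- -2 * ll_hat
  pd <- dbar - dhat
  list(bpic = dbar + 2 * pd, dbar = dbar, dhat = dhat, pd = pd)
}

cell_row <- function(design, cell) {
  vars <- setdiff(all.vars(design$formula), "eeg")
  row <- list()
  for (v in vars) {
    levs <- design$xlevels[[v]]
    if (is.null(cell[[v]]))
      stop("cell does not specify factor `", v, "`")
    if (!cell[[v]] %in% levs)
      stop("unknown level '", cell[[v]], "' for factor `", v, "` (levels: ",
           paste(levs, collapse = ", "), ")")
    row[[v]] <- factor(cell[[v]], levels = levs)
  }
  if ("eeg" %in% all.vars(design$formula))
    row$eeg <- if (is.null(cell$eeg)) 0 else cell$eeg
  stats::model.matrix(design$formula, as.data.frame(row))
}

#' Posterior drift-rate contrast between two design cells
#'
#' For each posterior sample of the group-level coefficient means, computes
#' the drift rate implied by each cell and their difference
#' `Delta = v(cellA) - v(cellB)`; reports the posterior mean, the
#' equal-tailed 95% credible interval and the one-sided posterior
#' probabilities `P(Delta > 0)` / `P(Delta < 0)`.
#'
#' @param posterior An `lba_posterior`.
#' @param cellA,cellB Named lists of factor levels (plus optional numeric
#'   `eeg`, default 0 = at the mean of the standardized regressor), e.g.
#'   `list(match = "match", direction = "flattened", cue = "native",
#'   vertical = "up", horizontal = "front")`.
#' @param level Credible-interval level.
#' @return List of class `contrast_report`: `delta` (posterior mean), `ci`,
#'   `p_positive`, `p_negative`, `samples`.
#' @export
contrast_delta <- function(posterior, cellA, cellB, level = 0.95) {
  stopifnot(inherits(posterior, "lba_posterior"))
  xa <- cell_row(posterior$design, cellA)
  xb <- cell_row(posterior$design, cellB)
  beta_idx <- 3 + seq_len(ncol(posterior$design$X))
  mu_beta <- matrix(posterior$mu[, , beta_idx],
                    ncol = length(beta_idx))
  d <- as.vector(mu_beta %*% t(xa - xb))
  a <- (1 - level) / 2
  structure(list(delta = mean(d),
                 ci = stats::quantile(d, c(a, 1 - a), names = FALSE),
                 p_positive = mean(d > 0),
                 p_negative = mean(d < 0),
                 level = level, samples = d),
            class = "contrast_report")
}

#' Posterior of the EEG-amplitude drift slope
#'
#' Extracts the group-level posterior of the `eeg` coefficient, on the
#' standardized scale used for fitting and rescaled back to raw
#' 1/(microvolt second) units via the mean within-subject amplitude SD.
#'
#' @param posterior An `lba_posterior` fitted with an `eeg` term.
#' @return List with `std` and `raw` sample vectors, posterior means and
#'   `p_negative`.
#' @export
eeg_slope <- function(posterior) {
  j <- grep("^eeg$", posterior$param_names)
  if (!length(j)) stop("posterior has no eeg coefficient")
  s <- as.vector(posterior$mu[, , j])
  scale <- if (!is.null(posterior$design$eeg_sd))
    mean(posterior$design$eeg_sd) else 1
  list(std = s, raw = s / scale,
       mean_std = mean(s), mean_raw = mean(s) / scale,
       p_negative = mean(s < 0))
}

#' Prior-to-posterior contraction statistic
#'
#' One minus the ratio of posterior to prior variance per group-level mean;
#' near 0 means the data barely updated the prior, near 1 strong updating.
#'
#' @param posterior An `lba_posterior`.
#' @return Named vector of contraction values.
#' @export
contraction <- function(posterior) {
  pr_var <- posterior$priors$mu_sd^2
  po_var <- apply(posterior$mu, 3, function(ch) stats::var(as.vector(ch)))
  stats::setNames(1 - po_var / pr_var,
                  paste0("mu_", posterior$param_names))
}
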