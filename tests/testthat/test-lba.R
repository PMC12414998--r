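test_that("node density integrates to 1 and CDF matches a Monte-Carlo oracle", {
  q <- stats::integrate(function(t) dlba_node(t, A = 0.5, b = 1.5, v = 2),
                        0, Inf)
  expect_lt(abs(q$value - 1), 1e-6)
  # MC oracle: direct simulation of one accumulator, independent of the
  # closed form
  sim_node <- function(n, A, b, v, sv, seed) {
    set.seed(seed)
    k <- stats::runif(n, 0, A)
    u <- stats::runif(n, stats::pnorm(-v / sv), 1)
    d <- v + sv * stats::qnorm(u)
    (b - k) / d
  }
  tt <- seq(0.01, 8, by = 0.005)
  for (pars in list(c(0.3, 1, 1.5), c(0.5, 1.5, 2.5), c(0.8, 2, 1))) {
    T <- sim_node(5e4, pars[1], pars[2], pars[3], 1, seed = 13)
    ks <- max(abs(stats::ecdf(T)(tt) -
                  plba_node(tt, pars[1], pars[2], pars[3], 1)))
    expect_lt(ks, 0.015)
  }
  # CDF monotone with limits 0 / 1
  p <- plba_node(tt, 0.5, 1.5, 2, 1)
  expect_true(all(diff(p) >= -1e-12))
  expect_equal(plba_node(1e6, 0.5, 1.5, 2, 1), 1, tolerance = 1e-6)
  expect_equal(plba_node(-1, 0.5, 1.5, 2, 1), 0)
  expect_error(dlba_node(1, A = -1, b = 1, v = 1), "A must")
})

test_that("deterministic limit gives passage time exactly b/v", {
  expect_equal(plba_node(0.499, 0, 1, 2, sv = 0), 0)
  expect_equal(plba_node(0.501, 0, 1, 2, sv = 0), 1)
  sim <- simulate_lba(5, lba_params(0, 1, 0.2, c(2, 1), sv = 0), seed = 1)
  expect_true(all(sim$rt == 0.7))
  expect_true(all(sim$choice == 1))
})

test_that("defective densities normalize and match simulated proportions", {
  p <- lba_params(A = 0.5, B = 1, t0 = 0.2, v = c(2, 1.2))
  # quadrature over both choices
  tot <- stats::integrate(function(t) defective_density(t, 1, p), p$t0, Inf,
                          rel.tol = 1e-9)$value +
         stats::integrate(function(t) defective_density(t, 2, p), p$t0, Inf,
                          rel.tol = 1e-9)$value
  expect_lt(abs(tot - 1), 1e-4)
  # symmetric accumulators: 0.5/0.5
  ps <- lba_params(0.5, 1, 0, c(1.5, 1.5))
  half <- stats::integrate(function(t) defective_density(t, 1, ps), 0, Inf,
                           rel.tol = 1e-9)$value
  expect_lt(abs(half - 0.5), 1e-4)
  # MC cross-check of P(choice 1)
  p1 <- stats::integrate(function(t) defective_density(t, 1, p), p$t0, Inf,
                         rel.tol = 1e-9)$value
  sim <- simulate_lba(2e5, p, seed = 21)
  expect_lt(abs(mean(sim$choice == 1) - p1), 0.005)
  # rt <= t0 contract
  expect_equal(defective_density(0.1, 1, p), 0)
  expect_equal(defective_density(0.1, 1, p, log = TRUE), -Inf)
})

test_that("simulation is deterministic and faster with higher drift", {
  p <- lba_params(0.5, 1, 0.2, c(1, 1))
  expect_identical(simulate_lba(100, p, seed = 5),
                   simulate_lba(100, p, seed = 5))
  s1 <- simulate_lba(1e4, lba_params(0.5, 1, 0.2, c(1, 1)), seed = 6)
  s3 <- simulate_lba(1e4, lba_params(0.5, 1, 0.2, c(3, 3)), seed = 6)
  expect_gt(mean(s1$rt), mean(s3$rt))
})

test_that("the drift design expands the factorial formula correctly", {
  cfg <- small_config()
  beh <- gen_behavior(gen_subject_params(cfg, seed = 2), cfg, seed = 2)
  full <- build_design(beh, ~ match * direction * cue +
                         vertical * horizontal + eeg)
  # 8 factorial columns (incl. intercept) + 3 extra for vertical*horizontal
  # + 1 eeg = 12
  expect_equal(ncol(full$X), 12)
  expect_equal(nrow(full$X), 2 * nrow(beh))
  # intercept-only: one shared drift
  i0 <- build_design(beh, ~ 1)
  expect_equal(ncol(i0$X), 1)
  # eeg slope zero reproduces the no-eeg likelihood exactly
  d_eeg <- build_design(beh, ~ match + eeg)
  d_no <- build_design(beh, ~ match)
  pars_no <- list(A = 0.5, B = 1, t0 = 0.1, beta = c(2, -0.4))
  pars_eeg <- list(A = 0.5, B = 1, t0 = 0.1, beta = c(2, -0.4, 0))
  expect_equal(lba_loglik(beh, d_eeg, pars_eeg),
               lba_loglik(beh, d_no, pars_no))
  # rank deficiency is reported with the aliased term
  beh2 <- beh; beh2$cue <- "native"
  expect_error(build_design(beh2, ~ cue), "rank deficient")
})

test_that("log-likelihood is additive and equals summed defective densities", {
  cfg <- small_config()
  beh <- gen_behavior(gen_subject_params(cfg, seed = 7), cfg, seed = 7)
  ten <- beh[1:10, ]
  des <- build_design(ten, ~ match)
  pars <- list(A = 0.4, B = 1.1, t0 = 0.1, beta = c(2.2, -0.5))
  ll <- lba_loglik(ten, des, pars)
  # direct evaluation through defective_density per trial
  by_hand <- sum(vapply(1:10, function(i) {
    v <- as.vector(des$X[c(2 * i - 1, 2 * i), ] %*% pars$beta)
    pp <- lba_params(pars$A, pars$B, pars$t0, v)
    ch <- if (ten$choice[i] == "looming") 1 else 2
    defective_density(ten$rt[i], ch, pp, log = TRUE)
  }, 0))
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-10)
  # duplication scales the log-likelihood
  dup <- ten[rep(1:10, 3), ]
  des3 <- build_design(dup, ~ match)
  expect_equal(as.numeric(lba_loglik(dup, des3, pars)), 3 * by_hand,
               tolerance = 1e-9)
  # raising the threshold penalizes fast responses
  fast <- ten; fast$rt <- pmin(fast$rt, 0.45)
  pars_hi <- pars; pars_hi$B <- 3
  expect_lt(lba_loglik(fast, des, pars_hi), lba_loglik(fast, des, pars))
})

test_that("Gelman-Rubin flags divergent chains and passes mixed ones", {
  set.seed(8)
  iid <- array(rnorm(1000 * 3), c(1000, 3, 2))
  expect_true(all(gelman_rubin(iid) < 1.05))
  split <- iid
  split[, 2, ] <- split[, 2, ] + 10
  expect_true(all(gelman_rubin(split) > 2))
  expect_equal(unname(gelman_rubin(array(5, c(100, 2, 1)))), 1)
  expect_error(gelman_rubin(array(0, c(100, 1, 1))), "2 chains")
})

test_that("BF-from-BIC follows the closed form", {
  expect_equal(bf_from_bic(100, 100)$bf, 1)
  expect_equal(bf_from_bic(100, 100)$posterior_prob, 0.5)
  r <- bf_from_bic(102, 100)
  expect_equal(r$bf, exp(1))
  expect_equal(r$posterior_prob, exp(1) / (1 + exp(1)))
  expect_equal(bf_from_bic(7, 3)$bf, 1 / bf_from_bic(3, 7)$bf)
})

test_that("a short hierarchical fit recovers structure on small data", {
  cfg <- small_config()
  beh <- gen_behavior(gen_subject_params(cfg, seed = 31), cfg, seed = 31)
  fit <- suppressWarnings(
    fit_lba_hier(beh, ~ match, n_chains = 2, n_iter = 150, n_burn = 150,
                 seed = 3))
  # determinism under identical seeds
  fit2 <- suppressWarnings(
    fit_lba_hier(beh, ~ match, n_chains = 2, n_iter = 150, n_burn = 150,
                 seed = 3))
  expect_identical(fit$mu, fit2$mu)
  # self-contrast is exactly zero
  cd0 <- contrast_delta(fit, list(match = "match"), list(match = "match"))
  expect_equal(cd0$delta, 0)
  expect_equal(cd0$p_positive, 0)
  expect_equal(cd0$p_negative, 0)
  # match-mismatch contrast has the generating sign
  cd <- contrast_delta(fit, list(match = "match"), list(match = "mismatch"))
  expect_gt(cd$p_positive, 0.5)
  expect_true(cd$ci[1] < cd$delta && cd$delta < cd$ci[2])
  expect_error(contrast_delta(fit, list(match = "nope"),
                              list(match = "match")), "unknown level")
  # BPIC invariance to sample order
  b1 <- bpic(fit)
  fitr <- fit
  ord <- rev(seq_len(dim(fit$mu)[1]))
  fitr$loglik <- fit$loglik[ord, ]
  fitr$subject <- fit$subject[ord, , , , drop = FALSE]
  expect_equal(bpic(fitr)$bpic, b1$bpic, tolerance = 1e-10)
  # degenerate posterior: pD = 0, BPIC = D(theta_bar)
  fitd <- fit
  for (k in seq_len(dim(fit$mu)[1])) for (cc in 1:2) {
    fitd$subject[k, cc, , ] <- fit$subject[1, 1, , ]
    fitd$loglik[k, cc] <- fit$loglik[1, 1]
  }
  bd <- bpic(fitd)
  expect_lt(abs(bd$pd), 1e-8)
  expect_equal(bd$bpic, bd$dhat, tolerance = 1e-8)
})

test_that("prior-only fits leave the group means at their priors", {
  cfg <- small_config(n_subjects = 4)
  beh <- gen_behavior(gen_subject_params(cfg, seed = 41), cfg, seed = 41)
  pfit <- suppressWarnings(
    fit_lba_hier(beh, ~ match, n_chains = 2, n_iter = 200, n_burn = 100,
                 seed = 6, prior_only = TRUE))
  con <- contraction(pfit)
  # contraction should be small without data (hierarchy adds some shrinkage)
  expect_lt(stats::median(con), 0.5)
  dfit <- suppressWarnings(
    fit_lba_hier(beh, ~ match, n_chains = 2, n_iter = 200, n_burn = 100,
                 seed = 6))
  expect_gt(stats::median(contraction(dfit)), stats::median(con))
})
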