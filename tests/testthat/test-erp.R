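test_that("baseline correction zeroes the baseline and ignores DC offsets", {
  cfg <- small_config()
  ep <- gen_erp_epochs(cfg, seed = 3)
  bc <- baseline_correct(ep)
  sel <- bc$times >= -0.1 & bc$times <= 0
  a <- bc$data[[1]][[1]]
  expect_lt(max(abs(apply(a[, sel, , drop = FALSE], c(1, 3), mean))), 1e-12)
  # DC invariance
  ep2 <- ep
  ep2$data[[1]][[1]] <- ep2$data[[1]][[1]] + 7.3
  bc2 <- baseline_correct(ep2)
  expect_equal(bc2$data[[1]][[1]], bc$data[[1]][[1]], tolerance = 1e-12)
  # constant trials become exactly zero
  cst <- ep
  cst$data <- lapply(cst$data, function(s) lapply(s, function(a) a * 0 + 2))
  expect_equal(max(abs(baseline_correct(cst)$data[[1]][[1]])), 0)
  expect_error(baseline_correct(ep, c(-9, -8)), "no time samples")
})

test_that("trial equalization retains min(counts) at evenly spaced positions", {
  expect_equal(equalize_trials(c(a = 50, b = 50))$a, 1:50)
  e <- equalize_trials(c(a = 50, b = 48))
  expect_length(e$a, 48)
  expect_equal(setdiff(1:50, e$a), c(25, 50))
  expect_equal(equalize_trials(c(a = 10, b = 5))$a, c(1, 3, 5, 7, 9))
  # exhaustive: all pairs up to 20 give exactly equal counts
  for (n1 in 1:20) for (n2 in 1:20) {
    e <- equalize_trials(c(n1, n2))
    expect_equal(lengths(e), c(min(n1, n2), min(n1, n2)),
                 ignore_attr = TRUE)
    expect_true(all(e[[1]] %in% seq_len(n1)) && !anyDuplicated(e[[1]]))
  }
})

test_that("distance adjacency is symmetric, irreflexive and tunable", {
  # three collinear equidistant channels: chain under d < threshold < 2d
  lay <- channel_layout(c("a", "b", "c"),
                        cbind(c(0, 1, 2), 0, 0))
  adj <- neighbors_from_distance(lay, threshold = 1.5)
  expect_equal(unname(adj[[1]]), 2L)
  expect_equal(unname(adj[[2]]), c(1L, 3L))
  expect_equal(unname(adj[[3]]), 2L)
  # below minimal distance: empty
  none <- neighbors_from_distance(lay, threshold = 0.5)
  expect_equal(lengths(unclass(none)), c(0L, 0L, 0L), ignore_attr = TRUE)
  # symmetry + zero diagonal on a real layout
  cap <- test_layout(24)
  a2 <- neighbors_from_distance(cap, target_degree = 7)
  for (i in seq_along(a2)) {
    expect_false(i %in% a2[[i]])
    for (j in a2[[i]]) expect_true(i %in% a2[[j]])
  }
  expect_lt(abs(attr(a2, "mean_degree") - 7), 2)
})

test_that("identical conditions yield no clusters", {
  set.seed(1)
  x <- array(rnorm(8 * 16 * 30), c(8, 16, 30))
  adj <- neighbors_from_distance(test_layout(16), target_degree = 5)
  r <- cluster_permutation(x, x, adj, times = seq(0, 0.29, by = 0.01),
                           n_perm = 200, seed = 2)
  expect_length(r$clusters, 0)
})

test_that("single-location cluster test reduces to a sign-flip paired t test", {
  set.seed(2)
  d <- rnorm(12, 0.45, 1)
  condA <- array(d + 1, c(12, 1, 1))
  condB <- array(1, c(12, 1, 1))
  adj <- structure(list(integer(0)), class = "channel_adjacency")
  r <- cluster_permutation(condA, condB, adj, times = 0, window = c(-1, 1),
                           n_perm = 10000, seed = 3,
                           cluster_threshold = 1e-9)
  # independent oracle: exhaustive-ish sign-flip permutation p
  tstat <- function(x) mean(x) / stats::sd(x) * sqrt(length(x))
  tobs <- tstat(d)
  set.seed(77)
  tperm <- replicate(10000, tstat(sample(c(-1, 1), 12, TRUE) * d))
  p_oracle <- 2 * (sum(tperm >= tobs) + 1) / 10001
  expect_length(r$clusters, 1)
  expect_lt(abs(r$clusters[[1]]$p - p_oracle), 0.02)
})

test_that("an injected spatiotemporal effect is detected and scored", {
  lay <- test_layout(16)
  adj <- neighbors_from_distance(lay, target_degree = 5)
  D <- as.matrix(dist(lay$positions))
  effch <- order(D[1, ])[1:4]
  times <- seq(-0.1, 0.49, by = 0.01)
  win <- times >= 0.1 & times <= 0.2
  set.seed(9)
  nsub <- 14
  condA <- array(rnorm(nsub * 16 * 60, 0, 0.5), c(nsub, 16, 60))
  condB <- array(rnorm(nsub * 16 * 60, 0, 0.5), c(nsub, 16, 60))
  condA[, effch, win] <- condA[, effch, win] - 1.2   # negative deflection
  r <- cluster_permutation(condA, condB, adj, times, window = c(0, 0.3),
                           n_perm = 1000, seed = 5)
  expect_gte(length(r$clusters), 1)
  top <- r$clusters[[1]]
  expect_equal(top$polarity, "negative")
  expect_lt(top$p, 0.05)
  expect_true(all(effch %in% top$channels))
  expect_true(top$time_range[1] >= 0.05 && top$time_range[2] <= 0.3)
  # permutation p invariant to consistent channel relabelling
  perm <- c(16:1)
  r2 <- cluster_permutation(condA[, perm, ], condB[, perm, ],
                            structure(lapply(unclass(adj)[perm],
                                             function(v) match(v, perm)),
                                      class = "channel_adjacency"),
                            times, window = c(0, 0.3), n_perm = 1000,
                            seed = 5)
  expect_equal(r2$clusters[[1]]$p, top$p)
  expect_equal(r2$clusters[[1]]$mass, top$mass, tolerance = 1e-10)
})

test_that("cluster scores average the rectangular cluster window", {
  cfg <- small_config()
  ep <- gen_erp_epochs(cfg, seed = 4)
  # constant epochs: score equals the constant
  cst <- ep
  cst$data <- lapply(cst$data, function(s) lapply(s, function(a) a * 0 + 1))
  cl <- list(time_range = c(0.05, 0.15), channels = c(1L, 3L))
  sc <- cluster_score(cst, cl)
  expect_true(all(sc$score == 1))
  # two-channel mix of 0 and 2 gives 1
  mix <- ep
  mix$data <- lapply(mix$data, function(s) lapply(s, function(a) {
    a <- a * 0; a[3, , ] <- 2; a
  }))
  expect_true(all(cluster_score(mix, cl)$score == 1))
  # linearity: mean of per-trial scores equals score of the mean epoch
  a <- ep$data[[1]][[1]]
  tsel <- ep$times >= 0.05 & ep$times <= 0.15
  expect_equal(mean(cluster_score(ep, cl)$score[
    cluster_score(ep, cl)$subject == names(ep$data)[1] &
    cluster_score(ep, cl)$condition == names(ep$data[[1]])[1]]),
    mean(apply(a, c(1, 2), mean)[cl$channels, tsel]))
  expect_error(cluster_score(ep, list(time_range = c(0, 1),
                                      channels = integer(0))), "channels")
})
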