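#' EEG channel layout
#'
#' @param names Character vector of unique channel names.
#' @param positions Numeric matrix `n x 3` of channel positions (consistent
#'   length units, e.g. metres).
#' @return Object of class `channel_layout`.
#' @export
channel_layout <- function(names, positions) {
  positions <- as.matrix(positions)
  stopifnot(length(names) == nrow(positions), ncol(positions) == 3L,
            !anyDuplicated(names), all(is.finite(positions)))
  structure(list(names = as.character(names), positions = positions),
            class = "channel_layout")
}

#' Read a channel layout from plain text (name x y z)
#'
#' @param path Whitespace-delimited file with columns name, x, y, z.
#' @return [channel_layout()].
#' @export
read_channel_layout <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("name", "x", "y", "z"))
  channel_layout(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}

#' Epoched multichannel EEG container
#'
#' A nested list of epochs: `data[[subject]][[condition]]` is a numeric
#' array `(channel, time, trial)` in microvolts, with a shared time axis
#' (seconds relative to the transition) and a shared [channel_layout()].
#'
#' @param data Nested list as described.
#' @param times Numeric time axis in seconds.
#' @param layout A [channel_layout()].
#' @return Object of class `erp_epochs`.
#' @export
erp_epochs <- function(data, times, layout) {
  stopifnot(inherits(layout, "channel_layout"))
  a1 <- data[[1]][[1]]
  stopifnot(length(dim(a1)) == 3L,
            dim(a1)[1] == length(layout$names),
            dim(a1)[2] == length(times))
  structure(list(data = data, times = times, layout = layout),
            class = "erp_epochs")
}

#' Per-trial baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default the 100 ms before the event).
#'
#' @param epochs An [erp_epochs()] object.
#' @param window Length-2 baseline window in seconds.
#' @return Baseline-corrected [erp_epochs()].
#' @export
baseline_correct <- function(epochs, window = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "erp_epochs"))
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window contains no time samples")
  epochs$data <- lapply(epochs$data, function(subj)
    lapply(subj, function(a) {
      bl <- apply(a[, sel, , drop = FALSE], c(1, 3), mean)  # ch x trial
      sweep(a, c(1, 3), bl, "-")
    }))
  epochs
}

#' Blind trial-count equalization across conditions
#'
#' Finds the minimum trial count over conditions and removes surplus trials
#' from the others at session positions as evenly spaced as possible:
#' removing `r` of `n` trials drops session positions `ceiling(k * n / r)`,
#' `k = 1..r`. Deterministic and blind to the data.
#'
#' @param counts Named integer vector of per-condition trial counts.
#' @return Named list of retained session-position indices per condition
#'   (each of length `min(counts)`).
#' @export
equalize_trials <- function(counts) {
  stopifnot(all(counts >= 1))
  m <- min(counts)
  out <- lapply(counts, function(n) {
    r <- n - m
    if (r == 0) return(seq_len(n))
    drop <- ceiling(seq_len(r) * n / r)
    setdiff(seq_len(n), drop)
  })
  names(out) <- names(counts)
  out
}

#' Distance-threshold channel adjacency
#'
#' Channels are neighbours iff their Euclidean distance is below
#' `threshold`; the result is symmetric with an empty diagonal.
#'
#' @param layout A [channel_layout()].
#' @param threshold Positive distance threshold (same units as positions),
#'   or `NULL` to auto-select the threshold yielding a mean neighbour count
#'   closest to `target_degree`.
#' @param target_degree Desired mean number of neighbours for auto
#'   selection.
#' @return List of class `channel_adjacency`: per-channel integer vectors
#'   of neighbour indices; attributes `threshold` and `mean_degree`.
#' @export
neighbors_from_distance <- function(layout, threshold = NULL,
                                    target_degree = 7) {
  stopifnot(inherits(layout, "channel_layout"))
  D <- as.matrix(stats::dist(layout$positions))
  if (is.null(threshold)) {
    cand <- sort(unique(D[upper.tri(D)]))
    deg <- vapply(cand, function(th) mean(colSums(D < th) - 1), 0)
    threshold <- cand[which.min(abs(deg - target_degree))]
  }
  if (threshold <= 0) stop("threshold must be positive")
  adj <- lapply(seq_len(nrow(D)), function(i)
    unname(which(D[i, ] < threshold & seq_len(ncol(D)) != i)))
  structure(adj, class = "channel_adjacency", threshold = threshold,
            mean_degree = mean(lengths(adj)))
}

#' Spatiotemporal cluster-based permutation test for paired ERP contrasts
#'
#' Computes a paired (dependent-samples) t statistic per (channel, time)
#' sample inside the analysis window, groups suprathreshold samples of equal
#' sign into spatiotemporally connected clusters (neighbouring channels at
#' the same sample, adjacent time samples at the same channel), scores each
#' cluster by its summed t (cluster mass), and tests the masses against a
#' Monte-Carlo null of the maximal same-sign cluster mass under random
#' within-participant condition swaps (sign flips of the paired
#' differences); each tail is tested against its own null. One-sided
#' Monte-Carlo p values use `(b + 1) / (n_perm + 1)` and are doubled
#' (capped at 1) to correct for two-tailed testing.
#'
#' @param condA,condB Arrays `(participant, channel, time)` of
#'   per-participant condition averages (microvolts); paired by the first
#'   dimension.
#' @param adjacency A `channel_adjacency` from [neighbors_from_distance()].
#' @param times Time axis in seconds matching dim 3.
#' @param window Length-2 analysis window in seconds (default 0 to 0.3).
#' @param n_perm Number of random permutations.
#' @param alpha Sample-level alpha defining the cluster-forming t threshold
#'   (two-tailed critical value at participant df).
#' @param seed Integer seed for the permutation draws.
#' @param cluster_threshold Optional explicit cluster-forming |t| threshold
#'   overriding `alpha`.
#' @return List of class `cluster_test`: `clusters` (list with `mass`,
#'   `p`, `polarity`, `time_range`, `channels`, `members`), `threshold`,
#'   `null_max_mass`, `window`, `times` (window time axis).
#' @export
cluster_permutation <- function(condA, condB, adjacency, times,
                                window = c(0, 0.3), n_perm = 1000,
                                alpha = 0.05, seed = 1L,
                                cluster_threshold = NULL) {
  stopifnot(length(dim(condA)) == 3L, identical(dim(condA), dim(condB)))
  nsub <- dim(condA)[1]
  if (nsub < 2L) stop("need at least 2 participants for a paired test")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) stop("analysis window contains no time samples")
  d <- condA[, , sel, drop = FALSE] - condB[, , sel, drop = FALSE]
  nch <- dim(d)[2]; ntime <- dim(d)[3]
  thr <- if (is.null(cluster_threshold))
    stats::qt(1 - alpha / 2, df = nsub - 1) else cluster_threshold

  # observed t map
  dm <- apply(d, c(2, 3), mean)
  dsd <- apply(d, c(2, 3), stats::sd)
  tmat <- ifelse(dsd > 0, dm / dsd * sqrt(nsub), 0)
  found <- find_clusters_cpp(tmat, thr, unclass(adjacency))

  # permutation null: random sign flips of the participant differences
  set.seed(seed)
  flips <- matrix(sample(c(-1L, 1L), n_perm * nsub, replace = TRUE),
                  nrow = n_perm)
  diffs <- matrix(aperm(d, c(1, 2, 3)), nrow = nsub)  # subj x (ch*time)
  null_max <- perm_null_cpp(diffs, flips, nch, thr, unclass(adjacency))
  colnames(null_max) <- c("positive", "negative")

  tsel <- times[sel]
  clusters <- lapply(seq_along(found$mass), function(i) {
    memb <- which(found$labels == i, arr.ind = TRUE)
    tail_null <- null_max[, if (found$sign[i] > 0) 1L else 2L]
    p1 <- (sum(tail_null >= abs(found$mass[i])) + 1) / (n_perm + 1)
    list(mass = found$mass[i],
         p = min(1, 2 * p1),
         polarity = if (found$sign[i] > 0) "positive" else "negative",
         time_range = range(tsel[memb[, 2]]),
         channels = sort(unique(memb[, 1])),
         members = memb)
  })
  ord <- order(vapply(clusters, function(cl) -abs(cl$mass), 0))
  structure(list(clusters = clusters[ord], threshold = thr,
                 null_max_mass = null_max, window = window, times = tsel,
                 alpha = alpha),
            class = "cluster_test")
}

#' Per-trial cluster scores
#'
#' Averages each trial over the rectangular cluster window: the full time
#' extent of the cluster crossed with every channel that contributed to the
#' cluster at any point.
#'
#' @param epochs An [erp_epochs()] object.
#' @param cluster One element of `cluster_test$clusters` (needs
#'   `time_range` and `channels`).
#' @return Data frame with columns `subject`, `condition`, `trial`,
#'   `score` (microvolts).
#' @export
cluster_score <- function(epochs, cluster) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (!length(cluster$channels)) stop("cluster has no contributing channels")
  tsel <- epochs$times >= cluster$time_range[1] &
          epochs$times <= cluster$time_range[2]
  if (!any(tsel)) stop("cluster time range not covered by epochs")
  rows <- list()
  for (s in names(epochs$data)) {
    for (cond in names(epochs$data[[s]])) {
      a <- epochs$data[[s]][[cond]]
      sc <- apply(a[cluster$channels, tsel, , drop = FALSE], 3, mean)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s, condition = cond,
                   trial = seq_along(sc), score = sc)
    }
  }
  do.call(rbind, rows)
}

#' Per-participant condition averages from epochs
#'
#' @param epochs An [erp_epochs()] object.
#' @param condition Condition name present in every subject.
#' @return Array `(participant, channel, time)`.
#' @export
condition_average <- function(epochs, condition) {
  subj <- names(epochs$data)
  out <- array(NA_real_, c(length(subj), length(epochs$layout$names),
                           length(epochs$times)))
  for (i in seq_along(subj)) {
    a <- epochs$data[[subj[i]]][[condition]]
    if (is.null(a)) stop("condition '", condition, "' missing for subject ",
                         subj[i])
    out[i, , ] <- apply(a, c(1, 2), mean)
  }
  out
}
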