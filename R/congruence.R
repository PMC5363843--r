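# Compositional congruence between sampling schedules.
#
# Dissimilarity (Jaccard on presence/absence, Bray-Curtis on counts) ->
# principal coordinates -> Procrustes superimposition of the schedule's
# configuration onto the full-night configuration on the first few axes.
# Congruence is r = sqrt(1 - m2); significance by PROTEST permutation; the
# sample-area null model redraws random species subsets of the full-night
# matrix.

#' Dissimilarity matrix between night replicates
#'
#' All-zero rows are removed first (and reported): a night with no retained
#' captures has no defined composition. Jaccard operates on
#' presence/absence, Bray-Curtis on counts.
#'
#' @param mat Night x species abundance matrix.
#' @param metric `"jaccard"` or `"bray"`.
#' @return A `dist` object with attributes `dropped_rows` (labels removed)
#'   and `degenerate` (`TRUE` when fewer than 3 usable rows remain).
#' @export
dissimilarity <- function(mat, metric = c("jaccard", "bray")) {
  metric <- match.arg(metric)
  keep <- rowSums(mat) > 0
  dropped <- rownames(mat)[!keep]
  m <- mat[keep, , drop = FALSE]
  d <- if (metric == "jaccard") {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(m, method = "bray")
  }
  attr(d, "dropped_rows") <- dropped
  attr(d, "degenerate") <- nrow(m) < 3
  d
}

#' Principal coordinates analysis
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns scores
#' (eigenvectors scaled by the square root of their eigenvalues) on the
#' positive-eigenvalue axes. Negative eigenvalues are dropped without
#' correction; their total magnitude is reported.
#'
#' @param d A `dist` object (or square symmetric matrix).
#' @param n_axes Number of axes requested (default 5); fewer are returned
#'   (with a warning) when fewer positive axes exist.
#' @return List of class `nn_pcoa`: `scores` (rows keep the input labels),
#'   `eigenvalues` (positive ones), `prop_var` (fraction of positive-axis
#'   variance), `n_axes_used`, `negative_magnitude`.
#' @export
pcoa_scores <- function(d, n_axes = 5) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 rows for ordination")
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) < n_axes)
    warning("only ", length(pos), " positive axes available (",
            n_axes, " requested)")
  use <- pos[seq_len(min(n_axes, length(pos)))]
  scores <- e$vectors[, use, drop = FALSE] %*%
    diag(sqrt(e$values[use]), nrow = length(use))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCo", seq_along(use))
  structure(list(
    scores = scores,
    eigenvalues = e$values[pos],
    prop_var = e$values[pos] / sum(e$values[pos]),
    n_axes_used = length(use),
    negative_magnitude = sum(abs(e$values[e$values < -tol]))
  ), class = "nn_pcoa")
}

#' Procrustes superimposition statistics
#'
#' Both configurations are centered and scaled to unit sum of squares
#' (symmetric form); the target is optimally rotated (reflection allowed)
#' and scaled onto the reference. `m2` is the residual sum of squares and
#' `r = sqrt(1 - m2)` the congruence.
#'
#' @param scores_ref,scores_target Row-matched score matrices (same row
#'   labels, same order).
#' @return List `m2`, `r`.
#' @export
procrustes_r <- function(scores_ref, scores_target) {
  if (nrow(scores_ref) != nrow(scores_target))
    stop("configurations must have the same number of rows")
  if (!is.null(rownames(scores_ref)) && !is.null(rownames(scores_target)) &&
      !identical(rownames(scores_ref), rownames(scores_target)))
    stop("row labels of the two configurations do not match")
  if (nrow(scores_ref) < 3) stop("need at least 3 shared rows")
  fit <- vegan::procrustes(scores_ref, scores_target, symmetric = TRUE)
  m2 <- fit$ss
  list(m2 = m2, r = sqrt(max(0, 1 - m2)))
}

#' PROTEST permutation significance of a Procrustes fit
#'
#' Permutes the row order of the target `n_perm` times;
#' `p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1)`.
#'
#' @inheritParams procrustes_r
#' @param n_perm Number of permutations (default 999, must be >= 1).
#' @param seed Optional integer seed.
#' @return Permutation p-value.
#' @export
protest_p <- function(scores_ref, scores_target, n_perm = 999,
                      seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::protest(scores_ref, scores_target, permutations = n_perm)
  unname(pt$signif)
}

#' Congruence of a sampling schedule with the full night
#'
#' Ordinated separately (each matrix drops its own all-zero nights), the two
#' configurations are intersected on shared nights and superimposed on the
#' first `n_axes` principal coordinates. A comparison is degenerate — the
#' "too many zeros" failure mode of sparse split schedules — when either
#' ordination has fewer than 3 usable rows or fewer than 2 positive axes,
#' or fewer than 3 nights are shared.
#'
#' @param full_mat Full-night abundance matrix (reference).
#' @param strat_mat Schedule-restricted matrix on the same night universe.
#' @param metric `"jaccard"` or `"bray"`.
#' @param n_axes Ordination axes used (default 5).
#' @param n_perm PROTEST permutations (default 999); `0` skips the test
#'   (`p = NA`).
#' @param seed Optional integer seed (PROTEST only).
#' @param ref_ord Optional precomputed `nn_pcoa` of `full_mat` under
#'   `metric` (reused across many comparisons, e.g. null-model draws).
#' @return One-row data frame: `metric`, `m2`, `r`, `p`, `n_rows_shared`,
#'   `n_species_strategy`, `degenerate`.
#' @export
strategy_congruence <- function(full_mat, strat_mat,
                                metric = c("jaccard", "bray"), n_axes = 5,
                                n_perm = 999, seed = NULL, ref_ord = NULL) {
  metric <- match.arg(metric)
  res <- data.frame(metric = metric, m2 = NA_real_, r = NA_real_,
                    p = NA_real_, n_rows_shared = NA_integer_,
                    n_species_strategy = sum(colSums(strat_mat) > 0),
                    degenerate = TRUE, stringsAsFactors = FALSE)
  d_t <- dissimilarity(strat_mat, metric)
  if (attr(d_t, "degenerate")) return(res)
  if (is.null(ref_ord)) {
    d_r <- dissimilarity(full_mat, metric)
    if (attr(d_r, "degenerate")) return(res)
    ref_ord <- suppressWarnings(pcoa_scores(d_r, n_axes))
  }
  tar_ord <- suppressWarnings(pcoa_scores(d_t, n_axes))
  if (ref_ord$n_axes_used < 2 || tar_ord$n_axes_used < 2) return(res)
  shared <- intersect(rownames(ref_ord$scores), rownames(tar_ord$scores))
  res$n_rows_shared <- length(shared)
  if (length(shared) < 3) return(res)
  k <- min(ref_ord$n_axes_used, tar_ord$n_axes_used)
  pr <- procrustes_r(ref_ord$scores[shared, 1:k, drop = FALSE],
                     tar_ord$scores[shared, 1:k, drop = FALSE])
  res$m2 <- pr$m2
  res$r <- pr$r
  res$degenerate <- FALSE
  if (n_perm > 0)
    res$p <- protest_p(ref_ord$scores[shared, 1:k, drop = FALSE],
                       tar_ord$scores[shared, 1:k, drop = FALSE],
                       n_perm = n_perm, seed = seed)
  res
}

#' Random-species-subset null model for schedule congruence
#'
#' Each draw selects `k` species uniformly without replacement from the
#' full-night matrix, keeps their full-night counts on all nights, and
#' measures that subset's Procrustes congruence with the whole community.
#' The null isolates the sample-area effect (fewer species) from the
#' time-of-night effect a real schedule adds.
#'
#' In `"curve"` mode `k` sweeps a grid; in `"matched"` mode all draws use a
#' single `k` (a schedule's species count) so a schedule's r can be placed
#' within the null distribution via [null_percentile()].
#'
#' @param full_mat Full-night abundance matrix.
#' @param k Species-subset sizes: a vector (curve mode grid) or scalar
#'   (matched mode); each must lie in `[2, S - 1]` where `S` is the number
#'   of species, except that `k = S` is allowed (and gives `r = 1`).
#' @param n_draws Total number of draws (default 1000), spread round-robin
#'   over the `k` grid in curve mode.
#' @param metric,n_axes As in [strategy_congruence()].
#' @param seed Optional integer seed.
#' @return Data frame `k`, `r`, `failed` (degenerate ordination draws are
#'   recorded, not dropped), with attributes `mode`, `seed`, `n_draws`.
#' @export
null_model <- function(full_mat, k, n_draws = 1000,
                       metric = c("jaccard", "bray"), n_axes = 5,
                       seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(full_mat)
  if (any(k < 2 | k > S)) stop("k must lie in [2, S]")
  mode <- if (length(k) > 1) "curve" else "matched"
  kk <- rep(k, length.out = n_draws)
  ref_ord <- suppressWarnings(
    pcoa_scores(dissimilarity(full_mat, metric), n_axes))
  out <- data.frame(k = kk, r = NA_real_, failed = FALSE)
  for (i in seq_len(n_draws)) {
    cols <- sample.int(S, kk[i])
    sub <- full_mat[, cols, drop = FALSE]
    sc <- strategy_congruence(full_mat, sub, metric, n_axes = n_axes,
                              n_perm = 0, ref_ord = ref_ord)
    if (sc$degenerate) out$failed[i] <- TRUE else out$r[i] <- sc$r
  }
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "n_draws") <- n_draws
  out
}

#' Percentile of an observed congruence within a matched-k null
#'
#' Rank-based placement of a schedule's r among the null draws:
#' `(1 + #\{null r < r_obs\} + 0.5 #\{ties\}) / (n_ok + 1)` over the
#' non-failed draws. A schedule no better than a random species subset of
#' the same size sits uniformly within the null.
#'
#' @param null_draws Data frame from [null_model()] (matched mode).
#' @param r_obs Observed congruence.
#' @return Percentile in `(0, 1)`.
#' @export
null_percentile <- function(null_draws, r_obs) {
  r <- null_draws$r[!null_draws$failed & !is.na(null_draws$r)]
  if (!length(r)) stop("no usable null draws")
  (1 + sum(r < r_obs) + 0.5 * sum(r == r_obs)) / (length(r) + 1)
}
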