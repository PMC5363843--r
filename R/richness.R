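# Rarefaction and extrapolation of species richness.
#
# Individual-based (abundance) and sample-based (incidence) analytic
# rarefaction, with Chao-type estimates of undetected species driving
# extrapolation beyond the observed effort, so that schedules can be
# compared at the common effort of the full-night reference.

# log of binomial coefficient, safe for large n
.lchoose <- function(n, k) ifelse(k > n | k < 0, -Inf, lchoose(n, k))

#' Individual-based analytic rarefaction
#'
#' Expected richness in a random subsample of `m` individuals:
#' `E[S(m)] = S_obs - sum_i C(n - n_i, m) / C(n, m)`, evaluated with
#' log-gamma arithmetic.
#'
#' @param abundance Non-negative integer vector of per-species abundances.
#' @param m Subsample sizes, `1 <= m <= n` (vectorised).
#' @return Expected richness for each `m`.
#' @export
rarefy_individuals <- function(abundance, m) {
  x <- abundance[abundance > 0]
  n <- sum(x)
  if (any(m < 1 | m > n))
    stop("m must lie in [1, n]; use extrapolate_individuals() beyond n")
  vapply(m, function(mm) {
    miss <- exp(.lchoose(n - x, mm) - .lchoose(n, mm))
    length(x) - sum(miss)
  }, numeric(1))
}

#' Chao-type estimate of undetected species (abundance data)
#'
#' `f0 = f1^2 / (2 f2)` when doubletons exist; with `f2 = 0` the
#' bias-corrected convention `f1 (f1 - 1) / (2 (f2 + 1))` is used.
#'
#' @param f1,f2 Numbers of singletons and doubletons.
#' @return Estimated number of undetected species.
#' @export
chao_unseen <- function(f1, f2) {
  stopifnot(f1 >= 0, f2 >= 0)
  if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Individual-based extrapolation beyond the observed sample
#'
#' `S(n + g) = S_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^g)` — continuous at
#' `g = 0`, monotone in `g`, asymptote `S_obs + f0`.
#'
#' @param abundance Per-species abundances.
#' @param m_star Target efforts `> n` (vectorised).
#' @return Estimated richness at each `m_star`.
#' @export
extrapolate_individuals <- function(abundance, m_star) {
  x <- abundance[abundance > 0]
  n <- sum(x)
  if (any(m_star < n)) stop("m_star must be >= n")
  s_obs <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(rep(s_obs, length(m_star)))
  f0 <- chao_unseen(f1, f2)
  if (f0 == 0) return(rep(s_obs, length(m_star)))
  g <- m_star - n
  s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^g)
}

#' Sample-based analytic rarefaction (and its extrapolation inputs)
#'
#' Expected richness among `t` of the `R` sample units:
#' `E[S(t)] = S_obs - sum_i C(R - R_i, t) / C(R, t)` on incidence counts
#' `R_i`.
#'
#' @param incidence Per-species incidence counts `R_i` (numbers of sample
#'   units occupied), or a units x species matrix (converted via
#'   `colSums(mat > 0)`, with `R` taken as `nrow(mat)`).
#' @param t Numbers of sample units, `1 <= t <= R` (vectorised).
#' @param R Total number of sample units (required when `incidence` is a
#'   vector).
#' @return Expected richness for each `t`.
#' @export
rarefy_samples <- function(incidence, t, R = NULL) {
  if (is.matrix(incidence)) {
    R <- nrow(incidence)
    incidence <- colSums(incidence > 0)
  }
  if (is.null(R)) stop("R (number of sample units) is required")
  ri <- incidence[incidence > 0]
  if (any(t < 1 | t > R))
    stop("t must lie in [1, R]; use extrapolate_samples() beyond R")
  vapply(t, function(tt) {
    miss <- exp(.lchoose(R - ri, tt) - .lchoose(R, tt))
    length(ri) - sum(miss)
  }, numeric(1))
}

#' Sample-based extrapolation beyond the observed number of units
#'
#' Mirrors the individual-based form with uniques/duplicates `Q1`, `Q2`
#' and the Chao2-type `Q0 = Q1^2 / (2 Q2)` (or `Q1 (Q1 - 1) / 2` when
#' `Q2 = 0`): `S(R + g) = S_obs + Q0 * (1 - (1 - Q1 / (Q1 + R Q0))^g)`.
#'
#' @inheritParams rarefy_samples
#' @param t_star Target unit counts `> R`.
#' @return Estimated richness at each `t_star`.
#' @export
extrapolate_samples <- function(incidence, t_star, R = NULL) {
  if (is.matrix(incidence)) {
    R <- nrow(incidence)
    incidence <- colSums(incidence > 0)
  }
  if (is.null(R)) stop("R (number of sample units) is required")
  ri <- incidence[incidence > 0]
  if (any(t_star < R)) stop("t_star must be >= R")
  s_obs <- length(ri)
  q1 <- sum(ri == 1); q2 <- sum(ri == 2)
  if (q1 == 0) return(rep(s_obs, length(t_star)))
  q0 <- chao_unseen(q1, q2)
  if (q0 == 0) return(rep(s_obs, length(t_star)))
  g <- t_star - R
  s_obs + q0 * (1 - (1 - q1 / (q1 + R * q0))^g)
}

# analytic curve (rarefied + extrapolated) for one matrix
.richness_points <- function(mat, mode, efforts) {
  if (mode == "individual") {
    x <- colSums(mat)
    n <- sum(x)
    lo <- efforts[efforts <= n]; hi <- efforts[efforts > n]
    c(if (length(lo)) rarefy_individuals(x, lo),
      if (length(hi)) extrapolate_individuals(x, hi))
  } else {
    R <- nrow(mat)
    lo <- efforts[efforts <= R]; hi <- efforts[efforts > R]
    c(if (length(lo)) rarefy_samples(mat, lo),
      if (length(hi)) extrapolate_samples(mat, hi))
  }
}

#' Rarefaction/extrapolation curve with bootstrap confidence interval
#'
#' Analytic point estimates on an effort grid up to `target_effort`
#' (defaulting to the observed effort), with a percentile bootstrap over
#' sample units (rows resampled with replacement) giving 95% intervals.
#'
#' @param mat Night x species abundance matrix.
#' @param mode `"individual"` (effort = individuals) or `"sample"`
#'   (effort = sample units).
#' @param target_effort Extrapolation target; typically the full-night
#'   reference's total individuals (or nights) so schedules share a common
#'   effort.
#' @param n_boot Bootstrap resamples (default 200); `0` disables the CI.
#' @param n_knots Approximate number of grid points (default 40).
#' @param seed Optional integer seed.
#' @return Data frame `effort`, `S_est`, `ci_lo`, `ci_hi`, `extrapolated`;
#'   attributes `reference_n`, `f1`/`f2` (or `Q1`/`Q2`) and `S_obs`.
#' @export
richness_curve <- function(mat, mode = c("individual", "sample"),
                           target_effort = NULL, n_boot = 200,
                           n_knots = 40, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  x <- colSums(mat)
  ref_n <- if (mode == "individual") sum(x) else nrow(mat)
  if (ref_n < 1) stop("empty matrix")
  if (is.null(target_effort)) target_effort <- ref_n
  efforts <- sort(unique(c(
    round(seq(1, ref_n, length.out = min(n_knots, ref_n))),
    ref_n,
    if (target_effort > ref_n)
      round(seq(ref_n, target_effort,
                length.out = max(2, n_knots %/% 2)))
  )))
  s_est <- .richness_points(mat, mode, efforts)
  ci_lo <- ci_hi <- rep(NA_real_, length(efforts))
  if (n_boot > 0 && nrow(mat) > 1) {
    boots <- matrix(NA_real_, nrow = n_boot, ncol = length(efforts))
    for (b in seq_len(n_boot)) {
      bm <- mat[sample.int(nrow(mat), nrow(mat), replace = TRUE), ,
                drop = FALSE]
      if (mode == "individual") {
        bn <- sum(bm)
        if (bn == 0) next
        e_lo <- pmin(efforts, bn)
        bx <- colSums(bm)
        v <- numeric(length(efforts))
        v[efforts <= bn] <- rarefy_individuals(bx, efforts[efforts <= bn])
        if (any(efforts > bn))
          v[efforts > bn] <- extrapolate_individuals(bx, efforts[efforts > bn])
        boots[b, ] <- v
      } else {
        boots[b, ] <- .richness_points(bm, mode, efforts)
      }
    }
    ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci_lo <- ci[1, ]; ci_hi <- ci[2, ]
  } else if (n_boot > 0) {
    warning("single sample unit: returning point estimates without CI")
  }
  out <- data.frame(effort = efforts, S_est = s_est, ci_lo = ci_lo,
                    ci_hi = ci_hi, extrapolated = efforts > ref_n)
  attr(out, "reference_n") <- ref_n
  attr(out, "S_obs") <- sum(x > 0)
  if (mode == "individual") {
    attr(out, "f1") <- sum(x == 1); attr(out, "f2") <- sum(x == 2)
  } else {
    ri <- colSums(mat > 0)
    attr(out, "Q1") <- sum(ri == 1); attr(out, "Q2") <- sum(ri == 2)
  }
  out
}
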