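# Threshold Indicator Taxa Analysis along the nocturnal time gradient.
#
# Sample units are (site, night, check-interval) cells; the gradient is the
# interval midpoint in minutes since 18:00. For each taxon, midpoints
# between distinct observed capture times are candidate change points; the
# candidate maximizing the Dufrene-Legendre IndVal on either side is the
# observed change point. Significance comes from permutation z-scores and
# bootstrap purity/reliability; community-level thresholds are peaks of the
# cumulative z-score sums of negative (early-night) and positive
# (late-night) responders.

#' Build gradient sample units from capture records
#'
#' Expands the full (site, night, interval) grid — every check interval of
#' every sampled night is a unit, including intervals with no captures —
#' and tallies per-taxon counts.
#'
#' @param records Capture-record data frame with binned `time_min`.
#' @param check_interval Minutes per interval (default 30).
#' @param nights Night universe (data frame `site`, `night`); default the
#'   nights present in `records`.
#' @param species Column universe; default species present.
#' @return List with `counts` (units x species integer matrix), `gradient`
#'   (interval midpoints, minutes), and `units` (data frame `site`, `night`,
#'   `interval_start`).
#' @export
gradient_units <- function(records, check_interval = 30, nights = NULL,
                           species = NULL) {
  if (is.null(nights)) nights <- night_universe(records)
  if (is.null(species)) species <- sort(unique(records$species))
  starts <- seq(0, NIGHT_MINUTES - check_interval, by = check_interval)
  units <- data.frame(
    site = rep(nights$site, each = length(starts)),
    night = rep(nights$night, each = length(starts)),
    interval_start = rep(starts, nrow(nights)),
    stringsAsFactors = FALSE
  )
  key <- paste(units$site, units$night, units$interval_start, sep = ":")
  counts <- matrix(0L, nrow = nrow(units), ncol = length(species),
                   dimnames = list(key, species))
  if (nrow(records)) {
    rk <- paste(records$site, records$night, records$time_min, sep = ":")
    tab <- tapply(records$count, list(rk, records$species), sum)
    counts[rownames(tab), colnames(tab)] <-
      ifelse(is.na(tab), 0L, as.integer(tab))
  }
  list(counts = counts,
       gradient = units$interval_start + check_interval / 2,
       units = units)
}

#' Pool sparse species into guild-by-rarity composite taxa
#'
#' Species with fewer than `min_records` total records are merged into
#' composite columns keyed `"<guild>_<rarity_class>"`; richer species are
#' untouched. Pooling happens once — a composite still below the threshold
#' is retained as-is.
#'
#' @param mat Units-or-nights x species count matrix.
#' @param traits Data frame with `species`, `guild`, `rarity_class` covering
#'   every species column.
#' @param min_records Pooling threshold (default 9: species with < 9
#'   records are pooled).
#' @return Matrix with pooled columns; attribute `pooled` maps composite
#'   names to their member species.
#' @export
pool_sparse_taxa <- function(mat, traits, min_records = 9) {
  totals <- colSums(mat)
  sparse <- names(totals)[totals < min_records]
  if (!length(sparse)) return(mat)
  idx <- match(sparse, traits$species)
  if (anyNA(idx))
    stop("species lacking traits: ",
         paste(sparse[is.na(idx)], collapse = ", "))
  grp <- paste(traits$guild[idx], traits$rarity_class[idx], sep = "_")
  keep <- mat[, !(colnames(mat) %in% sparse), drop = FALSE]
  pooled_cols <- vapply(unique(grp), function(g) {
    rowSums(mat[, sparse[grp == g], drop = FALSE])
  }, numeric(nrow(mat)))
  pooled_cols <- matrix(pooled_cols, nrow = nrow(mat),
                        dimnames = list(rownames(mat), unique(grp)))
  out <- cbind(keep, pooled_cols)
  attr(out, "pooled") <- split(sparse, grp)
  out
}

#' Candidate change points for one taxon
#'
#' Midpoints between consecutive distinct observed capture times; candidates
#' leaving fewer than `min_split` sample units on either side (units with
#' gradient <= candidate count as left) are discarded.
#'
#' @param present_times Gradient values of units where the taxon is present.
#' @param gradient Gradient values of *all* units (used for the split-size
#'   rule); defaults to `present_times`.
#' @param min_split Minimum units required on each side (default 4).
#' @return Sorted numeric vector of candidate change points (possibly
#'   empty; fewer than 2 distinct presence values also give an empty list).
#' @export
candidate_change_points <- function(present_times, gradient = present_times,
                                    min_split = 4) {
  pts <- sort(unique(present_times))
  if (length(pts) < 2) return(numeric(0))
  cps <- (pts[-1] + pts[-length(pts)]) / 2
  g <- sort(gradient)
  n <- length(g)
  nleft <- findInterval(cps, g)
  cps[nleft >= min_split & (n - nleft) >= min_split]
}

#' Indicator values on both sides of a split
#'
#' For side `g`: `A_g` = (mean abundance in g) / (sum of the two side
#' means); `B_g` = fraction of units in g where the taxon is present;
#' `IndVal_g = 100 * A_g * B_g`.
#'
#' @param y Per-unit counts of the taxon.
#' @param gradient Per-unit gradient values.
#' @param split Split location; units with `gradient <= split` form the
#'   left (early-night) group.
#' @return Named vector `c(left = , right = )`, each in `[0, 100]`.
#' @export
indval <- function(y, gradient, split) {
  left <- gradient <= split
  if (!any(left) || all(left)) stop("split leaves an empty side")
  if (sum(y) == 0) stop("taxon absent from all units")
  mL <- mean(y[left]); mR <- mean(y[!left])
  A_L <- mL / (mL + mR); A_R <- mR / (mL + mR)
  B_L <- mean(y[left] > 0); B_R <- mean(y[!left] > 0)
  c(left = 100 * A_L * B_L, right = 100 * A_R * B_R)
}

# IndVal for all candidate split sizes k (counts of left units) on y sorted
# by gradient. Returns list(ivL, ivR). Assumes sum(y) > 0.
.iv_all <- function(y, kvec) {
  n <- length(y)
  cs <- cumsum(y); cp <- cumsum(y > 0)
  tot <- cs[n]; totp <- cp[n]
  csk <- cs[kvec]; cpk <- cp[kvec]
  mL <- csk / kvec; mR <- (tot - csk) / (n - kvec)
  d <- mL + mR
  list(ivL = 100 * (mL / d) * (cpk / kvec),
       ivR = 100 * (mR / d) * ((totp - cpk) / (n - kvec)))
}

# max over candidates and sides, scalar; same preconditions as .iv_all
.iv_max <- function(y, kvec) {
  n <- length(y)
  cs <- cumsum(y); cp <- cumsum(y > 0)
  tot <- cs[n]; totp <- cp[n]
  csk <- cs[kvec]; cpk <- cp[kvec]
  mL <- csk / kvec; mR <- (tot - csk) / (n - kvec)
  d <- mL + mR
  max(100 * (mL / d) * (cpk / kvec),
      100 * (mR / d) * ((totp - cpk) / (n - kvec)))
}

# candidates for sorted-gradient data: list(cp, k) or NULL
.titan_candidates <- function(y, g_sorted, min_split) {
  cps <- candidate_change_points(g_sorted[y > 0], g_sorted, min_split)
  if (!length(cps)) return(NULL)
  list(cp = cps, k = findInterval(cps, g_sorted))
}

#' TITAN analysis of a single taxon
#'
#' Selects the candidate change point maximizing IndVal on either side,
#' standardizes the observed score against permutations of the unit labels
#' (z-score and permutation p), and bootstraps the units (resampling with
#' replacement, rerunning the full candidate selection each time) to obtain
#' purity (fraction of resamples agreeing in direction), reliability
#' (fraction achieving permutation p <= `alpha`), and a 90% change-point
#' confidence interval (5th/95th bootstrap percentiles). A taxon is flagged
#' significant when purity and reliability both reach 0.95.
#'
#' @param y Per-unit counts of the taxon.
#' @param gradient Per-unit gradient values (minutes).
#' @param n_perm Permutations for the z-score (default 250).
#' @param n_boot Bootstrap resamples (default 500).
#' @param min_split Minimum units on each side of a candidate (default 4).
#' @param alpha Permutation significance level inside the reliability
#'   bootstrap (default 0.05).
#' @param seed Optional integer seed.
#' @return One-row data frame: `change_point`, `direction` (`"negative"` =
#'   early-night indicator, `"positive"` = late-night), `indval`, `z`,
#'   `p_perm`, `cp_lo`, `cp_hi`, `purity`, `reliability`, `n_records`,
#'   `significant`, `flag`.
#' @export
taxon_titan <- function(y, gradient, n_perm = 250, n_boot = 500,
                        min_split = 4, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- order(gradient)
  g <- gradient[ord]; y <- as.numeric(y[ord])
  n <- length(y)
  out <- data.frame(change_point = NA_real_, direction = NA_character_,
                    indval = NA_real_, z = NA_real_, p_perm = NA_real_,
                    cp_lo = NA_real_, cp_hi = NA_real_, purity = NA_real_,
                    reliability = NA_real_, n_records = sum(y),
                    significant = FALSE, flag = "", stringsAsFactors = FALSE)
  cand <- .titan_candidates(y, g, min_split)
  if (is.null(cand)) {
    out$flag <- "no_candidates"
    return(out)
  }
  iv <- .iv_all(y, cand$k)
  stat <- pmax(iv$ivL, iv$ivR)
  best <- which.max(stat)
  obs <- stat[best]
  direction <- if (iv$ivL[best] >= iv$ivR[best]) "negative" else "positive"
  out$change_point <- cand$cp[best]
  out$direction <- direction
  out$indval <- obs

  perm <- cpp_perm_max(y, cand$k, n_perm)
  sd_perm <- stats::sd(perm)
  if (sd_perm == 0) {
    out$flag <- "zero_perm_variance"
  } else {
    out$z <- (obs - mean(perm)) / sd_perm
  }
  out$p_perm <- (1 + sum(perm >= obs)) / (n_perm + 1)

  boot <- cpp_titan_boot(y, g, n_boot, n_perm, min_split)
  cp_b <- boot$cp
  dir_b <- ifelse(boot$dir == 1L, "negative", "positive")
  p_b <- boot$p
  ok <- !is.na(cp_b)
  out$purity <- sum(dir_b[ok] == direction) / n_boot
  out$reliability <- sum(p_b[ok] <= alpha) / n_boot
  if (any(ok)) {
    ci <- stats::quantile(cp_b[ok], c(0.05, 0.95), names = FALSE)
    out$cp_lo <- ci[1]; out$cp_hi <- ci[2]
  }
  out$significant <- !is.na(out$z) && out$purity >= 0.95 &&
    out$reliability >= 0.95
  out
}

#' Community-level activity thresholds from per-taxon results
#'
#' Cumulative z-score sums along the gradient: at each evaluation point,
#' the z-scores of negative responders whose change point lies at or below
#' it are summed (the z- curve), and likewise for positive responders (z+).
#' Peaks (argmax) locate the community thresholds.
#'
#' @param taxa Data frame of per-taxon results (as from [titan_analysis()]).
#' @param candidates Evaluation grid; default the sorted change points of
#'   the included taxa.
#' @param filter_significant Include only pure-and-reliable taxa (default
#'   `TRUE`); otherwise all taxa with a finite z.
#' @return List: `grid`, `sum_z_neg`, `sum_z_pos`, `peak_neg`, `peak_pos`
#'   (NA with a flag when a direction has no responders), `n_taxa_used`.
#' @export
community_thresholds <- function(taxa, candidates = NULL,
                                 filter_significant = TRUE) {
  use <- if (filter_significant) which(taxa$significant)
         else which(is.finite(taxa$z))
  taxa <- taxa[use, , drop = FALSE]
  if (is.null(candidates)) {
    candidates <- sort(unique(taxa$change_point))
    if (!length(candidates)) candidates <- numeric(0)
  }
  step_sum <- function(dirn) {
    sel <- taxa$direction == dirn & is.finite(taxa$z)
    vapply(candidates, function(x)
      sum(taxa$z[sel & taxa$change_point <= x]), numeric(1))
  }
  zn <- step_sum("negative")
  zp <- step_sum("positive")
  flags <- character(0)
  peak_neg <- if (any(zn > 0)) candidates[which.max(zn)] else {
    flags <- c(flags, "no_negative_responders"); NA_real_
  }
  peak_pos <- if (any(zp > 0)) candidates[which.max(zp)] else {
    flags <- c(flags, "no_positive_responders"); NA_real_
  }
  list(grid = candidates, sum_z_neg = zn, sum_z_pos = zp,
       peak_neg = peak_neg, peak_pos = peak_pos,
       n_taxa_used = nrow(taxa), flags = flags)
}

#' TITAN over a whole community matrix
#'
#' Optionally pools sparse species by guild and rarity class, runs
#' [taxon_titan()] on every (possibly composite) taxon with at least two
#' distinct presence times, and summarises community thresholds.
#'
#' @param mat Units x species count matrix (see [gradient_units()]).
#' @param gradient Per-unit gradient values.
#' @param traits Optional data frame `species`, `guild`, `rarity_class` for
#'   pooling; `NULL` disables pooling.
#' @param min_records Pooling threshold (default 9).
#' @param filter_significant Passed to [community_thresholds()].
#' @inheritParams taxon_titan
#' @return List with `taxa` (one row per taxon, columns of [taxon_titan()]
#'   plus `taxon`) and `community` (see [community_thresholds()]).
#' @export
titan_analysis <- function(mat, gradient, traits = NULL, min_records = 9,
                           n_perm = 250, n_boot = 500, min_split = 4,
                           alpha = 0.05, seed = NULL,
                           filter_significant = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(traits)) mat <- pool_sparse_taxa(mat, traits, min_records)
  rows <- lapply(colnames(mat), function(tx) {
    res <- taxon_titan(mat[, tx], gradient, n_perm = n_perm,
                       n_boot = n_boot, min_split = min_split,
                       alpha = alpha, seed = NULL)
    cbind(taxon = tx, res, stringsAsFactors = FALSE)
  })
  taxa <- do.call(rbind, rows)
  rownames(taxa) <- NULL
  list(taxa = taxa,
       community = community_thresholds(taxa,
                                        filter_significant =
                                          filter_significant))
}
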