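# Rarity metrics and the independence-weighted rarity index.
#
# Three complementary dimensions of rarity per species:
#   LA — local abundance: median over occupied sites of (mean captures per
#        replicate night at the site) / (total captures at the site);
#   RA — regional abundance: total dataset records / number of occupied
#        sites;
#   GR — geographic range: area (km^2) of the minimum convex polygon around
#        occupied-site coordinates.
# Each metric is log(x+1)-transformed and min-max standardized across
# species, combined into RI by independence weights derived from pairwise
# Pearson correlations, and species are classed Common / Uncommon / Rare by
# the quartile rule. The classification is dataset-relative.

#' Local abundance of a species
#'
#' For each site where the species occurs: (mean captures of the species per
#' replicate night at that site) divided by (total captures of all species
#' at that site). LA is the median of these per-site values across occupied
#' sites.
#'
#' @param records Capture-record data frame.
#' @param species Species id.
#' @param nights Optional night universe (data frame `site`, `night`); by
#'   default the nights present in `records`. Needed so that nights with
#'   zero captures of the focal species still count as effort.
#' @return LA (>= 0). Species with zero records return 0 with attribute
#'   `flag = "zero_records"`.
#' @export
local_abundance <- function(records, species, nights = NULL) {
  if (is.null(nights)) nights <- night_universe(records)
  sp_rec <- records[records$species == species, , drop = FALSE]
  if (nrow(sp_rec) == 0)
    return(structure(0, flag = "zero_records"))
  occupied <- unique(sp_rec$site)
  vals <- vapply(occupied, function(s) {
    n_nights <- sum(nights$site == s)
    site_total <- sum(records$count[records$site == s])
    if (n_nights == 0 || site_total == 0) return(NA_real_)
    mean_per_night <- sum(sp_rec$count[sp_rec$site == s]) / n_nights
    mean_per_night / site_total
  }, numeric(1))
  stats::median(vals, na.rm = TRUE)
}

#' Regional abundance of a species
#'
#' Total records of the species in the dataset divided by the number of
#' sites at which it was recorded.
#'
#' @inheritParams local_abundance
#' @return RA (>= 0); zero-record species return 0 with attribute
#'   `flag = "zero_records"`.
#' @export
regional_abundance <- function(records, species) {
  sp_rec <- records[records$species == species, , drop = FALSE]
  if (nrow(sp_rec) == 0)
    return(structure(0, flag = "zero_records"))
  sum(sp_rec$count) / length(unique(sp_rec$site))
}

#' Geographic range as minimum-convex-polygon area
#'
#' Area in km^2 of the convex hull of the occupied-site coordinates on the
#' WGS84 ellipsoid. Fewer than three non-collinear sites give a degenerate
#' (zero-area) hull.
#'
#' @param coords Matrix or data frame of occupied-site coordinates with
#'   columns `lon`, `lat` (decimal degrees); rows with missing coordinates
#'   are an error.
#' @return Area in km^2.
#' @export
geographic_range <- function(coords) {
  coords <- as.data.frame(coords)
  if (!all(c("lon", "lat") %in% names(coords)))
    stop("coords must have columns 'lon' and 'lat'")
  if (anyNA(coords$lon) || anyNA(coords$lat)) {
    bad <- which(is.na(coords$lon) | is.na(coords$lat))
    stop("missing coordinates for occupied site(s): ",
         paste(if (!is.null(rownames(coords))) rownames(coords)[bad]
               else bad, collapse = ", "))
  }
  pts <- unique(cbind(coords$lon, coords$lat))
  if (nrow(pts) < 3) return(0)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3) return(0)
  abs(geosphere::areaPolygon(pts[hull, , drop = FALSE])) / 1e6
}

#' Independence weights for the rarity metrics
#'
#' Each metric's weight grows with its independence from the other two:
#' with `r1`, `r2` the Pearson correlations (across species, on the
#' log-standardized metrics) between the focal metric and each other metric,
#' the default weight is `1/2 + (1 - |r1|)/2 + (1 - |r2|)/2`. The
#' `"squared"` variant replaces `|r|` with `r^2`.
#'
#' @param la,ra,gr Numeric vectors (one value per species) of the
#'   log-standardized metrics.
#' @param variant `"abs"` (default) or `"squared"`.
#' @return Named vector `c(omega_LA, omega_RA, omega_GR)`, each in
#'   `[0.5, 1.5]`.
#' @export
independence_weights <- function(la, ra, gr, variant = c("abs", "squared")) {
  variant <- match.arg(variant)
  if (length(la) < 3) stop("need >= 3 species to estimate correlations")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance metric: treating its correlation as 0")
      return(0)
    }
    stats::cor(x, y)
  }
  r_lr <- safe_cor(la, ra)
  r_lg <- safe_cor(la, gr)
  r_rg <- safe_cor(ra, gr)
  dep <- function(r) if (variant == "abs") abs(r) else r^2
  w <- function(r1, r2) 0.5 + (1 - dep(r1)) / 2 + (1 - dep(r2)) / 2
  c(omega_LA = w(r_lr, r_lg), omega_RA = w(r_lr, r_rg),
    omega_GR = w(r_lg, r_rg))
}

# log(x+1) then min-max standardize to [0,1]; constant vectors map to 0.
.log_standardize <- function(x) {
  lx <- log1p(x)
  rng <- range(lx)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (lx - rng[1]) / diff(rng)
}

#' Rarity index from standardized metrics and weights
#'
#' `RI = (LA_s*omega_LA + RA_s*omega_RA + GR_s*omega_GR) / sum(omegas)`.
#'
#' @param la_s,ra_s,gr_s Standardized metrics in `[0,1]`.
#' @param weights Named weight vector from [independence_weights()].
#' @return RI per species, in `[0,1]`.
#' @export
rarity_index <- function(la_s, ra_s, gr_s, weights) {
  if (length(la_s) < 2)
    stop("rarity index needs >= 2 species (standardization is relative)")
  (la_s * weights["omega_LA"] + ra_s * weights["omega_RA"] +
     gr_s * weights["omega_GR"]) / sum(weights)
}

#' Classify species into Common / Uncommon / Rare by RI quartiles
#'
#' Rare if `RI <= Q1`, Common if `RI >= Q3`, else Uncommon (Q1/Q3 the
#' 25th/75th percentiles under the linear-interpolation quantile rule).
#' Boundaries are inclusive so distinct RI values always yield non-empty R
#' and C classes.
#'
#' @param ri Numeric RI vector.
#' @return Character vector in `{"R","U","C"}`. Fewer than 4 species: all
#'   `"U"` with a warning. All-equal RI: all `"C"` with a warning.
#' @export
classify_quartiles <- function(ri) {
  if (length(ri) < 4) {
    warning("fewer than 4 species: all classified Uncommon")
    return(rep("U", length(ri)))
  }
  q <- stats::quantile(ri, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2] && all(ri == ri[1])) {
    warning("all rarity-index values equal: all classified Common")
    return(rep("C", length(ri)))
  }
  ifelse(ri <= q[1], "R", ifelse(ri >= q[2], "C", "U"))
}

#' Full per-species rarity profile for a dataset
#'
#' Computes LA, RA and GR for every species, log(x+1)-transforms and min-max
#' standardizes each across species, derives independence weights, combines
#' into RI, and assigns C/U/R quartile classes.
#'
#' @param records Capture-record data frame (one dataset).
#' @param sites Site table (`site`, `lon`, `lat`).
#' @param nights Optional night universe; default nights present in
#'   `records`.
#' @param gr_records,gr_sites Records and site table used for the
#'   geographic-range metric only. Defaults to `records`/`sites`
#'   (range within the dataset); pass pooled multi-dataset tables to
#'   measure range across all surveyed regions.
#' @param weight_variant Passed to [independence_weights()].
#' @return Data frame with one row per species: `species`, `LA`, `RA`,
#'   `GR`, `LA_s`, `RA_s`, `GR_s`, `omega_LA`, `omega_RA`, `omega_GR`,
#'   `RI`, `rarity_class`.
#' @export
rarity_profiles <- function(records, sites, nights = NULL,
                            gr_records = records, gr_sites = sites,
                            weight_variant = c("abs", "squared")) {
  weight_variant <- match.arg(weight_variant)
  if (is.null(nights)) nights <- night_universe(records)
  species <- sort(unique(records$species))
  if (length(species) < 2) stop("need >= 2 species for rarity profiles")
  la <- vapply(species, function(s)
    as.numeric(local_abundance(records, s, nights)), numeric(1))
  ra <- vapply(species, function(s)
    as.numeric(regional_abundance(records, s)), numeric(1))
  gr <- vapply(species, function(s) {
    occ <- unique(gr_records$site[gr_records$species == s])
    if (!length(occ)) return(0)
    idx <- match(occ, gr_sites$site)
    if (anyNA(idx))
      stop("missing coordinates for occupied site(s): ",
           paste(occ[is.na(idx)], collapse = ", "))
    geographic_range(gr_sites[idx, c("lon", "lat"), drop = FALSE])
  }, numeric(1))
  la_s <- .log_standardize(la)
  ra_s <- .log_standardize(ra)
  gr_s <- .log_standardize(gr)
  w <- independence_weights(la_s, ra_s, gr_s, variant = weight_variant)
  ri <- rarity_index(la_s, ra_s, gr_s, w)
  data.frame(
    species = species, LA = la, RA = ra, GR = gr,
    LA_s = la_s, RA_s = ra_s, GR_s = gr_s,
    omega_LA = unname(w["omega_LA"]), omega_RA = unname(w["omega_RA"]),
    omega_GR = unname(w["omega_GR"]),
    RI = unname(ri), rarity_class = classify_quartiles(ri),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
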