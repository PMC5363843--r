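# Pipeline orchestration: activity tables, yield comparisons, and the
# end-to-end run over a dataset (real CSVs or a simulation preset).

#' Capture-frequency activity table
#'
#' Tallies captures per time bin and category (species, rarity class, or
#' guild), with relative frequencies both within category (each category's
#' distribution over the night) and within bin.
#'
#' @param records Capture-record data frame.
#' @param category `"species"`, `"rarity"` or `"guild"`. Rarity classes are
#'   looked up in `traits`; guild comes from the records (or `traits`).
#' @param traits Optional data frame `species`, `guild`, `rarity_class`.
#' @param bin_minutes Bin width (default 30; use 60 for hourly tables).
#' @return Data frame `bin_start`, `category`, `n`, `rel_category`
#'   (fraction of the category's captures in the bin), `rel_bin` (fraction
#'   of the bin's captures in the category). Empty input gives an all-zero
#'   table with attribute `flag = "no_records"`.
#' @export
activity_table <- function(records, category = c("species", "rarity",
                                                 "guild"),
                           traits = NULL, bin_minutes = 30) {
  category <- match.arg(category)
  bins <- seq(0, NIGHT_MINUTES - bin_minutes, by = bin_minutes)
  cat_of <- switch(category,
    species = records$species,
    guild = {
      g <- records$guild
      if (all(is.na(g)) && !is.null(traits))
        g <- traits$guild[match(records$species, traits$species)]
      g
    },
    rarity = {
      if (is.null(traits) || is.null(traits$rarity_class))
        stop("rarity activity table needs traits with rarity_class")
      traits$rarity_class[match(records$species, traits$species)]
    })
  if (nrow(records) && anyNA(cat_of))
    stop("unknown ", category, " for species: ",
         paste(unique(records$species[is.na(cat_of)]), collapse = ", "))
  if (nrow(records) == 0) {
    out <- data.frame(bin_start = bins, category = NA_character_, n = 0,
                      rel_category = 0, rel_bin = 0)
    attr(out, "flag") <- "no_records"
    return(out)
  }
  bin_start <- (records$time_min %/% bin_minutes) * bin_minutes
  agg <- stats::aggregate(records$count,
                          by = list(bin_start = bin_start,
                                    category = cat_of), FUN = sum)
  full <- expand.grid(bin_start = bins,
                      category = sort(unique(cat_of)),
                      stringsAsFactors = FALSE)
  out <- merge(full, agg, all.x = TRUE)
  out$n <- ifelse(is.na(out$x), 0, out$x)
  out$x <- NULL
  cat_tot <- tapply(out$n, out$category, sum)
  bin_tot <- tapply(out$n, out$bin_start, sum)
  out$rel_category <- ifelse(cat_tot[out$category] > 0,
                             out$n / cat_tot[out$category], 0)
  out$rel_bin <- ifelse(bin_tot[as.character(out$bin_start)] > 0,
                        out$n / bin_tot[as.character(out$bin_start)], 0)
  out <- out[order(out$bin_start, out$category), ]
  rownames(out) <- NULL
  out
}

#' Capture-yield comparison between schedules
#'
#' Totals per schedule, pairwise percent differences
#' (`100 * (N_a - N_b) / N_b`), and cumulative totals by night order.
#'
#' @param matrices Named list of abundance matrices sharing the night
#'   universe (e.g. `list("12h" = ..., "6h" = ..., "6hB" = ...)`).
#' @return List: `totals` (named vector), `percent_diff` (data frame
#'   `schedule_a`, `schedule_b`, `pct_more` = how much more `a` yields than
#'   `b`; `NA` with a flag when the denominator is 0), and `cumulative`
#'   (night-order x schedule cumulative individuals).
#' @export
yield_comparison <- function(matrices) {
  stopifnot(length(matrices) >= 2, !is.null(names(matrices)))
  rn <- rownames(matrices[[1]])
  for (m in matrices) stopifnot(identical(rownames(m), rn))
  totals <- vapply(matrices, sum, numeric(1))
  pairs <- utils::combn(names(matrices), 2)
  pd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    data.frame(schedule_a = a, schedule_b = b,
               pct_more = if (totals[b] > 0)
                 100 * (totals[a] - totals[b]) / totals[b] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cum <- vapply(matrices, function(m) cumsum(rowSums(m)),
                numeric(length(rn)))
  cum <- as.data.frame(cum, check.names = FALSE)
  cum <- cbind(night = rn, night_order = seq_along(rn), cum)
  rownames(cum) <- NULL
  list(totals = totals, percent_diff = pd, cumulative = cum)
}

#' Percent yield advantage of the full night over the best half-night
#'
#' `100 * (N_12h - N_best6) / N_best6`, the headline sample-area figure.
#'
#' @param totals Named totals including `"12h"` and at least one `"6h"` /
#'   `"6hB"` entry.
#' @return Percent difference (scalar).
#' @export
yield_advantage_12h <- function(totals) {
  best6 <- max(totals[setdiff(names(totals), "12h")])
  if (best6 == 0) return(NA_real_)
  unname(100 * (totals["12h"] - best6) / best6)
}

.default_config <- function() {
  list(
    check_interval = 30,
    families = c("Phyllostomidae", "Vespertilionidae"),
    schedules = c("12h", "6h", "6hB"),
    metrics = c("jaccard", "bray"),
    n_axes = 5,
    n_perm_protest = 999,
    weight_variant = "abs",
    titan = list(run = TRUE, n_perm = 250, n_boot = 500, min_split = 4,
                 min_records = 9),
    richness = list(n_boot = 200, n_knots = 40),
    null_model = list(n_draws = 1000, mode = "matched"),
    seed = 1L
  )
}

# merge user config over defaults (one level of nesting)
.merge_config <- function(user) {
  cfg <- .default_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.log_stage <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[nightnets] %-12s %6.1fs", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Ingest (CSV paths or a simulation preset) -> family filter -> schedule
#' matrices -> rarity profiles -> TITAN -> rarefaction curves -> congruence
#' + null model -> activity/yield tables. All stage outputs are written as
#' CSV into `out_dir` together with a machine-readable `manifest.json`
#' (parameters, seed, versions) and a human-readable `summary.txt`. Given
#' the same config (including `seed`) the outputs are reproduced exactly.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{captures, sites}{input CSV paths (see [read_captures()],
#'       [read_sites()]), or}
#'     \item{preset}{one of `"amazonia"`, `"atlantic"`, `"cerrado"` to
#'       simulate instead;}
#'     \item{out_dir}{output directory (required);}
#'     \item{seed}{integer seed;}
#'     \item{schedules, metrics, n_axes, n_perm_protest, families,
#'       weight_variant}{analysis settings;}
#'     \item{titan}{list `run`, `n_perm`, `n_boot`, `min_split`,
#'       `min_records`;}
#'     \item{richness}{list `n_boot`, `n_knots`;}
#'     \item{null_model}{list `n_draws`, `mode` (`"matched"` or
#'       `"curve"`).}
#'   }
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the in-memory stage results (`records`,
#'   `matrices`, `rarity`, `titan`, `richness`, `congruence`, `null`,
#'   `yield`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  stage <- "ingest"
  res <- list()
  tryCatch({
    # --- ingest -----------------------------------------------------------
    if (!is.null(cfg$preset)) {
      preset_fun <- switch(cfg$preset,
                           amazonia = amazonia_like_preset,
                           atlantic = atlantic_like_preset,
                           cerrado = cerrado_like_preset,
                           stop("unknown preset: ", cfg$preset))
      sim <- simulate_dataset(preset_fun(seed = cfg$seed))
      records <- sim$records
      sites <- sim$sites
      nights <- sim$nights
    } else {
      records <- read_captures(cfg$captures,
                               check_interval = cfg$check_interval)
      sites <- read_sites(cfg$sites)
      nights <- NULL
    }
    if (!is.null(cfg$families) && !all(is.na(records$family)))
      records <- filter_families(records, cfg$families)
    if (is.null(nights)) nights <- night_universe(records)
    .log_stage(quiet, stage, t0)

    # --- schedule matrices ------------------------------------------------
    stage <- "matrices"
    scheds <- canonical_schedules()[cfg$schedules]
    species <- sort(unique(records$species))
    matrices <- lapply(scheds, function(s)
      build_matrix(restrict_to_schedule(records, s), species, nights))
    for (nm in names(matrices))
      write_matrix_csv(matrices[[nm]],
                       file.path(cfg$out_dir,
                                 paste0("matrix_", nm, ".csv")))
    .log_stage(quiet, stage, t0)

    # --- rarity -----------------------------------------------------------
    stage <- "rarity"
    rar <- rarity_profiles(records, sites, nights = nights,
                           weight_variant = cfg$weight_variant)
    utils::write.csv(rar, file.path(cfg$out_dir, "rarity.csv"),
                     row.names = FALSE)
    traits <- data.frame(species = rar$species,
                         guild = records$guild[match(rar$species,
                                                     records$species)],
                         rarity_class = rar$rarity_class,
                         stringsAsFactors = FALSE)
    .log_stage(quiet, stage, t0)

    # --- activity tables & yields ----------------------------------------
    stage <- "activity"
    for (catg in c("species", "rarity", "guild")) {
      at <- try(activity_table(records, catg, traits = traits,
                               bin_minutes = 60), silent = TRUE)
      if (!inherits(at, "try-error"))
        utils::write.csv(at,
                         file.path(cfg$out_dir,
                                   paste0("activity_", catg, ".csv")),
                         row.names = FALSE)
    }
    yield <- NULL
    if (length(matrices) >= 2) {
      yield <- yield_comparison(matrices)
      utils::write.csv(yield$percent_diff,
                       file.path(cfg$out_dir, "yield_percent_diff.csv"),
                       row.names = FALSE)
      utils::write.csv(yield$cumulative,
                       file.path(cfg$out_dir, "yield_cumulative.csv"),
                       row.names = FALSE)
    }
    .log_stage(quiet, stage, t0)

    # --- TITAN ------------------------------------------------------------
    stage <- "titan"
    titan_res <- NULL
    if (isTRUE(cfg$titan$run)) {
      gu <- gradient_units(records, check_interval = cfg$check_interval,
                           nights = nights, species = species)
      set.seed(cfg$seed + 1L)
      titan_res <- titan_analysis(gu$counts, gu$gradient, traits = traits,
                                  min_records = cfg$titan$min_records,
                                  n_perm = cfg$titan$n_perm,
                                  n_boot = cfg$titan$n_boot,
                                  min_split = cfg$titan$min_split)
      utils::write.csv(titan_res$taxa,
                       file.path(cfg$out_dir, "titan_taxa.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(gradient = titan_res$community$grid,
                   sum_z_neg = titan_res$community$sum_z_neg,
                   sum_z_pos = titan_res$community$sum_z_pos),
        file.path(cfg$out_dir, "titan_community.csv"), row.names = FALSE)
    }
    .log_stage(quiet, stage, t0)

    # --- richness ---------------------------------------------------------
    stage <- "richness"
    rich <- list()
    for (mode in c("individual", "sample")) {
      target <- if (mode == "individual") sum(matrices[["12h"]])
                else nrow(matrices[["12h"]])
      for (nm in names(matrices)) {
        set.seed(cfg$seed + 2L)
        rc <- richness_curve(matrices[[nm]], mode, target_effort = target,
                             n_boot = cfg$richness$n_boot,
                             n_knots = cfg$richness$n_knots)
        rc$schedule <- nm
        rc$mode <- mode
        rich[[paste(mode, nm)]] <- rc
      }
    }
    rich_df <- do.call(rbind, rich)
    utils::write.csv(rich_df, file.path(cfg$out_dir, "rarefaction.csv"),
                     row.names = FALSE)
    .log_stage(quiet, stage, t0)

    # --- congruence + null model -----------------------------------------
    stage <- "congruence"
    cong <- NULL
    nulls <- list()
    strat_names <- setdiff(names(matrices), "12h")
    if (length(strat_names) == 0) {
      if (!quiet) message("[nightnets] congruence skipped: ",
                          "no schedule to compare against 12h")
    } else {
      rows <- list()
      for (metric in cfg$metrics) {
        ref_ord <- suppressWarnings(
          pcoa_scores(dissimilarity(matrices[["12h"]], metric),
                      cfg$n_axes))
        for (nm in strat_names) {
          sc <- strategy_congruence(matrices[["12h"]], matrices[[nm]],
                                    metric, n_axes = cfg$n_axes,
                                    n_perm = cfg$n_perm_protest,
                                    seed = cfg$seed + 3L,
                                    ref_ord = ref_ord)
          sc$schedule <- nm
          if (!sc$degenerate && cfg$null_model$n_draws > 0) {
            kk <- if (identical(cfg$null_model$mode, "matched"))
              sc$n_species_strategy
            else seq(2, max(2, length(species) - 1))
            nd <- null_model(matrices[["12h"]], kk,
                             n_draws = cfg$null_model$n_draws,
                             metric = metric, n_axes = cfg$n_axes,
                             seed = cfg$seed + 4L)
            nd$metric <- metric
            nd$schedule <- nm
            sc$null_median_r <- stats::median(nd$r, na.rm = TRUE)
            sc$null_percentile <- null_percentile(nd, sc$r)
            nulls[[paste(metric, nm)]] <- nd
          } else {
            sc$null_median_r <- NA_real_
            sc$null_percentile <- NA_real_
          }
          rows[[paste(metric, nm)]] <- sc
        }
      }
      cong <- do.call(rbind, rows)
      rownames(cong) <- NULL
      utils::write.csv(cong, file.path(cfg$out_dir, "congruence.csv"),
                       row.names = FALSE)
      if (length(nulls))
        utils::write.csv(do.call(rbind, nulls),
                         file.path(cfg$out_dir, "null_curve.csv"),
                         row.names = FALSE)
    }
    .log_stage(quiet, stage, t0)

    # --- manifest & summary ----------------------------------------------
    stage <- "report"
    manifest <- list(
      package = "nightnets",
      version = as.character(utils::packageVersion("nightnets")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = cfg[setdiff(names(cfg), "out_dir")],
      n_records = nrow(records),
      n_species = length(species),
      n_nights = nrow(nights)
    )
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summ <- c(
      sprintf("nightnets pipeline summary"),
      sprintf("records: %d individuals, %d species, %d nights",
              sum(records$count), length(species), nrow(nights)),
      sprintf("totals: %s",
              paste(sprintf("%s=%d", names(matrices),
                            vapply(matrices, function(m) as.integer(sum(m)),
                                   integer(1))), collapse = "  ")),
      if (!is.null(yield))
        sprintf("12h yield advantage over best half-night: %.1f%%",
                yield_advantage_12h(yield$totals)),
      if (!is.null(cong))
        sprintf("congruence r: %s",
                paste(sprintf("%s/%s=%.3f", cong$metric, cong$schedule,
                              cong$r), collapse = "  ")),
      if (!is.null(titan_res))
        sprintf("TITAN: %d/%d taxa with significant thresholds",
                sum(titan_res$taxa$significant), nrow(titan_res$taxa))
    )
    writeLines(summ, file.path(cfg$out_dir, "summary.txt"))
    .log_stage(quiet, stage, t0)

    res <- list(records = records, matrices = matrices, rarity = rar,
                titan = titan_res, richness = rich_df, congruence = cong,
                null = nulls, yield = yield, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
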