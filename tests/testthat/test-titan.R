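# Threshold indicator taxa analysis: pooling, candidates, IndVal,
# per-taxon inference, community thresholds.

test_that("sparse species pool by guild and rarity class, once", {
  m <- cbind(rich = c(5, 5, 5), s1 = c(2, 1, 1), s2 = c(1, 1, 1))
  rownames(m) <- paste0("u", 1:3)
  traits <- data.frame(species = c("rich", "s1", "s2"),
                       guild = c("GI", "FR", "FR"),
                       rarity_class = c("C", "C", "C"))
  out <- pool_sparse_taxa(m, traits, min_records = 9)
  expect_true("FR_C" %in% colnames(out))
  expect_equal(unname(out[, "FR_C"]), c(3, 2, 2))  # columns added
  expect_equal(sum(out[, "FR_C"]), 7)              # still < 9: retained
  expect_equal(unname(out[, "rich"]), c(5, 5, 5))
  # all species at or above the threshold: untouched
  m2 <- cbind(a = c(5, 5), b = c(4, 5))
  expect_identical(pool_sparse_taxa(m2, data.frame(
    species = c("a", "b"), guild = "FR", rarity_class = "C")), m2)
  expect_error(pool_sparse_taxa(m, traits[-2, ]), "lacking traits")
})

test_that("candidate change points are presence midpoints under minSplt", {
  expect_equal(candidate_change_points(c(30, 90), min_split = 1), 60)
  expect_equal(candidate_change_points(c(30, 30, 90, 150), min_split = 1),
               c(60, 120))
  # 5 units total, minSplt = 4: no candidate leaves 4 on both sides
  g5 <- c(30, 90, 150, 210, 270)
  expect_length(candidate_change_points(g5, g5, min_split = 4), 0)
  expect_length(candidate_change_points(300, min_split = 1), 0)
})

test_that("IndVal matches hand-computed specificity x fidelity", {
  g <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(indval(rep(2, 8), g, 4.5), c(left = 50, right = 50))
  expect_equal(indval(c(1, 1, 1, 1, 0, 0, 0, 0), g, 4.5),
               c(left = 100, right = 0))
  expect_equal(indval(c(2, 0, 2, 0, 1, 1, 1, 1), g, 4.5),
               c(left = 25, right = 50))
  expect_error(indval(rep(0, 8), g, 4.5), "absent")
  expect_error(indval(rep(1, 8), g, 10), "empty side")
})

test_that("doubling counts leaves IndVal and the selected threshold fixed", {
  set.seed(5)
  g <- rep(seq(15, 705, by = 30), 3)
  y <- ifelse(g < 240, rpois(length(g), 2), rpois(length(g), 0.2))
  iv1 <- indval(y, g, 240)
  iv2 <- indval(2 * y, g, 240)
  expect_equal(iv1, iv2)
  r1 <- taxon_titan(y, g, n_perm = 50, n_boot = 50, seed = 8)
  r2 <- taxon_titan(2 * y, g, n_perm = 50, n_boot = 50, seed = 8)
  expect_equal(r1$change_point, r2$change_point)
  expect_equal(r1$indval, r2$indval)
})

test_that("a flat taxon is never significant and a perfect one always is", {
  g <- rep(seq(15, 705, by = 30), 2)
  flat <- taxon_titan(rep(1, length(g)), g, n_perm = 100, n_boot = 100,
                      seed = 1)
  expect_false(flat$significant)
  expect_equal(flat$flag, "zero_perm_variance")

  set.seed(2)
  y <- ifelse(g < 300, rpois(length(g), 4) + 1, 0)
  perfect <- taxon_titan(y, g, n_perm = 200, n_boot = 200, seed = 3)
  expect_equal(perfect$direction, "negative")
  expect_gt(perfect$change_point, 250)
  expect_lt(perfect$change_point, 350)
  expect_gte(perfect$purity, 0.95)
  expect_lte(perfect$p_perm, 1 / 200 + 0.01)
  expect_true(perfect$significant)
})

test_that("results are reproducible under a fixed seed", {
  set.seed(10)
  g <- rep(seq(15, 705, by = 30), 2)
  y <- rpois(length(g), 1)
  a <- taxon_titan(y, g, n_perm = 100, n_boot = 100, seed = 99)
  b <- taxon_titan(y, g, n_perm = 100, n_boot = 100, seed = 99)
  expect_identical(a, b)
})

test_that("IndVal stays within [0, 100] over random data", {
  set.seed(6)
  g <- seq(15, 705, by = 30)
  for (i in 1:20) {
    y <- rpois(length(g), runif(1, 0.2, 3))
    if (sum(y) == 0) next
    split <- sample(g[-c(1, length(g))], 1) + 15
    if (all(g <= split) || all(g > split)) next
    iv <- indval(y, g, split)
    expect_true(all(iv >= 0 & iv <= 100))
  }
})

test_that("community z-sum curves step and peak as expected", {
  one <- data.frame(taxon = "a", change_point = 120, direction = "negative",
                    z = 3, significant = TRUE)
  ct <- community_thresholds(one, candidates = c(60, 120, 300))
  expect_equal(ct$sum_z_neg, c(0, 3, 3))
  expect_equal(ct$peak_neg, 120)
  expect_true(is.na(ct$peak_pos))
  expect_true("no_positive_responders" %in% ct$flags)

  two <- data.frame(taxon = c("a", "b"), change_point = c(120, 300),
                    direction = "negative", z = c(2, 4),
                    significant = TRUE)
  ct2 <- community_thresholds(two)
  expect_equal(ct2$peak_neg, 300)
  expect_equal(max(ct2$sum_z_neg), 6)
  expect_true(all(ct2$sum_z_neg >= 0))
})

test_that("whole-community analysis pools, runs, and summarises", {
  sim <- simulate_dataset(simulation_config(
    n_species = 8, n_sites = 3, nights_per_site = 4,
    total_expected = 400,
    activity_mix = c(uniform = 0.5, early = 0.5, late = 0, bimodal = 0),
    seed = 12))
  gu <- gradient_units(sim$records, nights = sim$nights)
  expect_equal(nrow(gu$counts), 12 * 24)
  expect_equal(sum(gu$counts), sum(sim$records$count))
  traits <- data.frame(species = sort(unique(sim$records$species)))
  traits$guild <- sim$truth$species$guild[match(traits$species,
                                                sim$truth$species$species)]
  traits$rarity_class <- "C"
  res <- titan_analysis(gu$counts, gu$gradient, traits = traits,
                        n_perm = 50, n_boot = 50, seed = 5)
  expect_true(all(c("taxon", "change_point", "z", "purity",
                    "reliability") %in% names(res$taxa)))
  expect_true(all(res$taxa$purity >= 0 & res$taxa$purity <= 1, na.rm = TRUE))
  expect_true(all(res$taxa$reliability >= 0 & res$taxa$reliability <= 1,
                  na.rm = TRUE))
})
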