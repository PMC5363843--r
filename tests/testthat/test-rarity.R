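# Rarity metrics, independence weights, RI and quartile classes.

test_that("local abundance follows the per-site median definition", {
  # one site, 2 nights; focal species counts {2, 0}; site total 10
  recs <- rbind(
    rec("S1", "N1", "foc", 30)[rep(1, 2), ],
    rec("S1", "N1", "oth", 60)[rep(1, 4), ],
    rec("S1", "N2", "oth", 90)[rep(1, 4), ]
  )
  expect_equal(as.numeric(local_abundance(recs, "foc")), 0.1)
  # two occupied sites with per-site values 0.1 and 0.3 -> median 0.2
  recs2 <- rbind(
    recs,
    rec("S2", "N1", "foc", 30)[rep(1, 3), ],
    rec("S2", "N1", "oth", 60)[rep(1, 7), ]
  )
  expect_equal(as.numeric(local_abundance(recs2, "foc")), 0.2)
  absent <- local_abundance(recs, "ghost")
  expect_equal(as.numeric(absent), 0)
  expect_equal(attr(absent, "flag"), "zero_records")
})

test_that("regional abundance divides records by occupied sites", {
  recs <- rbind(
    rec("S1", "N1", "a", 30)[rep(1, 5), ],
    rec("S2", "N1", "a", 30)[rep(1, 4), ],
    rec("S3", "N1", "a", 30)[rep(1, 3), ]
  )
  expect_equal(as.numeric(regional_abundance(recs, "a")), 4)
  expect_equal(as.numeric(regional_abundance(rec("S1", "N1", "b", 0), "b")),
               1)
  z <- regional_abundance(recs, "ghost")
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "flag"), "zero_records")
})

test_that("geographic range is the spherical MCP area", {
  expect_equal(geographic_range(data.frame(lon = c(0, 1), lat = c(0, 0))), 0)
  square <- data.frame(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  area <- geographic_range(square)
  expect_equal(area, 111.32^2, tolerance = 0.01)  # ~12,392 km^2
  with_interior <- rbind(square, data.frame(lon = 0.5, lat = 0.5))
  expect_equal(geographic_range(with_interior), area)
  expect_error(geographic_range(data.frame(lon = c(0, NA), lat = c(0, 1))),
               "missing coordinates")
})

test_that("independence weights react to pairwise correlations", {
  # exactly orthogonal design -> omega = 1.5 everywhere
  la <- c(0, 1, 0, 1); ra <- c(0, 0, 1, 1); gr <- c(1, 0, 0, 1)
  w <- independence_weights(la, ra, gr)
  expect_equal(unname(w), rep(1.5, 3))
  # perfectly collinear -> omega = 0.5
  w2 <- independence_weights(la, la, 1 - la)
  expect_equal(unname(w2), rep(0.5, 3))
  # constructed correlations 0.5 and 0.3 -> omega_LA = 1.1
  set.seed(4)
  la3 <- rnorm(40)
  ra3 <- with_correlation(la3, 0.5, seed = 5)
  gr3 <- with_correlation(la3, 0.3, seed = 6)
  w3 <- independence_weights(la3, ra3, gr3)
  expect_equal(unname(w3["omega_LA"]), 1.1, tolerance = 1e-10)
  # squared variant
  w4 <- independence_weights(la3, ra3, gr3, variant = "squared")
  expect_equal(unname(w4["omega_LA"]),
               0.5 + (1 - 0.25) / 2 + (1 - 0.09) / 2, tolerance = 1e-10)
  w_all <- capture_warnings(independence_weights(c(1, 1, 1), ra3[1:3],
                                                 gr3[1:3]))
  expect_true(length(w_all) >= 1 && all(grepl("zero-variance", w_all)))
})

test_that("the rarity index is the weighted mean of standardized metrics", {
  w <- c(omega_LA = 1, omega_RA = 1, omega_GR = 2)
  expect_equal(rarity_index(c(0.2, 1), c(0.6, 1), c(1.0, 1), w)[1], 0.7)
  expect_equal(rarity_index(c(1, 0), c(1, 0), c(1, 0), w), c(1, 0))
})

test_that("quartile classification follows the inclusive-boundary rule", {
  ri <- (1:8) / 8
  cls <- classify_quartiles(ri)
  expect_equal(sum(cls == "R"), 2)
  expect_equal(sum(cls == "C"), 2)
  expect_equal(sum(cls == "U"), 4)
  expect_equal(classify_quartiles(c(0.1, 0.4, 0.6, 0.9)),
               c("R", "U", "U", "C"))
  expect_warning(cls_eq <- classify_quartiles(rep(0.5, 6)), "Common")
  expect_equal(cls_eq, rep("C", 6))
  expect_warning(cls_few <- classify_quartiles(c(0.2, 0.8)), "Uncommon")
  expect_equal(cls_few, c("U", "U"))
})

test_that("full profiles rank a dominant widespread species highest", {
  sim <- simulate_dataset(simulation_config(
    n_species = 10, n_sites = 6, nights_per_site = 4,
    total_expected = 600, occupancy_prob = 0.5, seed = 21))
  recs <- sim$records
  # plant a species that is everywhere, locally dominant, and maximally
  # spread: 40 records on every night of every site
  extra <- do.call(rbind, lapply(sim$sites$site, function(s)
    do.call(rbind, lapply(sprintf("N%02d", 1:4), function(nn)
      rec(s, nn, "dominant", 30, count = 1)[rep(1, 40), ]))))
  recs <- rbind(recs, extra)
  prof <- rarity_profiles(recs, sim$sites, nights = sim$nights)
  expect_equal(prof$species[which.max(prof$RI)], "dominant")
  expect_equal(max(prof$RI), prof$RI[prof$species == "dominant"])
  expect_true(all(prof$RI >= 0 & prof$RI <= 1))
  expect_true(all(prof$LA_s >= 0 & prof$LA_s <= 1))
  # permuting species labels permutes outputs identically
  prof2 <- rarity_profiles(recs[sample(nrow(recs)), ], sim$sites,
                           nights = sim$nights)
  expect_equal(prof2[order(prof2$species), ], prof[order(prof$species), ],
               ignore_attr = TRUE)
})

test_that("rescaling a raw metric far from zero barely moves RI", {
  # min-max after log absorbs common rescaling up to the +1 offset
  sim <- simulate_dataset(simulation_config(
    n_species = 8, n_sites = 5, nights_per_site = 4,
    total_expected = 500, seed = 31))
  prof <- rarity_profiles(sim$records, sim$sites, nights = sim$nights)
  gr_scaled <- nightnets:::.log_standardize(prof$GR * 1000)
  w <- independence_weights(prof$LA_s, prof$RA_s, gr_scaled)
  ri2 <- rarity_index(prof$LA_s, prof$RA_s, gr_scaled, w)
  expect_lt(max(abs(ri2 - prof$RI)), 0.05)
})
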