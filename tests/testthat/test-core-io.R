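# Capture I/O, time conventions, schedules, and matrix construction.

test_that("clock times map to minutes since 18:00 and are binned down", {
  df <- data.frame(dataset = "d", site = "S1", night = "N1",
                   species = c("a", "b", "c"), family = "Phyllostomidae",
                   time = c("18:30", "23:59", "05:30"))
  path <- write_captures_csv(df)
  recs <- read_captures(path)
  expect_equal(recs$time_min, c(30L, 330L, 690L))
})

test_that("times outside the half-open night window are rejected", {
  df <- data.frame(dataset = "d", site = "S1", night = "N1",
                   species = c("a", "b", "c"),
                   time = c("18:00", "06:00", "17:30"))
  path <- write_captures_csv(df)
  expect_warning(recs <- read_captures(path), "rejected")
  expect_equal(nrow(recs), 1L)       # only 18:00 (minute 0) survives
  expect_equal(attr(recs, "n_rejected"), 2L)
})

test_that("schema and row-level time errors are informative", {
  df <- data.frame(dataset = "d", site = "S1", species = "a", time = "19:00")
  path <- write_captures_csv(df)
  expect_error(read_captures(path), "night")
  df2 <- data.frame(dataset = "d", site = "S1", night = "N1",
                    species = c("a", "b"), time = c("19:00", "late"))
  expect_error(read_captures(write_captures_csv(df2)), "row")
})

test_that("numeric minutes-since-sunset columns are accepted directly", {
  df <- data.frame(dataset = "d", site = "S1", night = "N1",
                   species = "a", time_min = 47)
  recs <- read_captures(write_captures_csv(df))
  expect_equal(recs$time_min, 30L)   # snapped to interval start
})

test_that("family filtering counts and fraction match direct tallies", {
  recs <- rbind(
    rec("S1", "N1", "a", 30, family = "Phyllostomidae",
        count = 1)[rep(1, 98), ],
    rec("S1", "N1", "b", 60, family = "Vespertilionidae")[rep(1, 2), ],
    rec("S1", "N1", "c", 90, family = "Emballonuridae")[rep(1, 5), ]
  )
  out <- filter_families(recs, c("Phyllostomidae", "Vespertilionidae"))
  expect_equal(nrow(out), 100L)
  expect_equal(attr(out, "fraction_retained"), 100 / 105)
  expect_equal(nrow(filter_families(recs, "Emballonuridae")), 5L)
  all_one <- filter_families(recs[recs$family == "Phyllostomidae", ],
                             c("Phyllostomidae", "Vespertilionidae"))
  expect_equal(attr(all_one, "fraction_retained"), 1)
  expect_error(filter_families(recs, character(0)), "non-empty")
})

test_that("schedule restriction uses half-open windows and is idempotent", {
  sch <- canonical_schedules()
  recs <- rbind(rec("S1", "N1", "a", 30), rec("S1", "N1", "a", 200),
                rec("S1", "N1", "a", 400), rec("S1", "N1", "a", 600))
  expect_equal(restrict_to_schedule(recs, sch[["12h"]])$time_min,
               recs$time_min)
  r6 <- restrict_to_schedule(rbind(recs, rec("S1", "N1", "a", 360)),
                             sch[["6h"]])
  expect_false(360 %in% r6$time_min)  # minute 360 is second-half
  r6b <- restrict_to_schedule(recs, sch[["6hB"]])
  expect_equal(sort(r6b$time_min), c(30L, 600L))
  expect_identical(restrict_to_schedule(r6b, sch[["6hB"]]), r6b)
})

test_that("schedule validation rejects malformed windows", {
  expect_error(schedule("x", list(c(100, 50))), "a < b")
  expect_error(schedule("x", list(c(0, 400), c(300, 500))), "disjoint")
  expect_error(schedule("x", list(c(0, 800))), "within")
  expect_equal(schedule_minutes(canonical_schedules()[["6hB"]]), 360)
})

test_that("matrices respect declared universes and tally counts", {
  empty <- rec("S1", "N1", "a", 0)[0, ]
  m0 <- build_matrix(empty, species = c("a", "b", "c"),
                     nights = data.frame(site = "S1", night = c("N1", "N2")))
  expect_equal(dim(m0), c(2L, 3L))
  expect_true(all(m0 == 0))

  one <- rec("S1", "N1", "a", 30)[rep(1, 5), ]
  m1 <- build_matrix(one, species = c("a", "b"),
                     nights = data.frame(site = "S1", night = "N1"))
  expect_equal(m1["S1:N1", "a"], 5L)
  expect_equal(sum(m1), 5L)

  m7 <- build_matrix(toy_records())
  expect_equal(sum(m7), 7L)
  expect_equal(dim(m7), c(2L, 3L))
  expect_error(build_matrix(toy_records(), species = c("spA", "spB")),
               "spC")
})

test_that("half-night matrices add up to the full-night matrix", {
  sim <- simulate_dataset(simulation_config(
    n_species = 8, n_sites = 3, nights_per_site = 4,
    total_expected = 300, seed = 11))
  sp <- sort(unique(sim$records$species))
  sch <- canonical_schedules()
  second_half <- schedule("h2", list(c(360, 720)))
  m12 <- build_matrix(restrict_to_schedule(sim$records, sch[["12h"]]),
                      sp, sim$nights)
  m6 <- build_matrix(restrict_to_schedule(sim$records, sch[["6h"]]),
                     sp, sim$nights)
  mh2 <- build_matrix(restrict_to_schedule(sim$records, second_half),
                      sp, sim$nights)
  expect_identical(m6 + mh2, m12)
  # window containment implies cellwise domination
  m3 <- build_matrix(
    restrict_to_schedule(sim$records, schedule("3h", list(c(0, 180)))),
    sp, sim$nights)
  expect_true(all(m3 <= m6))
  expect_true(all(m6 <= m12))
})

test_that("matrix CSV round-trips preserve labels and counts", {
  m <- build_matrix(toy_records())
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(m, path)
  expect_identical(read_matrix_csv(path), m)
})
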