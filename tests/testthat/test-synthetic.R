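test_that("outbreak schedules validate their episodes", {
  sch <- build_outbreak_schedule()
  expect_equal(nrow(sch), 4L)
  expect_equal(sch$start, c(1870L, 1910L, 1950L, 1975L))
  expect_equal(nrow(build_outbreak_schedule(list())), 0L)
  expect_error(build_outbreak_schedule(list(c(1900, 1890))), "end before")
  expect_error(build_outbreak_schedule(list(c(1900, 1920), c(1910, 1930))),
               "overlap")
  expect_error(build_outbreak_schedule(list(c(1900, 1910)), severities = 2),
               "0, 1")
})

test_that("simulated series are seeded, positive, and constant when noiseless", {
  tm <- pattern_templates()
  lin <- tm[tm$name == "linear", ]
  cfg0 <- sim_config(noise_sigma = 0)
  s <- simulate_ring_series(lin, 1900L, build_outbreak_schedule(list()),
                            cfg0, seed = 1)$series
  # beyond the establishment ramp the level curve is flat
  expect_equal(unique(s$widths[(cfg0$ramp_years + 1):length(s$widths)]),
               lin$baseline_mm)
  expect_equal(s$first_year, 1900L)
  expect_equal(length(s$widths), cfg0$end_year - 1900L)
  a <- simulate_ring_series(tm[9, ], 1910L, config = sim_config(), seed = 7)
  b <- simulate_ring_series(tm[9, ], 1910L, config = sim_config(), seed = 7)
  expect_identical(a$series$widths, b$series$widths)
  expect_true(all(a$series$widths > 0))
})

test_that("a noiseless 1.5x release step lands on the major-release boundary", {
  tmpl <- list(name = "step", baseline_mm = 1, multiplier = 1.5,
               juvenile_years = 20, decline_rate = 0, release_offset = 1)
  sch <- build_outbreak_schedule(list(c(1930, 1940)))
  sim <- simulate_ring_series(tmpl, 1900L, sch, sim_config(noise_sigma = 0),
                              seed = 1)
  expect_equal(sim$release_year, 1941L)
  gc <- percent_growth_change(sim$series)
  expect_equal(gc$gc[gc$year == 1940], 50)
  # release truth matches detected major release within 2 years
  major_years <- gc$year[gc$class == "major_release"]
  expect_lte(min(abs(major_years - sim$release_year)), 2)
})

test_that("episode severity lets trees skip to a later episode", {
  tmpl <- list(name = "x", baseline_mm = 1, multiplier = 3,
               juvenile_years = 10, decline_rate = 0, release_offset = 1)
  sch <- build_outbreak_schedule(list(c(1920, 1930), c(1950, 1960)),
                                 severities = c(0.5, 1))
  set.seed(100)
  rel <- replicate(200, simulate_ring_series(
    tmpl, 1900L, sch, sim_config(noise_sigma = 0))$release_year)
  expect_setequal(unique(rel), c(1931L, 1961L))
  frac_first <- mean(rel == 1931L)
  expect_gt(frac_first, 0.38)
  expect_lt(frac_first, 0.62)
})

test_that("stand simulation produces aligned series, inventory and truth", {
  st <- simulate_stand(seed = 2)
  expect_equal(length(st$series), sum(sim_config()$n_per_template))
  expect_setequal(names(st$series), st$trees$tree_id)
  expect_setequal(st$truth$tree_id, st$trees$tree_id)
  expect_true(all(st$trees$dbh_cm >= 9))
  expect_true(all(st$trees$vitality %in% c("alive", "dead")))
  expect_equal(unique(st$trees$plot_area_m2), 400)
  expect_equal(nrow(st$saplings), 4L)
  # cohort truth: first cohort predates the first episode
  expect_true(all((st$truth$birth_year < 1870) == (st$truth$cohort == 1L)))
  # seeded determinism end-to-end
  st2 <- simulate_stand(seed = 2)
  expect_identical(st$trees, st2$trees)
  expect_identical(st$series$T100$widths, st2$series$T100$widths)
  # empty stand
  cfg0 <- sim_config(n_per_template = setNames(integer(9),
                                               pattern_templates()$name))
  st0 <- simulate_stand(cfg0, seed = 1)
  expect_equal(length(st0$series), 0L)
  expect_equal(nrow(st0$trees), 0L)
})

test_that("default stand ages stay inside the reported envelope", {
  st <- simulate_stand(seed = 6)
  ages <- vapply(st$series, length, 0L)
  expect_true(all(ages >= 55 & ages <= 271))
  # mean age within one reported standard deviation of the field mean
  expect_gt(mean(ages), 143 - 39.2)
  expect_lt(mean(ages), 143 + 39.2)
})

test_that("zero-noise archetypes classify as their own shapes over the whole window", {
  cfg0 <- sim_config(noise_sigma = 0)
  tm <- pattern_templates()
  for (i in seq_len(nrow(tm))) {
    want <- sub("^(low|moderate|high)_", "", tm$name[i])
    for (b in unique(c(tm$birth_min[i],
                       (tm$birth_min[i] + tm$birth_max[i]) %/% 2,
                       tm$birth_max[i]))) {
      sim <- simulate_ring_series(tm[i, ], b, config = cfg0, seed = 1)
      got <- classify_center_shape(segment_series(sim$series)$means)
      expect_equal(got$shape, want,
                   label = sprintf("%s born %d", tm$name[i], b))
      expect_false(got$ambiguous)
    }
  }
})
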