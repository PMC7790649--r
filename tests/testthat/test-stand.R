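test_that("dominant height uses the n tallest living trees per area", {
  trees <- toy_plot(c(14, 13, 12, 11, 9, 8, 5))
  expect_equal(dominant_height(trees), mean(c(14, 13, 12, 11)))
  # dead trees never enter the top set
  trees2 <- trees; trees2$vitality[1] <- "dead"
  expect_equal(dominant_height(trees2), mean(c(13, 12, 11, 9)))
  # an 800 m2 plot uses its eight tallest (100/ha scaling)
  trees3 <- toy_plot(20:5, plot_area_m2 = 800)
  expect_equal(dominant_height(trees3), mean(20:13))
  # degenerate plot: fewer trees than the top set, with a warning
  expect_warning(dh <- dominant_height(toy_plot(c(10, 8, 6))), "using all")
  expect_equal(dh, 8)
  no_h <- toy_plot(8); no_h$height_m <- NA_real_
  expect_error(dominant_height(no_h), "no measured")
})

test_that("canopy layers follow the DH thresholds with printed boundaries", {
  dh <- 13.64
  expect_equal(as.character(assign_canopy_layer(13.64, dh)), "dominant")
  expect_equal(as.character(assign_canopy_layer(10.0, dh)), "codominant")
  expect_equal(as.character(assign_canopy_layer(2 / 3 * dh, dh)), "codominant")
  expect_equal(as.character(assign_canopy_layer(7.5, dh)), "intermediary")
  expect_equal(as.character(assign_canopy_layer(6.0, dh)), "suppressed")
  # the intermediary lower bound is strict: exactly half DH is suppressed
  expect_equal(as.character(assign_canopy_layer(dh / 2, dh)), "suppressed")
  expect_equal(as.character(assign_canopy_layer(dh / 2 + 1e-9, dh)),
               "intermediary")
  expect_error(assign_canopy_layer(-1, dh), "positive")
})

test_that("every living tree gets exactly one layer and rows sum to 100%", {
  st <- simulate_stand(seed = 8)
  inv <- classify_canopy(st$trees)
  alive <- inv[inv$vitality == "alive", ]
  expect_true(all(!is.na(alive$canopy_layer)))
  expect_true(all(is.na(inv$canopy_layer[inv$vitality == "dead"])))
  ld <- layer_distribution(inv)
  tot <- as.numeric(tapply(ld$percent, ld$plot_id, sum))
  expect_equal(tot, rep(100, length(tot)))
})

test_that("stand summary reproduces the density and basal-area arithmetic", {
  trees <- toy_plot(rep(10, 45))
  saplings <- data.frame(plot_id = "P1", count = 4, area_m2 = 10)
  s <- suppressWarnings(stand_summary(trees, saplings))
  expect_equal(s$tree_density_ha, 1125)
  expect_equal(s$sapling_density_ha, 4000)
  one <- toy_plot(10, dbh = 20)
  s1 <- suppressWarnings(stand_summary(one))
  expect_equal(basal_area_m2(20), pi * 0.1^2)
  expect_equal(s1$tree_basal_area_ha, pi * 0.1^2 / 0.04)
  # composition percentages sum to 100
  mix <- toy_plot(c(10, 11, 12), dbh = c(10, 20, 30),
                  species = c("PIMA", "PIMA", "ABBA"))
  sm <- suppressWarnings(stand_summary(mix))
  expect_equal(sum(sm$composition_pct), 100)
  expect_equal(unname(sm$composition_pct["ABBA"]),
               100 * 30^2 / (10^2 + 20^2 + 30^2))
})

test_that("cohort assignment respects the age cutoffs", {
  ages <- c(a = 150, b = 130, c = 100, d = 60, e = 20)
  co <- assign_cohorts(ages, c(60, 130))
  expect_equal(unname(co), c(1L, 1L, 2L, 2L, 3L))
  expect_equal(names(co), names(ages))
  expect_true(all(assign_cohorts(c(200, 300), 130) == 1L))
  expect_true(all(assign_cohorts(c(50, 60), 130) == 2L))
  expect_warning(co0 <- assign_cohorts(ages, numeric()), "cohort 1")
  expect_true(all(co0 == 1L))
  expect_error(assign_cohorts(ages, c(130, 60)), "strictly increasing")
})

test_that("CBAP hits its endpoints exactly and is a basal-area proportion", {
  trees <- toy_plot(rep(10, 10), dbh = c(25, 20, 15, 10, 12, 9, 14, 30, 22, 18))
  expect_equal(compute_cbap(trees, rep(1L, 10)), 0)
  expect_equal(compute_cbap(trees, rep(2L, 10)), 1)
  expect_equal(compute_cbap(trees, c(rep(2L, 5), rep(3L, 5))), 1)
  # equal-BA split gives one half
  tr2 <- toy_plot(rep(10, 4), dbh = c(10, 20, 20, 10))
  expect_equal(compute_cbap(tr2, c(1L, 1L, 2L, 2L)), 0.5)
  # order invariance and DBH-rescaling invariance
  set.seed(1)
  co <- sample(1:3, 10, replace = TRUE)
  v0 <- compute_cbap(trees, co)
  perm <- sample(10)
  expect_equal(compute_cbap(trees[perm, ], co[perm]), v0)
  tr3 <- trees; tr3$dbh_cm <- 2.5 * tr3$dbh_cm
  expect_equal(compute_cbap(tr3, co), v0)
  expect_error(compute_cbap(toy_plot(10, dbh = 0), 1L), "zero")
})

test_that("synthetic stands land in the calibration envelopes", {
  st <- simulate_stand(seed = 5)
  inv <- classify_canopy(st$trees)
  dh <- attr(inv, "dh")
  expect_true(all(dh > 12 & dh < 18.5))
  expect_true(all(table(inv$canopy_layer) > 0))
  s <- stand_summary(inv[inv$plot_id == inv$plot_id[1], ],
                     ages = setNames(st$truth$age, st$truth$tree_id))
  expect_true(s$tree_density_ha > 500 && s$tree_density_ha < 2000)
  expect_true(s$mean_height_m > 8 && s$mean_height_m < 14)
})
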