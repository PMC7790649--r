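test_that("constant series has zero growth change at every defined year", {
  gc <- percent_growth_change(const_series(40))
  expect_equal(gc$gc, rep(0, nrow(gc)))
  expect_equal(as.character(unique(gc$class)), "none")
  # defined years: both 10-year windows complete
  expect_equal(gc$year, (1900 + 9):(1900 + 29))
})

test_that("a 1.5x step in window means gives exactly 50 percent at the boundary", {
  gc <- percent_growth_change(step_series(1.0, 1.5))
  expect_equal(nrow(gc), 1L)            # only one year has two full windows
  expect_equal(gc$gc, 50)
  expect_equal(as.character(gc$class), "major_release")
  expect_equal(gc$year, 1909)
})

test_that("class boundaries follow the printed inequalities", {
  thr <- release_thresholds()
  expect_equal(as.character(classify_growth_change(50, thr)), "major_release")
  expect_equal(as.character(classify_growth_change(49.999, thr)), "minor_release")
  expect_equal(as.character(classify_growth_change(25, thr)), "minor_release")
  expect_equal(as.character(classify_growth_change(24.999, thr)), "none")
  expect_equal(as.character(classify_growth_change(10, thr)), "none")
  expect_equal(as.character(classify_growth_change(-24.999, thr)), "none")
  expect_equal(as.character(classify_growth_change(-25, thr)), "minor_suppression")
  expect_equal(as.character(classify_growth_change(-49.999, thr)), "minor_suppression")
  expect_equal(as.character(classify_growth_change(-50, thr)), "major_suppression")
  expect_true(is.na(classify_growth_change(NA_real_, thr)))
})

test_that("%GC equals the brute-force two-window oracle on random series", {
  set.seed(21)
  for (r in 1:200) {
    L <- sample(20:90, 1L)
    w <- round(runif(L, 0, 3), 2)
    s <- ring_series("T", w, 1800L)
    gc <- percent_growth_change(s)
    oracle <- gc_oracle(w)
    expect_equal(gc$gc, oracle[10:(L - 10)], tolerance = 1e-12)
  }
})

test_that("zero first-window mean flags the year instead of erroring", {
  w <- c(rep(0, 10), rep(1, 10))
  gc <- percent_growth_change(ring_series("T", w, 1900L))
  expect_true(gc$undefined[1L])
  expect_true(is.na(gc$gc[1L]))
  expect_error(percent_growth_change(const_series(19)), "too short")
})

test_that("a clean multiplicative 1.6 step is a major release at the step year", {
  gc <- percent_growth_change(ring_series("T", c(rep(0.5, 15), rep(0.8, 15)),
                                          1900L))
  at_step <- gc[gc$year == 1914, ]
  expect_equal(at_step$gc, 60)
  expect_equal(as.character(at_step$class), "major_release")
})

test_that("site chronology percentages count eligible trees per year", {
  one <- percent_growth_change(step_series(1, 2, 10, 10, id = "A"))
  ch <- site_change_chronology(list(one), "S")
  expect_equal(ch$major_release[ch$year == 1909], 100)
  two <- percent_growth_change(const_series(20, id = "B"))
  ch2 <- site_change_chronology(list(one, two), "S")
  expect_equal(ch2$major_release[ch2$year == 1909], 50)
  expect_equal(ch2$n_trees[ch2$year == 1909], 2L)
  expect_equal(ch2$all_releases, ch2$major_release + ch2$minor_release)
  # exclusive classes never sum above 100
  st <- simulate_stand(seed = 3)
  gc <- do.call(rbind, lapply(st$series[1:40], percent_growth_change))
  ch3 <- site_change_chronology(gc, "S")
  sums <- ch3$major_release + ch3$minor_release + ch3$minor_suppression +
    ch3$major_suppression
  expect_true(all(sums <= 100 + 1e-9))
  # every defined tree-year carries exactly one class
  expect_true(all(!is.na(gc$class[!is.na(gc$gc)])))
})

test_that("loess smoothing reproduces constants, lines, and the WLS oracle", {
  x <- 1:40
  expect_equal(loess_smooth(x, rep(5, 40)), rep(5, 40), tolerance = 1e-8)
  y_lin <- 2 + 0.3 * x
  expect_equal(loess_smooth(x, y_lin), y_lin, tolerance = 1e-8)
  set.seed(5)
  y <- sin(x / 5) + rnorm(40, 0, 0.15)
  got <- loess_smooth(x, y, span = 0.5, degree = 2)
  want <- loess_oracle(as.numeric(x), y, span = 0.5, degree = 2)
  interior <- 5:36
  expect_equal(got[interior], want[interior], tolerance = 1e-6)
  expect_error(loess_smooth(1:3, 1:3), "too few")
  expect_error(loess_smooth(x, y, span = 0), "span")
})

test_that("peak detection finds constructed bumps and ignores flat curves", {
  mkchron <- function(y, years = seq_along(y) + 1899) {
    data.frame(year = years, n_trees = 100L, all_releases = y,
               smoothed_all_releases = y)
  }
  expect_equal(nrow(detect_release_peaks(mkchron(rep(3, 80)))), 0L)
  yrs <- 1900:1999
  bump <- function(c0) 40 * exp(-((yrs - c0) / 6)^2)
  ch <- mkchron(bump(1930) + bump(1970), yrs)
  pk <- detect_release_peaks(ch, min_height = 10, min_separation = 15,
                             span = 0.2)
  expect_equal(nrow(pk), 2L)
  expect_true(all(abs(pk$peak_year - c(1930, 1970)) <= 3))
  expect_true(all(pk$start_year < pk$peak_year & pk$peak_year < pk$end_year))
  # low-sample-depth years are excluded from detection
  ch$n_trees[ch$year < 1940] <- 3L
  pk2 <- detect_release_peaks(ch, min_height = 10, min_separation = 15,
                              span = 0.2, min_trees = 10)
  expect_equal(nrow(pk2), 1L)
})

test_that("pattern-by-section frequencies use the any-year-in-section rule", {
  s <- ring_series("A", c(rep(0.5, 60), rep(1.2, 20)), 1900L)
  gc <- percent_growth_change(s)
  prof <- segment_series(s)
  part <- structure(list(k = 1L, cluster = c(A = 1L), labels = NULL),
                    class = "pattern_partition")
  freq <- pattern_section_frequencies(list(gc), list(prof), part)
  # the step at ring 61 puts major releases around sections 14-16
  got <- freq[freq$class == "major_release" & freq$percent > 0, ]
  expect_true(all(got$percent == 100))
  expect_true(all(got$section %in% 13:17))
  # suppressed-free series produce an all-zero table
  s2 <- const_series(80, id = "A")
  freq2 <- pattern_section_frequencies(list(percent_growth_change(s2)),
                                       list(segment_series(s2)), part)
  expect_true(all(freq2$percent == 0))
  # missing tree in the partition is an error listing the id
  part_bad <- structure(list(k = 1L, cluster = c(B = 1L), labels = NULL),
                        class = "pattern_partition")
  expect_error(pattern_section_frequencies(list(gc), list(prof), part_bad),
               "A")
})

test_that("threshold constructor enforces its invariants", {
  expect_error(release_thresholds(major = 20, minor = 25), "major > minor")
  expect_error(release_thresholds(window = 1), "window")
  thr <- release_thresholds(major = 40, minor = 20, window = 5)
  gc <- percent_growth_change(step_series(1, 1.3, 5, 5), thr)
  expect_equal(gc$gc, 30)
  expect_equal(as.character(gc$class), "minor_release")
})
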