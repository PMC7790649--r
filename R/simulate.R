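#' Outbreak schedule
#'
#' Episodes of insect-outbreak-driven canopy mortality. Each episode has a
#' start year, an end year and a severity in (0, 1]: the probability that a
#' waiting (responsive) understory tree is released by that episode. The
#' default schedule mirrors the four documented release periods of the
#' spruce-budworm region the generator emulates: 1870-1890, 1910-1940,
#' 1950-1960 and 1975-1990.
#'
#' @param periods list of `c(start, end)` year pairs, ordered and
#'   non-overlapping.
#' @param severities numeric vector in (0, 1], one per period. The default
#'   1 makes every waiting tree respond to its first eligible episode;
#'   lower values let trees skip an episode and wait for the next.
#' @return data.frame of class `outbreak_schedule` (start, end, severity).
#' @export
build_outbreak_schedule <- function(periods = list(c(1870, 1890),
                                                   c(1910, 1940),
                                                   c(1950, 1960),
                                                   c(1975, 1990)),
                                    severities = rep(1, length(periods))) {
  if (!length(periods)) {
    out <- data.frame(start = integer(), end = integer(),
                      severity = numeric())
    class(out) <- c("outbreak_schedule", "data.frame")
    return(out)
  }
  if (length(severities) != length(periods))
    stop("need one severity per period")
  start <- vapply(periods, `[[`, 0, 1L)
  end <- vapply(periods, `[[`, 0, 2L)
  if (any(end < start)) stop("episode end before start")
  if (any(severities <= 0 | severities > 1))
    stop("severities must lie in (0, 1]")
  o <- order(start)
  start <- start[o]; end <- end[o]; severities <- severities[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("outbreak episodes overlap")
  out <- data.frame(start = as.integer(start), end = as.integer(end),
                    severity = severities)
  class(out) <- c("outbreak_schedule", "data.frame")
  out
}

#' Library of archetypal growth-pattern templates
#'
#' The nine archetypes observed in outbreak-driven old-growth stands, as a
#' template table for the simulator. Each template is a mechanistic recipe:
#' the tree grows at `baseline_mm` (after a short establishment ramp),
#' waits out a juvenile suppression of `juvenile_years`, is released by the
#' first outbreak episode ending after that wait (step to `baseline_mm x
#' multiplier`, one major step), and may then decline exponentially at
#' `decline_rate` per year:
#' \itemize{
#'   \item linear: never released; narrow constant growth.
#'   \item bell (low/high): released young (short juvenile wait), so growth
#'     peaks in the first half of life and declines afterwards.
#'   \item ascending (low/moderate/high): long suppression, late release,
#'     no decline - growth still rising at the bark.
#'   \item sine (low/moderate/high): mid-life release followed by a marked
#'     decline over the last third.
#' }
#' `birth_min`/`birth_max` give the default establishment window used by
#' [simulate_stand()]; together with the default schedule they place each
#' release at the life stage that produces the template's shape, and keep
#' simulated ages inside the 55-271 year envelope of the stands emulated.
#'
#' @return data.frame, one row per template.
#' @export
pattern_templates <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name               baseline_mm multiplier juvenile_years decline_rate release_offset birth_min birth_max
linear                    0.42        1.0            Inf        0.000              1      1810      1925
low_bell                  0.65       1.50              8        0.012              1      1916      1928
high_bell                 0.80        2.6              5        0.016              1      1918      1930
low_ascending             0.18       1.45             90        0.000              1      1765      1779
moderate_ascending        0.30        3.0             55        0.000              1      1925      1935
high_ascending            0.38        4.6             70        0.004              1      1898      1904
low_sine                  0.26        3.0             50        0.020              1      1898      1906
moderate_sine             0.34        4.2             45        0.020              1      1882      1888
high_sine                 0.42        5.2             40        0.022              1      1906      1912
")
}

#' Default simulation configuration
#'
#' Study-condition defaults for [simulate_stand()]: per-template tree
#' counts (20 each, 7 for the rare high-bell archetype), multiplicative
#' lognormal AR(1) ring noise (sigma 0.15, autocorrelation 0.3), the
#' sampling year 2009, a height allometry `h = 1.3 + a * dbh^b * lognormal`
#' calibrated to dominant heights of 13-18 m, a black-spruce-dominated
#' species mix, four 400-m2 plots and two 5-m2 sapling subplots per plot.
#'
#' @param ... named overrides of any default.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    end_year = 2009L,
    n_per_template = c(linear = 20L, low_bell = 20L, high_bell = 7L,
                       low_ascending = 20L, moderate_ascending = 20L,
                       high_ascending = 20L, low_sine = 20L,
                       moderate_sine = 20L, high_sine = 20L),
    noise_sigma = 0.15,
    ar1 = 0.3,
    ramp_years = 5L,
    height_a = 1.75, height_b = 0.6, height_sigma = 0.16,
    bark_cm = 1.2, radial_expansion = 1.08,
    dbh_sigma = 0.04,
    prop_dead = 0.08, prop_broken = 0.10,
    species_mix = c(PIMA = 0.75, ABBA = 0.25),
    n_plots = 4L, plot_area_m2 = 400,
    sapling_mean = 5, sapling_subplots = 2L, sapling_area_m2 = 5,
    site_id = "SYN1")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (abs(cfg$ar1) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1")
  if (cfg$plot_area_m2 <= 0 || cfg$sapling_area_m2 <= 0)
    stop("areas must be positive")
  structure(cfg, class = "sim_config")
}

# release year of a tree: first episode whose end falls after the juvenile
# wait, thinned by episode severity (draws from the current RNG stream)
.draw_release_year <- function(birth_year, juvenile_years, schedule,
                               end_year, offset) {
  if (!nrow(schedule) || !is.finite(juvenile_years)) return(NA_integer_)
  ready <- birth_year + juvenile_years
  for (i in seq_len(nrow(schedule))) {
    if (schedule$end[i] < ready || schedule$end[i] >= end_year) next
    if (stats::runif(1L) <= schedule$severity[i])
      return(as.integer(schedule$end[i] + offset))
  }
  NA_integer_
}

#' Simulate one outbreak-driven ring-width series
#'
#' Builds a deterministic level curve from the template (establishment
#' ramp, juvenile suppression, a single-step release triggered by the first
#' sufficiently late outbreak episode, exponential post-release decline)
#' and multiplies it by lognormal AR(1) noise. All widths are strictly
#' positive and, given a seed, the series is fully reproducible.
#'
#' @param template one row of [pattern_templates()] (data.frame or list).
#' @param birth_year year of the first ring.
#' @param schedule an [build_outbreak_schedule()] result.
#' @param config a [sim_config()].
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param tree_id identifier for the series.
#' @return list: `series` (a [ring_series()]) and `release_year` (NA when
#'   the tree was never released).
#' @export
simulate_ring_series <- function(template, birth_year,
                                 schedule = build_outbreak_schedule(),
                                 config = sim_config(), seed = NULL,
                                 tree_id = "sim") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  template <- as.list(template)
  if (birth_year >= config$end_year)
    stop("birth_year must precede the simulation end year")
  yrs <- birth_year:(config$end_year - 1L)
  n <- length(yrs)
  rel <- .draw_release_year(birth_year, template$juvenile_years, schedule,
                            config$end_year, template$release_offset)
  level <- rep(template$baseline_mm, n)
  if (!is.na(rel)) {
    i <- which(yrs >= rel)
    level[i] <- template$baseline_mm * template$multiplier *
      exp(-template$decline_rate * (yrs[i] - rel))
  }
  ramp <- min(config$ramp_years, n)
  if (ramp > 1L)
    level[seq_len(ramp)] <- level[seq_len(ramp)] *
      seq(0.75, 1, length.out = ramp)
  if (config$noise_sigma > 0) {
    z <- stats::rnorm(n)
    e <- numeric(n)
    e[1L] <- config$noise_sigma * z[1L]
    if (n > 1L)
      for (t in 2:n)
        e[t] <- config$ar1 * e[t - 1L] +
          config$noise_sigma * sqrt(1 - config$ar1^2) * z[t]
    level <- level * exp(e)
  }
  list(series = ring_series(tree_id, level, as.integer(birth_year),
                            site_id = config$site_id),
       release_year = rel)
}

#' Simulate a stand: ring series, inventory, saplings and truth tables
#'
#' Draws trees from every template in [pattern_templates()] (counts set by
#' `config$n_per_template`), simulates their ring series against the
#' outbreak schedule, and derives the plot inventory: DBH from the summed
#' ring widths (plus bark and a cross-section expansion), height from a
#' noisy allometry on DBH, species from the configured mix, vitality and
#' crown status from the configured rates, and a round-robin random plot
#' assignment. Truth tables record each tree's template (pattern), release
#' year and cohort (1 = established before the first scheduled episode),
#' so recovery by the analysis modules can be scored.
#'
#' @param config a [sim_config()].
#' @param schedule an [build_outbreak_schedule()] result.
#' @param seed integer seed.
#' @return list of class `sim_stand`: `series` (named list of
#'   [ring_series()]), `trees` (inventory data.frame), `saplings`
#'   (data.frame plot_id, count, area_m2), `truth` (data.frame tree_id,
#'   template, shape, level, birth_year, age, release_year, cohort),
#'   `schedule`, `config`.
#' @export
simulate_stand <- function(config = sim_config(),
                           schedule = build_outbreak_schedule(),
                           seed = 1L) {
  set.seed(as.integer(seed))
  templates <- pattern_templates()
  counts <- config$n_per_template
  total <- sum(counts)
  if (total == 0L) {
    empty_inv <- data.frame(tree_id = character(), species = character(),
                            dbh_cm = numeric(), height_m = numeric(),
                            vitality = character(), crown_status = character(),
                            plot_id = character(), plot_area_m2 = numeric())
    return(structure(list(series = list(), trees = empty_inv,
                          saplings = data.frame(plot_id = character(),
                                                count = integer(),
                                                area_m2 = numeric()),
                          truth = data.frame(), schedule = schedule,
                          config = config),
                     class = "sim_stand"))
  }
  series <- list()
  truth <- list()
  idx <- 0L
  for (tn in names(counts)) {
    tmpl <- templates[templates$name == tn, ]
    if (!nrow(tmpl)) stop("unknown template in n_per_template: ", tn)
    for (j in seq_len(counts[[tn]])) {
      idx <- idx + 1L
      id <- sprintf("T%03d", idx)
      birth <- sample(tmpl$birth_min:tmpl$birth_max, 1L)
      sim <- simulate_ring_series(tmpl, birth, schedule, config,
                                  seed = NULL, tree_id = id)
      series[[id]] <- sim$series
      shape <- sub("^(low|moderate|high)_", "", tn)
      level <- if (grepl("_", tn)) sub("_.*$", "", tn) else "none"
      truth[[id]] <- data.frame(
        tree_id = id, template = tn, shape = shape, level = level,
        birth_year = birth, age = length(sim$series$widths),
        release_year = sim$release_year,
        cohort = if (nrow(schedule) && birth < schedule$start[1L]) 1L else 2L,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  # inventory: DBH from cumulative radial growth, height from allometry
  radius_mm <- vapply(series, function(s) sum(s$widths), 0)
  dbh <- (2 * radius_mm / 10) * config$radial_expansion *
    exp(stats::rnorm(total, 0, config$dbh_sigma)) + config$bark_cm
  # only merchantable stems (DBH >= 9 cm) enter the inventory; slower trees
  # are pinned just above the threshold rather than dropped, so the ring
  # collection and the inventory stay aligned
  dbh <- pmax(dbh, 9 + abs(stats::rnorm(total, 0, 0.25)))
  height <- 1.3 + config$height_a * dbh^config$height_b *
    exp(stats::rnorm(total, 0, config$height_sigma))
  trees <- data.frame(
    tree_id = truth$tree_id,
    species = sample(names(config$species_mix), total, replace = TRUE,
                     prob = config$species_mix),
    dbh_cm = round(dbh, 1),
    height_m = round(height, 1),
    vitality = ifelse(stats::runif(total) < config$prop_dead,
                      "dead", "alive"),
    crown_status = ifelse(stats::runif(total) < config$prop_broken,
                          "broken", "intact"),
    plot_id = sample(paste0(config$site_id, "-P",
                            seq_len(config$n_plots))[
                              1L + (seq_len(total) - 1L) %% config$n_plots]),
    plot_area_m2 = config$plot_area_m2,
    stringsAsFactors = FALSE)
  saplings <- do.call(rbind, lapply(seq_len(config$n_plots), function(p) {
    data.frame(plot_id = paste0(config$site_id, "-P", p),
               count = sum(stats::rpois(config$sapling_subplots,
                                        config$sapling_mean)),
               area_m2 = config$sapling_subplots * config$sapling_area_m2)
  }))
  structure(list(series = series, trees = trees, saplings = saplings,
                 truth = truth, schedule = schedule, config = config),
            class = "sim_stand")
}

#' @export
print.sim_stand <- function(x, ...) {
  cat(sprintf("<sim_stand> %d trees, %d plots, %d outbreak episodes\n",
              length(x$series),
              length(unique(x$trees$plot_id)),
              nrow(x$schedule)))
  invisible(x)
}
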