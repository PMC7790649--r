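#' Release / suppression classification thresholds
#'
#' Percent-growth-change thresholds: a major release is %GC >= `major`
#' (default 50), a minor release `[minor, major)`, a minor suppression
#' `(-major, -minor]`, a major suppression <= `-major`; everything else is
#' `none`. `window` is the length in years of each of the two averaging
#' windows (default 10).
#'
#' @param major,minor percent thresholds, `major > minor > 0`.
#' @param window window length in years, >= 2.
#' @return list of class `release_thresholds`.
#' @export
release_thresholds <- function(major = 50, minor = 25, window = 10L) {
  if (!(major > minor && minor > 0)) stop("need major > minor > 0")
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 years")
  structure(list(major = major, minor = minor, window = window),
            class = "release_thresholds")
}

#' Growth-change class labels, most positive first
#' @return character vector of the five class labels.
#' @export
gc_classes <- function() {
  c("major_release", "minor_release", "none",
    "minor_suppression", "major_suppression")
}

#' Classify percent-growth-change values
#'
#' Boundary conventions follow the defining inequalities: `>= major` is a
#' major release, `[minor, major)` a minor release, `(-major, -minor]` a
#' minor suppression, `<= -major` a major suppression.
#'
#' @param gc numeric vector of %GC values (percent); NA stays NA.
#' @param thresholds a [release_thresholds()].
#' @return factor with levels [gc_classes()].
#' @export
classify_growth_change <- function(gc, thresholds = release_thresholds()) {
  out <- rep(NA_character_, length(gc))
  ok <- is.finite(gc)
  g <- gc[ok]
  cls <- rep("none", length(g))
  cls[g >= thresholds$major] <- "major_release"
  cls[g >= thresholds$minor & g < thresholds$major] <- "minor_release"
  cls[g <= -thresholds$minor & g > -thresholds$major] <- "minor_suppression"
  cls[g <= -thresholds$major] <- "major_suppression"
  out[ok] <- cls
  factor(out, levels = gc_classes())
}

#' Percent growth change of a ring series
#'
#' For each year t with two complete windows, compares the mean ring width
#' of the preceding window (M1, years `t-window+1 .. t`, inclusive of t)
#' with the mean of the subsequent window (M2, years `t+1 .. t+window`):
#' \deqn{\%GC = (M2 - M1)/M1 \times 100.}
#' Edge years without two full windows are omitted rather than computed on
#' truncated windows. Years where M1 = 0 get `NA` %GC and are flagged.
#'
#' @param series a [ring_series()].
#' @param thresholds a [release_thresholds()]; sets the window length and
#'   the class boundaries.
#' @return data.frame of class `gc_series`: tree_id, year, m1, m2, gc,
#'   class (factor), undefined (logical flag for M1 = 0 years).
#' @export
percent_growth_change <- function(series, thresholds = release_thresholds()) {
  stopifnot(inherits(series, "ring_series"))
  w <- series$widths
  win <- thresholds$window
  L <- length(w)
  if (L < 2L * win)
    stop(sprintf("series too short for %%GC: %d rings < 2 x %d-year windows",
                 L, win))
  cs <- cumsum(c(0, w))
  t_idx <- win:(L - win)                       # positions with both windows
  m1 <- (cs[t_idx + 1L] - cs[t_idx + 1L - win]) / win
  m2 <- (cs[t_idx + 1L + win] - cs[t_idx + 1L]) / win
  gc <- ifelse(m1 == 0, NA_real_, (m2 - m1) / m1 * 100)
  out <- data.frame(tree_id = series$tree_id,
                    year = series_years(series)[t_idx],
                    m1 = m1, m2 = m2, gc = gc,
                    class = classify_growth_change(gc, thresholds),
                    undefined = m1 == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("gc_series", "data.frame")
  out
}

#' Site-level release/suppression chronology
#'
#' For each calendar year, the percentage of trees (among those with a
#' defined %GC that year) in each growth-change class, plus the combined
#' `all_releases` (minor + major) and `all_suppressions` percentages and
#' their loess-smoothed curves. Years with no eligible tree are omitted.
#'
#' @param gc_list list of `gc_series` (one per tree) or one stacked
#'   data.frame.
#' @param site_id site label stored on the result.
#' @param span,degree loess smoothing parameters (fraction of points;
#'   polynomial degree).
#' @return data.frame of class `site_chronology`: year, n_trees, one
#'   percentage column per class, all_releases, all_suppressions, and
#'   smoothed_* columns; attribute `site_id`.
#' @export
site_change_chronology <- function(gc_list, site_id = "site",
                                   span = 0.5, degree = 2L) {
  gc <- if (is.data.frame(gc_list)) gc_list else do.call(rbind, gc_list)
  if (!nrow(gc)) stop("no growth-change records supplied")
  gc <- gc[!is.na(gc$gc), , drop = FALSE]
  if (!nrow(gc)) stop("no defined %GC values supplied")
  years <- sort(unique(gc$year))
  n <- as.integer(table(factor(gc$year, levels = years)))
  out <- data.frame(year = years, n_trees = n)
  for (cl in gc_classes()) {
    cnt <- tapply(gc$class == cl, factor(gc$year, levels = years), sum)
    out[[cl]] <- 100 * as.numeric(cnt) / n
  }
  out$all_releases <- out$major_release + out$minor_release
  out$all_suppressions <- out$major_suppression + out$minor_suppression
  for (col in c("all_releases", "all_suppressions")) {
    out[[paste0("smoothed_", col)]] <-
      if (nrow(out) >= degree + 2L)
        loess_smooth(out$year, out[[col]], span = span, degree = degree)
      else out[[col]]
  }
  attr(out, "site_id") <- site_id
  class(out) <- c("site_chronology", "data.frame")
  out
}

#' Loess smoothing of a chronology curve
#'
#' Local polynomial regression with tricube weights over the span-nearest
#' neighbours, evaluated at each input point (the smoother used for site
#' chronologies, with a 50% span).
#'
#' @param x,y numeric vectors (e.g. years and percentages).
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param degree local polynomial degree (1 or 2).
#' @return numeric vector of smoothed values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.5, degree = 2L) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < degree + 2L)
    stop("too few points for loess smoothing")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Detect release peaks in a site chronology
#'
#' Finds local maxima of the combined-release percentage curve, smoothed at
#' a detection scale, with height at least `min_height` percent and
#' pairwise separation of at least `min_separation` years (when two
#' candidate peaks are closer, the higher one is kept). Each peak is
#' reported with its bounding interval: the years of the nearest flanking
#' local minima of the smoothed curve.
#'
#' Two practical choices distinguish detection from display. First, years
#' with fewer than `min_trees` trees of sample depth are dropped: with a
#' handful of old trees a single release reads as a huge percentage, which
#' is sampling noise, not a disturbance signal. Second, the curve is
#' re-smoothed with a narrower `span` than the wide display smoothing of
#' the chronology plots, because a half-span loess over two centuries
#' flattens adjacent decadal-scale release episodes into a single bump;
#' a 20% span keeps them apart while still suppressing year-to-year noise.
#'
#' @param chronology a [site_change_chronology()] result.
#' @param min_height minimum smoothed release percentage of a peak
#'   (default 10: a tenth of the stand releasing at once).
#' @param min_separation minimum distance between peak years, in years.
#' @param span loess span used for detection.
#' @param min_trees minimum sample depth (trees with defined %GC) for a
#'   year to take part in detection.
#' @return data.frame (peak_year, height, start_year, end_year), possibly
#'   with zero rows.
#' @export
detect_release_peaks <- function(chronology, min_height = 10,
                                 min_separation = 15, span = 0.2,
                                 min_trees = 10L) {
  chronology <- chronology[chronology$n_trees >= min_trees, , drop = FALSE]
  yr <- chronology$year
  s <- if (nrow(chronology) >= 4L)
    loess_smooth(yr, chronology$all_releases, span = span)
  else chronology$all_releases
  n <- length(s)
  if (n < 3L)
    return(data.frame(peak_year = integer(), height = numeric(),
                      start_year = integer(), end_year = integer()))
  # run-length compression makes plateau maxima single candidates; maxima
  # touching the chronology edges count too (a response to the most recent
  # outbreak is typically still rising when sampling cuts the record off)
  r <- rle(s)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer()
  if (nr >= 3L)
    for (j in 2:(nr - 1L))
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        cand <- c(cand, (run_start[j] + run_end[j]) %/% 2L)
  if (nr >= 2L) {
    if (r$values[1L] > r$values[2L]) cand <- c(1L, cand)
    if (r$values[nr] > r$values[nr - 1L]) cand <- c(cand, n)
  }
  cand <- cand[s[cand] >= min_height]
  if (!length(cand))
    return(data.frame(peak_year = integer(), height = numeric(),
                      start_year = integer(), end_year = integer()))
  # greedy: keep highest peaks, enforce separation
  cand <- cand[order(-s[cand], yr[cand])]
  kept <- integer()
  for (i in cand)
    if (!length(kept) || all(abs(yr[i] - yr[kept]) >= min_separation))
      kept <- c(kept, i)
  kept <- sort(kept)
  mins <- c(1L)
  if (nr >= 3L)
    for (j in 2:(nr - 1L))
      if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L])
        mins <- c(mins, (run_start[j] + run_end[j]) %/% 2L)
  mins <- sort(unique(c(mins, n)))
  data.frame(
    peak_year = yr[kept],
    height = s[kept],
    start_year = vapply(kept, function(i) {
      lo <- mins[mins < i]
      yr[if (length(lo)) max(lo) else 1L]
    }, 0L),
    end_year = vapply(kept, function(i) {
      hi <- mins[mins > i]
      yr[if (length(hi)) min(hi) else n]
    }, 0L))
}

#' Release/suppression frequency by growth pattern and section
#'
#' A tree counts for (pattern, section, class) when any year inside that
#' section's calendar span carries that growth-change class; frequencies
#' are percentages of the trees belonging to the pattern. Mirrors the
#' pattern-by-section frequency panels used to interpret the growth
#' patterns.
#'
#' @param gc_list list of `gc_series` or a stacked data.frame.
#' @param profiles list of `segment_profile` (year spans of the sections).
#' @param partition a labeled `pattern_partition` (see [name_patterns()]);
#'   an unlabeled one uses cluster numbers as pattern names.
#' @return data.frame (pattern, section, class, n_trees, percent).
#' @export
pattern_section_frequencies <- function(gc_list, profiles, partition) {
  gc <- if (is.data.frame(gc_list)) gc_list else do.call(rbind, gc_list)
  prof_ids <- vapply(profiles, `[[`, "", "tree_id")
  names(profiles) <- prof_ids
  ids <- unique(gc$tree_id)
  missing_part <- setdiff(ids, names(partition$cluster))
  if (length(missing_part))
    stop("trees missing from the partition: ",
         paste(utils::head(missing_part, 5L), collapse = ", "))
  missing_prof <- setdiff(ids, prof_ids)
  if (length(missing_prof))
    stop("trees missing segment profiles: ",
         paste(utils::head(missing_prof, 5L), collapse = ", "))
  pat_of <- function(cl)
    if (!is.null(partition$labels)) partition$labels$pattern[cl]
    else paste0("cluster_", cl)
  tree_pattern <- stats::setNames(pat_of(as.integer(partition$cluster)),
                                  names(partition$cluster))
  n_seg <- profiles[[1L]]$n_segments
  pats <- sort(unique(tree_pattern[ids]))
  classes <- setdiff(gc_classes(), "none")
  counts <- array(0L, dim = c(length(pats), n_seg, length(classes)),
                  dimnames = list(pats, NULL, classes))
  pat_n <- table(factor(tree_pattern[ids], levels = pats))
  gc_by_tree <- split(gc, gc$tree_id)
  for (id in ids) {
    g <- gc_by_tree[[id]]
    p <- profiles[[id]]
    pat <- tree_pattern[[id]]
    for (s in seq_len(n_seg)) {
      in_seg <- g$year >= p$first_years[s] & g$year <= p$last_years[s]
      if (!any(in_seg)) next
      present <- intersect(unique(as.character(g$class[in_seg])), classes)
      for (cl in present) counts[pat, s, cl] <- counts[pat, s, cl] + 1L
    }
  }
  out <- expand.grid(pattern = pats, section = seq_len(n_seg),
                     class = classes, stringsAsFactors = FALSE)
  out$n_trees <- mapply(function(p, s, cl) counts[p, s, cl],
                        out$pattern, out$section, out$class)
  out$percent <- 100 * out$n_trees / as.numeric(pat_n[out$pattern])
  out[order(out$pattern, out$section, out$class), , drop = FALSE]
}
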