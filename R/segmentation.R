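#' Resample a ring series into near-equal segments
#'
#' Divides a tree's ring-width series into `n_segments` contiguous segments
#' each holding a near-equal number of rings (counts never differ by more
#' than one ring), so that trees of different ages can be compared on a
#' common 20-variable growth profile. The first segment starts at the first
#' ring after the pith and the last segment ends at the last ring.
#'
#' Segment boundaries follow the cumulative-quota rule: segment i (1-based)
#' holds rings `floor((i-1)*L/n) + 1` through `floor(i*L/n)`, which spreads
#' the longer segments evenly along the series and is deterministic.
#'
#' @param series a [ring_series()].
#' @param n_segments number of segments (default 20).
#' @return An object of class `segment_profile`: a list with `tree_id`,
#'   `means` (mm), `counts`, `first_years`, `last_years`.
#' @export
segment_series <- function(series, n_segments = 20L) {
  stopifnot(inherits(series, "ring_series"))
  L <- length(series$widths)
  n <- as.integer(n_segments)
  if (n < 1L) stop("n_segments must be >= 1")
  if (L < n)
    stop(sprintf("series too short to segment: %d rings < %d segments", L, n))
  bounds <- floor(seq_len(n) * L / n)
  starts <- c(0L, bounds[-n]) + 1L
  yrs <- series_years(series)
  idx <- Map(seq, starts, bounds)
  structure(
    list(tree_id = series$tree_id,
         n_segments = n,
         means = vapply(idx, function(j) mean(series$widths[j]), 0),
         counts = as.integer(bounds - starts + 1L),
         first_years = yrs[starts],
         last_years = yrs[bounds]),
    class = "segment_profile"
  )
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %s: %d segments over %d rings\n",
              x$tree_id, x$n_segments, sum(x$counts)))
  invisible(x)
}

#' Tabulate segment profiles
#' @param profiles list of `segment_profile` objects.
#' @return Long data.frame (tree_id, segment, mean_mm, n_rings, first_year,
#'   last_year).
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(tree_id = p$tree_id, segment = seq_len(p$n_segments),
               mean_mm = p$means, n_rings = p$counts,
               first_year = p$first_years, last_year = p$last_years,
               stringsAsFactors = FALSE)
  }))
}

#' Scale and center segment profiles into a clustering matrix
#'
#' Stacks the per-segment mean widths of all trees into a trees x segments
#' matrix and standardizes each segment column to mean 0 and sd 1, treating
#' each segment as a separate explanatory variable. The per-column centers
#' and scales are stored so raw (mm) cluster centers can be recovered.
#'
#' @param profiles list of `segment_profile` objects with equal
#'   `n_segments`.
#' @return An object of class `segment_matrix`: list with `x` (standardized
#'   matrix, rownames = tree ids), `center`, `scale`, `raw`.
#' @export
standardize_segment_matrix <- function(profiles) {
  if (length(profiles) < 2L)
    stop("need at least 2 profiles to standardize")
  ns <- unique(vapply(profiles, function(p) p$n_segments, 0L))
  if (length(ns) != 1L) stop("profiles have differing segment counts")
  raw <- do.call(rbind, lapply(profiles, `[[`, "means"))
  rownames(raw) <- vapply(profiles, `[[`, "", "tree_id")
  colnames(raw) <- paste0("seg", seq_len(ns))
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop("segment column(s) with zero variance: ",
         paste(zero, collapse = ", "))
  x <- scale(raw, center = ctr, scale = scl)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(list(x = x, center = ctr, scale = scl, raw = raw),
            class = "segment_matrix")
}

#' Undo the standardization of a segment matrix
#' @param sm a `segment_matrix`.
#' @param x optional matrix on the standardized scale (defaults to `sm$x`);
#'   e.g. cluster centers.
#' @return Matrix on the raw mm scale.
#' @export
destandardize <- function(sm, x = sm$x) {
  stopifnot(inherits(sm, "segment_matrix"))
  sweep(sweep(x, 2L, sm$scale, "*"), 2L, sm$center, "+")
}

#' Per-tree growth attributes
#'
#' Age (ring count), mean ring width, ring-width standard deviation
#' (sample, n-1) and the 5th and 95th percentile ring widths (linear
#' interpolation between order statistics).
#'
#' @param series a [ring_series()].
#' @return data.frame with one row: tree_id, age, mean_rw, sd_rw, p5_rw,
#'   p95_rw (mm).
#' @export
growth_attributes <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  w <- series$widths
  if (length(w) < 2L) stop("need at least 2 rings to compute growth attributes")
  q <- stats::quantile(w, c(0.05, 0.95), names = FALSE, type = 7)
  data.frame(tree_id = series$tree_id, age = length(w),
             mean_rw = mean(w), sd_rw = stats::sd(w),
             p5_rw = q[[1L]], p95_rw = q[[2L]],
             stringsAsFactors = FALSE)
}

#' Growth attributes for a collection of series
#' @param series list of [ring_series()].
#' @return data.frame, one row per tree.
#' @export
growth_attribute_table <- function(series) {
  do.call(rbind, lapply(series, growth_attributes))
}
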