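#' Construct a ring-width series for one tree
#'
#' A `ring_series` holds one dated annual ring-width chronology (mm/year)
#' for a single tree, typically the per-year mean of two measured radii.
#' Years are consecutive: the i-th width belongs to `first_year + i - 1`.
#' A width of 0 encodes a locally absent ring.
#'
#' @param tree_id character scalar identifier (<= 8 characters to be
#'   representable in Tucson files).
#' @param widths numeric vector of annual ring widths in mm, all >= 0.
#' @param first_year calendar year of the first (innermost) ring.
#' @param site_id,species optional metadata (species as a 4-letter code,
#'   e.g. "PIMA" for black spruce, "ABBA" for balsam fir).
#' @param radius_id optional radius identifier; set for radius series that
#'   have not yet been merged with [combine_radii()].
#' @return An object of class `ring_series`.
#' @seealso [combine_radii()], [read_rwl()], [segment_series()]
#' @export
ring_series <- function(tree_id, widths, first_year,
                        site_id = NA_character_, species = NA_character_,
                        radius_id = NULL) {
  stopifnot(is.character(tree_id), length(tree_id) == 1L, nzchar(tree_id))
  widths <- as.numeric(widths)
  if (length(widths) < 1L) stop("ring series must contain at least one ring")
  if (anyNA(widths)) stop("ring widths must not be NA")
  if (any(widths < 0)) stop("ring widths must be >= 0 (0 encodes a missing ring)")
  first_year <- as.integer(first_year)
  structure(
    list(tree_id = tree_id, site_id = site_id, species = species,
         first_year = first_year, widths = widths, radius_id = radius_id),
    class = "ring_series"
  )
}

#' Calendar years covered by a ring series
#' @param x a `ring_series`.
#' @return Integer vector of years, one per ring.
#' @export
series_years <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  x$first_year + seq_along(x$widths) - 1L
}

#' Last (outermost) ring year of a series
#' @param x a `ring_series`.
#' @return Integer year.
#' @export
last_year <- function(x) x$first_year + length(x$widths) - 1L

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %s (%s) %d-%d, %d rings, mean %.3f mm\n",
              x$tree_id,
              if (is.na(x$species)) "?" else x$species,
              x$first_year, last_year(x), length(x$widths),
              mean(x$widths)))
  invisible(x)
}

#' @export
length.ring_series <- function(x) length(x$widths)

#' Average two radius series into one tree series
#'
#' Each tree is usually measured along two radii; the tree-level series is
#' the per-year mean of the radii. Years present in only one radius keep
#' that radius's value, so the merged span is the union of the two spans
#' and the full pith-to-bark record is preserved for ageing.
#'
#' @param a,b `ring_series` objects (radius series) of the same tree. Their
#'   calendar spans must overlap.
#' @param tree_id identifier for the merged series; defaults to `a$tree_id`.
#' @return A `ring_series` spanning the union of the input spans.
#' @export
combine_radii <- function(a, b, tree_id = a$tree_id) {
  stopifnot(inherits(a, "ring_series"), inherits(b, "ring_series"))
  if (last_year(a) < b$first_year || last_year(b) < a$first_year)
    stop("radius series have disjoint year spans; they cannot belong to one tree")
  yrs <- min(a$first_year, b$first_year):max(last_year(a), last_year(b))
  wa <- wb <- rep(NA_real_, length(yrs))
  wa[match(series_years(a), yrs)] <- a$widths
  wb[match(series_years(b), yrs)] <- b$widths
  w <- rowMeans(cbind(wa, wb), na.rm = TRUE)
  ring_series(tree_id, w, yrs[1L],
              site_id = a$site_id, species = a$species)
}

#' Convert ring series to a long table
#'
#' @param series a `ring_series` or a list of them.
#' @return A data.frame with columns `tree_id`, `year`, `width_mm`.
#' @export
as_ring_table <- function(series) {
  if (inherits(series, "ring_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s) {
    data.frame(tree_id = s$tree_id, year = series_years(s),
               width_mm = s$widths, stringsAsFactors = FALSE)
  }))
}
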