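#' Plot cluster growth profiles
#'
#' Scatter of the per-segment mean widths of every tree, faceted by the
#' cluster (growth pattern) it belongs to, with a loess curve per cluster.
#'
#' @param profiles list of `segment_profile`.
#' @param partition a (preferably labeled) `pattern_partition`.
#' @param span loess span.
#' @return A ggplot object.
#' @export
plot_pattern_clusters <- function(profiles, partition, span = 0.5) {
  tab <- profile_table(profiles)
  asg <- assignment_table(partition)
  lab <- if ("pattern" %in% names(asg)) asg$pattern else
    paste0("cluster ", asg$cluster)
  tab$pattern <- lab[match(tab$tree_id, asg$tree_id)]
  ggplot2::ggplot(tab, ggplot2::aes(x = segment, y = mean_mm)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "grey40") +
    ggplot2::geom_smooth(method = "loess", span = span, se = FALSE,
                         formula = y ~ x) +
    ggplot2::facet_wrap(~pattern, scales = "free_y") +
    ggplot2::labs(x = "section of the 20-segment series",
                  y = "mean ring width (mm)")
}

#' Plot the SSI model-selection curve
#' @param selection a [select_pattern_count()] result.
#' @return A ggplot object.
#' @export
plot_ssi_curve <- function(selection) {
  cv <- selection$curve
  best <- cv[cv$k == selection$k_best, , drop = FALSE]
  ggplot2::ggplot(cv, ggplot2::aes(x = k, y = ssi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::labs(x = "number of clusters", y = "simple structure index")
}

#' Plot a site release/suppression chronology
#'
#' Annual percentages of trees in release and suppression (points) with
#' their loess-smoothed curves, and the outbreak episodes as shaded bands.
#'
#' @param chronology a [site_change_chronology()] result.
#' @param schedule optional [build_outbreak_schedule()] drawn as bands.
#' @return A ggplot object.
#' @export
plot_release_chronology <- function(chronology, schedule = NULL) {
  long <- rbind(
    data.frame(year = chronology$year, what = "all releases",
               pct = chronology$all_releases,
               smooth = chronology$smoothed_all_releases),
    data.frame(year = chronology$year, what = "all suppressions",
               pct = chronology$all_suppressions,
               smooth = chronology$smoothed_all_suppressions))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = year))
  if (!is.null(schedule) && nrow(schedule))
    p <- p + ggplot2::annotate("rect", xmin = schedule$start,
                               xmax = schedule$end, ymin = -Inf, ymax = Inf,
                               alpha = 0.15)
  p + ggplot2::geom_point(ggplot2::aes(y = pct),
                          colour = "lightblue3", size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = smooth), colour = "darkblue") +
    ggplot2::facet_wrap(~what, ncol = 1L) +
    ggplot2::labs(x = "year", y = "% of trees")
}

#' Plot growth-pattern occurrence per canopy layer
#' @param assignments [assignment_table()] output.
#' @param inventory inventory with `canopy_layer` (see [classify_canopy()]).
#' @return A ggplot object.
#' @export
plot_layer_occurrence <- function(assignments, inventory) {
  m <- merge(assignments, inventory, by = "tree_id")
  m <- m[!is.na(m$canopy_layer), , drop = FALSE]
  tab <- as.data.frame(prop.table(table(layer = m$canopy_layer,
                                        pattern = m$pattern),
                                  margin = 1L) * 100)
  ggplot2::ggplot(tab, ggplot2::aes(x = pattern, y = Freq)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "occurrence (%)")
}
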