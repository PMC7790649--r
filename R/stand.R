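#' Dominant height of a plot
#'
#' Dominant height (DH) is the mean height of the 100 tallest trees per
#' hectare; a 400 m2 plot therefore uses its four tallest trees. Only
#' living trees enter the top set. If the plot holds fewer living trees
#' than the top-set size, all of them are used with a warning.
#'
#' @param trees inventory data.frame for one plot (columns `height_m`,
#'   `vitality`, optionally `crown_status`).
#' @param plot_area_m2 plot area; defaults to the `plot_area_m2` column.
#' @param intact_only if TRUE, broken-crown trees are excluded from the top
#'   set (default FALSE: field DH uses measured heights as-is).
#' @return DH in metres.
#' @export
dominant_height <- function(trees, plot_area_m2 = NULL, intact_only = FALSE) {
  if (is.null(plot_area_m2)) {
    plot_area_m2 <- unique(trees$plot_area_m2)
    if (length(plot_area_m2) != 1L)
      stop("trees span several plot areas; pass plot_area_m2 explicitly")
  }
  h <- trees$height_m[trees$vitality == "alive"]
  if (intact_only && "crown_status" %in% names(trees))
    h <- trees$height_m[trees$vitality == "alive" &
                          trees$crown_status == "intact"]
  h <- h[is.finite(h)]
  if (!length(h)) stop("no measured living-tree heights in plot")
  n_top <- max(1L, as.integer(round(100 * plot_area_m2 / 10000)))
  if (length(h) < n_top) {
    warning(sprintf("only %d living trees for a top set of %d; using all",
                    length(h), n_top))
    n_top <- length(h)
  }
  mean(sort(h, decreasing = TRUE)[seq_len(n_top)])
}

#' Assign a canopy layer from height and dominant height
#'
#' Layers relative to dominant height DH: `dominant` when height >= DH,
#' `codominant` when 2/3 DH <= height < DH, `intermediary` when
#' 1/2 DH < height < 2/3 DH, and `suppressed` when height <= 1/2 DH
#' (the intermediary lower bound is strict, so exactly half of DH falls in
#' the suppressed layer).
#'
#' @param height_m tree height(s), m (> 0).
#' @param dh dominant height, m (> 0).
#' @return factor with levels dominant, codominant, intermediary,
#'   suppressed.
#' @export
assign_canopy_layer <- function(height_m, dh) {
  if (any(height_m <= 0) || dh <= 0) stop("heights and DH must be positive")
  layer <- ifelse(height_m >= dh, "dominant",
           ifelse(height_m >= 2 / 3 * dh, "codominant",
           ifelse(height_m > dh / 2, "intermediary", "suppressed")))
  factor(layer, levels = canopy_layers())
}

#' Canopy layer levels, tallest first
#' @return character vector of the four layer names.
#' @export
canopy_layers <- function() {
  c("dominant", "codominant", "intermediary", "suppressed")
}

#' Add canopy layers to an inventory
#'
#' Computes DH per plot and assigns every living tree a layer; dead trees
#' get NA.
#'
#' @param inventory inventory data.frame (several plots allowed).
#' @return The inventory with a `canopy_layer` column and a `dh` attribute
#'   (named vector, one DH per plot).
#' @export
classify_canopy <- function(inventory) {
  dh <- vapply(split(inventory, inventory$plot_id), dominant_height, 0)
  alive <- inventory$vitality == "alive"
  layer <- rep(NA_character_, nrow(inventory))
  for (p in names(dh)) {
    i <- which(alive & inventory$plot_id == p)
    layer[i] <- as.character(assign_canopy_layer(inventory$height_m[i],
                                                 dh[[p]]))
  }
  inventory$canopy_layer <- factor(layer, levels = canopy_layers())
  attr(inventory, "dh") <- dh
  inventory
}

#' Basal area of a tree, m2
#' @param dbh_cm diameter at breast height, cm.
#' @return basal area(s) in m2.
#' @export
basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Stand summary statistics for one plot
#'
#' Densities per hectare (trees, snags, saplings), basal areas (m2/ha),
#' species composition as percent of living-tree basal area, height
#' statistics (max, dominant, mean, sd over living trees) and, when tree
#' ages are supplied, age statistics (oldest, mean, sd).
#'
#' @param trees inventory data.frame for one plot.
#' @param saplings optional data.frame with `count` and `area_m2` (total
#'   sapling-subplot area).
#' @param ages optional named numeric vector of tree ages (names =
#'   tree_id).
#' @return list of class `stand_summary`.
#' @export
stand_summary <- function(trees, saplings = NULL, ages = NULL) {
  area_ha <- unique(trees$plot_area_m2) / 10000
  if (length(area_ha) != 1L) stop("stand_summary expects a single plot")
  alive <- trees[trees$vitality == "alive", , drop = FALSE]
  dead <- trees[trees$vitality == "dead", , drop = FALSE]
  no_dbh <- !is.finite(alive$dbh_cm)
  if (any(no_dbh)) {
    warning("trees without DBH excluded from basal area: ",
            paste(alive$tree_id[no_dbh], collapse = ", "))
    alive_ba <- alive[!no_dbh, , drop = FALSE]
  } else alive_ba <- alive
  ba <- basal_area_m2(alive_ba$dbh_cm)
  comp <- 100 * tapply(ba, alive_ba$species, sum) / sum(ba)
  out <- list(
    plot_id = unique(trees$plot_id),
    tree_density_ha = nrow(alive) / area_ha,
    snag_density_ha = nrow(dead) / area_ha,
    sapling_density_ha = if (!is.null(saplings))
      sum(saplings$count) / (sum(saplings$area_m2) / 10000) else NA_real_,
    tree_basal_area_ha = sum(ba) / area_ha,
    snag_basal_area_ha = sum(basal_area_m2(dead$dbh_cm)) / area_ha,
    composition_pct = comp,
    max_height_m = max(alive$height_m, na.rm = TRUE),
    dominant_height_m = dominant_height(trees),
    mean_height_m = mean(alive$height_m, na.rm = TRUE),
    sd_height_m = stats::sd(alive$height_m, na.rm = TRUE))
  if (!is.null(ages)) {
    a <- ages[intersect(names(ages), alive$tree_id)]
    out$oldest_age <- max(a)
    out$mean_age <- mean(a)
    out$sd_age <- stats::sd(a)
  }
  structure(out, class = "stand_summary")
}

#' @export
print.stand_summary <- function(x, ...) {
  cat(sprintf("<stand_summary> plot %s\n", x$plot_id))
  cat(sprintf("  trees %.0f /ha (BA %.2f m2/ha), snags %.0f /ha, saplings %s /ha\n",
              x$tree_density_ha, x$tree_basal_area_ha, x$snag_density_ha,
              if (is.na(x$sapling_density_ha)) "NA"
              else sprintf("%.0f", x$sapling_density_ha)))
  cat(sprintf("  heights: max %.1f, DH %.2f, mean %.1f (sd %.1f) m\n",
              x$max_height_m, x$dominant_height_m, x$mean_height_m,
              x$sd_height_m))
  invisible(x)
}

#' Assign trees to cohorts by age cutoffs
#'
#' Cohort 1 holds the trees at least as old as the largest cutoff (i.e.
#' established before or at the last primary disturbance); each successive
#' interval between cutoffs defines the next cohort.
#'
#' @param ages numeric vector of tree ages (years); names preserved.
#' @param breaks strictly increasing age cutoffs. `c(60, 130)` makes
#'   cohort 1 = age >= 130, cohort 2 = 60 <= age < 130, cohort 3 =
#'   age < 60. Empty breaks put every tree in cohort 1 (with a warning).
#' @return integer vector of cohort indices (1 = oldest cohort).
#' @export
assign_cohorts <- function(ages, breaks) {
  if (!length(breaks)) {
    warning("no cohort breaks supplied; assigning all trees to cohort 1")
    return(stats::setNames(rep(1L, length(ages)), names(ages)))
  }
  if (is.unsorted(breaks, strictly = TRUE))
    stop("cohort breaks must be strictly increasing")
  stats::setNames(
    1L + length(breaks) - findInterval(ages, breaks),
    names(ages))
}

#' Cohort basal area proportion (CBAP)
#'
#' Degree to which post-disturbance cohorts have replaced the first
#' cohort's basal area: `1 - BA(cohort 1) / BA(all living trees)`.
#' 0 means every living tree belongs to the first cohort; 1 means the
#' first cohort has been entirely replaced (a true old-growth stand).
#'
#' @param trees inventory data.frame (living trees are used; must have
#'   `dbh_cm`).
#' @param cohorts integer cohort index per tree: either a vector aligned
#'   with `trees` rows or named by `tree_id`.
#' @return CBAP in [0, 1].
#' @export
compute_cbap <- function(trees, cohorts) {
  alive <- trees$vitality == "alive"
  if (!is.null(names(cohorts)))
    cohorts <- cohorts[trees$tree_id]
  if (length(cohorts) != nrow(trees))
    stop("cohorts must align with the inventory rows or be named by tree_id")
  if (anyNA(cohorts[alive])) stop("every living tree needs a cohort")
  ba <- basal_area_m2(trees$dbh_cm[alive])
  if (anyNA(ba)) stop("every living tree needs a DBH")
  tot <- sum(ba)
  if (tot == 0) stop("total living basal area is zero")
  1 - sum(ba[cohorts[alive] == 1L]) / tot
}

#' Canopy-layer distribution per plot
#' @param inventory inventory with a `canopy_layer` column (see
#'   [classify_canopy()]).
#' @return data.frame (plot_id, layer, n, percent); percentages per plot
#'   sum to 100 over living trees.
#' @export
layer_distribution <- function(inventory) {
  alive <- inventory[inventory$vitality == "alive", , drop = FALSE]
  tab <- table(plot_id = alive$plot_id,
               layer = factor(alive$canopy_layer, levels = canopy_layers()))
  out <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  tot <- tapply(out$n, out$plot_id, sum)
  out$percent <- 100 * out$n / as.numeric(tot[out$plot_id])
  out
}
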