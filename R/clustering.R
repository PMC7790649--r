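#' Best-of-restarts k-means on a segment matrix
#'
#' Runs `n_restarts` seeded k-means fits (Hartigan-Wong) with initial
#' centers drawn from the data rows, and keeps the partition with the
#' smallest total within-cluster sum of squares. Restarts that yield an
#' empty cluster or otherwise fail are discarded and redrawn, so the result
#' always has `k` non-empty clusters. Given the same seed the result is
#' fully reproducible.
#'
#' @param sm a [standardize_segment_matrix()] result, or a plain numeric
#'   matrix (rows = trees).
#' @param k number of clusters, `2 <= k <= nrow`.
#' @param n_restarts number of random restarts (default 1000).
#' @param seed integer seed for the restart stream.
#' @param iter_max maximum k-means iterations per restart.
#' @return An object of class `pattern_partition`: list with `k`,
#'   `cluster` (named integer vector), `centers` (standardized scale),
#'   `centers_raw` (mm scale, when `sm` is a `segment_matrix`), `size`,
#'   `withinss` (per cluster), `tot_withinss`, `ssi`, and `labels`
#'   (filled by [name_patterns()]).
#' @export
best_kmeans <- function(sm, k, n_restarts = 1000L, seed = 1L,
                        iter_max = 100L) {
  x <- if (inherits(sm, "segment_matrix")) sm$x else as.matrix(sm)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and the number of trees")
  if (nrow(unique(x)) < k)
    stop("fewer distinct profiles than clusters requested")
  set.seed(as.integer(seed))
  if (k == n) {
    # one tree per cluster: the partition is forced and exact
    best <- list(cluster = seq_len(n), centers = x, size = rep(1L, n),
                 withinss = rep(0, n), tot.withinss = 0)
    km_done <- TRUE
  } else km_done <- FALSE
  best <- if (km_done) best else NULL
  done <- 0L
  guard <- 0L
  while (!km_done && done < n_restarts) {
    guard <- guard + 1L
    if (guard > 20L * n_restarts)
      stop("too many failed k-means restarts")
    init <- x[sample.int(n, k), , drop = FALSE]
    if (anyDuplicated(init)) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = iter_max,
                                     algorithm = "Hartigan-Wong")),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0L)) next
    done <- done + 1L
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  part <- structure(
    list(k = k,
         cluster = stats::setNames(best$cluster, rownames(x)),
         centers = best$centers,
         centers_raw = if (inherits(sm, "segment_matrix"))
           destandardize(sm, best$centers) else NULL,
         size = best$size,
         withinss = best$withinss,
         tot_withinss = best$tot.withinss,
         ssi = NA_real_,
         labels = NULL),
    class = "pattern_partition")
  part$ssi <- if (k >= 2L) ssi_score(part) else NA_real_
  part
}

#' @export
print.pattern_partition <- function(x, ...) {
  cat(sprintf("<pattern_partition> k = %d, within-SS = %.3f, SSI = %.4f\n",
              x$k, x$tot_withinss, x$ssi))
  if (!is.null(x$labels))
    print(data.frame(cluster = seq_len(x$k), size = x$size,
                     pattern = x$labels$pattern))
  invisible(x)
}

#' Simple structure index of a k-means partition
#'
#' Cluster-validity index used to choose the number of radial growth
#' patterns: the partition with the highest SSI is retained. The index
#' multiplicatively combines, per variable, the spread between the two most
#' extreme cluster centers, the (geometric mean) sizes of the clusters
#' realizing that spread, and a down-weighting of variables whose center
#' mean sits far from the grand center mean, normalised so the index is
#' invariant to duplicating every observation:
#' \deqn{SSI = \frac{\sum_j span_j \, e^{-a_j} \sqrt{s^{max}_j s^{min}_j}}
#'   {p \cdot \max_j(s^{max}_j, s^{min}_j) \cdot e^{-\min_j a_j}}}
#' where for variable j, \eqn{span_j} is the max minus min cluster-center
#' value, \eqn{s^{max}_j, s^{min}_j} the sizes of the clusters attaining
#' them, \eqn{a_j = |\bar c_j - \bar{\bar c}|} the absolute deviation of
#' the center column mean from the grand mean, and p the number of
#' variables.
#'
#' @param partition a `pattern_partition`, or a matrix of cluster centers.
#' @param sizes cluster sizes (needed when `partition` is a matrix).
#' @return Nonnegative scalar; higher means a more interpretable partition.
#' @export
ssi_score <- function(partition, sizes = NULL) {
  if (inherits(partition, "pattern_partition")) {
    centers <- partition$centers
    sizes <- partition$size
  } else {
    centers <- as.matrix(partition)
    if (is.null(sizes)) stop("sizes required when passing a center matrix")
  }
  k <- nrow(centers)
  if (k < 2L) stop("SSI is undefined for fewer than 2 clusters")
  p <- ncol(centers)
  cmax <- apply(centers, 2L, max)
  cmin <- apply(centers, 2L, min)
  ord <- apply(centers, 2L, order)
  imax <- ord[k, ]
  imin <- ord[1L, ]
  span <- cmax - cmin
  a <- abs(colMeans(centers) - mean(centers))
  smax <- sizes[imax]
  smin <- sizes[imin]
  denom <- p * max(smax, smin) * exp(-min(a))
  as.numeric((span * exp(-a)) %*% sqrt(smax * smin) / denom)
}

#' Choose the number of growth patterns by the SSI criterion
#'
#' Fits [best_kmeans()] for every k in `k_range` and returns the k with the
#' highest simple structure index (ties broken toward the smaller k, for
#' parsimony). A low-confidence flag is raised when the SSI maximum barely
#' stands out of the curve (low prominence), as happens on unstructured
#' data.
#'
#' @param sm a `segment_matrix` (or plain matrix).
#' @param k_range integer vector of candidate cluster numbers, within
#'   `[2, n-1]`.
#' @param n_restarts,seed passed to [best_kmeans()] (each k uses the same
#'   seed so restart streams are comparable).
#' @param flat_tol prominence threshold for the low-confidence flag: the
#'   selection is flagged when the SSI maximum exceeds the curve's median
#'   by less than `flat_tol` of the maximum.
#' @return Object of class `ssi_selection`: list with `k_best`,
#'   `partition` (the winning `pattern_partition`), `curve` (data.frame k,
#'   ssi, tot_withinss), `low_confidence`.
#' @export
select_pattern_count <- function(sm, k_range = 2:15, n_restarts = 1000L,
                                 seed = 1L, flat_tol = 0.25) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("k_range is empty")
  n <- if (inherits(sm, "segment_matrix")) nrow(sm$x) else nrow(sm)
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within [2, n_trees - 1]")
  fits <- lapply(k_range, function(k)
    best_kmeans(sm, k, n_restarts = n_restarts, seed = seed))
  ssi <- vapply(fits, `[[`, 0, "ssi")
  best_i <- which.max(ssi)            # which.max takes the first (smallest k) tie
  prominence <- (max(ssi) - stats::median(ssi)) / max(ssi)
  structure(
    list(k_best = k_range[[best_i]],
         partition = fits[[best_i]],
         curve = data.frame(k = k_range, ssi = ssi,
                            tot_withinss = vapply(fits, `[[`, 0,
                                                  "tot_withinss")),
         low_confidence = length(k_range) > 1L &&
           prominence < flat_tol),
    class = "ssi_selection")
}

#' @export
print.ssi_selection <- function(x, ...) {
  cat(sprintf("<ssi_selection> k_best = %d (SSI = %.4f)%s\n", x$k_best,
              max(x$curve$ssi),
              if (x$low_confidence) " [low confidence: flat SSI curve]" else ""))
  invisible(x)
}

#' Classify the shape of one raw-scale cluster center
#'
#' Deterministic rules on the de-standardized (mm) center, using its thirds
#' and the position of its maximum:
#' \itemize{
#'   \item \strong{linear}: total range below `flat_tol` of the center mean
#'     (narrow, constant growth).
#'   \item \strong{ascending}: last-third mean is the largest third and
#'     the mean level from the maximum onward stays within `decline_tol`
#'     of the maximum (suppressed start, late release, no real decline).
#'   \item \strong{sine}: interior maximum (past two fifths of the series,
#'     before the last fifth) rising at least `decline_tol` of the peak
#'     above the suppressed first third, then declining by at least
#'     `decline_tol` of the peak on average after it.
#'   \item \strong{bell}: maximum in the first half followed by a decline
#'     (fast early growth, later suppression).
#' }
#' Centers matching no rule exactly are assigned the nearest canonical
#' prototype by correlation and flagged ambiguous.
#'
#' @param center numeric vector of segment means on the mm scale.
#' @param flat_tol,decline_tol rule thresholds (fractions).
#' @return list(shape, ambiguous).
#' @export
classify_center_shape <- function(center, flat_tol = 0.25,
                                  decline_tol = 0.25) {
  S <- length(center)
  i3 <- floor(S / 3)
  t1 <- mean(center[seq_len(i3)])
  t2 <- mean(center[(i3 + 1):(2 * i3)])
  t3 <- mean(center[(2 * i3 + 1):S])
  m <- which.max(center)
  u <- m / S
  peak <- center[[m]]
  post_decline <- (peak - mean(center[m:S])) / peak
  rise <- (peak - t1) / peak
  if (diff(range(center)) < flat_tol * mean(center))
    return(list(shape = "linear", ambiguous = FALSE))
  if (t3 >= t1 && t3 >= t2 && post_decline < decline_tol)
    return(list(shape = "ascending", ambiguous = FALSE))
  if (post_decline >= decline_tol) {
    if (rise >= decline_tol && u > 2/5 && u < 4/5)
      return(list(shape = "sine", ambiguous = FALSE))
    if (u <= 1/2)
      return(list(shape = "bell", ambiguous = FALSE))
  }
  # ambiguous: nearest canonical prototype by correlation
  s <- seq(0, 1, length.out = S)
  protos <- rbind(linear = rep(1, S),
                  bell = stats::dnorm(s, 0.3, 0.2),
                  ascending = stats::plogis(s, 0.6, 0.05),
                  sine = stats::dnorm(s, 0.5, 0.15))
  cors <- apply(protos, 1L, function(pr)
    suppressWarnings(stats::cor(center, pr)))
  cors[is.na(cors)] <- -Inf
  cors[["linear"]] <- 0   # flat center already caught by the range rule
  list(shape = names(which.max(cors)), ambiguous = TRUE)
}

#' Name clusters by growth-pattern shape and level
#'
#' Assigns each cluster a shape (`linear`, `bell`, `ascending`, `sine`) via
#' [classify_center_shape()] on its raw-scale center, then a level within
#' each shape group by ranking the centers' mean width: one cluster in a
#' group gets level `none`; two get `low`/`high`; three or more get
#' `low`/`moderate`(s)/`high`.
#'
#' @param partition a `pattern_partition` with `centers_raw` available
#'   (i.e. fitted on a `segment_matrix`).
#' @param flat_tol,decline_tol passed to [classify_center_shape()].
#' @return The partition with `labels`: a data.frame (cluster, shape,
#'   level, pattern, ambiguous) where `pattern` is e.g. `"high_sine"`.
#' @export
name_patterns <- function(partition, flat_tol = 0.25, decline_tol = 0.25) {
  stopifnot(inherits(partition, "pattern_partition"))
  if (is.null(partition$centers_raw))
    stop("raw-scale centers unavailable; fit best_kmeans on a segment_matrix")
  ctr <- partition$centers_raw
  cls <- lapply(seq_len(nrow(ctr)), function(i)
    classify_center_shape(ctr[i, ], flat_tol, decline_tol))
  shape <- vapply(cls, `[[`, "", "shape")
  ambiguous <- vapply(cls, `[[`, TRUE, "ambiguous")
  level <- rep("none", length(shape))
  for (sh in unique(shape)) {
    i <- which(shape == sh)
    if (length(i) == 1L) next
    r <- rank(rowMeans(ctr[i, , drop = FALSE]), ties.method = "first")
    lv <- if (length(i) == 2L) c("low", "high") else
      c("low", rep("moderate", length(i) - 2L), "high")
    level[i] <- lv[r]
  }
  partition$labels <- data.frame(
    cluster = seq_len(nrow(ctr)), shape = shape, level = level,
    pattern = ifelse(level == "none", shape, paste(level, shape, sep = "_")),
    ambiguous = ambiguous, stringsAsFactors = FALSE)
  partition
}

#' Per-tree pattern assignments as a table
#' @param partition a labeled `pattern_partition`.
#' @return data.frame (tree_id, cluster, shape, level, pattern).
#' @export
assignment_table <- function(partition) {
  stopifnot(inherits(partition, "pattern_partition"))
  cl <- partition$cluster
  out <- data.frame(tree_id = names(cl), cluster = as.integer(cl),
                    stringsAsFactors = FALSE)
  if (!is.null(partition$labels))
    out <- cbind(out,
                 partition$labels[out$cluster,
                                  c("shape", "level", "pattern")],
                 row.names = NULL)
  out
}
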