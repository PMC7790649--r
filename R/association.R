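#' Monte-Carlo association test for a pattern-by-layer table
#'
#' Tests independence of the rows (growth patterns) and columns (canopy
#' layers or species) of a contingency table by comparing the observed
#' chi-square statistic with its distribution over random tables drawn with
#' both margins fixed (via [stats::r2dtable()]). This is a Monte-Carlo
#' stand-in for an exact r x c Fisher test: assumption-light and feasible
#' for any table size. The p-value uses the add-one estimator
#' `(1 + #(perm >= obs)) / (1 + n_permutations)`, so its smallest
#' attainable value is `1/(n_permutations + 1)`.
#'
#' @param tab matrix or table of nonnegative counts, at least 2 x 2.
#' @param n_permutations number of random tables (default 9999).
#' @param seed integer seed.
#' @return list of class `assoc_test`: statistic (chi-square), p_value,
#'   n_permutations, table.
#' @export
pattern_association_test <- function(tab, n_permutations = 9999L, seed = 1L) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margins: empty row or column")
  chisq <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- chisq(tab)
  set.seed(as.integer(seed))
  perm <- vapply(stats::r2dtable(n_permutations, rs, cs), chisq, 0)
  structure(list(statistic = obs,
                 p_value = (1 + sum(perm >= obs)) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 table = tab),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo independence test: chi-square = %.3f, p = %.4g (%d tables)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

# one-way F statistic; returns NA when there is no within- or
# between-group variation to compare
.oneway_F <- function(values, groups) {
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0) return(if (ssb == 0) NA_real_ else Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Stratified permutation test for attribute differences between patterns
#'
#' Compares a numeric tree attribute (age, mean ring width, DBH, height,
#' ...) between growth patterns with a permutation F-test: the one-way F
#' statistic is recomputed after shuffling pattern labels, with shuffles
#' restricted to within strata (sites) so site-level differences in e.g.
#' fertility cannot masquerade as pattern effects. This is a
#' methodological stand-in for a mixed-effects ANOVA with site as random
#' effect followed by Tukey HSD. Pairwise contrasts use permutation tests
#' on the absolute mean difference, Holm-adjusted, summarised as a compact
#' letter display.
#'
#' @param values numeric attribute per tree.
#' @param groups pattern label per tree.
#' @param strata optional site id per tree; NULL = unrestricted shuffles.
#' @param n_permutations permutations for the overall and pairwise tests.
#' @param seed integer seed.
#' @param alpha significance level for the letter display.
#' @param drop_outliers if TRUE, values below the 1st or above the 99th
#'   percentile are removed before testing.
#' @param pairwise if FALSE, skip the pairwise contrasts and letter
#'   display (faster when only the overall p-value is needed).
#' @return list of class `group_test`: statistic (F), p_value, group_means,
#'   pairwise (data.frame), letters (named character vector),
#'   n_permutations.
#' @export
attribute_group_test <- function(values, groups, strata = NULL,
                                 n_permutations = 999L, seed = 1L,
                                 alpha = 0.05, drop_outliers = FALSE,
                                 pairwise = TRUE) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  strata <- if (is.null(strata)) rep("all", length(values))
            else as.character(strata)[keep]
  if (drop_outliers) {
    q <- stats::quantile(values, c(0.01, 0.99), names = FALSE)
    inl <- values >= q[1L] & values <= q[2L]
    values <- values[inl]; groups <- groups[inl]; strata <- strata[inl]
  }
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("groups with < 2 values excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !(groups %in% small)
    values <- values[keep2]; groups <- groups[keep2]; strata <- strata[keep2]
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 values each")
  obs <- .oneway_F(values, g)
  if (is.na(obs)) {
    # no variation at all: report no difference
    lv <- levels(g)
    return(structure(list(statistic = NA_real_, p_value = 1,
                          group_means = tapply(values, g, mean),
                          pairwise = NULL,
                          letters = stats::setNames(rep("a", length(lv)), lv),
                          n_permutations = n_permutations),
                     class = "group_test"))
  }
  set.seed(as.integer(seed))
  str_idx <- split(seq_along(values), strata)
  permute_within <- function() {
    idx <- seq_along(values)
    for (ii in str_idx) idx[ii] <- ii[sample.int(length(ii))]
    g[idx]
  }
  perm <- vapply(seq_len(n_permutations), function(i)
    .oneway_F(values, permute_within()), 0)
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + n_permutations)

  if (!pairwise)
    return(structure(list(statistic = obs, p_value = p,
                          group_means = tapply(values, g, mean),
                          pairwise = NULL, letters = NULL,
                          n_permutations = n_permutations),
                     class = "group_test"))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  pair_p <- apply(pairs, 2L, function(pr) {
    sel <- g %in% pr
    v <- values[sel]; gg <- droplevels(g[sel]); st <- strata[sel]
    d_obs <- abs(diff(tapply(v, gg, mean)))
    sidx <- split(seq_along(v), st)
    pd <- vapply(seq_len(n_permutations), function(i) {
      idx <- seq_along(v)
      for (ii in sidx) idx[ii] <- ii[sample.int(length(ii))]
      abs(diff(tapply(v, gg[idx], mean)))
    }, 0)
    (1 + sum(pd >= d_obs)) / (1 + n_permutations)
  })
  pair_adj <- stats::p.adjust(pair_p, method = "holm")
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         p_raw = pair_p, p_holm = pair_adj,
                         stringsAsFactors = FALSE)
  structure(list(statistic = obs, p_value = p,
                 group_means = tapply(values, g, mean),
                 pairwise = pairwise,
                 letters = .compact_letters(lv, pairwise,
                                            tapply(values, g, mean), alpha),
                 n_permutations = n_permutations),
            class = "group_test")
}

# compact letter display: order groups by decreasing mean, give runs of
# mutually non-significant groups a shared letter
.compact_letters <- function(levels, pairwise, means, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  sig <- function(a, b) {
    i <- (pairwise$group1 == a & pairwise$group2 == b) |
         (pairwise$group1 == b & pairwise$group2 == a)
    any(pairwise$p_holm[i] < alpha)
  }
  k <- length(ord)
  # maximal runs of consecutive (by mean rank) mutually non-significant groups
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply(i:j, function(m) sig(ord[m], ord[j + 1L]),
                                TRUE)))
      j <- j + 1L
    runs[[i]] <- i:j
  }
  keep <- vapply(seq_along(runs), function(i)
    !any(vapply(seq_along(runs), function(j)
      i != j && all(runs[[i]] %in% runs[[j]]), TRUE)), TRUE)
  runs <- unique(runs[keep])
  letters_out <- stats::setNames(rep("", k), ord)
  for (r in seq_along(runs))
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])
  letters_out[levels]
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Stratified permutation F-test: F = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  if (length(x$letters)) {
    df <- data.frame(mean = round(x$group_means[names(x$letters)], 3),
                     letters = x$letters)
    print(df)
  }
  invisible(x)
}
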