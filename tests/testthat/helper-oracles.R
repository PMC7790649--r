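# Independent oracle implementations used to cross-check the package.
# Each is written directly from the defining formula, favouring plain
# loops over the vectorised forms used in R/.

# two-window percent growth change by explicit means
gc_oracle <- function(widths, window = 10L) {
  L <- length(widths)
  out <- rep(NA_real_, L)
  for (t in seq_len(L)) {
    if (t < window || t + window > L) next
    m1 <- mean(widths[(t - window + 1):t])
    m2 <- mean(widths[(t + 1):(t + window)])
    out[t] <- if (m1 == 0) NA_real_ else (m2 - m1) / m1 * 100
  }
  out
}

# simple structure index, loop form
ssi_oracle <- function(centers, sizes) {
  p <- ncol(centers)
  grand <- mean(centers)
  num <- 0
  a_all <- numeric(p)
  smax_all <- smin_all <- numeric(p)
  for (j in seq_len(p)) {
    cj <- centers[, j]
    a <- abs(mean(cj) - grand)
    a_all[j] <- a
    smax_all[j] <- sizes[which.max(cj)]
    smin_all[j] <- sizes[which.min(cj)]
    num <- num + (max(cj) - min(cj)) * exp(-a) *
      sqrt(smax_all[j] * smin_all[j])
  }
  num / (p * max(c(smax_all, smin_all)) * exp(-min(a_all)))
}

# local quadratic regression with tricube weights over the span-nearest
# neighbours, evaluated at every x
loess_oracle <- function(x, y, span = 0.5, degree = 2L) {
  n <- length(x)
  q <- floor(n * span)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(0, 1 - pmin(d / h, 1)^3)^3
    X <- outer(x - x[i], 0:degree, `^`)
    stats::lm.wfit(X, y, w)$coefficients[[1L]]
  }, 0)
}

# convenience builders
const_series <- function(n, w = 1, first_year = 1900, id = "T1")
  ring_series(id, rep(w, n), first_year)

step_series <- function(pre, post, n_pre = 10L, n_post = 10L,
                        first_year = 1900, id = "T1")
  ring_series(id, c(rep(pre, n_pre), rep(post, n_post)), first_year)

# a minimal plot inventory
toy_plot <- function(heights, dbh = rep(20, length(heights)),
                     vitality = rep("alive", length(heights)),
                     species = rep("PIMA", length(heights)),
                     plot_area_m2 = 400, plot_id = "P1") {
  data.frame(tree_id = sprintf("T%02d", seq_along(heights)),
             species = species, dbh_cm = dbh, height_m = heights,
             vitality = vitality,
             crown_status = "intact",
             plot_id = plot_id, plot_area_m2 = plot_area_m2,
             stringsAsFactors = FALSE)
}
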