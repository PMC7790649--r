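#' Read a Tucson (rwl) decadal ring-width file
#'
#' Parses the standard Tucson exchange format: one record per series id and
#' decade, ten values per full decade, terminated by a stop marker. The stop
#' marker determines the measurement unit: `999` means values are in
#' 0.01 mm, `-9999` means 0.001 mm. Widths are returned in mm.
#'
#' @param path path to an rwl file.
#' @return A named list of [ring_series()], one per series id.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("rwl file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur_id <- NULL; cur_first <- NULL; cur_vals <- NULL; cur_next <- NULL
  # the stop marker is identified by position (the value after the last
  # ring), never by value alone: in the 0.001 mm dialect "999" mid-series
  # is a perfectly valid 0.999 mm ring
  flush_series <- function() {
    if (is.null(cur_id)) return(invisible())
    marker <- cur_vals[length(cur_vals)]
    if (!marker %in% c(999, -9999))
      stop("series '", cur_id,
           "' does not end with a 999 or -9999 stop marker")
    precision <- if (marker == -9999) 0.001 else 0.01
    vals <- cur_vals[-length(cur_vals)]
    if (any(vals < 0))
      stop("negative ring value inside series '", cur_id, "'")
    if (cur_id %in% names(out))
      stop("duplicate series id in rwl file: ", cur_id)
    out[[cur_id]] <<- ring_series(cur_id, vals * precision, cur_first)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 3L)
      stop(sprintf("malformed rwl record at line %d: '%s'", i, ln))
    id <- toks[1L]
    year <- suppressWarnings(as.integer(toks[2L]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(year) || anyNA(vals))
      stop(sprintf("malformed rwl record at line %d: '%s'", i, ln))
    if (is.null(cur_id) || id != cur_id) {
      flush_series()
      cur_id <- id; cur_first <- year; cur_vals <- numeric(); cur_next <- year
    }
    if (year != cur_next)
      stop(sprintf("non-consecutive decade record at line %d (expected year %d)",
                   i, cur_next))
    cur_vals <- c(cur_vals, vals)
    cur_next <- year + length(vals)
  }
  flush_series()
  out
}

#' Write ring series to a Tucson (rwl) file
#'
#' @param series a `ring_series` or list of them.
#' @param path output path.
#' @param precision measurement unit in mm: `0.01` (stop marker 999, the
#'   common dialect) or `0.001` (stop marker -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, precision = 0.01) {
  if (inherits(series, "ring_series")) series <- list(series)
  if (!precision %in% c(0.01, 0.001))
    stop("precision must be 0.01 or 0.001 mm")
  marker <- if (precision == 0.001) -9999L else 999L
  con <- file(path, "w"); on.exit(close(con))
  for (s in series) {
    if (nchar(s$tree_id) > 8L)
      stop("series id '", s$tree_id, "' exceeds the 8-character Tucson limit")
    vals <- as.integer(round(s$widths / precision))
    yrs <- series_years(s)
    vals <- c(vals, marker)
    yrs <- c(yrs, last_year(s) + 1L)
    repeat {
      if (!length(vals)) break
      dec_end <- (yrs[1L] %/% 10L) * 10L + 9L
      take <- min(length(vals), dec_end - yrs[1L] + 1L)
      writeLines(paste0(sprintf("%-8s", s$tree_id), sprintf("%4d", yrs[1L]),
                        paste0(sprintf("%6d", vals[seq_len(take)]),
                               collapse = "")),
                 con)
      vals <- vals[-seq_len(take)]
      yrs <- yrs[-seq_len(take)]
    }
  }
  invisible(path)
}

#' Read ring widths from a long-form CSV
#'
#' Accepts the columns `tree_id`, `year`, `width_mm` (UTF-8, header row
#' required). Years within each tree must be consecutive.
#'
#' @param path CSV path.
#' @return A named list of [ring_series()].
#' @export
read_rings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "year", "width_mm")
  if (!all(need %in% names(df)))
    stop("ring CSV must contain columns: ", paste(need, collapse = ", "))
  split_df <- split(df, df$tree_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$year), , drop = FALSE]
    if (any(diff(d$year) != 1L))
      stop("years are not consecutive for tree ", d$tree_id[[1L]])
    ring_series(as.character(d$tree_id[[1L]]), d$width_mm, d$year[[1L]])
  })
  out[unique(as.character(df$tree_id))]
}

#' Write ring series to a long-form CSV
#' @param series a `ring_series` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rings_csv <- function(series, path) {
  utils::write.csv(as_ring_table(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a plot inventory table
#'
#' The inventory lists every merchantable tree (DBH >= 9 cm) of each plot
#' with the columns `tree_id`, `species`, `DBH_cm`, `height_m`, `vitality`
#' (`alive`/`dead`), `crown_status` (`intact`/`broken`), `plot_id`,
#' `plot_area_m2`. A `canopy_layer` column is optional.
#'
#' @param path CSV path (UTF-8, header row required).
#' @param min_dbh_cm merchantability threshold; rows below it are an error.
#' @return A data.frame with normalised lower-case column names
#'   (`dbh_cm`, `height_m`, ...).
#' @export
read_inventory <- function(path, min_dbh_cm = 9) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("tree_id", "species", "dbh_cm", "height_m", "vitality",
            "crown_status", "plot_id", "plot_area_m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("inventory is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(df$dbh_cm < min_dbh_cm)
  if (length(bad))
    stop("inventory rows below the merchantable DBH threshold (",
         min_dbh_cm, " cm): ",
         paste(df$tree_id[utils::head(bad, 5L)], collapse = ", "))
  if (any(df$plot_area_m2 <= 0)) stop("plot_area_m2 must be > 0")
  if (!all(df$vitality %in% c("alive", "dead")))
    stop("vitality must be 'alive' or 'dead'")
  df
}
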