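#' Define an annual capture-recapture study design
#'
#' A study design records the ordered annual sampling occasions, the years in
#' which no fieldwork took place (capture probability is fixed to zero there
#' for every individual), and the monitoring panels: disjoint sets of nests
#' followed over different eras of the study, each with its own active year
#' range. Individuals belong to exactly one panel and can only be detected
#' in that panel's active, non-gap years.
#'
#' @param years Integer vector of calendar years, strictly increasing; one
#'   sampling occasion per year.
#' @param gap_years Integer vector (subset of `years`) with no fieldwork.
#' @param panels A data frame with columns `panel`, `start`, `end` giving each
#'   monitoring panel's active year range, or `NULL` for a single panel
#'   spanning all years.
#' @return An object of class `study_design`.
#' @examples
#' study_design(2001:2010, gap_years = 2005, panels = NULL)
#' shearwater_design()
#' @export
study_design <- function(years, gap_years = integer(), panels = NULL) {
  years <- as.integer(years)
  gap_years <- as.integer(gap_years)
  if (length(years) < 2L || any(diff(years) <= 0L)) {
    stop("`years` must be a strictly increasing vector of length >= 2", call. = FALSE)
  }
  if (!all(gap_years %in% years)) {
    stop("`gap_years` must be a subset of `years`", call. = FALSE)
  }
  if (is.null(panels)) {
    panels <- tibble::tibble(panel = "panel-1",
                             start = min(years), end = max(years))
  }
  panels <- tibble::as_tibble(panels)
  stopifnot(all(c("panel", "start", "end") %in% names(panels)))
  panels$panel <- as.character(panels$panel)
  panels$start <- as.integer(panels$start)
  panels$end <- as.integer(panels$end)
  if (!all(panels$start %in% years) || !all(panels$end %in% years)) {
    stop("panel year ranges must lie within `years`", call. = FALSE)
  }
  if (anyDuplicated(panels$panel)) stop("duplicated panel labels", call. = FALSE)
  structure(
    list(years = years, gap_years = gap_years, panels = panels),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$years), " occasions ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  if (length(x$gap_years)) {
    cat("  gap years: ", paste(range(x$gap_years), collapse = "-"), "\n", sep = "")
  }
  for (i in seq_len(nrow(x$panels))) {
    cat("  ", x$panels$panel[i], ": ", x$panels$start[i], "-",
        x$panels$end[i], "\n", sep = "")
  }
  invisible(x)
}

#' The two-panel Cory's shearwater monitoring layout
#'
#' Convenience constructor for the long-term colony monitoring design used
#' throughout the package examples: 34 annual occasions 1978--2011, a
#' four-year interruption 2000--2003 with no fieldwork, and two disjoint nest
#' panels (panel-1 followed 1978--1999, panel-2 followed 2004--2011).
#'
#' @return A `study_design`.
#' @export
shearwater_design <- function() {
  study_design(
    years = 1978:2011,
    gap_years = 2000:2003,
    panels = tibble::tibble(
      panel = c("panel-1", "panel-2"),
      start = c(1978L, 2004L),
      end   = c(1999L, 2011L)
    )
  )
}

n_occasions <- function(design) length(design$years)

is_gap <- function(design) design$years %in% design$gap_years

#' Capture-permission mask by panel and occasion
#'
#' Capture probability is structurally zero in gap years for every panel and
#' outside a panel's active year range (individuals from one panel are not
#' searched for in the other panel's era).
#'
#' @param design A `study_design`.
#' @return Logical matrix, panels x occasions; `TRUE` where capture is
#'   possible.
#' @export
capture_mask <- function(design) {
  K <- n_occasions(design)
  gap <- is_gap(design)
  m <- matrix(FALSE, nrow(design$panels), K,
              dimnames = list(design$panels$panel, design$years))
  for (i in seq_len(nrow(design$panels))) {
    ok <- design$years >= design$panels$start[i] &
      design$years <= design$panels$end[i] & !gap
    m[i, ] <- ok
  }
  m
}

# index of the immediately preceding non-gap occasion for each occasion
# (NA for the first non-gap occasion and anything before it)
prev_nongap <- function(design) {
  K <- n_occasions(design)
  gap <- is_gap(design)
  prev <- rep(NA_integer_, K)
  last <- NA_integer_
  for (j in seq_len(K)) {
    prev[j] <- last
    if (!gap[j]) last <- j
  }
  prev
}

# first non-gap occasion strictly after each occasion (NA if none)
next_nongap <- function(design) {
  K <- n_occasions(design)
  gap <- is_gap(design)
  nxt <- rep(NA_integer_, K)
  nextone <- NA_integer_
  for (j in rev(seq_len(K))) {
    nxt[j] <- nextone
    if (!gap[j]) nextone <- j
  }
  nxt
}
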