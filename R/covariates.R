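#' Seasonal averages of monthly environmental series
#'
#' Reduces a monthly series to one value per year for the season of
#' interest: the breeding window averages April--September of year `t`; the
#' non-breeding window averages December of year `t - 1` with January and
#' February of year `t` and is labelled year `t` (the winter preceding
#' breeding season `t`).
#'
#' @param monthly A tibble with columns `year`, `month`, `value`, optionally
#'   grouped by extra identifying columns (e.g. `region`, `variable`) which
#'   are preserved.
#' @param season `"breeding"` (Apr--Sep) or `"nonbreeding"` (Dec--Feb).
#' @param years Optional integer vector of season-years to return; an error
#'   names any missing month. When `NULL`, all complete windows are
#'   returned.
#' @return A tibble with the identifying columns, `year`, and the seasonal
#'   mean `value`.
#' @export
seasonal_average <- function(monthly, season = c("breeding", "nonbreeding"),
                             years = NULL) {
  season <- match.arg(season)
  monthly <- tibble::as_tibble(monthly)
  stopifnot(all(c("year", "month", "value") %in% names(monthly)))
  keys <- setdiff(names(monthly), c("year", "month", "value"))
  if (season == "breeding") {
    dat <- monthly[monthly$month %in% 4:9, ]
    dat$season_year <- dat$year
    expected <- 6L
  } else {
    dat <- monthly[monthly$month %in% c(12L, 1L, 2L), ]
    dat$season_year <- ifelse(dat$month == 12L, dat$year + 1L, dat$year)
    expected <- 3L
  }
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "season_year")))) |>
    dplyr::summarise(value = mean(.data$value), n_months = dplyr::n(),
                     .groups = "drop") |>
    dplyr::rename(year = "season_year")
  if (!is.null(years)) {
    for (y in years) {
      sub <- out[out$year == y, ]
      if (!nrow(sub) || any(sub$n_months < expected)) {
        months <- if (season == "breeding") 4:9 else c(12L, 1L, 2L)
        src_year <- if (season == "breeding") y else c(y - 1L, y, y)[c(1, 2, 3)]
        have <- dat[dat$season_year == y, c(keys, "month"), drop = FALSE]
        miss <- setdiff(months, have$month)
        stop("season-year ", y, " is missing month(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
    out <- out[out$year %in% years, ]
  } else {
    out <- out[out$n_months == expected, ]
  }
  out$n_months <- NULL
  out
}

#' Lag a season-indexed covariate by one to four seasons
#'
#' A seasonal series alternates non-breeding (winter preceding breeding
#' season `t`) and breeding values within each year. A lag of `k` seasons
#' shifts values `k` half-year steps forward, so lag 2 equals a one-year
#' shift and lag 1 maps a breeding value onto the following non-breeding
#' slot (or vice versa).
#'
#' @param seasonal A tibble with columns `year`, `season` (`"nonbreeding"`
#'   or `"breeding"`), `value`.
#' @param lag_seasons Integer in 1..4.
#' @return The tibble with `value` replaced by the lagged series (leading
#'   slots become `NA`).
#' @export
lag_covariate <- function(seasonal, lag_seasons) {
  if (!is.numeric(lag_seasons) || length(lag_seasons) != 1 ||
      !(lag_seasons %in% 1:4)) {
    stop("`lag_seasons` must be one of 1, 2, 3, 4", call. = FALSE)
  }
  seasonal <- tibble::as_tibble(seasonal)
  stopifnot(all(c("year", "season", "value") %in% names(seasonal)))
  half <- 2L * seasonal$year + (seasonal$season == "breeding")
  ord <- order(half)
  seasonal <- seasonal[ord, ]
  half <- half[ord]
  if (any(diff(half) != 1L)) {
    stop("seasonal series must be contiguous in half-year steps",
         call. = FALSE)
  }
  v <- seasonal$value
  n <- length(v)
  seasonal$value <- c(rep(NA_real_, lag_seasons),
                      v[seq_len(n - lag_seasons)])
  seasonal
}

#' Standardize a covariate to zero mean and unit variance
#'
#' @param x Numeric vector.
#' @return The z-scored vector with attributes `center` and `scale`;
#'   [destandardize()] inverts the transform.
#' @export
standardize_covariate <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  structure((x - m) / s, center = m, scale = s)
}

#' @rdname standardize_covariate
#' @param z A vector produced by [standardize_covariate()].
#' @export
destandardize <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}

#' PCA reduction of correlated covariates of mixed units
#'
#' Principal components of the correlation matrix (members are standardized
#' first, as required when units differ). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each retained
#' component is positive.
#'
#' @param tbl A wide tibble with a `year` column and the member columns.
#' @param cols Character vector of member column names.
#' @param n_keep Number of components to retain.
#' @return A list with `scores` (tibble `year` + `PC1..`), `loadings`,
#'   `variance_fraction` (per retained component, of the total).
#' @export
pca_reduce <- function(tbl, cols, n_keep = 2) {
  X <- as.matrix(tbl[, cols])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  n_keep <- min(n_keep, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_keep), drop = FALSE]
  scores <- pc$x[, seq_len(n_keep), drop = FALSE]
  for (j in seq_len(n_keep)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble::as_tibble(scores)
  names(out) <- paste0("PC", seq_len(n_keep))
  list(scores = dplyr::bind_cols(tbl["year"], out),
       loadings = rot,
       variance_fraction = vf[seq_len(n_keep)],
       all_variance_fractions = vf)
}

#' Reduce a candidate covariate set by correlation screening
#'
#' Pairwise Pearson correlations are tested (two-sided t-test); pairs with
#' `p < alpha` and `|r| >= r_min` are flagged, and flagged pairs are merged
#' into groups by transitive closure. Groups whose members share units are
#' replaced by their (standardized) member average; mixed-unit groups are
#' replaced by their first `n_pc` principal components (correlation-matrix
#' PCA). Singleton candidates pass through standardized.
#'
#' @param tbl Wide tibble: `year` plus one column per candidate covariate.
#' @param units Named character vector mapping candidate names to units.
#' @param alpha Significance threshold for flagging a correlated pair.
#' @param r_min Minimum absolute correlation to flag (default 0).
#' @param n_pc Components retained for mixed-unit groups.
#' @return A list with `covariates` (wide tibble of standardized reduced
#'   covariates), `provenance` (tibble: output name, members, method), and
#'   `pca` (per-group PCA details).
#' @export
reduce_correlated <- function(tbl, units, alpha = 0.05, r_min = 0,
                              n_pc = 2) {
  tbl <- tibble::as_tibble(tbl)
  cand <- setdiff(names(tbl), "year")
  stopifnot(all(cand %in% names(units)))
  k <- length(cand)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ct <- stats::cor.test(tbl[[cand[i]]], tbl[[cand[j]]])
        if (!is.na(ct$p.value) && ct$p.value < alpha &&
            abs(ct$estimate) >= r_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  groups <- split(cand, root)
  out <- tbl["year"]
  prov <- list()
  pca_details <- list()
  for (g in groups) {
    if (length(g) == 1L) {
      nm <- g
      out[[nm]] <- as.numeric(standardize_covariate(tbl[[g]]))
      prov[[length(prov) + 1L]] <- tibble::tibble(
        name = nm, members = g, method = "passthrough")
    } else if (length(unique(units[g])) == 1L) {
      nm <- paste(g, collapse = "_avg_")
      avg <- rowMeans(as.matrix(tbl[, g]))
      out[[nm]] <- as.numeric(standardize_covariate(avg))
      prov[[length(prov) + 1L]] <- tibble::tibble(
        name = nm, members = paste(g, collapse = "+"), method = "average")
    } else {
      pr <- pca_reduce(tbl, g, n_keep = n_pc)
      base <- paste0("PC", seq_len(ncol(pr$loadings)), "_",
                     paste(g, collapse = "."))
      for (j in seq_along(base)) {
        out[[base[j]]] <- as.numeric(
          standardize_covariate(pr$scores[[j + 1L]]))
      }
      pca_details[[paste(g, collapse = "+")]] <- pr
      prov[[length(prov) + 1L]] <- tibble::tibble(
        name = paste(base, collapse = ","),
        members = paste(g, collapse = "+"), method = "pca")
    }
  }
  list(covariates = out, provenance = dplyr::bind_rows(prov),
       pca = pca_details)
}
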