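#' @importFrom stats pchisq
NULL

# ---- contingency-table machinery ------------------------------------------

# Pearson chi-square with column pooling: sparse columns are merged into a
# neighbour until every expected count reaches `pool_target` (or only two
# columns remain). The pooled table is retained when all expected counts are
# at least `min_expected`; otherwise it contributes nothing (chi2 = 0,
# df = 0). Pooling toward a denser target than the retention threshold keeps
# the chi-square approximation honest in multi-column timing tables without
# discarding informative 2x2 tables that have one modest margin.
pooled_chisq <- function(tab, min_expected = 2, pool_target = 5) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(chi2 = 0, df = 0L, degenerate = TRUE, table = tab))
  }
  expected <- function(t) outer(rowSums(t), colSums(t)) / sum(t)
  while (min(expected(tab)) < pool_target && ncol(tab) > 2L) {
    cs <- colSums(tab)
    j <- which.min(cs)
    nb <- if (j > 1L) j - 1L else j + 1L
    tab[, nb] <- tab[, nb] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  E <- expected(tab)
  if (min(E) < min_expected) {
    return(list(chi2 = 0, df = 0L, degenerate = TRUE, table = tab))
  }
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df, degenerate = FALSE, table = tab)
}

new_gof_component <- function(name, pieces) {
  chi2 <- sum(vapply(pieces, `[[`, numeric(1), "chi2"))
  df <- sum(vapply(pieces, `[[`, integer(1), "df"))
  signs <- vapply(pieces, function(p) p$sign %||% 0, numeric(1))
  chis <- vapply(pieces, `[[`, numeric(1), "chi2")
  used <- df > 0 && any(chis > 0)
  direction <- if (used) {
    sum(signs * sqrt(chis)) / sqrt(max(1L, sum(chis > 0)))
  } else NA_real_
  structure(
    list(name = name, chi2 = chi2, df = df,
         p = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
         direction = direction,
         degenerate = df == 0L,
         tables = pieces),
    class = "gof_component"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gof_component <- function(x, ...) {
  cat(sprintf("<gof_component> %s: chi2 = %.2f, df = %d, p = %s\n",
              x$name, x$chi2, x$df,
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3)))
  invisible(x)
}

#' @rdname gof_components
#' @param x A `gof_component`.
#' @param ... Unused.
#' @method tidy gof_component
#' @export
tidy.gof_component <- function(x, ...) {
  tibble::tibble(test = x$name, df = x$df, chi2 = x$chi2, p = x$p,
                 direction = x$direction)
}

# shared per-occasion scaffolding: for each individual, the occasion of next
# re-encounter strictly after j (NA if never)
next_encounter_after <- function(H) {
  K <- ncol(H)
  nxt <- matrix(NA_integer_, nrow(H), K)
  nextseen <- rep(NA_integer_, nrow(H))
  for (j in K:1) {
    nxt[, j] <- nextseen
    nextseen[H[, j] == 1L] <- j
  }
  nxt
}

# ---- the four components ---------------------------------------------------

#' Goodness-of-fit components of the time-dependent CJS model
#'
#' These four contingency-table tests decompose the lack of fit of the
#' fully time-dependent Cormack-Jolly-Seber model. `gof_3sr()` contrasts
#' newly against previously marked animals in whether they are ever
#' re-encountered (an excess of never-seen-again newly marked animals
#' signals transience; the signed `direction` is then positive).
#' `gof_3sm()` compares, among animals re-encountered later, *when* the next
#' re-encounter happens between the two marking classes. `gof_2ct()` tests
#' whether capture at occasion `i` predicts immediate recapture at `i + 1`
#' among animals known alive (direction positive for trap-happiness), and
#' `gof_2cl()` tests whether capture at `i` predicts the timing of the next
#' re-encounter among animals not re-encountered at `i + 1`.
#'
#' Each per-occasion table is pooled (sparse columns merged) until all
#' expected counts reach `min_expected`; tables that cannot are skipped.
#' Component chi-squares, degrees of freedom and upper-tail p-values are
#' summed over occasions.
#'
#' @name gof_components
#' @inheritParams history_matrix
#' @param min_expected Retention threshold: a pooled table is kept only if
#'   all expected counts reach this value.
#' @param pool_target Pooling target: columns are merged until expected
#'   counts reach this denser value (or two columns remain), which keeps the
#'   chi-square approximation honest in sparse timing tables.
#' @return A `gof_component` object (chi2, df, p, signed direction, and the
#'   per-occasion tables).
NULL

#' @rdname gof_components
#' @export
gof_3sr <- function(histories, design, min_expected = 2, pool_target = 5) {
  H <- history_matrix(histories, design)
  K <- ncol(H)
  if (K < 3L) stop("test 3SR needs at least 3 occasions", call. = FALSE)
  f <- first_capture(H)
  pieces <- list()
  for (i in 2:(K - 1L)) {
    rel <- H[, i] == 1L
    if (!any(rel)) next
    new <- f[rel] == i
    seen_after <- rowSums(H[rel, (i + 1L):K, drop = FALSE]) > 0L
    tab <- rbind(new = c(sum(new & seen_after), sum(new & !seen_after)),
                 old = c(sum(!new & seen_after), sum(!new & !seen_after)))
    colnames(tab) <- c("seen_again", "never")
    pc <- pooled_chisq(tab, min_expected, pool_target)
    if (!pc$degenerate) {
      p_new <- tab["new", 1] / sum(tab["new", ])
      p_old <- tab["old", 1] / sum(tab["old", ])
      pc$sign <- sign(p_old - p_new)  # positive: new animals re-sighted less
    }
    pc$occasion <- design$years[i]
    pieces[[length(pieces) + 1L]] <- pc
  }
  new_gof_component("3SR", pieces)
}

#' @rdname gof_components
#' @export
gof_3sm <- function(histories, design, min_expected = 2, pool_target = 5) {
  H <- history_matrix(histories, design)
  K <- ncol(H)
  if (K < 4L) stop("test 3SM needs at least 4 occasions", call. = FALSE)
  f <- first_capture(H)
  nxt <- next_encounter_after(H)
  pieces <- list()
  for (i in 2:(K - 1L)) {
    rel <- which(H[, i] == 1L & !is.na(nxt[, i]))
    if (!length(rel)) next
    cls <- factor(ifelse(f[rel] == i, "new", "old"), levels = c("new", "old"))
    when <- factor(nxt[rel, i], levels = (i + 1L):K)
    tab <- table(cls, when)
    pc <- pooled_chisq(tab, min_expected, pool_target)
    if (!pc$degenerate && ncol(pc$table) == 2L) {
      # sign: positive when new animals are re-encountered sooner
      p_new <- pc$table[1, 1] / sum(pc$table[1, ])
      p_old <- pc$table[2, 1] / sum(pc$table[2, ])
      pc$sign <- sign(p_new - p_old)
    }
    pc$occasion <- design$years[i]
    pieces[[length(pieces) + 1L]] <- pc
  }
  new_gof_component("3SM", pieces)
}

#' @rdname gof_components
#' @export
gof_2ct <- function(histories, design, min_expected = 2, pool_target = 5) {
  H <- history_matrix(histories, design)
  K <- ncol(H)
  if (K < 3L) stop("test 2CT needs at least 3 occasions", call. = FALSE)
  f <- first_capture(H)
  nxt <- next_encounter_after(H)
  pieces <- list()
  for (i in 2:(K - 1L)) {
    # animals released at or before i and re-encountered at i+1 or later
    known <- which(f <= i & !is.na(nxt[, i]))
    if (!length(known)) next
    caught <- H[known, i] == 1L
    imm <- nxt[known, i] == i + 1L
    tab <- rbind(caught = c(sum(caught & imm), sum(caught & !imm)),
                 missed = c(sum(!caught & imm), sum(!caught & !imm)))
    colnames(tab) <- c("at_i1", "later")
    pc <- pooled_chisq(tab, min_expected, pool_target)
    if (!pc$degenerate) {
      p_c <- tab["caught", 1] / sum(tab["caught", ])
      p_m <- tab["missed", 1] / sum(tab["missed", ])
      pc$sign <- sign(p_c - p_m)  # positive: trap-happiness
    }
    pc$occasion <- design$years[i]
    pieces[[length(pieces) + 1L]] <- pc
  }
  new_gof_component("2CT", pieces)
}

#' @rdname gof_components
#' @export
gof_2cl <- function(histories, design, min_expected = 2, pool_target = 5) {
  H <- history_matrix(histories, design)
  K <- ncol(H)
  if (K < 4L) stop("test 2CL needs at least 4 occasions", call. = FALSE)
  f <- first_capture(H)
  nxt <- next_encounter_after(H)
  pieces <- list()
  for (i in 2:(K - 2L)) {
    # released at or before i, next re-encounter strictly after i+1
    sel <- which(f <= i & !is.na(nxt[, i]) & nxt[, i] > i + 1L)
    if (!length(sel)) next
    cls <- factor(ifelse(H[sel, i] == 1L, "caught", "missed"),
                  levels = c("caught", "missed"))
    when <- factor(nxt[sel, i], levels = (i + 2L):K)
    tab <- table(cls, when)
    pc <- pooled_chisq(tab, min_expected, pool_target)
    pc$occasion <- design$years[i]
    pieces[[length(pieces) + 1L]] <- pc
  }
  new_gof_component("2CL", pieces)
}

# ---- suite -----------------------------------------------------------------

#' Full goodness-of-fit decomposition with overdispersion factor
#'
#' Runs the four component tests within each sex x panel subgroup, sums
#' chi-squares and degrees of freedom, and computes the variance inflation
#' factor `c_hat` = total chi2 / total df over a configurable subset of
#' components (all four by default).
#'
#' @inheritParams gof_components
#' @param by Character vector of grouping columns (subset of
#'   `c("sex", "panel")`).
#' @param components Which test components enter the totals and `c_hat`.
#' @return A `gof_report`: list with `$components` (tibble of per-group
#'   per-test rows), `$total_chi2`, `$total_df`, `$total_p`, `$c_hat`.
#' @export
gof_suite <- function(histories, design, by = c("sex", "panel"),
                      components = c("3SR", "3SM", "2CT", "2CL"),
                      min_expected = 2, pool_target = 5) {
  by <- intersect(by, c("sex", "panel"))
  groups <- if (length(by)) {
    split(histories, histories[by], drop = TRUE)
  } else {
    list(all = histories)
  }
  funs <- list(`3SR` = gof_3sr, `3SM` = gof_3sm,
               `2CT` = gof_2ct, `2CL` = gof_2cl)
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (comp in components) {
      res <- funs[[comp]](g, design, min_expected, pool_target)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(group = gname), tidy(res)
      )
    }
  }
  comp_tbl <- dplyr::bind_rows(rows)
  total_chi2 <- sum(comp_tbl$chi2)
  total_df <- sum(comp_tbl$df)
  structure(
    list(components = comp_tbl,
         total_chi2 = total_chi2,
         total_df = total_df,
         total_p = if (total_df > 0) {
           pchisq(total_chi2, total_df, lower.tail = FALSE)
         } else NA_real_,
         c_hat = if (total_df > 0) c_hat(total_chi2, total_df) else NA_real_),
    class = "gof_report"
  )
}

#' @export
print.gof_report <- function(x, ...) {
  cat("<gof_report>\n")
  print(x$components)
  cat(sprintf("total: chi2 = %.1f on %d df (p = %s), c-hat = %.3f\n",
              x$total_chi2, x$total_df,
              if (is.na(x$total_p)) "NA" else format.pval(x$total_p, digits = 3),
              x$c_hat))
  invisible(x)
}

#' @rdname gof_suite
#' @param x A `gof_report`.
#' @param ... Unused.
#' @method tidy gof_report
#' @export
tidy.gof_report <- function(x, ...) x$components

#' Variance inflation factor from a residual goodness-of-fit statistic
#'
#' @param chi2 Residual chi-square statistic.
#' @param df Its degrees of freedom.
#' @return `chi2 / df`.
#' @examples
#' c_hat(354.7, 203)
#' @export
c_hat <- function(chi2, df) {
  if (df <= 0) stop("df must be positive", call. = FALSE)
  chi2 / df
}
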