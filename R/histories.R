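#' @importFrom rlang .data
NULL

#' Encounter-history tibbles
#'
#' Throughout the package an encounter-history table is a tibble with one row
#' per individual: columns `id`, `sex`, `panel`, then one 0/1 column per
#' calendar year of the study design (named by the year). [history_matrix()]
#' extracts the detection matrix; [validate_histories()] checks the table
#' against a design.
#'
#' @param histories An encounter-history tibble.
#' @param design A [study_design()].
#' @return `history_matrix()`: an integer matrix, individuals x occasions,
#'   with year column names.
#' @export
history_matrix <- function(histories, design) {
  yr <- as.character(design$years)
  missing <- setdiff(yr, names(histories))
  if (length(missing)) {
    stop("histories lack year columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(histories[, yr])
  storage.mode(m) <- "integer"
  rownames(m) <- histories$id
  m
}

new_histories <- function(ids, sex, panel, H, design) {
  out <- tibble::tibble(id = as.character(ids),
                        sex = as.character(sex),
                        panel = as.character(panel))
  colnames(H) <- as.character(design$years)
  dplyr::bind_cols(out, tibble::as_tibble(H))
}

#' Validate encounter histories against a study design
#'
#' Checks that every detection vector is 0/1 with at least one detection,
#' that no detection falls in a gap year, and that no detection falls outside
#' the individual's panel range. Errors name the offending individual.
#'
#' @inheritParams history_matrix
#' @return The input tibble, invisibly, on success.
#' @export
validate_histories <- function(histories, design) {
  H <- history_matrix(histories, design)
  if (!all(H %in% c(0L, 1L))) {
    bad <- histories$id[which(rowSums(!(H == 0L | H == 1L)) > 0)[1]]
    stop("non-binary detection value for individual ", bad, call. = FALSE)
  }
  none <- rowSums(H) == 0L
  if (any(none)) {
    stop("individual ", histories$id[which(none)[1]], " has no detections",
         call. = FALSE)
  }
  gap <- is_gap(design)
  if (any(gap) && any(H[, gap, drop = FALSE] > 0L)) {
    bad <- which(rowSums(H[, gap, drop = FALSE]) > 0)[1]
    stop("individual ", histories$id[bad], " detected in a gap year",
         call. = FALSE)
  }
  mask <- capture_mask(design)
  pn <- match(histories$panel, rownames(mask))
  if (anyNA(pn)) {
    stop("unknown panel label for individual ",
         histories$id[which(is.na(pn))[1]], call. = FALSE)
  }
  viol <- rowSums(H * !mask[pn, , drop = FALSE]) > 0
  if (any(viol)) {
    stop("individual ", histories$id[which(viol)[1]],
         " detected outside its panel's active years", call. = FALSE)
  }
  invisible(histories)
}

first_capture <- function(H) {
  apply(H == 1L, 1L, function(r) which(r)[1])
}

last_capture <- function(H) {
  K <- ncol(H)
  K + 1L - apply(H[, K:1, drop = FALSE] == 1L, 1L, function(r) which(r)[1])
}

#' Read MARK-style .inp encounter histories
#'
#' Parses the classic `.inp` dialect: one record per line, a detection string
#' over all occasions followed by whitespace-separated group-count columns
#' (one per sex), terminated by `;`. `/* ... */` comments are ignored. Each
#' record is expanded to `count` individual rows per sex. Panel membership is
#' inferred from the year of first capture.
#'
#' @param path Path to the `.inp` file.
#' @param design A [study_design()].
#' @param sexes Character vector naming the group-count columns, in order.
#' @return A validated encounter-history tibble.
#' @export
read_inp <- function(path, design, sexes = c("male", "female")) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)
  recs <- strsplit(txt, ";", fixed = TRUE)[[1]]
  recs <- trimws(recs)
  recs <- recs[nzchar(recs)]
  K <- n_occasions(design)
  rows <- list()
  n <- 0L
  for (r in recs) {
    parts <- strsplit(r, "\\s+")[[1]]
    hist <- parts[1]
    if (nchar(hist) != K) {
      stop("history string '", hist, "' has length ", nchar(hist),
           ", expected ", K, call. = FALSE)
    }
    digits <- strsplit(hist, "")[[1]]
    if (!all(digits %in% c("0", "1"))) {
      stop("history string '", hist, "' contains characters other than 0/1",
           call. = FALSE)
    }
    counts <- as.numeric(parts[-1])
    if (length(counts) != length(sexes) || anyNA(counts)) {
      stop("expected ", length(sexes), " group counts after history '",
           hist, "'", call. = FALSE)
    }
    det <- as.integer(digits)
    for (g in seq_along(sexes)) {
      cnt <- counts[g]
      if (cnt > 0) {
        for (k in seq_len(cnt)) {
          n <- n + 1L
          rows[[n]] <- list(sex = sexes[g], det = det)
        }
      }
    }
  }
  if (!n) stop("no records parsed from ", path, call. = FALSE)
  H <- do.call(rbind, lapply(rows, `[[`, "det"))
  sex <- vapply(rows, `[[`, character(1), "sex")
  panel <- infer_panel(H, design)
  out <- new_histories(sprintf("ind%05d", seq_len(n)), sex, panel, H, design)
  validate_histories(out, design)
  out
}

infer_panel <- function(H, design) {
  f <- first_capture(H)
  fy <- design$years[f]
  pn <- rep(NA_character_, nrow(H))
  for (i in seq_len(nrow(design$panels))) {
    inrange <- fy >= design$panels$start[i] & fy <= design$panels$end[i]
    pn[inrange & is.na(pn)] <- design$panels$panel[i]
  }
  if (anyNA(pn)) {
    stop("first capture outside every panel range for some individuals",
         call. = FALSE)
  }
  pn
}

#' Write encounter histories in MARK .inp format
#'
#' Identical (history, sex) records are collapsed into group counts, written
#' in a fixed ordering so output is reproducible byte-for-byte.
#'
#' @inheritParams history_matrix
#' @param path Output file path.
#' @param sexes Group-column order.
#' @return `path`, invisibly.
#' @export
write_inp <- function(histories, path, design, sexes = c("male", "female")) {
  H <- history_matrix(histories, design)
  hs <- apply(H, 1L, paste, collapse = "")
  tab <- table(hist = hs, sex = factor(histories$sex, levels = sexes))
  keys <- sort(rownames(tab))
  lines <- vapply(keys, function(k) {
    paste0(k, " ", paste(as.integer(tab[k, sexes]), collapse = " "), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write encounter histories as CSV
#'
#' The CSV schema is `id, sex, panel` followed by one 0/1 column per year.
#'
#' @inheritParams read_inp
#' @return A validated encounter-history tibble.
#' @export
read_histories_csv <- function(path, design) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           sex = readr::col_character(),
                           panel = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  validate_histories(tbl, design)
  tbl
}

#' @rdname read_histories_csv
#' @inheritParams write_inp
#' @export
write_histories_csv <- function(histories, path) {
  readr::write_csv(histories, path)
  invisible(path)
}

#' Suppress each individual's first encounter
#'
#' Transient individuals (passing birds marked once and never resident) can
#' be removed from a capture-recapture dataset by recoding every animal's
#' first detection to zero, so each record effectively begins at its second
#' detection. Individuals with a single detection are dropped entirely and
#' counted.
#'
#' @inheritParams history_matrix
#' @return The reduced encounter-history tibble with attribute `n_dropped`
#'   (number of single-detection individuals removed).
#' @examples
#' d <- study_design(2001:2004)
#' h <- tibble::tibble(id = c("a", "b"), sex = "female", panel = "panel-1",
#'                     `2001` = c(0L, 1L), `2002` = c(1L, 0L),
#'                     `2003` = c(0L, 0L), `2004` = c(1L, 0L))
#' r <- suppress_first_encounter(h, d)
#' attr(r, "n_dropped")  # 1: individual "b" had a single detection
#' @export
suppress_first_encounter <- function(histories, design) {
  H <- history_matrix(histories, design)
  f <- first_capture(H)
  H[cbind(seq_len(nrow(H)), f)] <- 0L
  keep <- rowSums(H) > 0L
  out <- new_histories(histories$id[keep], histories$sex[keep],
                       histories$panel[keep], H[keep, , drop = FALSE], design)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build the m-array sufficient statistic
#'
#' The m-array tabulates, for each release occasion `i`, the number of
#' animals released (captured or recaptured) at `i` and, among those, the
#' number next re-encountered at each later occasion `j`. Together with the
#' count never seen again it is the sufficient statistic for the
#' Cormack-Jolly-Seber likelihood without individual covariates.
#'
#' @inheritParams history_matrix
#' @param sex,panel Optional filters (character); `NULL` keeps everything.
#' @return An object of class `cjs_marray` with elements `releases` (R_i,
#'   occasions 1..K-1), `recaptures` (matrix m_ij, j = 2..K), `never_seen`,
#'   and `years`.
#' @export
build_m_array <- function(histories, design, sex = NULL, panel = NULL) {
  if (!is.null(sex)) histories <- histories[histories$sex %in% sex, ]
  if (!is.null(panel)) histories <- histories[histories$panel %in% panel, ]
  if (!nrow(histories)) stop("no histories left after filtering", call. = FALSE)
  H <- history_matrix(histories, design)
  K <- ncol(H)
  R <- integer(K - 1L)
  m <- matrix(0L, K - 1L, K - 1L,
              dimnames = list(release = design$years[-K],
                              recapture = design$years[-1L]))
  for (i in seq_len(K - 1L)) {
    rel <- H[, i] == 1L
    R[i] <- sum(rel)
    if (!R[i]) next
    later <- H[rel, (i + 1L):K, drop = FALSE]
    nxt <- apply(later == 1L, 1L, function(r) which(r)[1])
    nxt <- nxt[!is.na(nxt)] + i  # absolute occasion index
    if (length(nxt)) {
      tb <- tabulate(nxt - 1L, nbins = K - 1L)
      m[i, ] <- tb
    }
  }
  structure(
    list(releases = stats::setNames(R, design$years[-K]),
         recaptures = m,
         never_seen = R - rowSums(m),
         years = design$years),
    class = "cjs_marray"
  )
}

#' @export
print.cjs_marray <- function(x, ...) {
  cat("<cjs_marray> ", length(x$releases), " release occasions, ",
      sum(x$releases), " releases\n", sep = "")
  invisible(x)
}

#' @rdname build_m_array
#' @param x A `cjs_marray`.
#' @param ... Unused.
#' @method tidy cjs_marray
#' @export
tidy.cjs_marray <- function(x, ...) {
  rec <- tibble::as_tibble(as.data.frame.table(x$recaptures,
                                               stringsAsFactors = FALSE))
  names(rec) <- c("release", "recapture", "m")
  rec$release <- as.integer(rec$release)
  rec$recapture <- as.integer(rec$recapture)
  rec <- rec[rec$recapture > rec$release, ]
  dplyr::arrange(rec, .data$release, .data$recapture)
}

#' Annotate post-first-capture occasions with the Markovian trap state
#'
#' After an individual's first capture, each occasion carries state `m1` if
#' the animal was detected at the immediately preceding non-gap occasion and
#' `m2` otherwise; gap years carry no state. Across the monitoring gap the
#' "previous occasion" of the first post-gap year is the last pre-gap year.
#'
#' @inheritParams history_matrix
#' @return A long tibble `(id, year, detected, trap_state)` with one row per
#'   individual x occasion after first capture; `trap_state` is `NA` in gap
#'   years.
#' @export
split_by_trap_state <- function(histories, design) {
  H <- history_matrix(histories, design)
  f <- first_capture(H)
  prev <- prev_nongap(design)
  gap <- is_gap(design)
  K <- ncol(H)
  n <- nrow(H)
  S <- matrix(NA_character_, n, K)
  for (j in seq_len(K)[-1L]) {
    after <- f < j
    if (gap[j] || is.na(prev[j])) next
    S[after, j] <- ifelse(H[after, prev[j]] == 1L, "m1", "m2")
  }
  idx <- which(outer(f, seq_len(K), `<`))
  tibble::tibble(
    id = histories$id[((idx - 1L) %% n) + 1L],
    year = design$years[((idx - 1L) %/% n) + 1L],
    detected = as.integer(H[idx]),
    trap_state = S[idx]
  ) |> dplyr::arrange(.data$id, .data$year)
}
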