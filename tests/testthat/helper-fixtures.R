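# Build an encounter-history tibble from a character vector of 0/1 strings.
hist_tbl <- function(strings, design, sex = "female", panel = NULL,
                     counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(strings))
  strings <- rep(strings, counts)
  sex <- rep_len(sex, length(strings))
  H <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  colnames(H) <- as.character(design$years)
  if (is.null(panel)) panel <- design$panels$panel[1]
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("h%04d", seq_along(strings)),
                   sex = sex, panel = rep_len(panel, length(strings))),
    tibble::as_tibble(H)
  )
}

# Independent per-individual m-array scan used as an oracle.
marray_by_scan <- function(histories, design) {
  H <- shearwaterCMR::history_matrix(histories, design)
  K <- ncol(H)
  R <- integer(K - 1L)
  m <- matrix(0L, K - 1L, K - 1L)
  for (ind in seq_len(nrow(H))) {
    dets <- which(H[ind, ] == 1L)
    for (d in dets) {
      if (d == K) next
      R[d] <- R[d] + 1L
      later <- dets[dets > d]
      if (length(later)) {
        j <- min(later)
        m[d, j - 1L] <- m[d, j - 1L] + 1L
      }
    }
  }
  list(releases = R, recaptures = m, never_seen = R - rowSums(m))
}

# Small single-panel design without gaps.
plain_design <- function(n_years, start = 2001L) {
  study_design(seq(start, start + n_years - 1L))
}

# Null CJS simulation config (no transients, no trap effect, constant rates).
null_config <- function(n, design, phi = 0.85, p = 0.5) {
  sim_config(n_individuals = n, design = design, slopes = numeric(),
             phi_intercept = qlogis(phi), p_intercept = qlogis(p),
             trap_offset = 0, transient_fraction = 0,
             panel_weights = 1, recruitment = "uniform")
}
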