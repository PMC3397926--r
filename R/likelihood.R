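# Internal likelihood machinery for the Cormack-Jolly-Seber model with
# Markovian trap-dependent capture and fixed-zero capture masks.
#
# Histories are collapsed to unique (sex, panel, detection-vector) records
# with multiplicities; the conditional-on-first-release log-likelihood is
# evaluated with matrix operations per (sex, panel) group:
#   * each inter-detection segment contributes survival x capture terms,
#   * the terminal segment contributes the never-seen-again recursion
#       chi_j = (1 - phi_j) + phi_j * (1 - p_{j+1}) * chi_{j+1},
#     with capture probability resolved by trap state (m1 immediately after
#     the last capture, m2 beyond) and forced to 0 where masked.

prep_histories <- function(histories, design) {
  validate_histories(histories, design)
  H <- history_matrix(histories, design)
  K <- ncol(H)
  sex <- as.character(histories$sex)
  panel <- as.character(histories$panel)
  key <- paste(sex, panel, apply(H, 1L, paste, collapse = ""))
  ord <- order(key)
  key <- key[ord]
  uniq <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[uniq])))
  Hu <- H[ord, , drop = FALSE][uniq, , drop = FALSE]
  sexu <- sex[ord][uniq]
  panelu <- panel[ord][uniq]

  sexes <- sort(unique(sex))
  panels <- design$panels$panel
  f <- first_capture(Hu)
  l <- last_capture(Hu)

  # trap-state matrix: 1 when detected at the preceding non-gap occasion
  prev <- prev_nongap(design)
  S <- matrix(0L, nrow(Hu), K)
  for (j in seq_len(K)) {
    if (!is.na(prev[j])) S[, j] <- Hu[, prev[j]]
  }

  list(H = Hu, w = w, f = f, l = l, S = S,
       sex = factor(sexu, levels = sexes),
       panel = factor(panelu, levels = panels),
       sexes = sexes, K = K, design = design,
       mask = capture_mask(design),
       n_individuals = nrow(H),
       n_releases = sum(H[, -K, drop = FALSE]))
}

# phi_mat: (K-1) x S survival probabilities by interval and sex
# pm1_mat, pm2_mat: K x S capture probabilities by occasion, sex and trap
#   state (row 1 unused). Masking by panel happens here.
# Returns total negative log-likelihood.
cjs_nll_arrays <- function(prep, phi_mat, pm1_mat, pm2_mat) {
  K <- prep$K
  design <- prep$design
  nxt <- next_nongap(design)
  total <- 0
  for (s in seq_along(prep$sexes)) {
    for (pidx in seq_len(nrow(prep$mask))) {
      sel <- which(as.integer(prep$sex) == s & as.integer(prep$panel) == pidx)
      if (!length(sel)) next
      phi <- phi_mat[, s]
      allowed <- prep$mask[pidx, ]
      pm1 <- ifelse(allowed, pm1_mat[, s], 0)
      pm2 <- ifelse(allowed, pm2_mat[, s], 0)

      # never-seen-again recursion under state m2 everywhere
      chi <- numeric(K)
      chi[K] <- 1
      for (k in (K - 1L):1L) {
        chi[k] <- (1 - phi[k]) + phi[k] * (1 - pm2[k + 1L]) * chi[k + 1L]
      }
      # tail probability at last capture l: survive (unseen, p = 0 in gaps)
      # to the next non-gap occasion jstar, miss it in state m1, then chi
      clp <- c(0, cumsum(log(phi)))  # sum log phi over intervals 1..k
      tail_l <- numeric(K)
      tail_l[K] <- 1
      for (lv in seq_len(K - 1L)) {
        js <- nxt[lv]
        if (is.na(js)) {
          tail_l[lv] <- 1
        } else {
          surv <- exp(clp[js] - clp[lv])  # prod phi over [lv, js-1]
          tail_l[lv] <- (1 - surv) + surv * (1 - pm1[js]) * chi[js]
        }
      }

      Hg <- prep$H[sel, , drop = FALSE]
      Sg <- prep$S[sel, , drop = FALSE]
      fg <- prep$f[sel]
      lg <- prep$l[sel]
      wg <- prep$w[sel]

      PM <- Sg * rep(pm1, each = length(sel)) +
        (1L - Sg) * rep(pm2, each = length(sel))
      val <- Hg * PM + (1L - Hg) * (1 - PM)
      lv_mat <- log(val)
      active <- outer(fg, seq_len(K), `<`) & outer(lg, seq_len(K), `>=`)
      lv_mat[!active] <- 0
      inner_p <- rowSums(lv_mat)
      inner_phi <- clp[lg] - clp[fg]
      ll <- inner_phi + inner_p + log(tail_l[lg])
      total <- total - sum(wg * ll)
    }
  }
  if (!is.finite(total)) total <- 1e10
  total
}

#' Conditional CJS log-likelihood at given survival and capture values
#'
#' Evaluates the Cormack-Jolly-Seber log-likelihood (conditional on first
#' release) of a set of encounter histories at explicit per-interval
#' survival and per-occasion capture probabilities, with capture resolved by
#' trap state and forced to zero in gap years and outside each individual's
#' panel range. Mostly useful for teaching, checking and enumeration tests;
#' model fitting goes through [fit_cjs()].
#'
#' @inheritParams history_matrix
#' @param phi Survival probabilities: vector of length K-1 (intervals), or a
#'   (K-1) x n_sex matrix with columns in sorted sex order.
#' @param p Capture probabilities in trap state m2 (not captured at the
#'   previous non-gap occasion): vector of length K (first entry unused) or
#'   K x n_sex matrix.
#' @param p_m1 Capture probabilities in trap state m1; defaults to `p`
#'   (no trap-dependence).
#' @return The total log-likelihood (a scalar).
#' @examples
#' d <- study_design(2001:2002)
#' h <- tibble::tibble(id = "a", sex = "f", panel = "panel-1",
#'                     `2001` = 1L, `2002` = 1L)
#' cjs_loglik(h, d, phi = 0.9, p = c(NA, 0.5))  # log(0.9 * 0.5)
#' @export
cjs_loglik <- function(histories, design, phi, p, p_m1 = p) {
  prep <- prep_histories(histories, design)
  S <- length(prep$sexes)
  K <- prep$K
  as_mat <- function(x, nr) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == nr)
      if (ncol(x) == 1L && S > 1L) x <- x[, rep(1L, S), drop = FALSE]
      x
    } else {
      stopifnot(length(x) == nr)
      matrix(x, nr, S)
    }
  }
  phi_mat <- as_mat(phi, K - 1L)
  pm2 <- as_mat(p, K)
  pm1 <- as_mat(p_m1, K)
  pm2[1L, ] <- 0
  pm1[1L, ] <- 0
  -cjs_nll_arrays(prep, phi_mat, pm1, pm2)
}

# m-array multinomial negative log-likelihood (single group, no trap
# dependence): independent cross-check for the history-based code path.
# phi: K-1 interval survivals; p: K occasion capture probabilities (entry 1
# unused). Masked occasions must already carry p = 0.
cjs_marray_nll <- function(marr, phi, p) {
  K <- length(marr$releases) + 1L
  stopifnot(length(phi) == K - 1L, length(p) == K)
  chi <- numeric(K)
  chi[K] <- 1
  for (k in (K - 1L):1L) {
    chi[k] <- (1 - phi[k]) + phi[k] * (1 - p[k + 1L]) * chi[k + 1L]
  }
  nll <- 0
  for (i in seq_len(K - 1L)) {
    Ri <- marr$releases[i]
    if (!Ri) next
    # cell probability of next re-encounter at j
    pr <- numeric(K)
    surv <- 1
    for (j in (i + 1L):K) {
      surv <- surv * phi[j - 1L]
      if (j > i + 1L) surv <- surv * (1 - p[j - 1L])
      pr[j] <- surv * p[j]
      # note: the (1 - p) factor for occasion j is applied when advancing
    }
    m_ij <- marr$recaptures[i, ]
    for (j in (i + 1L):K) {
      mij <- m_ij[j - 1L]
      if (mij > 0) nll <- nll - mij * log(pr[j])
    }
    nev <- marr$never_seen[i]
    if (nev > 0) nll <- nll - nev * log(chi[i])
  }
  as.numeric(nll)
}
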