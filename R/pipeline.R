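#' Run the full survival-analysis pipeline
#'
#' Orchestrates the analysis sequence end-to-end on one dataset:
#' goodness-of-fit decomposition of the time-dependent model, suppression of
#' first encounters to remove transients, goodness-of-fit re-evaluation,
#' overdispersion factor, fitting of a declarative model roster, QAICc
#' ranking, and ANODEV / deviance R-squared for every roster entry that
#' names a constant reference model.
#'
#' @param histories Encounter-history tibble, or `NULL` to simulate.
#' @param design A [study_design()]; defaults to the simulation config's
#'   design when simulating.
#' @param covariates Annual covariate tibble `(year, ...)` for covariate
#'   models (the simulated covariates are used when simulating).
#' @param sim A [sim_config()] used when `histories` is `NULL`.
#' @param roster A list of model entries, each a list with elements `name`,
#'   `phi`, `p` (formulas), optionally `mcst` (name of the constant
#'   reference model for ANODEV/R-squared) and `n_cov` (number of
#'   covariates). The entry named by `time_model` is the time-dependent
#'   reference.
#' @param time_model Name of the time-dependent reference model in the
#'   roster.
#' @param gof_by Grouping for the goodness-of-fit suite.
#' @param c_hat_components Goodness-of-fit components (after transience
#'   removal) whose pooled chi-square over degrees of freedom gives the
#'   variance inflation factor. The default excludes 3SR (absorbed by
#'   first-encounter suppression) and 2CT (absorbed by the trap-dependence
#'   capture structure), leaving the residual lack of fit.
#' @param anodev_n Number of time-varying survival parameters of the
#'   time-dependent reference; defaults to the number of separately
#'   estimable annual survival parameters of the design.
#' @param seed Seed (simulation and random restarts).
#' @return A `cmr_pipeline` bundle: `gof_before`, `gof_after`, `n_transients_dropped`,
#'   `c_hat`, `fits`, `selection`, `covariate_tests`, `survival`, `seed`.
#' @export
run_pipeline <- function(histories = NULL, design = NULL, covariates = NULL,
                         sim = NULL, roster, time_model = NULL,
                         gof_by = c("sex", "panel"),
                         c_hat_components = c("3SM", "2CL"),
                         anodev_n = NULL, seed = 1) {
  if (is.null(histories) == is.null(sim)) {
    stop("supply exactly one of `histories` or `sim`", call. = FALSE)
  }
  if (!is.null(sim)) {
    dataset <- simulate_histories(sim, covariates = covariates, seed = seed)
    histories <- dataset$histories
    covariates <- dataset$covariates
    design <- sim$design
  }
  if (is.null(design)) stop("`design` is required", call. = FALSE)
  validate_histories(histories, design)

  gof_before <- gof_suite(histories, design, by = gof_by)
  reduced <- suppress_first_encounter(histories, design)
  n_dropped <- attr(reduced, "n_dropped")
  gof_after <- gof_suite(reduced, design, by = gof_by)
  residual <- gof_suite(reduced, design, by = gof_by,
                        components = c_hat_components)
  chat <- if (is.na(residual$c_hat)) 1 else max(1, residual$c_hat)

  fits <- list()
  rows <- list()
  for (entry in roster) {
    fit <- fit_cjs(reduced, design, phi = entry$phi, p = entry$p,
                   covariates = covariates, c_hat = chat)
    fits[[entry$name]] <- fit
    rows[[length(rows) + 1L]] <- tibble::tibble(
      model = entry$name, np = fit$np, dev = fit$deviance)
  }
  sel <- selection_table(dplyr::bind_rows(rows), c_hat = chat)

  covtests <- NULL
  if (!is.null(time_model)) {
    dev_t <- fits[[time_model]]$deviance
    if (is.null(anodev_n)) {
      K <- n_occasions(design)
      anodev_n <- sum(!spans_gap_flag(design)[seq_len(K - 1L)])
    }
    ct <- list()
    for (entry in roster) {
      if (is.null(entry$mcst)) next
      dev_cst <- fits[[entry$mcst]]$deviance
      dev_cov <- fits[[entry$name]]$deviance
      an <- anodev(dev_cst, dev_cov, dev_t, n_cov = entry$n_cov,
                   n = anodev_n)
      an$model <- entry$name
      an$mcst <- entry$mcst
      an$r_squared <- r_squared(dev_cst, dev_cov, dev_t)
      ct[[length(ct) + 1L]] <- an
    }
    if (length(ct)) covtests <- dplyr::bind_rows(ct)
  }

  best <- sel$model[which.min(sel$qaicc)]
  structure(
    list(gof_before = gof_before, gof_after = gof_after,
         n_transients_dropped = n_dropped,
         c_hat = chat, fits = fits, selection = sel,
         covariate_tests = covtests,
         survival = predict_survival(fits[[best]]),
         best_model = best, seed = seed),
    class = "cmr_pipeline"
  )
}

#' @export
print.cmr_pipeline <- function(x, ...) {
  cat("<cmr_pipeline> seed ", x$seed, "\n", sep = "")
  cat(sprintf("  c-hat = %.3f (after removing %d single-capture records)\n",
              x$c_hat, x$n_transients_dropped))
  cat("  best model:", x$best_model, "\n")
  print(x$selection)
  invisible(x)
}
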