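# Report assembly: tidy CSVs plus a markdown summary for any subset of
# the five analysis surfaces (single-metal OA fits, metal -> marker fits,
# marker -> OA fits, WQS, mediation), and a one-call pipeline driver.

#' Assemble report files from a results bundle
#'
#' Writes one tidy CSV per analysis surface present in the bundle plus a
#' `report.md` markdown summary echoing every seed and configuration
#' value supplied. Partial bundles are allowed; an empty bundle is an
#' error. Output is deterministic: regenerating from the same bundle
#' yields byte-identical files.
#'
#' @param bundle named list with any of: `single_metal`, `metal_markers`,
#'   `marker_oa` (regression_result data.frames), `wqs` (a `wqs_fit`),
#'   `mediation` (list of `mediation_result`s), `exclusions` (exclusion
#'   log), `config` (named values echoed verbatim).
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
build_report <- function(bundle, dir) {
  sections <- intersect(c("single_metal", "metal_markers", "marker_oa",
                          "wqs", "mediation", "exclusions"), names(bundle))
  if (length(sections) == 0) stop("empty results bundle: nothing to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  md <- c("# Metal mixtures, biological aging and OA: analysis report", "")

  if (!is.null(bundle$config)) {
    md <- c(md, "## Run configuration", "",
            paste0("- ", names(bundle$config), ": ",
                   vapply(bundle$config, function(v)
                     paste(format(v, digits = 10), collapse = ", "),
                     character(1))),
            "")
  }
  if ("exclusions" %in% sections) {
    f <- file.path(dir, "exclusions.csv")
    write.csv(bundle$exclusions, f, row.names = FALSE)
    paths["exclusions"] <- f
    md <- c(md, "## Participant exclusions", "",
            sprintf("- %s: %d -> %d (excluded %d: %s)",
                    bundle$exclusions$stage, bundle$exclusions$n_before,
                    bundle$exclusions$n_after, bundle$exclusions$n_excluded,
                    bundle$exclusions$reason),
            "")
  }
  for (nm in intersect(c("single_metal", "metal_markers", "marker_oa"),
                       sections)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(bundle[[nm]], f, row.names = FALSE)
    paths[nm] <- f
    lab <- c(single_metal = "Single-metal associations with OA",
             metal_markers = "Metal associations with aging markers",
             marker_oa = "Aging-marker associations with OA")[nm]
    res <- bundle[[nm]]
    top <- res[res$encoding == "continuous", , drop = FALSE]
    md <- c(md, paste0("## ", lab), "",
            sprintf("- %s on %s: %s %.3f (%.3f, %.3f), p = %.3g, FDR p = %.3g",
                    top$exposure,
                    if (is.null(top$outcome)) "outcome" else top$outcome,
                    ifelse(top$model_family == "logistic", "OR", "beta"),
                    top$or_or_beta, top$ci_low, top$ci_high, top$p_value,
                    top$p_fdr),
            "")
  }
  if ("wqs" %in% sections) {
    fit <- bundle$wqs
    wdf <- data.frame(metal = names(fit$weights), weight = unname(fit$weights),
                      stringsAsFactors = FALSE)
    wdf <- wdf[order(-wdf$weight), ]
    f <- file.path(dir, "wqs_weights.csv")
    write.csv(wdf, f, row.names = FALSE)
    paths["wqs"] <- f
    lab <- if (fit$model_family == "logistic") "OR" else "beta"
    md <- c(md, "## WQS mixture model", "",
            sprintf("- index %s per one-quantile increase: %.3f (%.3f, %.3f), p = %.3g",
                    lab, fit$or_or_beta, fit$ci_low, fit$ci_high, fit$p_value),
            sprintf("- %d bootstraps, %.0f%% converged, %d quantiles, split seed %d",
                    fit$n_bootstrap, 100 * fit$converged_fraction,
                    fit$n_quantiles, fit$split_seed),
            sprintf("- top weights: %s",
                    paste(sprintf("%s %.1f%%", wdf$metal[1:3],
                                  100 * wdf$weight[1:3]), collapse = ", ")),
            "")
  }
  if ("mediation" %in% sections) {
    med <- bundle$mediation
    if (inherits(med, "mediation_result")) med <- list(med)
    rows <- do.call(rbind, lapply(med, function(mr) {
      eff <- mr$effects
      data.frame(exposure = mr$exposure, mediators = mr$mediators,
                 outcome = mr$outcome, mode = mr$mode, n = mr$n,
                 n_sim = mr$n_sim, seed = mr$seed, eff,
                 stringsAsFactors = FALSE)
    }))
    f <- file.path(dir, "mediation.csv")
    write.csv(rows, f, row.names = FALSE)
    paths["mediation"] <- f
    props <- rows[rows$effect == "prop_mediated", , drop = FALSE]
    md <- c(md, "## Mediation", "",
            sprintf("- %s via %s (%s): proportion mediated %.2f%% (%.2f%%, %.2f%%), p = %.3g",
                    props$exposure, props$mediators, props$mode,
                    100 * props$estimate, 100 * props$ci_low,
                    100 * props$ci_high, props$p_value),
            "")
  }
  f <- file.path(dir, "report.md")
  writeLines(md, f)
  paths["report"] <- f
  invisible(paths)
}

#' Run the full analysis pipeline on a cohort
#'
#' Convenience driver reproducing the study's analysis surfaces on one
#' cohort: exclusion cascade, covariate imputation, exposure encoding,
#' aging-marker scoring, single-metal OA fits, metal -> marker fits,
#' marker -> OA fits, WQS mixture model, and parallel mediation of the
#' WQS index through each aging marker plus the two serial
#' telomere-then-whole-body-aging paths.
#'
#' @param cohort a validated cohort table.
#' @param seed integer seed for the WQS split/bootstraps and the
#'   mediation draws.
#' @param covariates adjustment set, default [oa_covariates()].
#' @param weights optional survey-weight column name.
#' @param n_bootstrap WQS bootstrap count (default 100).
#' @param n_sim quasi-Bayesian mediation draws (default 1000).
#' @return a results bundle suitable for [build_report()], with elements
#'   `exclusions`, `single_metal`, `metal_markers`, `marker_oa`, `wqs`,
#'   `mediation`, `config`.
#' @export
run_study <- function(cohort, seed = 1L, covariates = oa_covariates(),
                      weights = NULL, n_bootstrap = 100, n_sim = 1000) {
  validate_cohort(cohort)
  excl <- apply_exclusions(cohort)
  cohort <- impute_covariates(excl$cohort)
  cohort <- add_exposure_columns(cohort)
  cohort <- attach_aging_markers(cohort, quiet = TRUE)

  single <- fit_single_metals(cohort, covariates = covariates,
                              weights = weights)
  markers <- fit_metal_markers(cohort, covariates = covariates,
                               weights = weights)
  marker_oa <- fit_marker_oa(cohort, covariates = covariates,
                             weights = weights)
  wqs <- fit_wqs(cohort, "oa_status", covariates = covariates,
                 weights = weights, direction = "positive",
                 n_bootstrap = n_bootstrap, seed = seed)
  cohort$wqs_index <- wqs_index(wqs, cohort)

  med <- list()
  for (mk in c("biological_age", "phenotypic_age", "telomere_ts")) {
    med[[paste0("parallel_", mk)]] <- mediate_parallel(
      cohort, "wqs_index", mk, "oa_status", covariates = covariates,
      n_sim = n_sim, seed = seed, weights = weights)
  }
  for (mk in c("biological_age", "phenotypic_age")) {
    med[[paste0("serial_telomere_", mk)]] <- mediate_serial(
      cohort, "wqs_index", c("telomere_ts", mk), "oa_status",
      covariates = covariates, n_sim = n_sim, seed = seed, weights = weights)
  }
  list(exclusions = excl$log, single_metal = single, metal_markers = markers,
       marker_oa = marker_oa, wqs = wqs, mediation = med,
       config = list(seed = seed, n_bootstrap = n_bootstrap, n_sim = n_sim,
                     weighted = !is.null(weights),
                     covariates = paste(covariates, collapse = "+"),
                     n_participants = nrow(cohort)))
}
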