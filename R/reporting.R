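## Multi-disease orchestration: filters, automatic household inclusion by
## case count, full-data fits for significance, family bootstrap for
## intervals, and Benjamini-Hochberg correction across diseases.

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest down, cap at 1), returned in the original
#' order.  A thin validated front over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise `>=` the input and `<= 1`.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}

#' Run the full multi-disease heritability study
#'
#' For each disease surviving the exclusion filters: builds the design,
#' decides household inclusion by the case-count rule (`>=
#' min_cases_household` cases, overridable per disease), fits the polygenic
#' model on the full data for the boundary-LRT p-values, and runs the
#' family bootstrap for point estimates (bootstrap means), 95% percentile
#' intervals and distribution-shape diagnostics.  P-values are then
#' FDR-adjusted across diseases, by default separately within the h2 family
#' and the c2 family of tests.
#'
#' @param cohort a `ped_cohort`.
#' @param diseases diseases to analyse (default: all that survive filters).
#' @param boot_config a [bootstrap_config()]; its `include_household` flag
#'   is combined with the per-disease case-count rule.
#' @param rules an [exclusion_rules()] object applied before analysis.
#' @param min_cases_household case-count threshold for the household
#'   component.
#' @param household_override optional named logical vector forcing
#'   household inclusion/exclusion for specific diseases.
#' @param fdr_family `"separate"` adjusts h2 and c2 p-values as two
#'   families; `"pooled"` adjusts them jointly.
#' @param trait `"status"` or `"liability"` (see [build_design()]).
#' @param output_dir if non-`NULL`, writes `summary.tsv`,
#'   `exclusion_log.tsv` and per-disease `replicates_<disease>.tsv` there.
#' @return object of class `study_result`: `summary` (one row per disease),
#'   `fits`, `bootstraps`, `exclusion_log`.
#' @export
run_study <- function(cohort, diseases = NULL,
                      boot_config = bootstrap_config(),
                      rules = exclusion_rules(),
                      min_cases_household = 225L,
                      household_override = NULL,
                      fdr_family = c("separate", "pooled"),
                      trait = c("status", "liability"),
                      output_dir = NULL) {
  fdr_family <- match.arg(fdr_family)
  trait <- match.arg(trait)
  filt <- apply_exclusion_filters(cohort, rules)
  cohort <- filt$cohort
  exclusion_log <- filt$log
  todo <- if (is.null(diseases)) cohort$diseases else
    intersect(diseases, cohort$diseases)
  if (!length(todo)) stop("no diseases survive the exclusion filters")
  fits <- boots <- list()
  rows <- list()
  for (d in todo) {
    design <- build_design(cohort, d, trait = trait)
    exclusion_log <- rbind(exclusion_log, design$exclusions)
    household <- if (!is.null(household_override) &&
                     d %in% names(household_override)) {
      isTRUE(household_override[[d]])
    } else {
      boot_config$include_household &&
        (trait == "liability" || design$n_cases >= min_cases_household)
    }
    structures <- cohortStructures(cohort, family_ids = unique(design$fid),
                                   ids = design$ids)
    fit <- fit_polygenic(design, structures, include_household = household,
                         min_cases_household = min_cases_household)
    cfg <- boot_config
    cfg$include_household <- household
    bt <- run_bootstrap(cohort, d, cfg, trait = trait,
                        min_cases_household = min_cases_household)
    fits[[d]] <- fit
    boots[[d]] <- bt
    rows[[d]] <- data.frame(
      disease = d,
      n_cases = design$n_cases,
      n_families_with_case = design$n_families_with_case,
      h2_percent = 100 * bt$point_h2,
      h2_ci_lower = 100 * bt$ci_h2[1],
      h2_ci_upper = 100 * bt$ci_h2[2],
      c2_percent = if (household) 100 * bt$point_c2 else NA_real_,
      c2_ci_lower = if (household) 100 * bt$ci_c2[1] else NA_real_,
      c2_ci_upper = if (household) 100 * bt$ci_c2[2] else NA_real_,
      p_h2 = fit$p_h2,
      p_c2 = if (household) fit$p_c2 else NA_real_,
      household_included = household,
      shape = if (is.null(bt$shape)) NA_character_ else bt$shape$label,
      n_boot_success = bt$n_success,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (fdr_family == "separate") {
    summary$p_h2_fdr <- bh_fdr(summary$p_h2)
    has_c2 <- !is.na(summary$p_c2)
    summary$p_c2_fdr <- NA_real_
    if (any(has_c2)) summary$p_c2_fdr[has_c2] <- bh_fdr(summary$p_c2[has_c2])
  } else {
    has_c2 <- !is.na(summary$p_c2)
    pooled <- bh_fdr(c(summary$p_h2, summary$p_c2[has_c2]))
    summary$p_h2_fdr <- pooled[seq_len(nrow(summary))]
    summary$p_c2_fdr <- NA_real_
    if (any(has_c2)) {
      summary$p_c2_fdr[has_c2] <- pooled[-seq_len(nrow(summary))]
    }
  }
  res <- structure(list(summary = summary, fits = fits, bootstraps = boots,
                        exclusion_log = exclusion_log),
                   class = "study_result")
  if (!is.null(output_dir)) write_study_outputs(res, output_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("Heritability study over", nrow(x$summary), "disease(s)\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s h2 = %5.1f%% (%.0f-%.0f)  p_fdr = %-8.3g",
                s$disease[i], s$h2_percent[i], s$h2_ci_lower[i],
                s$h2_ci_upper[i], s$p_h2_fdr[i]))
    if (!is.na(s$c2_percent[i])) {
      cat(sprintf("  c2 = %4.1f%% (%.0f-%.0f)", s$c2_percent[i],
                  s$c2_ci_lower[i], s$c2_ci_upper[i]))
    }
    cat("  [", s$shape[i], "]\n", sep = "")
  }
  invisible(x)
}

#' Write study outputs
#'
#' Writes the summary table (`summary.tsv`), the exclusion log
#' (`exclusion_log.tsv`) and one replicate log per disease
#' (`replicates_<disease>.tsv`) to a directory.  Output is
#' deterministic for a given study result.
#'
#' @param result a `study_result`.
#' @param output_dir directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_study_outputs <- function(result, output_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$summary, file.path(output_dir, "summary.tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  write.table(result$exclusion_log,
              file.path(output_dir, "exclusion_log.tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  for (d in names(result$bootstraps)) {
    write_bootstrap_log(result$bootstraps[[d]],
                        file.path(output_dir,
                                  paste0("replicates_", d, ".tsv")))
  }
  invisible(output_dir)
}

#' Plot a bootstrap heritability distribution
#'
#' Histogram with a density overlay of the per-replicate h2 estimates,
#' annotated with the shape label; the visual counterpart of
#' [summarize_distribution()].
#'
#' @param x a `bootstrap_result`.
#' @param ... passed to [graphics::hist()].
#' @importFrom graphics hist lines abline legend
#' @importFrom stats density
#' @export
plot.bootstrap_result <- function(x, ...) {
  h2 <- x$estimates$h2[x$estimates$converged]
  hist(h2, breaks = 30, freq = FALSE, xlim = c(0, 1),
       main = paste0("Bootstrap h2: ", x$disease,
                     if (!is.null(x$shape)) paste0(" (", x$shape$label, ")")),
       xlab = expression(h^2), ...)
  if (length(h2) > 1 && sd(h2) > 0) lines(density(h2), lwd = 2)
  abline(v = x$point_h2, lty = 2)
  invisible(x)
}
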