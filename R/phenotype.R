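## Phenotype preparation: disease-category merging, exclusion rules (rare
## diseases, implausibly early onsets, incomplete records), the analysis-age
## precedence (onset > assessment > death), and the per-disease design
## matrix with sex/age covariates.

#' Merge disease categories
#'
#' Replaces a set of source disease labels by one target label: an
#' individual is affected for the target iff affected for any source, the
#' merged onset is the earliest source onset, and the source columns are
#' removed.  Typical use: pooling a specific diagnosis with its unspecified
#' counterpart (e.g. Alzheimer's disease with dementia of unspecified
#' etiology) to capture familial aggregation of one clinical entity.
#'
#' @param cohort a `ped_cohort`.
#' @param source_labels existing disease names to pool.
#' @param target_label name of the merged disease (may equal one source).
#' @return the modified cohort.
#' @export
merge_disease_categories <- function(cohort, source_labels, target_label) {
  stopifnot(inherits(cohort, "ped_cohort"))
  unknown <- setdiff(source_labels, cohort$diseases)
  if (length(unknown)) {
    stop("unknown disease label(s): ", paste(unknown, collapse = ", "))
  }
  ind <- cohort$individuals
  st <- sapply(source_labels, function(d) ind[[paste0(d, "_status")]])
  on <- sapply(source_labels, function(d) ind[[paste0(d, "_onset")]])
  st <- matrix(st, nrow = nrow(ind))
  on <- matrix(on, nrow = nrow(ind))
  any1 <- apply(st, 1, function(r) any(!is.na(r) & r == 1L))
  all_na <- apply(st, 1, function(r) all(is.na(r)))
  status <- ifelse(any1, 1L, ifelse(all_na, NA_integer_, 0L))
  onset <- apply(on, 1, function(r) if (all(is.na(r))) NA_real_ else
    min(r, na.rm = TRUE))
  onset[is.na(status) | status == 0L] <- NA_real_
  drop_cols <- unlist(lapply(source_labels, function(d) {
    paste0(d, c("_status", "_onset", "_liability"))
  }))
  ind <- ind[setdiff(names(ind), drop_cols)]
  ind[[paste0(target_label, "_status")]] <- as.integer(status)
  ind[[paste0(target_label, "_onset")]] <- onset
  cohort$individuals <- ind
  cohort$diseases <- c(setdiff(cohort$diseases, source_labels),
                       target_label)
  cohort
}

#' Exclusion rules
#'
#' @param min_cases diseases with `min_cases` cases or fewer are removed
#'   from the analysis (strict: a disease with exactly `min_cases` cases is
#'   dropped).
#' @param min_onset named numeric vector, disease -> minimum plausible age
#'   at onset (years); earlier onsets are not considered age-related disease.
#' @param early_onset_action `"exclude"` removes the individual from that
#'   disease's analysis (status set to missing); `"recode"` keeps the
#'   individual as unaffected.
#' @return a list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_cases = 50L,
                            min_onset = c(AD = 20, VaD = 20, FTD = 20,
                                          DLB = 20, iCVA = 10, hCVA = 10),
                            early_onset_action = c("exclude", "recode")) {
  structure(list(min_cases = as.integer(min_cases),
                 min_onset = min_onset,
                 early_onset_action = match.arg(early_onset_action)),
            class = "exclusion_rules")
}

#' Apply exclusion filters
#'
#' Applies, per disease: (1) the early-onset rule - affected individuals
#' with onset below the disease's minimum are excluded from that disease's
#' analysis (or recoded unaffected, per the rules), staying in the cohort
#' for all other diseases; (2) the rare-disease rule - diseases whose
#' remaining case count is `min_cases` or fewer are dropped entirely.
#' Every action is logged with a reason code.  The operation is idempotent.
#'
#' @param cohort a `ped_cohort`.
#' @param rules an [exclusion_rules()] object.
#' @return list with elements `cohort` (filtered) and `log` (data.frame
#'   `fid`, `iid`, `disease`, `reason`, `rule_value`; disease-level drops
#'   have `iid = NA`).
#' @export
apply_exclusion_filters <- function(cohort, rules = exclusion_rules()) {
  stopifnot(inherits(cohort, "ped_cohort"),
            inherits(rules, "exclusion_rules"))
  ind <- cohort$individuals
  log <- list()
  note <- function(fid, iid, disease, reason, value) {
    log[[length(log) + 1L]] <<- data.frame(
      fid = fid, iid = iid, disease = disease, reason = reason,
      rule_value = value, stringsAsFactors = FALSE)
  }
  keep <- character(0)
  for (d in cohort$diseases) {
    sc <- paste0(d, "_status"); oc <- paste0(d, "_onset")
    minage <- if (d %in% names(rules$min_onset)) rules$min_onset[[d]] else NA
    if (!is.na(minage)) {
      early <- which(!is.na(ind[[sc]]) & ind[[sc]] == 1L &
                       !is.na(ind[[oc]]) & ind[[oc]] < minage)
      if (length(early)) {
        if (rules$early_onset_action == "exclude") {
          ind[[sc]][early] <- NA_integer_
          reason <- "early_onset"
        } else {
          ind[[sc]][early] <- 0L
          reason <- "early_onset_recoded"
        }
        ind[[oc]][early] <- NA_real_
        for (i in early) note(ind$fid[i], ind$iid[i], d, reason, minage)
      }
    }
    ncase <- sum(ind[[sc]] == 1L, na.rm = TRUE)
    if (ncase <= rules$min_cases) {
      note(NA_character_, NA_character_, d, "rare_disease",
           rules$min_cases)
      ind <- ind[setdiff(names(ind),
                         paste0(d, c("_status", "_onset", "_liability")))]
    } else {
      keep <- c(keep, d)
    }
  }
  cohort$individuals <- ind
  cohort$diseases <- keep
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(fid = character(), iid = character(), disease = character(),
               reason = character(), rule_value = numeric(),
               stringsAsFactors = FALSE)
  list(cohort = cohort, log = log)
}

#' Analysis age per disease
#'
#' The age entering the covariate model, determined per disease with the
#' precedence: reported age at symptom onset (for affected individuals with
#' a known onset), then age at assessment, then age at death.  `NA` when all
#' three are missing (such individuals are excluded from the design).
#'
#' @param cohort a `ped_cohort`.
#' @param disease disease name.
#' @return numeric vector along `cohort$individuals`.
#' @export
analysis_age <- function(cohort, disease) {
  ind <- cohort$individuals
  st <- ind[[paste0(disease, "_status")]]
  if (is.null(st)) stop("unknown disease '", disease, "'")
  onset <- ind[[paste0(disease, "_onset")]]
  age <- ifelse(!is.na(st) & st == 1L & !is.na(onset), onset,
                ifelse(!is.na(ind$age_at_assessment), ind$age_at_assessment,
                       ind$age_at_death))
  as.numeric(age)
}

#' Build the analysis design for one disease
#'
#' Restricts to individuals with complete sex, analysis age and disease
#' status, and assembles the fixed-effect covariate matrix with columns
#' `intercept`, `sex` (0 = male, 1 = female), `age`, `age2`, `age_x_sex`,
#' `age2_x_sex`, where age is centered at the included-sample mean before
#' squaring (conditioning only; the fitted model space is unchanged).
#' Rank-deficient designs (e.g. single-sex subsamples) degrade gracefully:
#' the offending columns are dropped with a warning and recorded.
#'
#' @param cohort a `ped_cohort`.
#' @param disease disease name.
#' @param trait `"status"` fits the observed 0/1 disease scale;
#'   `"liability"` fits the simulated latent liability (available for
#'   synthetic cohorts; used for calibration studies).
#' @return object of class `phenotype_design`: list with `disease`, `ids`,
#'   `fid`, `response`, `covariates` (matrix), `n_cases`,
#'   `n_families_with_case`, `exclusions` (missing-data log) and
#'   `dropped_columns`.
#' @export
build_design <- function(cohort, disease, trait = c("status", "liability")) {
  trait <- match.arg(trait)
  ind <- cohort$individuals
  sc <- paste0(disease, "_status")
  if (is.null(ind[[sc]])) stop("unknown disease '", disease, "'")
  status <- ind[[sc]]
  age <- analysis_age(cohort, disease)
  y <- if (trait == "status") as.numeric(status) else {
    lc <- ind[[paste0(disease, "_liability")]]
    if (is.null(lc)) stop("no liability column for '", disease, "'")
    lc
  }
  ok_sex <- !is.na(ind$sex)
  ok_age <- !is.na(age)
  ok_y <- !is.na(y) & !is.na(status)
  inc <- ok_sex & ok_age & ok_y
  excl <- list()
  for (why in c("missing_sex", "missing_age", "missing_status")) {
    bad <- switch(why, missing_sex = !ok_sex,
                  missing_age = ok_sex & !ok_age,
                  missing_status = ok_sex & ok_age & !ok_y)
    if (any(bad)) {
      excl[[why]] <- data.frame(fid = ind$fid[bad], iid = ind$iid[bad],
                                disease = disease, reason = why,
                                rule_value = NA_real_,
                                stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE)) else
    data.frame(fid = character(), iid = character(), disease = character(),
               reason = character(), rule_value = numeric(),
               stringsAsFactors = FALSE)
  n_cases <- sum(status[inc] == 1L, na.rm = TRUE)
  if (!any(inc)) stop("no analysable individuals for '", disease, "'",
                      call. = FALSE)
  yv <- y[inc]
  if (trait == "status" && (n_cases == 0L || var(yv) == 0)) {
    stop("unfittable design for '", disease,
         "': response has no variation", call. = FALSE)
  }
  sexv <- ind$sex[inc] - 1L
  agev <- age[inc]
  age_c <- agev - mean(agev)
  X <- cbind(intercept = 1, sex = sexv, age = age_c, age2 = age_c^2,
             age_x_sex = age_c * sexv, age2_x_sex = age_c^2 * sexv)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("rank-deficient design for '", disease, "': dropping column(s) ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  structure(list(disease = disease, ids = ind$iid[inc], fid = ind$fid[inc],
                 response = yv, covariates = X, n_cases = n_cases,
                 n_families_with_case =
                   length(unique(ind$fid[inc][status[inc] == 1L])),
                 trait = trait, exclusions = exclusions,
                 dropped_columns = dropped),
            class = "phenotype_design")
}

#' @export
print.phenotype_design <- function(x, ...) {
  cat("Design for '", x$disease, "' (", x$trait, " scale): ",
      length(x$response), " individuals in ", length(unique(x$fid)),
      " families; ", x$n_cases, " cases in ", x$n_families_with_case,
      " families\n", sep = "")
  cat("covariates: ", paste(colnames(x$covariates), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
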