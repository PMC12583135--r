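## Core container: a cohort of extended families with per-disease phenotypes.
## One data.frame row per individual; disease d contributes columns
## "<d>_status" (0/1/NA), "<d>_onset" (years, NA unless affected) and, for
## simulated cohorts, "<d>_liability" (latent scale).

.COHORT_COLS <- c("fid", "iid", "pat", "mat", "sex", "birth_year",
                  "alive", "age_at_assessment", "age_at_death")

#' Construct a pedigree cohort
#'
#' Bundles a per-individual table (pedigree structure, demographics and
#' per-disease phenotype columns) into a `ped_cohort` object used by all
#' downstream stages.
#'
#' @param individuals data.frame with columns `fid`, `iid`, `pat`, `mat`
#'   (parent IDs, `"0"` = unknown), `sex` (1 = male, 2 = female),
#'   `birth_year`, `alive` (logical), `age_at_assessment`, `age_at_death`,
#'   plus per-disease columns `<disease>_status` and `<disease>_onset`.
#' @param diseases character vector of disease names carried by the
#'   phenotype columns; defaults to the names inferred from `*_status`
#'   columns.
#' @return An object of class `ped_cohort`: a list with elements
#'   `individuals` (the table, IDs coerced to character) and `diseases`.
#' @examples
#' trio <- data.frame(
#'   fid = "f1", iid = c("p1", "p2", "k1"),
#'   pat = c("0", "0", "p1"), mat = c("0", "0", "p2"),
#'   sex = c(1L, 2L, 1L), birth_year = c(1940, 1942, 1970),
#'   alive = TRUE, age_at_assessment = c(84, 82, 54), age_at_death = NA_real_,
#'   ad_status = c(1L, 0L, 0L), ad_onset = c(78, NA, NA))
#' cohort(trio)
#' @export
cohort <- function(individuals, diseases = NULL) {
  stopifnot(is.data.frame(individuals))
  missing_cols <- setdiff(.COHORT_COLS, names(individuals))
  if (length(missing_cols)) {
    stop("individuals table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ind <- as.data.frame(individuals, stringsAsFactors = FALSE)
  for (cc in c("fid", "iid", "pat", "mat")) ind[[cc]] <- as.character(ind[[cc]])
  ind$sex <- as.integer(ind$sex)
  ind$alive <- as.logical(ind$alive)
  if (is.null(diseases)) {
    st <- grep("_status$", names(ind), value = TRUE)
    diseases <- sub("_status$", "", st)
  }
  for (d in diseases) {
    sc <- paste0(d, "_status")
    if (!sc %in% names(ind)) {
      stop("no status column for declared disease '", d, "'")
    }
    ind[[sc]] <- as.integer(ind[[sc]])
    oc <- paste0(d, "_onset")
    if (!oc %in% names(ind)) ind[[oc]] <- NA_real_
  }
  if (anyDuplicated(ind$iid)) {
    dup <- unique(ind$iid[duplicated(ind$iid)])
    stop("duplicate individual IDs: ", paste(head(dup, 5), collapse = ", "))
  }
  bad_sex <- !(ind$sex %in% c(1L, 2L))
  if (any(bad_sex)) {
    stop("sex must be coded 1 (male) or 2 (female); offending IDs: ",
         paste(head(ind$iid[bad_sex], 5), collapse = ", "))
  }
  structure(list(individuals = ind, diseases = diseases),
            class = "ped_cohort")
}

#' @export
print.ped_cohort <- function(x, ...) {
  ind <- x$individuals
  cat("Pedigree cohort: ", nrow(ind), " individuals in ",
      length(unique(ind$fid)), " families\n", sep = "")
  if (length(x$diseases)) {
    ncase <- vapply(x$diseases, function(d) {
      sum(ind[[paste0(d, "_status")]] == 1L, na.rm = TRUE)
    }, integer(1))
    cat("Diseases (cases): ",
        paste(sprintf("%s=%d", x$diseases, ncase), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Disease names carried by a cohort
#' @param x a `ped_cohort`
#' @return character vector of disease names
#' @export
diseases <- function(x) {
  stopifnot(inherits(x, "ped_cohort"))
  x$diseases
}

#' Family identifiers of a cohort
#' @param x a `ped_cohort`
#' @return character vector of unique family IDs, in order of appearance
#' @export
familyIDs <- function(x) {
  stopifnot(inherits(x, "ped_cohort"))
  unique(x$individuals$fid)
}

#' Number of cases and of families with at least one case
#' @param x a `ped_cohort`
#' @param disease disease name
#' @return named integer vector `c(n_cases, n_families_with_case)`
#' @export
caseCounts <- function(x, disease) {
  ind <- x$individuals
  st <- ind[[paste0(disease, "_status")]]
  if (is.null(st)) stop("unknown disease '", disease, "'")
  aff <- !is.na(st) & st == 1L
  c(n_cases = sum(aff),
    n_families_with_case = length(unique(ind$fid[aff])))
}

## rows of one family, in stored order
.family_rows <- function(cohort, fid) {
  which(cohort$individuals$fid == fid)
}
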