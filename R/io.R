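## Reading and writing cohorts: LINKAGE/PLINK-fam-style pedigree file
## (FID IID PAT MAT SEX, "0" = unknown parent) plus a tab-delimited
## phenotype table keyed by FID + IID.

#' Write a cohort to a pedigree file and a phenotype table
#'
#' The pedigree file is whitespace-delimited with header
#' `FID IID PAT MAT SEX` (`0` marks an unknown parent, sex is 1 = male,
#' 2 = female).  The phenotype file is tab-delimited, keyed by `FID` and
#' `IID`, with `birth_year`, `alive`, `age_at_assessment`, `age_at_death`
#' and the per-disease `<disease>_status` / `<disease>_onset` columns
#' (liability columns of simulated cohorts are carried along so that a
#' round trip reproduces the cohort exactly).
#'
#' @param cohort a `ped_cohort`.
#' @param ped_file,pheno_file output paths.
#' @return invisibly, the two paths.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, ped_file, pheno_file) {
  stopifnot(inherits(cohort, "ped_cohort"))
  ind <- cohort$individuals
  ped <- data.frame(FID = ind$fid, IID = ind$iid, PAT = ind$pat,
                    MAT = ind$mat, SEX = ind$sex)
  write.table(ped, ped_file, quote = FALSE, row.names = FALSE, sep = " ")
  keep <- setdiff(names(ind), c("fid", "iid", "pat", "mat", "sex"))
  ph <- cbind(data.frame(FID = ind$fid, IID = ind$iid), ind[keep])
  write.table(ph, pheno_file, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(c(ped = ped_file, pheno = pheno_file))
}

#' Read a cohort from a pedigree file and a phenotype table
#'
#' Parses the formats written by [write_cohort()].  Structural problems are
#' reported with their line numbers: malformed rows (wrong column count),
#' sex codes outside `{1, 2, M, F}`, duplicate individual IDs, and parent
#' IDs that do not resolve to an individual in the same family.
#'
#' @param ped_file,pheno_file input paths.
#' @return a `ped_cohort`.
#' @export
read_cohort <- function(ped_file, pheno_file) {
  lines <- readLines(ped_file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("pedigree file is empty: ", ped_file)
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toupper(toks[[1]])
  body <- toks[-1]
  lineno <- seq_along(toks)[-1]
  if (!identical(header[1:5], c("FID", "IID", "PAT", "MAT", "SEX"))) {
    stop("pedigree file must have header 'FID IID PAT MAT SEX' (line 1)")
  }
  bad <- which(lengths(body) != 5L)
  if (length(bad)) {
    stop("malformed pedigree line(s) (expected 5 fields): line ",
         paste(lineno[bad], collapse = ", "))
  }
  m <- do.call(rbind, body)
  ped <- data.frame(fid = m[, 1], iid = m[, 2], pat = m[, 3], mat = m[, 4],
                    sex_raw = m[, 5], stringsAsFactors = FALSE)
  sex_map <- c("1" = 1L, "2" = 2L, "M" = 1L, "F" = 2L, "m" = 1L, "f" = 2L)
  sex <- unname(sex_map[ped$sex_raw])
  if (anyNA(sex)) {
    bad <- which(is.na(sex))[1]
    stop("invalid sex code '", ped$sex_raw[bad], "' at line ", lineno[bad],
         " (expected 1/2 or M/F)")
  }
  ped$sex <- sex
  dup <- duplicated(ped$iid)
  if (any(dup)) {
    b <- which(dup)[1]
    stop("duplicate individual ID '", ped$iid[b], "' at line ", lineno[b])
  }
  for (role in c("pat", "mat")) {
    ref <- ped[[role]]
    known <- ref != "0"
    hit <- match(ref[known], ped$iid)
    miss <- which(known)[is.na(hit)]
    if (length(miss)) {
      b <- miss[1]
      stop("dangling ", if (role == "pat") "father" else "mother",
           " ID '", ref[b], "' at line ", lineno[b],
           " (no such individual)")
    }
    cross <- which(known)[ped$fid[hit] != ped$fid[known]]
    if (length(cross)) {
      b <- cross[1]
      stop("parent ID '", ref[b], "' at line ", lineno[b],
           " belongs to a different family")
    }
  }
  ph <- read.table(pheno_file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(FID = "character", IID = "character"))
  key <- match(ped$iid, ph$IID)
  if (anyNA(key)) {
    stop("phenotype table is missing individual(s): ",
         paste(head(ped$iid[is.na(key)], 5), collapse = ", "))
  }
  ph <- ph[key, , drop = FALSE]
  ind <- data.frame(fid = ped$fid, iid = ped$iid, pat = ped$pat,
                    mat = ped$mat, sex = ped$sex, stringsAsFactors = FALSE)
  for (cc in setdiff(names(ph), c("FID", "IID"))) ind[[cc]] <- ph[[cc]]
  need <- setdiff(c("birth_year", "alive", "age_at_assessment",
                    "age_at_death"), names(ind))
  if (length(need)) {
    stop("phenotype table is missing column(s): ",
         paste(need, collapse = ", "))
  }
  rownames(ind) <- NULL
  cohort(ind)
}

#' Write / read a simulation configuration as YAML
#'
#' Serialises every [sim_config()] field to one structured text file so a
#' simulation scenario can be stored next to its outputs and re-run.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `write_sim_config()`: the path, invisibly.  `read_sim_config()`:
#'   a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  for (f in c("target_prevalences", "onset_mean", "onset_sd")) {
    out[[f]] <- as.list(out[[f]])   # keep names through YAML maps
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("target_prevalences", "onset_mean", "onset_sd")) {
    raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}
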