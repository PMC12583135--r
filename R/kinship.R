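## Pedigree validation and kinship: the genetic covariance structure of the
## polygenic model is 2*Phi (twice the kinship matrix), computed by the
## classic recursion, plus an all-ones household matrix H per family.

#' Validate pedigree structure
#'
#' Scans a cohort for structural problems: parent IDs that do not resolve,
#' parents recorded in a different family, self-parenting, sex-inconsistent
#' parents (a father must be male, a mother female), and cycles through the
#' parent links.  Issues are returned as data, not raised as errors.
#'
#' @param cohort a `ped_cohort`.
#' @return data.frame with columns `fid`, `iid`, `issue`, `detail`;
#'   zero rows when the pedigree is valid.
#' @export
validate_pedigree <- function(cohort) {
  stopifnot(inherits(cohort, "ped_cohort"))
  ind <- cohort$individuals
  issues <- list()
  note <- function(fid, iid, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      fid = fid, iid = iid, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  fi <- match(ind$pat, ind$iid)
  mi <- match(ind$mat, ind$iid)
  for (i in seq_len(nrow(ind))) {
    for (role in c("pat", "mat")) {
      pid <- ind[[role]][i]
      if (pid == "0") next
      pidx <- if (role == "pat") fi[i] else mi[i]
      lbl <- if (role == "pat") "father" else "mother"
      if (pid == ind$iid[i]) {
        note(ind$fid[i], ind$iid[i], "self_parent",
             paste0("individual is its own ", lbl))
        next
      }
      if (is.na(pidx)) {
        note(ind$fid[i], ind$iid[i], "dangling_parent",
             paste0(lbl, " ID '", pid, "' not found"))
        next
      }
      if (ind$fid[pidx] != ind$fid[i]) {
        note(ind$fid[i], ind$iid[i], "cross_family_parent",
             paste0(lbl, " '", pid, "' belongs to family ",
                    ind$fid[pidx]))
      }
      want <- if (role == "pat") 1L else 2L
      if (ind$sex[pidx] != want) {
        note(ind$fid[i], ind$iid[i], "parent_sex",
             paste0(lbl, " '", pid, "' has sex ", ind$sex[pidx]))
      }
    }
  }
  depth <- .pedigree_depth(fi, mi)
  cyc <- which(!is.finite(depth) & ind$pat != ind$iid & ind$mat != ind$iid)
  for (i in cyc) {
    note(ind$fid[i], ind$iid[i], "cycle",
         "parent links form a cycle through this individual")
  }
  if (!length(issues)) {
    return(data.frame(fid = character(), iid = character(),
                      issue = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

## kinship matrix Phi for one family given parent indices (NA = founder),
## by the standard recursion in depth order:
##   Phi(i,i) = (1 + Phi(f_i, m_i)) / 2
##   Phi(i,j) = (Phi(f_i, j) + Phi(m_i, j)) / 2  for previously placed j
.kinship_matrix <- function(fi, mi) {
  n <- length(fi)
  K <- matrix(0, n, n)
  ord <- order(.pedigree_depth(fi, mi))
  placed <- integer(0)
  for (i in ord) {
    pf <- fi[i]; pm <- mi[i]
    if (length(placed)) {
      row <- 0.5 * ((if (!is.na(pf)) K[pf, placed] else 0) +
                      (if (!is.na(pm)) K[pm, placed] else 0))
      K[i, placed] <- row
      K[placed, i] <- row
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(pf) && !is.na(pm)) K[pf, pm] else 0)
    placed <- c(placed, i)
  }
  K
}

#' Kinship coefficient between two individuals
#'
#' Probability that one allele drawn at random from each individual is
#' identical by descent, computed by the classic pedigree recursion
#' (unknown parents contribute zero; inbreeding is supported, so
#' `2 * phi(i, i)` may exceed 1).  Individuals in different families are
#' unrelated by construction and return 0.  Relatedness as "percent shared
#' genetic factors" is `2 * phi * 100`: 50% for parent-child and full
#' siblings, 25% for grandparent-grandchild and half-siblings, 0% for
#' unrelated partners.
#'
#' @param cohort a `ped_cohort`.
#' @param id1,id2 individual IDs.
#' @return the kinship coefficient, a number in `[0, 1]`.
#' @export
kinship_coefficient <- function(cohort, id1, id2) {
  ind <- cohort$individuals
  i1 <- match(id1, ind$iid)
  i2 <- match(id2, ind$iid)
  if (is.na(i1)) stop("unknown individual ID '", id1, "'")
  if (is.na(i2)) stop("unknown individual ID '", id2, "'")
  if (ind$fid[i1] != ind$fid[i2]) return(0)
  rows <- .family_rows(cohort, ind$fid[i1])
  fi <- match(ind$pat[rows], ind$iid[rows])
  mi <- match(ind$mat[rows], ind$iid[rows])
  K <- .kinship_matrix(fi, mi)
  K[match(i1, rows), match(i2, rows)]
}

#' Relatedness and household structure of one family
#'
#' Computes the genetic relatedness matrix `2 * Phi` over the family's
#' members together with the household indicator matrix `H`, which is 1 for
#' every pair in the family (each family shares one household) including the
#' diagonal.
#'
#' @param cohort a `ped_cohort`.
#' @param family_id family ID.
#' @param ids optional subset of individual IDs to retain (rows/columns are
#'   computed on the full family, then restricted, so relatives excluded
#'   from an analysis still connect the remaining members).
#' @return an object of class `relatedness_structure`: list with
#'   `family_id`, `member_order`, `relatedness` (2*Phi) and `household`.
#' @export
relatedness_matrix <- function(cohort, family_id, ids = NULL) {
  rows <- .family_rows(cohort, family_id)
  if (!length(rows)) stop("unknown family '", family_id, "'")
  ind <- cohort$individuals
  iid <- ind$iid[rows]
  fi <- match(ind$pat[rows], iid)
  mi <- match(ind$mat[rows], iid)
  K2 <- 2 * .kinship_matrix(fi, mi)
  dimnames(K2) <- list(iid, iid)
  if (!is.null(ids)) {
    keep <- match(ids, iid)
    if (anyNA(keep)) {
      stop("IDs not in family ", family_id, ": ",
           paste(ids[is.na(keep)], collapse = ", "))
    }
    K2 <- K2[keep, keep, drop = FALSE]
    iid <- iid[keep]
  }
  n <- length(iid)
  H <- matrix(1, n, n, dimnames = list(iid, iid))
  structure(list(family_id = family_id, member_order = iid,
                 relatedness = K2, household = H),
            class = "relatedness_structure")
}

#' @export
print.relatedness_structure <- function(x, ...) {
  cat("Relatedness structure for family ", x$family_id, ": ",
      length(x$member_order), " members\n", sep = "")
  cat("mean off-diagonal 2*Phi = ",
      signif(mean(x$relatedness[upper.tri(x$relatedness)]), 3), "\n",
      sep = "")
  invisible(x)
}

#' Relatedness structures for many families
#'
#' @param cohort a `ped_cohort`.
#' @param family_ids families to include (default: all).
#' @param ids optional individual subset (e.g. the rows of a design);
#'   families with no retained member are dropped.
#' @return named list of `relatedness_structure`, keyed by family ID.
#' @export
cohortStructures <- function(cohort, family_ids = familyIDs(cohort),
                             ids = NULL) {
  out <- list()
  for (f in family_ids) {
    rows <- .family_rows(cohort, f)
    fam_ids <- cohort$individuals$iid[rows]
    keep <- if (is.null(ids)) fam_ids else intersect(fam_ids, ids)
    if (!length(keep)) next
    out[[f]] <- relatedness_matrix(cohort, f, ids = keep)
  }
  out
}

#' Export relatedness in long format
#'
#' Writes `IID1 IID2 value` rows (upper triangle including the diagonal) for
#' each family, the delimited layout common to kinship-matrix consumers.
#'
#' @param structures list of `relatedness_structure`
#'   (see [cohortStructures()]).
#' @param path output path (tab-delimited).
#' @return the path, invisibly.
#' @export
write_relatedness <- function(structures, path) {
  rows <- lapply(structures, function(s) {
    n <- length(s$member_order)
    idx <- which(upper.tri(s$relatedness, diag = TRUE), arr.ind = TRUE)
    data.frame(IID1 = s$member_order[idx[, 1]],
               IID2 = s$member_order[idx[, 2]],
               relatedness = s$relatedness[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
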