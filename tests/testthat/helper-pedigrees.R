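# Hand-built pedigree fixtures and independent oracles used across tests.

# minimal individuals table; disease columns added by callers
ped_df <- function(iid, pat, mat, sex, fid = "FAM1") {
  data.frame(fid = fid, iid = iid, pat = pat, mat = mat, sex = sex,
             birth_year = 1950, alive = TRUE, age_at_assessment = 70,
             age_at_death = NA_real_, stringsAsFactors = FALSE)
}

# two founders and two full-sib children
nuclear_family <- function(fid = "FAM1") {
  ped_df(iid = c("dad", "mum", "kid1", "kid2"),
         pat = c("0", "0", "dad", "dad"),
         mat = c("0", "0", "mum", "mum"),
         sex = c(1L, 2L, 1L, 2L), fid = fid)
}

# three generations: founder couple, child + spouse, grandchild
threegen_family <- function(fid = "FAM1") {
  ped_df(iid = c("gpa", "gma", "par", "sps", "gkid"),
         pat = c("0", "0", "gpa", "0", "par"),
         mat = c("0", "0", "gma", "0", "sps"),
         sex = c(1L, 2L, 1L, 2L, 1L), fid = fid)
}

# one shared mother, two unrelated fathers -> half-sibs k1, k2
halfsib_family <- function(fid = "FAM1") {
  ped_df(iid = c("f1", "f2", "mom", "k1", "k2"),
         pat = c("0", "0", "0", "f1", "f2"),
         mat = c("0", "0", "0", "mom", "mom"),
         sex = c(1L, 1L, 2L, 1L, 2L), fid = fid)
}

# 12 members over 4 generations: includes full sibs, first cousins,
# grandparents and great-grandchildren
twelvemember_family <- function(fid = "FAM1") {
  ped_df(iid = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L"),
         pat = c("0", "0", "A", "0", "A", "0", "C", "C", "F", "0", "I", "I"),
         mat = c("0", "0", "B", "0", "B", "0", "D", "D", "E", "0", "J", "J"),
         sex = c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L),
         fid = fid)
}

# attach a binary disease with given affected IDs / onsets
with_disease <- function(df, disease, affected = character(),
                         onset = NULL) {
  st <- as.integer(df$iid %in% affected)
  on <- rep(NA_real_, nrow(df))
  if (!is.null(onset)) on[match(names(onset), df$iid)] <- unname(onset)
  df[[paste0(disease, "_status")]] <- st
  df[[paste0(disease, "_onset")]] <- on
  df
}

# ---- independent oracles -------------------------------------------------

# Monte-Carlo gene-dropping estimate of 2*phi for every pair, with the
# per-pair Monte-Carlo standard error.  Founders get unique allele labels;
# each transmission picks one parental allele at random.
gene_drop_2phi <- function(df, ndrop = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(df)
  fi <- match(df$pat, df$iid)
  mi <- match(df$mat, df$iid)
  ord <- order(pedherit:::.pedigree_depth(fi, mi))
  a1 <- a2 <- matrix(NA_integer_, n, ndrop)
  next_allele <- 0L
  for (i in ord) {
    if (is.na(fi[i])) {
      a1[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrop) < 0.5
      a1[i, ] <- ifelse(pick, a1[fi[i], ], a2[fi[i], ])
    }
    if (is.na(mi[i])) {
      a2[i, ] <- next_allele + 1L; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(ndrop) < 0.5
      a2[i, ] <- ifelse(pick, a1[mi[i], ], a2[mi[i], ])
    }
  }
  est <- se <- matrix(0, n, n, dimnames = list(df$iid, df$iid))
  for (i in seq_len(n)) {
    for (j in i:n) {
      per_drop <- 0.5 * ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                           (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ]))
      est[i, j] <- est[j, i] <- mean(per_drop)
      se[i, j] <- se[j, i] <- stats::sd(per_drop) / sqrt(ndrop)
    }
  }
  list(est = est, se = se)
}

# dense multivariate-normal log-likelihood over the whole cohort, assembled
# as one block-diagonal system and evaluated with solve()/determinant()
dense_block_ll <- function(design, structures, components, beta,
                           include_household = TRUE) {
  n <- length(design$response)
  omega <- matrix(0, n, n)
  for (f in unique(design$fid)) {
    rows <- which(design$fid == f)
    s <- structures[[f]]
    idx <- match(design$ids[rows], s$member_order)
    om <- s$relatedness[idx, idx, drop = FALSE] * components$sigma_g2 +
      diag(components$sigma_e2, length(rows))
    if (include_household) om <- om + components$sigma_c2
    omega[rows, rows] <- om
  }
  r <- design$response - drop(design$covariates %*% beta)
  ld <- as.numeric(determinant(omega, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(omega, r)))
}

# construct a bare phenotype_design (for hand fixtures)
manual_design <- function(y, X, fid, ids, disease = "trait",
                          trait = "liability") {
  structure(list(disease = disease, ids = ids, fid = fid, response = y,
                 covariates = X, n_cases = sum(y > 0),
                 n_families_with_case = length(unique(fid)),
                 trait = trait,
                 exclusions = NULL, dropped_columns = character()),
            class = "phenotype_design")
}

# all full-sib pairs (both parents known and shared) as an index matrix
sib_pairs <- function(co) {
  ind <- co$individuals
  known <- ind$pat != "0" & ind$mat != "0"
  key <- paste(ind$fid, ind$pat, ind$mat)
  out <- lapply(unique(key[known]), function(k) {
    idx <- which(known & key == k)
    if (length(idx) < 2) return(NULL)
    t(utils::combn(idx, 2))
  })
  do.call(rbind, out)
}

# parent-offspring pairs (father-child) as an index matrix
po_pairs <- function(co) {
  ind <- co$individuals
  kid <- which(ind$pat != "0")
  cbind(match(ind$pat[kid], ind$iid), kid)
}
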