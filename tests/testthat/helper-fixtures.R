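# Shared helpers: small genotype tables and trio sets built in code, a
# brute-force AUC oracle, and a generic box-constrained QP oracle.

# genotype table for a configurable set of nuclear families.
# fams: list of lists with elements father, mother, children (each a list
# with geno vector and pheno code); geno vectors are rare-allele counts.
make_family_table <- function(fams, n_sites) {
  rows <- list()
  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    fid <- sprintf("F%d", fi)
    rows[[length(rows) + 1]] <- list(fid, "1", "0", "0", 1, fam$father$pheno %||% "0", fam$father$geno)
    rows[[length(rows) + 1]] <- list(fid, "2", "0", "0", 2, fam$mother$pheno %||% "0", fam$mother$geno)
    for (ci in seq_along(fam$children)) {
      ch <- fam$children[[ci]]
      rows[[length(rows) + 1]] <- list(fid, sprintf("%d", 2 + ci),
                                       ch$father %||% "1", ch$mother %||% "2",
                                       0, ch$pheno, ch$geno)
    }
  }
  samples <- data.frame(
    family_id = vapply(rows, `[[`, "", 1),
    individual_id = vapply(rows, `[[`, "", 2),
    father_id = vapply(rows, `[[`, "", 3),
    mother_id = vapply(rows, `[[`, "", 4),
    sex = vapply(rows, function(r) as.integer(r[[5]]), 1L),
    phenotype = vapply(rows, function(r) as.character(r[[6]]), ""),
    stringsAsFactors = FALSE)
  geno <- do.call(rbind, lapply(rows, `[[`, 7))
  sites <- data.frame(site_id = sprintf("s%d", seq_len(n_sites)),
                      chrom = "1", pos = 1000 * seq_len(n_sites),
                      allele_ref = "A", allele_rare = "C", cm = 0,
                      stringsAsFactors = FALSE)
  genotype_table(samples, sites, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trio set with explicit genotype matrices
make_trio_set <- function(Gf, Gm, Gc, affected, ids = NULL) {
  n <- nrow(Gf)
  m <- ncol(Gf)
  ids <- ids %||% sprintf("trio%02d", seq_len(n))
  sites <- data.frame(site_id = sprintf("s%d", seq_len(m)), chrom = "1",
                      pos = 1000 * seq_len(m), allele_ref = "A",
                      allele_rare = "C", cm = 0, stringsAsFactors = FALSE)
  trio_set(ids, paste0(ids, "_f"), paste0(ids, "_m"), Gc, Gf, Gm, affected,
           sites)
}

# random score matrix with guaranteed informative columns and both classes
random_score_matrix <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    vals <- matrix(sample(c(-1, -0.5, 0, 0.5, 1), n * m, replace = TRUE,
                          prob = c(0.05, 0.2, 0.5, 0.2, 0.05)), n, m)
    if (all(apply(vals, 2, var) > 0)) break
  }
  labels <- rep(c(-1, 1), length.out = n)
  score_matrix(vals, labels, sprintf("s%d", seq_len(m)),
               sprintf("t%02d", seq_len(n)))
}

# all-pairs brute-force AUC: the independent oracle for auc_mann_whitney
brute_force_auc <- function(cases, controls) {
  tot <- 0
  for (x in cases) {
    for (y in controls) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(cases) * length(controls))
}

# generic box-constrained QP oracle for the SVM dual (interior-point
# method, kernlab::ipop); returns the attained dual objective
qp_oracle_objective <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = matrix(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       r = 0, l = matrix(0, n), u = matrix(C, n),
                       sigf = 12, maxiter = 400)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
}

# random small SVM instance with both classes present
random_svm_instance <- function(max_n = 12, d = 3) {
  n <- sample(4:max_n, 1)
  x <- matrix(rnorm(n * d), n)
  y <- c(-1, -1, 1, 1, sample(c(-1, 1), n - 4, replace = TRUE))
  list(x = x, y = y, C = runif(1, 0.5, 10))
}
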