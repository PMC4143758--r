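# Observed-minus-expected transmission scores: the SVM feature space.

#' Mendelian expected transmission from one parent
#'
#' Under additive coding a parent carrying `g` rare alleles transmits the
#' rare allele with probability `g / 2`.
#'
#' @param parent_count rare-allele count in `{0, 1, 2}` (vectorized).
#' @return Expected number of rare alleles transmitted, in `{0, 0.5, 1}`.
#' @export
expected_transmission <- function(parent_count) {
  if (any(is.na(parent_count)) || !all(parent_count %in% 0:2)) {
    stop("parent_count must be 0, 1 or 2")
  }
  parent_count / 2
}

#' Per-site transmission-distortion score for a trio
#'
#' `score = child_g - (father_g + mother_g) / 2`, the observed minus the
#' Mendelian-expected number of rare alleles the child received. A missing
#' child genotype is uninformative (score 0). Mendelian-inconsistent
#' combinations (child count outside the transmissible range) are zeroed and
#' flagged in the `"inconsistent"` attribute rather than treated as fatal,
#' since imputed pedigree data contain them.
#'
#' @param father_g,mother_g parental rare-allele counts in `{0, 1, 2}`
#'   (non-missing).
#' @param child_g child rare-allele count in `{0, 1, 2}` or `NA`.
#' @return Numeric scores in `{-1, -0.5, 0, 0.5, 1}` with a logical
#'   attribute `"inconsistent"`.
#' @export
trio_site_score <- function(father_g, mother_g, child_g) {
  if (any(is.na(father_g)) || any(is.na(mother_g)) ||
        !all(father_g %in% 0:2) || !all(mother_g %in% 0:2)) {
    stop("parental counts must be non-missing and in {0, 1, 2}")
  }
  if (!all(child_g %in% c(0:2, NA))) stop("child counts must be 0, 1, 2 or NA")
  score <- child_g - (father_g + mother_g) / 2
  miss <- is.na(child_g)
  score[miss] <- 0
  cmin <- (father_g == 2) + (mother_g == 2)
  cmax <- (father_g >= 1) + (mother_g >= 1)
  inconsistent <- !miss & (child_g < cmin | child_g > cmax)
  score[inconsistent] <- 0
  stopifnot(all(score >= -1 & score <= 1))
  attr(score, "inconsistent") <- inconsistent
  score
}

#' Construct a score matrix
#'
#' @param values trios-by-sites numeric matrix of feature values.
#' @param labels length-N vector in `{-1, +1}` (-1 = affected).
#' @param site_ids length-M character vector.
#' @param trio_ids length-N character vector (must be unique; used to key
#'   cross-validation fold assignment).
#' @param qc optional QC bookkeeping list.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, labels, site_ids, trio_ids, qc = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels), ncol(values) == length(site_ids),
            nrow(values) == length(trio_ids),
            all(labels %in% c(-1, 1)))
  if (anyDuplicated(trio_ids)) stop("trio_ids must be unique")
  structure(list(values = values, labels = as.integer(labels),
                 site_ids = as.character(site_ids),
                 trio_ids = as.character(trio_ids), qc = qc),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d rows (%d affected / %d unaffected) x %d sites\n",
              nrow(x$values), sum(x$labels == -1), sum(x$labels == 1),
              ncol(x$values)))
  invisible(x)
}

column_variances <- function(x) {
  colMeans(x^2) - colMeans(x)^2
}

#' Build the transmission-score matrix for a set of trios
#'
#' Computes per-trio, per-site transmission-distortion scores and removes
#' noninformative columns: a column whose score is identical across all
#' trios (zero variance, which subsumes sites at which no parent carries the
#' rare allele) carries no contrast. Missing genotypes (child or either
#' parent) and Mendelian inconsistencies are zeroed and counted in the QC
#' element.
#'
#' @param trios a [trio_set()].
#' @param site_indices site columns to use (default: all).
#' @return A [score_matrix()] whose `qc` lists `n_sites_input`,
#'   `n_sites_removed`, `n_missing_zeroed` and `n_inconsistent`.
#' @export
build_score_matrix <- function(trios, site_indices = NULL) {
  stopifnot(inherits(trios, "trio_set"))
  idx <- site_indices %||% seq_len(ncol(trios$G_child))
  fg <- trios$G_father[, idx, drop = FALSE]
  mg <- trios$G_mother[, idx, drop = FALSE]
  cg <- trios$G_child[, idx, drop = FALSE]

  score <- cg - (fg + mg) / 2
  miss <- is.na(fg) | is.na(mg) | is.na(cg)
  score[miss] <- 0
  cmin <- (fg == 2) + (mg == 2)
  cmax <- (fg >= 1) + (mg >= 1)
  inconsistent <- !miss & (cg < cmin | cg > cmax)   # FALSE wherever missing
  score[inconsistent] <- 0

  qc <- list(n_sites_input = length(idx),
             n_missing_zeroed = sum(miss),
             n_inconsistent = sum(inconsistent))
  keep <- column_variances(score) > 1e-12
  qc$n_sites_removed <- sum(!keep)
  if (!any(keep)) {
    stop_condition("triosvm_untestable",
                   "no informative sites: every score column is constant",
                   reason = "no_informative_sites", qc = qc)
  }
  score_matrix(score[, keep, drop = FALSE], trios$label,
               trios$sites$site_id[idx][keep], trios$child_id, qc = qc)
}

#' Case-control rare-allele count encoding
#'
#' For unrelated individuals the feature at each site is simply the
#' rare-allele count, the analogue of the trio transmission encoding when no
#' parental conditioning is available. Missing genotypes count 0;
#' zero-variance columns are removed as in [build_score_matrix()].
#'
#' @param table a [genotype_table()]; individuals with missing phenotype are
#'   dropped.
#' @param site_indices site columns to use (default: all).
#' @return A [score_matrix()] with values in `{0, 1, 2}`.
#' @export
case_control_encode <- function(table, site_indices = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  idx <- site_indices %||% seq_len(ncol(table$geno))
  aff <- pheno_to_affected(table$samples$phenotype)
  rows <- which(!is.na(aff))
  if (!length(rows)) {
    stop_condition("triosvm_untestable", "no phenotyped individuals",
                   reason = "no_phenotyped_individuals")
  }
  vals <- table$geno[rows, idx, drop = FALSE]
  n_missing <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  qc <- list(n_sites_input = length(idx), n_missing_zeroed = n_missing,
             n_inconsistent = 0L)
  keep <- column_variances(vals) > 1e-12
  qc$n_sites_removed <- sum(!keep)
  if (!any(keep)) {
    stop_condition("triosvm_untestable",
                   "no informative sites: every count column is constant",
                   reason = "no_informative_sites", qc = qc)
  }
  score_matrix(vals[, keep, drop = FALSE], ifelse(aff[rows], -1L, 1L),
               table$sites$site_id[idx][keep],
               sample_key(table$samples$family_id[rows],
                          table$samples$individual_id[rows]),
               qc = qc)
}
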