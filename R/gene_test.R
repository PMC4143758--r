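# The end-to-end per-gene pipeline: site selection -> feature encoding ->
# penalty selection -> out-of-fold scoring -> AUC test.

empty_gene_result <- function() {
  data.frame(gene = character(), n_case = integer(), n_control = integer(),
             n_sites_input = integer(), n_sites_used = integer(),
             penalty_chosen = numeric(), theta_hat = numeric(),
             se = numeric(), z = numeric(), p_one_sided = numeric(),
             reason_code = character(), stringsAsFactors = FALSE)
}

na_gene_result <- function(gene, n_case, n_control, n_sites_input, reason) {
  data.frame(gene = gene, n_case = as.integer(n_case),
             n_control = as.integer(n_control),
             n_sites_input = as.integer(n_sites_input), n_sites_used = 0L,
             penalty_chosen = NA_real_, theta_hat = NA_real_, se = NA_real_,
             z = NA_real_, p_one_sided = NA_real_, reason_code = reason,
             stringsAsFactors = FALSE)
}

# stratified half split keyed to ids; 1 = training, 2 = evaluation
split_halves <- function(ids, labels, seed) {
  fold_assignments(ids, labels, 2L, seed + 131L)
}

gene_test_core <- function(sm, gene, n_sites_input, n_case, n_control,
                           config, resubstitution = FALSE) {
  if (inherits(sm, "condition")) {
    return(na_gene_result(gene, n_case, n_control, n_sites_input,
                          sm$reason %||% "no_informative_sites"))
  }
  labels <- sm$labels
  n_case <- sum(labels == -1)
  n_control <- sum(labels == 1)
  if (n_case == 0 || n_control == 0) {
    return(na_gene_result(gene, n_case, n_control, n_sites_input,
                          "single_class"))
  }
  if (resubstitution) {
    # comparison mode: penalty by CV on all rows, then a full-data refit
    # scored on its own training rows (optimistically biased; see docs)
    sel <- select_penalty(sm, config)
    model <- train_svm(sm$values, labels, sel$penalty, sigma2 = config$sigma2)
    scores <- decision_scores(model, sm$values)
    eval_rows <- rep(TRUE, length(labels))
  } else {
    # split-sample evaluation: the penalty is selected by stratified k-fold
    # CV AUC inside the training half and the final model is fit there; the
    # held-out half, whose labels never enter any fit, carries the AUC
    # test. Scoring trios whose labels influenced the model (pooled
    # out-of-fold scores included) inflates the null variance of the AUC
    # beyond the DeLong estimate and breaks the type I error.
    half <- split_halves(sm$trio_ids, labels, config$seed)
    tr <- half == 1L
    if (min(sum(labels[tr] == -1), sum(labels[tr] == 1)) < config$folds) {
      return(na_gene_result(gene, n_case, n_control, n_sites_input,
                            "too_few_per_class"))
    }
    sm_tr <- score_matrix(sm$values[tr, , drop = FALSE], labels[tr],
                          sm$site_ids, sm$trio_ids[tr])
    sel <- select_penalty(sm_tr, config)
    model <- train_svm(sm_tr$values, sm_tr$labels, sel$penalty,
                       sigma2 = config$sigma2)
    scores <- rep(NA_real_, length(labels))
    scores[!tr] <- decision_scores(model, sm$values[!tr, , drop = FALSE])
    eval_rows <- !tr
  }
  n_case <- sum(labels[eval_rows] == -1)
  n_control <- sum(labels[eval_rows] == 1)
  if (n_case < 2 || n_control < 2) {
    return(na_gene_result(gene, n_case, n_control, n_sites_input,
                          "too_few_evaluation_scores"))
  }
  # orientation: affected children carry label -1 and are pushed toward
  # negative decision values, so -score ranks cases above controls when the
  # gene separates the classes
  cases <- -scores[eval_rows & labels == -1]
  controls <- -scores[eval_rows & labels == 1]
  theta <- auc_mann_whitney(cases, controls)
  se <- auc_se(cases, controls)
  if (se == 0) {
    out <- na_gene_result(gene, n_case, n_control, n_sites_input,
                          "degenerate_se")
    out$n_sites_used <- ncol(sm$values)
    out$penalty_chosen <- sel$penalty
    out$theta_hat <- theta
    out$se <- 0
    return(out)
  }
  zt <- auc_z_test(theta, se)
  out <- data.frame(gene = gene, n_case = as.integer(n_case),
                    n_control = as.integer(n_control),
                    n_sites_input = as.integer(n_sites_input),
                    n_sites_used = ncol(sm$values),
                    penalty_chosen = sel$penalty, theta_hat = theta, se = se,
                    z = zt$z, p_one_sided = zt$p_one_sided,
                    reason_code = "ok", stringsAsFactors = FALSE)
  attr(out, "cv_table") <- sel$table
  attr(out, "qc") <- sm$qc
  out
}

#' Gene-level Trio-SVM association test
#'
#' Runs the full per-gene pipeline: select rare sites in the region, encode
#' features (transmission-distortion scores for trios, rare-allele counts
#' for case-control), split the sample into stratified halves, choose the
#' SVM penalty by cross-validated AUC within the training half, fit the
#' final model there, and test the AUC of the held-out half's oriented
#' composite scores against 0.5. Confining the AUC test to scores whose
#' labels never entered any fit keeps the DeLong-based z test calibrated;
#' scores that share training data carry correlated noise that inflates the
#' null variance of the AUC. An untestable gene (no informative sites, too
#' few individuals, or a degenerate standard error) yields a result row
#' with `p_one_sided = NA` and a `reason_code`, never an error.
#'
#' @param x a [genotype_table()] or a [trio_set()].
#' @param region a [gene_region()] restricting sites, or `NULL` for all
#'   sites (the default for simulated trio sets).
#' @param maf_threshold upper MAF bound (exclusive) for site inclusion.
#' @param config a [kernel_config()].
#' @param mode `"trio"` (transmission scores) or `"case_control"`
#'   (rare-allele counts); genotype tables only.
#' @param resubstitution score every individual with a full-data refit at a
#'   penalty chosen by CV on all rows, for comparison only. Resubstitution
#'   AUC of a Gaussian-kernel SVM is optimistically biased; the default
#'   (split-sample evaluation) preserves the null calibration of the test.
#' @param gene gene name for the result row (trio-set method).
#' @param ... unused.
#' @return One-row data.frame: `gene`, `n_case`, `n_control` (the counts
#'   whose scores enter the AUC test, i.e. the evaluation half),
#'   `n_sites_input`, `n_sites_used`, `penalty_chosen`, `theta_hat`, `se`,
#'   `z`, `p_one_sided`, `reason_code`; the per-penalty CV AUC table and QC
#'   counts are attached as attributes `cv_table` and `qc`.
#' @export
gene_test <- function(x, ...) UseMethod("gene_test")

#' @rdname gene_test
#' @export
gene_test.genotype_table <- function(x, region, maf_threshold = 0.01,
                                     config = kernel_config(),
                                     mode = c("trio", "case_control"),
                                     resubstitution = FALSE, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(region, "gene_region"))
  idx <- select_sites(x, region, maf_threshold)
  if (mode == "trio") {
    trios <- extract_trios(x)
    n_case <- sum(trios$affected)
    n_control <- sum(!trios$affected)
    if (length(trios) == 0) {
      return(na_gene_result(region$gene, 0, 0, length(idx), "no_trios"))
    }
    sm <- if (length(idx) == 0) {
      structure(class = c("triosvm_untestable", "condition"),
                list(message = "no sites selected",
                     reason = "no_informative_sites"))
    } else {
      tryCatch(build_score_matrix(trios, idx),
               triosvm_untestable = function(e) e)
    }
  } else {
    aff <- pheno_to_affected(x$samples$phenotype)
    n_case <- sum(aff, na.rm = TRUE)
    n_control <- sum(!aff, na.rm = TRUE)
    sm <- if (length(idx) == 0) {
      structure(class = c("triosvm_untestable", "condition"),
                list(message = "no sites selected",
                     reason = "no_informative_sites"))
    } else {
      tryCatch(case_control_encode(x, idx),
               triosvm_untestable = function(e) e)
    }
  }
  gene_test_core(sm, region$gene, length(idx), n_case, n_control, config,
                 resubstitution)
}

#' @rdname gene_test
#' @export
gene_test.trio_set <- function(x, region = NULL, maf_threshold = 0.03,
                               config = kernel_config(),
                               resubstitution = FALSE, gene = "gene", ...) {
  maf <- maf_from_parents(x)
  in_region <- if (is.null(region)) {
    rep(TRUE, nrow(x$sites))
  } else {
    x$sites$chrom == region$chromosome & x$sites$pos >= region$start_bp &
      x$sites$pos <= region$end_bp
  }
  idx <- which(in_region & !is.na(maf) & maf > 0 & maf < maf_threshold)
  idx <- idx[order(x$sites$pos[idx])]
  if (!is.null(region)) gene <- region$gene
  n_case <- sum(x$affected)
  n_control <- sum(!x$affected)
  sm <- if (length(idx) == 0) {
    structure(class = c("triosvm_untestable", "condition"),
              list(message = "no sites selected",
                   reason = "no_informative_sites"))
  } else {
    tryCatch(build_score_matrix(x, idx), triosvm_untestable = function(e) e)
  }
  gene_test_core(sm, gene, length(idx), n_case, n_control, config,
                 resubstitution)
}
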