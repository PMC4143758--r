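# Soft-margin Gaussian-kernel SVM in the dual, with stratified
# cross-validated scoring and penalty selection.

#' Kernel and cross-validation configuration
#'
#' @param sigma2 Gaussian kernel scale sigma^2 (> 0). Default 1.
#' @param penalty_grid candidate box penalties C (> 0). Default integers
#'   1 to 10.
#' @param folds number of stratified cross-validation folds (>= 2).
#'   Default 5.
#' @param seed integer seed keying fold assignment.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(sigma2 = 1, penalty_grid = 1:10, folds = 5,
                          seed = 1L) {
  stopifnot(sigma2 > 0, length(penalty_grid) >= 1, all(penalty_grid > 0),
            folds >= 2)
  structure(list(sigma2 = as.numeric(sigma2),
                 penalty_grid = sort(unique(as.numeric(penalty_grid))),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "kernel_config")
}

#' Gaussian (RBF) kernel between two vectors
#'
#' `exp(-||x - x'||^2 / (2 sigma2))`, in `(0, 1]`.
#'
#' @param x,x_prime numeric vectors of equal length.
#' @param sigma2 kernel scale (> 0).
#' @return Scalar kernel value.
#' @export
gaussian_kernel <- function(x, x_prime, sigma2 = 1) {
  if (length(x) != length(x_prime)) stop("vectors must have equal length")
  stopifnot(sigma2 > 0)
  exp(-sum((x - x_prime)^2) / (2 * sigma2))
}

#' Gaussian kernel matrix
#'
#' @param x numeric matrix (rows = observations).
#' @param y optional second matrix; `NULL` gives the symmetric
#'   `x`-by-`x` matrix with unit diagonal.
#' @param sigma2 kernel scale (> 0).
#' @return Kernel matrix `nrow(x)` x `nrow(y %||% x)`.
#' @export
rbf_kernel <- function(x, y = NULL, sigma2 = 1) {
  stopifnot(sigma2 > 0)
  x <- as.matrix(x)
  if (is.null(y)) {
    sq <- rowSums(x^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    d2[d2 < 0] <- 0
    k <- exp(-d2 / (2 * sigma2))
    k <- (k + t(k)) / 2
    diag(k) <- 1
    k
  } else {
    y <- as.matrix(y)
    if (ncol(y) != ncol(x)) stop("feature dimensions differ")
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    exp(-d2 / (2 * sigma2))
  }
}

#' Solve the soft-margin SVM dual
#'
#' Maximizes `sum(alpha) - 0.5 t(alpha * y) K (alpha * y)` subject to
#' `0 <= alpha_i <= C` and `sum(alpha_i y_i) = 0`, by sequential minimal
#' optimization on maximal violating pairs. The offset `b` is the mean of
#' `y_s - sum_i alpha_i y_i K_is` over unbounded support vectors, or the
#' midpoint of the feasible KKT interval when every support vector is at
#' the box bound.
#'
#' @param kernel_matrix symmetric PSD kernel matrix (symmetrized
#'   numerically).
#' @param labels vector in `{-1, +1}`; both classes must be present.
#' @param penalty box constraint C (> 0).
#' @param tol first-order optimality gap at which to stop.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   carrying the residual gap.
#' @return An object of class `triosvm_model` with elements `alpha`,
#'   `labels`, `b`, `penalty`, `objective` (dual objective attained),
#'   `gap`, `iterations`, `support` (indices with `alpha > 0` numerically).
#' @export
solve_dual <- function(kernel_matrix, labels, penalty, tol = 1e-6,
                       max_iter = 1e5) {
  k <- as.matrix(kernel_matrix)
  labels <- as.numeric(labels)
  stopifnot(nrow(k) == ncol(k), length(labels) == nrow(k),
            all(labels %in% c(-1, 1)), penalty > 0, tol > 0)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to train")
  }
  k <- (k + t(k)) / 2
  res <- smo_solve(k, labels, penalty, tol, as.integer(max_iter))
  if (res$gap >= tol) {
    stop_condition("triosvm_convergence",
                   sprintf("SMO did not converge in %d iterations (gap %.3g)",
                           as.integer(max_iter), res$gap),
                   gap = res$gap)
  }
  alpha <- res$alpha
  f0 <- as.vector(k %*% (alpha * labels))
  eps_a <- 1e-8 * penalty
  free <- alpha > eps_a & alpha < penalty - eps_a
  if (any(free)) {
    b <- mean(labels[free] - f0[free])
  } else {
    at0 <- alpha <= eps_a
    atC <- alpha >= penalty - eps_a
    # y (f0 + b) >= 1 when alpha = 0, <= 1 when alpha = C
    lo <- suppressWarnings(max(c((1 - f0)[at0 & labels > 0],
                                 (-1 - f0)[atC & labels < 0])))
    hi <- suppressWarnings(min(c((-1 - f0)[at0 & labels < 0],
                                 (1 - f0)[atC & labels > 0])))
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
         else if (is.finite(lo)) lo
         else if (is.finite(hi)) hi
         else 0
  }
  structure(list(alpha = alpha, labels = labels, b = b,
                 penalty = penalty, sigma2 = NA_real_, X = NULL,
                 objective = res$objective, gap = res$gap,
                 iterations = res$iterations,
                 support = which(alpha > eps_a)),
            class = "triosvm_model")
}

#' @export
print.triosvm_model <- function(x, ...) {
  cat(sprintf(
    "Gaussian-kernel SVM: n = %d, C = %g, %d support vectors, b = %.4g\n",
    length(x$alpha), x$penalty, length(x$support), x$b))
  invisible(x)
}

#' Train a Gaussian-kernel SVM on feature rows
#'
#' Convenience wrapper computing the kernel matrix, solving the dual and
#' retaining the rows needed by [decision_scores()].
#'
#' @param x numeric matrix of feature rows.
#' @param labels vector in `{-1, +1}`.
#' @param penalty box constraint C.
#' @param sigma2 Gaussian kernel scale.
#' @param tol,max_iter passed to [solve_dual()].
#' @return A `triosvm_model` with `X` and `sigma2` populated.
#' @export
train_svm <- function(x, labels, penalty, sigma2 = 1, tol = 1e-6,
                      max_iter = 1e5) {
  x <- as.matrix(x)
  model <- solve_dual(rbf_kernel(x, sigma2 = sigma2), labels, penalty,
                      tol = tol, max_iter = max_iter)
  model$X <- x
  model$sigma2 <- sigma2
  model
}

#' Composite decision scores
#'
#' `score_i = sum_s alpha_s y_s K(x_s, row_i) + b` over the support
#' vectors. Higher scores indicate the +1 (unaffected) class.
#'
#' @param model a `triosvm_model` from [train_svm()].
#' @param rows matrix (or single vector) of feature rows with the training
#'   feature length.
#' @return Numeric vector of one score per row.
#' @export
decision_scores <- function(model, rows) {
  stopifnot(inherits(model, "triosvm_model"))
  if (is.null(model$X)) stop("model carries no feature rows; use train_svm()")
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows <- as.matrix(rows)
  if (ncol(rows) != ncol(model$X)) {
    stop("row length does not match the training feature length")
  }
  s <- model$support
  if (!length(s)) return(rep(model$b, nrow(rows)))
  kc <- rbf_kernel(model$X[s, , drop = FALSE], rows, model$sigma2)
  drop(crossprod(kc, model$alpha[s] * model$labels[s])) + model$b
}

# deterministic per-id hash (Lehmer-mixed polynomial hash), used so that
# fold membership is a function of (trio id, seed) and never of row order
id_hash <- function(ids, seed) {
  seed <- seed %% 2147483647
  vapply(ids, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
    h <- (h + seed) %% 2147483647
    h <- (h * 48271) %% 2147483647
    (h * 48271) %% 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

# stratified fold assignment keyed to ids; returns integers in 1..folds
fold_assignments <- function(ids, labels, folds, seed) {
  out <- integer(length(ids))
  h <- id_hash(ids, seed)
  for (cl in sort(unique(labels))) {
    w <- which(labels == cl)
    if (length(w) < folds) {
      stop(sprintf(
        "class %+d has %d members, fewer than %d folds; use fewer folds",
        cl, length(w), folds))
    }
    ord <- w[order(h[w], ids[w])]
    out[ord] <- rep(seq_len(folds), length.out = length(w))
  }
  out
}

# out-of-fold scores given a precomputed full kernel matrix
cv_scores_from_kernel <- function(k, labels, ids, penalty, config,
                                  tol = 1e-6) {
  fold <- fold_assignments(ids, labels, config$folds, config$seed)
  scores <- numeric(length(ids))
  for (f in seq_len(config$folds)) {
    te <- fold == f
    tr <- !te
    m <- solve_dual(k[tr, tr, drop = FALSE], labels[tr], penalty, tol = tol)
    ay <- m$alpha * labels[tr]
    scores[te] <- drop(crossprod(k[tr, te, drop = FALSE], ay)) + m$b
  }
  scores
}

#' Out-of-fold cross-validated decision scores
#'
#' Stratified k-fold partition keyed to trio ids through the configuration
#' seed; each trio is scored by the model trained on the other folds, so
#' scores are deterministic given the seed and invariant to row order.
#'
#' @param features a [score_matrix()].
#' @param penalty box constraint C.
#' @param config a [kernel_config()].
#' @return Numeric vector of out-of-fold scores in input row order.
#' @export
cross_validated_scores <- function(features, penalty, config = kernel_config()) {
  stopifnot(inherits(features, "score_matrix"))
  k <- rbf_kernel(features$values, sigma2 = config$sigma2)
  cv_scores_from_kernel(k, features$labels, features$trio_ids, penalty, config)
}

# AUC of affected vs unaffected on sign-oriented scores: decision scores
# are negated so that greater distortion in affected children maps above 0.5
oriented_auc <- function(scores, labels) {
  auc_mann_whitney(-scores[labels == -1], -scores[labels == 1])
}

#' Select the SVM penalty by cross-validated AUC
#'
#' Evaluates every C in the grid with the same fold partition and returns
#' the value maximizing the out-of-fold AUC; exact ties break toward the
#' smallest C.
#'
#' @param features a [score_matrix()].
#' @param config a [kernel_config()].
#' @return List with `penalty` (chosen C), `table` (data.frame of penalty
#'   and cv_auc), and `scores` (out-of-fold scores at the chosen C).
#' @export
select_penalty <- function(features, config = kernel_config()) {
  stopifnot(inherits(features, "score_matrix"))
  k <- rbf_kernel(features$values, sigma2 = config$sigma2)
  grid <- config$penalty_grid
  score_list <- lapply(grid, function(C) {
    cv_scores_from_kernel(k, features$labels, features$trio_ids, C, config)
  })
  aucs <- vapply(score_list, oriented_auc, numeric(1),
                 labels = features$labels)
  best <- which.max(aucs)   # grid is sorted ascending: first max = smallest C
  list(penalty = grid[best],
       table = data.frame(penalty = grid, cv_auc = aucs),
       scores = score_list[[best]])
}
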