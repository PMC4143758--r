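# Gaussian kernel, dual solver (vs closed form, QP oracle, libsvm),
# KKT conditions, and cross-validated scoring.

test_that("gaussian_kernel matches the closed form and handles errors", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2)), 1)
  expect_equal(gaussian_kernel(0, sqrt(2), sigma2 = 1), exp(-1))
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), sigma2 = 2), exp(-25 / 4))
  expect_lt(gaussian_kernel(0, 100), 1e-300)
  expect_error(gaussian_kernel(c(1, 2), 1), "equal length")
})

test_that("rbf_kernel is symmetric with unit diagonal and PSD", {
  set.seed(3)
  x <- matrix(rnorm(30), 10)
  k <- rbf_kernel(x, sigma2 = 0.7)
  expect_equal(k, t(k))
  expect_equal(diag(k), rep(1, 10))
  expect_gt(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # cross-kernel agrees with the scalar form
  y <- matrix(rnorm(6), 2)
  kc <- rbf_kernel(x, y, sigma2 = 0.7)
  expect_equal(kc[3, 2], gaussian_kernel(x[3, ], y[2, ], 0.7))
})

test_that("solve_dual recovers the symmetric two-point solution", {
  # two 1-D points at -1 and +1 with opposite labels: by stationarity of
  # 2a - a^2 (1 - K12), alpha = 1 / (1 - exp(-2)) for both, b = 0
  x <- matrix(c(-1, 1), ncol = 1)
  m <- train_svm(x, c(-1, 1), penalty = 10, sigma2 = 1)
  a_expected <- 1 / (1 - exp(-2))
  expect_equal(m$alpha, rep(a_expected, 2), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-8)
  expect_equal(decision_scores(m, 0), 0, tolerance = 1e-8)
  # unbounded support vectors sit exactly on the margin
  expect_equal(decision_scores(m, x), c(-1, 1), tolerance = 1e-6)
})

test_that("coincident opposite-label points are driven to the box bound", {
  x <- matrix(c(0.5, 0.5), ncol = 1)
  k <- rbf_kernel(x, sigma2 = 1)
  m <- solve_dual(k, c(-1, 1), penalty = 0.25)
  expect_equal(m$alpha, c(0.25, 0.25), tolerance = 1e-8)
  # analytic objective: with both alphas at the bound and K12 = 1 the
  # quadratic term vanishes, so W = 2C
  expect_equal(m$objective, 0.5, tolerance = 1e-10)
})

test_that("dual objective matches a generic box-constrained QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(421)
  for (i in 1:25) {
    inst <- random_svm_instance()
    k <- rbf_kernel(inst$x, sigma2 = 1)
    m <- solve_dual(k, inst$y, inst$C, tol = 1e-8)
    expect_equal(sum(m$alpha * inst$y), 0, tolerance = 1e-8)
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= inst$C + 1e-12))
    obj <- qp_oracle_objective(k, inst$y, inst$C)
    expect_equal(m$objective, obj,
                 tolerance = 1e-6 * max(1, abs(obj)))
  }
})

test_that("fitted models satisfy the KKT conditions", {
  set.seed(99)
  for (i in 1:10) {
    inst <- random_svm_instance(max_n = 20)
    m <- train_svm(inst$x, inst$y, inst$C, sigma2 = 1, tol = 1e-8)
    yf <- inst$y * decision_scores(m, inst$x)
    tol <- 1e-4
    at0 <- m$alpha < 1e-8 * inst$C
    atC <- m$alpha > inst$C * (1 - 1e-8)
    free <- !at0 & !atC
    expect_true(all(yf[at0] >= 1 - tol))
    expect_true(all(abs(yf[free] - 1) <= tol))
    expect_true(all(yf[atC] <= 1 + tol))
  }
})

test_that("decision scores match libsvm (e1071) up to sign convention", {
  skip_if_not_installed("e1071")
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rep(c(-1, 1), 20)
  C <- 2
  m <- train_svm(x, y, C, sigma2 = 1, tol = 1e-8)
  fit <- e1071::svm(x, factor(y), scale = FALSE, kernel = "radial",
                    gamma = 0.5, cost = C, tolerance = 1e-6)
  dv <- drop(attr(predict(fit, x, decision.values = TRUE),
                  "decision.values"))
  ours <- decision_scores(m, x)
  s <- sign(sum(dv * ours))
  expect_equal(ours, s * dv, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("single-class input and length mismatches are errors", {
  x <- matrix(rnorm(6), 3)
  expect_error(solve_dual(rbf_kernel(x), c(1, 1, 1), 1), "both classes")
  m <- train_svm(matrix(rnorm(8), 4), c(-1, -1, 1, 1), 1)
  expect_error(decision_scores(m, matrix(0, 1, 5)), "length")
})

test_that("label-flip antisymmetry: negated labels negate all scores", {
  set.seed(17)
  x <- matrix(rnorm(12 * 2), 12)
  y <- rep(c(-1, 1), 6)
  m1 <- train_svm(x, y, 3, tol = 1e-8)
  m2 <- train_svm(x, -y, 3, tol = 1e-8)
  probe <- matrix(rnorm(10), 5)
  expect_equal(decision_scores(m1, probe), -decision_scores(m2, probe),
               tolerance = 1e-6)
})

test_that("cross-validated scores are stratified, deterministic and order-invariant", {
  sm <- random_score_matrix(20, 6, seed = 31)
  cfg <- kernel_config(folds = 5, seed = 42)
  fold <- triosvm:::fold_assignments(sm$trio_ids, sm$labels, 5, 42)
  for (f in 1:5) {
    expect_equal(sum(fold == f & sm$labels == -1), 2)
    expect_equal(sum(fold == f & sm$labels == 1), 2)
  }
  s1 <- cross_validated_scores(sm, penalty = 2, cfg)
  s2 <- cross_validated_scores(sm, penalty = 2, cfg)
  expect_identical(s1, s2)
  # permuting rows permutes the scores (fold membership keyed to trio id)
  set.seed(8)
  perm <- sample(20)
  smp <- score_matrix(sm$values[perm, ], sm$labels[perm], sm$site_ids,
                      sm$trio_ids[perm])
  sp <- cross_validated_scores(smp, penalty = 2, cfg)
  # same fold membership per trio; scores agree up to solver tolerance
  expect_equal(sp[order(perm)], s1, tolerance = 1e-4)
  # a different seed gives a different partition
  expect_false(identical(
    triosvm:::fold_assignments(sm$trio_ids, sm$labels, 5, 43), fold))
})

test_that("too few class members for the folds is a clear error", {
  sm <- random_score_matrix(6, 4, seed = 13)
  expect_error(cross_validated_scores(sm, 1, kernel_config(folds = 5)),
               "fewer folds")
})

test_that("select_penalty returns the grid table and breaks ties toward small C", {
  sm <- random_score_matrix(20, 5, seed = 77)
  cfg <- kernel_config(penalty_grid = c(4, 1, 2), folds = 4, seed = 3)
  sel <- select_penalty(sm, cfg)
  expect_equal(sel$table$penalty, c(1, 2, 4))
  expect_equal(nrow(sel$table), 3)
  expect_true(sel$penalty %in% c(1, 2, 4))
  expect_equal(sel$table$cv_auc[sel$table$penalty == sel$penalty],
               max(sel$table$cv_auc))
  # degenerate grid: single value is always chosen
  expect_equal(select_penalty(sm, kernel_config(penalty_grid = 7,
                                                folds = 4))$penalty, 7)
  # exact ties (duplicated grid values collapse; identical AUCs -> smallest)
  cfg2 <- kernel_config(penalty_grid = c(5, 5, 5), folds = 4)
  expect_equal(select_penalty(sm, cfg2)$penalty, 5)
})
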