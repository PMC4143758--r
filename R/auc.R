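# AUC point estimate, DeLong standard error, and the one-sided Gaussian
# test of theta > 0.5.

#' Mann-Whitney AUC estimate
#'
#' `theta_hat` is the probability that a randomly chosen case score exceeds
#' a randomly chosen control score, with ties counted one half; computed
#' via midranks, which is algebraically identical to the all-pairs count.
#' Scores must already be oriented so that greater transmission distortion
#' in cases yields values above 0.5 (see [gene_test()]).
#'
#' @param case_scores,control_scores nonempty numeric vectors.
#' @return `theta_hat` in `[0, 1]`.
#' @export
auc_mann_whitney <- function(case_scores, control_scores) {
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  if (n1 == 0 || n0 == 0) stop("both score groups must be nonempty")
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# per-element placement of `a` within `b`: fraction of b strictly below,
# plus half the ties
placement_values <- function(a, b) {
  vapply(a, function(v) mean(b < v) + 0.5 * mean(b == v), numeric(1))
}

#' DeLong standard error of the AUC
#'
#' `SE^2 = S10 / n1 + S01 / n0`, where `S10` is the sample variance over
#' cases of the per-case placement (fraction of controls it beats, ties
#' half) and `S01` symmetrically over controls. An SE of exactly 0
#' (degenerate placements, e.g. perfect separation or all-tied scores)
#' signals that the asymptotic test does not apply.
#'
#' @param case_scores,control_scores numeric vectors with at least 2
#'   elements each.
#' @return Nonnegative `se`.
#' @export
auc_se <- function(case_scores, control_scores) {
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  if (n1 < 2 || n0 < 2) stop("need at least 2 scores per group")
  v10 <- placement_values(case_scores, control_scores)
  v01 <- 1 - placement_values(control_scores, case_scores)
  sqrt(max(var(v10) / n1 + var(v01) / n0, 0))
}

#' One-sided Gaussian AUC test
#'
#' Tests H0: theta <= 0.5 against Ha: theta > 0.5 with the centered
#' statistic `z = (theta_hat - 0.5) / se`, asymptotically standard normal
#' under H0; `p` is the upper-tail probability.
#'
#' @param theta_hat AUC point estimate.
#' @param se standard error (> 0; a degenerate `se = 0` is an error — the
#'   asymptotics do not apply).
#' @return List with elements `z` and `p_one_sided`.
#' @export
auc_z_test <- function(theta_hat, se) {
  stopifnot(is.finite(theta_hat), theta_hat >= 0, theta_hat <= 1)
  if (!is.finite(se) || se <= 0) {
    stop_condition("triosvm_degenerate",
                   "degenerate standard error: asymptotic test undefined")
  }
  z <- (theta_hat - 0.5) / se
  list(z = z, p_one_sided = pnorm(z, lower.tail = FALSE))
}
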