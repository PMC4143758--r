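# Synthetic trio generator: HWE parents, Mendelian transmission, a logistic
# liability model with mixed-direction rare-variant effects, ascertainment
# into case/control trio quotas, optional two-subpopulation stratification,
# bootstrap resampling, and the type-I-error / power experiment harness.

#' Simulation configuration
#'
#' Defaults describe the reference study condition used throughout the
#' package's calibration experiments: a 50-site gene with per-site MAF
#' uniform on `[0.001, 0.03]`, no causal effects (a pure null gene), and
#' ascertainment of 66 affected-child and 209 unaffected-child trios.
#'
#' @param n_sites number of variant sites in the simulated gene.
#' @param maf_low,maf_high bounds of the uniform per-site MAF spectrum.
#' @param n_causal number of causal sites (0 = null gene).
#' @param effect_sizes per-causal-site log-odds effects of one rare allele;
#'   mixed signs model risk and protective variants. Default alternates
#'   +2/-2 across the causal sites.
#' @param baseline_logodds intercept of the logistic disease model; the
#'   default corresponds to a background prevalence of 0.2.
#' @param n_case_trios,n_control_trios ascertainment quotas.
#' @param n_subpops 1, or 2 for the stratification stress test.
#' @param subpop_maf_multiplier MAF multiplier of the second subpopulation
#'   (clipped at 0.5).
#' @param subpop_baseline_shift added to `baseline_logodds` in the second
#'   subpopulation (different background prevalence).
#' @param draw_cap maximum number of trios drawn while filling quotas.
#' @param seed integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 50, maf_low = 0.001, maf_high = 0.03,
                       n_causal = 0,
                       effect_sizes = rep(c(2, -2), length.out = n_causal),
                       baseline_logodds = qlogis(0.2),
                       n_case_trios = 66, n_control_trios = 209,
                       n_subpops = 1, subpop_maf_multiplier = 1,
                       subpop_baseline_shift = 0,
                       draw_cap = 200000, seed = 1L) {
  stopifnot(n_sites >= 1, maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            n_causal >= 0, n_causal <= n_sites,
            length(effect_sizes) == n_causal,
            n_case_trios >= 0, n_control_trios >= 0,
            n_subpops %in% 1:2, subpop_maf_multiplier > 0, draw_cap >= 1)
  structure(list(n_sites = as.integer(n_sites), maf_low = maf_low,
                 maf_high = maf_high, n_causal = as.integer(n_causal),
                 effect_sizes = as.numeric(effect_sizes),
                 baseline_logodds = baseline_logodds,
                 n_case_trios = as.integer(n_case_trios),
                 n_control_trios = as.integer(n_control_trios),
                 n_subpops = as.integer(n_subpops),
                 subpop_maf_multiplier = subpop_maf_multiplier,
                 subpop_baseline_shift = subpop_baseline_shift,
                 draw_cap = as.integer(draw_cap), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d sites, MAF U(%g, %g), %d causal, quotas %d/%d, %d subpop(s), seed %d\n",
    x$n_sites, x$maf_low, x$maf_high, x$n_causal, x$n_case_trios,
    x$n_control_trios, x$n_subpops, x$seed))
  invisible(x)
}

# one gene draw from the current RNG stream
draw_gene <- function(config) {
  mafs <- runif(config$n_sites, config$maf_low, config$maf_high)
  effects <- numeric(config$n_sites)
  causal <- integer(0)
  if (config$n_causal > 0) {
    causal <- sample(config$n_sites, config$n_causal)
    effects[causal] <- config$effect_sizes
  }
  list(mafs = mafs, effects = effects, causal = sort(causal))
}

#' Simulate a gene: MAF spectrum and causal-effect vector
#'
#' Per-site MAFs are uniform on `[maf_low, maf_high]`; `n_causal` sites are
#' chosen uniformly without replacement and given the configured
#' (mixed-sign) log-odds effects. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `mafs`, full-length `effects` (0 at non-causal sites)
#'   and the sorted `causal` indices.
#' @export
simulate_gene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_gene(config)
}

# vectorized trio batch: HWE parents, per-parent Mendelian transmission,
# logistic affection on the child's causal-allele counts
draw_trio_batch <- function(n, mafs, effects, baseline_logodds) {
  m <- length(mafs)
  p <- rep(mafs, each = n)
  fg <- matrix(rbinom(n * m, 2, p), n, m)
  mg <- matrix(rbinom(n * m, 2, p), n, m)
  cg <- matrix(rbinom(n * m, 1, fg / 2) + rbinom(n * m, 1, mg / 2), n, m)
  eta <- baseline_logodds + as.vector(cg %*% effects)
  affected <- runif(n) < plogis(eta)
  list(fg = fg, mg = mg, cg = cg, affected = affected)
}

#' Simulate one parent-child trio
#'
#' Parent genotypes are Binomial(2, MAF) per site (HWE); the child receives
#' one allele per parent per site with probability `count / 2`; affection
#' is Bernoulli with probability
#' `plogis(baseline_logodds + sum(effects * child_count))`. Uses the
#' current RNG stream.
#'
#' @param mafs per-site MAF vector.
#' @param effects per-site log-odds effects (same length; 0 = non-causal).
#' @param baseline_logodds logistic intercept.
#' @param id trio id.
#' @return A single-trio [trio_set()].
#' @export
simulate_trio <- function(mafs, effects = numeric(length(mafs)),
                          baseline_logodds = qlogis(0.2), id = "t1") {
  stopifnot(length(effects) == length(mafs))
  b <- draw_trio_batch(1, mafs, effects, baseline_logodds)
  trio_set(child_id = id, father_id = paste0(id, "_f"),
           mother_id = paste0(id, "_m"),
           G_child = b$cg, G_father = b$fg, G_mother = b$mg,
           affected = b$affected, sites = default_sim_sites(mafs, effects))
}

default_sim_sites <- function(mafs, effects) {
  m <- length(mafs)
  data.frame(site_id = sprintf("s%03d", seq_len(m)), chrom = "1",
             pos = 1000 * seq_len(m), allele_ref = "A", allele_rare = "C",
             cm = 0, true_maf = mafs, effect = effects,
             stringsAsFactors = FALSE)
}

#' Simulate an ascertained sample of trios
#'
#' Trios are drawn and assigned to the affected-child (case) or
#' unaffected-child (control) quota until both fill. With two
#' subpopulations, consecutive draws alternate between populations whose
#' MAFs differ by `subpop_maf_multiplier` and whose baseline log-odds
#' differ by `subpop_baseline_shift` — the stratification stress test.
#' Deterministic given `config$seed` (the gene is drawn first from the
#' same stream unless supplied).
#'
#' @param config a [sim_config()].
#' @param gene optional gene from [simulate_gene()]; drawn if `NULL`.
#' @return A [trio_set()] with cases first, then controls; the `subpop`
#'   attribute records each trio's subpopulation.
#' @export
simulate_trio_sample <- function(config, gene = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(gene)) gene <- draw_gene(config)
  mafs2 <- pmin(gene$mafs * config$subpop_maf_multiplier, 0.5)
  base2 <- config$baseline_logodds + config$subpop_baseline_shift

  need_case <- config$n_case_trios
  need_ctrl <- config$n_control_trios
  acc <- list()
  drawn <- 0L
  while (need_case > 0 || need_ctrl > 0) {
    if (drawn >= config$draw_cap) {
      stop_condition("triosvm_ascertainment",
                     sprintf(paste0("draw cap %d reached with %d case and ",
                                    "%d control trios still missing"),
                             config$draw_cap, need_case, need_ctrl),
                     achieved = list(
                       n_case = config$n_case_trios - need_case,
                       n_control = config$n_control_trios - need_ctrl))
    }
    batch_n <- min(config$draw_cap - drawn,
                   max(100L, 4L * (need_case + need_ctrl)))
    subpop <- if (config$n_subpops == 2) {
      (drawn + seq_len(batch_n) - 1L) %% 2L + 1L
    } else {
      rep(1L, batch_n)
    }
    b1 <- draw_trio_batch(sum(subpop == 1), gene$mafs, gene$effects,
                          config$baseline_logodds)
    fg <- matrix(0L, batch_n, config$n_sites)
    mg <- fg; cg <- fg
    affected <- logical(batch_n)
    fg[subpop == 1, ] <- b1$fg
    mg[subpop == 1, ] <- b1$mg
    cg[subpop == 1, ] <- b1$cg
    affected[subpop == 1] <- b1$affected
    if (any(subpop == 2)) {
      b2 <- draw_trio_batch(sum(subpop == 2), mafs2, gene$effects, base2)
      fg[subpop == 2, ] <- b2$fg
      mg[subpop == 2, ] <- b2$mg
      cg[subpop == 2, ] <- b2$cg
      affected[subpop == 2] <- b2$affected
    }
    take_case <- which(affected)[seq_len(min(need_case, sum(affected)))]
    take_ctrl <- which(!affected)[seq_len(min(need_ctrl, sum(!affected)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc[[length(acc) + 1]] <- list(fg = fg[take, , drop = FALSE],
                                     mg = mg[take, , drop = FALSE],
                                     cg = cg[take, , drop = FALSE],
                                     affected = affected[take],
                                     subpop = subpop[take])
    }
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
    drawn <- drawn + batch_n
  }
  fg <- do.call(rbind, lapply(acc, `[[`, "fg"))
  mg <- do.call(rbind, lapply(acc, `[[`, "mg"))
  cg <- do.call(rbind, lapply(acc, `[[`, "cg"))
  affected <- unlist(lapply(acc, `[[`, "affected"))
  subpop <- unlist(lapply(acc, `[[`, "subpop"))
  ord <- order(!affected)        # cases first, stable
  n <- length(affected)
  ids <- sprintf("t%05d", seq_len(n))
  ts <- trio_set(child_id = ids, father_id = paste0(ids, "_f"),
                 mother_id = paste0(ids, "_m"),
                 G_child = cg[ord, , drop = FALSE],
                 G_father = fg[ord, , drop = FALSE],
                 G_mother = mg[ord, , drop = FALSE],
                 affected = affected[ord],
                 sites = default_sim_sites(gene$mafs, gene$effects))
  attr(ts, "subpop") <- subpop[ord]
  attr(ts, "gene") <- gene
  ts
}

#' Bootstrap-resample trios to a larger sample
#'
#' Samples `n` trios with replacement, preserving each trio's label, so the
#' class proportions match the source in expectation. Resampled trios get
#' fresh unique ids (fold assignment treats repeated draws of one source
#' trio as distinct sampling units). Uses the current RNG stream unless
#' `seed` is given.
#'
#' @param trios a [trio_set()].
#' @param n target number of trios.
#' @param seed optional seed.
#' @return A [trio_set()] of `n` trios.
#' @export
bootstrap_trios <- function(trios, n, seed = NULL) {
  stopifnot(inherits(trios, "trio_set"), length(trios) >= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- if (n > 0) sample.int(length(trios), n, replace = TRUE) else integer(0)
  out <- trios[idx]
  out$child_id <- sprintf("b%05d_%s", seq_len(n), trios$child_id[idx])
  out$father_id <- paste0(out$child_id, "_f")
  out$mother_id <- paste0(out$child_id, "_m")
  out
}

# deterministic per-replicate seed below 2^31
derive_seed <- function(master, k) {
  ((as.numeric(master) %% 2147483647) * 31 + k * 1000003) %% 2147483629 + 1
}

#' Run a type-I-error or power experiment
#'
#' Per replicate: draw a fresh gene and ascertained trio sample (seed
#' derived from the master seed and the replicate index), optionally
#' bootstrap to a larger trio count, run [gene_test()], and record theta
#' and p. With causal effects the rejection rates estimate power; with a
#' null configuration they estimate the type I error. Untestable replicates
#' (NA p) are counted and excluded from the denominators with a warning.
#'
#' @param config a [sim_config()].
#' @param replicates number of independent replicates.
#' @param alpha_levels nominal levels at which to report rejection rates.
#' @param analysis a [kernel_config()].
#' @param maf_threshold site-inclusion MAF bound applied to the
#'   parental-genotype MAF estimate.
#' @param n_boot if non-`NULL`, bootstrap each replicate's sample to this
#'   many trios before testing.
#' @param verbose print one line per replicate.
#' @return An object of class `triosvm_experiment`: `replicates`, `n_used`,
#'   `alpha_levels`, `rejection_rates`, `mc_se`, `mean_theta`,
#'   `theta_mc_se`, and the per-replicate `results` data.frame.
#' @export
run_experiment <- function(config, replicates,
                           alpha_levels = c(0.05, 0.01, 0.001, 1e-4),
                           analysis = kernel_config(), maf_threshold = 0.03,
                           n_boot = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1,
            all(alpha_levels > 0), all(alpha_levels <= 1))
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, r)
    ts <- simulate_trio_sample(cfg)
    if (!is.null(n_boot)) ts <- bootstrap_trios(ts, n_boot)
    ana <- analysis
    ana$seed <- derive_seed(cfg$seed, 7L)
    res <- gene_test(ts, maf_threshold = maf_threshold, config = ana,
                     gene = sprintf("rep%04d", r))
    if (verbose) {
      message(sprintf("replicate %d/%d: theta = %.3f, p = %.3g (%s)",
                      r, replicates, res$theta_hat, res$p_one_sided,
                      res$reason_code))
    }
    rows[[r]] <- res
  }
  results <- do.call(rbind, rows)
  p <- results$p_one_sided
  ok <- !is.na(p)
  n_used <- sum(ok)
  if (n_used < replicates) {
    warning(sprintf("%d of %d replicates untestable; excluded from rates",
                    replicates - n_used, replicates))
  }
  rates <- vapply(alpha_levels, function(a) mean(p[ok] < a), numeric(1))
  theta <- results$theta_hat[!is.na(results$theta_hat)]
  structure(list(replicates = replicates, n_used = n_used,
                 alpha_levels = alpha_levels, rejection_rates = rates,
                 mc_se = sqrt(rates * (1 - rates) / max(n_used, 1)),
                 mean_theta = mean(theta),
                 theta_mc_se = sd(theta) / sqrt(length(theta)),
                 results = results),
            class = "triosvm_experiment")
}

#' @export
print.triosvm_experiment <- function(x, ...) {
  cat(sprintf("triosvm_experiment: %d replicates (%d testable)\n",
              x$replicates, x$n_used))
  cat(sprintf("  mean AUC %.4f (MC se %.4f)\n", x$mean_theta, x$theta_mc_se))
  tab <- data.frame(alpha = x$alpha_levels, rejection = x$rejection_rates,
                    mc_se = x$mc_se)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an experiment result as TSV
#'
#' One row per nominal level: `alpha`, `rejection_rate`, `mc_se`,
#' `replicates_used`.
#'
#' @param x a `triosvm_experiment`.
#' @param path output path.
#' @return Invisibly, the written data.frame.
#' @export
write_experiment <- function(x, path) {
  stopifnot(inherits(x, "triosvm_experiment"))
  df <- data.frame(alpha = x$alpha_levels, rejection_rate = x$rejection_rates,
                   mc_se = x$mc_se, replicates_used = x$n_used)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
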