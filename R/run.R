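# File-level orchestration: the per-gene analysis over a regions table,
# and a small self-contained fixture generator.

#' Convert a trio set to a genotype table
#'
#' Writes each trio as a nuclear family (father and mother as founders, one
#' child) so that simulated data round-trip through the linkage-format
#' pipeline. Parents get missing phenotype; the child gets linkage coding
#' 2/1 from its affection status.
#'
#' @param trios a [trio_set()].
#' @return A [genotype_table()].
#' @export
as_genotype_table <- function(trios) {
  stopifnot(inherits(trios, "trio_set"))
  n <- length(trios)
  fam <- sprintf("f%05d", seq_len(n))
  samples <- data.frame(
    family_id = rep(fam, each = 3),
    individual_id = rep(c("1", "2", "3"), n),
    father_id = rep(c("0", "0", "1"), n),
    mother_id = rep(c("0", "0", "2"), n),
    sex = rep(c(1L, 2L, 0L), n),
    phenotype = as.vector(rbind("0", "0", ifelse(trios$affected, "2", "1"))),
    stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, 3 * n, ncol(trios$G_child))
  geno[seq(1, 3 * n, by = 3), ] <- trios$G_father
  geno[seq(2, 3 * n, by = 3), ] <- trios$G_mother
  geno[seq(3, 3 * n, by = 3), ] <- trios$G_child
  sites <- trios$sites
  genotype_table(samples, sites, geno)
}

#' Run the per-gene analysis over a regions file
#'
#' Reads PED/MAP genotypes and a 4-column regions TSV, runs [gene_test()]
#' for every region, and writes a per-gene results TSV whose comment header
#' records the package version, seed and configuration. Untestable genes
#' produce NA rows with a reason code; the exit is clean either way.
#'
#' @param ped_path,map_path linkage-format input.
#' @param regions_path regions TSV (gene, chrom, start, end; with header).
#' @param output_path results TSV path.
#' @param maf_threshold site-inclusion MAF bound (exclusive).
#' @param mode `"trio"` or `"case_control"`.
#' @param config a [kernel_config()].
#' @param resubstitution see [gene_test()].
#' @param verbose log the per-penalty CV AUC table per gene.
#' @return Invisibly, the results data.frame.
#' @export
run_analysis <- function(ped_path, map_path, regions_path, output_path,
                         maf_threshold = 0.01, mode = "trio",
                         config = kernel_config(), resubstitution = FALSE,
                         verbose = FALSE) {
  table <- read_ped(ped_path, map_path)
  regions <- read_regions(regions_path)
  trios <- extract_trios(table)
  message(sprintf("%d samples, %d sites; %d trios extracted (%d affected)",
                  nrow(table$samples), nrow(table$sites), length(trios),
                  sum(trios$affected)))
  if (!is.null(trios$skipped)) {
    message(sprintf("children skipped: %d missing parent, %d missing phenotype",
                    trios$skipped$no_parent, trios$skipped$no_phenotype))
  }
  if (length(regions) > 1) {
    message(sprintf(
      "note: %d genes tested; reported p-values are not adjusted for multiplicity",
      length(regions)))
  }
  rows <- lapply(regions, function(rg) {
    res <- gene_test(table, rg, maf_threshold = maf_threshold,
                     config = config, mode = mode,
                     resubstitution = resubstitution)
    if (verbose && !is.null(attr(res, "cv_table"))) {
      tab <- attr(res, "cv_table")
      message(sprintf("%s CV AUC by penalty: %s", rg$gene,
                      paste(sprintf("C=%g:%.3f", tab$penalty, tab$cv_auc),
                            collapse = " ")))
    }
    res
  })
  results <- if (length(rows)) do.call(rbind, rows) else empty_gene_result()
  con <- file(output_path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# triosvm %s", as.character(packageVersion("triosvm"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# sigma2: %g | penalty grid: %s | folds: %d | maf_threshold: %g | mode: %s",
            config$sigma2, paste(config$penalty_grid, collapse = ","),
            config$folds, maf_threshold, mode)), con)
  suppressWarnings(write.table(results, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(results)
}

#' Generate a small self-contained PED/MAP/regions fixture
#'
#' Writes a two-gene toy dataset: gene A carries three causal sites with
#' mixed-direction effects, gene B is null. To keep a dataset of this size
#' informative the fixture uses low-frequency (rather than strictly rare)
#' variants, MAF uniform on `[0.05, 0.2]`; pair it with a permissive
#' `maf_threshold` such as 0.25. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_case,n_control trio quotas.
#' @param n_sites_per_gene sites per gene.
#' @return Invisibly, a named list of the written paths (`ped`, `map`,
#'   `regions`, `truth`).
#' @export
make_fixture <- function(dir, seed = 1L, n_case = 15, n_control = 15,
                         n_sites_per_gene = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- 2L * n_sites_per_gene
  cfg <- sim_config(n_sites = m, maf_low = 0.05, maf_high = 0.20,
                    baseline_logodds = qlogis(0.3),
                    n_case_trios = n_case, n_control_trios = n_control,
                    seed = seed)
  set.seed(derive_seed(seed, 1L))   # gene stream distinct from the trio stream
  gene <- draw_gene(cfg)
  causal <- sort(sample(n_sites_per_gene, 3))      # causal sites in gene A
  gene$effects <- numeric(m)
  gene$effects[causal] <- c(2.5, -2.5, 2.5)
  gene$causal <- causal
  ts <- simulate_trio_sample(cfg, gene = gene)
  tab <- as_genotype_table(ts)
  tab$sites$chrom <- "1"
  tab$sites$pos <- 100000 * seq_len(m)
  paths <- list(ped = file.path(dir, "fixture.ped"),
                map = file.path(dir, "fixture.map"),
                regions = file.path(dir, "fixture.regions.tsv"),
                truth = file.path(dir, "fixture.truth.tsv"))
  write_genotype_table(tab, paths$ped, paths$map)
  regions <- data.frame(
    gene = c("geneA", "geneB"), chrom = "1",
    start = c(tab$sites$pos[1], tab$sites$pos[n_sites_per_gene + 1]),
    end = c(tab$sites$pos[n_sites_per_gene], tab$sites$pos[m]))
  write.table(regions, paths$regions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- data.frame(site_id = tab$sites$site_id, maf = gene$mafs,
                      effect = gene$effects)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
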