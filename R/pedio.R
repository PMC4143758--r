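# Linkage-format (PED/MAP) input, trio extraction, allele frequencies and
# rare-site selection.

#' Construct a genotype table
#'
#' A genotype table holds pedigree sample metadata, biallelic variant-site
#' metadata, and a samples-by-sites matrix of rare-allele counts.
#'
#' @param samples data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype` (linkage coding:
#'   2 = affected, 1 = unaffected, 0 or -9 = missing).
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (1-based),
#'   `allele_ref`, `allele_rare` (and optionally `cm`).
#' @param geno integer matrix, `nrow(samples)` x `nrow(sites)`, of rare-allele
#'   counts in `{0, 1, 2}`; `NA` = missing genotype.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, sites, geno) {
  stopifnot(is.data.frame(samples), is.data.frame(sites))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(sites)) {
    stop("genotype matrix must be samples x sites")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype entries must be 0, 1, 2 or NA")
  }
  if (!all(c("family_id", "individual_id", "father_id", "mother_id",
             "sex", "phenotype") %in% names(samples))) {
    stop("samples is missing required columns")
  }
  if (!all(c("site_id", "chrom", "pos", "allele_ref", "allele_rare") %in%
             names(sites))) {
    stop("sites is missing required columns")
  }
  if (is.null(sites$cm)) sites$cm <- 0
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d sites (%d founders)\n",
              nrow(x$samples), nrow(x$sites), sum(is_founder(x))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

is_founder <- function(table) {
  table$samples$father_id == "0" & table$samples$mother_id == "0"
}

# linkage phenotype coding -> logical affected (NA = missing)
pheno_to_affected <- function(phenotype) {
  p <- suppressWarnings(as.numeric(phenotype))
  ifelse(!is.na(p) & p == 2, TRUE, ifelse(!is.na(p) & p == 1, FALSE, NA))
}

sample_key <- function(family_id, individual_id) {
  paste(family_id, individual_id, sep = ":")
}

#' Read pedigree genotypes in linkage (PED/MAP) format
#'
#' Sites are oriented so that genotype counts are counts of the minor allele
#' among founders (individuals with both parent ids `0`); when no founders
#' are present all individuals are used for orientation. Alleles coded `0`
#' are missing; a genotype with either allele missing is `NA`. Sites with
#' more than two observed alleles are dropped with a warning.
#'
#' @param ped_path path to a PED file (family, individual, father, mother,
#'   sex, phenotype, then two allele columns per site).
#' @param map_path path to the matching MAP file (3 or 4 columns:
#'   chromosome, site id, \[genetic position,\] base-pair position).
#' @return A [genotype_table()].
#' @export
read_ped <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(map) == 4) {
    names(map) <- c("chrom", "site_id", "cm", "pos")
  } else if (ncol(map) == 3) {
    names(map) <- c("chrom", "site_id", "pos")
    map$cm <- "0"
  } else {
    stop("MAP file must have 3 or 4 columns")
  }
  m <- nrow(map)
  map$pos <- as.numeric(map$pos)
  if (any(is.na(map$pos)) || any(map$pos < 1)) {
    stop("MAP positions must be numbers >= 1")
  }

  ped <- read.table(ped_path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(ped) != 6 + 2 * m) {
    stop(sprintf(
      "PED/MAP mismatch: PED has %d allele columns for %d mapped sites",
      ncol(ped) - 6, m))
  }
  samples <- data.frame(
    family_id = ped[[1]], individual_id = ped[[2]],
    father_id = ped[[3]], mother_id = ped[[4]],
    sex = suppressWarnings(as.integer(ped[[5]])), phenotype = ped[[6]],
    stringsAsFactors = FALSE)

  A1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  A2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])

  founder <- samples$father_id == "0" & samples$mother_id == "0"
  if (!any(founder)) {
    warning("no founders present; orienting alleles on all individuals")
    founder <- rep(TRUE, nrow(samples))
  }

  geno <- matrix(NA_integer_, nrow(samples), m)
  allele_ref <- allele_rare <- character(m)
  keep <- rep(TRUE, m)
  for (j in seq_len(m)) {
    a1 <- A1[, j]
    a2 <- A2[, j]
    obs <- sort(setdiff(unique(c(a1, a2)), "0"))
    if (length(obs) > 2) {
      warning(sprintf("site %s has %d alleles; dropped (biallelic only)",
                      map$site_id[j], length(obs)))
      keep[j] <- FALSE
      next
    }
    miss <- a1 == "0" | a2 == "0"
    if (length(obs) <= 1) {
      allele_ref[j] <- if (length(obs)) obs else "."
      allele_rare[j] <- "."
      g <- rep(0L, nrow(samples))
    } else {
      ok <- founder & !miss
      n1 <- sum(a1[ok] == obs[1]) + sum(a2[ok] == obs[1])
      n2 <- sum(a1[ok] == obs[2]) + sum(a2[ok] == obs[2])
      # minor allele in founders is the rare allele; tie -> the
      # lexicographically larger allele (deterministic)
      rare <- if (n2 <= n1) obs[2] else obs[1]
      allele_rare[j] <- rare
      allele_ref[j] <- setdiff(obs, rare)
      g <- (a1 == rare) + (a2 == rare)
    }
    g[miss] <- NA_integer_
    geno[, j] <- g
  }

  sites <- data.frame(site_id = map$site_id, chrom = map$chrom,
                      pos = map$pos, allele_ref = allele_ref,
                      allele_rare = allele_rare, cm = map$cm,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(sites) <- NULL
  genotype_table(samples, sites, geno[, keep, drop = FALSE])
}

#' Write a genotype table in linkage (PED/MAP) format
#'
#' Inverse of [read_ped()] up to allele order within a genotype: counts,
#' sample metadata and site metadata round-trip exactly.
#'
#' @param table a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_genotype_table <- function(table, ped_path, map_path) {
  s <- table$samples
  st <- table$sites
  g <- table$geno
  m <- nrow(st)
  alleles <- matrix("0", nrow(g), 2 * m)
  for (j in seq_len(m)) {
    ref <- st$allele_ref[j]
    rare <- st$allele_rare[j]
    if (rare == ".") rare <- ref     # monomorphic: write the observed allele
    a1 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] >= 1, rare, ref))
    a2 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] == 2, rare, ref))
    alleles[, 2 * j - 1] <- a1
    alleles[, 2 * j] <- a2
  }
  ped <- cbind(s$family_id, s$individual_id, s$father_id, s$mother_id,
               s$sex, s$phenotype, alleles)
  write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  map <- cbind(st$chrom, st$site_id, st$cm, format(st$pos, scientific = FALSE,
                                                   trim = TRUE))
  write.table(map, map_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(c(ped_path, map_path))
}

#' Compute per-site minor-allele frequency
#'
#' @param table a [genotype_table()].
#' @param founders_only use founders only (default), avoiding the
#'   double-counting of transmitted alleles in parent-child sets.
#' @return Numeric vector of per-site MAF in `[0, 0.5]`; `NA` where every
#'   genotype is missing.
#' @export
compute_maf <- function(table, founders_only = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  if (nrow(table$samples) == 0 || nrow(table$sites) == 0) {
    stop("cannot compute allele frequencies on an empty table")
  }
  rows <- if (founders_only) is_founder(table) else rep(TRUE, nrow(table$geno))
  if (!any(rows)) {
    warning("no founders in table; using all individuals")
    rows <- rep(TRUE, nrow(table$geno))
  }
  g <- table$geno[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  freq <- ifelse(n_obs == 0, NA_real_, colSums(g, na.rm = TRUE) / (2 * n_obs))
  # orientation guarantee: report the minor allele frequency
  pmin(freq, 1 - freq)
}

#' Define a gene region
#'
#' @param gene gene name.
#' @param chromosome chromosome label as in the MAP file.
#' @param start_bp,end_bp 1-based inclusive span.
#' @return An object of class `gene_region`.
#' @export
gene_region <- function(gene, chromosome, start_bp, end_bp) {
  start_bp <- as.numeric(start_bp)
  end_bp <- as.numeric(end_bp)
  stopifnot(start_bp >= 1, start_bp <= end_bp)
  structure(list(gene = as.character(gene),
                 chromosome = as.character(chromosome),
                 start_bp = start_bp, end_bp = end_bp),
            class = "gene_region")
}

#' Read gene regions from a 4-column TSV (gene, chrom, start, end)
#'
#' @param path TSV path; a header line is required.
#' @return List of [gene_region()] objects.
#' @export
read_regions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("regions file needs columns gene, chrom, start, end")
  lapply(seq_len(nrow(df)), function(i) {
    gene_region(df[[1]][i], df[[2]][i], df[[3]][i], df[[4]][i])
  })
}

#' Select rare-variant sites within a gene region
#'
#' Keeps polymorphic sites whose MAF lies strictly between 0 and
#' `maf_threshold` and whose position falls inside the region, in position
#' order. Monomorphic sites carry no transmission information and are
#' excluded even below threshold.
#'
#' @param table a [genotype_table()].
#' @param region a [gene_region()], or `NULL` to keep all sites.
#' @param maf_threshold MAF upper bound (exclusive), e.g. 0.01 or 0.03.
#' @param maf optional precomputed MAF vector (defaults to
#'   `compute_maf(table)`).
#' @return Integer vector of site indices (possibly empty).
#' @export
select_sites <- function(table, region, maf_threshold, maf = NULL) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5)
  if (is.null(maf)) maf <- compute_maf(table)
  stopifnot(length(maf) == nrow(table$sites))
  in_region <- if (is.null(region)) {
    rep(TRUE, nrow(table$sites))
  } else {
    table$sites$chrom == region$chromosome &
      table$sites$pos >= region$start_bp &
      table$sites$pos <= region$end_bp
  }
  idx <- which(in_region & !is.na(maf) & maf > 0 & maf < maf_threshold)
  idx[order(table$sites$pos[idx])]
}

#' Extract complete parent-child trios
#'
#' One trio per child whose father and mother are both genotyped rows of the
#' table and whose phenotype is non-missing. Trios are returned in file
#' order; children sharing parents each yield their own trio, and trios are
#' treated as independent downstream.
#'
#' @param table a [genotype_table()].
#' @return A `trio_set`; the `skipped` element counts children excluded for
#'   a missing parent or phenotype.
#' @export
extract_trios <- function(table) {
  s <- table$samples
  key <- sample_key(s$family_id, s$individual_id)
  if (anyDuplicated(key)) stop("duplicated family:individual ids")
  fkey <- sample_key(s$family_id, s$father_id)
  mkey <- sample_key(s$family_id, s$mother_id)
  aff <- pheno_to_affected(s$phenotype)

  has_parent_ids <- s$father_id != "0" & s$mother_id != "0"
  parents_present <- has_parent_ids & fkey %in% key & mkey %in% key
  usable <- parents_present & !is.na(aff)
  skipped <- list(no_parent = sum(has_parent_ids & !parents_present),
                  no_phenotype = sum(parents_present & is.na(aff)))

  ci <- which(usable)
  fi <- match(fkey[ci], key)
  mi <- match(mkey[ci], key)
  trio_set(child_id = key[ci], father_id = key[fi], mother_id = key[mi],
           G_child = table$geno[ci, , drop = FALSE],
           G_father = table$geno[fi, , drop = FALSE],
           G_mother = table$geno[mi, , drop = FALSE],
           affected = aff[ci], sites = table$sites, skipped = skipped)
}

#' Construct a set of parent-child trios
#'
#' @param child_id,father_id,mother_id character vectors of ids.
#' @param G_child,G_father,G_mother trios-by-sites matrices of rare-allele
#'   counts in `{0, 1, 2}` (`NA` = missing).
#' @param affected logical; the child's affection status. The SVM label is
#'   -1 for affected children and +1 otherwise.
#' @param sites site metadata data.frame (as in [genotype_table()]).
#' @param skipped optional bookkeeping list from [extract_trios()].
#' @return An object of class `trio_set`.
#' @export
trio_set <- function(child_id, father_id, mother_id, G_child, G_father,
                     G_mother, affected, sites, skipped = NULL) {
  n <- length(child_id)
  stopifnot(length(father_id) == n, length(mother_id) == n,
            length(affected) == n,
            nrow(G_child) == n, nrow(G_father) == n, nrow(G_mother) == n,
            ncol(G_child) == nrow(sites),
            ncol(G_father) == ncol(G_child), ncol(G_mother) == ncol(G_child))
  structure(list(child_id = as.character(child_id),
                 father_id = as.character(father_id),
                 mother_id = as.character(mother_id),
                 G_child = G_child, G_father = G_father, G_mother = G_mother,
                 affected = as.logical(affected),
                 label = ifelse(affected, -1L, 1L),
                 sites = sites, skipped = skipped),
            class = "trio_set")
}

#' @export
length.trio_set <- function(x) length(x$child_id)

#' @export
`[.trio_set` <- function(x, i, ...) {
  trio_set(x$child_id[i], x$father_id[i], x$mother_id[i],
           x$G_child[i, , drop = FALSE], x$G_father[i, , drop = FALSE],
           x$G_mother[i, , drop = FALSE], x$affected[i], x$sites,
           skipped = x$skipped)
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d trios (%d affected, %d unaffected) x %d sites\n",
              length(x), sum(x$affected), sum(!x$affected), ncol(x$G_child)))
  if (!is.null(x$skipped)) {
    cat(sprintf("  children skipped: %d missing parent, %d missing phenotype\n",
                x$skipped$no_parent, x$skipped$no_phenotype))
  }
  invisible(x)
}

# MAF estimated from the parental genotypes of a trio set (parents are the
# founders of each trio; shared parents are counted once per trio)
maf_from_parents <- function(trios) {
  g <- rbind(trios$G_father, trios$G_mother)
  n_obs <- colSums(!is.na(g))
  freq <- ifelse(n_obs == 0, NA_real_, colSums(g, na.rm = TRUE) / (2 * n_obs))
  pmin(freq, 1 - freq)
}
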