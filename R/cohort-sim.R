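#' Specification of a simulated genotype/phenotype cohort
#'
#' Bundles the parameters of the cohort simulator: sample and marker counts,
#' the number of subpopulations and their Balding-Nichols divergence (F_ST),
#' the ancestral minor-allele-frequency range, the linkage-disequilibrium
#' block length (in SNPs) and within-block haplotype copying strength, the
#' number of additive QTLs, the narrow-sense heritability of the liability,
#' and the liability threshold of the binary trait (in liability standard
#' deviations; the default 0 gives a balanced mild/severe split).
#'
#' @param n_samples Number of diploid accessions (>= 2).
#' @param n_snps Number of biallelic SNPs.
#' @param n_pops Number of subpopulations (>= 1).
#' @param fst Balding-Nichols divergence of subpopulation allele frequencies
#'   from the ancestral frequency (>= 0; 0 means a panmictic cohort).
#' @param maf_range Ancestral allele-frequency range, in (0, 0.5].
#' @param ld_block_len LD block length in SNPs; SNPs in different blocks are
#'   independent, adjacent SNPs within a block are correlated.
#' @param ld_rho Latent autocorrelation of the within-block haplotype copying
#'   process; adjacent-SNP dosage correlation is somewhat below this value.
#' @param n_qtl Number of causal SNPs for the simulated trait.
#' @param h2 Heritability of the liability in \[0, 1\].
#' @param liability_threshold Binary trait is 1 (severe) iff the standardized
#'   liability exceeds this threshold.
#' @param missing_rate Fraction of dosages set missing (NA / "./." in VCF).
#' @param seed Master seed of the cohort.
#' @return An object of class `sim_cohort_spec`.
#' @export
sim_cohort_spec <- function(n_samples = 231L, n_snps = 5000L, n_pops = 3L,
                            fst = 0.1, maf_range = c(0.05, 0.5),
                            ld_block_len = 10L, ld_rho = 0.85,
                            n_qtl = 50L, h2 = 0.6, liability_threshold = 0,
                            missing_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 2, n_snps >= 1, n_pops >= 1, fst >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], ld_block_len >= 1,
            ld_rho >= 0, ld_rho < 1, n_qtl >= 0, n_qtl <= n_snps,
            h2 >= 0, h2 <= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 n_pops = as.integer(n_pops), fst = fst, maf_range = maf_range,
                 ld_block_len = as.integer(ld_block_len), ld_rho = ld_rho,
                 n_qtl = as.integer(n_qtl), h2 = h2,
                 liability_threshold = liability_threshold,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_cohort_spec")
}

#' Construct a genotype matrix object
#'
#' Container for diploid dosages (0/1/2, `NA` = missing) plus the marker map.
#' Positions must be strictly increasing within a chromosome.
#'
#' @param dosages `n_samples x n_snps` integer matrix, entries 0/1/2/NA.
#' @param chrom Integer chromosome per SNP.
#' @param pos Integer 1-based position per SNP.
#' @param snp_ids,sample_ids,ref,alt Optional identifiers and alleles.
#' @param pop_labels Optional integer subpopulation label per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, snp_ids = NULL,
                            sample_ids = NULL, ref = NULL, alt = NULL,
                            pop_labels = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); m <- ncol(dosages)
  stopifnot(n >= 2, length(chrom) == m, length(pos) == m)
  if (!all(dosages %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) stop("pos must be strictly increasing within chrom")
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%d_%d", chrom, pos)
  if (is.null(sample_ids)) sample_ids <- sprintf("acc_%03d", seq_len(n))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages,
                 map = data.frame(snp_id = snp_ids, chrom = as.integer(chrom),
                                  pos = as.integer(pos), ref = ref, alt = alt,
                                  stringsAsFactors = FALSE),
                 sample_ids = sample_ids, pop_labels = pop_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate structured diploid genotypes with LD
#'
#' Draws per-SNP ancestral frequencies uniformly from `maf_range`, then
#' Balding-Nichols subpopulation frequencies
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around them so that the expected Hudson
#' F_ST between subpopulations equals `fst`. Haplotypes are generated by a
#' latent-Gaussian copying process: within each LD block an AR(1) latent
#' series with autocorrelation `ld_rho` is thresholded at the subpopulation
#' frequency quantile, so neighbouring-SNP r2 decays geometrically with
#' distance and SNPs in different blocks are independent. Dosage = sum of two
#' independent haplotypes. Optional missingness is injected completely at
#' random at `missing_rate`.
#'
#' SNPs are laid out on a single chromosome at 1 kb spacing by default
#' (positions `1, 1001, 2001, ...`).
#'
#' @param spec A [sim_cohort_spec()].
#' @param chrom_count Number of chromosomes to spread the SNPs over.
#' @param spacing_bp Base-pair spacing between adjacent SNPs.
#' @return A `genotype_matrix` with `pop_labels` filled in.
#' @export
simulate_genotypes <- function(spec, chrom_count = 1L, spacing_bp = 1000L) {
  stopifnot(inherits(spec, "sim_cohort_spec"))
  n <- spec$n_samples; m <- spec$n_snps; K <- spec$n_pops
  with_seed(derive_seed(spec$seed, 1L), {
    p_anc <- runif(m, spec$maf_range[1], spec$maf_range[2])
    ## subpopulation frequencies: Balding-Nichols
    pf <- matrix(p_anc, K, m, byrow = TRUE)
    if (spec$fst > 0 && K > 1) {
      F <- spec$fst
      for (k in seq_len(K))
        pf[k, ] <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
      ## guard against Beta draws collapsing to 0/1 at extreme frequencies
      pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
    }
    pop <- rep(seq_len(K), length.out = n)  # balanced subpopulation sizes
    blocks <- rep(seq_len(ceiling(m / spec$ld_block_len)),
                  each = spec$ld_block_len)[seq_len(m)]
    new_block <- c(TRUE, diff(blocks) != 0)

    ## two haplotypes per sample via the latent AR(1) threshold model
    dos <- matrix(0L, n, m)
    thr <- qnorm(pf)                        # K x m threshold matrix
    for (hap in 1:2) {
      z <- matrix(rnorm(n * m), n, m)
      for (j in seq_len(m)[-1]) {
        if (!new_block[j])
          z[, j] <- spec$ld_rho * z[, j - 1] +
                    sqrt(1 - spec$ld_rho^2) * z[, j]
      }
      dos <- dos + (z < matrix(thr[pop, ], n, m))
    }
    storage.mode(dos) <- "integer"
    if (spec$missing_rate > 0) {
      miss <- runif(n * m) < spec$missing_rate
      dos[matrix(miss, n, m)] <- NA_integer_
    }
    chrom <- rep(seq_len(chrom_count), length.out = m)
    chrom <- sort(chrom)
    pos <- integer(m)
    for (cc in seq_len(chrom_count))
      pos[chrom == cc] <- 1L + spacing_bp * (seq_len(sum(chrom == cc)) - 1L)
    genotype_matrix(dos, chrom, pos, pop_labels = pop)
  })
}

#' Simulate additive liability phenotypes on a genotype matrix
#'
#' Picks `n_qtl` causal SNPs uniformly at random, draws their additive
#' effects from N(0, 1), and forms the genetic value `g = sum(beta_k * x_k)`
#' (missing dosages contribute the SNP mean). Environmental noise is scaled
#' so that `Var(g) / Var(g + e)` equals `h2` exactly in-sample. The liability
#' `l = g + e` is standardized; the binary phenotype is
#' `1 iff l > liability_threshold` and the continuous phenotype is the affine
#' map of `l` onto \[0, 5\] (min to 0, max to 5).
#'
#' @param G A `genotype_matrix`.
#' @param spec A [sim_cohort_spec()] (supplies `n_qtl`, `h2`,
#'   `liability_threshold` and the seed).
#' @return A list with `pheno` (a `phenotype_table` data frame with columns
#'   `accession_id`, `binary_pheno`, `continuous_pheno`, `true_genetic_value`)
#'   and `qtl` (data frame of causal SNP indices and effects).
#' @export
simulate_phenotypes <- function(G, spec) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "sim_cohort_spec"))
  m <- ncol(G$dosages); n <- nrow(G$dosages)
  if (spec$n_qtl > m) stop("n_qtl exceeds the number of SNPs")
  with_seed(derive_seed(spec$seed, 2L), {
    qtl_idx <- sort(sample.int(m, spec$n_qtl))
    beta <- rnorm(spec$n_qtl)
    X <- G$dosages[, qtl_idx, drop = FALSE]
    ## missing dosages enter at the SNP mean so g is defined for everyone
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      for (j in seq_along(qtl_idx)) X[is.na(X[, j]), j] <- mu[j]
    }
    g <- as.numeric(X %*% beta)
    vg <- var(g)
    if (spec$h2 == 0 || vg == 0) {
      liab <- rnorm(n)
      g <- g * 0
    } else if (spec$h2 == 1) {
      liab <- g
    } else {
      e <- rnorm(n)
      e <- e * sqrt(vg * (1 - spec$h2) / spec$h2) / sd(e)
      liab <- g + e
    }
    liab_std <- if (sd(liab) > 0) (liab - mean(liab)) / sd(liab) else liab
    cont <- if (diff(range(liab)) > 0)
      5 * (liab - min(liab)) / (max(liab) - min(liab)) else rep(2.5, n)
    pheno <- data.frame(
      accession_id = G$sample_ids,
      binary_pheno = as.integer(liab_std > spec$liability_threshold),
      continuous_pheno = cont,
      true_genetic_value = g,
      stringsAsFactors = FALSE)
    class(pheno) <- c("phenotype_table", "data.frame")
    list(pheno = pheno,
         qtl = data.frame(index = qtl_idx, snp_id = G$map$snp_id[qtl_idx],
                          beta = beta, stringsAsFactors = FALSE))
  })
}

#' Simulate a tree whose ladder order tracks the phenotype by tunable strength
#'
#' Builds a pectinate (ladder) tree over the accessions whose tip order
#' interpolates between the phenotype rank order (`signal = 1`) and a uniform
#' random permutation (`signal = 0`). Intermediate signal shuffles a random
#' subset of `round((1 - signal) * n)` tip positions. Phenotype ties are
#' broken by accession id so the target order is deterministic.
#'
#' @param pheno A `phenotype_table` (uses `continuous_pheno`).
#' @param signal Association strength in \[0, 1\].
#' @param seed Integer seed.
#' @return A list of class `ordered_tree` with `newick` (string), `tip_order`
#'   (character vector of accession ids in ladder order) and `phylo` (the
#'   parsed \pkg{ape} tree).
#' @export
simulate_ordered_tree <- function(pheno, signal, seed = 1L) {
  stopifnot(signal >= 0, signal <= 1)
  ids <- pheno$accession_id
  n <- length(ids)
  stopifnot(n >= 3)
  target <- ids[order(pheno$continuous_pheno, pheno$accession_id)]
  ord <- with_seed(derive_seed(seed, 3L), {
    k <- round((1 - signal) * n)
    ord <- target
    if (k >= 2) {
      posn <- sort(sample.int(n, k))
      ord[posn] <- ord[posn][sample.int(k)]
    }
    ord
  })
  ## pectinate newick: ladder order = tip order
  nwk <- ord[1]
  for (i in 2:n) nwk <- sprintf("(%s,%s)", nwk, ord[i])
  nwk <- paste0(nwk, ";")
  tr <- ape::read.tree(text = nwk)
  structure(list(newick = nwk, tip_order = ord, phylo = tr),
            class = "ordered_tree")
}

#' Ladderized tip order of a tree
#'
#' The top-to-bottom tip order a plotted ladderized phylogeny displays; used
#' as the tree-side ranking in the footrule association test.
#'
#' @param tree An \pkg{ape} `phylo` object, an `ordered_tree`, or a path to a
#'   Newick file.
#' @return Character vector of tip labels in ladder order.
#' @export
tree_tip_order <- function(tree) {
  if (inherits(tree, "ordered_tree")) return(tree$tip_order)
  if (is.character(tree) && length(tree) == 1) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::ladderize(tree)
  tree$tip.label[tree$edge[tree$edge[, 2] <= ape::Ntip(tree), 2]]
}
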