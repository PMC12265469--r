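test_that("SNP filters apply the missingness and MAF rules with kept boundaries", {
  ## hand-built matrix: 100 samples, 4 SNPs
  set.seed(1)
  n <- 100
  d <- cbind(rbinom(n, 2, 0.3),              # clean, maf ~0.3
             rbinom(n, 2, 0.3),              # 6% missing -> removed
             rep(0L, n),                      # monomorphic -> removed
             c(rep(1L, 10), rep(0L, 90)))     # maf exactly 0.05 -> retained
  d[1:6, 2] <- NA
  G <- genotype_matrix(d, chrom = rep(1L, 4), pos = c(100L, 200L, 300L, 400L))
  Gf <- filter_snps(G)
  expect_equal(Gf$map$pos, c(100L, 400L))
  ## idempotence
  expect_identical(filter_snps(Gf)$map, Gf$map)
  ## exactly 5% missing is retained
  d2 <- d[, 1, drop = FALSE]; d2[1:5, 1] <- NA
  G2 <- genotype_matrix(cbind(d2, d[, 1]), chrom = c(1L, 1L), pos = c(1L, 2L))
  expect_equal(ncol(filter_snps(G2)$dosages), 2)
  expect_error(filter_snps(genotype_matrix(matrix(0L, 10, 2), c(1L, 1L),
                                           c(1L, 2L))), "no SNPs")
})

test_that("kinship is a centered PSD GRM with the expected structure", {
  sc <- small_cohort()
  K <- sc$K
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  ## duplicated individuals have matching self- and cross-entries
  G <- sc$G
  d <- G$dosages[c(1, 1, 2:20), ]
  Gd <- genotype_matrix(d, G$map$chrom, G$map$pos)
  Kd <- kinship(Gd)
  expect_equal(Kd[1, 1], Kd[2, 2], tolerance = 1e-12)
  expect_equal(Kd[1, 1], Kd[1, 2], tolerance = 1e-12)

  ## unrelated panmictic samples: off-diagonal near zero
  sp <- sim_cohort_spec(n_samples = 80, n_snps = 4000, n_pops = 1, fst = 0,
                        ld_block_len = 1, n_qtl = 10, seed = 31)
  Ku <- kinship(simulate_genotypes(sp))
  off <- Ku[upper.tri(Ku)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("the LMM degenerates to per-SNP least squares when K = 0", {
  ## 50 random instances across 2 cohorts
  for (s in 1:2) {
    sp <- sim_cohort_spec(n_samples = 70, n_snps = 25, n_qtl = 5, h2 = 0.5,
                          seed = 300 + s)
    G <- filter_snps(simulate_genotypes(sp))
    y <- simulate_phenotypes(G, sp)$pheno$continuous_pheno
    a <- lmm_assoc(y, G, K = matrix(0, 70, 70))
    for (j in seq_len(ncol(G$dosages))) {
      f <- summary(lm(y ~ G$dosages[, j]))$coefficients
      expect_equal(a$beta[j], f[2, 1], tolerance = 1e-8)
      expect_equal(a$se[j], f[2, 2], tolerance = 1e-8)
      expect_equal(a$p_wald[j],
                   pchisq((f[2, 1] / f[2, 2])^2, 1, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  }
})

test_that("the LMM recovers a strong planted QTL as the top hit", {
  sp <- sim_cohort_spec(n_samples = 150, n_snps = 300, n_pops = 2, fst = 0.1,
                        ld_block_len = 5, n_qtl = 1, h2 = 0.35, seed = 55)
  G <- filter_snps(simulate_genotypes(sp))
  sim <- simulate_phenotypes(G, sp)
  a <- lmm_assoc(sim$pheno$continuous_pheno, G, K = kinship(G))
  expect_equal(which.min(a$p_wald), sim$qtl$index)
  expect_lt(min(a$p_wald), 1e-5)
  ## binary phenotype analysed as quantitative also flags the region
  ab <- lmm_assoc(sim$pheno$binary_pheno, G, K = kinship(G))
  expect_lt(abs(which.min(ab$p_wald) - sim$qtl$index), 6)
})

test_that("association scans reject malformed inputs", {
  sc <- small_cohort()
  y <- sc$pheno$continuous_pheno
  expect_error(lmm_assoc(c(y[-1], NA), sc$G, K = sc$K), "finite")
  expect_error(lmm_assoc(y[-1], sc$G, K = sc$K), "length n")
  W <- cbind(1, 1)  # collinear covariates
  expect_error(lmm_assoc(y, sc$G, K = sc$K, W = W), "singular")
})

test_that("significant hits merge into QTL intervals by distance", {
  a <- data.frame(snp_id = sprintf("s%d", 1:6), chrom = c(1, 1, 1, 1, 2, 2),
                  pos = c(100L, 10100L, 200000L, 201000L, 500L, 600L),
                  p_wald = c(1e-7, 1e-6, 0.5, 1e-8, 0.5, 0.5))
  class(a) <- c("assoc_result", "data.frame")
  hits <- significant_hits(a, threshold = 1e-5, merge_kb = 50)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$lead_snp, c("s1", "s4"))
  expect_equal(hits$n_snps, c(2L, 1L))
  expect_true(all(hits$pos_lo <= hits$pos_hi))
  ## no hits below threshold -> empty result
  a$p_wald[] <- 0.5
  expect_equal(nrow(significant_hits(a)), 0)
})

test_that("windowed F_ST and pi match a per-SNP brute-force oracle", {
  set.seed(9)
  n1 <- 6; n2 <- 8
  d <- rbind(matrix(rbinom(n1 * 10, 2, 0.2), n1),
             matrix(rbinom(n2 * 10, 2, 0.7), n2))
  G <- genotype_matrix(d, chrom = rep(1L, 10),
                       pos = as.integer(seq(50, 950, 100)),
                       pop_labels = rep(1:2, c(n1, n2)))
  fst <- window_fst(G, window_bp = 500L, step_bp = 500L)
  pi <- window_pi(G, window_bp = 500L, step_bp = 500L)

  ## brute-force Hudson per window
  for (w in seq_len(nrow(fst))) {
    idx <- which(G$map$pos >= fst$start[w] & G$map$pos <= fst$end[w])
    num <- den <- 0
    for (j in idx) {
      p1 <- mean(d[1:n1, j]) / 2; p2 <- mean(d[(n1 + 1):(n1 + n2), j]) / 2
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
        p2 * (1 - p2) / (2 * n2 - 1)
      den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    }
    expect_equal(fst$value[w], min(max(num / den, 0), 1), tolerance = 1e-10)
  }
  ## brute-force pi per window
  nn <- n1 + n2
  for (w in seq_len(nrow(pi))) {
    idx <- which(G$map$pos >= pi$start[w] & G$map$pos <= pi$end[w])
    tot <- 0
    for (j in idx) {
      p <- mean(d[, j]) / 2
      tot <- tot + 2 * p * (1 - p) * (2 * nn) / (2 * nn - 1)
    }
    expect_equal(pi$value[w], tot / 500, tolerance = 1e-10)
  }
  ## doubling the window length halves pi for the same SNPs
  pi2 <- window_pi(G, window_bp = 1000L, step_bp = 1000L)
  expect_equal(pi2$value[1], sum(pi$value[1:2]) * 500 / 1000, tolerance = 1e-10)
})

test_that("F_ST hits its fixed points", {
  ## identical frequencies -> ~0; fixed difference -> 1
  d_same <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), 5), 4, 5),
                  matrix(rep(c(0L, 1L, 2L, 1L), 5), 4, 5))
  G1 <- genotype_matrix(d_same, rep(1L, 5), as.integer(1:5 * 10),
                        pop_labels = rep(1:2, each = 4))
  expect_lt(window_fst(G1, window_bp = 1000L)$value[1], 0.05)

  d_fix <- rbind(matrix(0L, 4, 1), matrix(2L, 4, 1))
  G2 <- genotype_matrix(cbind(d_fix, c(rep(0:1, 4))), rep(1L, 2), c(10L, 20L),
                        pop_labels = rep(1:2, each = 4))
  w <- window_fst(G2, window_bp = 15L, step_bp = 15L)
  expect_equal(w$value[1], 1)
  expect_error(window_fst(G2, pop_labels = rep(1, 8), window_bp = 10L),
               "two populations")
})

test_that("LD r2 matches squared dosage correlation and handles missing", {
  sc <- small_cohort()
  G <- sc$G
  ## identical and perfectly anti-correlated columns give 1
  d <- G$dosages[, 1]
  Gd <- genotype_matrix(cbind(d, d, 2L - d), rep(1L, 3), c(1L, 2L, 3L))
  expect_equal(ld_r2(Gd, 1, 2), 1)
  expect_equal(ld_r2(Gd, 1, 3), 1)
  ## agrees with cor()^2 on complete pairs
  x <- G$dosages[, 5]; y <- G$dosages[, 6]
  expect_equal(ld_r2(G, 5, 6), cor(x, y)^2)
  ## monomorphic -> undefined signal
  Gm <- genotype_matrix(cbind(d, rep(1L, length(d))), rep(1L, 2), c(1L, 2L))
  expect_error(ld_r2(Gm, 1, 2), "undefined")
})

test_that("null r2 between independent SNPs is near 1/n", {
  sp <- sim_cohort_spec(n_samples = 500, n_snps = 200, n_pops = 1, fst = 0,
                        ld_block_len = 1, n_qtl = 10, seed = 71)
  G <- simulate_genotypes(sp)
  set.seed(3)
  pairs <- cbind(sample(100, 300, TRUE), sample(101:200, 300, TRUE))
  r2 <- apply(pairs, 1, function(pr) ld_r2(G, pr[1], pr[2]))
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / 500), 3 * se + 1e-3)
})
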