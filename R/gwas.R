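#' Quality-filter SNPs on missingness and minor allele frequency
#'
#' Retains SNPs whose missing-genotype rate is at most `max_missing` and
#' whose minor allele frequency is at least `min_maf` (boundary values are
#' kept: the exclusion rules are strict inequalities). The marker map is
#' subset in step. Idempotent.
#'
#' @param G A `genotype_matrix`.
#' @param max_missing Maximum tolerated per-SNP missing rate (default 0.05).
#' @param min_maf Minimum tolerated minor allele frequency (default 0.05).
#' @return The filtered `genotype_matrix`; errors if every SNP is removed.
#' @export
filter_snps <- function(G, max_missing = 0.05, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- colMeans(is.na(G$dosages))
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) stop("no SNPs survive the filters")
  subset_snps(G, which(keep))
}

#' Subset a genotype matrix to selected SNP columns
#'
#' @param G A `genotype_matrix`.
#' @param idx Integer SNP column indices (genomic order is preserved if
#'   `idx` is increasing).
#' @return A `genotype_matrix` restricted to those SNPs.
#' @export
subset_snps <- function(G, idx) {
  structure(list(dosages = G$dosages[, idx, drop = FALSE],
                 map = G$map[idx, , drop = FALSE],
                 sample_ids = G$sample_ids, pop_labels = G$pop_labels),
            class = "genotype_matrix")
}

#' Minor allele frequency per SNP
#'
#' @param G A `genotype_matrix`.
#' @return Numeric vector of per-SNP minor allele frequencies (computed on
#'   non-missing calls).
#' @export
snp_maf <- function(G) {
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  maf
}

#' Centered genomic relationship matrix (kinship)
#'
#' `K = Z Z' / m` with `Z` the column-centered dosage matrix. Missing
#' dosages are mean-imputed for this computation only (so they center to
#' zero). K is symmetric positive semidefinite.
#'
#' @param G A `genotype_matrix` (typically already filtered).
#' @return An `n x n` kinship matrix.
#' @export
kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  m <- ncol(X)
  if (m == 0) stop("no SNPs")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  Z <- sweep(X, 2, mu)
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / m
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  K
}

# Restricted log-likelihood (up to a lambda-free constant) of the rotated
# LMM at variance ratio lambda = sigma2_g / sigma2_e, for the design
# [W, x] with one SNP. Works for any number of covariate columns via the
# Schur complement of the covariate block. s = eigenvalues of K; Wt, xt, yt
# are the rotated covariates, SNP and phenotype. Returns the fitted GLS
# pieces so the caller can reuse them at the profiled optimum.
.reml_fit <- function(lambda, s, Wt, xt, yt, n) {
  v <- 1 / (lambda * s + 1)
  p <- ncol(Wt)
  A <- crossprod(Wt, Wt * v)
  r <- crossprod(Wt, yt * v)
  b <- crossprod(Wt, xt * v)
  cc <- sum(v * xt * xt)
  e <- sum(v * xt * yt)
  f <- sum(v * yt * yt)
  Ai <- tryCatch(solve(A), error = function(err) NULL)
  if (is.null(Ai)) return(list(ll = -Inf))
  schur <- cc - as.numeric(crossprod(b, Ai %*% b))
  if (schur <= 0) return(list(ll = -Inf))
  beta <- (e - as.numeric(crossprod(b, Ai %*% r))) / schur
  rss <- f - as.numeric(crossprod(r, Ai %*% r)) - beta^2 * schur
  if (rss <= 0) return(list(ll = -Inf))
  ld <- determinant(A, logarithm = TRUE)$modulus + log(schur)
  ll <- -0.5 * ((n - p - 1) * log(rss) + sum(log(lambda * s + 1)) + ld)
  list(ll = as.numeric(ll), beta = beta, schur = schur, rss = rss)
}

#' Linear mixed model association scan
#'
#' Fits, for every SNP, the standard LMM
#' `y = W alpha + x beta + u + e` with `u ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)`, using one global eigendecomposition of `K` and
#' exact per-SNP restricted-likelihood profiling of the variance ratio
#' `lambda = sigma2_g / sigma2_e` on a 100-point log10 grid over
#' \[1e-5, 1e5\] followed by golden-section refinement of the bracketing
#' interval. The SNP effect is then the GLS estimate at the profiled ratio
#' and the p-value is the Wald chi-square test on `(beta / se)^2` with 1 df.
#'
#' Binary 0/1 phenotypes are analysed as quantitative under the same model.
#' Missing dosages are mean-imputed for the test statistic (the cohort-level
#' data are never imputed); `n_used` records the non-missing count per SNP.
#'
#' @param y Numeric phenotype vector of length n (binary traits as 0/1).
#' @param G A filtered `genotype_matrix`.
#' @param K Kinship matrix from [kinship()] (recomputed when `NULL`).
#' @param W Fixed-effect covariate matrix; defaults to an intercept. Use
#'   [pc_covariates()] to append principal components.
#' @param n_grid Number of grid points for the variance-ratio profile.
#' @return A data frame of class `assoc_result` with per-SNP `snp_id`,
#'   `chrom`, `pos`, `maf`, `n_used`, `beta`, `se`, `p_wald`, `lambda`
#'   (fitted ratio) and `converged`; the null-model ratio and its
#'   heritability-like share `pve` are attached as attributes
#'   `null_lambda` / `null_pve`.
#' @export
lmm_assoc <- function(y, G, K = NULL, W = NULL, n_grid = 100L) {
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.numeric(y)
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  if (length(y) != n || any(!is.finite(y))) stop("phenotype must be finite, length n")
  if (is.null(K)) K <- kinship(G)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  p <- ncol(W)
  if (qr(W)$rank < p) stop("singular covariate matrix W")

  X <- G$dosages
  storage.mode(X) <- "double"
  n_used <- colSums(!is.na(X))
  maf <- snp_maf(G)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }

  eg <- eigen(K, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, y))
  Wt <- crossprod(U, W)
  Xt <- crossprod(U, X)                  # n x m rotated dosages

  yt2 <- yt^2
  Xt2 <- Xt * Xt
  YtXt <- Xt * yt

  ## profile the restricted likelihood on a log grid, vectorized over SNPs
  grid <- 10^seq(-5, 5, length.out = n_grid)
  best_ll <- rep(-Inf, m); best_i <- rep(1L, m)
  for (i in seq_along(grid)) {
    v <- 1 / (grid[i] * s + 1)
    A <- crossprod(Wt, Wt * v)                      # p x p, shared
    r <- crossprod(Wt, yt * v)
    Ai <- solve(A)
    Air <- Ai %*% r
    f <- sum(v * yt2)
    B <- crossprod(Wt, Xt * v)                      # p x m
    cc <- as.numeric(crossprod(Xt2, v))
    e <- as.numeric(crossprod(YtXt, v))
    schur <- cc - colSums(B * (Ai %*% B))
    num <- e - as.numeric(crossprod(B, Air))
    rss <- f - as.numeric(crossprod(r, Air)) - num^2 / schur
    ll <- -0.5 * ((n - p - 1) * log(rss) + sum(log(grid[i] * s + 1)) +
                  as.numeric(determinant(A, logarithm = TRUE)$modulus) +
                  log(schur))
    ll[!is.finite(ll) | schur <= 0 | rss <= 0] <- -Inf
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_i[upd] <- i
  }

  ## local refinement of the bracketing grid interval, per SNP
  beta <- se <- lam <- rep(NA_real_, m)
  converged <- best_ll > -Inf
  for (j in seq_len(m)) {
    if (!converged[j]) next
    i0 <- best_i[j]
    lo <- log(grid[max(1L, i0 - 1L)]); hi <- log(grid[min(n_grid, i0 + 1L)])
    opt <- optimize(function(loglam)
      .reml_fit(exp(loglam), s, Wt, Xt[, j], yt, n)$ll,
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-4)
    lam[j] <- exp(opt$maximum)
    fit <- .reml_fit(lam[j], s, Wt, Xt[, j], yt, n)
    if (!is.finite(fit$ll)) { converged[j] <- FALSE; next }
    beta[j] <- fit$beta
    se[j] <- sqrt(fit$rss / (n - p - 1) / fit$schur)
  }
  p_wald <- pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  p_wald[p_wald == 0] <- .Machine$double.xmin

  ## null-model (no SNP) variance ratio, for the heritability-like share
  null_opt <- optimize(function(loglam) {
    l <- exp(loglam)
    v <- 1 / (l * s + 1)
    A <- crossprod(Wt, Wt * v)
    r <- crossprod(Wt, yt * v)
    Ai <- tryCatch(solve(A), error = function(err) NULL)
    if (is.null(Ai)) return(-Inf)
    rss <- sum(v * yt2) - as.numeric(crossprod(r, Ai %*% r))
    if (rss <= 0) return(-Inf)
    -0.5 * ((n - p) * log(rss) + sum(log(l * s + 1)) +
            as.numeric(determinant(A, logarithm = TRUE)$modulus))
  }, lower = log(1e-5), upper = log(1e5), maximum = TRUE)
  null_lambda <- exp(null_opt$maximum)
  null_pve <- null_lambda * mean(s) / (null_lambda * mean(s) + 1)

  out <- data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom,
                    pos = G$map$pos, maf = maf, n_used = n_used,
                    beta = beta, se = se, p_wald = p_wald, lambda = lam,
                    converged = converged, stringsAsFactors = FALSE)
  attr(out, "null_lambda") <- null_lambda
  attr(out, "null_pve") <- null_pve
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Principal-component covariates from a kinship matrix
#'
#' Top eigenvectors of K, for optional population-structure covariates.
#'
#' @param K Kinship matrix.
#' @param n_pc Number of components.
#' @return An `n x n_pc` matrix of eigenvectors.
#' @export
pc_covariates <- function(K, n_pc = 3L) {
  eigen(K, symmetric = TRUE)$vectors[, seq_len(n_pc), drop = FALSE]
}

#' Genomic-control inflation factor
#'
#' Median Wald chi-square of the scan divided by the null median; a
#' well-calibrated scan has `lambda_gc` close to 1.
#'
#' @param p Vector of p-values (or an `assoc_result`).
#' @return The genomic-control lambda.
#' @export
genomic_control <- function(p) {
  if (inherits(p, "assoc_result")) p <- p$p_wald
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Call significant QTLs from an association scan
#'
#' SNPs with `p_wald` below `threshold` are grouped into QTLs by merging
#' hits within `merge_kb` kilobases on the same chromosome; each QTL reports
#' its minimum-p lead SNP, interval and member SNPs.
#'
#' @param assoc An `assoc_result`.
#' @param threshold Genome-wide significance cutoff (default 1e-5).
#' @param merge_kb Merge distance in kb (default 100).
#' @return A data frame of QTLs (possibly empty) with `lead_snp`, `chrom`,
#'   `pos_lo`, `pos_hi`, `lead_p`, `n_snps` and a list column `members`.
#' @export
significant_hits <- function(assoc, threshold = 1e-5, merge_kb = 100) {
  stopifnot(nrow(assoc) > 0)
  hits <- assoc[!is.na(assoc$p_wald) & assoc$p_wald < threshold, , drop = FALSE]
  empty <- data.frame(lead_snp = character(0), chrom = integer(0),
                      pos_lo = integer(0), pos_hi = integer(0),
                      lead_p = numeric(0), n_snps = integer(0))
  if (nrow(hits) == 0) { empty$members <- list(); return(empty) }
  hits <- hits[order(hits$chrom, hits$pos), ]
  gap <- merge_kb * 1000
  grp <- cumsum(c(TRUE, diff(hits$pos) > gap | diff(hits$chrom) != 0))
  do.call(rbind, lapply(split(hits, grp), function(h) {
    lead <- which.min(h$p_wald)
    data.frame(lead_snp = h$snp_id[lead], chrom = h$chrom[1],
               pos_lo = min(h$pos), pos_hi = max(h$pos),
               lead_p = h$p_wald[lead], n_snps = nrow(h),
               members = I(list(h$snp_id)), stringsAsFactors = FALSE)
  }))
}

# Per-SNP Hudson F_ST numerator and denominator for two populations.
.hudson_terms <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  a1 <- 2 * n1; a2 <- 2 * n2      # allele counts
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (a1 - 1) - p2 * (1 - p2) / (a2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

# Shared sliding-window machinery: windows are [start, start + window_bp - 1],
# 1-based inclusive, advanced by step_bp; windows containing no SNP are
# omitted.
.windows_over <- function(map, window_bp, step_bp, fun) {
  out <- list()
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    pos <- map$pos[idx]
    starts <- seq(1, max(pos), by = as.numeric(step_bp))
    for (st in starts) {
      en <- st + as.numeric(window_bp) - 1
      inw <- idx[pos >= st & pos <= en]
      if (length(inw) == 0) next
      out[[length(out) + 1L]] <- fun(cc, st, en, inw)
    }
  }
  do.call(rbind, out)
}

#' Windowed Hudson F_ST between two populations
#'
#' Ratio-of-averages Hudson estimator: per window, the per-SNP numerator and
#' denominator are summed over SNPs and then ratioed. The result is clipped
#' to \[0, 1\]. Windows with no SNPs are omitted.
#'
#' @param G A `genotype_matrix`.
#' @param pop_labels Population label per sample (2 populations, each with at
#'   least 2 samples); defaults to `G$pop_labels`.
#' @param window_bp,step_bp Window and step size in base pairs.
#' @return A data frame of `chrom`, `start`, `end`, `n_snps`, `value`.
#' @export
window_fst <- function(G, pop_labels = NULL, window_bp = 10000L,
                       step_bp = window_bp) {
  if (is.null(pop_labels)) pop_labels <- G$pop_labels
  pops <- sort(unique(pop_labels))
  if (length(pops) < 2) stop("need at least two populations")
  if (length(pops) > 2) stop("Hudson F_ST is defined pairwise; supply two populations")
  if (any(table(pop_labels) < 2)) stop("each population needs >= 2 samples")
  d1 <- G$dosages[pop_labels == pops[1], , drop = FALSE]
  d2 <- G$dosages[pop_labels == pops[2], , drop = FALSE]
  storage.mode(d1) <- "double"; storage.mode(d2) <- "double"
  ht <- .hudson_terms(d1, d2)
  .windows_over(G$map, window_bp, step_bp, function(cc, st, en, inw) {
    den <- sum(ht$den[inw])
    val <- if (den > 0) sum(ht$num[inw]) / den else 0
    data.frame(chrom = cc, start = st, end = en, n_snps = length(inw),
               value = min(max(val, 0), 1))
  })
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, the sum over SNPs of the unbiased expected heterozygosity
#' `2 p (1 - p) * 2n / (2n - 1)` divided by the window length in base pairs
#' (monomorphic sites contribute zero).
#'
#' @inheritParams window_fst
#' @return A data frame of `chrom`, `start`, `end`, `n_snps`, `value`.
#' @export
window_pi <- function(G, window_bp = 10000L, step_bp = window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive")
  d <- G$dosages; storage.mode(d) <- "double"
  nchr <- 2 * colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  het <- 2 * p * (1 - p) * nchr / (nchr - 1)
  .windows_over(G$map, window_bp, step_bp, function(cc, st, en, inw) {
    data.frame(chrom = cc, start = st, end = en, n_snps = length(inw),
               value = sum(het[inw]) / window_bp)
  })
}

#' LD r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over samples that are
#' non-missing at both SNPs.
#'
#' @param G A `genotype_matrix`.
#' @param snp_i,snp_j SNP column indices or ids.
#' @return r-squared in \[0, 1\]; errors if either SNP has zero variance on
#'   the shared samples.
#' @export
ld_r2 <- function(G, snp_i, snp_j) {
  if (is.character(snp_i)) snp_i <- match(snp_i, G$map$snp_id)
  if (is.character(snp_j)) snp_j <- match(snp_j, G$map$snp_id)
  x <- G$dosages[, snp_i]; y <- G$dosages[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0)
    stop("r2 undefined: a SNP is monomorphic on the shared samples")
  cor(x, y)^2
}

#' Write an association scan as a GEMMA-style TSV
#'
#' @param assoc An `assoc_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assoc <- function(assoc, path) {
  df <- data.frame(chr = assoc$chrom, pos = assoc$pos, snp_id = assoc$snp_id,
                   n = assoc$n_used, maf = assoc$maf, beta = assoc$beta,
                   se = assoc$se, p_wald = assoc$p_wald)
  write_tsv(df, path)
}
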