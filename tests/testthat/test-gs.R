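test_that("LD pruning removes high-r2 pairs and nothing else", {
  sc <- small_cohort()
  G <- sc$G
  kept <- ld_prune(G, window = 50, step = 25, r2_max = 0.2)
  expect_true(all(diff(kept) > 0))
  ## post-condition: no retained within-window pair above the threshold
  X <- G$dosages[, kept, drop = FALSE]
  storage.mode(X) <- "double"
  for (st in seq(1, length(kept), by = 25)) {
    win <- st:min(length(kept), st + 49)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(X[, win])^2)
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.2)
  }

  ## identical columns collapse to a single survivor
  d <- G$dosages[, rep(1, 10)]
  colnames(d) <- NULL
  Gd <- genotype_matrix(d, rep(1L, 10), as.integer(1:10))
  expect_equal(length(ld_prune(Gd, window = 10, step = 5)), 1)

  ## independent SNPs are all retained
  sp <- sim_cohort_spec(n_samples = 200, n_snps = 60, n_pops = 1, fst = 0,
                        ld_block_len = 1, n_qtl = 5, seed = 13)
  Gi <- simulate_genotypes(sp)
  expect_equal(length(ld_prune(Gi, window = 30, step = 15, r2_max = 0.5)), 60)
  expect_error(ld_prune(G, window = 1), ">= 2")
})

test_that("marker ranking selects by ascending p with positional tie-break", {
  a <- data.frame(snp_id = sprintf("s%d", 1:6), chrom = rep(1L, 6),
                  pos = as.integer(1:6 * 100),
                  p_wald = c(0.5, 1e-6, 0.5, 1e-3, 0.5, 1e-6))
  class(a) <- c("assoc_result", "data.frame")
  pruned <- 1:6
  expect_equal(rank_and_select(a, pruned, 1), 2)  # first of the tied minima
  expect_equal(rank_and_select(a, pruned, 3), c(2, 4, 6))
  expect_equal(rank_and_select(a, pruned, 6), 1:6)
  expect_error(rank_and_select(a, pruned, 0), "positive")
  expect_error(rank_and_select(a, pruned, 7), "exceeds")
})

test_that("default marker grids follow the stepwise protocol", {
  gb <- default_grids("binary")
  gc <- default_grids("continuous")
  expect_true(all(c(1, 10, 50, 100, 500, 2000, 5000) %in% gb))
  expect_true(all(c(10, 52, 100, 500, 2000, 5000, 10000) %in% gc))
  ## the all-significant entry is cohort-specific
  expect_true(37 %in% default_grids("binary", n_significant = 37))
  expect_false(50 %in% default_grids("binary", n_significant = 37))
  ## capping and the ALL entry
  g <- default_grids("continuous", n_significant = 20, total = 800)
  expect_equal(max(g), 800)
  expect_true(all(g <= 800))
  expect_true(all(diff(g) > 0))
})

test_that("learner wrappers fit and predict on both trait types", {
  sc <- small_cohort()
  yb <- sc$pheno$binary_pheno
  yc <- sc$pheno$continuous_pheno
  ## informative markers: GWAS-top 40, as the GS protocol supplies them
  a <- lmm_assoc(yc, sc$G, K = sc$K)
  X <- sc$G$dosages[, rank_and_select(a, seq_len(nrow(a)), 40)]
  storage.mode(X) <- "double"
  for (ln in c("logistic", "svc", "rfc", "naive_bayes")) {
    f <- fit_gs(ln, X, yb, seed = 3)
    p <- predict_gs(f, X)
    expect_true(all(p >= 0 & p <= 1), info = ln)
    ## in-sample accuracy beats chance on a heritable trait
    expect_gt(mean(as.integer(p >= 0.5) == yb), 0.6)
  }
  for (ln in c("lasso", "ridge", "elasticnet", "svr", "rfr", "gblup")) {
    f <- fit_gs(ln, X, yc, seed = 3)
    p <- predict_gs(f, X)
    expect_true(all(is.finite(p)), info = ln)
    expect_gt(cor(p, yc), 0.3)
  }
  expect_error(fit_gs("mystery", X, yc), "arg")
})

test_that("the GS cross-validation protocol is deterministic and leak-proof", {
  sc <- small_cohort()
  a <- lmm_assoc(sc$pheno$continuous_pheno, sc$G, K = sc$K)
  pr <- ld_prune(sc$G, window = 50, step = 25)
  r1 <- gs_crossvalidate(sc$G, sc$pheno, a, "continuous",
                         learners = c("ridge", "rfr"), counts = c(5, 20),
                         pruned = pr, n_iter = 3, seed = 21)
  r2 <- gs_crossvalidate(sc$G, sc$pheno, a, "continuous",
                         learners = c("ridge", "rfr"), counts = c(5, 20),
                         pruned = pr, n_iter = 3, seed = 21)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$holdout_idx, r2$holdout_idx)

  ## report means equal brute-force recomputation from per-iteration values
  for (i in seq_len(nrow(r1$summary))) {
    sel <- r1$per_iteration$learner == r1$summary$learner[i] &
      r1$per_iteration$n_markers == r1$summary$n_markers[i]
    expect_equal(r1$summary$mean_metric[i],
                 mean(r1$per_iteration$metric[sel]), tolerance = 1e-12)
  }

  ## holdout leakage guard: permuting holdout phenotypes does not change
  ## the model-comparison results at all
  ph2 <- sc$pheno
  set.seed(1)
  ph2$continuous_pheno[r1$holdout_idx] <-
    sample(ph2$continuous_pheno[r1$holdout_idx])
  r3 <- gs_crossvalidate(sc$G, ph2, a, "continuous",
                         learners = c("ridge", "rfr"), counts = c(5, 20),
                         pruned = pr, n_iter = 3, seed = 21)
  expect_identical(r1$summary, r3$summary)

  ## folds are 4:1 within the non-holdout 90%
  n <- nrow(sc$G$dosages)
  expect_equal(length(r1$holdout_idx), round(0.1 * n))
})

test_that("final evaluation refits on the working set and scores the holdout", {
  sc <- small_cohort()
  a <- lmm_assoc(sc$pheno$continuous_pheno, sc$G, K = sc$K)
  pr <- ld_prune(sc$G, window = 50, step = 25)
  rep <- gs_crossvalidate(sc$G, sc$pheno, a, "continuous",
                          learners = "ridge", counts = c(10, 30),
                          pruned = pr, n_iter = 4, seed = 5)
  fe <- final_evaluate(sc$G, sc$pheno, rep)
  expect_equal(nrow(fe$predictions), length(rep$holdout_idx))
  expect_true(is.finite(fe$metric))
  ## a heritable trait with real signal scores above zero on the holdout
  expect_gt(fe$metric, 0)
})

test_that("kernel selection prefers the kernel that fits the architecture of the signal", {
  ## linear signal: the chosen kernel performs within 0.05 of the best
  sc <- small_cohort()
  a <- lmm_assoc(sc$pheno$continuous_pheno, sc$G, K = sc$K)
  pr <- ld_prune(sc$G, window = 50, step = 25)
  ks <- svm_kernel_select(sc$G, sc$pheno, a, "continuous",
                          kernels = c("linear", "radial"), counts = 20,
                          pruned = pr, n_iter = 3, seed = 2)
  expect_true(ks$kernel %in% c("linear", "radial"))
  expect_lt(max(ks$metrics) - ks$metrics[ks$kernel], 0.05 + 1e-9)

  ## xor-like epistatic toy trait: radial clearly beats linear
  set.seed(8)
  n <- 240
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.5)
  y <- as.numeric(xor(x1 > 0, x2 > 0)) + rnorm(n, 0, 0.1)
  X <- cbind(x1, x2)
  tr <- 1:180; va <- 181:240
  mets <- sapply(c("linear", "radial"), function(kn) {
    f <- e1071::svm(X[tr, ], y[tr], kernel = kn)
    cor(as.numeric(predict(f, X[va, ])), y[va])
  })
  expect_gt(mets["radial"] - mets["linear"], 0.1)

  ## single kernel passes through unchanged
  expect_equal(svm_kernel_select(sc$G, sc$pheno, a, "continuous",
                                 kernels = "linear")$kernel, "linear")
})
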