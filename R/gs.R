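#' LD-prune markers with a sliding SNP window
#'
#' PLINK-style pruning: windows of `window` SNPs advanced by `step` SNPs.
#' Within each window, while any retained pair has r-squared above `r2_max`,
#' the first offending pair in genomic order loses its lower-MAF member
#' (ties broken by removing the later position). The retained set preserves
#' genomic order, and after a full pass no within-window pair exceeds the
#' threshold.
#'
#' @param G A filtered `genotype_matrix`.
#' @param window Window size in SNPs (>= 2).
#' @param step Step size in SNPs.
#' @param r2_max LD threshold.
#' @return Integer vector of retained SNP column indices.
#' @export
ld_prune <- function(G, window = 100L, step = 50L, r2_max = 0.2) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (window < 2) stop("window must be >= 2")
  stopifnot(step >= 1, r2_max > 0)
  m <- ncol(G$dosages)
  maf <- snp_maf(G)
  X <- G$dosages
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  keep <- rep(TRUE, m)
  ## windows slide over the *currently retained* markers and the sweep
  ## repeats until a full pass removes nothing, so that after pruning no
  ## window of the retained set contains a pair above the threshold
  repeat {
    removed <- FALSE
    ret <- which(keep)                   # genomic order by construction
    if (length(ret) < 2) break
    starts <- seq(1L, max(1L, length(ret) - 1L), by = step)
    for (st in starts) {
      en <- min(length(ret), st + window - 1L)
      win <- ret[st:en]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(cor(X[, win, drop = FALSE])^2)
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      repeat {
        off <- which(r2 > r2_max, arr.ind = TRUE)
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        if (nrow(off) == 0) break
        off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
        i <- off[1, 1]; j <- off[1, 2]
        victim <- if (maf[win[i]] < maf[win[j]]) i
                  else if (maf[win[j]] < maf[win[i]]) j
                  else j                  # tie: drop the later position
        keep[win[victim]] <- FALSE
        removed <- TRUE
        r2[victim, ] <- 0; r2[, victim] <- 0
      }
    }
    if (!removed) break
  }
  which(keep)
}

#' Rank pruned markers by GWAS p-value and take the top k
#'
#' @param assoc An `assoc_result` covering (at least) the pruned markers.
#' @param pruned Integer indices (into `assoc`) of LD-pruned markers.
#' @param k Number of markers to select (1 <= k <= length(pruned)).
#' @return Integer vector of the selected marker indices, ties in p broken
#'   by (chrom, pos), output restored to genomic order.
#' @export
rank_and_select <- function(assoc, pruned, k) {
  if (k <= 0) stop("k must be positive")
  if (k > length(pruned)) stop("k exceeds the number of pruned markers")
  o <- pruned[order(assoc$p_wald[pruned], assoc$chrom[pruned],
                    assoc$pos[pruned])]
  sort(o[seq_len(k)])
}

#' Default marker-count grids for genomic selection
#'
#' The stepwise marker-count grids evaluated during model comparison. The
#' binary grid is `1, 10, 50, 100, 500, 2000, 5000` (+ ALL); the continuous
#' grid is `10, 52, 100, 500, 2000, 5000, 10000` (+ ALL). The 50/52 entries
#' are the all-significant-SNP counts of the cohort these defaults were
#' derived from; when `n_significant` is supplied they are replaced by the
#' actual significant-hit count of the cohort at hand. Entries exceeding
#' `total` are dropped, and `total` itself is appended when `include_all`.
#'
#' @param trait_type `"binary"` or `"continuous"`.
#' @param n_significant Optional count of significant SNPs in this cohort.
#' @param total Optional total number of available (pruned) markers.
#' @param include_all Append the all-markers entry when `total` is given.
#' @return Increasing integer vector of marker counts.
#' @export
default_grids <- function(trait_type = c("binary", "continuous"),
                          n_significant = NULL, total = NULL,
                          include_all = TRUE) {
  trait_type <- match.arg(trait_type)
  counts <- if (trait_type == "binary")
    c(1L, 10L, 50L, 100L, 500L, 2000L, 5000L)
  else
    c(10L, 52L, 100L, 500L, 2000L, 5000L, 10000L)
  cohort_entry <- if (trait_type == "binary") 50L else 52L
  if (!is.null(n_significant)) {
    counts[counts == cohort_entry] <- as.integer(n_significant)
    counts <- counts[counts >= 1L]
  }
  if (!is.null(total)) {
    counts <- counts[counts <= total]
    if (include_all) counts <- c(counts, as.integer(total))
  }
  sort(unique(counts))
}

# --- learner wrappers -------------------------------------------------------
# One fit/predict pair per learner name. Penalized and linear learners see
# column-standardized dosages (glmnet standardizes internally; svm scales);
# tree learners take raw dosages. Regularization defaults follow the widely
# used library defaults (glmnet lambda by internal CV on the training split;
# svm cost 1; 100 trees).

gs_learners <- function() {
  c("logistic", "svc", "rfc", "naive_bayes",
    "lasso", "ridge", "elasticnet", "svr", "rfr", "gblup")
}

# Drop zero-variance columns (constant markers break naive Bayes and add
# nothing elsewhere); returns the kept column indices.
.informative_cols <- function(X) {
  which(apply(X, 2, function(col) length(unique(col)) > 1))
}

.fit_glmnet <- function(X, y, alpha, family, seed) {
  foldid <- rep_len(1:5, nrow(X))
  foldid <- with_seed(seed, sample(foldid))
  if (ncol(X) == 1) X <- cbind(X, 0)     # glmnet needs >= 2 columns
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, family = family,
                          foldid = foldid, nfolds = 5)
  list(model = cv, pad = TRUE)
}

.predict_glmnet <- function(fit, X, type) {
  if (ncol(X) == 1) X <- cbind(X, 0)
  as.numeric(predict(fit$model, newx = X, s = "lambda.min", type = type))
}

#' Fit a single genomic-selection learner
#'
#' @param name Learner name, one of [gs_learners()]: `logistic` (L2
#'   logistic regression), `svc` / `svr` (support vector machine), `rfc` /
#'   `rfr` (random forest), `naive_bayes` (Gaussian), `lasso` / `ridge` /
#'   `elasticnet` (penalized linear regression), `gblup` (closed-form
#'   kinship ridge, an optional baseline).
#' @param X Training dosage matrix (samples x markers).
#' @param y Phenotype (0/1 for classifiers, numeric for regressors).
#' @param kernel SVM kernel (`linear`, `polynomial`, `radial`); ignored
#'   elsewhere.
#' @param seed Integer seed for learners with internal randomness.
#' @return A fitted learner object for [predict_gs()].
#' @export
fit_gs <- function(name, X, y, kernel = "radial", seed = 1L) {
  name <- match.arg(name, gs_learners())
  if (!is.null(kernel)) kernel <- match.arg(kernel, c("linear", "polynomial", "radial"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  keep <- .informative_cols(X)
  if (length(keep) == 0) keep <- 1L
  Xk <- X[, keep, drop = FALSE]
  binary <- name %in% c("logistic", "svc", "rfc", "naive_bayes")
  fit <- switch(name,
    logistic = .fit_glmnet(Xk, y, alpha = 0, family = "binomial", seed = seed),
    lasso = .fit_glmnet(Xk, y, alpha = 1, family = "gaussian", seed = seed),
    ridge = .fit_glmnet(Xk, y, alpha = 0, family = "gaussian", seed = seed),
    elasticnet = .fit_glmnet(Xk, y, alpha = 0.5, family = "gaussian", seed = seed),
    svc = e1071::svm(Xk, factor(y), kernel = kernel,
                     scale = apply(Xk, 2, sd) > 0),
    svr = e1071::svm(Xk, y, kernel = kernel, scale = apply(Xk, 2, sd) > 0),
    rfc = with_seed(seed, ranger::ranger(
      y = factor(y), x = as.data.frame(Xk), num.trees = 100,
      probability = TRUE, num.threads = 1, seed = seed)),
    rfr = with_seed(seed, ranger::ranger(
      y = y, x = as.data.frame(Xk), num.trees = 100, num.threads = 1,
      seed = seed)),
    naive_bayes = e1071::naiveBayes(Xk, factor(y)),
    gblup = .fit_gblup(Xk, y))
  structure(list(name = name, fit = fit, keep = keep, binary = binary,
                 kernel = kernel), class = "gs_fit")
}

# GBLUP as kinship ridge: y = mu + g, g ~ N(0, sigma2_g K_train); predictions
# for new samples use the train/test kinship cross-block. The variance ratio
# is profiled by REML on the training kinship.
.fit_gblup <- function(X, y) {
  mu_col <- colMeans(X)
  Z <- sweep(X, 2, mu_col)
  K <- tcrossprod(Z) / ncol(Z)
  eg <- eigen(K, symmetric = TRUE)
  s <- pmax(eg$values, 0); U <- eg$vectors
  yc <- y - mean(y)
  yt <- as.numeric(crossprod(U, yc))
  opt <- optimize(function(loglam) {
    l <- exp(loglam)
    v <- 1 / (l * s + 1)
    rss <- sum(v * yt^2)
    -0.5 * ((length(y) - 1) * log(rss) + sum(log(l * s + 1)))
  }, lower = log(1e-4), upper = log(1e4), maximum = TRUE)
  lam <- exp(opt$maximum)
  ## BLUP of marker effects: alpha = Z' (K + I/lam)^{-1} yc / m
  Vinv_y <- U %*% (crossprod(U, yc) / (s + 1 / lam))
  alpha <- crossprod(Z, Vinv_y) / ncol(Z)
  list(mu = mean(y), mu_col = mu_col, alpha = alpha)
}

#' Predict from a fitted genomic-selection learner
#'
#' @param object A `gs_fit` from [fit_gs()].
#' @param X New dosage matrix.
#' @param ... Unused.
#' @return For classifiers, the severe-class probability; for regressors,
#'   the predicted phenotype.
#' @export
predict_gs <- function(object, X, ...) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  Xk <- X[, object$keep, drop = FALSE]
  switch(object$name,
    logistic = .predict_glmnet(object$fit, Xk, type = "response"),
    lasso = , ridge = , elasticnet = .predict_glmnet(object$fit, Xk,
                                                     type = "response"),
    svc = {
      ## probability from the decision value through a logistic link; the
      ## sign is oriented from the decision-column label so the 0.5
      ## threshold coincides with the SVM class boundary (e1071's Platt
      ## probabilities can come out inverted on small training sets)
      pd <- predict(object$fit, Xk, decision.values = TRUE)
      d <- attr(pd, "decision.values")
      first <- strsplit(colnames(d)[1], "/")[[1]][1]
      stats::plogis(if (first == "1") d[, 1] else -d[, 1])
    },
    svr = as.numeric(predict(object$fit, Xk)),
    rfc = as.numeric(predict(object$fit, as.data.frame(Xk))$predictions[, "1"]),
    rfr = as.numeric(predict(object$fit, as.data.frame(Xk))$predictions),
    naive_bayes = {
      pr <- predict(object$fit, Xk, type = "raw")
      as.numeric(pr[, "1"])
    },
    gblup = object$fit$mu +
      as.numeric(sweep(Xk, 2, object$fit$mu_col) %*% object$fit$alpha))
}

# Metric used throughout GS: accuracy at threshold 0.5 for binary traits,
# Pearson r for continuous ones. An undefined correlation (zero-variance
# predictions, e.g. a single constant marker) counts as 0: no signal found.
gs_metric <- function(pred, y, trait_type) {
  if (trait_type == "binary") {
    mean(as.integer(pred >= 0.5) == y)
  } else {
    if (sd(pred) == 0 || sd(y) == 0) return(0)
    cor(pred, y)
  }
}

#' Multi-model, multi-marker-count genomic-selection cross-validation
#'
#' Implements the evaluation protocol: 10% of samples are held out once per
#' master seed and never touched during model comparison; in each of
#' `n_iter` iterations the remaining 90% are re-split 4:1 into train and
#' validation sets (per-iteration seeds derived from the master seed), every
#' (learner, marker count) pair is fit on the train split, and its metric
#' (accuracy for binary traits, Pearson r for continuous) is computed on the
#' validation fifth. The report averages the metric over iterations; the
#' best pair is the argmax of the mean metric.
#'
#' @param G A `genotype_matrix` (markers are selected from its columns).
#' @param pheno A `phenotype_table` aligned with `G`'s samples.
#' @param assoc An `assoc_result` for marker ranking.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param learners Character vector of learner names (defaults: the four
#'   classifiers for binary traits, the five regressors for continuous).
#' @param counts Marker-count grid (default [default_grids()] capped at the
#'   pruned total).
#' @param pruned Optional pre-computed [ld_prune()] indices.
#' @param n_iter Number of 4:1 re-splits (default 100).
#' @param holdout Held-out fraction (default 0.10).
#' @param kernel SVM kernel passed to [fit_gs()].
#' @param seed Master seed.
#' @return A list of class `gs_report`: `summary` (data frame of learner,
#'   n_markers, mean/sd metric), `per_iteration` (long data frame),
#'   `best` (learner, n_markers, mean metric), `holdout_idx`, `trait_type`,
#'   `marker_sets` (selected indices per count), `n_iter` and `seed`.
#' @export
gs_crossvalidate <- function(G, pheno, assoc,
                             trait_type = c("binary", "continuous"),
                             learners = NULL, counts = NULL, pruned = NULL,
                             n_iter = 100L, holdout = 0.10,
                             kernel = "radial", seed = 1L) {
  trait_type <- match.arg(trait_type)
  n <- nrow(G$dosages)
  if (n < 20) stop("need at least 20 samples")
  y <- if (trait_type == "binary") pheno$binary_pheno else pheno$continuous_pheno
  stopifnot(length(y) == n)
  if (is.null(learners))
    learners <- if (trait_type == "binary")
      c("logistic", "svc", "rfc", "naive_bayes")
    else c("lasso", "ridge", "elasticnet", "svr", "rfr")
  if (is.null(pruned)) pruned <- ld_prune(G)
  n_sig <- sum(assoc$p_wald[pruned] < 1e-5, na.rm = TRUE)
  if (is.null(counts))
    counts <- default_grids(trait_type,
                            n_significant = if (n_sig > 0) n_sig else NULL,
                            total = length(pruned))
  counts <- sort(unique(pmin(as.integer(counts), length(pruned))))
  marker_sets <- lapply(counts, function(k) rank_and_select(assoc, pruned, k))
  names(marker_sets) <- as.character(counts)

  n_hold <- max(1L, round(holdout * n))
  holdout_idx <- with_seed(derive_seed(seed, 10L), sample.int(n, n_hold))
  work <- setdiff(seq_len(n), holdout_idx)

  X <- G$dosages
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }

  rows <- list()
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, 100L + it)
    val <- with_seed(it_seed, sample(work, round(length(work) / 5)))
    tr <- setdiff(work, val)
    if (length(val) == 0 || length(tr) == 0) stop("empty train or validation split")
    for (ci in seq_along(counts)) {
      mk <- marker_sets[[ci]]
      for (ln in learners) {
        fit <- fit_gs(ln, X[tr, mk, drop = FALSE], y[tr], kernel = kernel,
                      seed = derive_seed(it_seed, ci))
        pred <- predict_gs(fit, X[val, mk, drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, learner = ln, n_markers = counts[ci],
          metric = gs_metric(pred, y[val], trait_type),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_iter <- do.call(rbind, rows)
  agg <- aggregate(metric ~ learner + n_markers, per_iter,
                   function(v) c(mean = mean(v), sd = sd(v)))
  summary <- data.frame(learner = agg$learner, n_markers = agg$n_markers,
                        mean_metric = agg$metric[, "mean"],
                        sd_metric = agg$metric[, "sd"],
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$learner, summary$n_markers), ]
  rownames(summary) <- NULL
  bi <- which.max(summary$mean_metric)
  structure(list(summary = summary, per_iteration = per_iter,
                 best = summary[bi, , drop = FALSE],
                 holdout_idx = sort(holdout_idx), trait_type = trait_type,
                 marker_sets = marker_sets, learners = learners,
                 kernel = kernel, n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "gs_report")
}

#' @export
print.gs_report <- function(x, ...) {
  cat(sprintf("gs_report (%s trait, %d iterations): best %s with %d markers, mean metric %.3f\n",
              x$trait_type, x$n_iter, x$best$learner, x$best$n_markers,
              x$best$mean_metric))
  invisible(x)
}

#' Select the best SVM kernel by cross-validated metric
#'
#' Runs [gs_crossvalidate()] restricted to the SVM learner once per kernel
#' and returns the kernel with the best mean metric (ties resolved in favour
#' of the linear kernel).
#'
#' @inheritParams gs_crossvalidate
#' @param kernels Candidate kernels.
#' @return A list with `kernel` (chosen name) and `metrics` (named vector of
#'   mean CV metrics per kernel).
#' @export
svm_kernel_select <- function(G, pheno, assoc,
                              trait_type = c("binary", "continuous"),
                              kernels = c("linear", "polynomial", "radial"),
                              counts = NULL, pruned = NULL, n_iter = 10L,
                              seed = 1L) {
  trait_type <- match.arg(trait_type)
  if (length(kernels) == 1) return(list(kernel = kernels, metrics = NULL))
  stopifnot(length(kernels) >= 2)
  learner <- if (trait_type == "binary") "svc" else "svr"
  mets <- vapply(kernels, function(kn) {
    rep <- gs_crossvalidate(G, pheno, assoc, trait_type, learners = learner,
                            counts = counts, pruned = pruned, n_iter = n_iter,
                            kernel = kn, seed = seed)
    max(rep$summary$mean_metric)
  }, numeric(1))
  ord <- order(-mets, kernels != "linear")  # ties -> linear first
  list(kernel = kernels[ord[1]], metrics = mets)
}

#' Final evaluation of the chosen model on the untouched holdout
#'
#' Refits the best (learner, marker count) pair from a [gs_crossvalidate()]
#' report on the full 90% working set and evaluates on the 10% holdout that
#' model comparison never saw. Binary traits report accuracy and the
#' point-biserial correlation of the predicted probability with the labels;
#' continuous traits report Pearson r.
#'
#' @param G,pheno As in [gs_crossvalidate()].
#' @param report A `gs_report`.
#' @return A list with `metric`, `correlation`, `predictions` (data frame of
#'   accession_id, y_true, y_pred), `learner` and `n_markers`.
#' @export
final_evaluate <- function(G, pheno, report) {
  stopifnot(inherits(report, "gs_report"))
  n <- nrow(G$dosages)
  y <- if (report$trait_type == "binary") pheno$binary_pheno
       else pheno$continuous_pheno
  test <- report$holdout_idx
  train <- setdiff(seq_len(n), test)
  if (length(test) == 0) stop("empty test set")
  mk <- report$marker_sets[[as.character(report$best$n_markers)]]
  X <- G$dosages
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  fit <- fit_gs(report$best$learner, X[train, mk, drop = FALSE], y[train],
                kernel = report$kernel, seed = derive_seed(report$seed, 999L))
  pred <- predict_gs(fit, X[test, mk, drop = FALSE])
  metric <- gs_metric(pred, y[test], report$trait_type)
  correlation <- if (sd(pred) > 0 && sd(y[test]) > 0) cor(pred, y[test]) else NA_real_
  list(metric = metric, correlation = correlation,
       predictions = data.frame(accession_id = G$sample_ids[test],
                                y_true = y[test], y_pred = pred,
                                stringsAsFactors = FALSE),
       learner = report$best$learner, n_markers = report$best$n_markers)
}
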