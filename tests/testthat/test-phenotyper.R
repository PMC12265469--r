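nf <- pestgs:::net_forward
nb <- pestgs:::net_backward

## a micro configuration small enough for numerical gradient checks
micro_cfg <- function() {
  pds_net_config("tiny", input_size = 32, backbone_channels = list(4L),
                 residual_block_filters = c(4L, 3L, 3L, 3L),
                 block_pools = c(TRUE, FALSE, FALSE, FALSE), fc_width = 5L)
}

test_that("image preprocessing resizes and normalizes", {
  set.seed(2)
  raw <- array(runif(500 * 400 * 3, 0, 255), c(500, 400, 3))
  out <- preprocess_image(raw, size = 224)
  expect_equal(dim(out), c(224, 224, 3))
  expect_lte(max(out), 1)
  expect_gte(min(out), 0)

  ## conforming input passes through unchanged
  z <- array(0, c(224, 224, 3))
  expect_identical(preprocess_image(z, 224), z)

  ## constant 128/255 image stays constant at ~0.502
  cst <- array(128, c(64, 64, 3))
  out2 <- preprocess_image(cst, 32)
  expect_equal(unique(round(as.numeric(out2), 6)), round(128 / 255, 6))

  expect_error(preprocess_image(matrix(0, 5, 5)), "RGB")
  expect_error(preprocess_image(array(0, c(5, 5, 4))), "RGB")
})

test_that("augmentation is seeded, bounded and respects symmetry", {
  leaf <- small_leaves()[[2]]
  a1 <- augment(leaf$pixels, seed = 3)
  a2 <- augment(leaf$pixels, seed = 3)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(leaf$pixels))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_false(identical(a1, augment(leaf$pixels, seed = 4)))

  ## flip-only augmentation of a mirror-symmetric image is the identity
  sym <- leaf$pixels
  sym <- (sym + sym[, dim(sym)[2]:1, , drop = FALSE]) / 2
  for (s in 1:6) {
    out <- augment(sym, seed = s, rotate = 0, shift = 0, zoom = 0, flip = TRUE)
    expect_equal(out, sym, tolerance = 1e-12)
  }
})

test_that("the leaf detector finds the generated leaf and fails cleanly", {
  leaf <- generate_leaf_image(0.2, size = 64, seed = 21)
  bb <- detect_leaf_bbox(leaf$pixels)
  expect_false(is.null(bb))
  inside <- matrix(FALSE, 64, 64)
  inside[bb$row_lo:bb$row_hi, bb$col_lo:bb$col_hi] <- TRUE
  ## box covers essentially the whole leaf mask
  expect_gte(sum(leaf$leaf_mask & inside) / sum(leaf$leaf_mask), 0.99)

  ## all-background image: not found
  bg <- array(rep(c(0.5, 0.4, 0.3), each = 32 * 32), c(32, 32, 3))
  expect_null(detect_leaf_bbox(bg))

  ## leaf filling the frame: box is the full frame
  full <- array(rep(c(0.1, 0.6, 0.1), each = 32 * 32), c(32, 32, 3))
  bb2 <- detect_leaf_bbox(full)
  expect_equal(c(bb2$row_lo, bb2$col_lo), c(1, 1))
  expect_equal(c(bb2$row_hi, bb2$col_hi), c(32, 32))
  expect_equal(dim(crop_bbox(full, bb2)), c(32, 32, 3))
})

test_that("network builds are deterministic with bounded outputs", {
  cfg <- micro_cfg()
  n1 <- build_pds_network(cfg, seed = 11)
  n2 <- build_pds_network(cfg, seed = 11)
  expect_equal(net_n_params(n1), net_n_params(n2))
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  expect_identical(net_predict(n1, x), net_predict(n2, x))

  ## sigmoid x 5 bound holds for arbitrary weights
  for (s in 1:3) {
    nr <- build_pds_network(cfg, seed = 100 + s)
    for (li in seq_along(nr$layers))
      for (nm in pestgs:::.param_names(nr$layers[[li]]))
        nr$layers[[li]][[nm]] <- nr$layers[[li]][[nm]] * 10
    p <- net_predict(nr, x)
    expect_true(all(p >= 0 & p <= 5))
  }

  ## binary network: output strictly inside (0, 1); all six named backbones
  ## plus tiny are accepted
  for (bn in c("tiny", "alexnet", "vgg16", "resnet50", "resnet101",
               "inceptionv3", "densenet121"))
    expect_s3_class(binary_net_config(bn), "binary_net_config")
  bnet <- build_binary_network(binary_net_config("tiny"), seed = 2)
  set.seed(2)
  xb <- array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  pb <- net_predict(bnet, xb)
  expect_true(all(pb > 0 & pb < 1))
  expect_error(binary_net_config("yolo"))
})

test_that("backpropagation matches numerical gradients", {
  net <- build_pds_network(micro_cfg(), seed = 42)
  ## nudge biases off zero so no pre-activation sits exactly on a ReLU kink
  set.seed(5)
  for (li in seq_along(net$layers))
    for (nm in pestgs:::.param_names(net$layers[[li]]))
      if (grepl("^b", nm))
        net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] +
          rnorm(length(net$layers[[li]][[nm]]), 0, 0.05)
  set.seed(9)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  y <- c(1.5, 4.0)
  loss_of <- function(nn) mean((as.numeric(nf(nn, x, FALSE, FALSE)$out) - y)^2)
  fw <- nf(net, x, FALSE, TRUE)
  out <- as.numeric(fw$out)
  p <- out / 5
  dz <- (2 * (out - y) / 2) * 5 * p * (1 - p)
  gr <- nb(net, fw$caches, dz)
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    if (is.null(gr[[li]])) next
    for (nm in names(gr[[li]])) {
      g <- gr[[li]][[nm]]
      idx <- order(-abs(g))[seq_len(min(3, length(g)))]
      for (ii in idx) {
        n2 <- net; n2$layers[[li]][[nm]][ii] <- n2$layers[[li]][[nm]][ii] + eps
        n3 <- net; n3$layers[[li]][[nm]][ii] <- n3$layers[[li]][[nm]][ii] - eps
        num <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
        expect_lt(abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])), 1e-4)
      }
    }
  }
})

test_that("im2col and col2im are adjoint", {
  ## <im2col(x), M> == <x, col2im(M)> for random x, M
  set.seed(4)
  H <- 6L; W <- 5L; B <- 2L; C <- 3L
  x <- array(rnorm(H * W * B * C), c(H, W, B, C))
  M <- matrix(rnorm(H * W * B * 9 * C), H * W * B, 9 * C)
  lhs <- sum(pestgs:::im2col3(x, H, W, B, C) * M)
  rhs <- sum(x * pestgs:::col2im3(M, H, W, B, C))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("early stopping follows the strict-improvement patience rule", {
  es <- pestgs:::early_stop_scan
  ## strictly decreasing: runs to the end
  expect_equal(es(seq(1, 0.1, length.out = 20), patience = 5, max_epochs = 20), 20)
  ## constant after epoch 1 with patience 5: stops at epoch 6
  expect_equal(es(c(1, rep(1, 19)), patience = 5, max_epochs = 20), 6)
  expect_equal(es(c(1, 0.5, rep(0.5, 18)), patience = 5, max_epochs = 20), 7)
  ## improvement below the 1e-6 delta does not reset patience
  expect_equal(es(1 - (1:10) * 1e-8, patience = 3, max_epochs = 10), 4)
})

test_that("a short training run reduces loss deterministically", {
  leaves <- small_leaves()
  y <- vapply(leaves, function(l) l$severity_class, integer(1))
  x <- pestgs:::images_to_tensor(leaves)
  cfg <- pds_net_config("tiny", input_size = 64, backbone_channels = list(6L),
                        residual_block_filters = c(6L, 4L, 4L, 4L),
                        block_pools = c(TRUE, TRUE, FALSE, FALSE),
                        fc_width = 8L)
  net <- build_pds_network(cfg, seed = 3)
  tr <- list(x = x[, , 1:16, , drop = FALSE], y = y[1:16])
  va <- list(x = x[, , 17:24, , drop = FALSE], y = y[17:24])
  r1 <- train_with_early_stopping(net, tr, va, max_epochs = 4, lr = 1e-3,
                                  batch_size = 8, seed = 6)
  expect_lt(r1$report$train_losses[4], r1$report$train_losses[1])
  expect_equal(r1$report$best_epoch, which.min(r1$report$val_losses))
  expect_lte(r1$report$stopped_epoch, 4)
  ## bit-reproducible under the same seed
  r2 <- train_with_early_stopping(net, tr, va, max_epochs = 4, lr = 1e-3,
                                  batch_size = 8, seed = 6)
  expect_identical(r1$report$val_losses, r2$report$val_losses)
  expect_identical(net_predict(r1$net, va$x), net_predict(r2$net, va$x))

  ## binary head trains a step on a few leaves without error
  bnet <- build_binary_network(binary_net_config("tiny", fc_width = 8L), seed = 1)
  yb <- vapply(leaves, function(l) l$binary_label, integer(1))
  rb <- train_with_early_stopping(bnet, list(x = tr$x, y = yb[1:16]),
                                  list(x = va$x, y = yb[17:24]),
                                  max_epochs = 1, lr = 1e-3, batch_size = 8,
                                  seed = 2)
  expect_length(rb$report$val_losses, 1)
  expect_error(train_with_early_stopping(net, list(x = tr$x, y = numeric(0)),
                                         va, max_epochs = 1), "length")
})

test_that("hyperparameter cross-validation picks the planted optimum", {
  ## cheap surrogate family: logistic regression whose "lr" controls ridge
  ## shrinkage so one grid point is clearly optimal, "batch" is inert
  set.seed(12)
  n <- 100
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(x[, 1] + x[, 2] + rnorm(n, 0, 0.3) > 0)
  data <- list(x = lapply(seq_len(n), function(i) x[i, ]), y = y)
  train_fn <- function(tr, va, lr, batch, seed) {
    Xtr <- do.call(rbind, tr$x); Xva <- do.call(rbind, va$x)
    lam <- c("1e-04" = 1000, "0.001" = 0.01, "0.01" = 1000)[[as.character(lr)]]
    f <- glmnet::glmnet(Xtr, tr$y, family = "binomial", alpha = 0,
                        lambda = lam)
    mean(as.integer(predict(f, Xva, type = "response") >= 0.5) == va$y)
  }
  cv <- crossvalidate(train_fn, data, k = 5, seed = 31)
  expect_equal(cv$best$lr, 1e-3)
  ## fold structure: disjoint cover
  expect_equal(sort(unique(cv$fold_metrics$fold)), 1:5)
  cv2 <- crossvalidate(train_fn, data, k = 5, seed = 31)
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
  expect_error(crossvalidate(train_fn, data, k = 5, lr_grid = numeric(0)),
               "non-empty")
})

test_that("classifier and regressor metrics match brute-force computation", {
  ## the printed worked example: 169 + 176 correct of 362
  labels <- c(rep(1, 178), rep(0, 184))
  probs <- c(rep(0.9, 169), rep(0.1, 9),     # 169 true positives, 9 misses
             rep(0.1, 176), rep(0.9, 8))     # 176 true negatives, 8 false alarms
  ev <- evaluate_classifier(probs, labels)
  expect_equal(ev$confusion["1", "1"], 169)
  expect_equal(ev$confusion["0", "0"], 176)
  expect_equal(round(100 * ev$accuracy, 1), 95.3)

  expect_equal(evaluate_classifier(c(0.9, 0.1), c(1, 0))$accuracy, 1)
  expect_equal(evaluate_classifier(c(0.9, 0.1), c(1, 0))$f1, 1)
  expect_equal(evaluate_classifier(c(0.1, 0.9), c(1, 0))$accuracy, 0)
  expect_error(evaluate_classifier(numeric(0), integer(0)), "empty")

  ## random small prediction sets against hand-rolled formulas
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    pr <- runif(n); lb <- rbinom(n, 1, 0.5)
    ev <- evaluate_classifier(pr, lb)
    pd <- as.integer(pr >= 0.5)
    expect_equal(ev$accuracy, sum(pd == lb) / n)
    preds <- runif(n, 0, 5); labs <- runif(n, 0, 5)
    er <- evaluate_regressor(preds, labs)
    expect_equal(er$mse, sum((preds - labs)^2) / n)
    expect_equal(er$mae, sum(abs(preds - labs)) / n)
    expect_equal(er$r2, cor(preds, labs)^2)
  }

  ## regression identities
  er <- evaluate_regressor(c(1, 2, 3), c(1, 2, 3))
  expect_equal(er$mse, 0); expect_equal(er$pearson_r, 1)
  er2 <- evaluate_regressor(c(3, 2, 1), c(1, 2, 3))
  expect_equal(er2$pearson_r, -1)
  expect_equal(er2$mse, 8 / 3)
  ## r = 0.94 pairs with R2 = 0.8836
  expect_equal(round(0.94^2, 2), 0.88)
  expect_warning(evaluate_regressor(c(1, 1, 1), c(1, 2, 3)), "undefined")
})

test_that("scores aggregate into accession phenotypes end to end", {
  leaves <- small_leaves()
  ids <- rep(sprintf("acc%02d", 1:4), 6)
  for (i in seq_along(leaves)) leaves[[i]]$accession_id <- ids[i]
  net <- build_pds_network(micro_cfg(), seed = 1)
  ## untrained network still produces a structurally valid pipeline
  st <- score_images(build_binary_network(binary_net_config("tiny",
                                                            fc_width = 8L),
                                          seed = 1),
                     leaves)
  expect_true(all(st$prob_severe > 0 & st$prob_severe < 1))
  ph <- aggregate_scores(st)
  expect_equal(nrow(ph), 4)
  expect_true(all(ph$binary_pheno %in% 0:1))
})
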