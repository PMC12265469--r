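# Early-stopping bookkeeping shared by the trainer: given the sequence of
# validation losses seen so far, improvement means a strict decrease of the
# best value by at least min_delta. Returns the epoch at which training
# stops (the epoch after `patience` non-improving epochs, or max_epochs).
early_stop_scan <- function(val_losses, patience, max_epochs,
                            min_delta = 1e-6) {
  best <- Inf; since <- 0L
  for (ep in seq_along(val_losses)) {
    if (val_losses[ep] < best - min_delta) {
      best <- val_losses[ep]; since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(ep)
  }
  min(length(val_losses), max_epochs)
}

#' Train a network with Adam and early stopping
#'
#' Minibatch training with the Adam optimizer. Per epoch the training set is
#' reshuffled (seeded), the loss (`mse` for regression on the 0-5 score,
#' `bce` for binary classification) is minimized, and the validation loss is
#' recorded; training halts once the validation loss has failed to improve
#' (strict decrease by at least 1e-6) for `patience` consecutive epochs, or
#' at `max_epochs`. The returned network carries the weights of the best
#' validation epoch. For regression the validation MAE is tracked alongside
#' as the performance metric.
#'
#' @param net A network from [build_pds_network()] / [build_binary_network()].
#' @param train_set,val_set Lists with `x` (tensor `(H, W, N, 3)` or list of
#'   images) and `y` (numeric labels: 0-5 scores or 0/1).
#' @param loss `"mse"` or `"bce"` (defaults to the network's task).
#' @param patience Early-stopping patience in epochs (default 35 for
#'   regression; binary configs carry their own default).
#' @param max_epochs Maximum number of epochs (default 300).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Integer seed driving shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return A list with `net` (best-epoch weights) and `report` (class
#'   `train_report`: `best_epoch`, `stopped_epoch`, `train_losses`,
#'   `val_losses`, `val_maes` (regression), `best_val_metric`,
#'   `hyperparams`).
#' @export
train_with_early_stopping <- function(net, train_set, val_set, loss = NULL,
                                      patience = NULL, max_epochs = 300L,
                                      lr = 1e-3, batch_size = 32L, seed = 1L,
                                      verbose = FALSE) {
  if (is.list(train_set$x) && !is.array(train_set$x))
    train_set$x <- images_to_tensor(train_set$x)
  if (is.list(val_set$x) && !is.array(val_set$x))
    val_set$x <- images_to_tensor(val_set$x)
  n <- dim(train_set$x)[3]
  if (n == 0 || dim(val_set$x)[3] == 0) stop("empty training or validation set")
  stopifnot(length(train_set$y) == n)
  if (is.null(loss)) loss <- if (net$task == "regression") "mse" else "bce"
  loss <- match.arg(loss, c("mse", "bce"))
  if (is.null(patience))
    patience <- if (!is.null(net$cfg$patience)) net$cfg$patience else 35L

  scale <- if (loss == "mse") net$cfg$output_scale else 1
  state <- adam_init(net)
  tstep <- 0L
  train_losses <- val_losses <- val_maes <- numeric(0)
  best <- Inf; best_epoch <- 0L; best_net <- net; since <- 0L
  stopped <- max_epochs

  val_loss_of <- function(nn) {
    pred <- net_predict(nn, val_set$x)
    if (loss == "mse") {
      c(mean((pred - val_set$y)^2), mean(abs(pred - val_set$y)))
    } else {
      p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
      c(-mean(val_set$y * log(p) + (1 - val_set$y) * log(1 - p)),
        mean(abs(pred - val_set$y)))
    }
  }

  with_seed(derive_seed(seed, 7L), {
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (st in seq(1, n, by = batch_size)) {
        idx <- ord[st:min(n, st + batch_size - 1L)]
        xb <- train_set$x[, , idx, , drop = FALSE]
        yb <- train_set$y[idx]
        fw <- net_forward(net, xb, train = TRUE)
        out <- as.numeric(fw$out)
        if (any(!is.finite(out))) stop("non-finite network output; reduce lr")
        B <- length(yb)
        if (loss == "mse") {
          ep_loss <- ep_loss + mean((out - yb)^2)
          p <- out / scale
          dz <- (2 * (out - yb) / B) * scale * p * (1 - p)
        } else {
          p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
          ep_loss <- ep_loss - mean(yb * log(p) + (1 - yb) * log(1 - p))
          dz <- (out - yb) / B
        }
        grads <- net_backward(net, fw$caches, dz)
        tstep <- tstep + 1L
        upd <- adam_step(net, grads, state, lr, tstep)
        net <- upd$net; state <- upd$state
        nb <- nb + 1L
      }
      train_losses[ep] <- ep_loss / nb
      vl <- val_loss_of(net)
      val_losses[ep] <- vl[1]; val_maes[ep] <- vl[2]
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val MAE %.4f",
                        ep, train_losses[ep], val_losses[ep], val_maes[ep]))
      if (val_losses[ep] < best - 1e-6) {
        best <- val_losses[ep]; best_epoch <- ep; best_net <- net; since <- 0L
      } else {
        since <- since + 1L
      }
      if (since >= patience) { stopped <- ep; break }
      stopped <- ep
    }
  })

  report <- structure(list(
    best_epoch = best_epoch, stopped_epoch = stopped,
    train_losses = train_losses, val_losses = val_losses,
    val_maes = val_maes, best_val_metric = best,
    hyperparams = list(loss = loss, lr = lr, batch_size = batch_size,
                       patience = patience, max_epochs = max_epochs,
                       seed = seed)), class = "train_report")
  list(net = best_net, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("train_report: stopped at epoch %d (best %d), best val loss %.4f\n",
              x$stopped_epoch, x$best_epoch, x$best_val_metric))
  invisible(x)
}

#' k-fold cross-validation over a learning-rate x batch-size grid
#'
#' Splits the data into `k` seed-reproducible folds, trains the supplied
#' model family on each fold complement for every (lr, batch size)
#' combination, and evaluates the fold metric (higher is better). The best
#' combination is the argmax of the mean fold metric; ties are broken by
#' lower learning rate, then smaller batch size.
#'
#' @param train_fn Function `(train_set, val_set, lr, batch_size, seed)`
#'   returning a scalar metric where larger is better (e.g. minus the
#'   validation loss, or accuracy).
#' @param data List with `x` (tensor `(H, W, N, 3)`) and `y`.
#' @param k Number of folds (default 5; requires `N >= k`).
#' @param lr_grid,batch_grid Hyperparameter grids (defaults
#'   `1e-4, 1e-3, 1e-2` and `32, 64, 128`).
#' @param seed Integer seed fixing fold membership and training streams.
#' @return A list with `best` (list of `lr`, `batch_size`), `fold_metrics`
#'   (data frame of lr, batch_size, fold, metric) and `mean_metrics`.
#' @export
crossvalidate <- function(train_fn, data, k = 5L,
                          lr_grid = c(1e-4, 1e-3, 1e-2),
                          batch_grid = c(32L, 64L, 128L), seed = 1L) {
  if (length(lr_grid) == 0 || length(batch_grid) == 0)
    stop("hyperparameter grids must be non-empty")
  n <- if (is.array(data$x)) dim(data$x)[3] else length(data$x)
  if (n < k) stop("need at least k samples")
  folds <- with_seed(derive_seed(seed, 5L), sample(rep_len(seq_len(k), n)))
  rows <- list()
  for (lr in sort(lr_grid)) for (bs in sort(batch_grid)) {
    for (fd in seq_len(k)) {
      tr_i <- which(folds != fd); va_i <- which(folds == fd)
      slice <- function(idx) list(
        x = if (is.array(data$x)) data$x[, , idx, , drop = FALSE]
            else data$x[idx],
        y = data$y[idx])
      met <- train_fn(slice(tr_i), slice(va_i), lr, bs,
                      derive_seed(seed, 50L + fd))
      rows[[length(rows) + 1L]] <- data.frame(lr = lr, batch_size = bs,
                                              fold = fd, metric = met)
    }
  }
  fm <- do.call(rbind, rows)
  mm <- aggregate(metric ~ lr + batch_size, fm, mean)
  ## argmax; ties -> lower lr, then smaller batch
  mm <- mm[order(-mm$metric, mm$lr, mm$batch_size), ]
  list(best = list(lr = mm$lr[1], batch_size = mm$batch_size[1]),
       fold_metrics = fm, mean_metrics = mm)
}

#' Score leaf images with a trained network
#'
#' @param net A trained network.
#' @param images List of images (arrays or `leaf_image` objects) or a
#'   tensor.
#' @param image_ids,accession_ids Optional identifiers for the output table.
#' @return A `score_table` data frame with `image_id`, `accession_id` and
#'   `pds_score` (regression nets) or `prob_severe` (binary nets).
#' @export
score_images <- function(net, images, image_ids = NULL, accession_ids = NULL) {
  pred <- net_predict(net, images)
  n <- length(pred)
  if (is.null(image_ids)) image_ids <- sprintf("img_%04d", seq_len(n))
  if (is.null(accession_ids)) {
    accession_ids <- if (is.list(images) && inherits(images[[1]], "leaf_image"))
      vapply(images, function(l) l$accession_id, character(1))
    else rep(NA_character_, n)
  }
  out <- data.frame(image_id = image_ids, accession_id = accession_ids,
                    stringsAsFactors = FALSE)
  if (net$task == "regression") out$pds_score <- pred else out$prob_severe <- pred
  class(out) <- c("score_table", "data.frame")
  out
}
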