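#' Training configurations
#'
#' `pretrain_config()` controls InfoNCE contrastive pre-training: minibatches
#' of `batch_n` recordings, each randomly truncated into two `crop_s`-second
#' crops (audio domain) that form a positive pair, Adam at `lr`, temperature
#' `tau`, a checkpoint with running loss every `checkpoint_every` epochs, and
#' a held-out fraction of the unlabeled recordings on which checkpoint
#' selection is done by validation loss. Defaults follow the training
#' protocol of the full-scale experiment (200 epochs, batch 64, lr 1e-4);
#' desk-scale runs shrink `epochs`.
#'
#' `finetune_config()` controls supervised training: `init` chooses the
#' initialization arm (`"scratch"`, `"external_checkpoint"` or
#' `"contrastive_checkpoint"`); unless `epochs` is given explicitly it is 40
#' from scratch and 20 from any checkpoint, with batch 16 and lr 1e-4 in all
#' arms. No augmentation is applied: training uses the middle-20-s segment of
#' each recording.
#'
#' @param batch_n Recordings per pre-training minibatch (>= 2).
#' @param epochs Number of epochs.
#' @param checkpoint_every Checkpoint cadence in epochs.
#' @param lr Adam learning rate.
#' @param tau InfoNCE temperature (> 0, default 0.5).
#' @param crop_s Crop length in seconds (default 5).
#' @param val_fraction Fraction of unlabeled recordings held out for
#'   checkpoint selection.
#' @param seed Integer seed.
#' @return An object of class `pretrain_config` / `finetune_config`.
#' @export
pretrain_config <- function(batch_n = 64, epochs = 200, checkpoint_every = 10,
                            lr = 1e-4, tau = 0.5, crop_s = 5,
                            val_fraction = 0.1, seed = 1L) {
  stopifnot(batch_n >= 2, tau > 0, epochs >= 1, checkpoint_every >= 1,
            lr > 0, crop_s > 0, val_fraction >= 0, val_fraction < 1)
  structure(list(batch_n = as.integer(batch_n), epochs = as.integer(epochs),
                 checkpoint_every = as.integer(checkpoint_every), lr = lr,
                 tau = tau, crop_s = crop_s, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' @rdname pretrain_config
#' @param init Initialization arm: `"scratch"`, `"external_checkpoint"` or
#'   `"contrastive_checkpoint"`.
#' @param batch Supervised minibatch size (default 16).
#' @export
finetune_config <- function(init = c("scratch", "external_checkpoint",
                                     "contrastive_checkpoint"),
                            epochs = NULL, batch = 16, lr = 1e-4, seed = 1L) {
  init <- match.arg(init)
  if (is.null(epochs)) epochs <- if (init == "scratch") 40L else 20L
  stopifnot(epochs >= 1, batch >= 1, lr > 0)
  structure(list(init = init, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, seed = as.integer(seed)),
            class = "finetune_config")
}

# epochs at which checkpoints are written
checkpoint_epochs <- function(epochs, every) {
  seq_len(epochs)[seq_len(epochs) %% every == 0]
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# merge updated batch-norm running statistics back into the parameter list
merge_running <- function(params, running) {
  for (nm in names(running)) params[[nm]] <- running[[nm]]
  params
}

# accept records data frame (column `path`), list of waveforms, or list of paths
load_middle_segments <- function(x, length_s = 20) {
  ws <- if (is.data.frame(x)) lapply(x$path, read_wav)
        else if (inherits(x, "waveform")) list(x)
        else lapply(x, function(el) if (inherits(el, "waveform")) el else read_wav(el))
  lapply(ws, middle_segment, length_s = length_s)
}

# ---- Contrastive pre-training --------------------------------------------

#' Contrastive pre-training with InfoNCE on unlabeled recordings
#'
#' Per epoch: shuffle the training recordings, form minibatches of `batch_n`
#' (the last incomplete batch is dropped, as the loss assumes exactly N
#' pairs), take two seeded random crops of each recording's middle-20-s
#' segment, featurize, embed through the (optional) projection head and take
#' one Adam step on the InfoNCE loss. A checkpoint (parameters + epoch +
#' running loss + validation loss on a held-out unlabeled split) is written
#' every `checkpoint_every` epochs; the checkpoint with the lowest validation
#' loss is the recommended initialization and is returned.
#'
#' @param unlabeled Data frame with a `path` column (e.g. unlabeled rows of a
#'   corpus manifest), or a list of waveforms/paths.
#' @param p A [pretrain_config()].
#' @param m A [cnn14_config()].
#' @param mel A [mel_config()].
#' @param out_dir Directory for checkpoints and the training-log CSV; `NULL`
#'   keeps everything in memory.
#' @param verbose Print per-epoch loss lines?
#' @return List of class `bruit_pretrain`: `params` (best by validation loss),
#'   `history` (epoch, loss, val_loss), `checkpoints` (paths or in-memory
#'   list), `config`s.
#' @export
pretrain_contrastive <- function(unlabeled, p = pretrain_config(),
                                 m = cnn14_config(), mel = mel_config(),
                                 out_dir = NULL, verbose = FALSE) {
  segs <- load_middle_segments(unlabeled)
  n <- length(segs)
  if (n < p$batch_n)
    stop("pretrain_contrastive: need at least batch_n = ", p$batch_n,
         " unlabeled recordings, got ", n)
  n_val <- floor(n * p$val_fraction)
  idx <- with_seed(derive_seed(p$seed, "pretrain-split"), sample.int(n))
  val_idx <- if (n_val >= 2) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) < p$batch_n)
    stop("pretrain_contrastive: too few recordings after validation split")
  params <- cnn14_init(m, derive_seed(p$seed, "init"))
  state <- adam_init(params)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  crop_batch <- function(ids, seed_tag) {
    specs <- vector("list", 2 * length(ids))
    for (j in seq_along(ids)) {
      crops <- random_crops(segs[[ids[j]]], p$crop_s, k = 2,
                            seed = derive_seed(p$seed, seed_tag, ids[j]))
      specs[[2 * j - 1]] <- melspec(crops[[1]], mel)$values
      specs[[2 * j]] <- melspec(crops[[2]], mel)$values
    }
    specs
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  checkpoints <- list()
  best <- list(val = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(p$epochs)) {
    order_ep <- with_seed(derive_seed(p$seed, "epoch-order", epoch),
                          sample(tr_idx))
    n_batches <- length(order_ep) %/% p$batch_n
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      ids <- order_ep[((bi - 1) * p$batch_n + 1):(bi * p$batch_n)]
      specs <- crop_batch(ids, sprintf("crops-e%d", epoch))
      res <- cnn_lossgrad_cpp(specs, params, m, "nce", NULL, p$tau,
                              training = TRUE, update_running = TRUE)
      if (!is.finite(res$loss))
        stop("pretrain_contrastive: non-finite loss at epoch ", epoch,
             " batch ", bi, " (diverged; lower lr or check features)")
      params <- merge_running(params, res$running)
      upd <- adam_step(params, res$grads, state, p$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss
    }
    ep_loss <- ep_loss / max(1, n_batches)
    val_loss <- NA_real_
    if (epoch %in% checkpoint_epochs(p$epochs, p$checkpoint_every)) {
      if (length(val_idx) >= 2) {
        vspecs <- crop_batch(val_idx, sprintf("valcrops-e%d", epoch))
        vres <- cnn_lossgrad_cpp(vspecs, params, m, "nce", NULL, p$tau,
                                 training = TRUE, update_running = FALSE)
        val_loss <- vres$loss
      } else val_loss <- ep_loss
      ck <- list(epoch = epoch, loss = ep_loss, val_loss = val_loss)
      if (!is.null(out_dir)) {
        ck_path <- file.path(out_dir, sprintf("pretrain_epoch%04d.rds", epoch))
        save_checkpoint(params, m, ck_path, meta = ck)
        checkpoints[[length(checkpoints) + 1]] <- ck_path
      } else {
        ck$params <- params
        checkpoints[[length(checkpoints) + 1]] <- ck
      }
      if (val_loss <= best$val) best <- list(val = val_loss, params = params,
                                             epoch = epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("pretrain epoch %d/%d: loss %.4f", epoch, p$epochs, ep_loss))
  }
  if (!is.null(out_dir))
    write.csv(history, file.path(out_dir, "pretrain_log.csv"), row.names = FALSE)
  structure(list(params = best$params, best_epoch = best$epoch,
                 history = history, checkpoints = checkpoints,
                 pretrain_config = p, model_config = m, mel_config = mel),
            class = "bruit_pretrain")
}

#' @export
print.bruit_pretrain <- function(x, ...) {
  cat(sprintf("<bruit_pretrain: %d epochs, final loss %.4f, best checkpoint epoch %d>\n",
              nrow(x$history), x$history$loss[nrow(x$history)], x$best_epoch))
  invisible(x)
}

# ---- Supervised fitting ---------------------------------------------------

label_targets <- function(labels) {
  y <- matrix(0, length(labels), 2)
  y[labels == "normal", 1] <- 1
  y[labels == "abnormal", 2] <- 1
  y
}

#' Fit the bruit classifier
#'
#' Supervised training of the CNN14 classifier on labeled recordings with
#' one-hot binary cross-entropy over the two sigmoid outputs. All layers are
#' trained; features are the log-mel spectrograms of the middle-20-s segments
#' and no augmentation is applied. Initial weights come from `init_params`
#' (a contrastive or external checkpoint) or from seeded random
#' initialization; `f$init` and `init_params` must agree.
#'
#' @param labeled Data frame with columns `path` (or a `spectrograms` list
#'   passed via `features`) and `label` (`"normal"`/`"abnormal"`); both
#'   classes must be present.
#' @param f A [finetune_config()].
#' @param m A [cnn14_config()].
#' @param mel A [mel_config()].
#' @param init_params Optional parameter list (required unless
#'   `f$init == "scratch"`).
#' @param features Optional precomputed list of frames x 64 matrices aligned
#'   with `labeled` rows (skips WAV reading).
#' @param verbose Print per-epoch loss lines?
#' @return An object of class `bruit_model` with parameters, configs and a
#'   per-epoch training history; see [predict.bruit_model()].
#' @export
bruit_fit <- function(labeled, f = finetune_config(), m = cnn14_config(),
                      mel = mel_config(), init_params = NULL, features = NULL,
                      verbose = FALSE) {
  labels <- as.character(labeled$label)
  keep <- labels %in% c("normal", "abnormal")
  labeled <- labeled[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("bruit_fit: need at least one example of each class")
  if (f$init == "scratch") {
    if (!is.null(init_params))
      stop("bruit_fit: init = 'scratch' but init_params supplied")
    params <- cnn14_init(m, derive_seed(f$seed, "finetune-init"))
  } else {
    if (is.null(init_params))
      stop("bruit_fit: init = '", f$init, "' requires init_params")
    params <- init_params
  }
  if (is.null(features)) {
    segs <- load_middle_segments(labeled)
    features <- lapply(segs, function(s) melspec(s, mel)$values)
  } else {
    features <- features[keep]
  }
  y <- label_targets(labels)
  n <- length(features)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0))
  for (epoch in seq_len(f$epochs)) {
    ord <- with_seed(derive_seed(f$seed, "sup-epoch", epoch), sample.int(n))
    ep_loss <- 0; nb <- 0; ep_correct <- 0
    for (start in seq(1, n, by = f$batch)) {
      ids <- ord[start:min(start + f$batch - 1, n)]
      if (length(ids) < 1) next
      res <- cnn_lossgrad_cpp(features[ids], params, m, "bce",
                              y[ids, , drop = FALSE], 0.5,
                              training = TRUE, update_running = TRUE)
      if (!is.finite(res$loss))
        stop("bruit_fit: non-finite loss at epoch ", epoch)
      # online training accuracy from the batch forward already computed
      ep_correct <- ep_correct +
        sum((res$probs[, 2] > res$probs[, 1]) == (labels[ids] == "abnormal"))
      params <- merge_running(params, res$running)
      upd <- adam_step(params, res$grads, state, f$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / nb,
                                         train_acc = ep_correct / n))
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f train_acc %.3f",
                      epoch, f$epochs, ep_loss / nb, ep_correct / n))
  }
  structure(list(params = params, model_config = m, mel_config = mel,
                 finetune_config = f, history = history,
                 classes = c("normal", "abnormal"), n_train = n),
            class = "bruit_model")
}

#' Predict from a fitted bruit classifier
#'
#' @param object A `bruit_model` from [bruit_fit()].
#' @param newdata A data frame with a `path` column, a waveform, a list of
#'   waveforms/paths, a `mel_spectrogram`, or a list of frames x 64 matrices.
#' @param type `"prob"` for the two sigmoid scores, `"class"` for the argmax
#'   label (ties resolved to `"normal"`: a screening alarm should not fire on
#'   a tie), `"score"` for just the abnormal-class score.
#' @param ... Unused.
#' @return Matrix of scores, factor of classes, or numeric vector.
#' @export
predict.bruit_model <- function(object, newdata, type = c("prob", "class", "score"),
                                ...) {
  type <- match.arg(type)
  is_spec_like <- inherits(newdata, "mel_spectrogram") || is.matrix(newdata) ||
    (is.list(newdata) && length(newdata) > 0 &&
       (is.matrix(newdata[[1]]) || inherits(newdata[[1]], "mel_spectrogram")))
  feats <- if (is_spec_like) newdata
  else lapply(load_middle_segments(newdata),
              function(s) melspec(s, object$mel_config)$values)
  p <- forward_classify(feats, object$params, object$model_config)
  switch(type,
         prob = p,
         score = p[, 2],
         class = factor(ifelse(p[, 2] > p[, 1], "abnormal", "normal"),
                        levels = c("normal", "abnormal")))
}

#' @export
print.bruit_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<bruit_model: CNN14 width 1/%d, %s init, %d recordings, %d epochs>\n",
              x$model_config$width_scale, x$finetune_config$init,
              x$n_train, nrow(h)))
  cat(sprintf("  final training loss %.4f, training accuracy %.3f\n",
              h$loss[nrow(h)], h$train_acc[nrow(h)]))
  invisible(x)
}

#' @export
summary.bruit_model <- function(object, ...) {
  cfg <- object$model_config
  cat("CNN14 bruit classifier\n")
  cat(sprintf("  blocks: %s channels, embed %d, width scale 1/%d\n",
              paste(cfg$channels, collapse = "/"), cfg$embed_dim,
              cfg$width_scale))
  cat(sprintf("  parameters: %s (conv: %s)\n",
              format(cnn14_n_params(cfg), big.mark = ","),
              format(cnn14_n_params(cfg, conv_only = TRUE), big.mark = ",")))
  cat(sprintf("  init: %s, epochs %d, batch %d, lr %g\n",
              object$finetune_config$init, object$finetune_config$epochs,
              object$finetune_config$batch, object$finetune_config$lr))
  print(utils::tail(object$history, 3), row.names = FALSE)
  invisible(object)
}

#' @export
plot.bruit_model <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "bruit classifier training", ...)
  invisible(x)
}
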