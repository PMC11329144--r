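#' CNN14 model configuration
#'
#' The backbone is the 14-layer audio CNN: six convolution blocks, each two
#' (3x3 conv -> batch-norm -> ReLU) layers with channel widths
#' 64/128/256/512/1024/2048, 2x2 max-pooling between blocks 1-5, global
#' (mean + max) pooling over the remaining time-frequency extent, a
#' 2048-unit ReLU embedding layer and a 2-unit sigmoid classification head.
#' `width_scale` divides every width (channels, embedding, projection dims) to
#' produce a desk-scale variant with the same layer structure and roughly
#' `width_scale^2` fewer convolutional parameters.
#'
#' An optional SimCLR-style projection head (embedding -> 512 -> 128 before
#' scaling) is used only during contrastive pre-training and discarded before
#' fine-tuning; set `projection_head = FALSE` to contrast on the embedding
#' directly.
#'
#' @param block_channels Base channel widths of the 6 blocks (strictly
#'   increasing).
#' @param embed_dim Base embedding width (default 2048).
#' @param n_outputs Number of sigmoid outputs (default 2; class 2 = abnormal).
#' @param width_scale Integer divisor >= 1 applied to all widths.
#' @param projection_head Use the projection head during pre-training?
#' @param proj_hidden,proj_out Base projection head widths.
#' @return An object of class `cnn14_config` (also carries the fields the
#'   compiled engine reads: `channels`, `bn_eps`, `input_offset`, ...).
#' @export
cnn14_config <- function(block_channels = c(64, 128, 256, 512, 1024, 2048),
                         embed_dim = 2048, n_outputs = 2, width_scale = 1,
                         projection_head = TRUE,
                         proj_hidden = 512, proj_out = 128) {
  stopifnot(length(block_channels) == 6, width_scale >= 1,
            all(diff(block_channels) > 0), n_outputs >= 1)
  ws <- as.integer(width_scale)
  ch <- as.integer(pmax(1, round(block_channels / ws)))
  if (any(diff(ch) <= 0))
    stop("cnn14_config: width_scale collapses channel progression")
  structure(list(
    block_channels = as.integer(block_channels),
    width_scale = ws,
    channels = ch,
    embed_dim = as.integer(max(4, round(embed_dim / ws))),
    n_outputs = as.integer(n_outputs),
    projection_head = isTRUE(projection_head),
    proj_hidden = as.integer(max(4, round(proj_hidden / ws))),
    proj_out = as.integer(max(4, round(proj_out / ws))),
    bn_eps = 1e-5, bn_momentum = 0.1,
    # log-mel inputs live around [-100, 0] dB; affine rescale to O(1)
    input_offset = -60, input_scale = 20,
    n_pool_blocks = 5L
  ), class = "cnn14_config")
}

#' Parameter shapes of a CNN14 configuration
#'
#' Returns the full named table of parameter dimensions without allocating any
#' weights, so the architecture can be audited row-for-row (conv kernels are
#' stored as `Cout x (9 Cin)` im2col matrices).
#'
#' @param cfg A [cnn14_config()].
#' @return Named list of integer dimension vectors.
#' @export
cnn14_param_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "cnn14_config"))
  ch <- cfg$channels
  shapes <- list()
  cin <- 1L
  for (b in 1:6) {
    for (l in 1:2) {
      cout <- ch[b]
      shapes[[sprintf("c%d_%d_W", b, l)]] <- c(cout, 9L * cin)
      shapes[[sprintf("c%d_%d_b", b, l)]] <- cout
      for (suf in c("g", "b", "rm", "rv"))
        shapes[[sprintf("bn%d_%d_%s", b, l, suf)]] <- cout
      cin <- cout
    }
  }
  shapes[["fc1_W"]] <- c(cfg$embed_dim, ch[6])
  shapes[["fc1_b"]] <- cfg$embed_dim
  shapes[["fc2_W"]] <- c(cfg$n_outputs, cfg$embed_dim)
  shapes[["fc2_b"]] <- cfg$n_outputs
  if (cfg$projection_head) {
    shapes[["p1_W"]] <- c(cfg$proj_hidden, cfg$embed_dim)
    shapes[["p1_b"]] <- cfg$proj_hidden
    shapes[["p2_W"]] <- c(cfg$proj_out, cfg$proj_hidden)
    shapes[["p2_b"]] <- cfg$proj_out
  }
  shapes
}

#' Initialize CNN14 parameters
#'
#' He-normal initialization for weights (sd `sqrt(2 / fan_in)`), zeros for
#' biases and batch-norm shifts, ones for batch-norm scales and running
#' variances. Deterministic given `seed`.
#'
#' @param cfg A [cnn14_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors.
#' @export
cnn14_init <- function(cfg, seed = 1L) {
  shapes <- cnn14_param_shapes(cfg)
  with_seed(seed, {
    params <- list()
    for (nm in names(shapes)) {
      d <- shapes[[nm]]
      if (grepl("_W$", nm)) {
        fan_in <- d[2]
        params[[nm]] <- matrix(rnorm(d[1] * d[2], 0, sqrt(2 / fan_in)), d[1], d[2])
      } else if (grepl("(_g$|_rv$)", nm)) {
        params[[nm]] <- rep(1, d)
      } else {
        params[[nm]] <- rep(0, d)
      }
    }
    params
  })
}

#' Count parameters
#'
#' @param cfg A [cnn14_config()].
#' @param conv_only Count only convolution weights/biases (the part that
#'   scales as `width_scale^-2`).
#' @return Total number of scalar parameters (running stats excluded).
#' @export
cnn14_n_params <- function(cfg, conv_only = FALSE) {
  shapes <- cnn14_param_shapes(cfg)
  keep <- !grepl("(rm|rv)$", names(shapes))
  if (conv_only) keep <- keep & grepl("^c[1-6]_", names(shapes))
  sum(vapply(shapes[keep], prod, numeric(1)))
}

as_input_list <- function(spec) {
  one <- function(s) {
    v <- if (inherits(s, "mel_spectrogram")) s$values else as.matrix(s)
    if (ncol(v) != 64) stop("model input must have 64 mel bins")
    if (nrow(v) < 32) stop("model input needs at least 32 frames")
    v
  }
  if (inherits(spec, "mel_spectrogram") || is.matrix(spec)) list(one(spec))
  else lapply(spec, one)
}

#' Embed spectrograms
#'
#' Runs the backbone in eval mode (batch-norm uses running statistics, so the
#' output is deterministic and independent of batch composition) up to the
#' embedding layer. Global pooling makes the embedding dimension independent
#' of the input frame count.
#'
#' @param spec A `mel_spectrogram`, a frames x 64 matrix, or a list of either.
#' @param params Parameter list from [cnn14_init()] or a trained model.
#' @param cfg The matching [cnn14_config()].
#' @return Matrix of embeddings, one row per input.
#' @export
forward_embed <- function(spec, params, cfg) {
  out <- cnn_forward_cpp(as_input_list(spec), params, cfg, training = FALSE)
  out$embed
}

#' Classify spectrograms
#'
#' Eval-mode forward pass through the sigmoid head. Each input yields
#' `n_outputs` independent sigmoid scores in \[0, 1\]; column 2 (abnormal) is
#' the score used for ROC analysis, and the predicted label is the argmax with
#' ties broken toward normal.
#'
#' @inheritParams forward_embed
#' @return Matrix of scores (rows = inputs, columns = classes
#'   `normal`, `abnormal`).
#' @export
forward_classify <- function(spec, params, cfg) {
  out <- cnn_forward_cpp(as_input_list(spec), params, cfg, training = FALSE)
  p <- out$probs
  colnames(p) <- c("normal", "abnormal")[seq_len(ncol(p))]
  p
}

#' Save / load self-describing checkpoints
#'
#' A checkpoint stores the full model configuration, a hash of it, the
#' parameters and free-form metadata (epoch, losses). [load_checkpoint()]
#' verifies the stored hash and, optionally, compatibility with an expected
#' configuration.
#'
#' @param params Parameter list.
#' @param cfg The [cnn14_config()].
#' @param path Output path (RDS).
#' @param meta Named list of metadata.
#' @return `path` invisibly; for the loader, a list with `params`, `config`,
#'   `meta`.
#' @export
save_checkpoint <- function(params, cfg, path, meta = list()) {
  obj <- list(config = cfg, config_hash = config_hash(unclass(cfg)),
              params = params, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_cfg If supplied, the checkpoint's configuration must agree on
#'   channels, embedding width and output count.
#' @export
load_checkpoint <- function(path, expect_cfg = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$config_hash, config_hash(unclass(obj$config))))
    stop("load_checkpoint: config hash mismatch (corrupt or edited file)")
  if (!is.null(expect_cfg)) {
    for (f in c("channels", "embed_dim", "n_outputs"))
      if (!identical(obj$config[[f]], expect_cfg[[f]]))
        stop("load_checkpoint: checkpoint ", f, " incompatible with model config")
  }
  obj
}

# PANNs-style key -> internal parameter name translation (conv weights are
# (Cout, Cin, 3, 3) arrays; ours are Cout x (9 Cin) im2col matrices)
external_key_map <- function() {
  map <- list()
  for (b in 1:6) for (l in 1:2) {
    pre <- sprintf("conv_block%d", b)
    map[[sprintf("%s.conv%d.weight", pre, l)]] <- sprintf("c%d_%d_W", b, l)
    map[[sprintf("%s.bn%d.weight", pre, l)]] <- sprintf("bn%d_%d_g", b, l)
    map[[sprintf("%s.bn%d.bias", pre, l)]] <- sprintf("bn%d_%d_b", b, l)
    map[[sprintf("%s.bn%d.running_mean", pre, l)]] <- sprintf("bn%d_%d_rm", b, l)
    map[[sprintf("%s.bn%d.running_var", pre, l)]] <- sprintf("bn%d_%d_rv", b, l)
  }
  map[["fc1.weight"]] <- "fc1_W"
  map[["fc1.bias"]] <- "fc1_b"
  map
}

#' Load an externally supplied CNN14 checkpoint
#'
#' Accepts an RDS file containing a named list of arrays using PANNs-style
#' keys (`conv_block{i}.conv{j}.weight` as `(Cout, Cin, 3, 3)` arrays,
#' `...bn{j}.weight/bias/running_mean/running_var`, `fc1.weight/bias`) and
#' maps them onto a freshly initialized parameter list; the classification
#' head is never taken from the external file. Any shape mismatch with `cfg`
#' is an error, so external weights can only initialize a width-compatible
#' model.
#'
#' @param path RDS file of named arrays.
#' @param cfg A [cnn14_config()].
#' @param seed Seed for the parts not present in the file (heads).
#' @return Parameter list ready for [bruit_fit()].
#' @export
load_external_checkpoint <- function(path, cfg, seed = 1L) {
  ext <- readRDS(path)
  if (is.null(names(ext))) stop("external checkpoint must be a named list")
  params <- cnn14_init(cfg, seed)
  map <- external_key_map()
  used <- 0L
  for (key in names(ext)) {
    nm <- map[[key]]
    if (is.null(nm)) next
    val <- ext[[key]]
    if (grepl("^c[1-6].*_W$", nm)) {
      d <- dim(val)
      if (length(d) != 4 || d[3] != 3 || d[4] != 3)
        stop("external checkpoint: ", key, " is not a (Cout, Cin, 3, 3) array")
      W <- matrix(0, d[1], 9 * d[2])
      for (ci in seq_len(d[2])) for (ki in 1:3) for (kj in 1:3)
        W[, (ci - 1) * 9 + (ki - 1) * 3 + kj] <- val[, ci, ki, kj]
      val <- W
    }
    tgt <- params[[nm]]
    if (!identical(dim(tgt), dim(val)) && !(is.null(dim(tgt)) && length(tgt) == length(val)))
      stop("external checkpoint: ", key, " has incompatible shape for this config")
    params[[nm]] <- if (is.null(dim(tgt))) as.numeric(val) else val
    used <- used + 1L
  }
  if (used == 0L) stop("external checkpoint: no recognized keys")
  params
}
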