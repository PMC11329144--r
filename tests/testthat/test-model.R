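test_that("the full-width architecture matches the published layer table row for row", {
  cfg <- cnn14_config()
  sh <- cnn14_param_shapes(cfg)
  ch <- c(64, 128, 256, 512, 1024, 2048)
  cin <- 1
  for (b in 1:6) {
    expect_equal(sh[[sprintf("c%d_1_W", b)]], c(ch[b], 9 * cin))
    expect_equal(sh[[sprintf("c%d_2_W", b)]], c(ch[b], 9 * ch[b]))
    expect_equal(sh[[sprintf("bn%d_1_g", b)]], ch[b])
    expect_equal(sh[[sprintf("bn%d_2_g", b)]], ch[b])
    cin <- ch[b]
  }
  expect_equal(sh$fc1_W, c(2048, 2048))        # embedding layer
  expect_equal(sh$fc2_W, c(2, 2048))           # 2-unit sigmoid head
  expect_equal(cfg$embed_dim, 2048L)
})

test_that("width scaling shrinks conv parameters by about the square of the divisor", {
  for (ws in c(8, 16)) {
    ratio <- cnn14_n_params(cnn14_config(), conv_only = TRUE) /
      cnn14_n_params(cnn14_config(width_scale = ws), conv_only = TRUE)
    expect_gt(ratio, 0.8 * ws^2)
    expect_lt(ratio, 1.3 * ws^2)
  }
})

test_that("global pooling makes the embedding dimension independent of frame count", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 1)
  set.seed(3)
  e500 <- forward_embed(matrix(rnorm(500 * 64, -60, 15), 500, 64), params, cfg)
  e1000 <- forward_embed(matrix(rnorm(1000 * 64, -60, 15), 1000, 64), params, cfg)
  expect_equal(ncol(e500), cfg$embed_dim)
  expect_equal(ncol(e500), ncol(e1000))
})

test_that("eval-mode forward passes are deterministic", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 2)
  set.seed(4)
  x <- matrix(rnorm(128 * 64, -60, 15), 128, 64)
  expect_identical(forward_classify(x, params, cfg),
                   forward_classify(x, params, cfg))
})

test_that("scores are sigmoids: in [0, 1], and 0.5 under a zeroed final layer", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 5)
  set.seed(6)
  p <- forward_classify(matrix(rnorm(96 * 64, -60, 15), 96, 64), params, cfg)
  expect_true(all(p >= 0 & p <= 1))
  params$fc2_W[] <- 0
  params$fc2_b[] <- 0
  p0 <- forward_classify(matrix(rnorm(96 * 64, -60, 15), 96, 64), params, cfg)
  expect_equal(as.numeric(p0), c(0.5, 0.5))
})

test_that("malformed inputs are rejected", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 1)
  expect_error(forward_classify(matrix(0, 128, 32), params, cfg), "64 mel")
  expect_error(forward_classify(matrix(0, 16, 64), params, cfg), "frames")
  expect_error(cnn14_config(block_channels = c(64, 64, 128, 256, 512, 1024)))
})

test_that("analytic gradients match finite differences for both objectives", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 42)
  set.seed(7)
  inputs <- lapply(1:4, function(i) matrix(rnorm(64 * 64, -60, 15), 64, 64))
  y <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  fd_check <- function(objective, targets, picks) {
    lg <- bruitlearn:::cnn_lossgrad_cpp(inputs, params, cfg, objective,
                                        targets, 0.5, TRUE, FALSE)
    eps <- 1e-5
    for (nm in names(picks)) {
      idx <- picks[[nm]]
      p2 <- params
      p2[[nm]][idx] <- p2[[nm]][idx] + eps
      l1 <- bruitlearn:::cnn_lossgrad_cpp(inputs, p2, cfg, objective,
                                          targets, 0.5, TRUE, FALSE)$loss
      p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
      l0 <- bruitlearn:::cnn_lossgrad_cpp(inputs, p2, cfg, objective,
                                          targets, 0.5, TRUE, FALSE)$loss
      num <- (l1 - l0) / (2 * eps)
      expect_equal(lg$grads[[nm]][idx], num, tolerance = 1e-4,
                   label = paste(objective, nm))
    }
  }
  fd_check("bce", y, list(c1_1_W = 3, c3_2_W = 10, bn2_1_g = 1, bn5_2_b = 2))
  fd_check("nce", NULL, list(c2_1_W = 7, fc1_W = 11, p1_W = 3))
})

test_that("checkpoints round-trip and detect tampering", {
  cfg <- tiny_model()
  params <- cnn14_init(cfg, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, path, meta = list(epoch = 3))
  ck <- load_checkpoint(path, expect_cfg = cfg)
  expect_identical(ck$params$c1_1_W, params$c1_1_W)
  expect_equal(ck$meta$epoch, 3)
  bad <- readRDS(path)
  bad$config$embed_dim <- 999L
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "hash mismatch")
})

test_that("external checkpoints load through the documented key mapping", {
  cfg <- tiny_model()
  ref <- cnn14_init(cfg, seed = 9)
  # synthetic external file with PANNs-style keys and (Cout, Cin, 3, 3) kernels
  ext <- list()
  for (b in 1:6) for (l in 1:2) {
    W <- ref[[sprintf("c%d_%d_W", b, l)]]
    cout <- nrow(W); cin <- ncol(W) / 9
    A <- array(0, c(cout, cin, 3, 3))
    for (ci in seq_len(cin)) for (ki in 1:3) for (kj in 1:3)
      A[, ci, ki, kj] <- W[, (ci - 1) * 9 + (ki - 1) * 3 + kj]
    ext[[sprintf("conv_block%d.conv%d.weight", b, l)]] <- A
    ext[[sprintf("conv_block%d.bn%d.weight", b, l)]] <- ref[[sprintf("bn%d_%d_g", b, l)]]
  }
  ext[["fc1.weight"]] <- ref$fc1_W
  ext[["fc1.bias"]] <- ref$fc1_b
  path <- tempfile(fileext = ".rds")
  saveRDS(ext, path)
  loaded <- load_external_checkpoint(path, cfg)
  for (b in 1:6) for (l in 1:2)
    expect_equal(loaded[[sprintf("c%d_%d_W", b, l)]],
                 ref[[sprintf("c%d_%d_W", b, l)]])
  expect_equal(loaded$fc1_W, ref$fc1_W)
  # width-incompatible weights must be refused
  saveRDS(list("conv_block1.conv1.weight" = array(0, c(64, 1, 3, 3))), path)
  expect_error(load_external_checkpoint(path, cfg), "incompatible")
})
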