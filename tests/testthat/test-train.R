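test_that("checkpoint cadence follows the every-10-epochs protocol", {
  expect_equal(bruitlearn:::checkpoint_epochs(200, 10), seq(10, 200, by = 10))
  expect_length(bruitlearn:::checkpoint_epochs(200, 10), 20)
  expect_equal(bruitlearn:::checkpoint_epochs(7, 3), c(3, 6))
})

test_that("fine-tuning defaults follow the protocol: 40 epochs from scratch, 20 from checkpoints", {
  f <- finetune_config("scratch")
  expect_equal(f$epochs, 40L)
  expect_equal(f$batch, 16L)
  expect_equal(f$lr, 1e-4)
  expect_equal(finetune_config("contrastive_checkpoint")$epochs, 20L)
  expect_equal(finetune_config("external_checkpoint")$epochs, 20L)
  expect_equal(finetune_config("scratch", epochs = 5)$epochs, 5L)
})

test_that("contrastive pre-training reduces the running loss on a desk fixture", {
  unl <- synth_waveforms(100, "patent", seed0 = 300)
  p <- pretrain_config(batch_n = 32, epochs = 2, checkpoint_every = 1,
                       crop_s = 5, seed = 1)
  pre <- pretrain_contrastive(unl, p, tiny_model(), tiny_mel())
  expect_s3_class(pre, "bruit_pretrain")
  expect_equal(nrow(pre$history), 2)
  expect_lt(pre$history$loss[2], pre$history$loss[1])
})

test_that("pre-training writes one checkpoint per cadence tick and is seed-reproducible", {
  unl <- synth_waveforms(40, "patent", seed0 = 500)
  out1 <- file.path(tempdir(), "pre-ck1")
  p <- pretrain_config(batch_n = 16, epochs = 4, checkpoint_every = 2,
                       crop_s = 5, seed = 9)
  pre1 <- pretrain_contrastive(unl, p, tiny_model(), tiny_mel(), out_dir = out1)
  cks <- list.files(out1, pattern = "^pretrain_epoch.*rds$")
  expect_length(cks, 2)
  expect_true(file.exists(file.path(out1, "pretrain_log.csv")))
  pre2 <- pretrain_contrastive(unl, p, tiny_model(), tiny_mel())
  expect_equal(pre1$history$loss, pre2$history$loss, tolerance = 1e-10)
  # the selected checkpoint verifies and matches the model config
  best <- load_checkpoint(file.path(out1, cks[1]), expect_cfg = tiny_model())
  expect_true(is.list(best$params))
})

test_that("pre-training refuses corpora smaller than one batch", {
  unl <- synth_waveforms(4, "patent")
  expect_error(pretrain_contrastive(unl, pretrain_config(batch_n = 64),
                                    tiny_model(), tiny_mel()),
               "at least batch_n")
})

test_that("a separable fixture reaches perfect training accuracy within 40 epochs", {
  cfg <- synth_config(duration = 21, murmur_gain = 0.35, noise_sd = 0.02,
                      patient_gain_sd = 0, recording_gain_sd = 0)
  ws <- c(synth_waveforms(10, "stenotic", cfg, seed0 = 700),
          synth_waveforms(10, "patent", cfg, seed0 = 800))
  labeled <- data.frame(label = rep(c("abnormal", "normal"), each = 10))
  feats <- lapply(ws, function(w) melspec(middle_segment(w), tiny_mel())$values)
  fit <- bruit_fit(labeled, finetune_config("scratch", seed = 2),
                   tiny_model(), tiny_mel(), features = feats)
  expect_s3_class(fit, "bruit_model")
  expect_true(any(fit$history$train_acc == 1))
  pred <- predict(fit, feats, type = "class")
  expect_true(all(pred == labeled$label))
})

test_that("initialization arm and supplied parameters must agree", {
  labeled <- data.frame(label = c("abnormal", "normal"))
  feats <- list(matrix(0, 64, 64), matrix(0, 64, 64))
  params <- cnn14_init(tiny_model(), 1)
  expect_error(bruit_fit(labeled, finetune_config("scratch"), tiny_model(),
                         tiny_mel(), init_params = params, features = feats),
               "init_params supplied")
  expect_error(bruit_fit(labeled, finetune_config("contrastive_checkpoint"),
                         tiny_model(), tiny_mel(), features = feats),
               "requires init_params")
  expect_error(bruit_fit(data.frame(label = c("normal", "normal")),
                         finetune_config("scratch"), tiny_model(), tiny_mel(),
                         features = feats),
               "each class")
})
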