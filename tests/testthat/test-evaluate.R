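r4 <- function(x) floor(x * 1e4 + 0.5) / 1e4

test_that("metrics reproduce the published worked examples from their counts", {
  m1 <- compute_metrics(confusion_matrix(TP = 17, FP = 6, FN = 9, TN = 79))
  expect_equal(r4(m1$accuracy), 0.8649)
  expect_equal(r4(m1$precision), 0.7391)
  expect_equal(r4(m1$recall), 0.6538)
  expect_equal(r4(m1$f1), 0.6939)
  m2 <- compute_metrics(confusion_matrix(TP = 18, FP = 4, FN = 8, TN = 81))
  expect_equal(r4(m2$accuracy), 0.8919)
  expect_equal(r4(m2$precision), 0.8182)
  expect_equal(r4(m2$recall), 0.6923)
  expect_equal(r4(m2$f1), 0.7500)
  m3 <- compute_metrics(confusion_matrix(TP = 5, FP = 0, FN = 0, TN = 7))
  expect_equal(c(m3$accuracy, m3$precision, m3$recall, m3$f1), rep(1, 4))
})

test_that("zero denominators give NaN with a warning, never a silent zero", {
  expect_warning(m <- compute_metrics(confusion_matrix(0, 0, 3, 5)), "precision")
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$f1))
  expect_false(is.nan(m$accuracy))
})

test_that("metric bounds hold and F1 lies between precision and recall", {
  set.seed(21)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(1:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(1:30, 1))
    m <- suppressWarnings(compute_metrics(cm))
    vals <- c(m$accuracy, m$precision, m$recall, m$f1)
    vals <- vals[!is.nan(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
    if (!is.nan(m$f1)) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("AUC matches hand-counted orderings and handles ties", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 3 of the 4 abnormal-normal pairs correctly ordered
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal ROC integration equals the pair-counting statistic", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    label <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    score <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auc_roc(score, label), paircount_auc(score, label),
                 tolerance = 1e-9)
  }
})

test_that("stratified folds reproduce the 111-recording split shape", {
  labels <- rep(c("abnormal", "normal"), c(26, 85))
  fold <- stratified_folds(labels, k = 5, seed = 3)
  expect_length(fold, 111)
  expect_setequal(unique(fold), 1:5)
  expect_equal(sort(as.integer(table(fold))), c(22, 22, 22, 22, 23))
  pos_per_fold <- as.integer(table(fold[labels == "abnormal"]))
  expect_equal(sort(pos_per_fold), c(5, 5, 5, 5, 6))
  expect_identical(stratified_folds(labels, 5, seed = 3), fold)
  expect_false(identical(stratified_folds(labels, 5, seed = 4), fold))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 50)), k = 5), "fewer than")
})

test_that("printed rows reconstruct to unique integer confusion matrices", {
  a1 <- reconstruct_confusion(0.8649, 0.7391, 0.6538, 26, 85)
  expect_true(a1$unique)
  cm <- a1$matches[[1]]
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(17, 6, 9, 79))

  # printed recall 0.8461 is a truncation of 22/26 = 0.84615...
  a2 <- reconstruct_confusion(0.7117, 0.4400, 0.8461, 26, 85)
  cm2 <- a2$matches[[1]]
  expect_equal(c(cm2$TP, cm2$FP, cm2$FN, cm2$TN), c(22, 28, 4, 57))

  a3 <- reconstruct_confusion(1.0, 1.0, 1.0, 26, 85)
  cm3 <- a3$matches[[1]]
  expect_equal(c(cm3$TP, cm3$FP, cm3$FN, cm3$TN), c(26, 0, 0, 85))
})

test_that("an impossible printed row is reported as inconsistent", {
  ref <- reference_metrics()
  row <- ref[ref$method == "contrastive", ]
  expect_error(reconstruct_confusion(row$accuracy, row$precision, row$recall,
                                     row$n_pos, row$n_neg),
               "inconsistent printed row")
  audit <- audit_reference_metrics(quiet = TRUE)
  expect_false(audit$consistent[audit$method == "contrastive"])
  expect_true(all(audit$consistent[audit$method %in%
                                     c("scratch", "panns", "human1", "human2")]))
})

test_that("McNemar on identical predictions gives p = 1 and counts discordants", {
  a <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(mcnemar_paired(a, a)$p_value, 1)
  r <- mcnemar_paired(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$b, 2)
  expect_equal(r$c, 1)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_equal(r$p_value,
               mcnemar_paired(c(FALSE, FALSE, TRUE, TRUE),
                              c(TRUE, TRUE, TRUE, FALSE))$p_value)
})

test_that("the cross-validated experiment scores every labeled recording once", {
  corp <- small_corpus()
  prof <- desk_profile(5)
  prof$mel <- tiny_mel()
  prof$model <- tiny_model()
  prof$pretrain <- pretrain_config(batch_n = 16, epochs = 1,
                                   checkpoint_every = 1, crop_s = 5, seed = 5)
  prof$finetune_epochs <- c(scratch = 2L, external_checkpoint = 1L,
                            contrastive_checkpoint = 1L)
  ex <- run_experiment(corp$records, corp$events,
                       arms = c("scratch", "contrastive"),
                       profile = prof, k = 3)
  expect_s3_class(ex, "bruit_experiment")
  for (arm in c("scratch", "contrastive")) {
    res <- ex$arms[[arm]]
    expect_false(any(is.na(res$scores$score)))          # CV coverage
    expect_equal(nrow(res$scores), sum(ex$labeled$label != "unlabeled"))
    m <- res$metrics
    expect_true(all(!is.na(c(m$accuracy, m$auc))))
    cm <- res$confusion
    expect_equal(cm$TP + cm$FN, sum(ex$labeled$label == "abnormal"))
    expect_equal(cm$FP + cm$TN, sum(ex$labeled$label == "normal"))
  }
  expect_length(ex$comparisons, 1)
  p <- ex$comparisons[[1]]$p_value
  expect_true(p >= 0 && p <= 1)
  out <- file.path(tempdir(), "exp-report")
  write_experiment_report(ex, out)
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "roc_scratch.csv")))
})

test_that("the external arm demands a checkpoint file", {
  corp <- small_corpus()
  expect_error(run_experiment(corp$records, corp$events,
                              arms = c("external_checkpoint"),
                              profile = desk_profile(1)),
               "checkpoint file")
})
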