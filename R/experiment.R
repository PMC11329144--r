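#' Desk-scale experiment profile
#'
#' Problem sizes chosen so a full three-arm, 5-fold, multi-seed experiment on
#' the synthetic corpus runs on a single CPU in minutes while keeping the
#' cohort shape of the full-scale study: 30 patients x 15 weekly 1-minute
#' recordings at 4 kHz, about 60 labeled (roughly 3:1 normal:abnormal) and
#' 390 unlabeled recordings; log-mel frames at 25 frames/s (a 20-s segment is
#' 500 x 64, a 5-s crop 125 x 64); CNN14 at width 1/16; contrastive
#' pre-training for 6 epochs with checkpoints every 3, minibatches of 32
#' recordings and lr 1e-3; supervised epochs 12 from scratch and 6 from a
#' checkpoint (the full-scale 40/20 protocol scaled down, keeping their 2:1
#' ratio). The full-scale pre-training protocol performs on the order of a
#' thousand optimizer steps; a faithful desk-scale emulation must still
#' perform enough optimization for the InfoNCE loss to move well below its
#' no-information baseline `log(2N - 1)`, hence the smaller batches (more
#' steps per epoch at the same cost) and the proportionally larger learning
#' rate. Full-scale defaults in [pretrain_config()] are unchanged (batch 64,
#' lr 1e-4, 200 epochs).
#'
#' @param seed Global seed fanned out to every stage.
#' @return Named list of configs: `synth`, `mel`, `model`, `pretrain`,
#'   `policy`, plus `finetune_epochs` (named vector by init arm).
#' @export
desk_profile <- function(seed = 1L) {
  list(
    synth = synth_config(n_patients = 30, recordings_per_patient = 15,
                         stenosis_fraction = 0.5, seed = derive_seed(seed, "synth")),
    mel = mel_config(sample_rate = 4000, window_s = 0.064, hop_s = 0.04),
    model = cnn14_config(width_scale = 16),
    pretrain = pretrain_config(epochs = 6, checkpoint_every = 3, batch_n = 32,
                               lr = 1e-3, crop_s = 5,
                               seed = derive_seed(seed, "pretrain")),
    policy = label_policy(),
    finetune_epochs = c(scratch = 12L, external_checkpoint = 6L,
                        contrastive_checkpoint = 6L),
    seed = as.integer(seed)
  )
}

#' Cross-validated comparison of training arms
#'
#' Runs the full evaluation protocol on a labeled + unlabeled corpus: weak
#' labels from PTA events, stratified 5-fold cross-validation (train on 4
#' folds, score every held-out recording individually), pooled confusion
#' matrix with accuracy / precision / recall / F1 / AUC per arm, and exact
#' McNemar tests on the paired per-recording correctness between arms.
#'
#' Arms: `"scratch"` (random initialization), `"contrastive"` (InfoNCE
#' pre-training on the corpus's unlabeled recordings, then fine-tuning) and
#' `"external_checkpoint"` (initialization from a supplied CNN14 checkpoint
#' file, then fine-tuning).
#'
#' @param records Data frame with `patient_id`, `timestamp`, `path` (e.g.
#'   `generate_corpus()$records` or a read manifest).
#' @param events PTA events data frame (`patient_id`, `event_date`).
#' @param arms Character subset of
#'   `c("scratch", "external_checkpoint", "contrastive")`.
#' @param profile A [desk_profile()]-style list of configs (fields `mel`,
#'   `model`, `pretrain`, `policy`, `finetune_epochs`, `seed`).
#' @param k Number of folds (default 5).
#' @param external_checkpoint Path to an external checkpoint file (required
#'   for the `external_checkpoint` arm).
#' @param patient_folds If `TRUE`, all recordings of a patient share a fold
#'   (grouped CV); default `FALSE`, recording-level stratification.
#' @param verbose Progress messages.
#' @return An object of class `bruit_experiment`: per-arm `metrics`,
#'   `confusion`, per-recording `scores`, the fold assignment, pairwise
#'   McNemar `comparisons`, and the profile used.
#' @export
run_experiment <- function(records, events,
                           arms = c("scratch", "contrastive"),
                           profile = desk_profile(),
                           k = 5, external_checkpoint = NULL,
                           patient_folds = FALSE, verbose = FALSE) {
  arms <- match.arg(arms, c("scratch", "external_checkpoint", "contrastive"),
                    several.ok = TRUE)
  if ("external_checkpoint" %in% arms && is.null(external_checkpoint))
    stop("run_experiment: the external_checkpoint arm needs a checkpoint file")
  seed <- profile$seed
  labeled_all <- assign_labels(records, events, profile$policy)
  lab <- labeled_all[labeled_all$label != "unlabeled", , drop = FALSE]
  unlab <- labeled_all[labeled_all$label == "unlabeled", , drop = FALSE]
  if (nrow(lab) < 2 * k) stop("run_experiment: too few labeled recordings")

  if (patient_folds) {
    pats <- unique(lab$patient_id)
    has_abn <- vapply(pats, function(p)
      any(lab$label[lab$patient_id == p] == "abnormal"), logical(1))
    pf <- stratified_folds(ifelse(has_abn, "abn", "norm"), k,
                           derive_seed(seed, "folds"))
    fold <- pf[match(lab$patient_id, pats)]
  } else {
    fold <- stratified_folds(lab$label, k, derive_seed(seed, "folds"))
  }

  if (verbose) message("featurizing ", nrow(lab), " labeled recordings")
  feats <- lapply(load_middle_segments(lab),
                  function(s) melspec(s, profile$mel)$values)
  truth_abn <- lab$label == "abnormal"

  pre <- NULL
  if ("contrastive" %in% arms) {
    if (verbose) message("contrastive pre-training on ", nrow(unlab),
                         " unlabeled recordings")
    pre <- pretrain_contrastive(unlab, profile$pretrain, profile$model,
                                profile$mel, verbose = verbose)
  }
  ext_params <- if ("external_checkpoint" %in% arms)
    load_external_checkpoint(external_checkpoint, profile$model,
                             derive_seed(seed, "ext-init"))

  arm_results <- list()
  for (arm in arms) {
    scores <- rep(NA_real_, nrow(lab))       # abnormal-class sigmoid (ROC)
    pred <- rep(NA, nrow(lab))               # argmax; tie resolves to normal
    init_name <- switch(arm, scratch = "scratch",
                        contrastive = "contrastive_checkpoint",
                        external_checkpoint = "external_checkpoint")
    for (fd in seq_len(k)) {
      tr <- fold != fd
      fcfg <- finetune_config(init_name,
                              epochs = profile$finetune_epochs[[init_name]],
                              seed = derive_seed(seed, paste0(arm, "-fold"), fd))
      init <- switch(arm, scratch = NULL, contrastive = pre$params,
                     external_checkpoint = ext_params)
      fit <- bruit_fit(lab[tr, , drop = FALSE], fcfg, profile$model,
                       profile$mel, init_params = init, features = feats[tr])
      p <- forward_classify(feats[!tr], fit$params, profile$model)
      scores[!tr] <- p[, 2]
      pred[!tr] <- p[, 2] > p[, 1]
      if (verbose) message(sprintf("  %s fold %d done", arm, fd))
    }
    arm_results[[arm]] <- list(scores = scores, pred = pred)
  }

  results <- list()
  for (arm in arms) {
    sc <- arm_results[[arm]]$scores
    pred_abn <- arm_results[[arm]]$pred
    cm <- confusion_matrix(TP = sum(pred_abn & truth_abn),
                           FP = sum(pred_abn & !truth_abn),
                           FN = sum(!pred_abn & truth_abn),
                           TN = sum(!pred_abn & !truth_abn))
    met <- compute_metrics(cm, scores = list(score = sc,
                                             label = as.integer(truth_abn)))
    results[[arm]] <- list(metrics = met, confusion = cm,
                           scores = data.frame(patient_id = lab$patient_id,
                                               timestamp = lab$timestamp,
                                               label = lab$label,
                                               score = sc, pred_abnormal = pred_abn,
                                               fold = fold),
                           correct = pred_abn == truth_abn)
  }

  comparisons <- list()
  if (length(arms) > 1) {
    prs <- utils::combn(arms, 2, simplify = FALSE)
    for (pr in prs) {
      comparisons[[paste(pr, collapse = " vs ")]] <-
        mcnemar_paired(results[[pr[1]]]$correct, results[[pr[2]]]$correct)
    }
  }

  structure(list(arms = results, comparisons = comparisons, fold = fold,
                 labeled = lab, pretrain = pre, profile = profile, k = k),
            class = "bruit_experiment")
}

#' @export
print.bruit_experiment <- function(x, ...) {
  cat("Cross-validated bruit classification (", x$k, "-fold)\n", sep = "")
  cat(sprintf("%-22s %8s %9s %8s %8s %8s\n", "Arm", "Accuracy", "Precision",
              "Recall", "F1", "AUC"))
  for (arm in names(x$arms)) {
    m <- x$arms[[arm]]$metrics
    cat(sprintf("%-22s %8.4f %9.4f %8.4f %8.4f %8.4f\n", arm,
                round_half_up(m$accuracy), round_half_up(m$precision),
                round_half_up(m$recall), round_half_up(m$f1),
                round_half_up(m$auc)))
  }
  for (nm in names(x$comparisons))
    cat(sprintf("McNemar %s: p = %.4f\n", nm, x$comparisons[[nm]]$p_value))
  invisible(x)
}

#' Export an experiment report
#'
#' Writes per-arm metrics (CSV + JSON), per-recording scores and ROC points
#' (CSV), confusion matrices and McNemar p-values (JSON) under `out_dir`.
#'
#' @param x A `bruit_experiment`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_experiment_report <- function(x, out_dir) {
  stopifnot(inherits(x, "bruit_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(x$arms), function(arm) {
    m <- x$arms[[arm]]$metrics
    data.frame(arm = arm, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, auc = m$auc)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  full <- list(metrics = tab,
               confusion = lapply(x$arms, function(a) unclass(a$confusion)),
               mcnemar = x$comparisons)
  jsonlite::write_json(full, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (arm in names(x$arms)) {
    write.csv(x$arms[[arm]]$scores,
              file.path(out_dir, paste0("scores_", arm, ".csv")),
              row.names = FALSE)
    sc <- x$arms[[arm]]$scores
    pts <- roc_points(sc$score, as.integer(sc$label == "abnormal"))
    write.csv(pts, file.path(out_dir, paste0("roc_", arm, ".csv")),
              row.names = FALSE)
  }
  invisible(out_dir)
}
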