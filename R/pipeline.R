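#' Run the transfer-learning training stage
#'
#' Orchestrates the full training pipeline: pre-train the CNN on the source
#' subject, fine-tune it on the target subject with the feature layers
#' frozen, extract deep features from both subjects with their respective
#' networks, Euclidean-align each feature set with its own reference,
#' select the `k` source samples closest to the target mean, and train the
#' discriminative RBM on the union of the selected aligned source features
#' and all aligned target training features.
#'
#' Ablation switches: `use_finetune = FALSE` trains the target CNN from
#' scratch on the target data alone (no pre-training); `use_alignment =
#' FALSE` skips Euclidean alignment; `k = 0` drops the source features
#' entirely, degenerating to target-only classifier training.
#'
#' @param source_epochs,target_epochs [epoch_set()]s with matching T x C.
#' @param cnn_cfg a [cnn_config()].
#' @param train_cfg a [train_config()] used for pre-training, fine-tuning
#'   and (with `learning_rate = 0.05`, `max_epochs = 200`) DRBM training.
#' @param k source samples to keep (default: half of the source set;
#'   ignored when `use_selection = FALSE`, which keeps all).
#' @param eps alignment ridge (NULL: scale-aware default).
#' @param H DRBM hidden units.
#' @param use_finetune,use_alignment,use_selection ablation switches.
#' @param feature_layer `"fc1"` (deep features) or `"conv"`.
#' @param pretrained optional already pre-trained source `cnn_model` (a
#'   checkpoint to reuse); when supplied the pre-training stage is skipped.
#' @param seed integer master seed for the stage.
#' @return A `p300_artifacts` list with the trained networks, alignment
#'   references, selection result, DRBM parameters, configuration and the
#'   executed stage log.
#' @export
run_training_stage <- function(source_epochs, target_epochs, cnn_cfg,
                               train_cfg = train_config(), k = NULL, eps = NULL,
                               H = 10, use_finetune = TRUE, use_alignment = TRUE,
                               use_selection = TRUE, feature_layer = "fc1",
                               pretrained = NULL, seed = 1) {
  stopifnot(inherits(source_epochs, "epoch_set"), inherits(target_epochs, "epoch_set"))
  assert_that(all(dim(source_epochs$epochs)[2:3] == dim(target_epochs$epochs)[2:3]),
              "source and target epochs must share T x C")
  stages <- character(0)
  log_stage <- function(name) {
    stages <<- c(stages, name)
    message(sprintf("[stage %d] %s", length(stages), name))
  }
  run <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  cnn_source <- NULL
  if (use_finetune) {
    cnn_source <- if (!is.null(pretrained)) {
      stopifnot(inherits(pretrained, "cnn_model"))
      pretrained
    } else run("pretrain", {
      m <- build_cnn(cnn_cfg, seed = seed)
      train_cnn(m, source_epochs, train_cfg)
    })
    cnn_target <- run("finetune", fine_tune(cnn_source, target_epochs, train_cfg))
  } else {
    cnn_target <- run("train-scratch", {
      m <- build_cnn(cnn_cfg, seed = seed)
      train_cnn(m, target_epochs, train_cfg)
    })
  }

  feats <- run("extract", {
    list(source = if (!is.null(cnn_source))
           extract_features(cnn_source, source_epochs, feature_layer),
         target = extract_features(cnn_target, target_epochs, feature_layer))
  })

  ref_source <- NULL
  ref_target <- NULL
  if (use_alignment) {
    aligned <- run("align", {
      ref_target <- compute_reference(feats$target, eps)
      out <- list(target = align_features(feats$target, ref_target))
      if (!is.null(feats$source)) {
        ref_source <- compute_reference(feats$source, eps)
        out$source <- align_features(feats$source, ref_source)
      }
      out
    })
  } else {
    aligned <- feats[c("target", "source")]
  }

  selection <- NULL
  train_feats <- aligned$target
  if (!is.null(aligned$source)) {
    n_s <- nrow(aligned$source$features)
    k_use <- if (!use_selection) n_s else as.integer(k %||% floor(n_s / 2))
    selection <- run("select",
                     select_source_samples(aligned$target, aligned$source, k_use))
    if (k_use > 0)
      train_feats <- combine_features(subset_features(aligned$source, selection$indices),
                                      aligned$target)
  }

  drbm <- run("train-drbm", {
    opt <- train_config(learning_rate = 0.05, batch_size = train_cfg$batch_size,
                        max_epochs = 200, seed = seed)
    train_drbm(train_feats, H = H, opt = opt)
  })

  structure(list(cnn_source = cnn_source, cnn_target = cnn_target,
                 ref_source = ref_source, ref_target = ref_target,
                 selection = selection, drbm = drbm,
                 config = list(cnn = cnn_cfg, train = train_cfg, k = k, eps = eps,
                               H = H, use_finetune = use_finetune,
                               use_alignment = use_alignment,
                               use_selection = use_selection,
                               feature_layer = feature_layer, seed = seed),
                 stages = stages),
            class = "p300_artifacts")
}

#' @export
print.p300_artifacts <- function(x, ...) {
  cat("<p300_artifacts> stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Run the test stage
#'
#' Extracts deep features from test epochs with the fine-tuned target
#' network, aligns them into the Euclidean reference space, and classifies
#' them with the trained DRBM. In `"offline"` mode the test reference is
#' computed from all test trials before any classification; in `"online"`
#' mode the reference starts empty and is updated one unlabeled trial at a
#' time, each trial being aligned with the reference that includes it and
#' classified immediately. After the last trial the online reference equals
#' the offline one.
#'
#' @param artifacts a [run_training_stage()] result.
#' @param test_epochs an [epoch_set()].
#' @param mode `"offline"` or `"online"`.
#' @return A list with `p_target` (per-epoch target probability), `scores`
#'   (data.frame ready for [decode_session()]), `reference` (the final test
#'   reference or NULL when alignment is disabled) and `mode`.
#' @export
run_test_stage <- function(artifacts, test_epochs, mode = c("offline", "online")) {
  stopifnot(inherits(artifacts, "p300_artifacts"))
  mode <- match.arg(mode)
  assert_that(inherits(test_epochs, "epoch_set") && dim(test_epochs$epochs)[1] > 0,
              "test set must be a non-empty epoch_set")
  feats <- extract_features(artifacts$cnn_target, test_epochs,
                            artifacts$config$feature_layer)
  ref <- NULL
  if (artifacts$config$use_alignment) {
    if (mode == "offline") {
      ref <- compute_reference(feats, artifacts$config$eps)
      aligned <- align_features(feats, ref)
      p <- predict_drbm(artifacts$drbm, aligned)
    } else {
      ref <- empty_reference(ncol(feats$features), artifacts$config$eps)
      p <- numeric(nrow(feats$features))
      for (i in seq_len(nrow(feats$features))) {
        y <- feats$features[i, ]
        ref <- online_update(ref, y)
        p[i] <- drbm_conditional(artifacts$drbm, as.numeric(ref$W %*% y))[, 2]
      }
    }
  } else {
    p <- predict_drbm(artifacts$drbm, feats)
  }
  list(p_target = p,
       scores = data.frame(character_index = test_epochs$character_index,
                           repetition_index = test_epochs$repetition_index,
                           code = test_epochs$codes, p_target = p,
                           is_target = test_epochs$labels),
       reference = ref, mode = mode)
}

#' Decode a speller test session end to end
#'
#' Convenience wrapper: [run_test_stage()] followed by [decode_session()]
#' and [accuracy_curve()].
#'
#' @inheritParams run_test_stage
#' @param truth true symbols of the test characters.
#' @param Nr_range repetition budgets to evaluate.
#' @return List with `result` (the [decode_session()] output), `accuracy`
#'   (percent correct per Nr) and the test-stage output.
#' @export
evaluate_speller <- function(artifacts, test_epochs, truth,
                             mode = c("offline", "online"), Nr_range = NULL) {
  test <- run_test_stage(artifacts, test_epochs, mode)
  result <- decode_session(test$scores, Nr_range)
  list(result = result, accuracy = accuracy_curve(result, truth), test = test)
}

#' Evaluate a target-detection (RSVP) test session
#'
#' @inheritParams run_test_stage
#' @return List with `bca` (balanced classification accuracy at threshold
#'   0.5) and the test-stage output.
#' @export
evaluate_rsvp <- function(artifacts, test_epochs, mode = c("offline", "online")) {
  test <- run_test_stage(artifacts, test_epochs, mode)
  pred <- as.integer(test$p_target > 0.5)
  list(bca = bca_from_labels(test_epochs$labels, pred), test = test)
}
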