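#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 1e-5 and
#' weight decay 1e-3, batch size 1, light augmentation on. Width-reduced
#' desk-scale runs typically raise the learning rate and use few epochs (see
#' the package vignette).
#'
#' @param learning_rate Adam step size: either a single value used for every
#'   epoch or a vector with one entry per epoch (a simple step schedule;
#'   a zero entry freezes parameter updates for that epoch).
#' @param weight_decay L2 coefficient folded into the gradient.
#' @param batch_size Samples per optimisation step (gradients are averaged
#'   within a batch; the reference protocol uses 1).
#' @param epochs Passes over the training split.
#' @param augmentation An [augmentation_policy()].
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @param device Only `"cpu"` is available.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 1e-3,
                         batch_size = 1L, epochs = 100L,
                         augmentation = augmentation_policy(),
                         seed = 42L, device = "cpu") {
  stopifnot(all(learning_rate >= 0), weight_decay >= 0, batch_size >= 1,
            epochs >= 1, inherits(augmentation, "augmentation_policy"))
  if (!length(learning_rate) %in% c(1L, as.integer(epochs))) {
    stop("learning_rate must be a single value or give one rate per epoch",
         call. = FALSE)
  }
  device <- match.arg(device, "cpu")
  structure(list(learning_rate = as.numeric(learning_rate),
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augmentation = augmentation,
                 seed = as.integer(seed), device = device),
            class = "train_config")
}

#' Stratified random train/test splits
#'
#' Draws `n_repeats` independent random splits of the manifest; within each
#' split every class contributes `round_half_up(test_fraction * n_c)`
#' subjects to the test side. Splits are deterministic given `seed`.
#'
#' @param manifest Manifest `data.frame` (columns `subject_id`, `label`) or
#'   a path accepted by [read_manifest()].
#' @param n_repeats Number of independent splits (default 3).
#' @param test_fraction Per-class test fraction (default 0.3).
#' @param seed Integer seed.
#' @return List of `fold_split` objects with fields `fold_index`, `train`,
#'   `test` (subject-id vectors) and `seed`.
#' @export
stratified_splits <- function(manifest, n_repeats = 3L,
                              test_fraction = 0.3, seed = 42L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  classes <- unique(manifest$label)
  lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, r), function() {
      test <- character(0)
      for (cl in classes) {
        ids <- manifest$subject_id[manifest$label == cl]
        n_test <- as.integer(round_half_up(test_fraction * length(ids)))
        if (n_test < 1 || n_test >= length(ids)) {
          stop("class ", cl, " too small (", length(ids),
               ") to place at least one sample on each side of the split",
               call. = FALSE)
        }
        test <- c(test, sample(ids, n_test))
      }
      structure(list(fold_index = r,
                     train = setdiff(manifest$subject_id, test),
                     test = test, seed = seed),
                class = "fold_split")
    })
  })
}

# network input (D, H, W, 1) from a volume_sample
as_net_input <- function(v) {
  x <- v$voxels
  attributes(x) <- list(dim = c(dim(x), 1L))
  x
}

#' Train a network on one fold
#'
#' Class weights are computed from the fold's *training* labels only. Each
#' epoch visits the shuffled training split with single-sample optimisation
#' steps (batches larger than 1 accumulate and average gradients before
#' stepping); light augmentation is applied on the fly when enabled. Fully
#' deterministic given the configurations' seeds.
#'
#' @param cfg A [network_config()]; the fold's network is initialised from
#'   `derive`d per-fold seed so folds do not share initial weights.
#' @param tcfg A [train_config()].
#' @param fold A `fold_split` from [stratified_splits()].
#' @param dataset Named list of preprocessed [volume_sample()]s keyed by
#'   subject id (e.g. from [load_dataset()]).
#' @param on_epoch_end Optional callback `function(network, epoch,
#'   mean_loss)` invoked after each epoch (e.g. for monitoring); its return
#'   value is ignored and it must not modify the network.
#' @return List with `network` (trained), `loss_history` (per-epoch mean
#'   training loss) and `class_weights`.
#' @export
train_fold <- function(cfg, tcfg, fold, dataset, on_epoch_end = NULL) {
  stopifnot(inherits(cfg, "network_config"), inherits(tcfg, "train_config"),
            inherits(fold, "fold_split"))
  missing <- setdiff(fold$train, names(dataset))
  if (length(missing)) {
    stop("training subjects missing from dataset: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  train_labels <- vapply(dataset[fold$train], function(v) v$label, "")
  counts <- vapply(CLASS_LEVELS, function(cl) sum(train_labels == cl), 0L)
  cw <- compute_class_weights(counts)
  fold_cfg <- cfg
  fold_cfg$seed <- derive_seed(cfg$seed, fold$fold_index)
  net <- build_network(fold_cfg)
  params <- mod_flatten(net$module)
  state <- adam_init(params)
  loss_history <- numeric(tcfg$epochs)
  set.seed(derive_seed(tcfg$seed, fold$fold_index))
  for (ep in seq_len(tcfg$epochs)) {
    lr_ep <- if (length(tcfg$learning_rate) > 1L) {
      tcfg$learning_rate[[ep]]
    } else {
      tcfg$learning_rate
    }
    order_ids <- sample(fold$train)
    ep_losses <- numeric(length(order_ids))
    i <- 1L
    while (i <= length(order_ids)) {
      take <- seq.int(i, min(i + tcfg$batch_size - 1L, length(order_ids)))
      acc <- NULL
      for (j in seq_along(take)) {
        v <- dataset[[order_ids[take[j]]]]
        if (tcfg$augmentation$enabled) {
          v <- augment_volume(v, tcfg$augmentation)
        }
        r <- mod_forward(net$module, as_net_input(v), training = TRUE)
        net$module <- r$mod
        lb <- weighted_cross_entropy(r$y, v$label, cw)
        if (!is.finite(lb$total)) {
          stop("non-finite training loss at epoch ", ep, ", subject ",
               order_ids[take[j]], call. = FALSE)
        }
        ep_losses[take[j]] <- lb$total
        bk <- mod_backward(net$module, r$cache, as.numeric(lb$grad_logits))
        g <- grads_flatten(net$module, bk$grads)
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
      }
      if (length(take) > 1L) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(take)
      }
      params <- mod_flatten(net$module)
      upd <- adam_step(params, acc, state, lr_ep, tcfg$weight_decay)
      state <- upd$state
      net$module <- mod_set_params(net$module, upd$params)
      i <- i + length(take)
    }
    loss_history[ep] <- mean(ep_losses)
    if (!is.null(on_epoch_end)) on_epoch_end(net, ep, loss_history[ep])
  }
  list(network = net, loss_history = loss_history, class_weights = cw)
}

#' Predict class labels for volumes
#'
#' Evaluation-mode forward pass (deterministic: dropout off, batch-norm
#' running statistics); the predicted label is the argmax of the logits.
#'
#' @param net A trained `resvol_network`.
#' @param volumes List of [volume_sample()]s.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(net, volumes) {
  vapply(volumes, function(v) {
    logits <- classify(net, v$voxels)
    net$class_levels[which.max(logits)]
  }, "")
}

#' Evaluate a trained network on a fold's test split
#'
#' No augmentation is applied; predictions are deterministic.
#'
#' @param net A trained `resvol_network`.
#' @param fold A `fold_split`.
#' @param dataset Named list of preprocessed [volume_sample()]s.
#' @return A [confusion()] matrix over the test subjects.
#' @export
evaluate_fold <- function(net, fold, dataset) {
  missing <- setdiff(fold$test, names(dataset))
  if (length(missing)) {
    stop("test subjects missing from dataset: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  vols <- dataset[fold$test]
  truth <- vapply(vols, function(v) v$label, "")
  pred <- predict_labels(net, vols)
  confusion(truth, pred)
}

#' Run the full cross-validation experiment
#'
#' Draws the stratified splits, trains one network per fold from scratch,
#' evaluates each on its held-out test split, and assembles the
#' cross-validation report: per-fold confusion matrices and class-wise
#' metrics, per-class mean and SD of F1 over folds, and consolidated macro
#' F1, weighted F1 and accuracy computed on the pooled (summed) confusion
#' matrix (the mean of per-fold accuracies is also reported).
#'
#' @param cfg A [network_config()].
#' @param tcfg A [train_config()].
#' @param manifest Manifest `data.frame` or path.
#' @param dataset Optional preloaded named list of [volume_sample()]s; when
#'   `NULL` the volumes are read from the manifest directory and
#'   preprocessed with [preprocess_volume()].
#' @param n_repeats,test_fraction Split protocol (defaults 3 and 0.3).
#' @param out_dir Optional directory for artifacts: `report.json`,
#'   `confusion_fold<k>.csv` and per-fold checkpoints.
#' @param verbose Print per-fold progress.
#' @return A `crossval_report` list.
#' @export
run_experiment <- function(cfg, tcfg, manifest, dataset = NULL,
                           n_repeats = 3L, test_fraction = 0.3,
                           out_dir = NULL, verbose = interactive()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(dataset)) {
    dataset <- load_dataset(manifest)
    dataset <- lapply(dataset, preprocess_volume)
  }
  folds <- stratified_splits(manifest, n_repeats, test_fraction,
                             seed = tcfg$seed)
  fold_results <- lapply(folds, function(fold) {
    if (verbose) {
      message(sprintf("fold %d: training on %d, testing on %d subjects",
                      fold$fold_index, length(fold$train),
                      length(fold$test)))
    }
    tr <- train_fold(cfg, tcfg, fold, dataset)
    cm <- evaluate_fold(tr$network, fold, dataset)
    list(fold_index = fold$fold_index, confusion = cm,
         classwise = classwise_metrics(cm),
         aggregate = aggregate_metrics(cm),
         loss_history = tr$loss_history,
         class_weights = tr$class_weights, network = tr$network)
  })
  pooled <- Reduce(`+`, lapply(fold_results, function(f)
    unclass(f$confusion)))
  class(pooled) <- c("confusion_matrix", class(pooled))
  per_class_f1 <- lapply(stats::setNames(nm = CLASS_LEVELS), function(cl) {
    f1s <- vapply(fold_results, function(f) {
      f$classwise$f1[f$classwise$class == cl]
    }, 0)
    c(fold_mean_sd(f1s), list(values = f1s))
  })
  report <- structure(list(
    folds = lapply(fold_results, function(f) f[setdiff(names(f),
                                                       "network")]),
    per_class_f1 = per_class_f1,
    pooled_confusion = pooled,
    consolidated = aggregate_metrics(pooled),
    mean_fold_accuracy = mean(vapply(fold_results, function(f)
      f$aggregate$accuracy, 0)),
    config = cfg, train_config = tcfg
  ), class = "crossval_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, out_dir)
    for (f in fold_results) {
      save_checkpoint(f$network,
                      file.path(out_dir, sprintf("checkpoint_fold%d.rds",
                                                 f$fold_index)))
    }
  }
  report
}

#' Serialise a cross-validation report
#'
#' Writes `report.json` plus one labelled `confusion_fold<k>.csv` per fold.
#'
#' @param report A `crossval_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    per_class_f1 = lapply(report$per_class_f1, function(x)
      list(mean = x$mean, sd = x$sd, values = x$values)),
    consolidated = report$consolidated,
    mean_fold_accuracy = report$mean_fold_accuracy,
    folds = lapply(report$folds, function(f) list(
      fold_index = f$fold_index,
      confusion = unclass(f$confusion),
      classwise = f$classwise,
      aggregate = f$aggregate,
      loss_history = f$loss_history,
      class_weights = as.list(f$class_weights$W)
    ))
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (f in report$folds) {
    utils::write.csv(as.data.frame(unclass(f$confusion)),
                     file.path(out_dir, sprintf("confusion_fold%d.csv",
                                                f$fold_index)))
  }
  invisible(out_dir)
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %s, %d folds\n", x$config$kind,
              length(x$folds)))
  for (cl in names(x$per_class_f1)) {
    cat(sprintf("  %-8s F1 %.4f +/- %.4f\n", cl, x$per_class_f1[[cl]]$mean,
                x$per_class_f1[[cl]]$sd))
  }
  cat(sprintf("  macro F1 %.4f   weighted F1 %.4f   accuracy %.4f (pooled)\n",
              x$consolidated$macro_f1, x$consolidated$weighted_f1,
              x$consolidated$accuracy))
  cat(sprintf("  mean fold accuracy %.4f\n", x$mean_fold_accuracy))
  invisible(x)
}
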