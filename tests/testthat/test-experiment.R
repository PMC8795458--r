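fake_manifest <- function(sizes) {
  data.frame(
    subject_id = unlist(lapply(names(sizes), function(cl)
      sprintf("%s_%03d", tolower(cl), seq_len(sizes[[cl]])))),
    path = "x.nii.gz",
    label = rep(names(sizes), unlist(sizes)),
    stringsAsFactors = FALSE
  )
}

test_that("stratified splits give round-half-up per-class test counts", {
  m <- fake_manifest(c(LGG = 73L, HGG = 259L, HEALTHY = 259L))
  folds <- stratified_splits(m, n_repeats = 3L, test_fraction = 0.3,
                             seed = 5L)
  expect_length(folds, 3L)
  for (f in folds) {
    test_labels <- m$label[match(f$test, m$subject_id)]
    expect_equal(sum(test_labels == "LGG"), 22L)
    expect_equal(sum(test_labels == "HGG"), 78L)
    expect_equal(sum(test_labels == "HEALTHY"), 78L)
    expect_length(f$test, 178L)
    expect_length(f$train, 413L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), m$subject_id)
  }
  # the 3 repeats are genuinely different random splits
  expect_false(setequal(folds[[1]]$test, folds[[2]]$test))

  f2 <- stratified_splits(m, 3L, 0.3, seed = 5L)
  for (i in 1:3) {
    expect_identical(folds[[i]]$test, f2[[i]]$test)
    expect_identical(folds[[i]]$train, f2[[i]]$train)
  }

  expect_error(stratified_splits(fake_manifest(c(LGG = 1L, HGG = 10L,
                                                 HEALTHY = 10L))),
               "too small")
})

test_that("split invariants hold across random manifests", {
  set.seed(33)
  for (i in 1:25) {
    sizes <- stats::setNames(as.list(sample(4:40, 3)), CLASS_LEVELS)
    m <- fake_manifest(sizes)
    folds <- stratified_splits(m, 2L, 0.3, seed = i)
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0L)
      expect_setequal(c(f$train, f$test), m$subject_id)
      test_labels <- m$label[match(f$test, m$subject_id)]
      for (cl in CLASS_LEVELS) {
        expect_equal(sum(test_labels == cl),
                     floor(0.3 * sizes[[cl]] + 0.5))
      }
    }
  }
})

test_that("class weights come from the training split only", {
  env <- tiny_dataset()
  m <- env$manifest
  # test split takes one HGG and one HEALTHY; train has 2 LGG, 1 HGG, 1 HEALTHY
  fold <- structure(list(fold_index = 1L,
                         train = c("lgg_001", "lgg_002", "hgg_001",
                                   "healthy_001"),
                         test = c("hgg_002", "healthy_002"), seed = 1L),
                    class = "fold_split")
  cfg <- network_config("RESNET_MIXED", width = 2L, seed = 1L)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 1L, seed = 1L,
                       augmentation = augmentation_policy(enabled = FALSE))
  tr <- train_fold(cfg, tcfg, fold, env$ds)
  expect_equal(unname(tr$class_weights$class_counts), c(2L, 1L, 1L))
  expect_equal(unname(tr$class_weights$W), c(1 - 2 / 4, 1 - 1 / 4, 1 - 1 / 4))
  expect_true(all(is.finite(tr$loss_history)) && all(tr$loss_history >= 0))
})

test_that("per-epoch learning-rate schedules drive the optimiser", {
  env <- tiny_dataset()
  fold <- all_train_fold(env$manifest)
  cfg <- network_config("RESNET_MIXED", width = 2L, seed = 5L)
  # zero rates freeze every parameter despite full training epochs
  tcfg0 <- train_config(learning_rate = c(0, 0), epochs = 2L, seed = 5L,
                        augmentation = augmentation_policy(enabled = FALSE))
  tr0 <- train_fold(cfg, tcfg0, fold, env$ds)
  fold_cfg <- cfg
  fold_cfg$seed <- resvol:::derive_seed(cfg$seed, fold$fold_index)
  fresh <- build_network(fold_cfg)
  expect_equal(network_parameters(tr0$network), network_parameters(fresh))
  # a rate vector must match the number of epochs
  expect_error(train_config(learning_rate = c(1e-3, 1e-4), epochs = 3L),
               "one rate per epoch")
})

test_that("a width-reduced network overfits a small separable phantom set", {
  env <- tiny_dataset()
  fold <- all_train_fold(env$manifest)
  cfg <- network_config("RESNET_MIXED", width = 4L, dropout_p = 0,
                        seed = 1L)
  tcfg <- train_config(learning_rate = 3e-3, epochs = 30L, seed = 1L,
                       augmentation = augmentation_policy(enabled = FALSE))
  tr <- train_fold(cfg, tcfg, fold, env$ds)
  expect_true(all(is.finite(tr$loss_history)))
  expect_lt(tail(tr$loss_history, 1), head(tr$loss_history, 1))
  # training accuracy: training-regime forward (batch statistics), as used
  # during optimisation
  truth <- vapply(env$ds, function(v) v$label, "")
  preds <- vapply(env$ds, function(v) {
    CLASS_LEVELS[which.max(classify(tr$network, v$voxels,
                                    training = TRUE))]
  }, "")
  expect_equal(mean(preds == truth), 1.0)

  # training is deterministic under fixed seeds
  tr2 <- train_fold(cfg, tcfg, fold, env$ds)
  expect_identical(tr$loss_history, tr2$loss_history)
  expect_identical(network_parameters(tr$network),
                   network_parameters(tr2$network))

  # repeated evaluation of a fixed network is identical
  cm1 <- evaluate_fold(tr$network, fold, env$ds)
  cm2 <- evaluate_fold(tr$network, fold, env$ds)
  expect_identical(cm1, cm2)
  expect_equal(sum(cm1), length(fold$test))
})

test_that("evaluation ignores augmentation and missing subjects error", {
  env <- tiny_dataset()
  fold <- all_train_fold(env$manifest)
  net <- build_network(network_config("RESNET_MIXED", width = 2L,
                                      seed = 3L))
  cm <- evaluate_fold(net, fold, env$ds)
  expect_equal(sum(cm), nrow(env$manifest))
  bad <- fold
  bad$test <- c(bad$test, "missing_001")
  expect_error(evaluate_fold(net, bad, env$ds), "missing_001")
})
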