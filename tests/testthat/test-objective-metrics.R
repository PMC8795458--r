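test_that("class weights follow W_c = 1 - n_c/n_t and sum to n-1", {
  cw <- compute_class_weights(c(LGG = 73L, HGG = 259L, HEALTHY = 259L))
  expect_equal(unname(cw$W), c(0.87648, 0.56176, 0.56176),
               tolerance = 1e-5)
  expect_equal(sum(cw$W), 2, tolerance = 1e-12)

  expect_equal(unname(compute_class_weights(c(A = 50, B = 50))$W),
               c(0.5, 0.5))
  expect_warning(w1 <- compute_class_weights(c(A = 10)), "degenerate")
  expect_equal(unname(w1$W), 0)
  expect_error(compute_class_weights(c(A = 0, B = 0)), "> 0")

  set.seed(4)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    counts <- stats::setNames(sample(1:500, k), paste0("c", seq_len(k)))
    expect_equal(sum(compute_class_weights(counts)$W), k - 1,
                 tolerance = 1e-12)
  }
})

test_that("weighted cross-entropy matches direct -W*log-softmax", {
  w <- compute_class_weights(c(LGG = 73L, HGG = 259L, HEALTHY = 259L))
  # certain correct prediction: zero loss
  sure <- c(100, 0, 0)
  lb <- weighted_cross_entropy(sure, "LGG", w)
  expect_equal(lb$total, 0, tolerance = 1e-10)

  # uniform probabilities with unit weights: ln 3
  ones <- stats::setNames(rep(1, 3), CLASS_LEVELS)
  lb2 <- weighted_cross_entropy(c(0, 0, 0), "HGG", ones)
  expect_equal(lb2$total, log(3), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    logits <- rnorm(3, sd = 4)
    lab <- sample(CLASS_LEVELS, 1)
    lb <- weighted_cross_entropy(logits, lab, w)
    expect_equal(lb$total, unname(direct_wce(logits, lab, w$W)),
                 tolerance = 1e-9)
    expect_equal(lb$total, sum(lb$per_class), tolerance = 1e-12)
    # with unit weights it reduces to the standard cross-entropy
    std <- weighted_cross_entropy(logits, lab, ones)
    expect_equal(std$total, unname(direct_wce(logits, lab, ones)),
                 tolerance = 1e-9)
  }
  expect_error(weighted_cross_entropy(c(Inf, 0, 0), "LGG", w),
               "non-finite")
})

test_that("loss gradients wrt logits match central differences", {
  w <- compute_class_weights(c(LGG = 5L, HGG = 7L, HEALTHY = 9L))
  set.seed(5)
  logits <- rnorm(3)
  lb <- weighted_cross_entropy(logits, "HGG", w)
  eps <- 1e-6
  for (j in 1:3) {
    lp <- logits; lp[j] <- lp[j] + eps
    ln <- logits; ln[j] <- ln[j] - eps
    num <- (weighted_cross_entropy(lp, "HGG", w)$total -
            weighted_cross_entropy(ln, "HGG", w)$total) / (2 * eps)
    expect_equal(lb$grad_logits[1, j], num, tolerance = 1e-6)
  }
})

test_that("confusion matrices count true/predicted pairs in fixed order", {
  cm <- confusion(c("LGG", "LGG", "HGG"), c("LGG", "HGG", "HGG"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 3,
                      dimnames = list(true = CLASS_LEVELS,
                                      predicted = CLASS_LEVELS)),
               ignore_attr = FALSE)
  expect_equal(sum(cm), 3L)
  perfect <- confusion(rep(CLASS_LEVELS, 4), rep(CLASS_LEVELS, 4))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(sum(diag(perfect)) / sum(perfect), 1)
  expect_error(confusion(c("LGG", "GBM"), c("LGG", "LGG")), "unknown")
  expect_error(confusion(c("LGG"), c("LGG", "HGG")), "equal length")
})

test_that("classwise metrics reproduce the worked example and edge cases", {
  cm <- matrix(c(8L, 1L, 0L, 2L, 9L, 1L, 0L, 0L, 9L), 3,
               dimnames = list(true = CLASS_LEVELS,
                               predicted = CLASS_LEVELS))
  class(cm) <- c("confusion_matrix", class(cm))
  cwm <- classwise_metrics(cm)
  lgg <- cwm[cwm$class == "LGG", ]
  expect_equal(lgg$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(lgg$recall, 0.8, tolerance = 1e-12)
  expect_equal(lgg$specificity, 0.95, tolerance = 1e-12)
  expect_equal(lgg$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)

  perfect <- confusion(rep(CLASS_LEVELS, 5), rep(CLASS_LEVELS, 5))
  cwp <- classwise_metrics(perfect)
  expect_true(all(cwp[, c("precision", "recall", "specificity", "f1")] == 1))

  # class with zero support and zero predictions: zeros with a warning
  empty <- confusion(c("HGG", "HEALTHY"), c("HGG", "HEALTHY"))
  expect_warning(cwe <- classwise_metrics(empty), "zero denominator")
  lgg0 <- cwe[cwe$class == "LGG", ]
  expect_equal(unlist(lgg0[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("aggregate and classwise metrics agree with brute force", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    truth <- sample(CLASS_LEVELS, n, replace = TRUE)
    pred <- sample(CLASS_LEVELS, n, replace = TRUE)
    cm <- confusion(truth, pred)
    cwm <- suppressWarnings(classwise_metrics(cm))
    for (cl in CLASS_LEVELS) {
      bm <- brute_metrics(truth, pred, cl)
      row <- cwm[cwm$class == cl, ]
      expect_equal(unname(unlist(row[c("precision", "recall",
                                       "specificity", "f1")])),
                   unname(bm), tolerance = 1e-12)
    }
    agg <- suppressWarnings(aggregate_metrics(cm))
    f1s <- vapply(CLASS_LEVELS, function(cl)
      unname(brute_metrics(truth, pred, cl)["f1"]), 0)
    supp <- vapply(CLASS_LEVELS, function(cl) sum(truth == cl), 0)
    expect_equal(agg$macro_f1, mean(f1s), tolerance = 1e-12)
    expect_equal(agg$weighted_f1, sum(supp * f1s) / sum(supp),
                 tolerance = 1e-12)
    expect_equal(agg$accuracy, mean(truth == pred), tolerance = 1e-12)
    # micro-averaged recall equals accuracy
    expect_equal(sum(diag(cm)) / sum(cm), mean(truth == pred))
  }
})

test_that("weighted F1 uses test support as weights", {
  # class F1s (0.5, 0.7, 0.9) with supports (0, 10, 10): macro keeps the
  # unweighted mean; weighted drops the unsupported class
  f1s <- c(0.5, 0.7, 0.9)
  supp <- c(0, 10, 10)
  expect_equal(mean(f1s), 0.7)
  expect_equal(sum(supp * f1s) / sum(supp), 0.8)
})

test_that("fold mean/SD uses the sample (n-1) standard deviation", {
  r <- fold_mean_sd(c(0.8, 0.8, 0.8))
  expect_equal(r$mean, 0.8)
  expect_equal(r$sd, 0)
  r2 <- fold_mean_sd(c(0.7, 0.9))
  expect_equal(r2$mean, 0.8)
  expect_equal(r2$sd, sqrt(0.02), tolerance = 1e-9)
  expect_equal(r2$sd, 0.1414214, tolerance = 1e-6)
  expect_error(fold_mean_sd(0.8), "at least 2")
})
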