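#' Normalised class weights for the weighted cross-entropy loss
#'
#' For class c with `samples_c` training samples out of `samples_t` total,
#' the weight is \eqn{W_c = 1 - samples_c / samples_t}, so
#' under-represented classes receive weights close to 1 and
#' \eqn{\sum_c W_c = n - 1} exactly for n classes.
#'
#' @param class_counts Named nonnegative counts; names from [CLASS_LEVELS]
#'   (or any fixed label set). Unnamed vectors of length 3 are taken in
#'   [CLASS_LEVELS] order.
#' @return A `class_weights` object: list with `W` (named weights),
#'   `class_counts` and `total`.
#' @export
compute_class_weights <- function(class_counts) {
  if (is.null(names(class_counts)) && length(class_counts) == 3L) {
    names(class_counts) <- CLASS_LEVELS
  }
  if (any(class_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(class_counts)
  if (total <= 0) stop("total sample count must be > 0", call. = FALSE)
  w <- 1 - class_counts / total
  if (any(w == 0)) {
    warning("degenerate class weights: a single class holds all samples")
  }
  structure(list(W = w, class_counts = class_counts, total = total),
            class = "class_weights")
}

log_softmax <- function(z) {
  zmax <- max(z)
  z - zmax - log(sum(exp(z - zmax)))
}

#' Weighted cross-entropy loss
#'
#' Class probabilities are obtained by softmax over the logits. For a sample
#' of true class c the per-class loss is \eqn{loss_c = -W_c \log P(c)} (the
#' true distribution is one-hot, so the other per-class terms vanish) and
#' the total loss is the sum of per-class losses; over a batch, per-class
#' losses are the means of the per-sample contributions, so the total equals
#' the mean of per-sample totals.
#'
#' @param logits Numeric vector (one sample) or matrix (batch x classes).
#' @param true_label Class labels, one per row of `logits`; values from the
#'   weight names.
#' @param weights A [compute_class_weights()] result, or a named numeric
#'   vector of weights.
#' @return A `loss_breakdown` list: `per_class` (named), `total`, and
#'   `grad_logits` (gradient of the total wrt the logits, same shape as
#'   `logits` — used by the trainer).
#' @export
weighted_cross_entropy <- function(logits, true_label, weights) {
  if (inherits(weights, "class_weights")) weights <- weights$W
  lv <- names(weights)
  if (is.null(lv)) stop("weights must be named by class", call. = FALSE)
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  if (!all(is.finite(logits))) stop("non-finite logits", call. = FALSE)
  true_label <- as.character(true_label)
  if (length(true_label) != nrow(logits)) {
    stop("one true label per logits row required", call. = FALSE)
  }
  if (!all(true_label %in% lv)) {
    stop("unknown label(s): ",
         paste(setdiff(true_label, lv), collapse = ", "), call. = FALSE)
  }
  b <- nrow(logits)
  per_class <- stats::setNames(numeric(length(lv)), lv)
  grad <- matrix(0, b, ncol(logits))
  for (i in seq_len(b)) {
    ls <- log_softmax(logits[i, ])
    ci <- match(true_label[i], lv)
    w <- weights[[ci]]
    per_class[ci] <- per_class[ci] - w * ls[ci]
    p <- exp(ls)
    g <- w * p
    g[ci] <- g[ci] - w
    grad[i, ] <- g
  }
  per_class <- per_class / b
  grad <- grad / b
  structure(list(per_class = per_class, total = sum(per_class),
                 grad_logits = grad),
            class = "loss_breakdown")
}

#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class, both in the fixed
#' order of `levels`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param levels Class order (default [CLASS_LEVELS]).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      levels = CLASS_LEVELS) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), levels)
  if (length(bad)) {
    stop("unknown label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(true_labels, levels = levels),
              factor(predicted_labels, levels = levels))
  cm <- matrix(as.integer(cm), nrow = length(levels),
               dimnames = list(true = levels, predicted = levels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class one-vs-rest metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), specificity TN/(TN+FP) and F1
#' (harmonic mean of precision and recall) for each class of a confusion
#' matrix, treating that class as positive and all others as negative.
#' Zero-denominator cases yield 0 with a warning.
#'
#' @param cm A [confusion()] matrix.
#' @return `data.frame` with one row per class: `class`, `support`,
#'   `precision`, `recall`, `specificity`, `f1`.
#' @export
classwise_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") ||
              (is.matrix(cm) && nrow(cm) == ncol(cm)))
  lv <- rownames(cm)
  total <- sum(cm)
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      warning("zero denominator for ", what, " of class ", cls,
              "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    prec <- safe_div(tp, tp + fp, "precision", lv[i])
    rec <- safe_div(tp, tp + fn, "recall", lv[i])
    spec <- safe_div(tn, tn + fp, "specificity", lv[i])
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
      warning("zero denominator for F1 of class ", lv[i], "; reporting 0",
              call. = FALSE)
      0
    }
    data.frame(class = lv[i], support = sum(cm[i, ]), precision = prec,
               recall = rec, specificity = spec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consolidated metrics of a confusion matrix
#'
#' Macro F1 (unweighted mean of per-class F1), weighted F1 (mean weighted by
#' true-class support) and accuracy (trace over total).
#'
#' @param cm A [confusion()] matrix.
#' @return List with `macro_f1`, `weighted_f1`, `accuracy`.
#' @export
aggregate_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  cwm <- classwise_metrics(cm)
  list(macro_f1 = mean(cwm$f1),
       weighted_f1 = sum(cwm$support * cwm$f1) / sum(cwm$support),
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Mean and standard deviation over folds
#'
#' @param values Numeric vector of per-fold values (length >= 2).
#' @return List with `mean` and `sd` (sample SD, n-1 denominator).
#' @export
fold_mean_sd <- function(values) {
  if (length(values) < 2) {
    stop("need at least 2 fold values", call. = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows: true, cols: predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.4f\n", sum(diag(x)) / sum(x)))
  invisible(x)
}
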