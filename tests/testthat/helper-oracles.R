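# Independent test oracles, kept deliberately separate from the package's
# own code paths.

# Two-feature rule classifier for phantom volumes: (1) the maximum intensity
# inside the brain (nonzero) region decides lesion presence; (2) the minimum
# intensity around the centroid of the hyperintense region separates a
# rimmed lesion with a dark core (HGG) from a homogeneous bright one (LGG).
# By construction the hyperintense voxels of a phantom form the single
# lesion's bright region.
rule_classify <- function(v, spec) {
  vox <- v$voxels
  brain <- vox > 0
  bright_thr <- spec$brain_mean + spec$lgg_contrast / 2
  if (max(vox[brain]) < bright_thr) return("HEALTHY")
  bright <- which(vox >= bright_thr, arr.ind = TRUE)
  ctr <- round(colMeans(bright))
  dims <- dim(vox)
  nb <- rbind(ctr, ctr + c(1, 0, 0), ctr - c(1, 0, 0), ctr + c(0, 1, 0),
              ctr - c(0, 1, 0), ctr + c(0, 0, 1), ctr - c(0, 0, 1))
  nb <- nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
             nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3], ,
           drop = FALSE]
  core_min <- min(vox[nb])
  if (core_min < spec$brain_mean - spec$hgg_core_contrast / 2) "HGG"
  else "LGG"
}

# Slow reference 3D convolution (channels-last input, (out, in*K) weights
# with kernel offset fastest / slice offset innermost).
ref_conv3d <- function(x, wm, k, s, p) {
  d <- dim(x)
  C <- d[4]
  K <- prod(k)
  cout <- nrow(wm)
  od <- (d[1:3] + 2 * p - k) %/% s + 1
  xp <- array(0, c(d[1:3] + 2 * p, C))
  xp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), ] <- x
  y <- array(0, c(od, cout))
  for (co in seq_len(cout)) {
    for (dd in seq_len(od[1])) for (hh in seq_len(od[2])) {
      for (ww in seq_len(od[3])) {
        acc <- 0
        for (cc in seq_len(C)) {
          for (okw in seq_len(k[3])) for (okh in seq_len(k[2])) {
            for (okd in seq_len(k[1])) {
              o <- (okd - 1) + k[1] * ((okh - 1) + k[2] * (okw - 1))
              acc <- acc + wm[co, o + K * (cc - 1) + 1] *
                xp[(dd - 1) * s[1] + okd, (hh - 1) * s[2] + okh,
                   (ww - 1) * s[3] + okw, cc]
            }
          }
        }
        y[dd, hh, ww, co] <- acc
      }
    }
  }
  y
}

# Brute-force classwise metrics from raw label vectors (one-vs-rest).
brute_metrics <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  tn <- sum(truth != cls & pred != cls)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, specificity = spec, f1 = f1)
}

# Direct weighted cross-entropy: -W_c * log softmax(logits)[c].
# Closed form -w log softmax(l)_c = w log(1 + sum_{j != c} exp(l_j - l_c)),
# written with log1p so the oracle keeps full precision even when the loss
# itself is ~0 (true-class logit dominant), where log(sum(exp(...))) loses
# |loss|/eps_mach relative digits to cancellation.
direct_wce <- function(logits, label, w) {
  ci <- match(label, names(w))
  w[[ci]] * log1p(sum(exp(logits[-ci] - logits[ci])))
}
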