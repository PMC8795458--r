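#' A single-channel 3D volume with voxel spacing
#'
#' @param voxels 3D numeric array in (slice, row, col) order; all values
#'   finite.
#' @param spacing_mm Positive triple, mm per voxel along each axis.
#' @param subject_id Character identifier.
#' @param label Optional class label from [CLASS_LEVELS].
#' @return Object of class `volume_sample`.
#' @export
volume_sample <- function(voxels, spacing_mm, subject_id = "",
                          label = NULL) {
  if (length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(voxels))) {
    stop("voxels must be finite", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be a positive triple", call. = FALSE)
  }
  if (!is.null(label)) label <- match.arg(toupper(label), CLASS_LEVELS)
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 subject_id = subject_id, label = label),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample> %s  %s voxels @ %s mm  label: %s\n",
              x$subject_id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              x$label %||% "<none>"))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param label Optional class label to attach.
#' @param subject_id Identifier; defaults to the file name stem.
#' @return A [volume_sample()]; spacing is taken from the header. Axes are
#'   used in stored order, interpreted as (slice, row, col); datasets
#'   written by [make_dataset()]/[write_volume()] follow this convention.
#' @export
read_volume <- function(path, label = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  if (length(dm) != 3L) {
    stop("expected a 3D volume, got ", length(dm), "D: ", path,
         call. = FALSE)
  }
  vox <- array(as.numeric(img), dm)  # plain array, no NIfTI attributes
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume_sample(vox, spacing, subject_id = subject_id, label = label)
}

#' Write a NIfTI volume
#'
#' @param v A [volume_sample()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_sample"))
  vox <- v$voxels
  attributes(vox) <- list(dim = dim(vox))
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- v$spacing_mm
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    stop("failed to write NIfTI file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Load all volumes referenced by a manifest
#'
#' @param manifest A manifest `data.frame` from [read_manifest()], or a path
#'   accepted by it.
#' @param dir Directory the manifest paths are relative to (defaults to the
#'   manifest's own directory).
#' @return Named list of [volume_sample()]s keyed by subject id, labels
#'   joined from the manifest.
#' @export
load_dataset <- function(manifest, dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- dir %||% attr(manifest, "dir")
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$subject_id
  for (i in seq_len(nrow(manifest))) {
    fp <- file.path(dir, manifest$path[i])
    if (!file.exists(fp)) {
      stop("volume for subject '", manifest$subject_id[i],
           "' not found: ", fp, call. = FALSE)
    }
    out[[i]] <- read_volume(fp, label = manifest$label[i],
                            subject_id = manifest$subject_id[i])
  }
  out
}

#' Percentile intensity scaling
#'
#' Clips intensities to the `[lo_pct, hi_pct]` percentile range computed
#' over all voxels of the volume, then maps that range affinely onto
#' \eqn{[0, 1]} (or standardises it, with `method = "zscore"`). The
#' operation is monotone and invariant to positive affine transforms of the
#' input intensities.
#'
#' @param v A [volume_sample()].
#' @param lo_pct,hi_pct Percentiles in \[0, 100\].
#' @param method `"rescale"` (clip then min-max to \[0,1\], the default) or
#'   `"zscore"` (clip then subtract mean / divide by SD).
#' @return The rescaled [volume_sample()].
#' @export
percentile_clip_scale <- function(v, lo_pct = 0.5, hi_pct = 99.5,
                                  method = c("rescale", "zscore")) {
  stopifnot(inherits(v, "volume_sample"), lo_pct < hi_pct,
            lo_pct >= 0, hi_pct <= 100)
  method <- match.arg(method)
  q <- stats::quantile(v$voxels, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[1] >= q[2]) {
    stop("degenerate volume: percentiles P", lo_pct, " and P", hi_pct,
         " coincide", call. = FALSE)
  }
  x <- pmin(pmax(v$voxels, q[1]), q[2])
  if (method == "rescale") {
    x <- (x - q[1]) / (q[2] - q[1])
  } else {
    x <- (x - mean(x)) / stats::sd(x)
  }
  dim(x) <- dim(v$voxels)
  v$voxels <- x
  v
}

# Output grid size when resampling: round-half-up of the physical extent
# divided by the target spacing.
resampled_dim <- function(dims, spacing_mm, target_mm) {
  as.integer(round_half_up(dims * spacing_mm / target_mm))
}

#' Resample a volume to isotropic voxel spacing
#'
#' Trilinear interpolation onto a grid with `target_mm` spacing along every
#' axis; the output extent per axis is `round_half_up(dim * spacing /
#' target)`. Voxel centres are aligned so that resampling at the native
#' spacing is the identity; border samples are clamped, so output
#' intensities stay within the input range.
#'
#' @param v A [volume_sample()].
#' @param target_mm Target isotropic spacing (default 2 mm).
#' @return The resampled [volume_sample()] with spacing
#'   `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(v, target_mm = 2.0) {
  stopifnot(inherits(v, "volume_sample"), target_mm > 0)
  dims <- dim(v$voxels)
  od <- resampled_dim(dims, v$spacing_mm, target_mm)
  if (any(od < 1L)) {
    stop("resampling to ", target_mm, " mm collapses the grid (",
         paste(od, collapse = "x"), ")", call. = FALSE)
  }
  if (all(abs(v$spacing_mm - target_mm) < 1e-12)) {
    v$spacing_mm <- rep(target_mm, 3)
    return(v)
  }
  # voxel-centre alignment: output centre i maps to input coordinate
  # (i + 0.5) * target / spacing - 0.5 (0-based)
  co <- lapply(1:3, function(a) {
    (seq_len(od[a]) - 0.5) * target_mm / v$spacing_mm[a] - 0.5
  })
  grid <- expand.grid(d = co[[1]], h = co[[2]], w = co[[3]])
  out <- trilinear3d(v$voxels, dims, grid$d, grid$h, grid$w,
                     clamp = TRUE, fill = 0)
  dim(out) <- od
  v$voxels <- out
  v$spacing_mm <- rep(target_mm, 3)
  v
}

#' Light augmentation policy
#'
#' The training-time augmentation: a random affine transform (isotropic
#' scale in `scale_range`, rotations up to `rotation_max_degrees` about each
#' axis) followed by a random left-right flip with probability
#' `flip_probability`. Applied on the fly during training only; evaluation
#' always sees unaugmented volumes.
#'
#' @param scale_range Isotropic scale bounds (default 0.9-1.2).
#' @param rotation_max_degrees Per-axis rotation bound in degrees
#'   (default 10).
#' @param flip_probability Probability of reversing the left-right (column)
#'   axis (default 0.25).
#' @param enabled If `FALSE`, [augment_volume()] is the identity.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(scale_range = c(0.9, 1.2),
                                rotation_max_degrees = 10,
                                flip_probability = 0.25, enabled = TRUE) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            scale_range[1] > 0, rotation_max_degrees >= 0,
            flip_probability >= 0, flip_probability <= 1)
  structure(list(scale_range = scale_range,
                 rotation_max_degrees = rotation_max_degrees,
                 flip_probability = flip_probability,
                 enabled = isTRUE(enabled)),
            class = "augmentation_policy")
}

#' Random left-right flip
#'
#' With probability `p` (drawn from the current RNG stream) the column axis
#' — the left-right axis under this package's (slice, row, col) convention —
#' is reversed; otherwise the volume is returned unchanged.
#'
#' @param v A [volume_sample()].
#' @param p Flip probability.
#' @return A [volume_sample()] of identical shape and spacing.
#' @export
random_flip_lr <- function(v, p = 0.25) {
  stopifnot(inherits(v, "volume_sample"), p >= 0, p <= 1)
  if (p > 0 && stats::runif(1) < p) {
    v$voxels <- v$voxels[, , rev(seq_len(dim(v$voxels)[3])), drop = FALSE]
  }
  v
}

# Physical (mm) coordinates of all voxel centres relative to the volume
# centre, memoised per (dims, spacing): rebuilt grids dominate augmentation
# cost otherwise.
grid_cache <- new.env(parent = emptyenv())
centred_grid_mm <- function(dims, spacing_mm) {
  key <- paste(c(dims, signif(spacing_mm, 12)), collapse = "_")
  hit <- grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  ctr <- (dims + 1) / 2
  g <- cbind(
    rep.int(seq_len(dims[1]) - ctr[1], dims[2] * dims[3]) * spacing_mm[1],
    rep.int(rep(seq_len(dims[2]) - ctr[2], each = dims[1]), dims[3]) *
      spacing_mm[2],
    rep(seq_len(dims[3]) - ctr[3], each = dims[1] * dims[2]) * spacing_mm[3]
  )
  grid_cache[[key]] <- g
  g
}

# Rotation matrix about the three axes (degrees), applied as Rz %*% Ry %*% Rx
# in physical (mm) coordinates.
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Random affine augmentation
#'
#' Draws an isotropic scale from `policy$scale_range` and one rotation angle
#' per axis from `[-rotation_max_degrees, +rotation_max_degrees]`, applies
#' the transform about the volume centre in physical coordinates, and
#' resamples trilinearly back onto the original grid. The output shape and
#' spacing equal the input's; voxels mapped from outside the field of view
#' are 0.
#'
#' @param v A [volume_sample()].
#' @param policy An [augmentation_policy()].
#' @param scale,angles_deg Optional fixed overrides (mainly for testing);
#'   when `NULL` they are drawn from the current RNG stream.
#' @return The transformed [volume_sample()].
#' @export
random_affine <- function(v, policy = augmentation_policy(), scale = NULL,
                          angles_deg = NULL) {
  stopifnot(inherits(v, "volume_sample"),
            inherits(policy, "augmentation_policy"))
  if (is.null(scale)) {
    scale <- stats::runif(1, policy$scale_range[1], policy$scale_range[2])
  }
  if (is.null(angles_deg)) {
    angles_deg <- stats::runif(3, -policy$rotation_max_degrees,
                               policy$rotation_max_degrees)
  }
  dims <- dim(v$voxels)
  amat <- rotation_matrix(angles_deg) * scale
  ainv <- solve(amat)
  ctr <- (dims + 1) / 2
  # output voxel -> physical offset from centre -> inverse map -> input voxel
  phys <- centred_grid_mm(dims, v$spacing_mm)
  src <- phys %*% t(ainv)
  cd <- src[, 1] / v$spacing_mm[1] + ctr[1] - 1
  chh <- src[, 2] / v$spacing_mm[2] + ctr[2] - 1
  cww <- src[, 3] / v$spacing_mm[3] + ctr[3] - 1
  out <- trilinear3d(v$voxels, dims, cd, chh, cww, clamp = FALSE, fill = 0)
  dim(out) <- dims
  v$voxels <- out
  v
}

#' Apply the light augmentation pipeline to one volume
#'
#' Random affine followed by random left-right flip, drawing from the
#' current RNG stream; identity when the policy is disabled. Shape, spacing
#' and label are always preserved.
#'
#' @param v A [volume_sample()].
#' @param policy An [augmentation_policy()].
#' @return The augmented [volume_sample()].
#' @export
augment_volume <- function(v, policy = augmentation_policy()) {
  if (!policy$enabled) return(v)
  v <- random_affine(v, policy)
  random_flip_lr(v, policy$flip_probability)
}

#' Preprocess one volume
#'
#' The standard preprocessing chain: percentile intensity scaling
#' ([percentile_clip_scale()]) followed by isotropic resampling
#' ([resample_isotropic()]).
#'
#' @param v A [volume_sample()].
#' @param lo_pct,hi_pct Percentiles for intensity scaling.
#' @param target_mm Target isotropic spacing.
#' @param method Intensity scaling method, see [percentile_clip_scale()].
#' @return The preprocessed [volume_sample()].
#' @export
preprocess_volume <- function(v, lo_pct = 0.5, hi_pct = 99.5,
                              target_mm = 2.0, method = "rescale") {
  resample_isotropic(percentile_clip_scale(v, lo_pct, hi_pct, method),
                     target_mm)
}

#' Preprocess every volume in a manifest
#'
#' Reads each volume, applies [preprocess_volume()], writes the result to
#' `out_dir` and emits an updated manifest there. Sample count and labels
#' are unchanged.
#'
#' @param manifest Manifest `data.frame` or path ([read_manifest()]).
#' @param out_dir Output directory.
#' @inheritParams preprocess_volume
#' @return Invisibly, the new manifest `data.frame`.
#' @export
preprocess_dataset <- function(manifest, out_dir, lo_pct = 0.5,
                               hi_pct = 99.5, target_mm = 2.0,
                               method = "rescale") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  src_dir <- attr(manifest, "dir")
  for (i in seq_len(nrow(manifest))) {
    v <- read_volume(file.path(src_dir, manifest$path[i]),
                     label = manifest$label[i],
                     subject_id = manifest$subject_id[i])
    v <- preprocess_volume(v, lo_pct, hi_pct, target_mm, method)
    manifest$path[i] <- paste0(manifest$subject_id[i], ".nii.gz")
    write_volume(v, file.path(out_dir, manifest$path[i]))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}
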