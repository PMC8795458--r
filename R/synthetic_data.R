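#' Phantom-volume generation parameters
#'
#' Describes a family of skull-free phantom brain volumes with
#' class-dependent lesion structure, separable by construction:
#' \describe{
#'   \item{HEALTHY}{elliptical "brain" tissue plus noise, no lesion.}
#'   \item{LGG}{one homogeneous hyperintense ball inside the brain, mimicking
#'     a contrast-enhancing low-grade lesion.}
#'   \item{HGG}{one ball with a hypointense (necrotic) core and a
#'     hyperintense (actively enhancing) rim, the structure that
#'     distinguishes high-grade glioma on contrast-enhanced T1.}
#' }
#' Tissue texture and acquisition noise are Gaussian, truncated at 2
#' standard deviations so that the class margins hold deterministically
#' (maximum intensity deviation inside the brain is
#' `2 * (brain_sd + noise_sd)`, below half the lesion contrasts at the
#' defaults). Default lesion radii correspond to typical clinical sizes at
#' 2 mm spacing (LGG 2.4-4 cm diameter, HGG 3.2-5.2 cm), large enough that
#' an enhancing lesion occupies an appreciable share of the volume's upper
#' intensity tail, as it does in real contrast-enhanced T1.
#'
#' @param volume_shape Integer triple (slice, row, col) in voxels.
#' @param voxel_spacing_mm Positive triple, mm per voxel.
#' @param n_per_class Named counts, names from [CLASS_LEVELS].
#' @param brain_axes_frac Fraction of the volume extent occupied by the
#'   brain ellipsoid along each axis, in (0, 1].
#' @param brain_mean,brain_sd Brain-tissue intensity mean and texture SD
#'   (arbitrary units).
#' @param lgg_radius_range,hgg_radius_range Lesion radius bounds in voxels.
#' @param lgg_contrast Additive intensity of the LGG ball (positive).
#' @param hgg_rim_contrast Additive intensity of the HGG rim (positive).
#' @param hgg_core_contrast Subtractive depth of the HGG necrotic core
#'   (positive; core intensity is `brain_mean - hgg_core_contrast`).
#' @param noise_sd Acquisition noise SD.
#' @param seed Integer; fixed spec + seed reproduce bit-identical volumes.
#'
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(volume_shape = c(64L, 64L, 64L),
                           voxel_spacing_mm = c(2, 2, 2),
                           n_per_class = c(LGG = 60L, HGG = 60L,
                                           HEALTHY = 60L),
                           brain_axes_frac = c(0.85, 0.85, 0.85),
                           brain_mean = 0.5, brain_sd = 0.02,
                           lgg_radius_range = c(6, 10),
                           hgg_radius_range = c(8, 13),
                           lgg_contrast = 0.30, hgg_rim_contrast = 0.35,
                           hgg_core_contrast = 0.25, noise_sd = 0.05,
                           seed = 42L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            all(brain_axes_frac > 0), all(brain_axes_frac <= 1),
            brain_sd >= 0, noise_sd >= 0,
            lgg_contrast > 0, hgg_rim_contrast > 0, hgg_core_contrast > 0,
            diff(lgg_radius_range) >= 0, diff(hgg_radius_range) >= 0,
            all(lgg_radius_range > 0), all(hgg_radius_range > 0))
  if (is.null(names(n_per_class))) names(n_per_class) <- CLASS_LEVELS
  if (!all(names(n_per_class) %in% CLASS_LEVELS)) {
    stop("n_per_class names must be among ", paste(CLASS_LEVELS,
                                                   collapse = ", "),
         call. = FALSE)
  }
  if (any(n_per_class < 0)) stop("class counts must be >= 0", call. = FALSE)
  semi_axes <- brain_axes_frac * volume_shape / 2
  if (max(lgg_radius_range, hgg_radius_range) >= min(semi_axes) - 1) {
    stop("lesion radius range infeasible for the brain ellipsoid size",
         call. = FALSE)
  }
  structure(list(volume_shape = volume_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_per_class = n_per_class,
                 brain_axes_frac = brain_axes_frac,
                 brain_mean = brain_mean, brain_sd = brain_sd,
                 lgg_radius_range = lgg_radius_range,
                 hgg_radius_range = hgg_radius_range,
                 lgg_contrast = lgg_contrast,
                 hgg_rim_contrast = hgg_rim_contrast,
                 hgg_core_contrast = hgg_core_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Squared normalised ellipsoid coordinate of every voxel (1 on the surface),
# for an ellipsoid centred in the volume with the given semi-axes (voxels).
ellipsoid_dist2 <- function(shape, semi_axes) {
  ctr <- (shape + 1) / 2
  u1 <- ((seq_len(shape[1]) - ctr[1]) / semi_axes[1])^2
  u2 <- ((seq_len(shape[2]) - ctr[2]) / semi_axes[2])^2
  u3 <- ((seq_len(shape[3]) - ctr[3]) / semi_axes[3])^2
  outer(outer(u1, u2, `+`), u3, `+`)
}

# Truncated Gaussian draw (inverse-CDF, strictly within k standard
# deviations; smooth, no probability mass at the bounds).
rnorm_trunc <- function(n, sd, k = 2) {
  if (sd == 0) return(numeric(n))
  stats::qnorm(stats::runif(n, stats::pnorm(-k), stats::pnorm(k))) * sd
}

#' Generate one labelled phantom volume
#'
#' Background is exactly 0 outside the brain ellipsoid. HEALTHY volumes are
#' brain tissue plus noise only; LGG volumes add one homogeneous
#' hyperintense ball; HGG volumes add one ball whose inner half-radius core
#' is hypointense and whose outer shell is hyperintense. The lesion centre
#' is sampled uniformly inside the brain ellipsoid eroded by the lesion
#' radius, so lesions always lie fully within brain tissue.
#'
#' @param label One of [CLASS_LEVELS].
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this volume (defaults to the spec's).
#' @return A [volume_sample()] carrying the spec's spacing and the label.
#'   The attribute `"lesion_mask"` on the voxel array holds the generator's
#'   own lesion mask (logical), `NULL`-equivalent (all `FALSE`) for HEALTHY.
#' @export
make_volume <- function(label, spec, seed = spec$seed) {
  label <- match.arg(toupper(label), CLASS_LEVELS)
  stopifnot(inherits(spec, "synthetic_spec"))
  shape <- spec$volume_shape
  semi_axes <- spec$brain_axes_frac * shape / 2
  with_seed(seed, function() {
    d2 <- ellipsoid_dist2(shape, semi_axes)
    brain <- d2 <= 1
    n_brain <- sum(brain)
    vox <- array(0, shape)
    vox[brain] <- spec$brain_mean +
      rnorm_trunc(n_brain, spec$brain_sd) +
      rnorm_trunc(n_brain, spec$noise_sd)
    lesion <- array(FALSE, shape)
    if (label != "HEALTHY") {
      rng <- if (label == "LGG") spec$lgg_radius_range else
        spec$hgg_radius_range
      radius <- stats::runif(1, rng[1], rng[2])
      ctr <- (shape + 1) / 2
      eroded <- pmax(semi_axes - radius, 1e-6)
      # rejection-sample a centre uniformly inside the eroded ellipsoid
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      centre <- ctr + u * eroded
      g1 <- (seq_len(shape[1]) - centre[1])^2
      g2 <- (seq_len(shape[2]) - centre[2])^2
      g3 <- (seq_len(shape[3]) - centre[3])^2
      r2 <- outer(outer(g1, g2, `+`), g3, `+`)
      lesion <- r2 <= radius^2
      if (label == "LGG") {
        vox[lesion] <- vox[lesion] + spec$lgg_contrast
      } else {
        core <- r2 <= (radius / 2)^2
        rim <- lesion & !core
        vox[rim] <- vox[rim] + spec$hgg_rim_contrast
        vox[core] <- spec$brain_mean - spec$hgg_core_contrast +
          rnorm_trunc(sum(core), spec$noise_sd)
      }
    }
    v <- volume_sample(vox, spec$voxel_spacing_mm,
                       subject_id = sprintf("%s_seed%d", tolower(label),
                                            seed),
                       label = label)
    attr(v$voxels, "lesion_mask") <- lesion
    v
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes one gzipped NIfTI file per sample plus a manifest CSV with header
#' `subject_id,path,label` (paths relative to `out_dir`). Per-sample seeds
#' are derived deterministically from `spec$seed`, so the same spec and seed
#' reproduce identical voxel data.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest `data.frame`; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
make_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- list()
  idx <- 0L
  for (label in CLASS_LEVELS) {
    n <- spec$n_per_class[[label]] %||% 0L
    for (i in seq_len(n)) {
      idx <- idx + 1L
      v <- make_volume(label, spec, seed = derive_seed(spec$seed, idx))
      sid <- sprintf("%s_%03d", tolower(label), i)
      v$subject_id <- sid
      fn <- paste0(sid, ".nii.gz")
      write_volume(v, file.path(out_dir, fn))
      rows[[idx]] <- data.frame(subject_id = sid, path = fn, label = label,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV (`subject_id,path,label`) or a directory
#'   containing `manifest.csv`.
#' @return `data.frame` with an attribute `"dir"` holding the directory the
#'   `path` column is relative to.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(m$label), CLASS_LEVELS)
  if (length(bad)) {
    stop("unknown labels in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  attr(m, "dir") <- dirname(path)
  m
}
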