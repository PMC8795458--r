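# Shared fixtures. Unit tests use small phantom volumes (24^3) so the suite
# stays fast; the end-to-end acceptance run uses the full default spec.

tiny_spec <- function(n = 2L, seed = 11L) {
  synthetic_spec(volume_shape = c(24L, 24L, 24L),
                 n_per_class = c(LGG = n, HGG = n, HEALTHY = n),
                 lgg_radius_range = c(3, 4), hgg_radius_range = c(3.5, 5),
                 seed = seed)
}

# Built-once-per-session tiny dataset of preprocessed volumes.
tiny_dataset_env <- new.env()
tiny_dataset <- function() {
  if (is.null(tiny_dataset_env$ds)) {
    spec <- tiny_spec()
    dir <- file.path(tempdir(), "resvol-tiny")
    tiny_dataset_env$manifest <- make_dataset(spec, dir)
    tiny_dataset_env$ds <- lapply(load_dataset(tiny_dataset_env$manifest),
                                  preprocess_volume)
    tiny_dataset_env$spec <- spec
  }
  tiny_dataset_env
}

all_train_fold <- function(manifest) {
  structure(list(fold_index = 1L, train = manifest$subject_id,
                 test = manifest$subject_id, seed = 1L),
            class = "fold_split")
}

random_volume <- function(dims = c(12L, 13L, 14L), spacing = c(2, 2, 2)) {
  volume_sample(array(stats::rnorm(prod(dims)), dims), spacing,
                subject_id = "rand")
}
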