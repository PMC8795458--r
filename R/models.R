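#' Architecture kinds
#'
#' The three 18-layer residual architectures for single-channel 3D volumes:
#' `"RESNET3D"` (full 3D convolutions throughout), `"RESNET_2P1D"` (every 3D
#' convolution factorized into an in-plane 2D convolution followed by a
#' slice-axis 1D convolution, with batch-norm + ReLU between), and
#' `"RESNET_MIXED"` (3D stem and first stage, in-plane 2D stages 2-4).
#'
#' @export
ARCHITECTURE_KINDS <- c("RESNET3D", "RESNET_2P1D", "RESNET_MIXED")

#' Network configuration
#'
#' @param kind One of [ARCHITECTURE_KINDS].
#' @param in_channels Input channels (1 for single-contrast MRI).
#' @param n_classes Number of output classes (LGG, HGG, HEALTHY = 3).
#' @param dropout_p Dropout probability before the fully connected head.
#' @param width Channel width of the first stage; stages use
#'   `width * c(1, 2, 4, 8)` (the reference design has `width = 64`, i.e.
#'   stage widths 64/128/256/512). Smaller values give width-reduced variants
#'   for CPU-scale experiments.
#' @param stem_midplanes Intermediate channel count of the (2+1)D stem
#'   (45 at full width, scaled proportionally otherwise). Ignored by the
#'   other architectures.
#' @param zero_init_residual Initialise the final batch-norm scale of every
#'   residual block to zero, so blocks start as identities and the residual
#'   branches fade in during optimisation (helps short training schedules;
#'   parameter counts are unaffected).
#' @param seed Integer seed for weight initialization.
#'
#' @return A `network_config` list.
#' @export
network_config <- function(kind = c("RESNET_MIXED", "RESNET_2P1D", "RESNET3D"),
                           in_channels = 1L, n_classes = 3L, dropout_p = 0.3,
                           width = 64L, stem_midplanes = NULL,
                           zero_init_residual = TRUE, seed = 42L) {
  kind <- match.arg(toupper(kind), ARCHITECTURE_KINDS)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (in_channels < 1L) stop("in_channels must be >= 1", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must be in [0, 1)", call. = FALSE)
  }
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  if (is.null(stem_midplanes)) {
    stem_midplanes <- max(1L, as.integer(round(45 * width / 64)))
  }
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), dropout_p = dropout_p,
                 width = as.integer(width),
                 stage_widths = as.integer(width) * c(1L, 2L, 4L, 8L),
                 blocks_per_stage = c(2L, 2L, 2L, 2L),
                 stem_midplanes = as.integer(stem_midplanes),
                 zero_init_residual = isTRUE(zero_init_residual),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Intermediate width of a (2+1)D factorized convolution
#'
#' A 3D convolution with `n_in` input and `n_out` output channels and kernel
#' `t x d x d` is factorized into an in-plane `1 x d x d` convolution to `M`
#' channels followed by a slice-axis `t x 1 x 1` convolution to `n_out`
#' channels. `M` is chosen so that the factorized pair has approximately the
#' same number of weights as the original 3D kernel:
#' `M = floor(t d^2 n_in n_out / (d^2 n_in + t n_out))`.
#'
#' Within a residual block the width is computed once from the block's
#' input/output channel pair and shared by both of its convolutions.
#'
#' @param n_in,n_out Channel counts.
#' @param t Slice-axis kernel extent (default 3).
#' @param d In-plane kernel extent (default 3).
#' @return Integer intermediate channel count.
#' @export
midplanes_2p1d <- function(n_in, n_out, t = 3L, d = 3L) {
  stopifnot(n_in >= 1, n_out >= 1)
  as.integer((t * d^2 * n_in * n_out) %/% (d^2 * n_in + t * n_out))
}

# One conv "unit": a plain conv for 3D/2D modes, or the factorized
# 2D -> BN -> ReLU -> 1D sequence for (2+1)D mode.
make_conv_unit <- function(mode, in_ch, out_ch, stride, midplanes = NULL,
                           name = "conv") {
  if (mode == "3D") {
    nn_conv3d(in_ch, out_ch, c(3L, 3L, 3L), stride, c(1L, 1L, 1L),
              conv_mode = "3D", name = name)
  } else if (mode == "2D") {
    nn_conv3d(in_ch, out_ch, c(1L, 3L, 3L), stride, c(0L, 1L, 1L),
              conv_mode = "2D", name = name)
  } else if (mode == "2P1D") {
    mid <- midplanes
    nn_seq(list(
      conv2d = nn_conv3d(in_ch, mid, c(1L, 3L, 3L),
                         c(1L, stride[2], stride[3]), c(0L, 1L, 1L),
                         conv_mode = "2D", name = paste0(name, ".conv2d")),
      bn_mid = nn_bn3d(mid, name = paste0(name, ".bn_mid")),
      relu_mid = nn_relu(),
      conv1d = nn_conv3d(mid, out_ch, c(3L, 1L, 1L),
                         c(stride[1], 1L, 1L), c(1L, 0L, 0L),
                         conv_mode = "1D", name = paste0(name, ".conv1d"))
    ), name = name)
  } else {
    stop("unknown conv mode: ", mode)
  }
}

make_basic_block <- function(mode, in_ch, out_ch, downsample, name,
                             zero_init_residual = TRUE) {
  stride1 <- if (downsample) {
    if (mode == "2D") c(1L, 2L, 2L) else c(2L, 2L, 2L)
  } else {
    c(1L, 1L, 1L)
  }
  mid <- if (mode == "2P1D") midplanes_2p1d(in_ch, out_ch) else NULL
  main <- nn_seq(list(
    conv1 = make_conv_unit(mode, in_ch, out_ch, stride1, mid,
                           paste0(name, ".conv1")),
    bn1 = nn_bn3d(out_ch, name = paste0(name, ".bn1")),
    relu1 = nn_relu(),
    conv2 = make_conv_unit(mode, out_ch, out_ch, c(1L, 1L, 1L), mid,
                           paste0(name, ".conv2")),
    bn2 = nn_bn3d(out_ch, name = paste0(name, ".bn2"))
  ), name = paste0(name, ".main"))
  if (zero_init_residual) {
    # start each block as (a projection of) the identity: residual branches
    # fade in during training, which stabilises short schedules
    main$children$bn2$params$gamma <- rep(0, out_ch)
  }
  shortcut <- NULL
  if (downsample) {
    shortcut <- nn_seq(list(
      conv = nn_conv3d(in_ch, out_ch, c(1L, 1L, 1L), stride1, c(0L, 0L, 0L),
                       conv_mode = "3D", name = paste0(name, ".downsample")),
      bn = nn_bn3d(out_ch, name = paste0(name, ".downsample.bn"))
    ), name = paste0(name, ".shortcut"))
  }
  nn_block(main, shortcut, name = name)
}

mark_root <- function(conv) {
  conv$root_input <- TRUE
  conv
}

make_stem <- function(cfg) {
  if (cfg$kind == "RESNET_2P1D") {
    nn_seq(list(
      conv2d = mark_root(
        nn_conv3d(cfg$in_channels, cfg$stem_midplanes, c(1L, 7L, 7L),
                  c(1L, 2L, 2L), c(0L, 3L, 3L), conv_mode = "2D",
                  name = "stem.conv2d")),
      bn2d = nn_bn3d(cfg$stem_midplanes, name = "stem.bn2d"),
      relu2d = nn_relu(),
      conv1d = nn_conv3d(cfg$stem_midplanes, cfg$stage_widths[1],
                         c(3L, 1L, 1L), c(1L, 1L, 1L), c(1L, 0L, 0L),
                         conv_mode = "1D", name = "stem.conv1d"),
      bn1d = nn_bn3d(cfg$stage_widths[1], name = "stem.bn1d"),
      relu1d = nn_relu()
    ), name = "stem")
  } else {
    nn_seq(list(
      conv = mark_root(
        nn_conv3d(cfg$in_channels, cfg$stage_widths[1], c(3L, 7L, 7L),
                  c(1L, 2L, 2L), c(1L, 3L, 3L), conv_mode = "3D",
                  name = "stem.conv")),
      bn = nn_bn3d(cfg$stage_widths[1], name = "stem.bn"),
      relu = nn_relu()
    ), name = "stem")
  }
}

#' Per-stage convolution modes of an architecture
#'
#' @param kind One of [ARCHITECTURE_KINDS].
#' @return Character vector of length 4, entries in `c("3D", "2D", "2P1D")`.
#' @export
stage_conv_modes <- function(kind) {
  switch(kind,
         RESNET3D = rep("3D", 4),
         RESNET_MIXED = c("3D", "2D", "2D", "2D"),
         RESNET_2P1D = rep("2P1D", 4),
         stop("unknown architecture kind: ", kind))
}

#' Build a residual classification network
#'
#' Constructs one of the three architectures: a kind-specific stem, four
#' stages of two residual blocks with channel widths doubling from
#' `cfg$width`, identity-path downsampling (kernel-1 stride-2 convolution +
#' batch-norm) at stages 2-4, adaptive average pooling to 1x1x1, dropout,
#' and a fully connected layer to `n_classes` logits. All convolutions are
#' bias-free; batch normalisation is affine. Weights are initialised
#' He-style (fan-out) for convolutions, unit scale / zero shift for
#' batch-norm, and uniform fan-in for the head, deterministically from
#' `cfg$seed`.
#'
#' @param cfg A [network_config()].
#' @return An object of class `resvol_network`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  modes <- stage_conv_modes(cfg$kind)
  net_module <- with_seed(cfg$seed, function() {
    stages <- list()
    in_ch <- cfg$stage_widths[1]
    for (s in 1:4) {
      out_ch <- cfg$stage_widths[s]
      blocks <- list()
      for (b in 1:cfg$blocks_per_stage[s]) {
        downsample <- (s >= 2L && b == 1L)
        bi <- if (b == 1L) in_ch else out_ch
        blocks[[paste0("block", b)]] <- make_basic_block(
          modes[s], bi, out_ch, downsample,
          name = sprintf("stage%d.block%d", s, b),
          zero_init_residual = cfg$zero_init_residual)
      }
      stages[[paste0("stage", s)]] <- nn_seq(blocks,
                                             name = paste0("stage", s))
      in_ch <- out_ch
    }
    nn_seq(c(list(stem = make_stem(cfg)), stages,
             list(avgpool = nn_gap(),
                  head = nn_seq(list(dropout = nn_dropout(cfg$dropout_p),
                                     fc = nn_linear(cfg$stage_widths[4],
                                                    cfg$n_classes)),
                                name = "head"))),
           name = cfg$kind)
  })
  structure(list(config = cfg, module = net_module,
                 class_levels = if (cfg$n_classes == 3L) CLASS_LEVELS else
                   paste0("class", seq_len(cfg$n_classes))),
            class = "resvol_network")
}

#' Named trainable parameters of a network
#'
#' @param net A `resvol_network`.
#' @return Named list of parameter arrays; names are layer paths such as
#'   `"stage2.block1.main.conv1.weight"`.
#' @export
network_parameters <- function(net) {
  mod_flatten(net$module)
}

#' Replace a network's parameters
#'
#' @param net A `resvol_network`.
#' @param params Named list as returned by [network_parameters()]; only
#'   matching names are assigned.
#' @return The updated network.
#' @export
set_network_parameters <- function(net, params) {
  net$module <- mod_set_params(net$module, params)
  net
}

#' Count trainable parameters
#'
#' Sums the lengths of every learnable array in the network: bias-free
#' convolution weights, batch-norm scale/shift pairs, and the fully
#' connected head's weight and bias.
#'
#' @param net A `resvol_network`.
#' @return Integer-valued count.
#' @export
count_trainable_parameters <- function(net) {
  stopifnot(inherits(net, "resvol_network"))
  sum(vapply(network_parameters(net), length, numeric(1)))
}

# Recursively collect per-layer rows for architecture_summary().
summarise_module <- function(m, prefix = NULL) {
  rows <- list()
  path <- paste(prefix, collapse = ".")
  if (m$type == "conv3d") {
    rows[[1]] <- data.frame(
      layer = path, type = "conv3d", conv_mode = m$conv_mode,
      in_ch = m$in_ch, out_ch = m$out_ch,
      k_slice = m$kernel[1], k_row = m$kernel[2], k_col = m$kernel[3],
      stride = paste(m$stride, collapse = "x"),
      n_params = length(m$params$weight), stringsAsFactors = FALSE)
  } else if (m$type == "bn3d") {
    rows[[1]] <- data.frame(
      layer = path, type = "bn3d", conv_mode = "", in_ch = m$ch,
      out_ch = m$ch, k_slice = NA_integer_, k_row = NA_integer_,
      k_col = NA_integer_, stride = "",
      n_params = length(m$params$gamma) + length(m$params$beta),
      stringsAsFactors = FALSE)
  } else if (m$type == "linear") {
    rows[[1]] <- data.frame(
      layer = path, type = "linear", conv_mode = "", in_ch = m$in_f,
      out_ch = m$out_f, k_slice = NA_integer_, k_row = NA_integer_,
      k_col = NA_integer_, stride = "",
      n_params = length(m$params$weight) + length(m$params$bias),
      stringsAsFactors = FALSE)
  }
  if (!is.null(m$children)) {
    for (nm in names(m$children)) {
      rows <- c(rows, list(summarise_module(m$children[[nm]], c(prefix, nm))))
    }
  }
  if (!is.null(m$main)) {
    rows <- c(rows, list(summarise_module(m$main, c(prefix, "main"))))
  }
  if (!is.null(m$shortcut)) {
    rows <- c(rows, list(summarise_module(m$shortcut, c(prefix, "shortcut"))))
  }
  do.call(rbind, rows)
}

#' Layer table of a network
#'
#' One row per learnable layer (convolution, batch-norm, linear) with
#' channel counts, kernel shape in (slice, row, col) order, stride, and the
#' layer's trainable-parameter count, so that the network's total can be
#' audited layer by layer (convolutions contribute
#' `in_ch * out_ch * k_slice * k_row * k_col`, batch-norms `2 * channels`,
#' the head `in * out + out`).
#'
#' @param x A `resvol_network` or a `network_config` (which is then built).
#' @return A `data.frame`.
#' @export
architecture_summary <- function(x) {
  if (inherits(x, "network_config")) x <- build_network(x)
  stopifnot(inherits(x, "resvol_network"))
  tab <- summarise_module(x$module)
  rownames(tab) <- NULL
  tab
}

#' Forward pass: class logits for a batch of volumes
#'
#' @param net A `resvol_network`.
#' @param batch Either a 5D array (batch, channel, slice, row, col), a 4D
#'   array (channel, slice, row, col) for one sample, a 3D array (one
#'   single-channel volume) or a `volume_sample`.
#' @param training Logical; `TRUE` enables dropout and batch-statistics
#'   normalisation (training semantics). The default `FALSE` is the
#'   deterministic evaluation mode.
#' @return Numeric matrix (batch x n_classes) of logits.
#' @export
classify <- function(net, batch, training = FALSE) {
  stopifnot(inherits(net, "resvol_network"))
  if (inherits(batch, "volume_sample")) batch <- batch$voxels
  d <- dim(batch)
  if (length(d) == 3L) dim(batch) <- c(1L, 1L, d)
  if (length(dim(batch)) == 4L) dim(batch) <- c(1L, dim(batch))
  d <- dim(batch)
  if (length(d) != 5L) {
    stop("batch must have 3, 4 or 5 dimensions", call. = FALSE)
  }
  logits <- matrix(NA_real_, d[1], net$config$n_classes)
  for (i in seq_len(d[1])) {
    x <- aperm(array(batch[i, , , , ], d[2:5]), c(2, 3, 4, 1))
    r <- mod_forward(net$module, x, training = training)
    logits[i, ] <- r$y
  }
  colnames(logits) <- net$class_levels
  logits
}

#' Transfer non-stem, non-head parameters from a donor parameter set
#'
#' Implements the pre-trained-weight loading policy: every parameter outside
#' the stem and the final fully connected head is copied from `source`;
#' the stem and head keep their fresh random initialisation (a donor trained
#' on 3-channel video has an incompatible stem, and a donor head has the
#' wrong class count, so both are always re-learned).
#'
#' @param net A `resvol_network`.
#' @param source Named parameter list, e.g. `network_parameters(donor)`.
#' @return `net` with transferred weights.
#' @export
load_pretrained <- function(net, source) {
  stopifnot(inherits(net, "resvol_network"))
  params <- network_parameters(net)
  transfer <- names(params)[!grepl("^(stem|head)\\.", names(params))]
  for (nm in transfer) {
    if (is.null(source[[nm]])) {
      stop("pre-trained source is missing parameter '", nm, "'",
           call. = FALSE)
    }
    src <- source[[nm]]
    tgt <- params[[nm]]
    if (!identical(dim(src) %||% length(src), dim(tgt) %||% length(tgt))) {
      stop("shape mismatch for parameter '", nm, "': source ",
           paste(dim(src) %||% length(src), collapse = "x"), ", target ",
           paste(dim(tgt) %||% length(tgt), collapse = "x"), call. = FALSE)
    }
    params[[nm]] <- src
  }
  set_network_parameters(net, params)
}

#' Save / load a network checkpoint
#'
#' Stores the named parameters, batch-norm running statistics, and the
#' `network_config` used to build the network.
#'
#' @param net A `resvol_network`.
#' @param path File path (.rds).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the rebuilt network.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "resvol_network"))
  saveRDS(list(config = net$config,
               params = network_parameters(net),
               buffers = mod_flatten(net$module, what = "buffers")),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config)
  net <- set_network_parameters(net, ck$params)
  net$module <- mod_set_buffers(net$module, ck$buffers)
  net
}

mod_set_buffers <- function(m, flat, prefix = NULL) {
  if (!is.null(m$buffers)) {
    for (pn in names(m$buffers)) {
      key <- paste(c(prefix, pn), collapse = ".")
      if (!is.null(flat[[key]])) m$buffers[[pn]] <- flat[[key]]
    }
  }
  if (!is.null(m$children)) {
    for (nm in names(m$children)) {
      m$children[[nm]] <- mod_set_buffers(m$children[[nm]], flat,
                                          c(prefix, nm))
    }
  }
  if (!is.null(m$main)) {
    m$main <- mod_set_buffers(m$main, flat, c(prefix, "main"))
  }
  if (!is.null(m$shortcut)) {
    m$shortcut <- mod_set_buffers(m$shortcut, flat, c(prefix, "shortcut"))
  }
  m
}

#' @export
print.resvol_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<resvol_network> %s  (width %d, in %d, classes %d)\n",
              cfg$kind, cfg$width, cfg$in_channels, cfg$n_classes))
  cat(sprintf("  stage conv modes: %s\n",
              paste(stage_conv_modes(cfg$kind), collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}
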