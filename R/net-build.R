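#' Configuration of the pest-damage-score regression network
#'
#' The regression architecture is: a stack of plain 3x3 convolution stages
#' (each stage's convolutions followed by one 2x2 max-pool), then four
#' residual blocks of two 3x3 convolutions each (with a 1x1 projection on
#' the shortcut when the channel count changes), global average pooling,
#' `fc_count` fully connected ReLU layers of `fc_width` units each followed
#' by dropout, and a single sigmoid output unit scaled to
#' \[0, `output_scale`\]. The `full` preset uses the VGG16 convolution
#' stages (13 convolutions, widths 64-512) with residual filters
#' 512/256/128/64 and three 1024-unit FC layers; the `tiny` preset is the
#' desk-scale configuration (input 64, backbone 16/32, residual filters
#' 32/16/8/8, FC width 64) that trains in minutes on one CPU.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param input_size Input side length in pixels.
#' @param backbone_channels List of integer vectors: convolution widths per
#'   stage (one max-pool after each stage).
#' @param residual_block_filters Four filter counts for the residual blocks.
#' @param block_pools Logical length-4: max-pool after each residual block?
#' @param fc_width,fc_count Fully connected head width and depth.
#' @param dropout_fc Dropout rate after each FC layer.
#' @param output_scale Upper bound of the score range.
#' @param freeze_backbone Freeze backbone convolution weights during
#'   training (for use with externally supplied pretrained weights).
#' @return A `pds_net_config` list.
#' @export
pds_net_config <- function(preset = c("tiny", "full"), input_size = NULL,
                           backbone_channels = NULL,
                           residual_block_filters = NULL,
                           block_pools = NULL, fc_width = NULL, fc_count = 3L,
                           dropout_fc = 0.3, output_scale = 5,
                           freeze_backbone = FALSE) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    if (is.null(input_size)) input_size <- 64L
    if (is.null(backbone_channels)) backbone_channels <- list(16L, 32L)
    if (is.null(residual_block_filters)) residual_block_filters <- c(32L, 16L, 8L, 8L)
    if (is.null(block_pools)) block_pools <- c(TRUE, TRUE, FALSE, FALSE)
    if (is.null(fc_width)) fc_width <- 64L
  } else {
    if (is.null(input_size)) input_size <- 224L
    if (is.null(backbone_channels))
      backbone_channels <- list(c(64L, 64L), c(128L, 128L),
                                c(256L, 256L, 256L), c(512L, 512L, 512L),
                                c(512L, 512L, 512L))
    if (is.null(residual_block_filters))
      residual_block_filters <- c(512L, 256L, 128L, 64L)
    if (is.null(block_pools)) block_pools <- c(FALSE, FALSE, FALSE, FALSE)
    if (is.null(fc_width)) fc_width <- 1024L
  }
  if (length(residual_block_filters) != 4) stop("exactly 4 residual blocks")
  if (fc_count != 3) stop("the regression head has 3 FC layers")
  sp <- input_size / 2^(length(backbone_channels) + sum(block_pools))
  if (sp < 1 || sp != floor(sp))
    stop("input_size is not divisible by the pooling stages")
  structure(list(preset = preset, input_size = as.integer(input_size),
                 backbone_channels = backbone_channels,
                 residual_block_filters = as.integer(residual_block_filters),
                 conv_per_block = 2L, block_pools = block_pools,
                 fc_width = as.integer(fc_width), fc_count = 3L,
                 dropout_fc = dropout_fc, output_scale = output_scale,
                 freeze_backbone = freeze_backbone),
            class = "pds_net_config")
}

#' Configuration of a binary damage classifier
#'
#' Classification head: two fully connected ReLU layers of `fc_width` units
#' with dropout 0.5, then a 1-unit sigmoid. The named backbones
#' (`alexnet`, `vgg16`, `resnet50`, `resnet101`, `inceptionv3`,
#' `densenet121`) are provided as plain 3x3-convolution stage stacks with
#' that family's characteristic stage widths and depths (branching modules
#' are not reproduced); `tiny` is the desk-scale preset. Early-stopping
#' patience defaults scale with backbone depth, from 20 (alexnet, tiny) to
#' 40 (densenet121).
#'
#' @param backbone_name One of the six named backbones or `"tiny"`.
#' @param input_size Input side length (defaults: 224; tiny 64).
#' @param fc_width FC width (default 4096; tiny 64).
#' @param dropout_fc Dropout rate (default 0.5).
#' @param patience Early-stopping patience (defaults per backbone).
#' @param freeze_backbone Freeze backbone weights during training.
#' @return A `binary_net_config` list.
#' @export
binary_net_config <- function(backbone_name = c("tiny", "alexnet", "vgg16",
                                                "resnet50", "resnet101",
                                                "inceptionv3", "densenet121"),
                              input_size = NULL, fc_width = NULL,
                              dropout_fc = 0.5, patience = NULL,
                              freeze_backbone = FALSE) {
  backbone_name <- match.arg(backbone_name)
  stages <- switch(backbone_name,
    tiny = list(16L, 32L, 32L),
    alexnet = list(64L, 192L, c(384L, 256L, 256L)),
    vgg16 = list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                 c(512L, 512L, 512L), c(512L, 512L, 512L)),
    resnet50 = list(64L, c(256L, 256L, 256L), c(512L, 512L, 512L, 512L),
                    c(1024L, 1024L), 2048L),
    resnet101 = list(64L, c(256L, 256L, 256L), c(512L, 512L, 512L, 512L),
                     c(1024L, 1024L, 1024L), 2048L),
    inceptionv3 = list(c(32L, 64L), c(80L, 192L), c(288L, 288L),
                       c(768L, 768L), 1280L),
    densenet121 = list(64L, c(128L, 128L), c(256L, 256L), c(512L, 512L),
                       1024L))
  def_patience <- c(tiny = 20L, alexnet = 20L, vgg16 = 25L, resnet50 = 30L,
                    resnet101 = 35L, inceptionv3 = 30L, densenet121 = 40L)
  if (is.null(patience)) patience <- def_patience[[backbone_name]]
  if (is.null(input_size)) input_size <- if (backbone_name == "tiny") 64L else 224L
  if (is.null(fc_width)) fc_width <- if (backbone_name == "tiny") 64L else 4096L
  sp <- input_size / 2^length(stages)
  if (sp < 1 || sp != floor(sp))
    stop("input_size is not divisible by the pooling stages")
  structure(list(backbone_name = backbone_name,
                 input_size = as.integer(input_size),
                 backbone_channels = stages, fc_width = as.integer(fc_width),
                 fc_count = 2L, dropout_fc = dropout_fc,
                 patience = as.integer(patience),
                 freeze_backbone = freeze_backbone),
            class = "binary_net_config")
}

.build_backbone <- function(stages, c_in, trainable) {
  layers <- list()
  for (stage in stages) {
    for (ch in stage) {
      layers[[length(layers) + 1L]] <- new_conv3(c_in, ch, "relu",
                                                 trainable = trainable)
      c_in <- ch
    }
    layers[[length(layers) + 1L]] <- new_pool2()
  }
  list(layers = layers, c_out = c_in)
}

#' Build the pest-damage-score regression network
#'
#' Assembles backbone convolutions, four residual blocks, global average
#' pooling, three FC+dropout layers and the scaled sigmoid output from a
#' [pds_net_config()]. Initialization is seeded: the same configuration and
#' seed give identical weights.
#'
#' @param cfg A `pds_net_config`.
#' @param seed Integer seed for weight initialization.
#' @return A network object (list of layers plus the config) for
#'   [train_with_early_stopping()] and [net_predict()].
#' @export
build_pds_network <- function(cfg = pds_net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "pds_net_config"))
  with_seed(seed, {
    bb <- .build_backbone(cfg$backbone_channels, 3L, !cfg$freeze_backbone)
    layers <- bb$layers
    c_in <- bb$c_out
    for (i in 1:4) {
      layers[[length(layers) + 1L]] <-
        new_resblock(c_in, cfg$residual_block_filters[i])
      c_in <- cfg$residual_block_filters[i]
      if (cfg$block_pools[i]) layers[[length(layers) + 1L]] <- new_pool2()
    }
    layers[[length(layers) + 1L]] <- new_gap()
    d_in <- c_in
    for (i in seq_len(cfg$fc_count)) {
      layers[[length(layers) + 1L]] <-
        new_dense(d_in, cfg$fc_width, "relu", dropout = cfg$dropout_fc)
      d_in <- cfg$fc_width
    }
    layers[[length(layers) + 1L]] <- new_head(d_in, scale = cfg$output_scale)
    structure(list(layers = layers, cfg = cfg, task = "regression",
                   seed = as.integer(seed)), class = "pestgs_net")
  })
}

#' Build a binary damage classifier network
#'
#' Backbone stages, global average pooling, two FC+dropout layers and a
#' 1-unit sigmoid, from a [binary_net_config()]. Seeded like
#' [build_pds_network()].
#'
#' @param cfg A `binary_net_config`.
#' @param seed Integer seed for weight initialization.
#' @return A network object.
#' @export
build_binary_network <- function(cfg = binary_net_config(), seed = 1L) {
  stopifnot(inherits(cfg, "binary_net_config"))
  with_seed(seed, {
    bb <- .build_backbone(cfg$backbone_channels, 3L, !cfg$freeze_backbone)
    layers <- bb$layers
    layers[[length(layers) + 1L]] <- new_gap()
    d_in <- bb$c_out
    for (i in seq_len(cfg$fc_count)) {
      layers[[length(layers) + 1L]] <-
        new_dense(d_in, cfg$fc_width, "relu", dropout = cfg$dropout_fc)
      d_in <- cfg$fc_width
    }
    layers[[length(layers) + 1L]] <- new_head(d_in, scale = 1)
    structure(list(layers = layers, cfg = cfg, task = "binary",
                   seed = as.integer(seed)), class = "pestgs_net")
  })
}

#' @export
print.pestgs_net <- function(x, ...) {
  cat(sprintf("pestgs_net (%s): %d layers, %d parameters, input %dx%d\n",
              x$task, length(x$layers), net_n_params(x),
              x$cfg$input_size, x$cfg$input_size))
  invisible(x)
}
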