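## Encoder backbones. All three families emit a five-level feature pyramid
## {f_i, i = 1..5} at strides /2, /4, /8, /16, /32 of the input:
##   - "vgg":     plain 3x3 conv blocks, each closed by 2x2 max pooling;
##                f_i taps the i-th pool output.
##   - "resnet":  stride-2 stage transitions followed by bottleneck
##                residual blocks at constant shape.
##   - "res2net": as "resnet" but the bottleneck's 3x3 stage is replaced by
##                the hierarchical multi-scale group cascade.

#' Backbone specification
#'
#' @param variant one of `"res2net"`, `"resnet"`, `"vgg"`.
#' @param channels five per-level channel counts `c_1..c_5`
#'   (non-decreasing). Defaults to the canonical counts of the family:
#'   64/128/256/512/512 for VGG, 64/256/512/1024/2048 for the residual
#'   families.
#' @param pretrained load ImageNet-pretrained weights. Only `FALSE` is
#'   supported: this library trains from seeded random initialization.
#' @param res2net_scale number of channel groups `s` in the hierarchical
#'   residual block.
#' @param res2net_width per-group width `w`; default chosen so the block's
#'   internal width is a quarter of its channel count.
#' @param blocks_per_stage residual blocks per stage (levels 2..5).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(variant = c("res2net", "resnet", "vgg"),
                          channels = NULL, pretrained = FALSE,
                          res2net_scale = 4L, res2net_width = NULL,
                          blocks_per_stage = 1L) {
  variant <- match.arg(variant)
  if (is.null(channels)) {
    channels <- if (variant == "vgg") c(64L, 128L, 256L, 512L, 512L)
                else c(64L, 256L, 512L, 1024L, 2048L)
  }
  channels <- as.integer(channels)
  if (length(channels) != 5 || any(channels < 1)) {
    stop("channels must be five positive counts c_1..c_5")
  }
  if (is.unsorted(channels)) stop("channels must be non-decreasing")
  if (res2net_scale < 1) stop("res2net_scale must be >= 1")
  if (isTRUE(pretrained)) {
    stop("pretrained weights are not available in this build; ",
         "use pretrained = FALSE (seeded random initialization)")
  }
  structure(list(variant = variant, channels = channels,
                 pretrained = FALSE,
                 res2net_scale = as.integer(res2net_scale),
                 res2net_width = res2net_width,
                 blocks_per_stage = as.integer(blocks_per_stage)),
            class = "backbone_spec")
}

## Bottleneck residual block at constant channel count c:
## 1x1 reduce -> 3x3 -> 1x1 expand (+BN), residual add, ReLU.
bottleneck_block <- function(c) {
  mid <- max(1L, c %/% 4L)
  m <- new_module("bottleneck")
  m$children <- list(
    reduce = cbr_layer(c, mid, k = 1L),
    mid = cbr_layer(mid, mid, k = 3L),
    expand_conv = conv_layer(mid, c, k = 1L),
    expand_bn = bn_layer(c))
  m$forward <- function(x, training = TRUE) {
    h <- m$children$reduce$forward(x, training)
    h <- m$children$mid$forward(h, training)
    h <- m$children$expand_conv$forward(h)
    h <- m$children$expand_bn$forward(h, training)
    op_relu(op_add(h, x))
  }
  m
}

#' Hierarchical multi-scale residual block (Res2Net-style)
#'
#' Splits the bottleneck's internal width into `scale` groups. For
#' `scale >= 2`, group 1 passes through unchanged and every later group is
#' transformed by a 3x3 conv applied to (its own slice + the previous
#' group's output), so the receptive field grows hierarchically inside one
#' block. With `scale = 1` the single group is convolved directly and the
#' block degenerates to a plain bottleneck residual block.
#'
#' @param c input/output channel count of the block.
#' @param scale number of groups `s`.
#' @param width per-group channel width `w`; internal width is
#'   `scale * width`. Defaults to `max(1, c %/% (4 * scale))`.
#' @return a module; `$forward(x, training)` maps an `[H, W, c]` tensor to
#'   a same-shape tensor.
#' @export
res2_block <- function(c, scale = 4L, width = NULL) {
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  if (is.null(width)) width <- max(1L, c %/% (4L * scale))
  width <- as.integer(width)
  if (width < 1) stop("width must be >= 1")
  mid <- scale * width
  m <- new_module("res2")
  convs <- list()
  n_convs <- if (scale == 1L) 1L else scale - 1L
  for (k in seq_len(n_convs)) convs[[k]] <- cbr_layer(width, width, k = 3L)
  m$children <- c(list(reduce = cbr_layer(c, mid, k = 1L),
                       expand_conv = conv_layer(mid, c, k = 1L),
                       expand_bn = bn_layer(c)),
                  convs)
  m$scale <- scale
  m$width <- width
  m$forward <- function(x, training = TRUE) {
    h <- m$children$reduce$forward(x, training)
    groups <- lapply(seq_len(scale), function(j) {
      op_slice_c(h, (j - 1L) * width + 1L, j * width)
    })
    ys <- vector("list", scale)
    if (scale == 1L) {
      ys[[1]] <- m$children[[4]]$forward(groups[[1]], training)
    } else {
      ys[[1]] <- groups[[1]]
      for (j in 2:scale) {
        ys[[j]] <- m$children[[3L + j - 1L]]$forward(
          op_add(groups[[j]], ys[[j - 1]]), training)
      }
    }
    h <- if (scale == 1L) ys[[1]] else op_concat_c(ys)
    h <- m$children$expand_conv$forward(h)
    h <- m$children$expand_bn$forward(h, training)
    op_relu(op_add(h, x))
  }
  m
}

#' Build an encoder backbone from a specification
#'
#' @param spec a [backbone_spec()].
#' @param in_channels input channel count (grayscale inputs are replicated
#'   to 3 channels by [extract_features()] before reaching the stem).
#' @return a module whose `$forward(x, training)` returns the list
#'   `f1..f5` of pyramid tensors.
#' @export
build_backbone <- function(spec, in_channels = 3L) {
  stopifnot(inherits(spec, "backbone_spec"))
  ch <- spec$channels
  m <- new_module(paste0("backbone_", spec$variant))
  if (spec$variant == "vgg") {
    stages <- list()
    c_prev <- in_channels
    for (i in 1:5) {
      stages[[i]] <- list(a = cbr_layer(c_prev, ch[i], k = 3L),
                          b = cbr_layer(ch[i], ch[i], k = 3L))
      c_prev <- ch[i]
    }
    m$children <- unlist(stages, recursive = FALSE)
    m$forward <- function(x, training = TRUE) {
      f <- vector("list", 5)
      h <- x
      for (i in 1:5) {
        h <- stages[[i]]$a$forward(h, training)
        h <- stages[[i]]$b$forward(h, training)
        h <- op_maxpool2(h)
        f[[i]] <- h
      }
      names(f) <- paste0("f", 1:5)
      f
    }
  } else {
    inner <- function(c) {
      if (spec$variant == "resnet") bottleneck_block(c)
      else res2_block(c, spec$res2net_scale, spec$res2net_width)
    }
    stem <- cbr_layer(in_channels, ch[1], k = 3L, stride = 2L)
    stages <- list()
    c_prev <- ch[1]
    for (i in 2:5) {
      blocks <- lapply(seq_len(spec$blocks_per_stage),
                       function(k) inner(ch[i]))
      stages[[i - 1]] <- list(
        transition = cbr_layer(c_prev, ch[i], k = 3L, stride = 2L),
        blocks = blocks)
      c_prev <- ch[i]
    }
    m$children <- c(list(stem = stem),
                    unlist(lapply(stages, function(s) {
                      c(list(s$transition), s$blocks)
                    }), recursive = FALSE))
    m$forward <- function(x, training = TRUE) {
      f <- vector("list", 5)
      h <- stem$forward(x, training)
      f[[1]] <- h
      for (i in 2:5) {
        h <- stages[[i - 1]]$transition$forward(h, training)
        for (blk in stages[[i - 1]]$blocks) h <- blk$forward(h, training)
        f[[i]] <- h
      }
      names(f) <- paste0("f", 1:5)
      f
    }
  }
  m$spec <- spec
  m
}

#' Extract the five-level feature pyramid from an image
#'
#' @param image numeric matrix `[H, W]` or array `[H, W, 1|3]` with values
#'   in `[0, 1]`; `H` and `W` must be divisible by 32. Single-channel
#'   inputs are replicated to 3 channels before the stem.
#' @param spec a [backbone_spec()]; the backbone is built from the current
#'   RNG state, so seed beforehand for reproducibility.
#' @param backbone optionally a backbone built by [build_backbone()]
#'   (reused across calls; overrides `spec`).
#' @param training batch-norm mode; `FALSE` (default) uses running
#'   statistics.
#' @return list `f1..f5` of numeric arrays `[H/2^i, W/2^i, c_i]`.
#' @export
extract_features <- function(image, spec = backbone_spec(),
                             backbone = NULL, training = FALSE) {
  x <- image_to_input(image)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop(sprintf(
      "image size %dx%d not divisible by 32 (five stride-2 levels)",
      d[1], d[2]))
  }
  if (is.null(backbone)) backbone <- build_backbone(spec, in_channels = 3L)
  params <- module_params(backbone)
  pyr <- with_no_grad(params, backbone$forward(pt_const(x), training))
  lapply(pyr, function(f) f$value)
}

## Normalize user images to a 3-channel [H, W, 3] array.
image_to_input <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3 || !(d[3] %in% c(1L, 3L))) {
    stop("image must be [H, W], [H, W, 1] or [H, W, 3]")
  }
  if (d[3] == 1L) image <- array(rep(image, 3L), dim = c(d[1], d[2], 3L))
  image
}
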