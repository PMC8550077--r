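## Decoder-side feature-expression enhancement:
##   - edge attention on f2 (contour features + an edge side output S_e),
##   - parallel partial decoder fusing f3..f5 into the global map S_g,
##   - three cascaded reverse-attention stages refining levels 5 -> 4 -> 3,
##     each side output residually combined with the next-coarser map.

#' Edge attention module
#'
#' Two 3x3 conv+BN+ReLU stages reduce f2 to `reduce` channels (the edge
#' feature `e_att`); a 1x1 projection yields the single-channel edge logit
#' map `S_e` at f2's /4 resolution.
#'
#' @param c2 channel count of f2.
#' @param reduce reduced channel width (default 32).
#' @return a module; `$forward(f2, training)` returns
#'   `list(e_att = , S_e = )`.
#' @export
edge_attention_module <- function(c2, reduce = 32L) {
  m <- new_module("edge_attention")
  m$children <- list(a = cbr_layer(c2, reduce, k = 3L),
                     b = cbr_layer(reduce, reduce, k = 3L),
                     proj = conv_layer(reduce, 1L, k = 1L))
  m$forward <- function(f2, training = TRUE) {
    h <- m$children$a$forward(f2, training)
    h <- m$children$b$forward(h, training)
    list(e_att = h, S_e = m$children$proj$forward(h))
  }
  m
}

#' Parallel partial decoder
#'
#' Reduces each of f3/f4/f5 to `reduce` channels (1x1 conv + BN), applies
#' multiplicative top-down gating (each finer level is gated by upsampled
#' 3x3-convolved coarser levels), then concatenates everything at f3
#' resolution and projects to the single-channel global logit map S_g.
#'
#' @param c3,c4,c5 channel counts of the three coarse levels.
#' @param reduce reduced channel width.
#' @return a module; `$forward(f3, f4, f5, training)` returns the S_g
#'   logit tensor at /8 resolution.
#' @export
partial_decoder_module <- function(c3, c4, c5, reduce = 32L) {
  m <- new_module("partial_decoder")
  m$children <- list(
    red3 = cbr_layer(c3, reduce, k = 1L, relu = FALSE),
    red4 = cbr_layer(c4, reduce, k = 1L, relu = FALSE),
    red5 = cbr_layer(c5, reduce, k = 1L, relu = FALSE),
    c54 = cbr_layer(reduce, reduce, k = 3L, relu = FALSE),
    c53 = cbr_layer(reduce, reduce, k = 3L, relu = FALSE),
    c43 = cbr_layer(reduce, reduce, k = 3L, relu = FALSE),
    fuse = cbr_layer(3L * reduce, reduce, k = 3L),
    proj = conv_layer(reduce, 1L, k = 1L))
  m$forward <- function(f3, f4, f5, training = TRUE) {
    d3 <- dim(f3$value); d4 <- dim(f4$value)
    g3 <- m$children$red3$forward(f3, training)
    g4 <- m$children$red4$forward(f4, training)
    g5 <- m$children$red5$forward(f5, training)
    up_to <- function(t, d) op_resize_bilinear(t, d[1], d[2])
    g5p <- g5
    g4p <- op_mul(g4, up_to(m$children$c54$forward(g5, training), d4))
    g3p <- op_mul(op_mul(g3,
                         up_to(m$children$c43$forward(g4, training), d3)),
                  up_to(m$children$c53$forward(g5, training), d3))
    cat3 <- op_concat_c(list(g3p, up_to(g4p, d3), up_to(g5p, d3)))
    h <- m$children$fuse$forward(cat3, training)
    m$children$proj$forward(h)
  }
  m
}

#' Reverse attention module
#'
#' The next-coarser prediction is resized to this level, sigmoid-activated
#' and reversed (`A_i = 1 - sigmoid(.)`), so attention concentrates on the
#' regions the coarser map currently misses. The reversed map gates the
#' channel-reduced f_i; the gated feature is concatenated with the
#' downsampled edge feature, refined by two 3x3 conv+BN+ReLU stages, and
#' projected to one channel. The side output adds back the resized coarser
#' map (residual refinement).
#'
#' @param c_i channel count of f_i.
#' @param e_att_channels channel count of the edge feature.
#' @param reduce reduced channel width.
#' @param level pyramid level index, one of 3, 4, 5.
#' @return a module; `$forward(f_i, S_higher, e_att, training)` returns
#'   `list(R = , S = , A = )` (refined feature, side-output logits,
#'   reverse-attention map).
#' @export
reverse_attention_module <- function(c_i, e_att_channels = 32L,
                                     reduce = 32L, level = 3L) {
  if (!(level %in% 3:5)) stop("level must be one of 3, 4, 5")
  m <- new_module("reverse_attention")
  m$children <- list(
    red = cbr_layer(c_i, reduce, k = 1L, relu = FALSE),
    a = cbr_layer(reduce + e_att_channels, reduce, k = 3L),
    b = cbr_layer(reduce, reduce, k = 3L),
    proj = conv_layer(reduce, 1L, k = 1L))
  m$level <- as.integer(level)
  m$forward <- function(f_i, S_higher, e_att, training = TRUE) {
    d <- dim(f_i$value)
    s_res <- op_resize_bilinear(S_higher, d[1], d[2])
    A <- op_one_minus(op_sigmoid(s_res))
    f_red <- m$children$red$forward(f_i, training)
    gated <- op_mul(f_red, op_expand_c(A, dim(f_red$value)[3]))
    e_dn <- op_adaptive_avgpool(e_att, d[1], d[2])
    R <- op_concat_c(list(gated, e_dn))
    h <- m$children$a$forward(R, training)
    h <- m$children$b$forward(h, training)
    S <- op_add(m$children$proj$forward(h), s_res)
    list(R = R, S = S, A = A)
  }
  m
}

#' Assemble the full segmentation network
#'
#' Wires backbone, edge attention, parallel partial decoder and the three
#' cascaded reverse-attention stages (levels 5 -> 4 -> 3). The final
#' prediction is the sigmoid of the last side output upsampled to input
#' resolution.
#'
#' @param spec a [backbone_spec()].
#' @param reduce reduced channel width used throughout the decoder.
#' @param in_channels input channels fed to the stem (after grayscale
#'   replication).
#' @return an object of class `ppaseg_model`.
#' @export
ppa_unet <- function(spec = backbone_spec(), reduce = 32L,
                    in_channels = 3L) {
  ch <- spec$channels
  m <- new_module("ppa_unet")
  m$backbone <- build_backbone(spec, in_channels)
  m$ea <- edge_attention_module(ch[2], reduce)
  m$pd <- partial_decoder_module(ch[3], ch[4], ch[5], reduce)
  m$ra5 <- reverse_attention_module(ch[5], reduce, reduce, level = 5L)
  m$ra4 <- reverse_attention_module(ch[4], reduce, reduce, level = 4L)
  m$ra3 <- reverse_attention_module(ch[3], reduce, reduce, level = 3L)
  m$children <- list(m$backbone, m$ea, m$pd, m$ra5, m$ra4, m$ra3)
  m$spec <- spec
  m$reduce <- as.integer(reduce)
  class(m) <- c("ppaseg_model", class(m))
  m
}

#' @export
print.ppaseg_model <- function(x, ...) {
  n_par <- sum(vapply(module_params(x), function(p) length(p$value),
                      numeric(1)))
  cat(sprintf(
    "<ppaseg model: %s backbone, channels %s, decoder width %d, %s parameters>\n",
    x$spec$variant, paste(x$spec$channels, collapse = "/"), x$reduce,
    format(n_par, big.mark = ",")))
  invisible(x)
}

## Graph-building forward pass (tensor nodes in, tensor nodes out).
model_forward_nodes <- function(model, x_node, training = TRUE) {
  d <- dim(x_node$value)
  pyr <- model$backbone$forward(x_node, training)
  ea <- model$ea$forward(pyr$f2, training)
  S_g <- model$pd$forward(pyr$f3, pyr$f4, pyr$f5, training)
  r5 <- model$ra5$forward(pyr$f5, S_g, ea$e_att, training)
  r4 <- model$ra4$forward(pyr$f4, r5$S, ea$e_att, training)
  r3 <- model$ra3$forward(pyr$f3, r4$S, ea$e_att, training)
  up <- function(t) op_resize_bilinear(t, d[1], d[2])
  up_logits <- list(S_e = up(ea$S_e), S_g = up(S_g), S_5 = up(r5$S),
                    S_4 = up(r4$S), S_3 = up(r3$S))
  list(side = list(S_e = ea$S_e, S_g = S_g, S_5 = r5$S, S_4 = r4$S,
                   S_3 = r3$S),
       up = up_logits,
       attn = list(A_5 = r5$A, A_4 = r4$A, A_3 = r3$A),
       attn_input = list(A_5 = S_g, A_4 = r5$S, A_3 = r4$S),
       final = op_sigmoid(up_logits$S_3))
}

#' Run the full network on an image
#'
#' @param model a model from [ppa_unet()].
#' @param image matrix or `[H, W, 1|3]` array in `[0,1]`, sizes divisible
#'   by 32.
#' @param training batch-norm mode (default `FALSE`: eval, running stats).
#' @return list with `side` (logit maps S_e, S_g, S_5, S_4, S_3 at native
#'   resolutions), `up` (the same upsampled to input resolution),
#'   `prob` (final sigmoid probability map, input resolution).
#' @export
ppa_unet_forward <- function(model, image, training = FALSE) {
  x <- image_to_input(image)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop(sprintf("image size %dx%d not divisible by 32", d[1], d[2]))
  }
  params <- module_params(model)
  out <- with_no_grad(params,
                      model_forward_nodes(model, pt_const(x), training))
  list(side = lapply(out$side, function(t) drop3(t$value)),
       up = lapply(out$up, function(t) drop3(t$value)),
       prob = drop3(out$final$value))
}

drop3 <- function(a) {
  if (length(dim(a)) == 3 && dim(a)[3] == 1L) a[, , 1] else a
}
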