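# Network builders. Every builder returns a "vs_network": an environment
# holding its layers, a flat parameter list, a forward closure and structure
# metadata. Forward convention: net$forward(tp, x, ...) where `x` is a tape
# node id when `tp` is a tape, or a raw (H,W,C,N) array when `tp` is NULL
# (inference mode, no gradients recorded).

make_net <- function(subclass, layers, forward, meta, cfg) {
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$params <- collect_params(layers)
  net$forward <- forward
  net$meta <- meta
  net$cfg <- cfg
  class(net) <- c(subclass, "vs_network")
  net
}

#' Network configuration
#'
#' Hyperparameters shared by all architecture builders.
#'
#' @param base_width Channel width of the first convolution of the
#'   generators/critics; deeper stages scale multiples of it.
#' @param feature_width Channel width of every internal feature map of the
#'   parallel feature fusion generator. The staining model's convention is a
#'   single fixed width network-wide; default 512.
#' @param in_channels,out_channels Image channel counts (RGB default).
#' @param n_blocks Number of residual (or separable) body blocks in the
#'   translation generators.
#' @param unet_depth Number of downsampling stages of the baseline UNet.
#' @return A list of class `vs_network_config`.
#' @export
network_config <- function(base_width = 64L, feature_width = 512L,
                           in_channels = 3L, out_channels = 3L,
                           n_blocks = 6L, unet_depth = 8L) {
  stopifnot(base_width > 0, feature_width > 0, in_channels > 0,
            out_channels > 0, n_blocks >= 1, unet_depth >= 1)
  structure(list(base_width = as.integer(base_width),
                 feature_width = as.integer(feature_width),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_blocks = as.integer(n_blocks),
                 unet_depth = as.integer(unet_depth)),
            class = "vs_network_config")
}

#' Count trainable parameters of a network
#' @param net A network built by one of the `build_*` functions.
#' @return Integer scalar.
#' @export
count_params <- function(net) n_params(net$params)

# ---------------------------------------------------------------------------
# Residual translation generator (Johnson-style), the unpaired baseline.
# Layer list (W = base_width, body has n_blocks residual blocks):
#   head: conv 7x7 s1 p3 in->W, instance norm, ReLU
#   down1: conv 3x3 s2 p1 W->2W, IN, ReLU; down2: conv 3x3 s2 p1 2W->4W, IN, ReLU
#   block i: conv 3x3 4W->4W, IN, ReLU, conv 3x3 4W->4W, IN; + identity skip
#   up1: nearest x2 + conv 3x3 4W->2W, IN, ReLU; up2: x2 + conv 3x3 2W->W, IN, ReLU
#   tail: conv 7x7 s1 p3 W->out, tanh
# ---------------------------------------------------------------------------

#' Build the residual-block translation generator
#'
#' The classic image-to-image generator: 7x7 head, two stride-2
#' downsamplings, a stack of residual blocks with instance normalization,
#' two upsamplings and a 7x7 tail with tanh output. Serves as the unpaired
#' translation baseline and as the reference point for the separable
#' redesign.
#'
#' @param cfg A [network_config()].
#' @return A `vs_network` mapping (H,W,C,N) tiles to same-size tiles in
#'   \eqn{[-1,1]}. Spatial size must be divisible by 4.
#' @export
build_resnet_generator <- function(cfg = network_config()) {
  W <- cfg$base_width
  L <- list(
    head = ly_conv(cfg$in_channels, W, 7L, pad = 3L), head_in = ly_inorm(W),
    d1 = ly_conv(W, 2L * W, 3L, stride = 2L), d1_in = ly_inorm(2L * W),
    d2 = ly_conv(2L * W, 4L * W, 3L, stride = 2L), d2_in = ly_inorm(4L * W),
    u1 = ly_conv(4L * W, 2L * W, 3L), u1_in = ly_inorm(2L * W),
    u2 = ly_conv(2L * W, W, 3L), u2_in = ly_inorm(W),
    tail = ly_conv(W, cfg$out_channels, 7L, pad = 3L)
  )
  for (b in seq_len(cfg$n_blocks)) {
    L[[paste0("b", b, "_c1")]] <- ly_conv(4L * W, 4L * W, 3L)
    L[[paste0("b", b, "_n1")]] <- ly_inorm(4L * W)
    L[[paste0("b", b, "_c2")]] <- ly_conv(4L * W, 4L * W, 3L)
    L[[paste0("b", b, "_n2")]] <- ly_inorm(4L * W)
  }
  forward <- function(tp, x) {
    xv <- arg_val(tp, x)
    if (any(dim(xv)[1:2] %% 4L != 0L))
      stop("resnet generator: spatial size must be divisible by 4", call. = FALSE)
    h <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, x, L$head), L$head_in))
    h <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L$d1), L$d1_in))
    h <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L$d2), L$d2_in))
    for (b in seq_len(cfg$n_blocks)) {
      r <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L[[paste0("b", b, "_c1")]]),
                                L[[paste0("b", b, "_n1")]]))
      r <- fw_inorm(tp, fw_conv(tp, r, L[[paste0("b", b, "_c2")]]),
                    L[[paste0("b", b, "_n2")]])
      h <- fw_add(tp, h, r)
    }
    h <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, fw_upsample(tp, h, 2L), L$u1), L$u1_in))
    h <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, fw_upsample(tp, h, 2L), L$u2), L$u2_in))
    fw_tanh(tp, fw_conv(tp, h, L$tail))
  }
  make_net("vs_resnet_generator", L, forward,
           meta = list(kind = "resnet", n_blocks = cfg$n_blocks,
                       normalized_body = TRUE),
           cfg = cfg)
}

#' Build the depthwise-separable translation generator
#'
#' Same topology as [build_resnet_generator()] but every body block is a
#' separable (Xception-style) block -- depthwise 3x3 then pointwise 1x1,
#' twice, around an identity skip -- and the stride-2 down/upsampling
#' convolutions are depthwise-separable as well. Instance normalization is
#' removed from the body: decoupling spatial from channel mixing while
#' dropping per-feature-map normalization is what suppresses the dark
#' hole artifacts the normalized residual generator produces on sparse
#' unstained-domain data.
#'
#' @inheritParams build_resnet_generator
#' @return A `vs_network`; `net$meta$body_layers` names the separable body
#'   layers for structural inspection.
#' @export
build_sep_generator <- function(cfg = network_config()) {
  W <- cfg$base_width
  L <- list(
    head = ly_conv(cfg$in_channels, W, 7L, pad = 3L),
    d1 = ly_sepconv(W, 2L * W, 3L, stride = 2L),
    d2 = ly_sepconv(2L * W, 4L * W, 3L, stride = 2L),
    u1 = ly_sepconv(4L * W, 2L * W, 3L),
    u2 = ly_sepconv(2L * W, W, 3L),
    tail = ly_conv(W, cfg$out_channels, 7L, pad = 3L)
  )
  body <- character(0)
  for (b in seq_len(cfg$n_blocks)) {
    n1 <- paste0("b", b, "_s1"); n2 <- paste0("b", b, "_s2")
    L[[n1]] <- ly_sepconv(4L * W, 4L * W, 3L)
    L[[n2]] <- ly_sepconv(4L * W, 4L * W, 3L)
    body <- c(body, n1, n2)
  }
  forward <- function(tp, x) {
    xv <- arg_val(tp, x)
    if (any(dim(xv)[1:2] %% 4L != 0L))
      stop("separable generator: spatial size must be divisible by 4", call. = FALSE)
    h <- fw_relu(tp, fw_conv(tp, x, L$head))
    h <- fw_relu(tp, fw_sepconv(tp, h, L$d1))
    h <- fw_relu(tp, fw_sepconv(tp, h, L$d2))
    for (b in seq_len(cfg$n_blocks)) {
      r <- fw_relu(tp, fw_sepconv(tp, h, L[[paste0("b", b, "_s1")]]))
      r <- fw_sepconv(tp, r, L[[paste0("b", b, "_s2")]])
      h <- fw_add(tp, h, r)
    }
    h <- fw_relu(tp, fw_sepconv(tp, fw_upsample(tp, h, 2L), L$u1))
    h <- fw_relu(tp, fw_sepconv(tp, fw_upsample(tp, h, 2L), L$u2))
    fw_tanh(tp, fw_conv(tp, h, L$tail))
  }
  make_net("vs_sep_generator", L, forward,
           meta = list(kind = "separable", n_blocks = cfg$n_blocks,
                       normalized_body = FALSE,
                       body_layers = c("d1", "d2", body, "u1", "u2")),
           cfg = cfg)
}

# ---------------------------------------------------------------------------
# Patch critic. Layer list (W = base_width), no normalization so the same
# critic serves the Wasserstein gradient-penalty game:
#   conv 4x4 s2 p1 -> W,  LReLU        (receptive field 4)
#   conv 4x4 s2 p1 -> 2W, LReLU        (10)
#   conv 4x4 s2 p1 -> 4W, LReLU        (22)
#   conv 3x3 s1 p1 -> 8W, LReLU        (38)
#   conv 3x3 s1 p1 -> 8W, LReLU        (54)
#   conv 3x3 s1 p1 -> 1                (70)  patch score map, stride 8
# ---------------------------------------------------------------------------

#' Build the patch critic (discriminator)
#'
#' A fully convolutional critic scoring overlapping 70x70 patches: three
#' stride-2 4x4 convolutions followed by three stride-1 3x3 convolutions,
#' so the score map has 1/8 the input resolution. In conditional mode the
#' condition image is concatenated with the target image on channels. The
#' forward pass exposes the activation after every convolutional layer
#' (six layers) for the feature-matching objective.
#'
#' @param cfg A [network_config()].
#' @param conditional If `TRUE` the critic scores (condition, target) pairs.
#' @return A `vs_network`. `net$forward(tp, x, y, features = TRUE)` returns
#'   `list(score, feats)`.
#' @export
build_patch_critic <- function(cfg = network_config(), conditional = TRUE) {
  W <- cfg$base_width
  cin <- if (conditional) cfg$in_channels + cfg$out_channels else cfg$in_channels
  L <- list(
    c1 = ly_conv(cin, W, 4L, stride = 2L, pad = 1L),
    c2 = ly_conv(W, 2L * W, 4L, stride = 2L, pad = 1L),
    c3 = ly_conv(2L * W, 4L * W, 4L, stride = 2L, pad = 1L),
    c4 = ly_conv(4L * W, 8L * W, 3L),
    c5 = ly_conv(8L * W, 8L * W, 3L),
    out = ly_conv(8L * W, 1L, 3L)
  )
  forward <- function(tp, x, y = NULL, features = FALSE) {
    h <- if (conditional) {
      if (is.null(y)) stop("conditional critic needs a target image", call. = FALSE)
      fw_concat(tp, list(x, y))
    } else x
    feats <- list()
    h <- fw_lrelu(tp, fw_conv(tp, h, L$c1)); feats$f1 <- h
    h <- fw_lrelu(tp, fw_conv(tp, h, L$c2)); feats$f2 <- h
    h <- fw_lrelu(tp, fw_conv(tp, h, L$c3)); feats$f3 <- h
    h <- fw_lrelu(tp, fw_conv(tp, h, L$c4)); feats$f4 <- h
    h <- fw_lrelu(tp, fw_conv(tp, h, L$c5)); feats$f5 <- h
    s <- fw_conv(tp, h, L$out); feats$f6 <- s
    if (features) list(score = s, feats = unname(feats)) else s
  }
  make_net("vs_patch_critic", L, forward,
           meta = list(kind = "patch_critic", conditional = conditional,
                       n_feature_layers = 6L, output_stride = 8L,
                       receptive_field = 70L,
                       strides = c(2L, 2L, 2L, 1L, 1L, 1L),
                       kernels = c(4L, 4L, 4L, 3L, 3L, 3L),
                       pads = c(1L, 1L, 1L, 1L, 1L, 1L)),
           cfg = cfg)
}

#' Spatial size of the patch critic's score map
#' @param net A patch critic.
#' @param size Input spatial size in pixels.
#' @return Integer output size.
#' @export
critic_output_size <- function(net, size) {
  m <- net$meta
  s <- size
  for (i in seq_along(m$strides))
    s <- (s + 2L * m$pads[i] - m$kernels[i]) %/% m$strides[i] + 1L
  s
}

# ---------------------------------------------------------------------------
# Domain-consistency network: a two-input discriminator judging whether two
# images belong to the same domain.
# ---------------------------------------------------------------------------

#' Build the domain-consistency network
#'
#' Judges whether two images come from the same domain. Each input is
#' downsampled three times by stride-2 depthwise-separable convolutions with
#' LeakyReLU; the two feature stacks are concatenated and passed through a
#' stack of 1x1 convolutions down to a single-channel map. With three
#' stride-2 stages the output has 1/8 the input resolution -- by
#' construction the same spatial size as the patch critic's score map for
#' any input size, so the two discriminators supervise the generator at the
#' same patch granularity.
#'
#' @param cfg A [network_config()].
#' @return A `vs_network`; `net$forward(tp, a, b)` takes two same-size images.
#' @export
build_domain_consistency_net <- function(cfg = network_config()) {
  W <- cfg$base_width
  side <- function() list(
    s1 = ly_sepconv(cfg$in_channels, W, 4L, stride = 2L, pad = 1L),
    s2 = ly_sepconv(W, 2L * W, 4L, stride = 2L, pad = 1L),
    s3 = ly_sepconv(2L * W, 4L * W, 4L, stride = 2L, pad = 1L)
  )
  A <- side(); B <- side()
  L <- c(stats::setNames(A, paste0("a_", names(A))),
         stats::setNames(B, paste0("b_", names(B))),
         list(f1 = ly_conv(8L * W, 4L * W, 1L),
              f2 = ly_conv(4L * W, 2L * W, 1L),
              out = ly_conv(2L * W, 1L, 1L)))
  run_side <- function(tp, x, pre) {
    h <- fw_lrelu(tp, fw_sepconv(tp, x, L[[paste0(pre, "_s1")]]))
    h <- fw_lrelu(tp, fw_sepconv(tp, h, L[[paste0(pre, "_s2")]]))
    fw_lrelu(tp, fw_sepconv(tp, h, L[[paste0(pre, "_s3")]]))
  }
  forward <- function(tp, a, b) {
    av <- arg_val(tp, a); bv <- arg_val(tp, b)
    if (!identical(dim(av)[1:2], dim(bv)[1:2]))
      stop("domain-consistency net: input sizes differ", call. = FALSE)
    ha <- run_side(tp, a, "a"); hb <- run_side(tp, b, "b")
    h <- fw_concat(tp, list(ha, hb))
    h <- fw_lrelu(tp, fw_conv(tp, h, L$f1))
    h <- fw_lrelu(tp, fw_conv(tp, h, L$f2))
    fw_conv(tp, h, L$out)
  }
  make_net("vs_domain_net", L, forward,
           meta = list(kind = "domain_consistency", downsample_stages = 3L,
                       output_stride = 8L),
           cfg = cfg)
}

# ---------------------------------------------------------------------------
# Average-pooling pyramid and the parallel feature fusion generator.
# ---------------------------------------------------------------------------

#' Pyramid specification for the multi-scale generator
#'
#' Step `s` produces an average-pooled image of size `base_size / 2^(s-1)`;
#' the default steps 6..1 on a 256-pixel tile give the 8, 16, 32, 64, 128,
#' 256 scale ladder.
#'
#' @param steps Integer vector of sampling steps.
#' @param base_size Tile size in pixels; must be divisible by
#'   `2^(max(steps)-1)`.
#' @return A list of class `vs_pyramid_spec` with a `sizes` field.
#' @export
pyramid_spec <- function(steps = 6:1, base_size = 256L) {
  steps <- as.integer(steps); base_size <- as.integer(base_size)
  stopifnot(length(steps) >= 1, all(steps >= 1), !anyDuplicated(steps))
  if (base_size %% 2L^(max(steps) - 1L) != 0L)
    stop("base_size must be divisible by 2^(max(step)-1)", call. = FALSE)
  structure(list(steps = steps, base_size = base_size,
                 sizes = base_size %/% 2L^(steps - 1L)),
            class = "vs_pyramid_spec")
}

#' Average-pooling image pyramid
#'
#' Downsamples a tile by average pooling with window = stride = `2^(s-1)`
#' for every step `s` of the spec. Average pooling preserves the global mean
#' at every scale.
#'
#' @param tile A (H,W,C) or (H,W,C,N) array with H = W = `spec$base_size`.
#' @param spec A [pyramid_spec()].
#' @return Named list of arrays, one per step, names `"s<step>"`.
#' @export
avgpool_pyramid <- function(tile, spec = pyramid_spec()) {
  x <- as_batch(tile)
  if (dim(x)[1] != spec$base_size || dim(x)[2] != spec$base_size)
    stop("tile size does not match spec base_size", call. = FALSE)
  out <- lapply(spec$steps, function(s) {
    k <- 2L^(s - 1L)
    if (k == 1L) x else cpp_avgpool_fwd(x, k)
  })
  names(out) <- paste0("s", spec$steps)
  out
}

# depth of the UNet extractor assigned to a pyramid image size
unet_depth_for_size <- function(size) {
  if (size <= 16L) 2L else if (size <= 64L) 4L else 6L
}

#' Structure plan of the parallel feature fusion generator
#'
#' Computes, without allocating any weights, the per-scale layout the
#' builder realizes: pyramid image size, the feature-map size after the
#' FromRGB sampling branches (half the image size), the assigned UNet
#' extractor depth (8/16 px -> depth 2; 32/64 -> 4; 128/256 -> 6) and the
#' fixed feature channel width.
#'
#' @inheritParams build_pffn
#' @return A data.frame with one row per scale, coarse to fine.
#' @export
pffn_structure <- function(cfg = network_config(), spec = pyramid_spec()) {
  sizes <- sort(spec$sizes)
  depth <- vapply(sizes, unet_depth_for_size, 0L)
  feat <- sizes %/% 2L
  bad <- feat < 2L^depth
  if (any(bad))
    stop("base_size incompatible with deepest UNet at scale ",
         paste(sizes[bad], collapse = ","), call. = FALSE)
  data.frame(image_size = sizes, feature_size = feat,
             unet_depth = depth, feature_channels = cfg$feature_width)
}

# UNet_d feature extractor at constant channel width `fw`; d down/up stages,
# same-level skips plus one extra skip from each encoder level to the
# decoder level one step deeper (lower resolution).
unet_d_layers <- function(fw, d) {
  L <- list(e0 = ly_conv(fw, fw, 3L), e0_in = ly_inorm(fw))
  for (i in seq_len(d)) {
    L[[paste0("e", i)]] <- ly_conv(fw, fw, 3L)
    L[[paste0("e", i, "_in")]] <- ly_inorm(fw)
  }
  for (i in seq(d - 1L, 0L)) {
    cin <- if (i >= 1L) 3L * fw else 2L * fw
    L[[paste0("dfuse", i)]] <- ly_conv(cin, fw, 1L)
    L[[paste0("dconv", i)]] <- ly_conv(fw, fw, 3L)
    L[[paste0("dconv", i, "_in")]] <- ly_inorm(fw)
  }
  L
}

unet_d_forward <- function(tp, x, L, d) {
  e <- vector("list", d + 1L)
  e[[1]] <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, x, L$e0), L$e0_in))
  for (i in seq_len(d)) {
    h <- fw_avgpool(tp, e[[i]], 2L)
    e[[i + 1L]] <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L[[paste0("e", i)]]),
                                        L[[paste0("e", i, "_in")]]))
  }
  u <- e[[d + 1L]]
  for (i in seq(d - 1L, 0L)) {
    ins <- list(fw_upsample(tp, u, 2L), e[[i + 1L]])
    if (i >= 1L) ins <- c(ins, list(fw_avgpool(tp, e[[i]], 2L)))
    h <- fw_conv(tp, fw_concat(tp, ins), L[[paste0("dfuse", i)]])
    u <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L[[paste0("dconv", i)]]),
                              L[[paste0("dconv", i, "_in")]]))
  }
  u
}

#' Build the parallel feature fusion generator
#'
#' The paired stain-transfer generator. The input tile is average-pooled
#' into a scale ladder ([avgpool_pyramid()]); each scale passes through a
#' FromRGB module -- three parallel sampling branches (stride-2
#' convolution, average-pool + convolution, max-pool + convolution) fused
#' by a 1x1 convolution to the fixed feature width -- and then through a
#' UNet-style extractor whose sampling depth grows with scale (depth 2 for
#' 8/16 px images, 4 for 32/64, 6 for 128/256). Each extractor carries the
#' conventional same-level skip connections plus an extra skip from every
#' encoder level to the decoder level one step deeper. A fusion decoder
#' merges the per-scale features coarse to fine with skip connections and
#' ends in a tanh output head at the input resolution.
#'
#' @param cfg A [network_config()]; `cfg$feature_width` is the network-wide
#'   feature channel count (512 at full scale).
#' @param spec A [pyramid_spec()] matching the input tile size.
#' @return A `vs_network`; `net$meta$scales` records the realized per-scale
#'   structure (as in [pffn_structure()]), and `net$meta$unet_levels` the
#'   sampling depth of each extractor.
#' @export
build_pffn <- function(cfg = network_config(), spec = pyramid_spec()) {
  fw <- cfg$feature_width
  plan <- pffn_structure(cfg, spec)
  ns <- nrow(plan)
  L <- list()
  for (j in seq_len(ns)) {
    p <- paste0("s", plan$image_size[j], "_")
    L[[paste0(p, "rgb_b1")]] <- ly_conv(cfg$in_channels, fw, 3L, stride = 2L)
    L[[paste0(p, "rgb_b2")]] <- ly_conv(cfg$in_channels, fw, 3L)
    L[[paste0(p, "rgb_b3")]] <- ly_conv(cfg$in_channels, fw, 3L)
    L[[paste0(p, "rgb_fuse")]] <- ly_conv(3L * fw, fw, 1L)
    un <- unet_d_layers(fw, plan$unet_depth[j])
    L <- c(L, stats::setNames(un, paste0(p, "u_", names(un))))
  }
  for (j in seq_len(ns)[-1])
    L[[paste0("fuse", j)]] <- ly_conv(2L * fw, fw, 1L)
  L$head <- ly_conv(fw, fw, 3L)
  L$out <- ly_conv(fw, cfg$out_channels, 3L)
  forward <- function(tp, x) {
    xv <- arg_val(tp, x)
    if (dim(xv)[1] != spec$base_size || dim(xv)[2] != spec$base_size)
      stop("pffn: input size does not match pyramid spec", call. = FALSE)
    feats <- vector("list", ns)
    for (j in seq_len(ns)) {
      sz <- plan$image_size[j]
      k <- spec$base_size %/% sz
      pimg <- fw_avgpool(tp, x, k)
      p <- paste0("s", sz, "_")
      b1 <- fw_conv(tp, pimg, L[[paste0(p, "rgb_b1")]])
      b2 <- fw_conv(tp, fw_avgpool(tp, pimg, 2L), L[[paste0(p, "rgb_b2")]])
      b3 <- fw_conv(tp, fw_maxpool(tp, pimg, 2L), L[[paste0(p, "rgb_b3")]])
      h <- fw_relu(tp, fw_conv(tp, fw_concat(tp, list(b1, b2, b3)),
                               L[[paste0(p, "rgb_fuse")]]))
      sub <- L[grep(paste0("^", p, "u_"), names(L))]
      names(sub) <- sub(paste0(p, "u_"), "", names(sub), fixed = TRUE)
      feats[[j]] <- unet_d_forward(tp, h, sub, plan$unet_depth[j])
    }
    f <- feats[[1]]
    for (j in seq_len(ns)[-1])
      f <- fw_relu(tp, fw_conv(tp, fw_concat(tp, list(fw_upsample(tp, f, 2L),
                                                      feats[[j]])),
                               L[[paste0("fuse", j)]]))
    f <- fw_relu(tp, fw_conv(tp, fw_upsample(tp, f, 2L), L$head))
    fw_tanh(tp, fw_conv(tp, f, L$out))
  }
  make_net("vs_pffn", L, forward,
           meta = list(kind = "pffn", scales = plan,
                       unet_levels = stats::setNames(plan$unet_depth,
                                                     paste0("s", plan$image_size)),
                       feature_width = fw),
           cfg = cfg)
}

#' Build the baseline UNet generator
#'
#' Classic encoder-decoder with same-level skip connections and
#' `cfg$unet_depth` (default 8) stride-2 downsampling stages, used as the
#' architecture ablation baseline against the 6-level deepest extractor of
#' the fusion generator.
#'
#' @inheritParams build_resnet_generator
#' @return A `vs_network`; `net$meta$n_levels` is the number of
#'   downsampling stages. Input size must be divisible by `2^unet_depth`.
#' @export
build_unet_baseline <- function(cfg = network_config()) {
  W <- cfg$base_width; d <- cfg$unet_depth
  ch <- W * pmin(2L^(seq_len(d) - 1L), 8L)
  L <- list()
  cin <- cfg$in_channels
  for (l in seq_len(d)) {
    L[[paste0("e", l)]] <- ly_conv(cin, ch[l], 4L, stride = 2L, pad = 1L)
    if (l > 1L && l < d) L[[paste0("e", l, "_in")]] <- ly_inorm(ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(d - 1L))) {
    cin_l <- (if (l == d - 1L) ch[d] else ch[l + 1L]) + ch[l]
    L[[paste0("d", l)]] <- ly_conv(cin_l, ch[l], 3L)
    L[[paste0("d", l, "_in")]] <- ly_inorm(ch[l])
  }
  L$d0 <- ly_conv(ch[1L] + 0L, W, 3L)  # top decoder stage, no skip at input res
  L$out <- ly_conv(W, cfg$out_channels, 3L)
  forward <- function(tp, x) {
    xv <- arg_val(tp, x)
    if (any(dim(xv)[1:2] %% 2L^d != 0L))
      stop("unet baseline: size must be divisible by 2^depth", call. = FALSE)
    e <- vector("list", d)
    h <- x
    for (l in seq_len(d)) {
      h <- fw_conv(tp, h, L[[paste0("e", l)]])
      if (l > 1L && l < d) h <- fw_inorm(tp, h, L[[paste0("e", l, "_in")]])
      h <- fw_lrelu(tp, h)
      e[[l]] <- h
    }
    u <- e[[d]]
    for (l in rev(seq_len(d - 1L))) {
      h <- fw_concat(tp, list(fw_upsample(tp, u, 2L), e[[l]]))
      u <- fw_relu(tp, fw_inorm(tp, fw_conv(tp, h, L[[paste0("d", l)]]),
                                L[[paste0("d", l, "_in")]]))
    }
    u <- fw_relu(tp, fw_conv(tp, fw_upsample(tp, u, 2L), L$d0))
    fw_tanh(tp, fw_conv(tp, u, L$out))
  }
  make_net("vs_unet_baseline", L, forward,
           meta = list(kind = "unet_baseline", n_levels = d),
           cfg = cfg)
}
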