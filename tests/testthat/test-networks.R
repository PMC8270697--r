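# Architecture contracts: shapes, determinism, parameter counts against
# layer-by-layer oracles, and the multi-scale generator's structure.

small_cfg <- network_config(base_width = 4L, feature_width = 8L, n_blocks = 2L)

test_that("translation generators keep shape, stay in range, run deterministically", {
  set.seed(31)
  x <- rand_tile(16, 16, 3, 2, sd = 0.5)
  for (build in list(build_resnet_generator, build_sep_generator)) {
    net <- build(small_cfg)
    y1 <- net$forward(NULL, x)
    y2 <- net$forward(NULL, x)
    expect_identical(dim(y1), dim(x))
    expect_identical(y1, y2)
    expect_true(all(abs(y1) <= 1))
    expect_error(net$forward(NULL, rand_tile(18, 18, 3, 1)),
                 class = "simpleError")
  }
})

test_that("residual generator parameter count matches a layer-list oracle", {
  W <- 4L; nb <- 2L
  net <- build_resnet_generator(network_config(base_width = W, n_blocks = nb))
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  inorm_p <- function(c) 2L * c
  want <- conv_p(7, 3, W) + inorm_p(W) +
    conv_p(3, W, 2 * W) + inorm_p(2 * W) +
    conv_p(3, 2 * W, 4 * W) + inorm_p(4 * W) +
    nb * (2 * (conv_p(3, 4 * W, 4 * W) + inorm_p(4 * W))) +
    conv_p(3, 4 * W, 2 * W) + inorm_p(2 * W) +
    conv_p(3, 2 * W, W) + inorm_p(W) +
    conv_p(7, W, 3)
  expect_equal(count_params(net), want)
})

test_that("separable generator is depthwise throughout its body and smaller", {
  net <- build_sep_generator(small_cfg)
  base <- build_resnet_generator(small_cfg)
  for (nm in net$meta$body_layers) {
    ly <- net$layers[[nm]]
    expect_identical(ly$kind, "sepconv")
    expect_equal(ly$dw$groups, ly$dw$cin)   # one spatial filter per channel
  }
  expect_lt(count_params(net), count_params(base))
})

test_that("patch critic exposes layer features and matches size arithmetic", {
  D <- build_patch_critic(small_cfg, conditional = TRUE)
  x <- rand_tile(64, 64, 3, 1)
  out <- D$forward(NULL, x, x, features = TRUE)
  expect_gt(dim(out$score)[1], 1)            # a patch map, not a scalar
  expect_equal(dim(out$score)[3], 1)
  expect_length(out$feats, D$meta$n_feature_layers)
  expect_length(out$feats, length(D$meta$kernels))   # one per conv layer
  # analytic output-size arithmetic from the documented strides/kernels
  for (s in c(64L, 128L, 256L)) {
    want <- s
    for (i in seq_along(D$meta$kernels))
      want <- (want + 2L * D$meta$pads[i] - D$meta$kernels[i]) %/%
        D$meta$strides[i] + 1L
    expect_equal(critic_output_size(D, s), want)
    expect_equal(want, s %/% 8L)
  }
  # receptive field arithmetic: rf_{l} = rf_{l-1} + (k_l - 1) * prod(strides)
  rf <- 1L; j <- 1L
  for (i in seq_along(D$meta$kernels)) {
    rf <- rf + (D$meta$kernels[i] - 1L) * j
    j <- j * D$meta$strides[i]
  }
  expect_equal(rf, D$meta$receptive_field)
  expect_equal(rf, 70L)
})

test_that("domain-consistency net mirrors the critic's output shape", {
  C <- build_domain_consistency_net(small_cfg)
  D <- build_patch_critic(small_cfg)
  for (s in c(64L, 128L, 256L)) {
    a <- rand_tile(s, s, 3, 1); b <- rand_tile(s, s, 3, 1)
    out <- C$forward(NULL, a, b)
    expect_identical(dim(out)[1:2], rep(critic_output_size(D, s), 2L))
    expect_equal(dim(out)[3], 1)
    # argument order changes values only, never the shape
    expect_identical(dim(C$forward(NULL, b, a)), dim(out))
  }
  # three stride-2 stages: pre-fusion size is input/8
  expect_equal(dim(C$forward(NULL, rand_tile(256, 256, 3, 1),
                             rand_tile(256, 256, 3, 1)))[1], 256L %/% 8L)
  expect_error(C$forward(NULL, rand_tile(64, 64, 3, 1),
                         rand_tile(32, 32, 3, 1)), "sizes differ")
})

test_that("average-pooling pyramid gives the documented scale ladder", {
  spec <- pyramid_spec(6:1, 256L)
  x <- array(runif(256 * 256 * 3), c(256, 256, 3))
  p <- avgpool_pyramid(x, spec)
  expect_equal(unname(vapply(p, function(a) dim(a)[1], 0L)),
               c(8L, 16L, 32L, 64L, 128L, 256L))
  expect_identical(p$s1[, , , 1], x)          # step 1 is an identity copy
  for (a in p) expect_equal(mean(a), mean(x), tolerance = 1e-6)
  expect_error(pyramid_spec(6:1, 100L), "divisible")
})

test_that("fusion generator realizes the planned per-scale structure", {
  # full-scale structural plan: 512 channels everywhere, depths 2/2/4/4/6/6
  plan <- pffn_structure(network_config(), pyramid_spec())
  expect_true(all(plan$feature_channels == 512L))
  expect_equal(plan$unet_depth, c(2L, 2L, 4L, 4L, 6L, 6L))
  expect_equal(plan$image_size, c(8L, 16L, 32L, 64L, 128L, 256L))
  # a realized small-width net matches its own plan
  cfg <- network_config(base_width = 4L, feature_width = 8L)
  spec <- pyramid_spec(4:1, 64L)
  net <- build_pffn(cfg, spec)
  for (sz in net$meta$scales$image_size)
    expect_equal(net$layers[[paste0("s", sz, "_rgb_fuse")]]$cout, 8L)
  x <- rand_tile(64, 64, 3, 1, sd = 0.5)
  y <- net$forward(NULL, x)
  expect_identical(dim(y), dim(x))
  expect_identical(y, net$forward(NULL, x))
  expect_true(all(abs(y) <= 1))
  expect_error(net$forward(NULL, rand_tile(32, 32, 3, 1)), "pyramid")
  # forward also succeeds at full 256 base with reduced width
  net256 <- build_pffn(network_config(base_width = 2L, feature_width = 4L),
                       pyramid_spec(6:1, 256L))
  y256 <- net256$forward(NULL, rand_tile(256, 256, 3, 1, sd = 0.5))
  expect_identical(dim(y256), c(256L, 256L, 3L, 1L))
})

test_that("deepest extractor has 6 sampling levels versus the UNet baseline's 8", {
  net <- build_pffn(network_config(base_width = 2L, feature_width = 4L),
                    pyramid_spec(6:1, 256L))
  expect_equal(max(net$meta$unet_levels), 6L)
  ub <- build_unet_baseline(network_config(base_width = 2L))
  expect_equal(ub$meta$n_levels, 8L)
  expect_gt(ub$meta$n_levels, max(net$meta$unet_levels))
  set.seed(33)
  xb <- rand_tile(256, 256, 3, 1, sd = 0.5)
  y <- ub$forward(NULL, xb)
  expect_identical(dim(y), c(256L, 256L, 3L, 1L))
  expect_identical(y, ub$forward(NULL, xb))
})
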