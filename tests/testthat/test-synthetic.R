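# Synthetic histology generator: seeded determinism, geometry statistics
# against an independent re-draw of the documented recipe, and renderer
# color contracts.

test_that("zero density gives empty geometry and seeded repeats are identical", {
  g0 <- generate_geometry(256, 256, density = 0, n_classes = 4, seed = 1)
  expect_equal(nrow(g0$nuclei), 0)
  expect_false(any(g0$nucleus_mask))
  ga <- generate_geometry(64, 64, density = 8, n_classes = 4, seed = 42)
  gb <- generate_geometry(64, 64, density = 8, n_classes = 4, seed = 42)
  expect_identical(ga, gb)
  expect_error(generate_geometry(4, 64, 1, 4, 1), class = "vs_invalid_argument")
})

test_that("geometry sampling matches an independent re-implementation", {
  # oracle: rerun the documented recipe directly on the base RNG
  for (seed in c(3, 17, 91)) {
    g <- generate_geometry(256, 256, density = 5, n_classes = 4, seed = seed)
    oracle <- local({
      old <- saved_rng()
      on.exit(restore_rng(old))
      set.seed(seed)
      n <- rpois(1, 5 * 256 * 256 / 1e4)
      cx <- runif(n, 0, 256); cy <- runif(n, 0, 256)
      a <- runif(n, 3, 7); b <- runif(n, 2, 5); th <- runif(n, 0, pi)
      cls <- sample.int(4, 1) - 1L
      list(n = n, cx = cx, cls = cls)
    })
    expect_equal(nrow(g$nuclei), oracle$n)
    expect_equal(g$nuclei$cx, oracle$cx)
    expect_equal(g$tumor_class, oracle$cls)
    expect_true(all(g$nuclei$cx >= 0 & g$nuclei$cx <= 256))
    expect_lt(g$tumor_class, 4)
  }
})

test_that("stained render honors the palette exactly at zero noise", {
  p <- render_params(noise_sd = 0)
  g0 <- generate_geometry(32, 32, density = 0, seed = 5)
  t0 <- render_stained(g0, p)
  for (c in 1:3)
    expect_true(all(t0[, , c] == p$stain_palette$background[c]))
  expect_identical(tile_domain(t0), "stained")
  # nucleus-center pixel takes the nucleus color exactly
  g <- generate_geometry(64, 64, density = 10, seed = 6)
  t1 <- render_stained(g, p)
  i <- round(g$nuclei$cy[1]); j <- round(g$nuclei$cx[1])
  expect_equal(as.numeric(t1[i, j, ]), p$stain_palette$nucleus)
  # mean tile color equals the analytic area-weighted palette mix
  sh <- vs_ns$class_shift(g$tumor_class, g$n_classes)
  n_nuc <- sum(g$nucleus_mask); n_cyt <- sum(g$cytoplasm_mask)
  n_bg <- 64 * 64 - n_nuc - n_cyt
  for (c in 1:3) {
    want <- (n_nuc * p$stain_palette$nucleus[c] +
             n_cyt * (p$stain_palette$cytoplasm[c] + sh[c]) +
             n_bg * p$stain_palette$background[c]) / (64 * 64)
    expect_equal(mean(t1[, , c]), want, tolerance = 1e-10)
  }
})

test_that("unstained render is near-monochrome and shares geometry", {
  p <- render_params(noise_sd = 0)
  g0 <- generate_geometry(32, 32, density = 0, seed = 7)
  u0 <- render_unstained(g0, p)
  expect_equal(length(unique(as.numeric(u0[, , 1]))), 1)
  expect_identical(tile_domain(u0), "unstained")
  # channel correlation >= 0.95 on seeded tiles
  for (s in 1:10) {
    g <- generate_geometry(48, 48, density = 10, seed = 200 + s)
    u <- render_unstained(g, p)
    cc <- stats::cor(cbind(as.numeric(u[, , 1]), as.numeric(u[, , 2]),
                           as.numeric(u[, , 3])))
    expect_true(all(cc >= 0.95))
    # foreground (non-background) pixels coincide with the stained render
    st <- render_stained(g, p)
    fg_u <- u[, , 2] != u0[1, 1, 2]
    bg <- render_params(noise_sd = 0)$stain_palette$background[2]
    fg_s <- st[, , 2] != bg
    expect_identical(fg_u, fg_s)
  }
})

test_that("tiles respect the declared value range", {
  p <- render_params(noise_sd = 0.2, value_range = c(0, 1))
  for (s in 1:5) {
    g <- generate_geometry(32, 32, density = 15, seed = 300 + s)
    st <- render_stained(g, p); un <- render_unstained(g, p)
    expect_true(min(st) >= 0 && max(st) <= 1)
    expect_true(min(un) >= 0 && max(un) <= 1)
  }
})

test_that("make_dataset writes manifests and enforces pairing rules", {
  d <- withr::local_tempdir()
  expect_error(make_dataset(d, 3, 2, paired = TRUE, tile = 16),
               class = "vs_invalid_argument")
  m0 <- make_dataset(file.path(d, "empty"), 0, 0, tile = 16)
  expect_equal(nrow(m0), 0)
  expect_equal(length(list.files(file.path(d, "empty"), pattern = "png",
                                 recursive = TRUE)), 0)
  # paired tiles share foreground masks pixel for pixel at zero noise
  pp <- render_params(noise_sd = 0)
  m <- make_dataset(file.path(d, "paired"), 4, 4, paired = TRUE, tile = 32,
                    seed = 9, params = pp)
  expect_equal(nrow(m), 8)
  bg_s <- png::readPNG(file.path(d, "paired", m$path[1]))[1, 1, ]
  for (i in 1:4) {
    st <- png::readPNG(file.path(d, "paired",
                                 m$path[m$domain == "stained"][i]))
    un <- png::readPNG(file.path(d, "paired",
                                 m$path[m$domain == "unstained"][i]))
    fg_s <- st[, , 2] != st[1, 1, 2]
    fg_u <- un[, , 2] != un[1, 1, 2]
    inter <- sum(fg_s & fg_u); union <- sum(fg_s | fg_u)
    if (union > 0) expect_equal(inter / union, 1.0)
  }
  # unpaired mode draws disjoint geometry seeds per domain
  mu <- make_dataset(file.path(d, "unpaired"), 3, 3, tile = 16, seed = 9)
  expect_length(intersect(mu$seed[mu$domain == "stained"],
                          mu$seed[mu$domain == "unstained"]), 0)
  # byte-identical regeneration under the same seed
  m2 <- make_dataset(file.path(d, "paired2"), 4, 4, paired = TRUE, tile = 32,
                     seed = 9, params = pp)
  f1 <- file.path(d, "paired", m$path[1]); f2 <- file.path(d, "paired2", m2$path[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
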