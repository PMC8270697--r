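# Synthetic histology: procedurally generated stained / unstained tile pairs
# with shared cell geometry, so the translation and staining models are
# testable end to end without any external imagery.

#' Rendering parameters for synthetic tiles
#'
#' @param stain_palette Named list with `nucleus`, `cytoplasm`, `background`
#'   RGB triples (in `value_range` units). Defaults approximate H&E:
#'   blue-purple nuclei, pink cytoplasm, near-white background.
#' @param fluor_gain Overall intensity gain of the unstained
#'   (autofluorescence-like) rendering.
#' @param noise_sd Gaussian pixel noise standard deviation; 0 gives exact
#'   palette colors.
#' @param value_range Two-element `c(lo, hi)` value range of rendered tiles.
#' @return A list of class `vs_render_params`.
#' @export
render_params <- function(stain_palette = list(
                            nucleus = c(0.35, 0.22, 0.55),
                            cytoplasm = c(0.91, 0.65, 0.77),
                            background = c(0.97, 0.95, 0.97)),
                          fluor_gain = 1, noise_sd = 0.02,
                          value_range = c(0, 1)) {
  if (!all(c("nucleus", "cytoplasm", "background") %in% names(stain_palette)))
    vs_stop("stain_palette must define nucleus/cytoplasm/background",
            "vs_invalid_argument")
  if (noise_sd < 0) vs_stop("noise_sd must be >= 0", "vs_invalid_argument")
  if (value_range[1] >= value_range[2])
    vs_stop("value_range must satisfy lo < hi", "vs_invalid_argument")
  structure(list(stain_palette = stain_palette, fluor_gain = fluor_gain,
                 noise_sd = noise_sd, value_range = value_range),
            class = "vs_render_params")
}

# logical (H, W) mask of the union of ellipses, optionally scaled;
# rasterized per-ellipse within its bounding box
ellipse_mask <- function(width, height, nuc, scale = 1) {
  m <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(nuc))) {
    a <- nuc$a[i] * scale; b <- nuc$b[i] * scale; th <- nuc$angle[i]
    r <- max(a, b)
    cols <- max(1L, floor(nuc$cx[i] - r)):min(width, ceiling(nuc$cx[i] + r))
    rows <- max(1L, floor(nuc$cy[i] - r)):min(height, ceiling(nuc$cy[i] + r))
    dx <- matrix(cols, length(rows), length(cols), byrow = TRUE) - nuc$cx[i]
    dy <- matrix(rows, length(rows), length(cols)) - nuc$cy[i]
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    m[rows, cols] <- m[rows, cols] | (u * u + v * v <= 1)
  }
  m
}

#' Generate synthetic cell geometry
#'
#' Draws a tile's worth of cell geometry under a fixed seed. The sampling
#' recipe, in order, is: nucleus count `n ~ Poisson(density * width *
#' height / 1e4)`; then `runif(n, 0, width)` x-centers, `runif(n, 0,
#' height)` y-centers, `runif(n, 3, 7)` semi-major axes, `runif(n, 2, 5)`
#' semi-minor axes, `runif(n, 0, pi)` orientations; finally the tumor class
#' `sample.int(n_classes, 1) - 1`. Cytoplasm is the union of the nuclear
#' ellipses scaled 1.8x.
#'
#' @param width,height Canvas size in pixels (>= 8).
#' @param density Expected nuclei per 1e4 square pixels.
#' @param n_classes Number of tumor classes `K`; the class label is drawn
#'   uniformly from `0..K-1`.
#' @param seed Integer seed; identical arguments give identical geometry.
#' @return A list of class `vs_cell_geometry` with fields `nuclei`
#'   (data.frame cx, cy, a, b, angle), `nucleus_mask`, `cytoplasm_mask`
#'   (logical height x width matrices), `tumor_class`, `n_classes`,
#'   `width`, `height`, `seed`.
#' @export
generate_geometry <- function(width = 256L, height = 256L, density = 12,
                              n_classes = 4L, seed = 1L) {
  if (width < 8 || height < 8)
    vs_stop("width and height must be >= 8", "vs_invalid_argument")
  if (density < 0) vs_stop("density must be >= 0", "vs_invalid_argument")
  if (n_classes < 1) vs_stop("n_classes must be >= 1", "vs_invalid_argument")
  g <- with_seed(seed, {
    n <- stats::rpois(1L, density * width * height / 1e4)
    nuc <- data.frame(cx = stats::runif(n, 0, width),
                      cy = stats::runif(n, 0, height),
                      a = stats::runif(n, 3, 7),
                      b = stats::runif(n, 2, 5),
                      angle = stats::runif(n, 0, pi))
    cls <- sample.int(n_classes, 1L) - 1L
    list(nuc = nuc, cls = cls)
  })
  nucleus_mask <- ellipse_mask(width, height, g$nuc, scale = 1)
  cyto_mask <- ellipse_mask(width, height, g$nuc, scale = 1.8) & !nucleus_mask
  structure(list(nuclei = g$nuc, nucleus_mask = nucleus_mask,
                 cytoplasm_mask = cyto_mask, tumor_class = g$cls,
                 n_classes = as.integer(n_classes),
                 width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed)),
            class = "vs_cell_geometry")
}

# Small class-dependent cytoplasm hue rotation so the tumor class is
# learnable from color alone. The shift moves the mid-range G/B channels in
# opposite directions (never the near-saturated R channel), so no class is
# pushed against the value-range clamp where the signal would be destroyed.
class_shift <- function(cls, n_classes, strength = 0.15) {
  if (n_classes <= 1L) return(c(0, 0, 0))
  t <- cls / (n_classes - 1) - 0.5
  strength * t * c(0, 1, -1)
}

render_noise <- function(dims, sd, seed) {
  if (sd == 0) return(0)
  with_seed(seed, array(stats::rnorm(prod(dims), 0, sd), dims))
}

#' Render a stained (H&E-like) tile from geometry
#'
#' Paints background, cytoplasm and nucleus pixels with the palette colors
#' (the cytoplasm color is shifted slightly by the tumor class so the
#' class is learnable; the nucleus color is exact),
#' adds Gaussian noise and clamps to the value range. Rendering is
#' deterministic: the noise stream is seeded from the geometry seed.
#'
#' @param geom A [generate_geometry()] result.
#' @param params A [render_params()].
#' @return An (H, W, 3) tile with domain tag `"stained"`.
#' @export
render_stained <- function(geom, params = render_params()) {
  pal <- params$stain_palette
  lo <- params$value_range[1]; hi <- params$value_range[2]
  sh <- class_shift(geom$tumor_class, geom$n_classes)
  img <- array(0, c(geom$height, geom$width, 3L))
  for (c in 1:3) {
    ch <- matrix(pal$background[c], geom$height, geom$width)
    ch[geom$cytoplasm_mask] <- pal$cytoplasm[c] + sh[c]
    ch[geom$nucleus_mask] <- pal$nucleus[c]   # nucleus color is class-invariant
    img[, , c] <- ch
  }
  img <- img + render_noise(dim(img), params$noise_sd,
                            derive_seed(geom$seed, 101L))
  new_tile(clamp(img, lo, hi), "stained", params$value_range)
}

#' Render an unstained (autofluorescence-like) tile from geometry
#'
#' The unstained domain is intensity-dominated and nearly monochrome: a
#' single fluorescence intensity map (dim background, bright cytoplasm,
#' darker nuclei) is spread over the three channels with fixed channel
#' weights, so at `noise_sd = 0` the channels are perfectly correlated.
#' Foreground structure is pixel-identical to the stained render of the
#' same geometry.
#'
#' @inheritParams render_stained
#' @return An (H, W, 3) tile with domain tag `"unstained"`.
#' @export
render_unstained <- function(geom, params = render_params()) {
  lo <- params$value_range[1]; hi <- params$value_range[2]
  span <- hi - lo
  inten <- matrix(0.06, geom$height, geom$width)
  inten[geom$cytoplasm_mask] <- 0.65
  inten[geom$nucleus_mask] <- 0.30
  inten <- inten * params$fluor_gain
  w <- c(0.55, 1.0, 0.8)  # greenish autofluorescence channel weights
  img <- array(0, c(geom$height, geom$width, 3L))
  for (c in 1:3) img[, , c] <- lo + span * inten * w[c]
  img <- img + render_noise(dim(img), params$noise_sd,
                            derive_seed(geom$seed, 202L))
  new_tile(clamp(img, lo, hi), "unstained", params$value_range)
}

#' Write a synthetic stained/unstained tile data set to disk
#'
#' Emulates the study's data regime -- by default 400 stained tiles and 80
#' unstained tiles from disjoint geometries (unpaired mode). In paired mode
#' each stained/unstained pair shares one geometry, so foreground masks
#' coincide pixel for pixel. Tiles are written as 8-bit RGB PNG files under
#' `dir/stained` and `dir/unstained`, with a JSON manifest of relative
#' paths, domains, class labels and seeds.
#'
#' @param dir Output directory (created if missing).
#' @param n_stained,n_unstained Tile counts (defaults 400 and 80).
#' @param paired If `TRUE`, requires `n_stained == n_unstained` and reuses
#'   the geometry per pair.
#' @param tile Tile size in pixels.
#' @param seed Integer seed; per-tile geometry seeds are derived from it
#'   (disjoint between domains in unpaired mode).
#' @param density,n_classes Passed to [generate_geometry()].
#' @param params A [render_params()].
#' @return The manifest as a data.frame (path, domain, class, seed,
#'   pair_id), invisibly also written to `dir/manifest.json`.
#' @export
make_dataset <- function(dir, n_stained = 400L, n_unstained = 80L,
                         paired = FALSE, tile = 256L, seed = 1L,
                         density = 12, n_classes = 4L,
                         params = render_params()) {
  if (n_stained < 0 || n_unstained < 0)
    vs_stop("counts must be >= 0", "vs_invalid_argument")
  if (paired && n_stained != n_unstained)
    vs_stop("paired mode requires n_stained == n_unstained",
            "vs_invalid_argument")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(domain, i, gseed) {
    geom <- generate_geometry(tile, tile, density, n_classes, gseed)
    img <- if (domain == "stained") render_stained(geom, params)
           else render_unstained(geom, params)
    sub <- file.path(dir, domain)
    dir.create(sub, showWarnings = FALSE)
    rel <- file.path(domain, sprintf("%s_%04d.png", domain, i))
    write_tile(img, file.path(dir, rel), params$value_range)
    data.frame(path = rel, domain = domain, class = geom$tumor_class,
               seed = gseed, pair_id = if (paired) i else NA_integer_,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_stained)) {
    gseed <- if (paired) derive_seed(seed, i) else derive_seed(seed, 2L * i)
    rows[[length(rows) + 1L]] <- emit("stained", i, gseed)
  }
  for (i in seq_len(n_unstained)) {
    gseed <- if (paired) derive_seed(seed, i) else derive_seed(seed, 2L * i + 1L)
    rows[[length(rows) + 1L]] <- emit("unstained", i, gseed)
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(path = character(0), domain = character(0),
                    class = integer(0), seed = integer(0),
                    pair_id = integer(0))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(manifest)
}
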