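# Stage-1 augmentation suite and the per-domain input buffer that feeds the
# domain-consistency game. All geometric resampling is bilinear with a
# reflected border, so augmented tiles never acquire black corners that
# would confound the dark-hole artifact analysis.

#' Augmentation policy
#'
#' @param jitter_px Maximum absolute translation in pixels (0 disables).
#' @param p_hflip,p_vflip Flip probabilities in `[0,1]`.
#' @param rot_max_deg Maximum jitter-rotation angle in degrees; the applied
#'   angle is drawn uniformly from `[-rot_max_deg, rot_max_deg]`.
#' @param zoom Fixed upscale factor (>= 1) applied before the jitter
#'   rotation; the result is center-cropped back to the tile size.
#' @param elastic_alpha Elastic displacement amplitude in pixels (0 disables).
#' @param elastic_sigma Gaussian smoothing bandwidth of the elastic field.
#' @return A list of class `vs_augment_policy`. The identity policy
#'   (`augmentation_policy(0, 0, 0, 0, 1, 0)`) is a strict no-op.
#' @export
augmentation_policy <- function(jitter_px = 8L, p_hflip = 0.5, p_vflip = 0.5,
                                rot_max_deg = 10, zoom = 1.1,
                                elastic_alpha = 1.5, elastic_sigma = 8) {
  if (zoom < 1) vs_stop("zoom must be >= 1", "vs_invalid_argument")
  if (p_hflip < 0 || p_hflip > 1 || p_vflip < 0 || p_vflip > 1)
    vs_stop("flip probabilities must lie in [0,1]", "vs_invalid_argument")
  if (jitter_px < 0 || rot_max_deg < 0 || elastic_alpha < 0 || elastic_sigma < 0)
    vs_stop("policy magnitudes must be >= 0", "vs_invalid_argument")
  structure(list(jitter_px = as.integer(jitter_px), p_hflip = p_hflip,
                 p_vflip = p_vflip, rot_max_deg = rot_max_deg, zoom = zoom,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma),
            class = "vs_augment_policy")
}

#' The no-op augmentation policy
#' @export
identity_policy <- function() augmentation_policy(0L, 0, 0, 0, 1, 0, 0)

# reflect integer indices into 1..n
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p <= n - 1L, p + 1L, 2L * n - 1L - p)
}

# Sample img (H,W,C) at real-valued source coordinates (ys, xs), bilinear
# with reflected border. ys/xs are matrices of the output shape.
bilinear_gather <- function(img, ys, xs) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  i0 <- reflect_idx(as.integer(y0), H); i1 <- reflect_idx(as.integer(y0) + 1L, H)
  j0 <- reflect_idx(as.integer(x0), W); j1 <- reflect_idx(as.integer(x0) + 1L, W)
  out <- array(0, c(dim(ys), C))
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  for (c in seq_len(C)) {
    ch <- img[, , c]
    out[, , c] <- w00 * ch[cbind(c(i0), c(j0))] + w01 * ch[cbind(c(i0), c(j1))] +
                  w10 * ch[cbind(c(i1), c(j0))] + w11 * ch[cbind(c(i1), c(j1))]
  }
  out
}

bilinear_resize <- function(img, Ho, Wo) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- matrix((seq_len(Ho) - 0.5) * H / Ho + 0.5, Ho, Wo)
  xs <- matrix((seq_len(Wo) - 0.5) * W / Wo + 0.5, Ho, Wo, byrow = TRUE)
  bilinear_gather(img, ys, xs)
}

rotate_image <- function(img, theta) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  ys <- cy + cos(theta) * dy + sin(theta) * dx
  xs <- cx - sin(theta) * dy + cos(theta) * dx
  bilinear_gather(img, ys, xs)
}

center_crop <- function(img, H, W) {
  Hi <- dim(img)[1]; Wi <- dim(img)[2]
  r0 <- floor((Hi - H) / 2); c0 <- floor((Wi - W) / 2)
  img[r0 + seq_len(H), c0 + seq_len(W), , drop = FALSE]
}

# Gaussian smoothing of a matrix with reflected borders (separable kernel)
smooth_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), 0, sigma); k <- k / sum(k)
  pad_filter <- function(x) {  # filter columns of x
    n <- nrow(x)
    top <- x[reflect_idx(seq(1L - r, 0L), n), , drop = FALSE]
    bot <- x[reflect_idx(seq(n + 1L, n + r), n), , drop = FALSE]
    xp <- rbind(top, x, bot)
    f <- stats::filter(xp, k, sides = 2)
    matrix(f[r + seq_len(n), ], n, ncol(x))
  }
  t(pad_filter(t(pad_filter(m))))
}

#' Apply the stage-1 augmentation suite to one tile
#'
#' Order of operations: horizontal/vertical flips, random jitter
#' translation, the jitter-rotation path (bilinear upscale by `zoom`,
#' rotation by an angle drawn uniformly from the policy's range, center
#' crop back to the tile size), and elastic deformation (a Gaussian-smoothed
#' uniform displacement field scaled by `elastic_alpha`, warped with a
#' reflected border). Random draws happen only for steps the policy
#' enables, so the identity policy returns the input bit for bit.
#'
#' @param tile (H,W,C) tile (H, W >= 8).
#' @param policy An [augmentation_policy()].
#' @param seed Optional seed for a self-contained deterministic draw;
#'   by default the session RNG stream is used.
#' @return A tile of identical shape and value range.
#' @export
augment <- function(tile, policy = augmentation_policy(), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, augment(tile, policy)))
  d <- dim(tile)
  if (is.null(d) || length(d) != 3L || d[1] < 8L || d[2] < 8L)
    vs_stop("tile must be (H,W,C) with H,W >= 8", "vs_invalid_argument")
  at <- attributes(tile)
  rng <- attr(tile, "range", exact = TRUE)
  x <- unclass(tile); attributes(x) <- list(dim = d)
  H <- d[1]; W <- d[2]
  if (policy$p_hflip > 0 && stats::runif(1) < policy$p_hflip)
    x <- x[, W:1, , drop = FALSE]
  if (policy$p_vflip > 0 && stats::runif(1) < policy$p_vflip)
    x <- x[H:1, , , drop = FALSE]
  if (policy$jitter_px > 0) {
    j <- policy$jitter_px
    off <- sample.int(2L * j + 1L, 2L, replace = TRUE) - j - 1L
    ys <- matrix(seq_len(H) + off[1], H, W)
    xs <- matrix(seq_len(W) + off[2], H, W, byrow = TRUE)
    x <- bilinear_gather(x, ys, xs)
  }
  if (policy$zoom > 1 || policy$rot_max_deg > 0) {
    if (policy$zoom > 1)
      x <- bilinear_resize(x, round(H * policy$zoom), round(W * policy$zoom))
    if (policy$rot_max_deg > 0) {
      th <- stats::runif(1, -policy$rot_max_deg, policy$rot_max_deg) * pi / 180
      x <- rotate_image(x, th)
    }
    x <- center_crop(x, H, W)
  }
  if (policy$elastic_alpha > 0) {
    dy <- smooth_gauss(matrix(stats::runif(H * W, -1, 1), H, W),
                       policy$elastic_sigma) * policy$elastic_alpha
    dx <- smooth_gauss(matrix(stats::runif(H * W, -1, 1), H, W),
                       policy$elastic_sigma) * policy$elastic_alpha
    ys <- matrix(seq_len(H), H, W) + dy
    xs <- matrix(seq_len(W), H, W, byrow = TRUE) + dx
    x <- bilinear_gather(x, ys, xs)
  }
  if (!is.null(rng)) x <- clamp(x, rng[1], rng[2])
  attributes(x) <- c(list(dim = d), at[setdiff(names(at), "dim")])
  x
}

# --- input buffer ------------------------------------------------------------

#' Create a bounded FIFO input buffer
#'
#' Stores heavily augmented real tiles of one domain; the
#' domain-consistency game draws its same-domain batches from here. When
#' the buffer exceeds its capacity the oldest tiles are evicted first.
#'
#' @param capacity Maximum number of stored tiles (> 0).
#' @return An object of class `vs_input_buffer`.
#' @export
input_buffer <- function(capacity = 256L) {
  if (capacity <= 0) vs_stop("capacity must be > 0", "vs_invalid_argument")
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$items <- list()
  class(buf) <- "vs_input_buffer"
  buf
}

#' Push tiles into the buffer (FIFO eviction)
#' @param buf A [input_buffer()].
#' @param tiles A list of tiles (or a single tile array).
#' @return The buffer, invisibly; it is modified in place.
#' @export
buffer_push <- function(buf, tiles) {
  if (!inherits(buf, "vs_input_buffer"))
    vs_stop("not an input buffer", "vs_invalid_argument")
  if (!is.list(tiles)) tiles <- list(tiles)
  buf$items <- c(buf$items, tiles)
  n <- length(buf$items)
  if (n > buf$capacity)
    buf$items <- buf$items[(n - buf$capacity + 1L):n]
  invisible(buf)
}

#' Number of tiles currently stored
#' @param buf A [input_buffer()].
#' @export
buffer_size <- function(buf) length(buf$items)

#' Stored tiles, oldest first
#' @param buf A [input_buffer()].
#' @export
buffer_dump <- function(buf) buf$items

#' Draw random batches from the buffer
#'
#' Each batch is drawn uniformly without replacement within the batch;
#' batches are drawn independently of each other (a tile may recur across
#' batches). Deterministic under a fixed seed.
#'
#' @param buf A [input_buffer()].
#' @param batch Batch size (<= buffer size).
#' @param n_batches Number of independent batches.
#' @param seed Optional seed for a self-contained draw.
#' @return A list of `n_batches` lists of tiles.
#' @export
buffer_sample <- function(buf, batch, n_batches = 1L, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, buffer_sample(buf, batch, n_batches)))
  n <- length(buf$items)
  if (batch > n)
    vs_stop("batch size exceeds buffer size", "vs_insufficient_data")
  lapply(seq_len(n_batches), function(b) buf$items[sample.int(n, batch)])
}
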