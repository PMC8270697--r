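#' @useDynLib virtstain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Tensors are plain R arrays with dim (H, W, C, N). A "tape" records every
# operation of a forward pass so that reverse-mode gradients of a scalar loss
# can be pushed back to inputs and parameters. Layers own their parameters;
# all per-call caches live in the tape nodes, so a layer can appear several
# times in one forward pass (weight sharing) without state clashes.
# ---------------------------------------------------------------------------

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a plain vector", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a (H,W,C) or (H,W,C,N) array", call. = FALSE)
  x
}

# -- parameters --------------------------------------------------------------

vs_param <- function(dims, sd = NULL, const = NULL) {
  p <- new.env(parent = emptyenv())
  if (!is.null(const)) {
    p$v <- array(const, dims)
  } else {
    if (is.null(sd)) sd <- 0.02
    p$v <- array(rnorm(prod(dims), 0, sd), dims)
  }
  p$g <- array(0, dims)
  p$m <- array(0, dims)   # Adam first moment
  p$s <- array(0, dims)   # Adam second moment
  class(p) <- "vs_param"
  p
}

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

n_params <- function(params) sum(vapply(params, function(p) length(p$v), 0))

# -- tape --------------------------------------------------------------------

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- list(); tp$parents <- list(); tp$back <- list(); tp$n <- 0L
  class(tp) <- "vs_tape"
  tp
}

tp_push <- function(tp, value, parents = integer(0), back = NULL) {
  i <- tp$n + 1L
  tp$val[[i]] <- value
  tp$parents[[i]] <- as.integer(parents)
  tp$back[[i]] <- back
  tp$n <- i
  i
}

tp_value <- function(tp, id) {
  i <- id   # force before reading the node list (see arg_val)
  tp$val[[i]]
}

# Reverse sweep from node `id` seeded with `seed` (same shape as the node's
# value, or a scalar). Parameter gradients are accumulated into the layer
# parameter environments by the nodes' back() closures; returns the list of
# gradients for every node so callers can read input gradients.
tp_backward <- function(tp, id, seed = 1) {
  grads <- vector("list", tp$n)
  v <- tp$val[[id]]
  g0 <- if (length(seed) == 1L && !is.null(dim(v))) array(seed, dim(v)) else seed
  grads[[id]] <- g0
  for (i in seq(id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bk <- tp$back[[i]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tp$parents[[i]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      j <- ps[k]
      grads[[j]] <- if (is.null(grads[[j]])) pg[[k]] else grads[[j]] + pg[[k]]
    }
  }
  grads
}

# Resolve an op argument: with a live tape arguments are node ids; without
# one they are raw arrays/scalars. The id promise must be forced BEFORE
# tp$val is read: evaluating a nested op call appends to the tape, and
# subsetting a stale copy of the node list would miss it.
arg_val <- function(tp, x) {
  if (is.null(tp)) return(x)
  id <- x
  tp$val[[id]]
}

# -- layers ------------------------------------------------------------------

ly_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    groups = 1L, bias = TRUE, gain = 1) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad); ly$groups <- as.integer(groups)
  ly$cin <- as.integer(cin); ly$cout <- as.integer(cout)
  fan_in <- k * k * (cin / groups)
  ly$w <- vs_param(c(k, k, cin %/% groups, cout), sd = gain * sqrt(2 / fan_in))
  ly$b <- if (bias) vs_param(cout, const = 0) else NULL
  class(ly) <- "vs_layer"
  ly
}

fw_conv <- function(tp, x, ly) {
  xv <- arg_val(tp, x)
  bv <- if (is.null(ly$b)) numeric(0) else as.numeric(ly$b$v)
  y <- cpp_conv2d_fwd(xv, ly$w$v, bv, ly$stride, ly$pad, ly$groups)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    r <- cpp_conv2d_bwd(xv, ly$w$v, g, ly$stride, ly$pad, ly$groups, !is.null(ly$b))
    ly$w$g <- ly$w$g + r$gw
    if (!is.null(ly$b)) ly$b$g <- ly$b$g + r$gb
    list(r$gx)
  })
}

# Depthwise separable convolution: per-channel spatial filter then 1x1 mix.
ly_sepconv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "sepconv"
  ly$dw <- ly_conv(cin, cin, k, stride = stride, pad = pad, groups = cin, bias = FALSE)
  ly$pw <- ly_conv(cin, cout, 1L, bias = bias)
  class(ly) <- "vs_layer"
  ly
}

fw_sepconv <- function(tp, x, ly) {
  h <- fw_conv(tp, x, ly$dw)
  fw_conv(tp, h, ly$pw)
}

ly_inorm <- function(c, eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "inorm"; ly$c <- as.integer(c); ly$eps <- eps
  ly$gamma <- vs_param(c, const = 1)
  ly$beta  <- vs_param(c, const = 0)
  class(ly) <- "vs_layer"
  ly
}

fw_inorm <- function(tp, x, ly) {
  xv <- arg_val(tp, x)
  d <- dim(xv); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; CN <- C * N
  xm <- xv; dim(xm) <- c(HW, CN)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = HW)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + ly$eps)
  xhat <- xc * rep(inv, each = HW)
  ch <- rep_len(seq_len(C), CN)                 # channel index of each column
  gcol <- ly$gamma$v[ch]; bcol <- ly$beta$v[ch]
  y <- xhat * rep(gcol, each = HW) + rep(bcol, each = HW)
  dim(y) <- d
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gm <- g; dim(gm) <- c(HW, CN)
    dgam <- colSums(gm * xhat); dbet <- colSums(gm)
    ly$gamma$g <- ly$gamma$g + as.numeric(rowsum(dgam, ch))
    ly$beta$g  <- ly$beta$g  + as.numeric(rowsum(dbet, ch))
    dxhat <- gm * rep(gcol, each = HW)
    s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
    gx <- rep(inv / HW, each = HW) *
      (HW * dxhat - rep(s1, each = HW) - xhat * rep(s2, each = HW))
    dim(gx) <- d
    list(gx)
  })
}

# -- parameterless ops -------------------------------------------------------

fw_lrelu <- function(tp, x, slope = 0.2) {
  xv <- arg_val(tp, x)
  y <- pmax(xv, 0) + slope * pmin(xv, 0)
  dim(y) <- dim(xv)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gx <- g * ((xv > 0) + slope * (xv <= 0)); dim(gx) <- dim(xv); list(gx)
  })
}

fw_relu <- function(tp, x) fw_lrelu(tp, x, slope = 0)

fw_tanh <- function(tp, x) {
  y <- tanh(arg_val(tp, x))
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) list(g * (1 - y * y)))
}

fw_avgpool <- function(tp, x, k) {
  xv <- arg_val(tp, x); d <- dim(xv)
  if (k == 1L) { # identity copy
    if (is.null(tp)) return(xv)
    return(tp_push(tp, xv, parents = x, back = function(g) list(g)))
  }
  y <- cpp_avgpool_fwd(xv, as.integer(k))
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x,
          back = function(g) list(cpp_avgpool_bwd(g, as.integer(k), d[1], d[2])))
}

fw_maxpool <- function(tp, x, k) {
  xv <- arg_val(tp, x); d <- dim(xv)
  r <- cpp_maxpool_fwd(xv, as.integer(k))
  if (is.null(tp)) return(r$y)
  tp_push(tp, r$y, parents = x,
          back = function(g) list(cpp_maxpool_bwd(g, r$idx, d[1], d[2])))
}

fw_upsample <- function(tp, x, f) {
  xv <- arg_val(tp, x)
  y <- cpp_upsample_fwd(xv, as.integer(f))
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x,
          back = function(g) list(cpp_upsample_bwd(g, as.integer(f))))
}

concat_c_arrays <- function(xs) {
  ds <- lapply(xs, dim)
  d1 <- ds[[1]]
  cs <- vapply(ds, function(d) d[3], 0)
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , (at + 1L):(at + cs[i]), ] <- xs[[i]]
    at <- at + cs[i]
  }
  out
}

fw_concat <- function(tp, xs) {
  vs <- lapply(xs, function(x) arg_val(tp, x))
  y <- concat_c_arrays(vs)
  if (is.null(tp)) return(y)
  cs <- vapply(vs, function(v) dim(v)[3], 0)
  tp_push(tp, y, parents = unlist(xs), back = function(g) {
    out <- vector("list", length(cs)); at <- 0L
    for (i in seq_along(cs)) {
      out[[i]] <- g[, , (at + 1L):(at + cs[i]), , drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

fw_add <- function(tp, a, b) {
  av <- arg_val(tp, a); bv <- arg_val(tp, b)
  y <- av + bv
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = c(a, b), back = function(g) list(g, g))
}

fw_sub <- function(tp, a, b) {
  av <- arg_val(tp, a); bv <- arg_val(tp, b)
  y <- av - bv
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = c(a, b), back = function(g) list(g, -g))
}

fw_scale <- function(tp, x, s) {
  xv <- arg_val(tp, x)
  y <- xv * s
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) list(g * s))
}

# scalar reductions -----------------------------------------------------------

fw_mean_abs <- function(tp, x) {
  xv <- arg_val(tp, x); m <- length(xv)
  y <- mean(abs(xv))
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gx <- array(as.numeric(g) * sign(xv) / m, dim(xv)); list(gx)
  })
}

fw_mean_square <- function(tp, x) {
  xv <- arg_val(tp, x); m <- length(xv)
  y <- mean(xv * xv)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gx <- array(as.numeric(g) * 2 * xv / m, dim(xv)); list(gx)
  })
}

fw_mean <- function(tp, x) {
  xv <- arg_val(tp, x); m <- length(xv)
  y <- mean(xv)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gx <- array(as.numeric(g) / m, dim(xv)); list(gx)
  })
}

# mean(softplus(sign * x)) used by the non-saturating logistic objectives
fw_mean_softplus <- function(tp, x, sign = 1) {
  xv <- arg_val(tp, x) * sign; m <- length(xv)
  sp <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  y <- mean(sp)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) {
    gx <- array(as.numeric(g) * sign * stats::plogis(xv) / m, dim(arg_val(tp, x)))
    list(gx)
  })
}

fw_shift_const <- function(tp, x, const) {
  xv <- arg_val(tp, x)
  y <- xv + const
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = x, back = function(g) list(g))
}

# weighted sum of scalar nodes
fw_wsum <- function(tp, ids, w = rep(1, length(ids))) {
  vs <- vapply(ids, function(i) as.numeric(arg_val(tp, i)), 0)
  y <- sum(vs * w)
  if (is.null(tp)) return(y)
  tp_push(tp, y, parents = unlist(ids), back = function(g) {
    as.list(as.numeric(g) * w)
  })
}

# -- parameter collection, optimizer, weight IO ------------------------------

layer_params <- function(ly) {
  if (inherits(ly, "vs_param")) return(list(ly))
  if (!inherits(ly, "vs_layer")) return(list())
  switch(ly$kind,
    conv    = c(list(ly$w), if (!is.null(ly$b)) list(ly$b)),
    sepconv = c(layer_params(ly$dw), layer_params(ly$pw)),
    inorm   = list(ly$gamma, ly$beta),
    stop("unknown layer kind: ", ly$kind)
  )
}

collect_params <- function(layers) {
  out <- list()
  for (ly in layers) out <- c(out, layer_params(ly))
  out
}

adam_new <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params; opt$lr <- lr; opt$b1 <- beta1; opt$b2 <- beta2
  opt$eps <- eps; opt$t <- 0L
  class(opt) <- "vs_adam"
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t; bc2 <- 1 - opt$b2^opt$t
  for (p in opt$params) {
    p$m <- opt$b1 * p$m + (1 - opt$b1) * p$g
    p$s <- opt$b2 * p$s + (1 - opt$b2) * p$g * p$g
    p$v <- p$v - opt$lr * (p$m / bc1) / (sqrt(p$s / bc2) + opt$eps)
  }
  invisible(NULL)
}

get_weights <- function(net) {
  lapply(net$params, function(p) list(v = p$v, m = p$m, s = p$s))
}

set_weights <- function(net, ws) {
  if (length(ws) != length(net$params))
    stop("weight list length does not match network", call. = FALSE)
  for (i in seq_along(ws)) {
    p <- net$params[[i]]
    if (!identical(dim(p$v), dim(ws[[i]]$v)) && length(p$v) != length(ws[[i]]$v))
      stop("weight ", i, " has incompatible shape", call. = FALSE)
    p$v[] <- ws[[i]]$v; p$m[] <- ws[[i]]$m; p$s[] <- ws[[i]]$s
  }
  invisible(net)
}
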