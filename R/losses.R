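# Objectives: cycle consistency, the domain-consistency game, three
# adversarial variants (least-squares, Wasserstein + gradient penalty,
# non-saturating logistic + R1), pixel L1, feature matching and the total
# weighted loss. The exported functions here evaluate loss VALUES on raw
# arrays (audit mode); the trainers re-express the same formulas on the
# gradient tape.

#' Loss weights and adversarial variant
#'
#' @param lambda_gp Gradient-penalty weight (default 10).
#' @param lambda_pix Pixel L1 weight (default 100).
#' @param lambda_fm Feature-matching weight (default 10).
#' @param lambda_cyc Cycle-consistency weight (default 10, stage 1).
#' @param lambda_dc Domain-consistency weight (default 1, stage 1).
#' @param gamma_r1 R1 regularization weight (default 10).
#' @param adv_variant One of `"wgan_gp"`, `"l2"`, `"logistic_r1"`.
#' @return A list of class `vs_loss_weights`.
#' @export
loss_weights <- function(lambda_gp = 10, lambda_pix = 100, lambda_fm = 10,
                         lambda_cyc = 10, lambda_dc = 1, gamma_r1 = 10,
                         adv_variant = c("wgan_gp", "l2", "logistic_r1")) {
  adv_variant <- match.arg(adv_variant)
  w <- c(lambda_gp, lambda_pix, lambda_fm, lambda_cyc, lambda_dc, gamma_r1)
  if (any(!is.finite(w)) || any(w < 0))
    vs_stop("loss weights must be finite and >= 0", "vs_invalid_argument")
  structure(list(lambda_gp = lambda_gp, lambda_pix = lambda_pix,
                 lambda_fm = lambda_fm, lambda_cyc = lambda_cyc,
                 lambda_dc = lambda_dc, gamma_r1 = gamma_r1,
                 adv_variant = adv_variant),
            class = "vs_loss_weights")
}

# apply a generator that may be a vs_network or a plain function
apply_map <- function(G, x) {
  if (inherits(G, "vs_network")) {
    y <- G$forward(NULL, as_batch(unclass(x)))
    if (length(dim(x)) == 3L) y <- array(y, dim(y)[1:3])
    y
  } else G(x)
}

# evaluate a critic: per-sample scalar scores (patch maps averaged per sample)
critic_values <- function(D, x, y) {
  if (inherits(D, "vs_network")) {
    if (D$meta$conditional) {
      m <- D$forward(NULL, as_batch(unclass(x)), as_batch(unclass(y)))
    } else {
      m <- D$forward(NULL, as_batch(unclass(y)))
    }
    apply(m, 4, mean)
  } else {
    as.numeric(if (is.null(x)) D(y) else D(x, y))
  }
}

# per-sample gradient of the scalar critic score w.r.t. the target image
critic_input_grad <- function(D, x, y) {
  yb <- as_batch(unclass(y))
  if (inherits(D, "vs_network")) {
    tp <- tape_new()
    yid <- tp_push(tp, yb)
    sid <- if (D$meta$conditional) {
      xid <- tp_push(tp, as_batch(unclass(x)))
      D$forward(tp, xid, yid)
    } else D$forward(tp, yid)
    map <- tp_value(tp, sid)
    zero_grads(D$params)
    grads <- tp_backward(tp, sid, seed = 1 / (dim(map)[1] * dim(map)[2]))
    zero_grads(D$params)
    grads[[yid]]
  } else {
    h <- 1e-4
    g <- array(0, dim(yb))
    for (e in seq_along(yb)) {
      yp <- yb; yp[e] <- yp[e] + h
      ym <- yb; ym[e] <- ym[e] - h
      vp <- critic_values(D, x, if (length(dim(y)) == 3L) array(yp, dim(y)) else yp)
      vm <- critic_values(D, x, if (length(dim(y)) == 3L) array(ym, dim(y)) else ym)
      g[e] <- (sum(vp) - sum(vm)) / (2 * h)
    }
    g
  }
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    vs_stop(paste0(what, ": shape mismatch"), "vs_invalid_argument")
}

#' Cycle-consistency loss
#'
#' Mean absolute reconstruction error of both round trips,
#' `mean|F(G(x)) - x| + mean|G(F(y)) - y|`.
#'
#' @param F,G Mappings (networks or plain functions) between the two
#'   domains; `G` maps the domain of `x` to that of `y`, `F` the reverse.
#' @param x,y Tiles from each domain.
#' @return Non-negative scalar.
#' @export
cycle_loss <- function(F, G, x, y) {
  gx <- apply_map(G, x); fg <- apply_map(F, gx)
  fy <- apply_map(F, y); gf <- apply_map(G, fy)
  check_same_shape(unclass(fg), unclass(x), "cycle_loss")
  check_same_shape(unclass(gf), unclass(y), "cycle_loss")
  mean(abs(fg - x)) + mean(abs(gf - y))
}

#' Domain-consistency loss
#'
#' The two-input discriminator `C` judges whether a pair of images belongs
#' to the same domain: it sees two augmented real tiles drawn from the
#' target-domain buffer (same-domain pair) and an augmented real tile next
#' to the generator output (mixed pair). Under the least-squares
#' convention (default) `C` minimizes `mean((C(same) - t_same)^2) +
#' mean((C(mixed) - t_mixed)^2)` and the generator minimizes
#' `mean((C(aug_y1, G(x)) - t_same)^2)`. Mode `"as_printed"` evaluates the
#' raw published form `mean(C(same)^2) + mean((1 - C(mixed))^2)` for audit;
#' that form has an unbounded maximizing player, so it is not used for
#' training.
#'
#' @param C Domain-consistency network (or plain function of two images).
#' @param G Generator mapping `x` into the target domain (or `NULL` if
#'   `x` is already a generated tile).
#' @param aug_y1,aug_y2 Two augmented real tiles from the target domain.
#' @param x Source tile fed through `G`.
#' @param targets `c(same, mixed)` least-squares targets, default `c(1, 0)`.
#' @param mode `"least_squares"` or `"as_printed"`.
#' @return `list(loss_C, loss_G)`, both non-negative in least-squares mode.
#' @export
domain_consistency_loss <- function(C, G, aug_y1, aug_y2, x,
                                    targets = c(1, 0),
                                    mode = c("least_squares", "as_printed")) {
  mode <- match.arg(mode)
  gx <- if (is.null(G)) x else apply_map(G, x)
  check_same_shape(unclass(aug_y1), unclass(aug_y2), "domain_consistency_loss")
  check_same_shape(unclass(aug_y1), unclass(gx), "domain_consistency_loss")
  cf <- if (inherits(C, "vs_network")) {
    function(a, b) C$forward(NULL, as_batch(unclass(a)), as_batch(unclass(b)))
  } else C
  same <- cf(aug_y1, aug_y2)
  mixed <- cf(aug_y1, gx)
  if (mode == "as_printed") {
    L <- mean(same^2) + mean((1 - mixed)^2)
    return(list(loss_C = L, loss_G = L))
  }
  a <- targets[1]; b <- targets[2]
  list(loss_C = mean((same - a)^2) + mean((mixed - b)^2),
       loss_G = mean((mixed - a)^2))
}

#' Wasserstein adversarial loss with gradient penalty
#'
#' The critic objective (returned as a quantity the critic minimizes) is
#' `mean D(x, y_real) - mean D(x, y_fake) + lambda_gp * penalty` with
#' `penalty = mean_i (||grad_{x_hat} D(x, x_hat_i)||_2 - 1)^2` evaluated at
#' per-sample random interpolates `x_hat = eps*y_real + (1-eps)*y_fake`
#' of the target image (the condition is held fixed). The generator
#' minimizes `mean D(x, y_fake)`. Per-sample critic scores are patch-map
#' means; input gradients are exact reverse-mode for network critics and
#' central differences for plain-function critics.
#'
#' @param D Critic (network or function `D(x, y)` returning per-sample
#'   scalars; `x` may be `NULL` for unconditional critics).
#' @param x Condition image(s) or `NULL`.
#' @param y_real,y_fake Target-domain real and generated image batches.
#' @param lambda_gp Penalty weight (>= 0).
#' @param seed Optional seed for the interpolation draw.
#' @return `list(loss_D, loss_G, penalty)`.
#' @export
adv_wgan_gp <- function(D, x, y_real, y_fake, lambda_gp = 10, seed = NULL) {
  if (lambda_gp < 0) vs_stop("lambda_gp must be >= 0", "vs_invalid_argument")
  check_same_shape(unclass(y_real), unclass(y_fake), "adv_wgan_gp")
  yr <- as_batch(unclass(y_real)); yf <- as_batch(unclass(y_fake))
  N <- dim(yr)[4]
  eps <- if (is.null(seed)) stats::runif(N) else with_seed(seed, stats::runif(N))
  xhat <- yr
  for (i in seq_len(N))
    xhat[, , , i] <- eps[i] * yr[, , , i] + (1 - eps[i]) * yf[, , , i]
  g <- critic_input_grad(D, x, xhat)
  norms <- sqrt(apply(g^2, 4, sum))
  penalty <- mean((norms - 1)^2)
  d_real <- mean(critic_values(D, x, y_real))
  d_fake <- mean(critic_values(D, x, y_fake))
  list(loss_D = d_real - d_fake + lambda_gp * penalty,
       loss_G = d_fake, penalty = penalty)
}

#' Non-saturating logistic adversarial loss with R1 regularization
#'
#' `loss_D = mean softplus(-D(x, y_real)) + mean softplus(D(x, y_fake)) +
#' (gamma_r1/2) * mean_i ||grad_y D(x, y_real_i)||^2`;
#' `loss_G = mean softplus(-D(x, y_fake))`.
#'
#' @inheritParams adv_wgan_gp
#' @param gamma_r1 R1 weight (>= 0).
#' @return `list(loss_D, loss_G, r1)`.
#' @export
adv_logistic_r1 <- function(D, x, y_real, y_fake, gamma_r1 = 10) {
  if (gamma_r1 < 0) vs_stop("gamma_r1 must be >= 0", "vs_invalid_argument")
  check_same_shape(unclass(y_real), unclass(y_fake), "adv_logistic_r1")
  sp <- function(v) ifelse(v > 30, v, log1p(exp(pmin(v, 30))))
  dr <- critic_values(D, x, y_real)
  df <- critic_values(D, x, y_fake)
  r1 <- 0
  if (gamma_r1 > 0) {
    g <- critic_input_grad(D, x, y_real)
    r1 <- (gamma_r1 / 2) * mean(apply(g^2, 4, sum))
  }
  list(loss_D = mean(sp(-dr)) + mean(sp(df)) + r1,
       loss_G = mean(sp(-df)), r1 = r1)
}

#' Least-squares adversarial loss
#'
#' `loss_D = mean((D(x,y_real) - 1)^2) + mean(D(x,y_fake)^2)`;
#' `loss_G = mean((D(x,y_fake) - 1)^2)`. For network critics the targets
#' apply patch-wise to the score map.
#'
#' @inheritParams adv_wgan_gp
#' @return `list(loss_D, loss_G)`.
#' @export
adv_l2 <- function(D, x, y_real, y_fake) {
  check_same_shape(unclass(y_real), unclass(y_fake), "adv_l2")
  vals <- function(y) {
    if (inherits(D, "vs_network")) {
      if (D$meta$conditional)
        D$forward(NULL, as_batch(unclass(x)), as_batch(unclass(y)))
      else D$forward(NULL, as_batch(unclass(y)))
    } else if (is.null(x)) D(y) else D(x, y)
  }
  dr <- vals(y_real); df <- vals(y_fake)
  list(loss_D = mean((dr - 1)^2) + mean(df^2),
       loss_G = mean((df - 1)^2))
}

#' Pixel L1 loss
#'
#' Mean absolute difference over all elements; zero exactly on identical
#' inputs.
#'
#' @param y_hat,y Same-shape arrays.
#' @return Non-negative scalar.
#' @export
pixel_l1 <- function(y_hat, y) {
  check_same_shape(unclass(y_hat), unclass(y), "pixel_l1")
  mean(abs(y_hat - y))
}

#' Feature-matching loss
#'
#' Mean over the critic's `N` exposed layers of the mean absolute
#' difference between real and generated activations.
#'
#' @param feats_real,feats_fake Equal-length lists of feature arrays with
#'   matching shapes per layer.
#' @return Non-negative scalar.
#' @export
feature_matching <- function(feats_real, feats_fake) {
  if (length(feats_real) != length(feats_fake))
    vs_stop("feature lists differ in length", "vs_invalid_argument")
  if (!length(feats_real)) vs_stop("empty feature lists", "vs_invalid_argument")
  per <- vapply(seq_along(feats_real), function(i) {
    check_same_shape(feats_real[[i]], feats_fake[[i]], "feature_matching")
    mean(abs(feats_real[[i]] - feats_fake[[i]]))
  }, 0)
  mean(per)
}

#' Total stage-2 loss
#'
#' `adv + lambda_pix * pix + lambda_fm * fm`.
#'
#' @param adv,pix,fm Scalar loss components.
#' @param w A [loss_weights()].
#' @return Scalar weighted sum.
#' @export
total_loss <- function(adv, pix, fm, w = loss_weights()) {
  if (!all(is.finite(c(adv, pix, fm))))
    vs_stop("non-finite loss component", "vs_numeric_error")
  adv + w$lambda_pix * pix + w$lambda_fm * fm
}
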