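# Every objective against closed forms and independent scalar-loop oracles
# on tiny tensors.

test_that("cycle loss vanishes on involutions and matches a loop oracle", {
  set.seed(41)
  x <- rand_tile(); y <- rand_tile()
  id <- function(t) t
  expect_equal(cycle_loss(id, id, x, y), 0)
  neg <- function(t) -t
  expect_equal(cycle_loss(neg, neg, x, y), 0)
  f <- function(t) t * 0.5 + 0.1
  g <- function(t) tanh(t)
  # scalar-loop re-computation
  s <- 0
  gx <- g(x); fg <- f(gx); fy <- f(y); gf <- g(fy)
  for (e in seq_along(x)) s <- s + abs(fg[e] - x[e])
  s1 <- s / length(x); s <- 0
  for (e in seq_along(y)) s <- s + abs(gf[e] - y[e])
  expect_equal(cycle_loss(f, g, x, y), s1 + s / length(y), tolerance = 1e-6)
  expect_error(cycle_loss(function(t) t[1:2, , , , drop = FALSE], id, x, y),
               class = "vs_invalid_argument")
})

test_that("domain-consistency loss hits constant-case closed forms", {
  y1 <- rand_tile(); y2 <- rand_tile(); gx <- rand_tile()
  c_same <- function(a, b) array(1, c(2, 2))       # constant at same target
  r <- domain_consistency_loss(c_same, NULL, y1, y2, gx)
  expect_equal(r$loss_C, mean((1 - 0)^2))          # only the mixed term remains
  expect_equal(r$loss_G, 0)
  c_half <- function(a, b) array(0.5, c(2, 2))
  r2 <- domain_consistency_loss(c_half, NULL, y1, y2, gx, targets = c(0, 1))
  expect_equal(r2$loss_C, 0.25 + 0.25)
  expect_equal(r2$loss_G, 0.25)
})

test_that("domain-consistency loss matches the printed-formula oracle", {
  set.seed(42)
  # random two-sample batch, random linear two-input critic
  y1 <- rand_tile(2, 2, 1, 2); y2 <- rand_tile(2, 2, 1, 2)
  gx <- rand_tile(2, 2, 1, 2)
  wts <- rnorm(8)
  C <- function(a, b) {
    n <- dim(a)[4]
    vapply(seq_len(n), function(i)
      sum(c(a[, , , i]) * wts[1:4]) + sum(c(b[, , , i]) * wts[5:8]), 0)
  }
  r <- domain_consistency_loss(C, NULL, y1, y2, gx, mode = "as_printed")
  # direct re-computation of the printed form
  cs <- C(y1, y2); cm <- C(y1, gx)
  want <- mean(cs^2) + mean((1 - cm)^2)
  expect_equal(r$loss_C, want, tolerance = 1e-6)
  # least-squares convention against its own formula
  r2 <- domain_consistency_loss(C, NULL, y1, y2, gx)
  expect_equal(r2$loss_C, mean((cs - 1)^2) + mean(cm^2), tolerance = 1e-6)
  expect_equal(r2$loss_G, mean((cm - 1)^2), tolerance = 1e-6)
})

test_that("gradient penalty hits linear-critic closed forms", {
  y_real <- array(runif(4), c(2, 2, 1, 1))
  y_fake <- array(runif(4), c(2, 2, 1, 1))
  d_sum <- function(y) sum(y)                      # gradient is all-ones
  r <- adv_wgan_gp(d_sum, NULL, y_real, y_fake, lambda_gp = 10, seed = 1)
  expect_equal(r$penalty, (sqrt(4) - 1)^2)         # M = 4 gives exactly 1
  d_scaled <- function(y) sum(y) / sqrt(4)         # unit gradient norm
  r2 <- adv_wgan_gp(d_scaled, NULL, y_real, y_fake, lambda_gp = 10, seed = 1)
  expect_equal(r2$penalty, 0)
  # critic translation invariance: adding a constant leaves loss_D unchanged
  d_shift <- function(y) sum(y) + 5
  r3 <- adv_wgan_gp(d_shift, NULL, y_real, y_fake, lambda_gp = 10, seed = 1)
  expect_equal(r3$loss_D, r$loss_D, tolerance = 1e-10)
  expect_error(adv_wgan_gp(d_sum, NULL, y_real, y_fake, lambda_gp = -1),
               class = "vs_invalid_argument")
})

test_that("network-critic gradient penalty agrees with a finite-difference oracle", {
  set.seed(43)
  cfg <- network_config(base_width = 2L)
  D <- build_patch_critic(cfg, conditional = TRUE)
  x <- rand_tile(8, 8, 3, 2, sd = 0.3)
  yr <- rand_tile(8, 8, 3, 2, sd = 0.3); yf <- rand_tile(8, 8, 3, 2, sd = 0.3)
  r <- adv_wgan_gp(D, x, yr, yf, lambda_gp = 10, seed = 9)
  # oracle: finite-difference estimate of the per-sample gradient norm at
  # the same interpolates
  eps <- local({
    old <- saved_rng()
    set.seed(9); e <- runif(2)
    restore_rng(old); e
  })
  xhat <- yr
  for (i in 1:2) xhat[, , , i] <- eps[i] * yr[, , , i] + (1 - eps[i]) * yf[, , , i]
  dval <- function(y) {
    m <- D$forward(NULL, x, y)
    apply(m, 4, mean)
  }
  h <- 1e-4
  sq <- numeric(2)
  for (e in seq_len(length(xhat) / 2)) {
    for (i in 1:2) {
      yp <- xhat; ym <- xhat
      idx <- e + (i - 1) * length(xhat) / 2
      yp[idx] <- yp[idx] + h; ym[idx] <- ym[idx] - h
      gfd <- (dval(yp)[i] - dval(ym)[i]) / (2 * h)
      sq[i] <- sq[i] + gfd^2
    }
  }
  pen_fd <- mean((sqrt(sq) - 1)^2)
  expect_equal(r$penalty, pen_fd, tolerance = 1e-3)
})

test_that("logistic + R1 objectives hit their closed forms", {
  y_real <- array(runif(4), c(2, 2, 1, 1))
  y_fake <- array(runif(4), c(2, 2, 1, 1))
  d_zero <- function(y) 0
  r <- adv_logistic_r1(d_zero, NULL, y_real, y_fake, gamma_r1 = 10)
  expect_equal(r$loss_D, 2 * log(2), tolerance = 1e-8)
  expect_equal(r$r1, 0, tolerance = 1e-6)
  d_sum <- function(y) sum(y)
  r2 <- adv_logistic_r1(d_sum, NULL, y_real, y_fake, gamma_r1 = 6)
  expect_equal(r2$r1, (6 / 2) * 4, tolerance = 1e-4)   # (gamma/2) * M
  # random case against a direct softplus re-computation
  set.seed(44)
  wts <- rnorm(4)
  d_lin <- function(y) sum(c(y) * wts)
  r3 <- adv_logistic_r1(d_lin, NULL, y_real, y_fake, gamma_r1 = 0)
  sp <- function(v) log(1 + exp(v))
  expect_equal(r3$loss_D, sp(-sum(c(y_real) * wts)) + sp(sum(c(y_fake) * wts)),
               tolerance = 1e-6)
  expect_equal(r3$loss_G, sp(-sum(c(y_fake) * wts)), tolerance = 1e-6)
  expect_error(adv_logistic_r1(d_zero, NULL, y_real, y_fake, gamma_r1 = -1),
               class = "vs_invalid_argument")
})

test_that("least-squares adversarial loss hits its closed forms", {
  y_real <- rand_tile(2, 2, 1, 2); y_fake <- rand_tile(2, 2, 1, 2)
  d_perfect <- function(y) if (identical(y, y_real)) rep(1, 2) else rep(0, 2)
  r <- adv_l2(d_perfect, NULL, y_real, y_fake)
  expect_equal(r$loss_D, 0)
  d_half <- function(y) rep(0.5, 2)
  r2 <- adv_l2(d_half, NULL, y_real, y_fake)
  expect_equal(r2$loss_D, 0.25 + 0.25)
  expect_equal(r2$loss_G, 0.25)
  set.seed(45)
  wts <- rnorm(4)
  d_lin <- function(y) apply(y, 4, function(t) sum(c(t) * wts))
  r3 <- adv_l2(d_lin, NULL, y_real, y_fake)
  dr <- d_lin(y_real); df <- d_lin(y_fake)
  expect_equal(r3$loss_D, mean((dr - 1)^2) + mean(df^2), tolerance = 1e-6)
})

test_that("pixel L1 and feature matching match loop oracles", {
  a <- rand_tile()
  expect_equal(pixel_l1(a, a), 0)
  base <- array(0, c(2, 2, 1, 1))
  diffs <- array(c(1, -1, 0.5, 0), c(2, 2, 1, 1))
  expect_equal(pixel_l1(base + diffs, base), 0.625)
  b <- rand_tile()
  s <- 0; for (e in seq_along(a)) s <- s + abs(a[e] - b[e])
  expect_equal(pixel_l1(a, b), s / length(a), tolerance = 1e-6)
  expect_error(pixel_l1(a, rand_tile(2, 2)), class = "vs_invalid_argument")

  f1 <- list(rand_tile(2, 2, 2), rand_tile(3, 3, 1))
  expect_equal(feature_matching(f1, f1), 0)
  fr <- list(array(0, c(1, 5)), array(0, c(1, 5)))
  ff <- list(array(0.2, c(1, 5)), array(0.4, c(1, 5)))
  expect_equal(feature_matching(fr, ff), 0.3)
  f2 <- list(rand_tile(2, 2, 2), rand_tile(3, 3, 1))
  tot <- 0
  for (i in 1:2) {
    s <- 0; for (e in seq_along(f1[[i]])) s <- s + abs(f1[[i]][e] - f2[[i]][e])
    tot <- tot + s / length(f1[[i]])
  }
  expect_equal(feature_matching(f1, f2), tot / 2, tolerance = 1e-6)
  expect_error(feature_matching(f1, f1[1]), class = "vs_invalid_argument")
})

test_that("total loss is the exact weighted sum", {
  w0 <- loss_weights(lambda_pix = 0, lambda_fm = 0)
  expect_equal(total_loss(1, 2, 3, w0), 1)
  w10 <- loss_weights(lambda_pix = 10, lambda_fm = 10)
  expect_equal(total_loss(1, 2, 3, w10), 51)
  set.seed(46)
  for (i in 1:5) {
    lp <- runif(1, 0, 50); lf <- runif(1, 0, 50)
    v <- runif(3)
    expect_equal(total_loss(v[1], v[2], v[3],
                            loss_weights(lambda_pix = lp, lambda_fm = lf)),
                 v[1] + lp * v[2] + lf * v[3])
  }
  expect_error(total_loss(NaN, 1, 1), class = "vs_numeric_error")
  expect_error(loss_weights(lambda_pix = -1), class = "vs_invalid_argument")
})
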