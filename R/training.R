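# Training orchestration for both stages.
#
# Stage 1 (unpaired): generators G1 (stained -> unstained) and G2 (reverse),
# per-domain patch critics, per-domain domain-consistency networks fed from
# per-domain input buffers of augmented reals. Objective: adversarial +
# lambda_cyc * cycle + lambda_dc * domain consistency.
#
# Stage 2 (paired): the parallel feature fusion generator against a
# conditional patch critic with the selected adversarial variant plus
# pixel-L1 and feature-matching terms.
#
# Update order within a step: critics, then domain nets, then generators.

tiles_to_batch <- function(tiles) {
  if (is.array(tiles) && length(dim(tiles)) == 4L) return(tiles)
  if (!is.list(tiles)) tiles <- list(tiles)
  d <- dim(tiles[[1]])[1:3]
  out <- array(0, c(d, length(tiles)))
  for (i in seq_along(tiles)) out[, , , i] <- unclass(tiles[[i]])[, , 1:d[3]]
  out
}

# mean((v - target)^2) as a tape node
t_mse_to <- function(tp, id, target) {
  fw_mean_square(tp, fw_shift_const(tp, id, -target))
}

critic_score_tp <- function(D, tp, cond, y, features = FALSE) {
  if (D$meta$conditional) D$forward(tp, cond, y, features = features)
  else D$forward(tp, y, features = features)
}

# Exact per-sample input gradient of the critic's scalar (patch-mean) score.
critic_grad_exact <- function(D, cond_arr, y_arr) {
  tp <- tape_new()
  yid <- tp_push(tp, y_arr)
  sid <- if (D$meta$conditional) {
    cid <- tp_push(tp, cond_arr)
    D$forward(tp, cid, yid)
  } else D$forward(tp, yid)
  map <- tp_value(tp, sid)
  grads <- tp_backward(tp, sid, seed = 1 / (dim(map)[1] * dim(map)[2]))
  grads[[yid]]
}

# Accumulate the parameter gradient of `weight * penalty` into the critic,
# where penalty is the gradient penalty (mode "gp": (||g||-1)^2 at
# interpolates) or the R1 term (mode "r1": (gamma/2)||g||^2 at reals).
# The penalty value itself uses exact reverse-mode input gradients; the
# parameter gradient uses a central-difference Hessian-vector product
# (two extra forward/backward passes). Returns the penalty value.
penalty_accumulate <- function(D, cond_arr, point_arr, weight, mode = "gp") {
  g <- critic_grad_exact(D, cond_arr, point_arr)   # pollutes D grads ...
  zero_grads(D$params)                             # ... cleared here
  N <- dim(point_arr)[4]
  sq <- apply(g^2, 4, sum)
  if (mode == "gp") {
    norms <- sqrt(sq)
    pen <- mean((norms - 1)^2)
    v <- g
    for (i in seq_len(N)) {
      ni <- norms[i]
      v[, , , i] <- if (ni > 1e-12) (2 * (ni - 1) / (N * ni)) * g[, , , i] else 0
    }
  } else {
    pen <- mean(sq) / 2                            # (1/2)E||g||^2; gamma in weight
    v <- g / N
  }
  if (weight == 0 || max(abs(v)) < 1e-14) return(pen)
  h <- 1e-3 / max(abs(v))
  for (sgn in c(1, -1)) {
    tp <- tape_new()
    yid <- tp_push(tp, point_arr + sgn * h * v)
    sid <- if (D$meta$conditional) {
      cid <- tp_push(tp, cond_arr)
      D$forward(tp, cid, yid)
    } else D$forward(tp, yid)
    map <- tp_value(tp, sid)
    tp_backward(tp, sid, seed = weight * sgn / (2 * h * dim(map)[1] * dim(map)[2]))
  }
  pen
}

# One critic update. Returns the logged critic loss value.
critic_update <- function(D, opt, cond_arr, real_arr, fake_arr, w) {
  zero_grads(D$params)
  tp <- tape_new()
  cid <- if (!is.null(cond_arr)) tp_push(tp, cond_arr) else NULL
  rid <- tp_push(tp, real_arr)
  fid <- tp_push(tp, fake_arr)
  sr <- critic_score_tp(D, tp, cid, rid)
  sf <- critic_score_tp(D, tp, cid, fid)
  loss <- switch(w$adv_variant,
    l2 = fw_wsum(tp, list(t_mse_to(tp, sr, 1), t_mse_to(tp, sf, 0))),
    wgan_gp = fw_wsum(tp, list(fw_mean(tp, sr), fw_mean(tp, sf)), c(1, -1)),
    logistic_r1 = fw_wsum(tp, list(fw_mean_softplus(tp, sr, -1),
                                   fw_mean_softplus(tp, sf, 1)))
  )
  lv <- tp_value(tp, loss)
  tp_backward(tp, loss, 1)
  pen <- 0
  if (w$adv_variant == "wgan_gp" && w$lambda_gp > 0) {
    N <- dim(real_arr)[4]
    eps <- stats::runif(N)
    xhat <- real_arr
    for (i in seq_len(N))
      xhat[, , , i] <- eps[i] * real_arr[, , , i] + (1 - eps[i]) * fake_arr[, , , i]
    pen <- penalty_accumulate(D, cond_arr, xhat, w$lambda_gp, mode = "gp")
  } else if (w$adv_variant == "logistic_r1" && w$gamma_r1 > 0) {
    pen <- penalty_accumulate(D, cond_arr, real_arr, w$gamma_r1, mode = "r1")
  }
  adam_step(opt)
  zero_grads(D$params)
  lv + (if (w$adv_variant == "wgan_gp") w$lambda_gp else w$gamma_r1) * pen
}

# generator-side adversarial node for a critic score map
gen_adv_node <- function(tp, score, variant) {
  switch(variant,
    l2 = t_mse_to(tp, score, 1),
    wgan_gp = fw_mean(tp, score),
    logistic_r1 = fw_mean_softplus(tp, score, -1)
  )
}

fnv_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

cfg_hash <- function(cfg) fnv_hash(paste(deparse(cfg), collapse = ""))

new_checkpoint <- function(stage, nets, net_cfg, extra = list()) {
  ck <- c(list(stage = stage,
               weights = lapply(nets, get_weights),
               net_cfg = unclass(net_cfg),
               cfg_hash = cfg_hash(unclass(net_cfg)),
               rng_state = get(".Random.seed", envir = globalenv())),
          extra)
  class(ck) <- c(paste0("vs_checkpoint_stage", stage), "vs_checkpoint")
  ck
}

#' Save / load a training checkpoint
#'
#' Checkpoints hold network weights, Adam state, the step counter, a config
#' hash and the RNG state; a load/save round trip reproduces forward
#' passes exactly.
#'
#' @param ckpt A checkpoint returned by [train_stage1()] or [train_stage2()].
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) vs_stop(paste0("no checkpoint at ", path), "vs_io_error")
  readRDS(path)
}

restore_cfg <- function(ck) do.call(network_config, ck$net_cfg)

# rebuild a network deterministically and load checkpointed weights
restore_net <- function(builder, ck, name, ...) {
  net <- with_seed(0L, builder(...))
  set_weights(net, ck$weights[[name]])
  net
}

check_finite_log <- function(vals, step) {
  if (any(!is.finite(unlist(vals))))
    vs_stop(paste0("non-finite loss at step ", step), "vs_numeric_error")
}

#' Train stage 1: unpaired stained-to-unstained translation
#'
#' Cycle-consistent adversarial training extended with the
#' domain-consistency game: per-domain input buffers are refilled each step
#' with augmented real tiles; each domain-consistency network sees two
#' augmented reals as a same-domain pair and (augmented real, generated)
#' as a mixed pair. Update order per step: critics, domain nets,
#' generators.
#'
#' @param stained,unstained Lists of (H,W,3) tiles in `[-1,1]` (unbalanced
#'   sizes allowed, e.g. 400 vs 80).
#' @param steps Number of training steps.
#' @param batch Batch size.
#' @param net_cfg A [network_config()] (reduced widths train on CPU).
#' @param weights A [loss_weights()]; stage 1 defaults to the
#'   least-squares adversarial variant.
#' @param policy An [augmentation_policy()] for the buffer refills.
#' @param buffer_capacity Per-domain input-buffer capacity.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param critic_steps Critic (and domain-net) updates per generator update.
#' @param adv_weight Weight of the generators' adversarial term.
#' @param seed Seed controlling the entire run; identical arguments give
#'   identical loss logs and weights.
#' @param sep_generator Use the depthwise-separable generator (default)
#'   instead of the residual baseline.
#' @param log_path Optional JSONL path for the loss log.
#' @return A stage-1 checkpoint; `$log` holds the per-step loss
#'   data.frame, including `g1_mean`, the mean intensity of the generated
#'   unstained batch.
#' @export
train_stage1 <- function(stained, unstained, steps = 100L, batch = 2L,
                         net_cfg = network_config(base_width = 8L, n_blocks = 3L),
                         weights = loss_weights(adv_variant = "l2"),
                         policy = augmentation_policy(jitter_px = 2L, zoom = 1.05,
                                                      rot_max_deg = 5,
                                                      elastic_alpha = 1,
                                                      elastic_sigma = 4),
                         buffer_capacity = 256L, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.9, critic_steps = 1L, adv_weight = 1,
                         seed = 1L, sep_generator = TRUE, log_path = NULL) {
  if (!length(stained) || !length(unstained))
    vs_stop("both image pools must be non-empty", "vs_insufficient_data")
  if (lr <= 0) vs_stop("lr must be > 0", "vs_invalid_argument")
  if (steps <= 0) vs_stop("steps must be > 0", "vs_invalid_argument")
  sx <- lapply(stained, function(t) unclass(t)[, , 1:3, drop = FALSE])
  sy <- lapply(unstained, function(t) unclass(t)[, , 1:3, drop = FALSE])
  log <- NULL
  ck <- with_seed(derive_seed(seed, 1L), {
    gen_build <- if (sep_generator) build_sep_generator else build_resnet_generator
    G1 <- gen_build(net_cfg); G2 <- gen_build(net_cfg)
    DX <- build_patch_critic(net_cfg, conditional = FALSE)
    DY <- build_patch_critic(net_cfg, conditional = FALSE)
    C1 <- build_domain_consistency_net(net_cfg)
    C2 <- build_domain_consistency_net(net_cfg)
    opt_g <- adam_new(c(G1$params, G2$params), lr, beta1, beta2)
    opt_dx <- adam_new(DX$params, lr, beta1, beta2)
    opt_dy <- adam_new(DY$params, lr, beta1, beta2)
    opt_c1 <- adam_new(C1$params, lr, beta1, beta2)
    opt_c2 <- adam_new(C2$params, lr, beta1, beta2)
    bufX <- input_buffer(buffer_capacity); bufY <- input_buffer(buffer_capacity)
    rows <- vector("list", steps)
    for (st in seq_len(steps)) {
      # refill per-domain buffers with freshly augmented reals
      buffer_push(bufX, lapply(sample.int(length(sx), batch, replace = TRUE),
                               function(i) augment(sx[[i]], policy)))
      buffer_push(bufY, lapply(sample.int(length(sy), batch, replace = TRUE),
                               function(i) augment(sy[[i]], policy)))
      xb <- tiles_to_batch(sx[sample.int(length(sx), batch, replace = TRUE)])
      yb <- tiles_to_batch(sy[sample.int(length(sy), batch, replace = TRUE)])
      g1x <- G1$forward(NULL, xb)   # fake unstained (detached)
      g2y <- G2$forward(NULL, yb)   # fake stained (detached)
      l_dx <- l_dy <- 0
      for (k in seq_len(critic_steps)) {
        l_dx <- critic_update(DX, opt_dx, NULL, xb, g2y, weights)
        l_dy <- critic_update(DY, opt_dy, NULL, yb, g1x, weights)
      }
      # domain-consistency nets (least-squares targets 1 = same, 0 = mixed)
      upd_domain <- function(C, opt, buf, fake) {
        pairs <- buffer_sample(buf, min(batch, buffer_size(buf)), 2L)
        a1 <- tiles_to_batch(pairs[[1]]); a2 <- tiles_to_batch(pairs[[2]])
        zero_grads(C$params)
        tp <- tape_new()
        i1 <- tp_push(tp, a1); i2 <- tp_push(tp, a2); fi <- tp_push(tp, fake)
        same <- C$forward(tp, i1, i2)
        mixed <- C$forward(tp, i1, fi)
        loss <- fw_wsum(tp, list(t_mse_to(tp, same, 1), t_mse_to(tp, mixed, 0)))
        lv <- tp_value(tp, loss)
        tp_backward(tp, loss, 1)
        adam_step(opt)
        zero_grads(C$params)
        list(val = lv, a1 = a1)
      }
      r1 <- upd_domain(C1, opt_c1, bufY, g1x)
      r2 <- upd_domain(C2, opt_c2, bufX, g2y)
      # generators
      zero_grads(c(G1$params, G2$params, DX$params, DY$params,
                   C1$params, C2$params))
      tp <- tape_new()
      xid <- tp_push(tp, xb); yid <- tp_push(tp, yb)
      f1 <- G1$forward(tp, xid)          # stained -> unstained
      f2 <- G2$forward(tp, yid)          # unstained -> stained
      cyc1 <- fw_mean_abs(tp, fw_sub(tp, G2$forward(tp, f1), xid))
      cyc2 <- fw_mean_abs(tp, fw_sub(tp, G1$forward(tp, f2), yid))
      advy <- gen_adv_node(tp, critic_score_tp(DY, tp, NULL, f1), weights$adv_variant)
      advx <- gen_adv_node(tp, critic_score_tp(DX, tp, NULL, f2), weights$adv_variant)
      dc1 <- t_mse_to(tp, C1$forward(tp, tp_push(tp, r1$a1), f1), 1)
      dc2 <- t_mse_to(tp, C2$forward(tp, tp_push(tp, r2$a1), f2), 1)
      total <- fw_wsum(tp, list(advy, advx, cyc1, cyc2, dc1, dc2),
                       c(adv_weight, adv_weight,
                         weights$lambda_cyc, weights$lambda_cyc,
                         weights$lambda_dc, weights$lambda_dc))
      tv <- tp_value(tp, total)
      tp_backward(tp, total, 1)
      adam_step(opt_g)
      zero_grads(c(G1$params, G2$params, DX$params, DY$params,
                   C1$params, C2$params))
      row <- data.frame(step = st, d_x = l_dx, d_y = l_dy,
                        c1 = r1$val, c2 = r2$val,
                        g_adv = tp_value(tp, advy) + tp_value(tp, advx),
                        g_cyc = tp_value(tp, cyc1) + tp_value(tp, cyc2),
                        g_dc = tp_value(tp, dc1) + tp_value(tp, dc2),
                        g_total = tv,
                        g1_mean = mean(tp_value(tp, f1)))
      check_finite_log(row, st)
      rows[[st]] <- row
    }
    log <- do.call(rbind, rows)
    new_checkpoint(1L, list(g1 = G1, g2 = G2, dx = DX, dy = DY,
                            c1 = C1, c2 = C2),
                   net_cfg,
                   list(step = steps, sep_generator = sep_generator,
                        seed = seed))
  })
  ck$log <- log
  if (!is.null(log_path)) write_report(log, log_path)
  ck
}

restore_stage1_gen <- function(ckpt, which = c("g1", "g2")) {
  which <- match.arg(which)
  builder <- if (isTRUE(ckpt$sep_generator)) build_sep_generator
             else build_resnet_generator
  restore_net(builder, ckpt, which, restore_cfg(ckpt))
}

#' Synthesize the paired data set from a stage-1 checkpoint
#'
#' Runs the stained-to-unstained generator over every stained tile,
#' producing one generated unstained counterpart per tile; together the
#' pairs form the supervised training set for stage 2. Deterministic given
#' the checkpoint.
#'
#' @param ckpt A stage-1 checkpoint.
#' @param stained List of stained tiles in `[-1,1]`.
#' @param dir Optional directory: pairs are written as PNG with a JSON
#'   manifest.
#' @return A list of `list(x = generated unstained, y = stained)` pairs
#'   (model range `[-1,1]`), invisibly also on disk when `dir` is given.
#' @export
synthesize_pairs <- function(ckpt, stained, dir = NULL) {
  if (!inherits(ckpt, "vs_checkpoint_stage1"))
    vs_stop("needs a stage-1 checkpoint", "vs_invalid_state")
  if (!length(stained)) {
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(), file.path(dir, "pairs.json"))
    }
    return(invisible(list()))
  }
  G1 <- restore_stage1_gen(ckpt, "g1")
  pairs <- lapply(stained, function(t) {
    x <- as_batch(unclass(t)[, , 1:3, drop = FALSE])
    u <- G1$forward(NULL, x)
    list(x = array(u, dim(u)[1:3]), y = unclass(t)[, , 1:3, drop = FALSE])
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(seq_along(pairs), function(i) {
      px <- sprintf("unstained_%04d.png", i); py <- sprintf("stained_%04d.png", i)
      write_tile(pairs[[i]]$x, file.path(dir, px), range = c(-1, 1))
      write_tile(pairs[[i]]$y, file.path(dir, py), range = c(-1, 1))
      data.frame(pair_id = i, unstained = px, stained = py)
    })
    jsonlite::write_json(do.call(rbind, rows), file.path(dir, "pairs.json"),
                         dataframe = "rows")
  }
  invisible(pairs)
}

#' Train stage 2: paired virtual staining
#'
#' Trains the parallel feature fusion generator (unstained -> stained)
#' against a conditional patch critic with the selected adversarial
#' variant (Wasserstein + gradient penalty by default), plus pixel-L1 and
#' feature-matching terms: total = adversarial + lambda_pix * L1 +
#' lambda_fm * FM.
#'
#' @param pairs List of `list(x = unstained, y = stained)` tiles in
#'   `[-1,1]` (as from [synthesize_pairs()]).
#' @param steps Generator updates.
#' @param batch Batch size.
#' @param net_cfg A [network_config()]; `feature_width` scales the
#'   generator.
#' @param weights A [loss_weights()].
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param critic_steps Critic updates per generator update (5 is customary
#'   for the Wasserstein variant, 1 for the others; `NULL` selects by
#'   variant).
#' @param seed Run seed.
#' @param log_path Optional JSONL loss-log path.
#' @return A stage-2 checkpoint with `$log` (columns include `pix`, the
#'   per-step pixel L1).
#' @export
train_stage2 <- function(pairs, steps = 300L, batch = 2L,
                         net_cfg = network_config(base_width = 16L,
                                                  feature_width = 32L),
                         weights = loss_weights(),
                         lr = 2e-4, beta1 = 0.5, beta2 = 0.9,
                         critic_steps = NULL, seed = 1L, log_path = NULL) {
  if (!length(pairs)) vs_stop("empty paired set", "vs_insufficient_data")
  if (lr <= 0) vs_stop("lr must be > 0", "vs_invalid_argument")
  if (steps <= 0) vs_stop("steps must be > 0", "vs_invalid_argument")
  if (is.null(critic_steps))
    critic_steps <- if (weights$adv_variant == "wgan_gp") 5L else 1L
  size <- dim(pairs[[1]]$x)[1]
  spec <- pyramid_spec(steps = seq(log2(size) - 2L, 1L), base_size = size)
  log <- NULL
  ck <- with_seed(derive_seed(seed, 2L), {
    G <- build_pffn(net_cfg, spec)
    D <- build_patch_critic(net_cfg, conditional = TRUE)
    opt_g <- adam_new(G$params, lr, beta1, beta2)
    opt_d <- adam_new(D$params, lr, beta1, beta2)
    nfm <- D$meta$n_feature_layers
    rows <- vector("list", steps)
    adv_on <- TRUE
    for (st in seq_len(steps)) {
      idx <- sample.int(length(pairs), min(batch, length(pairs)))
      xb <- tiles_to_batch(lapply(pairs[idx], `[[`, "x"))
      yb <- tiles_to_batch(lapply(pairs[idx], `[[`, "y"))
      l_d <- 0
      yh <- G$forward(NULL, xb)          # detached fake for the critic
      for (k in seq_len(critic_steps))
        l_d <- critic_update(D, opt_d, xb, yb, yh, weights)
      zero_grads(c(G$params, D$params))
      tp <- tape_new()
      xid <- tp_push(tp, xb); yid <- tp_push(tp, yb)
      fid <- G$forward(tp, xid)
      sf <- critic_score_tp(D, tp, xid, fid, features = TRUE)
      sr <- critic_score_tp(D, tp, xid, yid, features = TRUE)
      adv <- gen_adv_node(tp, sf$score, weights$adv_variant)
      pix <- fw_mean_abs(tp, fw_sub(tp, fid, yid))
      fm_terms <- lapply(seq_len(nfm), function(i)
        fw_mean_abs(tp, fw_sub(tp, sr$feats[[i]], sf$feats[[i]])))
      fm <- fw_wsum(tp, fm_terms, rep(1 / nfm, nfm))
      total <- fw_wsum(tp, list(adv, pix, fm),
                       c(1, weights$lambda_pix, weights$lambda_fm))
      tv <- tp_value(tp, total)
      tp_backward(tp, total, 1)
      adam_step(opt_g)
      zero_grads(c(G$params, D$params))
      row <- data.frame(step = st, d = l_d, adv = tp_value(tp, adv),
                        pix = tp_value(tp, pix), fm = tp_value(tp, fm),
                        total = tv)
      check_finite_log(row, st)
      rows[[st]] <- row
    }
    log <- do.call(rbind, rows)
    new_checkpoint(2L, list(gen = G, critic = D), net_cfg,
                   list(step = steps, base_size = size, seed = seed))
  })
  ck$log <- log
  if (!is.null(log_path)) write_report(log, log_path)
  ck
}

#' Virtually stain an unstained tile
#'
#' Runs the stage-2 generator on an unstained tile; deterministic, output
#' in the model range `[-1,1]` with domain tag `"stained"`.
#'
#' @param ckpt A stage-2 checkpoint.
#' @param unstained An (H,W,3) tile in `[-1,1]` whose size matches the
#'   checkpoint's pyramid.
#' @return An (H,W,3) stained-domain tile.
#' @export
stain <- function(ckpt, unstained) {
  if (!inherits(ckpt, "vs_checkpoint_stage2"))
    vs_stop("needs a stage-2 checkpoint", "vs_invalid_state")
  x <- unclass(unstained)[, , 1:3, drop = FALSE]
  if (dim(x)[1] != ckpt$base_size || dim(x)[2] != ckpt$base_size)
    vs_stop("tile size incompatible with the checkpoint's pyramid",
            "vs_invalid_argument")
  spec <- pyramid_spec(steps = seq(log2(ckpt$base_size) - 2L, 1L),
                       base_size = ckpt$base_size)
  G <- with_seed(0L, build_pffn(restore_cfg(ckpt), spec))
  set_weights(G, ckpt$weights$gen)
  y <- G$forward(NULL, as_batch(x))
  new_tile(array(y, dim(y)[1:3]), "stained", c(-1, 1))
}
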