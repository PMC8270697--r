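# Shared fixtures, built in code at test time.

vs_ns <- asNamespace("virtstain")

# a small pool of synthetic tiles in the model range [-1, 1]
model_pool <- function(n, domain = "stained", size = 64L, seed0 = 100L,
                       density = 12, n_classes = 4L,
                       params = render_params()) {
  lapply(seq_len(n), function(i) {
    g <- generate_geometry(size, size, density, n_classes, seed0 + i)
    t <- if (domain == "stained") render_stained(g, params)
         else render_unstained(g, params)
    out <- unclass(t) * 2 - 1
    attr(out, "class_label") <- g$tumor_class
    out
  })
}

# Labelled class fixture: one tile per draw with a known tumor class.
# Density is high enough that essentially every tile contains cells -- an
# empty tile carries no class signal at all.
class_fixture <- function(n, size = 32L, seed0 = 1000L, n_classes = 4L,
                          noise_sd = 0.02, density = 60) {
  p <- render_params(noise_sd = noise_sd)
  tiles <- list(); labels <- integer(n)
  for (i in seq_len(n)) {
    g <- generate_geometry(size, size, density, n_classes, seed0 + i)
    tiles[[i]] <- unclass(render_stained(g, p)) * 2 - 1
    labels[i] <- g$tumor_class
  }
  list(tiles = tiles, labels = labels)
}

# independent nearest-centroid classifier oracle on mean tile color
centroid_oracle_accuracy <- function(train_tiles, train_labels,
                                     test_tiles, test_labels) {
  feat <- function(t) apply(t, 3, mean)
  Ftr <- t(vapply(train_tiles, feat, numeric(3)))
  cents <- do.call(rbind, lapply(sort(unique(train_labels)), function(k)
    colMeans(Ftr[train_labels == k, , drop = FALSE])))
  Fte <- t(vapply(test_tiles, feat, numeric(3)))
  pred <- apply(Fte, 1, function(f)
    sort(unique(train_labels))[which.min(colSums((t(cents) - f)^2))])
  mean(pred == test_labels)
}

# paired pyramid-compatible fixture for stage-2 tests
paired_fixture <- function(n, size = 64L, seed0 = 900L) {
  lapply(seq_len(n), function(i) {
    g <- generate_geometry(size, size, 12, 4, seed0 + i)
    list(x = unclass(render_unstained(g)) * 2 - 1,
         y = unclass(render_stained(g)) * 2 - 1)
  })
}

rand_tile <- function(h = 4L, w = 4L, c = 3L, n = 1L, sd = 1) {
  array(rnorm(h * w * c * n, 0, sd), c(h, w, c, n))
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
}
saved_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
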