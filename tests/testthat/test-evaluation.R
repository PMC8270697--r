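# Metric math against closed forms and loop oracles; classifier harness.

test_that("identity embedding returns pixel vectors with exact moments", {
  tiles <- list(array(1:12 / 12, c(2, 2, 3)), array(12:1 / 12, c(2, 2, 3)))
  fs <- embed(tiles, embedder_identity())
  expect_equal(fs$x[1, ], as.numeric(tiles[[1]]))
  expect_equal(fs$x[2, ], as.numeric(tiles[[2]]))
  fs2 <- embed(tiles, embedder_identity())
  expect_identical(fs$x, fs2$x)
  expect_error(embed(list(), embedder_identity()),
               class = "vs_insufficient_data")
  # moments of a seeded Gaussian fixture approach their closed forms
  set.seed(51)
  n <- 4000
  g <- lapply(seq_len(n), function(i) array(rnorm(4, mean = 2, sd = 3), c(2, 2, 1)))
  fg <- embed(g, embedder_identity())
  expect_equal(unname(fg$mu), rep(2, 4), tolerance = 0.2)
  expect_equal(unname(diag(fg$sigma)), rep(9, 4), tolerance = 0.6)
})

test_that("Frechet distance obeys its closed forms", {
  set.seed(52)
  A <- feature_set(matrix(rnorm(60), 20, 3))
  expect_equal(fid(A, A), 0, tolerance = 1e-8)
  # equal covariances, mean shift delta -> ||delta||^2 exactly
  delta <- c(1.5, -2, 0.5)
  B <- feature_set(sweep(A$x, 2, -delta))
  expect_equal(fid(A, B), sum(delta^2), tolerance = 1e-8)
  expect_equal(fid(A, B), fid(B, A), tolerance = 1e-10)
  # monotone in the size of a pure mean shift
  d1 <- fid(A, feature_set(sweep(A$x, 2, -c(0.5, 0, 0))))
  d2 <- fid(A, feature_set(sweep(A$x, 2, -c(1.0, 0, 0))))
  expect_lt(d1, d2)
  # 1-D Gaussians: (mu1-mu2)^2 + (sd1-sd2)^2 via the matrix square root
  x1 <- matrix(rnorm(5000, 1, 2)); x2 <- matrix(rnorm(5000, -1, 3))
  got <- fid(feature_set(x1), feature_set(x2))
  want <- (mean(x1) - mean(x2))^2 + (sd(x1) - sd(x2))^2
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("Inception Score hits its bounds and matches a loop oracle", {
  K <- 4
  expect_equal(inception_score(matrix(1 / K, 10, K)), 1.0, tolerance = 1e-10)
  expect_equal(inception_score(diag(K)), K, tolerance = 1e-10)
  set.seed(53)
  p <- matrix(rexp(5 * K), 5, K); p <- p / rowSums(p)
  marg <- colMeans(p)
  kl <- numeric(5)
  for (i in 1:5) {
    s <- 0
    for (k in 1:K) if (p[i, k] > 0) s <- s + p[i, k] * log(p[i, k] / marg[k])
    kl[i] <- s
  }
  expect_equal(inception_score(p), exp(mean(kl)), tolerance = 1e-6)
  expect_equal(inception_score(p), inception_score(p[sample(5), ]),
               tolerance = 1e-10)
  expect_true(inception_score(p) >= 1 && inception_score(p) <= K)
  expect_error(inception_score(matrix(0, 2, 2)), class = "vs_invalid_argument")
})

test_that("Mode Score reduces to IS under matched marginals", {
  K <- 4
  u <- matrix(1 / K, 8, K)
  expect_equal(mode_score(u, u), 1.0, tolerance = 1e-10)
  set.seed(54)
  p <- matrix(rexp(6 * K), 6, K); p <- p / rowSums(p)
  # real set with the same marginal as the fake set
  real <- matrix(colMeans(p), 10, K, byrow = TRUE)
  expect_equal(mode_score(p, real), inception_score(p, 1), tolerance = 1e-8)
  # random sets against a direct KL-term computation
  q <- matrix(rexp(7 * K), 7, K); q <- q / rowSums(q)
  mr <- colMeans(q); mf <- colMeans(p)
  kl1 <- mean(apply(p, 1, function(r) sum(r[r > 0] * log(r[r > 0] / mr[r > 0]))))
  kl2 <- sum(mf * log(mf / mr))
  expect_equal(mode_score(p, q), exp(kl1 - kl2), tolerance = 1e-6)
})

test_that("visual classifier separates the palette fixture and beats a centroid oracle", {
  fx <- class_fixture(200, size = 32L, seed0 = 4000L)
  tr <- 1:150; te <- 151:200
  clf <- train_visual_classifier(fx$tiles[tr], fx$labels[tr], seed = 5)
  acc_tr <- classifier_accuracy(clf, fx$tiles[tr], fx$labels[tr])
  acc_te <- classifier_accuracy(clf, fx$tiles[te], fx$labels[te])
  expect_gte(acc_te, 0.9)
  # seeded rerun reproduces the same accuracy
  clf2 <- train_visual_classifier(fx$tiles[tr], fx$labels[tr], seed = 5)
  expect_equal(classifier_accuracy(clf2, fx$tiles[te], fx$labels[te]), acc_te)
  # at least as good as an independent nearest-centroid baseline
  oracle <- centroid_oracle_accuracy(fx$tiles[tr], fx$labels[tr],
                                     fx$tiles[te], fx$labels[te])
  expect_gte(acc_te, oracle - 1e-9)
  expect_error(train_visual_classifier(fx$tiles[1:5], rep(0L, 5)),
               class = "vs_invalid_argument")
})

test_that("two-class linearly separable color fixture is learned perfectly", {
  set.seed(55)
  tiles <- c(lapply(1:20, function(i) array(rnorm(16 * 16 * 3, -0.5, 0.05),
                                            c(16, 16, 3))),
             lapply(1:20, function(i) array(rnorm(16 * 16 * 3, 0.5, 0.05),
                                            c(16, 16, 3))))
  labels <- rep(0:1, each = 20)
  clf <- train_visual_classifier(tiles, labels, steps = 150L, seed = 6)
  expect_equal(classifier_accuracy(clf, tiles, labels), 1.0)
})

test_that("visual-simulation accuracy behaves under identity and permutation", {
  fx <- class_fixture(80, size = 32L, seed0 = 6000L)
  clf <- train_visual_classifier(fx$tiles, fx$labels, seed = 7)
  acc <- classifier_accuracy(clf, fx$tiles, fx$labels)
  # generated = real tiles themselves: identical pass-through
  expect_equal(visual_simulation_accuracy(clf, fx$tiles, fx$labels), acc)
  expect_error(visual_simulation_accuracy(clf, list(), integer(0)),
               class = "vs_invalid_argument")
  expect_error(visual_simulation_accuracy(clf, fx$tiles, fx$labels[-1]),
               class = "vs_invalid_argument")
})

test_that("metric report bundles the metric family", {
  real <- model_pool(6, "stained", size = 32L, seed0 = 7000L)
  fake <- model_pool(6, "stained", size = 32L, seed0 = 7100L)
  rep <- evaluate_metrics(real, fake, feature_embedder = embedder_pool(4L))
  expect_gte(rep$fid, 0)
  expect_equal(rep$n_real, 6)
  expect_identical(rep$embedder, "pool-4")
})
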