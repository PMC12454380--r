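zeroCbam <- function(C, hidden = 2L)
  list(W1 = matrix(0, C, hidden), b1 = matrix(0, 1, hidden),
       W2 = matrix(0, hidden, C), b2 = matrix(0, 1, C),
       convW = matrix(0, 2, 1), convB = matrix(0, 1, 1))

test_that("channel attention: zero weights give exact 0.5 scaling, maps in (0,1)", {
  set.seed(1)
  F <- matrix(rnorm(60), 12, 5)
  w0 <- zeroCbam(5)
  ca <- channelAttention(F, w0)
  expect_identical(ca$map, matrix(0.5, 1, 5))
  expect_equal(ca$out, 0.5 * F)
  # random weights: map strictly inside (0,1), shape preserved
  set.seed(2)
  w <- list(W1 = matrix(rnorm(10), 5, 2), b1 = matrix(rnorm(2), 1),
            W2 = matrix(rnorm(10), 2, 5), b2 = matrix(rnorm(5), 1))
  ca2 <- channelAttention(F, w)
  expect_true(all(ca2$map > 0 & ca2$map < 1))
  expect_equal(dim(ca2$out), dim(F))
  # single point: avg-pool equals max-pool, so Mc = sigmoid(2 MLP(F))
  F1 <- matrix(rnorm(5), 1, 5)
  mlp <- function(x) pmax(x %*% w$W1 + matrix(w$b1, 1), 0) %*% w$W2 + w$b2
  expect_equal(channelAttention(F1, w)$map, 1 / (1 + exp(-2 * mlp(F1))),
               tolerance = 1e-12)
})

test_that("spatial attention: zero weights give 0.5, map is permutation-equivariant", {
  set.seed(3)
  F <- matrix(rnorm(60), 12, 5)
  sa0 <- spatialAttention(F, list(convW = matrix(0, 2, 1),
                                  convB = matrix(0, 1, 1)))
  expect_equal(sa0$out, 0.5 * F)
  w <- list(convW = matrix(rnorm(2), 2, 1), convB = matrix(rnorm(1), 1, 1))
  sa <- spatialAttention(F, w)
  expect_true(all(sa$map > 0 & sa$map < 1))
  expect_equal(dim(sa$out), dim(F))
  perm <- sample(12)
  expect_equal(spatialAttention(F[perm, ], w)$map, sa$map[perm, , drop = FALSE])
})

test_that("taped CBAM agrees with the reference attention implementations", {
  set.seed(4)
  F <- matrix(rnorm(80), 16, 5)
  w <- list(W1 = matrix(rnorm(10), 5, 2), b1 = matrix(rnorm(2), 1),
            W2 = matrix(rnorm(10), 2, 5), b2 = matrix(rnorm(5), 1),
            convW = matrix(rnorm(2), 2, 1), convB = matrix(rnorm(1), 1, 1))
  tape <- corncloud:::tapeNew()
  x <- corncloud:::tpConst(tape, F)
  taped <- corncloud:::.tpCbamSeg(x, w, rep(1L, 16), 1L, tape)$out$val
  ref <- spatialAttention(channelAttention(F, w)$out, w)$out
  expect_equal(taped, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("farthest-point sampling returns distinct input points, spread out", {
  set.seed(5)
  pts <- matrix(runif(300), 100, 3)
  idx <- corncloud:::fps_cpp(pts, 10L)
  expect_equal(length(unique(idx)), 10L)
  expect_true(all(idx %in% 1:100))
  # permutation invariance of the selected set
  perm <- sample(100)
  idx2 <- corncloud:::fps_cpp(pts[perm, ], 10L)
  expect_setequal(perm[idx2], idx)
})

test_that("forward pass: valid probabilities, deterministic, permutation-equivariant", {
  cfg <- tinyNetConfig()
  st <- initNet(cfg)
  set.seed(6)
  cl <- makeTinyCloud(32, seed = 8)
  f1 <- netForward(st, cl)
  expect_equal(rowSums(f1$probs), rep(1, 32), tolerance = 1e-5)
  expect_true(all(f1$labels %in% 0:1))
  expect_identical(netForward(st, cl)$probs, f1$probs)
  perm <- sample(32)
  f2 <- netForward(st, subsetCloud(cl, perm))
  expect_equal(f2$probs, f1$probs[perm, ], tolerance = 1e-5)
})

test_that("composite loss matches its closed forms", {
  expect_equal(compositeLoss(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(compositeLoss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(compositeLoss(c(1, 0), c(1, 0),
                             regPairs = cbind(c(1, 0), c(0.5, 0.25)),
                             lambda = 2),
               1.5, tolerance = 1e-6)
  expect_error(compositeLoss(0.5, 1, lambda = -1), "lambda")
  expect_gte(compositeLoss(runif(10), rbinom(10, 1, 0.5)), 0)
})

test_that("class rebalancing is inverse-frequency with mean 1", {
  expect_equal(classRebalanceWeights(rep(0:1, 50)), c(1, 1))
  w <- classRebalanceWeights(c(rep(0, 90), rep(1, 10)))
  expect_equal(w[2] / w[1], 9)
  expect_equal(mean(w), 1)
  expect_equal(classRebalanceWeights(rep(0, 20)), c(1, 1))
})

test_that("resampling pads small clouds by repetition, keeping all originals", {
  set.seed(7)
  idx <- corncloud:::.resampleIdx(10L, 16L)
  expect_equal(length(idx), 16L)
  expect_true(all(1:10 %in% idx))
  idx2 <- corncloud:::.resampleIdx(100L, 16L)
  expect_equal(anyDuplicated(idx2), 0L)
})

test_that("training is seeded-deterministic and predictCloud covers all points", {
  clouds <- lapply(1:2, function(s)
    generateScene(sceneSpec(nPlants = 1, seed = s, pointsPerPlant = 60L,
                            pointsOnTray = 100L))$cloud)
  cfg <- netConfig(npoint = 64L, saPoints = c(16L, 8L),
                   radii = list(c(0.2, 0.4), c(0.4, 0.8)),
                   nsample = list(c(4L, 8L), c(4L, 8L)),
                   mlps = list(c(8L, 16L), c(16L, 32L)),
                   fpMlps = list(c(32L, 16L), c(32L, 32L)),
                   headMlp = c(16L), epochs = 2L, batch = 2L, seed = 5L)
  s1 <- trainNet(clouds, clouds, cfg)
  s2 <- trainNet(clouds, clouds, cfg)
  expect_identical(s1$log$train_loss[1], s2$log$train_loss[1])
  expect_identical(s1$log, s2$log)
  pred <- predictCloud(clouds[[1]], s1)
  expect_equal(length(pred), nPoints(clouds[[1]]))
  expect_true(all(pred %in% 0:1))
  expect_error(predictCloud(clouds[[1]], initNet(cfg)), "untrained")
})
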