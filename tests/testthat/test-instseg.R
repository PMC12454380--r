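test_that("eps estimate matches the brute-force oracle", {
  # 56 collinear points at unit spacing: per point i the 55th-neighbour
  # distance is max(i, 55 - i); the mean over all points is 41.5
  pts <- cbind(0:55, 0, 0)
  expect_equal(estimateEps(pts, 55), 41.5)
  i <- 0:55
  expect_equal(mean(pmax(i, 55 - i)), 41.5)
  # random cloud vs exhaustive pairwise distances
  set.seed(1)
  q <- matrix(rnorm(90), 30, 3)
  expect_equal(estimateEps(q, 7), bruteEps(q, 7), tolerance = 1e-12)
  # homogeneity: scaling coordinates scales eps
  expect_equal(estimateEps(q * 3.5, 7), 3.5 * estimateEps(q, 7),
               tolerance = 1e-9)
  expect_error(estimateEps(q, 30), "more than")
})

test_that("coincident points give eps 0 and all-noise clustering", {
  pts <- matrix(1, 60, 3)
  expect_equal(estimateEps(pts, 55), 0)
  expect_warning(a <- cornDBSCAN(pts), "eps = 0")
  expect_true(all(clusterLabels(a) == -1L))
})

test_that("well-separated blobs cluster exactly, no noise", {
  b <- makeBlobs()
  a <- cornDBSCAN(b$points)
  expect_equal(length(unique(clusterLabels(a)[clusterLabels(a) >= 0])), 3L)
  expect_equal(sum(clusterLabels(a) == -1L), 0L)
  expect_gt(epsUsed(a), 0)
  # one dense blob -> one cluster
  one <- cornDBSCAN(makeBlobs(centers = rbind(c(0, 0)))$points)
  expect_equal(unique(clusterLabels(one)), 0L)
})

test_that("tiny clouds fall back gracefully", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_warning(a <- cornDBSCAN(two), "reducing k|minPts")
  expect_true(all(clusterLabels(a) == -1L))
})

test_that("clustering is invariant to point order and rigid motion", {
  b <- makeBlobs(n = 100, seed = 3)
  a <- cornDBSCAN(b$points)
  set.seed(4)
  perm <- sample(nrow(b$points))
  a2 <- cornDBSCAN(b$points[perm, ])
  # identical partitions up to renumbering: every matched pair at IoU 1
  m <- matchInstances(clusterLabels(a2), clusterLabels(a)[perm] + 1L)
  expect_equal(m$iou, rep(1, 3))
  R <- rodriguesRotation(c(1, 2, 3), 0.7)
  moved <- sweep(b$points %*% t(R), 2, c(5, -2, 1), "+")
  a3 <- cornDBSCAN(moved)
  m3 <- matchInstances(clusterLabels(a3), clusterLabels(a) + 1L)
  expect_equal(m3$iou, rep(1, 3))
})

test_that("cluster ids are renumbered by decreasing size", {
  small <- cbind(10 + 0.01 * (1:10), 0, 0)   # dense line segments
  large <- cbind(0.01 * (1:40), 0, 0)
  a <- cornDBSCAN(rbind(small, large), k = 5)
  lab <- clusterLabels(a)
  expect_equal(sum(lab == 0L), 40L)  # biggest cluster gets id 0
  expect_equal(sum(lab == 1L), 10L)
})

test_that("Hungarian matching equals exhaustive enumeration", {
  set.seed(6)
  for (t in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    cost <- matrix(runif(n * m), n, m)
    got <- solveAssignment(cost)$cost
    k <- min(n, m)
    combos <- utils::combn(seq_len(max(n, m)), k)
    best <- Inf
    perm <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm(v[-i]), function(p) c(v[i], p))))
    rowsets <- if (n <= m) list(seq_len(n)) else
      lapply(seq_len(ncol(utils::combn(n, k))), function(i) utils::combn(n, k)[, i])
    for (rs in rowsets)
      for (cp in perm(seq_len(m)))
        best <- min(best, sum(cost[cbind(rs, cp[seq_len(k)])]))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("instance matching recovers permuted ids and odd-shaped cases", {
  pred <- c(rep(0L, 10), rep(1L, 10))
  truth <- c(rep(2L, 10), rep(1L, 10))     # swapped ids
  m <- matchInstances(pred, truth)
  expect_equal(m$truth[m$pred == 0L], 2L)
  expect_equal(m$truth[m$pred == 1L], 1L)
  expect_equal(m$iou, c(1, 1))
  # identical labelings -> identity matching at IoU 1
  m2 <- matchInstances(c(0L, 0L, 1L), c(1L, 1L, 2L))
  expect_equal(m2$iou, c(1, 1))
  # 3 predictions vs 2 truths: agreement with brute-force best assignment
  set.seed(7)
  pred3 <- sample(0:2, 60, replace = TRUE)
  truth2 <- sample(1:2, 60, replace = TRUE)
  m3 <- matchInstances(pred3, truth2)
  iou <- function(p, t) {
    i <- sum(pred3 == p & truth2 == t)
    i / (sum(pred3 == p) + sum(truth2 == t) - i)
  }
  best <- max(iou(0, 1) + iou(1, 2), iou(0, 1) + iou(2, 2),
              iou(1, 1) + iou(0, 2), iou(1, 1) + iou(2, 2),
              iou(2, 1) + iou(0, 2), iou(2, 1) + iou(1, 2))
  expect_equal(sum(m3$iou), best, tolerance = 1e-12)
})
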