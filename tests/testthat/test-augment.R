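bigCloud <- function(n, seed = 1) {
  set.seed(seed)
  labeledCloud(matrix(stats::runif(3 * n), n, 3),
               semantic = rep(0:1, length.out = n),
               instance = rep(0:1, length.out = n))
}

test_that("fake dropout removes 10-20% of points, survivors in order", {
  cl <- bigCloud(1000)
  set.seed(2)
  out <- fakeDropout(cl)
  expect_gte(nPoints(out), 800)
  expect_lte(nPoints(out), 900)
  # forcing p = 0.10 keeps exactly 90 of 100
  cl2 <- bigCloud(100)
  set.seed(3)
  out2 <- fakeDropout(cl2, augmentConfig(dropoutRange = c(0.10, 0.10)))
  expect_equal(nPoints(out2), 90L)
  # survivors are a subset of the input rows, order preserved
  rows <- apply(cloudPoints(out), 1, paste, collapse = ",")
  inRows <- apply(cloudPoints(cl), 1, paste, collapse = ",")
  expect_true(all(rows %in% inRows))
  expect_false(is.unsorted(match(rows, inRows)))
  expect_error(fakeDropout(bigCloud(9)), "points")
})

test_that("jitter is bounded by the clip and has the configured sd", {
  cl <- bigCloud(100000)
  set.seed(4)
  out <- jitterCloud(cl)
  d <- cloudPoints(out) - cloudPoints(cl)
  expect_lte(max(abs(d)), 0.05 + 1e-12)
  expect_lt(abs(sd(d) - 0.01) / 0.01, 0.05)
  expect_identical(semanticLabels(out), semanticLabels(cl))
  expect_identical(cloudNormals(out), cloudNormals(cl))
  # zero-noise configuration is the identity
  idn <- jitterCloud(cl, augmentConfig(jitterSd = 0, jitterClip = 0))
  expect_identical(cloudPoints(idn), cloudPoints(cl))
})

test_that("rotation is an isometry and preserves unit normals", {
  cl <- makeTinyCloud(80)
  set.seed(5)
  out <- rotateCloud(cl)
  expect_equal(as.vector(dist(cloudPoints(out))),
               as.vector(dist(cloudPoints(cl))), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(cloudNormals(out)^2)), rep(1, 80),
               tolerance = 1e-9)
  # zero-degree angles leave the cloud unchanged
  idn <- rotateCloud(cl, augmentConfig(rotationRangeDeg = c(0, 0)))
  expect_equal(cloudPoints(idn), cloudPoints(cl), tolerance = 1e-12)
})

test_that("scaling multiplies all pairwise distances by one in-range factor", {
  cl <- makeTinyCloud(60)
  set.seed(6)
  out <- scaleCloud(cl)
  ratio <- as.vector(dist(cloudPoints(out)) / dist(cloudPoints(cl)))
  expect_lt(diff(range(ratio)), 1e-9)
  expect_gte(ratio[1], 0.67)
  expect_lte(ratio[1], 1.5)
  idn <- scaleCloud(cl, augmentConfig(scaleRange = c(1, 1)))
  expect_equal(cloudPoints(idn), cloudPoints(cl), tolerance = 1e-12)
  # drawn factors stay within [0.67, 1.5] over many draws
  two <- labeledCloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  set.seed(7)
  s <- replicate(10000, dist(cloudPoints(scaleCloud(two)))[1])
  expect_gte(min(s), 0.67)
  expect_lte(max(s), 1.5)
})

test_that("shuffle permutes rows jointly and uniformly", {
  cl <- makeTinyCloud(30)
  set.seed(8)
  out <- shuffleCloud(cl)
  key <- function(x) sort(apply(cbind(cloudPoints(x), semanticLabels(x)), 1,
                                paste, collapse = ","))
  expect_identical(key(out), key(cl))
  one <- labeledCloud(matrix(1:3, 1))
  expect_identical(cloudPoints(shuffleCloud(one)), cloudPoints(one))
  # all 6 orders of a 3-point cloud occur across 720 trials
  tri <- labeledCloud(diag(3))
  set.seed(9)
  orders <- replicate(720, paste(cloudPoints(shuffleCloud(tri)) %*% 1:3,
                                 collapse = ""))
  expect_equal(length(unique(orders)), 6L)
})

test_that("translation shifts every point by one bounded offset", {
  cl <- makeTinyCloud(40)
  set.seed(10)
  out <- translateCloud(cl)
  d <- cloudPoints(out) - cloudPoints(cl)
  expect_lt(max(apply(d, 2, function(v) diff(range(v)))), 1e-12)
  expect_lte(max(abs(d)), 0.1)
  idn <- translateCloud(cl, augmentConfig(translationRange = c(0, 0)))
  expect_equal(cloudPoints(idn), cloudPoints(cl), tolerance = 1e-12)
})

test_that("every augmentation keeps seedling points seedling points", {
  cl <- makeTinyCloud(100)
  cfg <- augmentConfig()
  set.seed(11)
  for (op in list(jitterCloud, rotateCloud, scaleCloud, shuffleCloud,
                  translateCloud))
    expect_equal(sum(semanticLabels(op(cl)) == 1L),
                 sum(semanticLabels(cl) == 1L))
  expect_equal(nPoints(rotateCloud(cl)), 100L)  # only dropout changes counts
})

test_that("dataset builder writes 7 files per input and a disjoint split", {
  src <- withr::local_tempdir()
  out <- withr::local_tempdir()
  generateDataset(6, src, seed = 12, pointsPerPlant = 60L,
                  pointsOnTray = 120L)
  man <- buildAugmentedDataset(src, out, augmentConfig(seed = 1))
  expect_equal(nrow(man), 42L)
  expect_equal(length(list.files(out, pattern = "\\.txt$")), 42L)
  expect_setequal(unique(man$technique),
                  c("orig", "drop", "jitter", "rot", "scale", "shuffle",
                    "trans"))
  expect_equal(anyDuplicated(man$file), 0L)
  splits <- utils::read.csv(file.path(out, "train.csv"))$file
  splits <- c(splits, utils::read.csv(file.path(out, "test.csv"))$file,
              utils::read.csv(file.path(out, "val.csv"))$file)
  expect_setequal(splits, man$file)
  expect_equal(anyDuplicated(splits), 0L)
  # reproducible under the same seed
  out2 <- withr::local_tempdir()
  man2 <- buildAugmentedDataset(src, out2, augmentConfig(seed = 1))
  expect_identical(man$split, man2$split)
})
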