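test_that("a plant-free spec yields a tray-only cloud", {
  sc <- generateScene(sceneSpec(nPlants = 0, seed = 3))
  expect_true(all(semanticLabels(sc$cloud) == 0L))
  expect_equal(nrow(sc$truth), 0L)
})

test_that("scene generation is deterministic in the seed", {
  a <- generateScene(sceneSpec(nPlants = 3, tiltAngleDeg = 12, seed = 7))
  b <- generateScene(sceneSpec(nPlants = 3, tiltAngleDeg = 12, seed = 7))
  expect_identical(cloudPoints(a$cloud), cloudPoints(b$cloud))
  expect_identical(a$truth, b$truth)
  c <- generateScene(sceneSpec(nPlants = 3, tiltAngleDeg = 12, seed = 8))
  expect_false(identical(cloudPoints(a$cloud), cloudPoints(c$cloud)))
})

test_that("designed height is the z-range of the untilted plant points", {
  sp <- sceneSpec(nPlants = 1, plantHeights = 10, tiltAngleDeg = 0,
                  noiseSd = 0, seed = 5)
  sc <- generateScene(sp)
  expect_equal(sc$truth$height_cm, 10)
  pp <- cloudPoints(sc$cloud)[instanceLabels(sc$cloud) == 1L, ]
  expect_equal(diff(range(pp[, 3])), 10, tolerance = 1e-9)
})

test_that("instance labels partition the seedling points, each above minpts", {
  sc <- generateScene(sceneSpec(nPlants = 4, seed = 11))
  sem <- semanticLabels(sc$cloud)
  inst <- instanceLabels(sc$cloud)
  expect_true(all(inst[sem == 1L] > 0L))
  expect_true(all(inst[sem == 0L] == 0L))
  expect_true(all(table(inst[sem == 1L]) >= 3))
  # plants are mutually separated well beyond intra-plant spacing
  pts <- cloudPoints(sc$cloud)
  d12 <- min(fields_min_dist <- sapply(1:3, function(i) {
    a <- pts[inst == i, , drop = FALSE]
    b <- pts[inst == i + 1L, , drop = FALSE]
    min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)))
  }))
  expect_gt(d12, 1)  # cm-scale gap between distinct plants
})

test_that("normals are unit length and tilt rotates them with the points", {
  sp <- sceneSpec(nPlants = 2, tiltAngleDeg = 20, noiseSd = 0, seed = 9)
  sc <- generateScene(sp)
  nn <- sqrt(rowSums(cloudNormals(sc$cloud)^2))
  expect_true(all(abs(nn - 1) < 1e-6))
  # tray normals all equal the tilted +z
  R <- rodriguesRotation(sp@tiltAxis, sp@tiltAngleDeg * pi / 180)
  zTilted <- as.vector(R %*% c(0, 0, 1))
  trayN <- cloudNormals(sc$cloud)[semanticLabels(sc$cloud) == 0L, ]
  expect_lt(max(abs(sweep(trayN, 2, zTilted))), 1e-9)
})

test_that("generateDataset writes readable files and a matching manifest", {
  d <- withr::local_tempdir()
  man <- generateDataset(5, d, seed = 4)
  files <- list.files(d, pattern = "^scene_.*\\.txt$")
  expect_equal(length(files), 5L)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_setequal(unique(man$file), files)
  # every file re-read passes the LabeledCloud validity contract
  for (f in files) expect_s4_class(readLabeledTxt(file.path(d, f)),
                                   "LabeledCloud")
  # same seed -> identical manifest
  d2 <- withr::local_tempdir()
  man2 <- generateDataset(5, d2, seed = 4)
  expect_equal(man$height_cm, man2$height_cm)
  expect_equal(man$canopy_cm, man2$canopy_cm)
})

test_that("impossible placements raise a generation error", {
  expect_error(
    generateScene(sceneSpec(nPlants = 40, traySide = 10, seed = 1)),
    "could not place")
})
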