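test_that("Rodrigues alignment maps detected normals exactly onto +z", {
  # quarter turn
  al <- alignToZ(labeledCloud(diag(3)), c(0, 1, 0))
  expect_equal(al$transform@theta, pi / 2)
  expect_equal(as.vector(al$transform@rotation %*% c(0, 1, 0)), c(0, 0, 1),
               tolerance = 1e-9)
  # identity and antiparallel conventions
  expect_equal(alignToZ(labeledCloud(diag(3)), c(0, 0, 1))$transform@rotation,
               diag(3))
  anti <- alignToZ(labeledCloud(diag(3)), c(0, 0, -1))$transform@rotation
  expect_equal(as.vector(anti %*% c(0, 0, -1)), c(0, 0, 1), tolerance = 1e-9)
  # random normals: orthonormal rotation with det +1, exact mapping
  set.seed(1)
  for (i in 1:200) {
    m <- rnorm(3); m <- m / sqrt(sum(m^2))
    R <- alignToZ(labeledCloud(diag(3)), m)$transform@rotation
    expect_lt(max(abs(R %*% m - c(0, 0, 1))), 1e-9)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("RANSAC finds the dominant plane and orients it toward the plants", {
  set.seed(2)
  plane <- cbind(runif(1000), runif(1000), rnorm(1000, 0, 0.002))
  above <- cbind(runif(50), runif(50), runif(50, 0.3, 1))
  res <- detectGroundPlane(rbind(plane, above), seed = 3)
  expect_gt(abs(res$normal[3]), 0.999)
  expect_gt(res$normal[3], 0)                      # oriented upward
  expect_gte(mean(res$inliers[1:1000]), 0.95)      # inlier recall
  # a vertical plane is found and oriented toward its outliers
  v <- rbind(cbind(0, runif(200), runif(200)),
             cbind(runif(30, 0.3, 1), runif(30), runif(30)))
  res2 <- detectGroundPlane(v, seed = 4)
  expect_gt(res2$normal[1], 0.999)
  # three exact points give their exact plane
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  expect_equal(abs(detectGroundPlane(tri, iterations = 10)$normal[3]), 1,
               tolerance = 1e-12)
  expect_error(detectGroundPlane(matrix(0, 2, 3)), "at least 3")
})

test_that("scale factor is the reference ratio and propagates as k, k^2, k^3", {
  expect_equal(computeScale(50, 25), 0.5)
  expect_equal(computeScale(25, 25), 1)
  expect_equal(computeScale(50, 25), computeScale(25, 25) / 2)
  expect_error(computeScale(0, 25), "positive")
  set.seed(3)
  p <- matrix(runif(150, 0, 5), 50, 3)
  expect_equal(plantHeight(p, 2), 2 * plantHeight(p, 1))
  expect_equal(canopyWidth(p, 2), 2 * canopyWidth(p, 1))
  # doubling k with a proportionally scaled voxel grid: exactly k^3
  expect_equal(voxelVolume(p, 2, 0.2), 8 * voxelVolume(p, 1, 0.1))
  g <- makeGridPatch()
  a1 <- bpaSurfaceArea(g$points, 1, 0.2, normals = g$normals)$area
  a2 <- bpaSurfaceArea(g$points, 2, 0.4, normals = g$normals)$area
  expect_equal(a2, 4 * a1, tolerance = 0.02)
})

test_that("height and canopy closed forms", {
  expect_equal(plantHeight(cbind(0, 0, c(0, 1.3, 5.2))), 5.2)
  expect_equal(plantHeight(matrix(c(1, 2, 3), 1)), 0)
  expect_error(plantHeight(matrix(0, 0, 3)), "empty")
  # 3-4-5 bounding box
  p <- rbind(c(0, 0, 0), c(3, 0, 5), c(3, 4, 2), c(0, 4, 1))
  expect_equal(canopyWidth(p), 5)
  expect_equal(canopyWidth(cbind(0, 0, 0:9)), 0)
  # translation invariance; z-rotation by 90 degrees preserves the diagonal
  expect_equal(canopyWidth(sweep(p, 2, c(5, -7, 2), "+")), 5)
  Rz <- rodriguesRotation(c(0, 0, 1), pi / 2)
  expect_equal(canopyWidth(p %*% t(Rz)), 5, tolerance = 1e-9)
})

test_that("voxel volume counts occupied 0.1 cm cubes", {
  g <- seq(0, 0.95, by = 0.05)
  cube <- as.matrix(expand.grid(g, g, g))
  expect_equal(voxelVolume(cube), 1.0, tolerance = 1e-12)   # 1000 voxels
  expect_equal(voxelVolume(matrix(c(3, 1, 2), 1)), 0.001)
  # monotone under adding points
  set.seed(4)
  p1 <- matrix(runif(90), 30, 3)
  p2 <- rbind(p1, matrix(runif(30), 10, 3))
  expect_gte(voxelVolume(p2), voxelVolume(p1))
  # translation moves the grid anchor with the cloud
  expect_equal(voxelVolume(sweep(cube, 2, c(0.03, 0.07, 0.01), "+")), 1.0)
  expect_warning(v0 <- voxelVolume(matrix(0, 0, 3)), "empty")
  expect_equal(v0, 0)
})

test_that("Heron's formula and mesh areas match closed-form oracles", {
  expect_equal(heronArea(3, 4, 5), 6)
  expect_equal(heronArea(1, 1, 2), 0)          # degenerate
  g <- makeGridPatch()
  res <- bpaSurfaceArea(g$points, 1, 0.2, normals = g$normals)
  expect_lt(abs(res$area - 1) / 1, 0.1)
  expect_equal(max(res$triangles), nrow(g$points))
  sp <- makeSphere(5000)
  res2 <- bpaSurfaceArea(sp, 1, 0.2, normals = sp)
  expect_lt(abs(res2$area - 4 * pi) / (4 * pi), 0.1)
  expect_warning(deg <- bpaSurfaceArea(cbind(1:5, 0, 0), 1, 0.2),
                 "degenerate|no triangles")
  expect_equal(deg$area, 0)
})

test_that("phenotypeScene recovers manifest traits through tilt and scaling", {
  sc <- generateScene(sceneSpec(nPlants = 3, tiltAngleDeg = 15,
                                worldScale = 2, seed = 21))
  ph <- phenotypeScene(sc$cloud, computeArea = FALSE)
  expect_equal(nrow(ph$records), 3L)           # one record per cluster
  expect_equal(ph$transform@scaleK, 0.5, tolerance = 0.02)
  sel <- which(semanticLabels(sc$cloud) == 1L)
  m <- matchInstances(ph$assignment@labels, instanceLabels(sc$cloud)[sel])
  for (r in seq_len(nrow(m))) {
    rec <- ph$records[ph$records$plant_id == m$pred[r] + 1L, ]
    tr <- sc$truth[sc$truth$plant_id == m$truth[r], ]
    expect_lt(abs(rec$height_cm - tr$height_cm) / tr$height_cm, 0.02)
  }
  # a plant-free scene yields an empty record table
  empty <- phenotypeScene(generateScene(sceneSpec(nPlants = 0, seed = 2))$cloud,
                          computeArea = FALSE)
  expect_equal(nrow(empty$records), 0L)
})
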