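# Trait extraction: RANSAC ground-plane detection, Rodrigues alignment of
# the plane normal onto +z, metric scaling against a reference object (the
# 25 cm tray side), then per-plant traits: height (z-range), canopy width
# (horizontal AABB diagonal), voxel-occupancy volume (0.1 cm cubes) and
# ball-pivoting mesh surface area (0.2 cm ball, Heron triangle areas).

#' Rodrigues rotation matrix
#'
#' The standard rotation by angle `theta` about a unit `axis`:
#' R = I cos(theta) + (1 - cos(theta)) a a^T + [a]_x sin(theta).
#'
#' @param axis rotation axis (any nonzero vector; normalized internally).
#' @param theta angle in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rodriguesRotation <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * cos(theta) + (1 - cos(theta)) * tcrossprod(a) + K * sin(theta)
}

#' Detect the ground plane by RANSAC
#'
#' Samples point triples, keeps the plane with the largest inlier set at the
#' distance threshold, and refits it to the inliers by least squares (the
#' smallest principal axis of the inlier scatter). The normal is oriented so
#' that the majority of non-inlier points (the plants) lie on its positive
#' side.
#'
#' @param cloud a \linkS4class{LabeledCloud} or an n x 3 matrix.
#' @param inlierThreshold absolute distance threshold; default 1% of the
#'   bounding-box diagonal.
#' @param iterations RANSAC iterations (default 1000).
#' @param minInlierFrac detection fails below this inlier fraction.
#' @param seed RNG seed.
#' @return A list with `normal` (unit vector), `offset` (plane is
#'   `normal . x = offset`) and `inliers` (logical mask).
#' @export
detectGroundPlane <- function(cloud, inlierThreshold = NULL,
                              iterations = 1000L, minInlierFrac = 0.3,
                              seed = 1L) {
  pts <- if (is(cloud, "LabeledCloud")) cloud@points else as.matrix(cloud)
  n <- nrow(pts)
  if (n < 3) stop("detectGroundPlane: need at least 3 points")
  if (is.null(inlierThreshold)) {
    diag <- sqrt(sum(apply(pts, 2, function(v) diff(range(v)))^2))
    inlierThreshold <- 0.01 * diag
  }
  set.seed(as.integer(seed))
  best <- 0L; bestMask <- NULL
  for (it in seq_len(iterations)) {
    tri <- pts[sample.int(n, 3L), , drop = FALSE]
    nv <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-12) next
    nv <- nv / nn
    d <- abs(pts %*% nv - sum(nv * tri[1, ]))
    mask <- d <= inlierThreshold
    cnt <- sum(mask)
    if (cnt > best) { best <- cnt; bestMask <- mask }
  }
  if (is.null(bestMask) || best < minInlierFrac * n)
    stop("detectGroundPlane: no plane with >= ", round(100 * minInlierFrac),
         "% inliers")
  # least-squares refit on the consensus set
  inl <- pts[bestMask, , drop = FALSE]
  ctr <- colMeans(inl)
  ev <- eigen(crossprod(sweep(inl, 2, ctr)), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  offset <- sum(normal * ctr)
  # orient towards the plants: majority of outliers on the positive side
  out <- pts[!bestMask, , drop = FALSE]
  if (nrow(out) > 0) {
    side <- out %*% normal - offset
    if (sum(side > 0) < sum(side < 0)) { normal <- -normal; offset <- -offset }
  } else if (normal[3] < 0) { normal <- -normal; offset <- -offset }
  list(normal = as.numeric(normal), offset = as.numeric(offset),
       inliers = as.vector(bestMask))
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Rotate a cloud so the detected ground normal points up
#'
#' Computes theta = acos(m . n / (|m| |n|)) between the detected plane normal
#' m and the z unit vector n, builds the Rodrigues rotation about m x n, and
#' applies it to points and normals. An antiparallel normal (theta = 180
#' degrees) is rotated about the x axis by convention.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param planeNormal the detected ground-plane normal.
#' @param scaleK metric scale recorded in the returned transform (default 1;
#'   set later via [computeScale()]).
#' @param referenceLengthReal reference length in cm (default 25).
#' @return A list with `cloud` (rotated) and `transform`
#'   (an \linkS4class{AlignmentTransform}).
#' @export
alignToZ <- function(cloud, planeNormal, scaleK = 1,
                     referenceLengthReal = 25) {
  m <- planeNormal / sqrt(sum(planeNormal^2))
  z <- c(0, 0, 1)
  cosTh <- max(-1, min(1, sum(m * z)))
  theta <- acos(cosTh)
  if (theta < 1e-12) {
    R <- diag(3)
  } else if (abs(pi - theta) < 1e-9) {
    R <- rodriguesRotation(c(1, 0, 0), pi)
  } else {
    R <- rodriguesRotation(.cross3(m, z), theta)
  }
  tr <- new("AlignmentTransform", rotation = R, planeNormal = m,
            theta = theta, scaleK = scaleK,
            referenceLengthReal = referenceLengthReal)
  rotated <- labeledCloud(cloud@points %*% t(R), cloud@normals %*% t(R),
                          cloud@semantic, cloud@instance)
  list(cloud = rotated, transform = tr)
}

#' Metric scale factor from a reference object
#'
#' k = L_real / L_virtual: centimetres per scene unit. Lengths multiply by
#' k, areas by k^2, volumes by k^3.
#'
#' @param referenceExtentVirtual measured extent of the reference object in
#'   scene units.
#' @param referenceLengthReal its real length in cm (default 25, a tray side).
#' @return The scalar k.
#' @export
computeScale <- function(referenceExtentVirtual, referenceLengthReal = 25) {
  if (referenceExtentVirtual <= 0 || referenceLengthReal <= 0)
    stop("computeScale: lengths must be positive")
  referenceLengthReal / referenceExtentVirtual
}

#' Plant height: z-range of the aligned plant points
#'
#' @param plantPoints n x 3 matrix (aligned frame, scene units).
#' @param k metric scale factor (cm per scene unit).
#' @return Height in cm.
#' @export
plantHeight <- function(plantPoints, k = 1) {
  plantPoints <- as.matrix(plantPoints)
  if (!nrow(plantPoints)) stop("plantHeight: empty point set")
  diff(range(plantPoints[, 3])) * k
}

#' Canopy width: horizontal AABB diagonal
#'
#' The axis-aligned bounding box of the plant's points in the aligned frame;
#' the canopy width is sqrt(L^2 + W^2) of its two horizontal extents.
#'
#' @inheritParams plantHeight
#' @return Canopy width in cm.
#' @export
canopyWidth <- function(plantPoints, k = 1) {
  plantPoints <- as.matrix(plantPoints)
  if (!nrow(plantPoints)) stop("canopyWidth: empty point set")
  L <- diff(range(plantPoints[, 1]))
  W <- diff(range(plantPoints[, 2]))
  sqrt(L^2 + W^2) * k
}

#' Voxel-occupancy volume
#'
#' Partitions the plant's AABB (anchored at its minimum corner) into cubes
#' of side `voxelSideCm` and returns occupied-voxel-count x side^3. Points
#' are first converted to cm via `k`.
#'
#' @inheritParams plantHeight
#' @param voxelSideCm voxel edge length in cm (default 0.1).
#' @return Volume in cm^3 (0, with a warning, for an empty set).
#' @export
voxelVolume <- function(plantPoints, k = 1, voxelSideCm = 0.1) {
  plantPoints <- as.matrix(plantPoints)
  if (!nrow(plantPoints)) { warning("voxelVolume: empty point set"); return(0) }
  p <- plantPoints * k
  p <- sweep(p, 2, apply(p, 2, min))
  idx <- floor(p / voxelSideCm + 1e-9)
  nOcc <- nrow(unique(idx))
  nOcc * voxelSideCm^3
}

#' Heron's formula
#'
#' Triangle area from its three side lengths (0 for degenerate triangles).
#'
#' @param a,b,c side lengths.
#' @return The area.
#' @examples heronArea(3, 4, 5)  # 6
#' @export
heronArea <- function(a, b, c) {
  s <- (a + b + c) / 2
  h <- s * (s - a) * (s - b) * (s - c)
  sqrt(pmax(h, 0))
}

#' Ball-pivoting surface area
#'
#' Reconstructs a triangle mesh by rolling a ball of radius `ballRadiusCm`
#' over the points (in cm, after applying `k`) and sums the triangle areas,
#' each computed from its side lengths with Heron's formula.
#'
#' @inheritParams plantHeight
#' @param ballRadiusCm pivot-ball radius in cm (default 0.2).
#' @param normals optional n x 3 normals used to pick the ball side for seed
#'   triangles; both sides are tried when absent.
#' @return A list with `area` (cm^2), `triangles` (1-based index matrix) and
#'   `vertices` (the cm-scaled coordinates). Degenerate input yields area 0
#'   and an empty mesh, with a warning.
#' @export
bpaSurfaceArea <- function(plantPoints, k = 1, ballRadiusCm = 0.2,
                           normals = NULL) {
  plantPoints <- as.matrix(plantPoints)
  storage.mode(plantPoints) <- "double"
  if (nrow(plantPoints) < 3) stop("bpaSurfaceArea: need at least 3 points")
  p <- plantPoints * k
  nm <- if (is.null(normals)) matrix(numeric(0), 0, 3) else as.matrix(normals)
  storage.mode(nm) <- "double"
  tri <- bpa_cpp(p, nm, ballRadiusCm)
  if (!nrow(tri)) {
    warning("bpaSurfaceArea: no triangles found (degenerate or too sparse)")
    return(list(area = 0, triangles = tri, vertices = p))
  }
  e <- function(i, j) sqrt(rowSums((p[tri[, i], , drop = FALSE] -
                                    p[tri[, j], , drop = FALSE])^2))
  area <- sum(heronArea(e(1, 2), e(2, 3), e(1, 3)))
  list(area = area, triangles = tri, vertices = p)
}

#' End-to-end trait extraction for one scene
#'
#' Segments (or takes given semantic labels), clusters seedling points into
#' instances with [cornDBSCAN()], detects and aligns the ground plane,
#' derives the metric scale from the reference object, and computes the four
#' traits per plant.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param netState optional trained network state from [trainNet()]; used
#'   when the cloud carries no semantic labels.
#' @param referenceLengthReal reference length in cm (default 25, tray side).
#' @param referenceExtentVirtual measured reference extent in scene units;
#'   when `NULL` it is taken as the larger horizontal AABB side of the
#'   detected ground-plane inliers after alignment.
#' @param voxelSideCm,ballRadiusCm trait resolution parameters.
#' @param computeArea set FALSE to skip the (relatively costly) mesh area.
#' @param k,minPts clustering parameters, see [cornDBSCAN()].
#' @param seed RANSAC seed.
#' @param csv optional path; when given the trait table is written there.
#' @return A list with `records` (data.frame: plant_id, height_cm, canopy_cm,
#'   volume_cm3, area_cm2, n_points), `assignment` (the
#'   \linkS4class{InstanceAssignment} over seedling points), `transform`
#'   (an \linkS4class{AlignmentTransform}) and `semantic` (labels used).
#' @export
phenotypeScene <- function(cloud, netState = NULL, referenceLengthReal = 25,
                           referenceExtentVirtual = NULL, voxelSideCm = 0.1,
                           ballRadiusCm = 0.2, computeArea = TRUE, k = 55L,
                           minPts = 3L, seed = 1L, csv = NULL) {
  sem <- if (hasLabels(cloud)) cloud@semantic
         else if (!is.null(netState)) predictCloud(cloud, netState)
         else stop("phenotypeScene: need semantic labels or a trained state")

  plane <- detectGroundPlane(cloud, seed = seed)
  al <- alignToZ(cloud, plane$normal,
                 referenceLengthReal = referenceLengthReal)
  aligned <- al$cloud
  if (is.null(referenceExtentVirtual)) {
    ground <- aligned@points[plane$inliers, , drop = FALSE]
    referenceExtentVirtual <- max(diff(range(ground[, 1])),
                                  diff(range(ground[, 2])))
  }
  kScale <- computeScale(referenceExtentVirtual, referenceLengthReal)
  al$transform@scaleK <- kScale

  emptyRec <- data.frame(plant_id = integer(0), height_cm = numeric(0),
                         canopy_cm = numeric(0), volume_cm3 = numeric(0),
                         area_cm2 = numeric(0), n_points = integer(0))
  seedIdx <- which(sem == 1L)
  if (!length(seedIdx))
    return(list(records = emptyRec, assignment = NULL,
                transform = al$transform, semantic = sem))

  seedPts <- aligned@points[seedIdx, , drop = FALSE]
  seedNrm <- aligned@normals[seedIdx, , drop = FALSE]
  asn <- cornDBSCAN(seedPts, k = k, minPts = minPts)

  ids <- sort(unique(asn@labels[asn@labels >= 0L]))
  recs <- lapply(ids, function(cid) {
    sel <- asn@labels == cid
    pp <- seedPts[sel, , drop = FALSE]
    area <- if (computeArea && sum(sel) >= 3)
      bpaSurfaceArea(pp, kScale, ballRadiusCm,
                     normals = seedNrm[sel, , drop = FALSE])$area
    else NA_real_
    data.frame(plant_id = cid + 1L,
               height_cm = plantHeight(pp, kScale),
               canopy_cm = canopyWidth(pp, kScale),
               volume_cm3 = voxelVolume(pp, kScale, voxelSideCm),
               area_cm2 = area, n_points = sum(sel))
  })
  records <- if (length(recs)) do.call(rbind, recs) else emptyRec
  if (!is.null(csv)) utils::write.csv(records, csv, row.names = FALSE)
  list(records = records, assignment = asn, transform = al$transform,
       semantic = sem)
}
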