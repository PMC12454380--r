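# Synthetic multi-plant tray scenes with ground truth known by construction.
# A scene is a planar tray (z = 0 square of side `traySide`) plus K seedlings,
# each a vertical stem with radial Gaussian spread and 2-4 parabolic leaf
# ribbons. Ground-truth traits are recorded from the untilted points, then
# the whole scene is tilted about a horizontal axis so that the alignment
# stage has real work to do.

#' Scene specification for the synthetic tray generator
#'
#' Defaults emulate a 25 cm cultivation tray holding maize seedlings in the
#' 8-15 cm height range. All lengths are in cm; the optional `worldScale`
#' multiplies every coordinate on output, emulating an arbitrary
#' photogrammetric reconstruction scale (so the reference tray side measures
#' `25 * worldScale` scene units and the metric scale factor k recovers cm).
#'
#' @slot nPlants number of seedlings (>= 0).
#' @slot plantHeights per-plant height, cm.
#' @slot canopyExtents nPlants x 2 matrix of horizontal extents, cm.
#' @slot leafCount integer leaves per plant.
#' @slot traySide tray side length, cm (reference object; default 25).
#' @slot tiltAxis horizontal unit vector, axis of the scene tilt.
#' @slot tiltAngleDeg tilt angle, degrees, in [0, 45].
#' @slot noiseSd additive Gaussian jitter sd, cm.
#' @slot pointsPerPlant,pointsOnTray sampling densities.
#' @slot worldScale scene units per cm on output.
#' @slot seed RNG seed; one stream drives the whole scene.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(nPlants = "integer", plantHeights = "numeric",
                 canopyExtents = "matrix", leafCount = "integer",
                 traySide = "numeric", tiltAxis = "numeric",
                 tiltAngleDeg = "numeric", noiseSd = "numeric",
                 pointsPerPlant = "integer", pointsOnTray = "integer",
                 worldScale = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@nPlants < 0L) msg <- c(msg, "nPlants must be >= 0")
  if (any(object@plantHeights <= 0)) msg <- c(msg, "heights must be positive")
  if (any(object@canopyExtents <= 0)) msg <- c(msg, "extents must be positive")
  if (object@traySide <= 0) msg <- c(msg, "traySide must be positive")
  if (object@tiltAngleDeg < 0 || object@tiltAngleDeg > 45)
    msg <- c(msg, "tilt angle must be in [0, 45] degrees")
  if (abs(object@tiltAxis[3]) > 1e-9)
    msg <- c(msg, "tilt axis must be horizontal")
  if (object@nPlants > 0L && object@pointsPerPlant < 3L)
    msg <- c(msg, "pointsPerPlant must be >= minpts (3)")
  if (object@worldScale <= 0) msg <- c(msg, "worldScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a SceneSpec
#'
#' Unspecified per-plant parameters are drawn (reproducibly, from `seed`)
#' from the default ranges: heights U(8, 15) cm, canopy extents U(2.5, 4) cm
#' per axis, 2-4 leaves.
#'
#' @param nPlants number of seedlings.
#' @param plantHeights optional numeric vector of heights, cm.
#' @param canopyExtents optional nPlants x 2 matrix (length, width), cm.
#' @param leafCount optional integer vector.
#' @param traySide tray side, cm.
#' @param tiltAxis horizontal tilt axis; `NULL` draws a random one.
#' @param tiltAngleDeg tilt angle, degrees.
#' @param noiseSd point jitter sd, cm.
#' @param pointsPerPlant,pointsOnTray sampling densities.
#' @param worldScale scene units per cm.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(nPlants, plantHeights = NULL, canopyExtents = NULL,
                      leafCount = NULL, traySide = 25, tiltAxis = NULL,
                      tiltAngleDeg = 0, noiseSd = 0.05,
                      pointsPerPlant = 600L, pointsOnTray = 1500L,
                      worldScale = 1, seed = 1L) {
  nPlants <- as.integer(nPlants)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(plantHeights))
    plantHeights <- if (nPlants) stats::runif(nPlants, 8, 15) else numeric(0)
  if (is.null(canopyExtents))
    canopyExtents <- matrix(stats::runif(2 * nPlants, 2.5, 4),
                            max(nPlants, 0), 2)
  canopyExtents <- matrix(as.numeric(canopyExtents), nPlants, 2)
  if (is.null(leafCount))
    leafCount <- if (nPlants) sample(2:4, nPlants, replace = TRUE) else integer(0)
  if (is.null(tiltAxis)) {
    phi <- stats::runif(1, 0, 2 * pi)
    tiltAxis <- c(cos(phi), sin(phi), 0)
  }
  tiltAxis <- tiltAxis / sqrt(sum(tiltAxis^2))
  new("SceneSpec", nPlants = nPlants,
      plantHeights = as.numeric(plantHeights),
      canopyExtents = canopyExtents, leafCount = as.integer(leafCount),
      traySide = as.numeric(traySide), tiltAxis = as.numeric(tiltAxis),
      tiltAngleDeg = as.numeric(tiltAngleDeg), noiseSd = as.numeric(noiseSd),
      pointsPerPlant = as.integer(pointsPerPlant),
      pointsOnTray = as.integer(pointsOnTray),
      worldScale = as.numeric(worldScale), seed = as.integer(seed))
}

# sample one seedling at the origin; returns list(points, normals, volume, area)
.samplePlant <- function(height, extents, nLeaves, nPts) {
  stemR <- 0.15
  nStem <- max(3L, round(nPts / 3))
  nLeafPts <- nPts - nStem
  # stem: vertical segment with radial Gaussian spread; endpoints forced so
  # the realized z-range equals the designed height exactly (noiseless case)
  t <- c(0, 1, stats::runif(max(nStem - 2L, 0)))
  az <- stats::runif(nStem, 0, 2 * pi)
  rr <- abs(stats::rnorm(nStem, 0, stemR / 2))
  stem <- cbind(rr * cos(az), rr * sin(az), t * height)
  stemN <- cbind(cos(az), sin(az), 0)
  pts <- stem; nrm <- stemN
  leafArea <- 0
  if (nLeaves > 0L && nLeafPts > 0L) {
    reach <- sqrt(sum((extents / 2)^2))        # radial reach of the longest leaf
    per <- diff(round(seq(0, nLeafPts, length.out = nLeaves + 1L)))
    phi0 <- stats::runif(1, 0, 2 * pi)
    for (l in seq_len(nLeaves)) {
      np <- per[l]
      if (np < 2L) next
      phi <- phi0 + (l - 1) * 2 * pi / nLeaves + stats::runif(1, -0.3, 0.3)
      z0 <- stats::runif(1, 0.3, 0.7) * height
      L <- reach * stats::runif(1, 0.8, 1)
      w <- 0.15 * L
      s <- c(1, stats::runif(np - 1L))          # force full reach once
      u <- stats::runif(np, -1, 1) * w * sin(pi * pmin(s, 1))
      rho <- s * L
      # z profile: rises from the node, stays below the stem tip
      zz <- z0 + 0.8 * (height - z0) * s * (1 - 0.6 * s)
      dirR <- c(cos(phi), sin(phi), 0)
      dirU <- c(-sin(phi), cos(phi), 0)
      p <- cbind(rho * dirR[1] + u * dirU[1],
                 rho * dirR[2] + u * dirU[2], zz)
      # surface normal from the analytic tangents of the ribbon
      dzds <- 0.8 * (height - z0) * (1 - 1.2 * s)
      tanS <- cbind(L * dirR[1], L * dirR[2], dzds)
      tanU <- matrix(dirU, np, 3, byrow = TRUE)
      nv <- cbind(tanS[, 2] * tanU[, 3] - tanS[, 3] * tanU[, 2],
                  tanS[, 3] * tanU[, 1] - tanS[, 1] * tanU[, 3],
                  tanS[, 1] * tanU[, 2] - tanS[, 2] * tanU[, 1])
      nv <- nv / sqrt(rowSums(nv^2))
      pts <- rbind(pts, p); nrm <- rbind(nrm, nv)
      leafArea <- leafArea + L * 2 * w * 2 / pi  # mean ribbon width
    }
  }
  list(points = pts, normals = nrm,
       volume = pi * stemR^2 * height + leafArea * 0.1,  # nominal 1 mm lamina
       area = 2 * pi * stemR * height + 2 * leafArea)
}

#' Generate a labeled synthetic tray scene
#'
#' Plants are placed by rejection sampling with a guaranteed edge-to-edge
#' canopy gap of 2.5 cm, so instances are well separated relative to the
#' intra-plant point spacing. Ground truth (realized z-extent, horizontal
#' AABB diagonal, nominal solid volume/area) is recorded from the untilted
#' points; the tilt and the world scale are applied afterwards, so the
#' alignment and scaling stages can be validated against the manifest.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A list with elements `cloud` (a \linkS4class{LabeledCloud}) and
#'   `truth` (a data.frame with columns plant_id, height_cm, canopy_cm,
#'   volume_cm3, area_cm2, n_points).
#' @examples
#' sc <- generateScene(sceneSpec(nPlants = 2, seed = 7))
#' sc$truth
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  set.seed(spec@seed %% .Machine$integer.max)
  side <- spec@traySide
  K <- spec@nPlants

  # tray
  nt <- spec@pointsOnTray
  tray <- cbind(stats::runif(nt, 0, side), stats::runif(nt, 0, side), 0)
  trayN <- matrix(rep(c(0, 0, 1), each = nt), nt, 3)

  # plant placement: uniform rejection sampling, 2.5 cm canopy clearance
  radii <- if (K) apply(spec@canopyExtents, 1, function(e) sqrt(sum((e / 2)^2)))
  centers <- matrix(0, K, 2)
  if (K > 0L) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      ok <- TRUE
      for (i in seq_len(K)) {
        margin <- min(radii[i] + 0.5, side / 2 - 1e-6)
        got <- FALSE
        for (tr in seq_len(100L)) {
          cand <- stats::runif(2, margin, side - margin)
          if (i == 1L || all(sqrt(colSums((t(centers[seq_len(i - 1L), ,
                 drop = FALSE]) - cand)^2)) >= radii[seq_len(i - 1L)] + radii[i] + 2.5)) {
            centers[i, ] <- cand; got <- TRUE; break
          }
        }
        if (!got) { ok <- FALSE; break }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("generateScene: could not place ", K,
           " non-overlapping plants on a ", side, " cm tray")
  }

  pts <- tray; nrm <- trayN
  sem <- rep(0L, nt); inst <- rep(0L, nt)
  truth <- data.frame(plant_id = integer(0), height_cm = numeric(0),
                      canopy_cm = numeric(0), volume_cm3 = numeric(0),
                      area_cm2 = numeric(0), n_points = integer(0))
  plantRows <- vector("list", K)
  for (i in seq_len(K)) {
    pl <- .samplePlant(spec@plantHeights[i], spec@canopyExtents[i, ],
                       spec@leafCount[i], spec@pointsPerPlant)
    p <- pl$points
    p[, 1] <- p[, 1] + centers[i, 1]
    p[, 2] <- p[, 2] + centers[i, 2]
    plantRows[[i]] <- nrow(pts) + seq_len(nrow(p))
    pts <- rbind(pts, p); nrm <- rbind(nrm, pl$normals)
    sem <- c(sem, rep(1L, nrow(p))); inst <- c(inst, rep(i, nrow(p)))
    truth <- rbind(truth, data.frame(
      plant_id = i, height_cm = NA_real_, canopy_cm = NA_real_,
      volume_cm3 = pl$volume, area_cm2 = pl$area, n_points = nrow(p)))
  }

  # additive jitter, then record ground truth from the realized untilted points
  if (spec@noiseSd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, spec@noiseSd), nrow(pts), 3)
  for (i in seq_len(K)) {
    pp <- pts[plantRows[[i]], , drop = FALSE]
    truth$height_cm[i] <- diff(range(pp[, 3]))
    truth$canopy_cm[i] <- sqrt(diff(range(pp[, 1]))^2 + diff(range(pp[, 2]))^2)
  }

  # tilt about a horizontal axis, then rescale to scene units
  if (spec@tiltAngleDeg > 0) {
    R <- rodriguesRotation(spec@tiltAxis, spec@tiltAngleDeg * pi / 180)
    pts <- pts %*% t(R)
    nrm <- nrm %*% t(R)
  }
  pts <- pts * spec@worldScale

  list(cloud = labeledCloud(pts, nrm, sem, inst), truth = truth)
}

#' Generate a directory of synthetic scenes with a ground-truth manifest
#'
#' Stands in for a collected multi-tray dataset: writes `nScenes` labeled
#' text files plus `manifest.csv` holding the per-plant ground truth.
#'
#' @param nScenes number of scenes (>= 1).
#' @param outDir output directory (created if missing).
#' @param nPlantsRange integer range for the per-scene plant count.
#' @param tiltRangeDeg range of tilt angles, degrees.
#' @param noiseSd jitter sd, cm.
#' @param seed integer seed; scene s uses `seed * 1000 + s`.
#' @param ... further arguments passed to [sceneSpec()].
#' @return Invisibly, the manifest data.frame (columns scene_id, file,
#'   plant_id, height_cm, canopy_cm, volume_cm3, area_cm2, n_points).
#' @export
generateDataset <- function(nScenes, outDir, nPlantsRange = c(2L, 6L),
                            tiltRangeDeg = c(5, 20), noiseSd = 0.05,
                            seed = 1L, ...) {
  stopifnot(nScenes >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nScenes)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  nP <- sample(seq(nPlantsRange[1], nPlantsRange[2]), nScenes, replace = TRUE)
  tilt <- stats::runif(nScenes, tiltRangeDeg[1], tiltRangeDeg[2])
  for (s in seq_len(nScenes)) {
    sp <- sceneSpec(nPlants = nP[s], tiltAngleDeg = tilt[s], noiseSd = noiseSd,
                    seed = (as.integer(seed) * 1000L + s) %% .Machine$integer.max,
                    ...)
    sc <- generateScene(sp)
    f <- file.path(outDir, sprintf("scene_%04d.txt", s))
    writeLabeledTxt(sc$cloud, f)
    if (nrow(sc$truth))
      rows[[s]] <- cbind(scene_id = s, file = basename(f), sc$truth)
  }
  manifest <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(manifest))
    manifest <- data.frame(scene_id = integer(0), file = character(0))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
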