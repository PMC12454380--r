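#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib corncloud, .registration = TRUE
NULL

#' LabeledCloud: a point cloud with normals and optional labels
#'
#' The universal exchange record of the package: an n x 3 coordinate matrix,
#' an n x 3 matrix of unit normals (all-zero rows allowed when normals are
#' absent), and two optional per-point label channels. The semantic channel
#' is binary (0 = non-seedling, 1 = seedling); the instance channel is 0 for
#' non-seedling points and 1..K for individual plants. Coordinates are
#' unitless scene units until the phenotyping stage applies the reference
#' scale factor.
#'
#' @slot points numeric matrix, n x 3 (x, y, z).
#' @slot normals numeric matrix, n x 3 (Nx, Ny, Nz); unit length or all zero.
#' @slot semantic integer vector of length n (values in \{0, 1\}) or length 0.
#' @slot instance integer vector of length n (values >= 0) or length 0.
#'
#' @exportClass LabeledCloud
setClass("LabeledCloud",
  representation(points = "matrix", normals = "matrix",
                 semantic = "integer", instance = "integer"),
  prototype(points = matrix(numeric(0), 0, 3),
            normals = matrix(numeric(0), 0, 3),
            semantic = integer(0), instance = integer(0)))

setValidity("LabeledCloud", function(object) {
  n <- nrow(object@points)
  msg <- character(0)
  if (ncol(object@points) != 3L) msg <- c(msg, "points must have 3 columns")
  if (!all(dim(object@normals) == c(n, 3L)))
    msg <- c(msg, "normals must be an n x 3 matrix")
  if (length(object@semantic) && length(object@semantic) != n)
    msg <- c(msg, "semantic labels must match point count")
  if (length(object@instance) && length(object@instance) != n)
    msg <- c(msg, "instance labels must match point count")
  if (length(object@semantic) && !all(object@semantic %in% c(0L, 1L)))
    msg <- c(msg, "semantic labels must be 0 or 1")
  if (length(object@instance) && any(object@instance < 0L))
    msg <- c(msg, "instance labels must be >= 0")
  if (length(object@semantic) && length(object@instance) &&
      any(object@instance > 0L & object@semantic == 0L))
    msg <- c(msg, "instance > 0 on a semantic-0 point")
  if (n > 0) {
    nn <- sqrt(rowSums(object@normals^2))
    if (!all(abs(nn - 1) <= 1e-3 | nn == 0))
      msg <- c(msg, "normals must be unit length (within 1e-3) or all-zero")
  }
  if (any(!is.finite(object@points)))
    msg <- c(msg, "non-finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledCloud
#'
#' @param points n x 3 numeric matrix of coordinates.
#' @param normals n x 3 numeric matrix of unit normals; defaults to all-zero.
#' @param semantic optional integer vector in \{0,1\}.
#' @param instance optional integer vector (0 = background, 1..K = plants).
#' @return A validated \linkS4class{LabeledCloud}.
#' @examples
#' cl <- labeledCloud(matrix(rnorm(30), 10, 3))
#' nPoints(cl)
#' @export
labeledCloud <- function(points, normals = NULL, semantic = NULL,
                         instance = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (is.null(normals)) normals <- matrix(0, nrow(points), 3)
  normals <- as.matrix(normals)
  storage.mode(normals) <- "double"
  dimnames(normals) <- NULL
  new("LabeledCloud", points = points, normals = normals,
      semantic = if (is.null(semantic)) integer(0) else as.integer(semantic),
      instance = if (is.null(instance)) integer(0) else as.integer(instance))
}

#' @describeIn labeledCloud Number of points in the cloud.
#' @param x a LabeledCloud.
#' @export
nPoints <- function(x) nrow(x@points)

#' Accessors for LabeledCloud slots
#'
#' @param x a \linkS4class{LabeledCloud}.
#' @return `cloudPoints` and `cloudNormals` return n x 3 matrices;
#'   `semanticLabels` and `instanceLabels` return integer vectors (length 0
#'   when the channel is absent); `hasLabels` returns a logical scalar.
#' @name cloud-accessors
NULL

#' @rdname cloud-accessors
#' @export
cloudPoints <- function(x) x@points

#' @rdname cloud-accessors
#' @export
cloudNormals <- function(x) x@normals

#' @rdname cloud-accessors
#' @export
semanticLabels <- function(x) x@semantic

#' @rdname cloud-accessors
#' @export
instanceLabels <- function(x) x@instance

#' @rdname cloud-accessors
#' @export
hasLabels <- function(x) length(x@semantic) > 0L

setMethod("show", "LabeledCloud", function(object) {
  n <- nPoints(object)
  cat("LabeledCloud with", n, "points\n")
  if (length(object@semantic))
    cat("  seedling points:", sum(object@semantic == 1L), "\n")
  if (length(object@instance)) {
    k <- length(setdiff(unique(object@instance), 0L))
    cat("  plant instances:", k, "\n")
  }
  if (n > 0) {
    rng <- apply(object@points, 2, range)
    cat(sprintf("  extent: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(NULL)
})

#' Subset a LabeledCloud by point index
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param idx integer index vector (may repeat or reorder points).
#' @return A LabeledCloud containing the selected points, labels carried along.
#' @export
subsetCloud <- function(cloud, idx) {
  labeledCloud(cloud@points[idx, , drop = FALSE],
               cloud@normals[idx, , drop = FALSE],
               if (length(cloud@semantic)) cloud@semantic[idx],
               if (length(cloud@instance)) cloud@instance[idx])
}

#' InstanceAssignment: clustering result over a point set
#'
#' Per-point cluster ids from density clustering: -1 marks noise, clusters
#' are numbered 0..K-1 in decreasing size order. Carries the neighbourhood
#' radius actually used.
#'
#' @slot labels integer vector, -1 or 0..K-1.
#' @slot epsUsed neighbourhood radius in scene units.
#' @slot kNeighbors the k of the k-th nearest-neighbour eps estimate.
#' @slot minPts minimum cluster size.
#' @exportClass InstanceAssignment
setClass("InstanceAssignment",
  representation(labels = "integer", epsUsed = "numeric",
                 kNeighbors = "integer", minPts = "integer"))

setValidity("InstanceAssignment", function(object) {
  msg <- character(0)
  if (any(object@labels < -1L)) msg <- c(msg, "labels must be >= -1")
  cl <- object@labels[object@labels >= 0L]
  if (length(cl)) {
    sizes <- table(cl)
    if (any(sizes < object@minPts))
      msg <- c(msg, "every cluster must have >= minPts members")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "InstanceAssignment", function(object) {
  k <- length(unique(object@labels[object@labels >= 0L]))
  cat("InstanceAssignment:", k, "clusters,",
      sum(object@labels == -1L), "noise points",
      sprintf("(eps = %.4g, k = %d, minpts = %d)\n",
              object@epsUsed, object@kNeighbors, object@minPts))
  invisible(NULL)
})

#' @rdname cloud-accessors
#' @export
clusterLabels <- function(x) x@labels

#' @rdname cloud-accessors
#' @export
epsUsed <- function(x) x@epsUsed

#' AlignmentTransform: ground-plane alignment and metric scaling
#'
#' @slot rotation 3 x 3 rotation matrix (orthonormal, det +1) mapping the
#'   detected ground normal onto +z.
#' @slot planeNormal the detected unit ground normal (before rotation).
#' @slot theta rotation angle in radians.
#' @slot scaleK centimetres per scene unit (reference length / virtual length).
#' @slot referenceLengthReal real-world reference length in cm.
#' @exportClass AlignmentTransform
setClass("AlignmentTransform",
  representation(rotation = "matrix", planeNormal = "numeric",
                 theta = "numeric", scaleK = "numeric",
                 referenceLengthReal = "numeric"),
  prototype(rotation = diag(3), planeNormal = c(0, 0, 1), theta = 0,
            scaleK = 1, referenceLengthReal = 25))

setValidity("AlignmentTransform", function(object) {
  R <- object@rotation
  msg <- character(0)
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9) msg <- c(msg, "rotation must have det +1")
  }
  if (object@scaleK <= 0) msg <- c(msg, "scaleK must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignmentTransform", function(object) {
  cat(sprintf("AlignmentTransform: theta = %.3f deg, k = %.5g cm/unit\n",
              object@theta * 180 / pi, object@scaleK))
  invisible(NULL)
})
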