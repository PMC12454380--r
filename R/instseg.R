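# CornDBSCAN: density clustering of segmented seedling points into plant
# instances, with the neighbourhood radius estimated from the data as the
# mean k-th nearest-neighbour distance (k = 55), and Hungarian matching of
# predicted clusters to ground-truth plants.

#' Estimate the DBSCAN eps from k-nearest-neighbour distances
#'
#' For each point, the Euclidean distance to its k-th nearest neighbour
#' (self excluded; the most distant member of the k-nearest set) is taken as
#' a local density indicator, and the arithmetic mean over all points is the
#' eps estimate.
#'
#' @param points n x 3 coordinate matrix.
#' @param k neighbour rank; default 55.
#' @return The eps estimate (scene units).
#' @examples
#' pts <- cbind(0:55, 0, 0)   # collinear, unit spacing
#' estimateEps(pts)           # 41.5
#' @export
estimateEps <- function(points, k = 55L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k)
    stop("estimateEps: need more than k = ", k, " points, got ", n)
  kd <- knn_cpp(points, points, as.integer(k), self = TRUE)
  mean(kd$dist[, k])
}

#' CornDBSCAN: adaptive-eps density clustering into plant instances
#'
#' Runs DBSCAN with `minPts = 3` and `eps` estimated by [estimateEps()] on
#' the points being clustered. Clusters are renumbered 0..K-1 by decreasing
#' size; noise points get label -1. Clouds with at most `k` points fall back
#' to `k = n - 1` (with a warning); clouds below `minPts`, or with all points
#' coincident (eps = 0), are labeled entirely as noise.
#'
#' @param points n x 3 matrix of seedling-class points, or a
#'   \linkS4class{LabeledCloud} (its semantic-1 subset is clustered and the
#'   result is reported over all points, background fixed at -1... see
#'   Details).
#' @param k neighbour rank for the eps estimate (default 55).
#' @param minPts minimum cluster size (default 3).
#' @param eps optional fixed radius; when supplied the estimation step is
#'   skipped (the plain fixed-eps DBSCAN baseline).
#' @return An \linkS4class{InstanceAssignment} over the supplied points.
#' @details When given a LabeledCloud, only the semantic-1 points are
#'   clustered and the returned labels cover that subset, in subset order.
#' @export
cornDBSCAN <- function(points, k = 55L, minPts = 3L, eps = NULL) {
  if (is(points, "LabeledCloud")) {
    if (!hasLabels(points))
      stop("cornDBSCAN: cloud has no semantic labels; pass the point matrix")
    points <- points@points[points@semantic == 1L, , drop = FALSE]
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n == 0L) stop("cornDBSCAN: empty point set")
  kUse <- as.integer(k)
  if (is.null(eps)) {
    if (n < as.integer(minPts)) {
      warning("cornDBSCAN: fewer points than minPts; all points are noise")
      return(new("InstanceAssignment", labels = rep(-1L, n), epsUsed = 0,
                 kNeighbors = kUse, minPts = as.integer(minPts)))
    }
    if (n <= kUse) {
      warning("cornDBSCAN: only ", n, " points; reducing k to ", n - 1L)
      kUse <- n - 1L
    }
    eps <- estimateEps(points, kUse)
  }
  if (eps <= 0) {
    warning("cornDBSCAN: degenerate input (eps = 0); all points are noise")
    return(new("InstanceAssignment", labels = rep(-1L, n), epsUsed = 0,
               kNeighbors = kUse, minPts = as.integer(minPts)))
  }
  raw <- dbscan_cpp(points, eps, as.integer(minPts))
  new("InstanceAssignment", labels = .renumberBySize(raw), epsUsed = eps,
      kNeighbors = kUse, minPts = as.integer(minPts))
}

#' Fixed-eps DBSCAN baseline
#'
#' @param points n x 3 coordinate matrix.
#' @param eps neighbourhood radius.
#' @param minPts minimum cluster size.
#' @return An \linkS4class{InstanceAssignment}.
#' @export
dbscanCluster <- function(points, eps, minPts = 3L) {
  cornDBSCAN(points, minPts = minPts, eps = eps)
}

# renumber cluster ids 0..K-1 by decreasing member count (ties: old id order)
.renumberBySize <- function(labels) {
  ids <- labels[labels >= 0L]
  if (!length(ids)) return(labels)
  sizes <- sort(table(ids), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- labels
  pos <- labels >= 0L
  out[pos] <- remap[as.character(labels[pos])]
  as.integer(out)
}

#' Match predicted clusters to ground-truth plants (Hungarian algorithm)
#'
#' Builds the contingency matrix of shared points between predicted clusters
#' and ground-truth instances and solves the assignment that maximizes the
#' summed pairwise IoU. Noise points (-1) belong to no predicted cluster;
#' matches with zero overlap are discarded, so unmatched predictions count
#' as false positives downstream.
#'
#' @param pred an \linkS4class{InstanceAssignment} or an integer vector of
#'   predicted labels (-1 noise, 0..K-1 clusters).
#' @param truth integer vector of ground-truth instance labels over the same
#'   points (0 = background, 1..M = plants).
#' @return A data.frame with columns `pred`, `truth`, `iou`, one row per
#'   matched pair.
#' @export
matchInstances <- function(pred, truth) {
  if (is(pred, "InstanceAssignment")) pred <- pred@labels
  stopifnot(length(pred) == length(truth))
  pid <- sort(unique(pred[pred >= 0L]))
  tid <- sort(unique(truth[truth > 0L]))
  if (!length(pid) || !length(tid))
    return(data.frame(pred = integer(0), truth = integer(0), iou = numeric(0)))
  inter <- matrix(0, length(pid), length(tid), dimnames = list(pid, tid))
  tab <- table(factor(pred, levels = pid), factor(truth, levels = tid))
  inter[] <- as.numeric(tab)
  sizeP <- as.numeric(table(factor(pred, levels = pid)))
  sizeT <- as.numeric(table(factor(truth, levels = tid)))
  iou <- inter / (outer(sizeP, sizeT, "+") - inter)
  sel <- solveAssignment(-iou)   # minimize negative IoU = maximize IoU
  out <- data.frame(pred = pid[sel$row], truth = tid[sel$col],
                    iou = iou[cbind(sel$row, sel$col)])
  out[out$iou > 0, , drop = FALSE]
}
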