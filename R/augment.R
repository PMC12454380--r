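# The six point-cloud augmentations used to enrich tray-scene training data:
# fake dropout, jitter, per-axis rotation, scaling, index shuffling and
# translation, plus the 7x dataset builder with an 8:1:1 split.
# All draws come from R's global RNG; callers seed with set.seed() for
# reproducibility (buildAugmentedDataset seeds internally from its config).

#' Augmentation configuration
#'
#' Defaults follow the standard tray-scene recipe: drop 10-20% of points,
#' Gaussian jitter sd 0.01 clipped at +/-0.05, +/-10 degree independent
#' per-axis rotations, scaling in [0.67, 1.5], +/-0.1 per-axis translation,
#' and an 8:1:1 train/test/val split.
#'
#' @param dropoutRange fraction interval of points to drop.
#' @param jitterSd Gaussian jitter standard deviation (scene units).
#' @param jitterClip hard bound on each jitter component; must be >= jitterSd.
#' @param rotationRangeDeg per-axis rotation interval, degrees.
#' @param scaleRange scaling-factor interval (about the centroid).
#' @param translationRange per-axis translation interval, scene units.
#' @param splitRatio train/test/val probabilities; must sum to 1.
#' @param seed integer seed used by [buildAugmentedDataset()].
#' @return A classed list of class `"AugmentConfig"`.
#' @export
augmentConfig <- function(dropoutRange = c(0.10, 0.20), jitterSd = 0.01,
                          jitterClip = 0.05, rotationRangeDeg = c(-10, 10),
                          scaleRange = c(0.67, 1.5),
                          translationRange = c(-0.1, 0.1),
                          splitRatio = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(all(dropoutRange > 0), all(dropoutRange < 1),
            jitterClip >= jitterSd, all(scaleRange > 0),
            abs(sum(splitRatio) - 1) < 1e-9)
  structure(list(dropoutRange = dropoutRange, jitterSd = jitterSd,
                 jitterClip = jitterClip, rotationRangeDeg = rotationRangeDeg,
                 scaleRange = scaleRange, translationRange = translationRange,
                 splitRatio = splitRatio, seed = as.integer(seed)),
            class = "AugmentConfig")
}

#' Fake dropout: randomly remove 10-20% of points
#'
#' Draws p uniformly from `dropoutRange` and removes `round(p * N)` points;
#' survivors keep their order and labels. Refuses clouds with fewer than 10
#' points, where the 10% granularity cannot be realized.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param config an [augmentConfig()].
#' @return The thinned LabeledCloud.
#' @export
fakeDropout <- function(cloud, config = augmentConfig()) {
  n <- nPoints(cloud)
  if (n < 10L)
    stop("fakeDropout: cloud has ", n, " points; need >= 10")
  p <- stats::runif(1, config$dropoutRange[1], config$dropoutRange[2])
  drop <- sample.int(n, round(p * n))
  subsetCloud(cloud, sort(setdiff(seq_len(n), drop)))
}

#' Jitter: clipped Gaussian coordinate noise
#'
#' Adds per-coordinate displacements drawn from Normal(0, `jitterSd`) and
#' hard-clipped to `[-jitterClip, jitterClip]`. Normals and labels are
#' unchanged.
#'
#' @inheritParams fakeDropout
#' @return The jittered LabeledCloud.
#' @export
jitterCloud <- function(cloud, config = augmentConfig()) {
  n <- nPoints(cloud)
  d <- matrix(stats::rnorm(3 * n, 0, config$jitterSd), n, 3)
  d <- pmin(pmax(d, -config$jitterClip), config$jitterClip)
  labeledCloud(cloud@points + d, cloud@normals, cloud@semantic, cloud@instance)
}

# rotation matrices about the coordinate axes
.rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
.rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Rotate: independent random rotations about x, y and z
#'
#' Applies Rz Ry Rx with each angle uniform in `rotationRangeDeg`, about the
#' cloud centroid, to points and normals alike.
#'
#' @inheritParams fakeDropout
#' @return The rotated LabeledCloud.
#' @export
rotateCloud <- function(cloud, config = augmentConfig()) {
  a <- stats::runif(3, config$rotationRangeDeg[1], config$rotationRangeDeg[2]) * pi / 180
  R <- .rotZ(a[3]) %*% .rotY(a[2]) %*% .rotX(a[1])
  ctr <- colMeans(cloud@points)
  p <- sweep(cloud@points, 2, ctr) %*% t(R)
  p <- sweep(p, 2, ctr, "+")
  labeledCloud(p, cloud@normals %*% t(R), cloud@semantic, cloud@instance)
}

#' Scale: one random factor about the centroid
#'
#' @inheritParams fakeDropout
#' @return The scaled LabeledCloud (normals untouched).
#' @export
scaleCloud <- function(cloud, config = augmentConfig()) {
  s <- stats::runif(1, config$scaleRange[1], config$scaleRange[2])
  ctr <- colMeans(cloud@points)
  p <- sweep(sweep(cloud@points, 2, ctr) * s, 2, ctr, "+")
  labeledCloud(p, cloud@normals, cloud@semantic, cloud@instance)
}

#' Shuffle: index-based random reordering
#'
#' Applies one uniform permutation jointly to points, normals and labels.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @return The reordered LabeledCloud.
#' @export
shuffleCloud <- function(cloud) {
  subsetCloud(cloud, sample.int(nPoints(cloud)))
}

#' Translate: one random offset per axis
#'
#' @inheritParams fakeDropout
#' @return The translated LabeledCloud.
#' @export
translateCloud <- function(cloud, config = augmentConfig()) {
  off <- stats::runif(3, config$translationRange[1], config$translationRange[2])
  labeledCloud(sweep(cloud@points, 2, off, "+"), cloud@normals,
               cloud@semantic, cloud@instance)
}

#' Build the augmented dataset with an 8:1:1 split
#'
#' Each input cloud yields its original plus one variant per technique
#' (7 files per input; 106 inputs give 742 files). Files are then assigned
#' to train/test/val independently with the configured probabilities, and a
#' manifest CSV is written per split.
#'
#' @param inputDir directory of labeled `.txt` clouds.
#' @param outDir output directory.
#' @param config an [augmentConfig()].
#' @return Invisibly, a data.frame with columns file, source, technique,
#'   split.
#' @export
buildAugmentedDataset <- function(inputDir, outDir, config = augmentConfig()) {
  files <- list.files(inputDir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt files in ", inputDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  techniques <- c("orig", "drop", "jitter", "rot", "scale", "shuffle", "trans")
  rows <- vector("list", length(files) * 7L)
  r <- 0L
  for (f in files) {
    cl <- readLabeledTxt(f)
    stem <- sub("\\.txt$", "", basename(f))
    for (tech in techniques) {
      v <- switch(tech,
        orig = cl,
        drop = fakeDropout(cl, config),
        jitter = jitterCloud(cl, config),
        rot = rotateCloud(cl, config),
        scale = scaleCloud(cl, config),
        shuffle = shuffleCloud(cl),
        trans = translateCloud(cl, config))
      out <- file.path(outDir, paste0(stem, "_", tech, ".txt"))
      writeLabeledTxt(v, out)
      r <- r + 1L
      rows[[r]] <- data.frame(file = basename(out), source = basename(f),
                              technique = tech)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$split <- sample(c("train", "test", "val"), nrow(manifest),
                           replace = TRUE, prob = config$splitRatio)
  for (sp in c("train", "test", "val"))
    utils::write.csv(manifest[manifest$split == sp, , drop = FALSE],
                     file.path(outDir, paste0(sp, ".csv")), row.names = FALSE)
  invisible(manifest)
}
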