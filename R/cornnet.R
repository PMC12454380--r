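# The CBAM-augmented hierarchical point network for binary semantic
# segmentation of tray scenes. Encoder: three cascaded set-abstraction (SA)
# levels with multi-scale grouping; inside each SA level the per-group MLP
# output passes through channel-then-spatial attention (CBAM) before max
# pooling. Decoder: three feature-propagation (FP) levels with
# inverse-distance interpolation and skip connections, then a shared MLP
# head producing per-point class logits. Training minimizes the composite
# loss (inverse-frequency-weighted binary cross-entropy plus an optional
# lambda-weighted L1 regression term) with Adam.

#' Network configuration
#'
#' The `"full"` preset follows the published multi-scale-grouping
#' segmentation architecture at npoint 4096; the `"small"` preset is the
#' same network scaled to npoint 1024 for CPU-sized experiments. Training
#' defaults: Adam, learning rate 5e-4, weight decay 1e-4, batch size 24,
#' up to 100 epochs.
#'
#' @param preset `"small"` or `"full"`.
#' @param npoint points per resampled chunk.
#' @param saPoints integer vector of SA-level centroid counts.
#' @param radii list of per-level radius vectors (fractions of the unit
#'   sphere the cloud is normalized into).
#' @param nsample list of per-level neighbour caps (one per radius).
#' @param mlps list of per-level MLP widths (shared across the level's
#'   radius branches).
#' @param fpMlps list of per-level FP MLP widths (coarse to fine).
#' @param headMlp widths of the point-wise head.
#' @param cbamReduction channel-attention bottleneck ratio (default 8).
#' @param lossLambda lambda of the composite loss (default 0: pure
#'   segmentation, no regression pairs).
#' @param epochs,batch,lr,weightDecay optimizer settings.
#' @param seed one integer seed driving initialization, resampling and
#'   data order.
#' @return A classed list of class `"NetConfig"`.
#' @export
netConfig <- function(preset = c("small", "full"), npoint = NULL,
                      saPoints = NULL, radii = NULL, nsample = NULL,
                      mlps = NULL, fpMlps = NULL, headMlp = NULL,
                      cbamReduction = 8L, lossLambda = 0, epochs = 100L,
                      batch = 24L, lr = 5e-4, weightDecay = 1e-4,
                      seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "full") list(
    npoint = 4096L, saPoints = c(1024L, 256L, 64L),
    radii = list(c(0.05, 0.1), c(0.1, 0.2), c(0.2, 0.4)),
    nsample = list(c(16L, 32L), c(16L, 32L), c(16L, 32L)),
    mlps = list(c(32L, 32L, 64L), c(64L, 64L, 128L), c(128L, 128L, 256L)),
    fpMlps = list(c(256L, 256L), c(256L, 128L), c(128L, 128L)),
    headMlp = c(128L)
  ) else list(
    npoint = 1024L, saPoints = c(256L, 64L, 16L),
    radii = list(c(0.1, 0.2), c(0.2, 0.4), c(0.4, 0.8)),
    nsample = list(c(8L, 16L), c(8L, 16L), c(8L, 16L)),
    mlps = list(c(16L, 16L, 32L), c(32L, 32L, 64L), c(64L, 64L, 128L)),
    fpMlps = list(c(128L, 64L), c(64L, 32L), c(32L, 32L)),
    headMlp = c(32L)
  )
  cfg <- list(npoint = npoint %||% def$npoint,
              saPoints = saPoints %||% def$saPoints,
              radii = radii %||% def$radii,
              nsample = nsample %||% def$nsample,
              mlps = mlps %||% def$mlps,
              fpMlps = fpMlps %||% def$fpMlps,
              headMlp = headMlp %||% def$headMlp,
              cbamReduction = as.integer(cbamReduction),
              lossLambda = lossLambda, epochs = as.integer(epochs),
              batch = as.integer(batch), lr = lr,
              weightDecay = weightDecay, seed = as.integer(seed))
  stopifnot(length(cfg$saPoints) == length(cfg$fpMlps),
            length(cfg$saPoints) == length(cfg$radii),
            all(unlist(cfg$mlps) > 0), cfg$lossLambda >= 0)
  structure(cfg, class = "NetConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.heInit <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                   sqrt(2 / nin)), nin, nout)

.mlpParams <- function(widths, nin) {
  out <- list()
  for (w in widths) {
    out[[length(out) + 1L]] <- list(W = .heInit(nin, w),
                                    b = matrix(0, 1, w))
    nin <- w
  }
  out
}

.cbamParams <- function(C, reduction) {
  hidden <- max(1L, C %/% reduction)
  list(W1 = .heInit(C, hidden), b1 = matrix(0, 1, hidden),
       W2 = .heInit(hidden, C), b2 = matrix(0, 1, C),
       convW = matrix(0.01 * stats::rnorm(2), 2, 1), convB = matrix(0, 1, 1))
}

#' Initialize the network parameters
#'
#' @param config a [netConfig()].
#' @param inChannels input feature channels (default 6: coordinates plus
#'   normals).
#' @return A list of class `"NetState"` holding the parameter matrices, the
#'   configuration and the seed.
#' @export
initNet <- function(config = netConfig(), inChannels = 6L) {
  set.seed(config$seed)
  L <- length(config$saPoints)
  sa <- vector("list", L)
  cIn <- inChannels
  cOuts <- integer(L)
  for (l in seq_len(L)) {
    nr <- length(config$radii[[l]])
    branches <- vector("list", nr)
    for (r in seq_len(nr)) {
      mlp <- .mlpParams(config$mlps[[l]], cIn + 3L)
      cbam <- .cbamParams(utils::tail(config$mlps[[l]], 1L),
                          config$cbamReduction)
      branches[[r]] <- list(mlp = mlp, cbam = cbam)
    }
    sa[[l]] <- branches
    cOuts[l] <- utils::tail(config$mlps[[l]], 1L) * nr
    cIn <- cOuts[l]
  }
  fp <- vector("list", L)
  skip <- c(inChannels, cOuts[-L])   # skip channels at each fine level
  for (l in rev(seq_len(L))) {       # fp[[l]] refines level l-1 from level l
    coarseC <- if (l == L) cOuts[L] else utils::tail(config$fpMlps[[l + 1L]], 1L)
    fp[[l]] <- .mlpParams(config$fpMlps[[l]], coarseC + skip[l])
  }
  headIn <- utils::tail(config$fpMlps[[1L]], 1L)
  head <- .mlpParams(c(config$headMlp, 2L), headIn)
  structure(list(sa = sa, fp = fp, head = head, config = config,
                 inChannels = inChannels, trained = FALSE),
            class = "NetState")
}

# ---- attention (value-only reference implementations) ---------------------

#' Channel attention over a point feature map
#'
#' Average- and max-pools the n x C feature map over points, feeds both
#' pooled vectors through a shared two-layer MLP, sums, and applies the
#' sigmoid: Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))). The map (one
#' weight per channel, in (0,1)) multiplies every row of F.
#'
#' @param features n x C numeric matrix.
#' @param weights a list with `W1`, `b1`, `W2`, `b2` (as in the network's
#'   CBAM blocks).
#' @return A list with `map` (1 x C attention map) and `out` (n x C weighted
#'   features).
#' @export
channelAttention <- function(features, weights) {
  stopifnot(all(is.finite(features)))
  mlp <- function(x) {
    h <- pmax(x %*% weights$W1 + matrix(weights$b1, nrow(x), ncol(weights$W1),
                                        byrow = TRUE), 0)
    h %*% weights$W2 + matrix(weights$b2, nrow(h), ncol(weights$W2),
                              byrow = TRUE)
  }
  avg <- matrix(colMeans(features), 1)
  mx <- matrix(apply(features, 2, max), 1)
  map <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  list(map = map, out = features * matrix(map, nrow(features), ncol(features),
                                          byrow = TRUE))
}

#' Spatial attention over a point feature map
#'
#' Per point, the channel-wise average and maximum are concatenated into an
#' n x 2 descriptor and passed through a shared 1-point convolution (a
#' linear map to one channel) and the sigmoid: one weight per point in
#' (0,1), multiplying that point's feature row.
#'
#' @param features n x C numeric matrix.
#' @param weights a list with `convW` (2 x 1) and `convB` (1 x 1).
#' @return A list with `map` (n x 1) and `out` (n x C).
#' @export
spatialAttention <- function(features, weights) {
  stopifnot(all(is.finite(features)))
  desc <- cbind(rowMeans(features), apply(features, 1, max))
  map <- 1 / (1 + exp(-(desc %*% weights$convW + weights$convB[1, 1])))
  list(map = map, out = features * as.vector(map))
}

# ---- taped building blocks ------------------------------------------------

# shared MLP that also returns the parameter nodes for gradient collection
.tpMlpG <- function(x, params, tape, lastRelu = TRUE) {
  nodes <- vector("list", length(params))
  for (i in seq_along(params)) {
    W <- tpParam(tape, params[[i]]$W)
    b <- tpParam(tape, params[[i]]$b)
    x <- tpAddBias(tpMatmul(x, W, tape), b, tape)
    if (i < length(params) || lastRelu) x <- tpRelu(x, tape)
    nodes[[i]] <- list(W = W, b = b)
  }
  list(out = x, nodes = nodes)
}

# CBAM over grouped rows: seg assigns each row to a group 1..G
.tpCbamSeg <- function(x, cb, seg, G, tape) {
  W1 <- tpParam(tape, cb$W1); b1 <- tpParam(tape, cb$b1)
  W2 <- tpParam(tape, cb$W2); b2 <- tpParam(tape, cb$b2)
  cw <- tpParam(tape, cb$convW); cbias <- tpParam(tape, cb$convB)
  mlp2 <- function(v) tpAddBias(tpMatmul(
    tpRelu(tpAddBias(tpMatmul(v, W1, tape), b1, tape), tape), W2, tape),
    b2, tape)
  avg <- tpSegMean(x, seg, G, tape)
  mx <- tpSegMax(x, seg, G, tape)
  mc <- tpSigmoid(tpAdd(mlp2(avg), mlp2(mx), tape), tape)
  x1 <- tpScaleSeg(x, mc, seg, tape)
  desc <- tpCbind(list(tpRowMean(x1, tape), tpRowMax(x1, tape)), tape)
  ms <- tpSigmoid(tpAddBias(tpMatmul(desc, cw, tape), cbias, tape), tape)
  x2 <- tpScaleRows(x1, ms, tape)
  list(out = x2,
       nodes = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                    convW = cw, convB = cbias))
}

# one SA level: returns coarser coords (value) + feature node + param nodes
.tpSaLevel <- function(xyz, fnode, level, lcfg, tape) {
  m <- lcfg$npointOut
  fidx <- fps_cpp(xyz, m)
  newXyz <- xyz[fidx, , drop = FALSE]
  pooled <- list()
  nodes <- vector("list", length(lcfg$radii))
  for (r in seq_along(lcfg$radii)) {
    ns <- lcfg$nsample[r]
    grp <- ball_group_cpp(newXyz, xyz, lcfg$radii[r], ns)
    gidx <- as.vector(t(grp))               # group-major row order
    seg <- rep(seq_len(m), each = ns)
    rel <- (xyz[gidx, , drop = FALSE] -
            newXyz[seg, , drop = FALSE]) / lcfg$radii[r]
    gin <- tpCbind(list(tpConst(tape, rel), tpGather(fnode, gidx, tape)),
                   tape)
    mlp <- .tpMlpG(gin, level[[r]]$mlp, tape)
    cbam <- .tpCbamSeg(mlp$out, level[[r]]$cbam, seg, m, tape)
    pooled[[r]] <- tpSegMax(cbam$out, seg, m, tape)
    nodes[[r]] <- list(mlp = mlp$nodes, cbam = cbam$nodes)
  }
  list(xyz = newXyz, out = tpCbind(pooled, tape), nodes = nodes)
}

# one FP level: interpolate coarse features to the fine level, concat skip
.tpFpLevel <- function(fineXyz, coarseXyz, coarseNode, skipNode, params,
                       tape) {
  if (nrow(coarseXyz) == 0) stop("fp: empty coarse level")
  k3 <- min(3L, nrow(coarseXyz))
  kn <- knn_cpp(fineXyz, coarseXyz, k3)
  d <- pmax(kn$dist, 1e-10)
  w <- 1 / (d * d)
  w <- w / rowSums(w)
  interp <- tpInterp(coarseNode, kn$idx, w, tape)
  mlp <- .tpMlpG(tpCbind(list(interp, skipNode), tape), params, tape)
  list(out = mlp$out, nodes = mlp$nodes)
}

# full forward pass on one normalized cloud (coords N x 3, feats N x C0).
# Returns logits node, probabilities, and all parameter nodes for updates.
.tpForward <- function(state, coords, feats, tape) {
  cfg <- state$config
  L <- length(cfg$saPoints)
  xyzs <- list(coords)
  fnodes <- list(tpConst(tape, feats))
  saNodes <- vector("list", L)
  for (l in seq_len(L)) {
    lcfg <- list(npointOut = cfg$saPoints[l], radii = cfg$radii[[l]],
                 nsample = cfg$nsample[[l]])
    res <- .tpSaLevel(xyzs[[l]], fnodes[[l]], state$sa[[l]], lcfg, tape)
    xyzs[[l + 1L]] <- res$xyz
    fnodes[[l + 1L]] <- res$out
    saNodes[[l]] <- res$nodes
  }
  fpNodes <- vector("list", L)
  cur <- fnodes[[L + 1L]]
  for (l in rev(seq_len(L))) {
    res <- .tpFpLevel(xyzs[[l]], xyzs[[l + 1L]], cur, fnodes[[l]],
                      state$fp[[l]], tape)
    cur <- res$out
    fpNodes[[l]] <- res$nodes
  }
  headRes <- .tpMlpG(cur, state$head, tape, lastRelu = FALSE)
  list(logits = headRes$out,
       nodes = list(sa = saNodes, fp = fpNodes, head = headRes$nodes))
}

# ---- user-facing forward / loss -------------------------------------------

# center the cloud and scale to the unit sphere; features = coords + normals
.normalizeInput <- function(cloud, idx) {
  p <- cloud@points[idx, , drop = FALSE]
  ctr <- colMeans(p)
  p <- sweep(p, 2, ctr)
  s <- max(sqrt(rowSums(p^2)), 1e-9)
  p <- p / s
  list(coords = p, feats = cbind(p, cloud@normals[idx, , drop = FALSE]))
}

# resample a cloud to npoint indices: uniform without replacement when large,
# repetition-padded when small (duplicates keep the original's label)
.resampleIdx <- function(n, npoint) {
  if (n >= npoint) sample.int(n, npoint)
  else c(seq_len(n), sample.int(n, npoint - n, replace = TRUE))
}

#' Forward pass: per-point class probabilities
#'
#' Runs the network in evaluation mode on one cloud chunk (already resampled
#' to `npoint` points). Deterministic for a fixed state.
#'
#' @param state a `"NetState"` from [initNet()] or [trainNet()].
#' @param cloud a \linkS4class{LabeledCloud} with exactly
#'   `state$config$npoint` points.
#' @return A list with `probs` (n x 2, rows summing to 1) and `labels`
#'   (integer 0/1).
#' @export
netForward <- function(state, cloud) {
  stopifnot(inherits(state, "NetState"))
  inp <- .normalizeInput(cloud, seq_len(nPoints(cloud)))
  tape <- tapeNew()
  fw <- .tpForward(state, inp$coords, inp$feats, tape)
  L <- fw$logits$val
  m <- pmax(L[, 1], L[, 2])
  lse <- m + log(exp(L[, 1] - m) + exp(L[, 2] - m))
  p <- exp(L - lse)
  list(probs = p, labels = as.integer(p[, 2] > 0.5))
}

#' Composite segmentation loss
#'
#' `L = Lcls + lambda * Lreg` with
#' `Lcls = -(1/N) sum w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` over the
#' seedling-class probabilities (clamped to [1e-7, 1 - 1e-7]) and
#' `Lreg = sum |t - tbar|` over the supplied regression pairs (an empty set
#' contributes 0).
#'
#' @param probs numeric vector of seedling-class probabilities, or an n x 2
#'   matrix (second column used).
#' @param targets 0/1 vector.
#' @param regPairs optional two-column matrix of (t, tbar) pairs.
#' @param lambda regression weight, >= 0.
#' @param classWeights optional per-class weights `c(w0, w1)` as from
#'   [classRebalanceWeights()]; default uniform.
#' @return The scalar loss (>= 0).
#' @examples
#' compositeLoss(0.5, 1)              # log(2)
#' compositeLoss(c(1, 0), c(1, 0))    # ~0
#' @export
compositeLoss <- function(probs, targets, regPairs = NULL, lambda = 0,
                          classWeights = c(1, 1)) {
  if (lambda < 0) stop("compositeLoss: lambda must be >= 0")
  if (is.matrix(probs)) probs <- probs[, 2]
  stopifnot(length(probs) == length(targets))
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  w <- classWeights[targets + 1L]
  lcls <- -mean(w * (targets * log(p) + (1 - targets) * log(1 - p)))
  lreg <- if (is.null(regPairs) || !length(regPairs)) 0
          else sum(abs(regPairs[, 1] - regPairs[, 2]))
  lcls + lambda * lreg
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class frequency, normalized to mean 1, so
#' the minority (seedling) class carries proportionally more of the
#' classification loss. A batch containing a single class gets uniform
#' weights.
#'
#' @param targets 0/1 vector.
#' @return `c(w0, w1)` with mean 1.
#' @export
classRebalanceWeights <- function(targets) {
  f0 <- mean(targets == 0)
  f1 <- 1 - f0
  if (f0 == 0 || f1 == 0) return(c(1, 1))
  w <- c(1 / f0, 1 / f1)
  w / mean(w)
}

# ---- Adam -----------------------------------------------------------------

.paramPaths <- function(state) {
  paths <- list()
  for (l in seq_along(state$sa))
    for (r in seq_along(state$sa[[l]])) {
      for (i in seq_along(state$sa[[l]][[r]]$mlp))
        for (nm in c("W", "b"))
          paths[[length(paths) + 1L]] <- c("sa", l, r, "mlp", i, nm)
      for (nm in c("W1", "b1", "W2", "b2", "convW", "convB"))
        paths[[length(paths) + 1L]] <- c("sa", l, r, "cbam", nm)
    }
  for (l in seq_along(state$fp))
    for (i in seq_along(state$fp[[l]]))
      for (nm in c("W", "b"))
        paths[[length(paths) + 1L]] <- c("fp", l, i, nm)
  for (i in seq_along(state$head))
    for (nm in c("W", "b"))
      paths[[length(paths) + 1L]] <- c("head", i, nm)
  paths
}

.getPath <- function(x, path) {
  for (p in path) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

.setPath <- function(x, path, val) {
  p <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  if (length(path) == 1L) x[[p]] <- val
  else x[[p]] <- .setPath(x[[p]], path[-1L], val)
  x
}

# map a parameter path to its node in the forward graph
.gradForPath <- function(fwNodes, path) {
  nd <- switch(path[1],
    sa = {
      l <- as.integer(path[2]); r <- as.integer(path[3])
      br <- fwNodes$sa[[l]][[r]]
      if (path[4] == "mlp") br$mlp[[as.integer(path[5])]][[path[6]]]
      else br$cbam[[path[5]]]
    },
    fp = fwNodes$fp[[as.integer(path[2])]][[as.integer(path[3])]][[path[4]]],
    head = fwNodes$head[[as.integer(path[2])]][[path[3]]])
  nd$grad
}

#' Train the network
#'
#' Adam with the configured learning rate, weight decay and batch size; one
#' cloud per forward pass, gradients accumulated over each batch. Per-epoch
#' training loss and validation loss/accuracy are logged; the state with the
#' best validation accuracy is retained. Fully seeded: two runs with the
#' same configuration produce identical logs.
#'
#' @param trainClouds list of labeled \linkS4class{LabeledCloud}s.
#' @param valClouds optional validation list; defaults to `trainClouds`.
#' @param config a [netConfig()].
#' @param stopValAcc optional early-stop threshold on validation accuracy
#'   (fraction, e.g. 0.995).
#' @param verbose print a line per epoch.
#' @return A `"NetState"` with the trained parameters and a `log` data.frame
#'   (epoch, train_loss, val_loss, val_acc).
#' @export
trainNet <- function(trainClouds, valClouds = NULL, config = netConfig(),
                     stopValAcc = NULL, verbose = FALSE) {
  if (!length(trainClouds)) stop("trainNet: empty training set")
  if (is.null(valClouds)) valClouds <- trainClouds
  state <- initNet(config)
  paths <- .paramPaths(state)
  mom <- lapply(paths, function(p) 0)
  vel <- lapply(paths, function(p) 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  step <- 0L
  set.seed(config$seed + 1L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_acc = numeric(0))
  bestAcc <- -1; bestParams <- NULL

  evalCloud <- function(st, cl) {
    idx <- .resampleIdx(nPoints(cl), config$npoint)
    inp <- .normalizeInput(cl, idx)
    y <- cl@semantic[idx]
    tape <- tapeNew()
    fw <- .tpForward(st, inp$coords, inp$feats, tape)
    ce <- tpSoftmaxCE(fw$logits, y, rep(1, length(y)), tape)
    list(loss = ce$node$val, acc = mean((ce$probs[, 2] > 0.5) == y))
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(trainClouds))
    epochLoss <- 0
    nb <- 0L
    bs <- min(config$batch, length(trainClouds))
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    for (batch in batches) {
      acc <- NULL
      batchLoss <- 0
      for (ci in batch) {
        cl <- trainClouds[[ci]]
        idx <- .resampleIdx(nPoints(cl), config$npoint)
        inp <- .normalizeInput(cl, idx)
        y <- cl@semantic[idx]
        wCls <- classRebalanceWeights(y)
        tape <- tapeNew()
        fw <- .tpForward(state, inp$coords, inp$feats, tape)
        ce <- tpSoftmaxCE(fw$logits, y, wCls[y + 1L], tape)
        tpBackward(tape, ce$node)
        batchLoss <- batchLoss + ce$node$val
        gs <- lapply(paths, function(p) {
          g <- .gradForPath(fw$nodes, p)
          if (is.null(g)) 0 else g
        })
        acc <- if (is.null(acc)) gs
               else Map(function(a, g) a + g, acc, gs)
      }
      step <- step + 1L
      for (i in seq_along(paths)) {
        W <- .getPath(state, paths[[i]])
        g <- acc[[i]] / length(batch) + config$weightDecay * W
        mom[[i]] <- b1 * mom[[i]] + (1 - b1) * g
        vel[[i]] <- b2 * vel[[i]] + (1 - b2) * g * g
        mhat <- mom[[i]] / (1 - b1^step)
        vhat <- vel[[i]] / (1 - b2^step)
        state <- .setPath(state, paths[[i]],
                          W - config$lr * mhat / (sqrt(vhat) + epsA))
      }
      epochLoss <- epochLoss + batchLoss / length(batch)
      nb <- nb + 1L
    }
    ev <- lapply(valClouds, function(cl) evalCloud(state, cl))
    valLoss <- mean(vapply(ev, `[[`, numeric(1), "loss"))
    valAcc <- mean(vapply(ev, `[[`, numeric(1), "acc"))
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epochLoss / nb,
                                 val_loss = valLoss, val_acc = valAcc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f",
                      epoch, epochLoss / nb, valLoss, valAcc))
    if (valAcc > bestAcc) {
      bestAcc <- valAcc
      bestParams <- state[c("sa", "fp", "head")]
    }
    if (!is.null(stopValAcc) && valAcc >= stopValAcc) break
  }
  state[c("sa", "fp", "head")] <- bestParams
  state$trained <- TRUE
  state$log <- log
  state
}

#' Predict semantic labels for every point of a cloud
#'
#' Covers the cloud with resampled chunks of `npoint` points (a random
#' partition, the last chunk padded by repetition), runs the network on each
#' chunk, and combines per-point class probabilities by summation wherever a
#' point is covered more than once (a probability-weighted majority vote).
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param state a trained `"NetState"`.
#' @param npoint chunk size; defaults to the trained configuration's.
#' @param seed seed for the chunk partition.
#' @return Integer 0/1 labels, one per input point.
#' @export
predictCloud <- function(cloud, state, npoint = NULL, seed = 1L) {
  stopifnot(inherits(state, "NetState"))
  if (!isTRUE(state$trained)) stop("predictCloud: untrained network state")
  npoint <- npoint %||% state$config$npoint
  n <- nPoints(cloud)
  set.seed(seed)
  ord <- sample.int(n)
  nChunks <- max(1L, ceiling(n / npoint))
  votes <- matrix(0, n, 2)
  for (ch in seq_len(nChunks)) {
    idx <- ord[((ch - 1L) * npoint + 1L):min(ch * npoint, n)]
    if (length(idx) < npoint)
      idx <- c(idx, idx[sample.int(length(idx), npoint - length(idx),
                                   replace = TRUE)])
    inp <- .normalizeInput(cloud, idx)
    tape <- tapeNew()
    fw <- .tpForward(state, inp$coords, inp$feats, tape)
    L <- fw$logits$val
    m <- pmax(L[, 1], L[, 2])
    p <- exp(L - (m + log(exp(L[, 1] - m) + exp(L[, 2] - m))))
    rs <- rowsum(p, idx)             # accumulate duplicate coverage
    tgt <- as.integer(rownames(rs))
    votes[tgt, ] <- votes[tgt, , drop = FALSE] + rs
  }
  as.integer(votes[, 2] > votes[, 1])
}
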