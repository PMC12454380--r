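# Shared fixtures, all generated in code.

# three well-separated compact blobs (uniform in a ball, so every point sits
# in a uniformly dense core and the blob diameter is bounded by construction)
makeBlobs <- function(n = 200, radius = 0.25,
                      centers = rbind(c(0, 0), c(5, 0), c(0, 5)), seed = 42) {
  set.seed(seed)
  ball <- function(n, r) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    v * r * stats::runif(n)^(1 / 3)
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(ball(n, radius), 2, c(centers[i, ], 0), "+")))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n))
}

# dense flat unit grid in the z = 0 plane (1 cm x 1 cm, spacing 0.05)
makeGridPatch <- function(spacing = 0.05) {
  g <- seq(0, 1, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = 0))
  list(points = pts,
       normals = matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3))
}

# Fibonacci sphere of radius 1 (normals = positions)
makeSphere <- function(n = 5000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# small labeled cloud with both channels
makeTinyCloud <- function(n = 50, seed = 7) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n), n, 3)
  nrm <- matrix(stats::rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  sem <- as.integer(stats::runif(n) > 0.5)
  inst <- ifelse(sem == 1L, 1L + (seq_len(n) %% 2L), 0L)
  labeledCloud(pts, nrm, sem, inst)
}

# a tiny network configuration used across network tests
tinyNetConfig <- function(seed = 3L)
  netConfig(npoint = 32L, saPoints = c(8L, 4L),
            radii = list(c(0.3, 0.6), c(0.5, 1)),
            nsample = list(c(4L, 6L), c(4L, 6L)),
            mlps = list(c(8L, 8L), c(8L, 16L)),
            fpMlps = list(c(16L, 8L), c(16L, 16L)),
            headMlp = c(8L), seed = seed)

# brute-force k-th nearest-neighbour mean distance (oracle for estimateEps)
bruteEps <- function(pts, k) {
  d <- as.matrix(stats::dist(pts))
  # sort(row)[1] is the self-distance 0, so the k-th neighbour is entry k+1
  mean(apply(d, 1, function(r) sort(r)[k + 1L]))
}
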