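# A minimal reverse-mode automatic-differentiation tape over numeric
# matrices: just the operations the hierarchical point network needs
# (dense layers, elementwise nonlinearities, gather/segment pooling with
# argmax routing, broadcast products for attention maps, inverse-distance
# interpolation, and a fused weighted softmax cross-entropy). Nodes are
# environments appended to a tape in creation order; backward() walks the
# tape in reverse, accumulating gradients into nodes that need them.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

.tpNode <- function(tape, val, parents = list(), bw = NULL, req = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  nd$req <- if (is.null(req))
    any(vapply(parents, function(p) p$req, logical(1))) else req
  n <- tape$n + 1L
  if (n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

tpConst <- function(tape, val) .tpNode(tape, val, req = FALSE)
tpParam <- function(tape, val) .tpNode(tape, val, req = TRUE)

tpBackward <- function(tape, root) {
  root$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw) || !nd$req) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

tpMatmul <- function(a, b, tape) {
  v <- a$val %*% b$val
  .tpNode(tape, v, list(a, b), function(g)
    list(g %*% t(b$val), crossprod(a$val, g)))
}

# x (n x C) + bias (1 x C), broadcast over rows
tpAddBias <- function(x, b, tape) {
  v <- sweep(x$val, 2, as.vector(b$val), "+")
  .tpNode(tape, v, list(x, b), function(g)
    list(g, matrix(colSums(g), 1)))
}

tpAdd <- function(a, b, tape)
  .tpNode(tape, a$val + b$val, list(a, b), function(g) list(g, g))

tpRelu <- function(x, tape) {
  v <- pmax(x$val, 0)
  .tpNode(tape, v, list(x), function(g) list(g * (x$val > 0)))
}

tpSigmoid <- function(x, tape) {
  v <- 1 / (1 + exp(-x$val))
  .tpNode(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

# elementwise product of equal-shaped nodes
tpMul <- function(a, b, tape)
  .tpNode(tape, a$val * b$val, list(a, b), function(g)
    list(g * b$val, g * a$val))

# scale each row i of x (n x C) by scalar s[i] (n x 1)
tpScaleRows <- function(x, s, tape) {
  sv <- as.vector(s$val)
  .tpNode(tape, x$val * sv, list(x, s), function(g)
    list(g * sv, matrix(rowSums(g * x$val), ncol = 1)))
}

# scale rows of x by per-segment channel maps m (G x C); seg in 1..G
tpScaleSeg <- function(x, m, seg, tape) {
  mv <- m$val[seg, , drop = FALSE]
  .tpNode(tape, x$val * mv, list(x, m), function(g)
    list(g * mv, rowsum(g * x$val, seg)))
}

tpGather <- function(x, idx, tape) {
  .tpNode(tape, x$val[idx, , drop = FALSE], list(x), function(g) {
    z <- matrix(0, nrow(x$val), ncol(x$val))
    rs <- rowsum(g, idx)
    z[as.integer(rownames(rs)), ] <- rs
    list(z)
  })
}

# per-segment max pooling; routes gradient to the argmax rows
tpSegMax <- function(x, seg, G, tape) {
  sm <- seg_max_cpp(x$val, as.integer(seg), as.integer(G))
  arg <- sm$argmax
  C <- ncol(x$val)
  .tpNode(tape, sm$max, list(x), function(g) {
    z <- matrix(0, nrow(x$val), C)
    z[cbind(as.vector(arg), rep(seq_len(C), each = G))] <- as.vector(g)
    list(z)
  })
}

tpSegMean <- function(x, seg, G, tape) {
  cnt <- as.vector(rowsum(rep(1, nrow(x$val)), seg))
  v <- rowsum(x$val, seg) / cnt
  .tpNode(tape, v, list(x), function(g)
    list((g / cnt)[seg, , drop = FALSE]))
}

# per-row mean / max over channels -> n x 1
tpRowMean <- function(x, tape) {
  C <- ncol(x$val)
  .tpNode(tape, matrix(rowMeans(x$val), ncol = 1), list(x), function(g)
    list(matrix(as.vector(g) / C, nrow(x$val), C)))
}

tpRowMax <- function(x, tape) {
  j <- max.col(x$val, ties.method = "first")
  n <- nrow(x$val)
  v <- matrix(x$val[cbind(seq_len(n), j)], ncol = 1)
  .tpNode(tape, v, list(x), function(g) {
    z <- matrix(0, n, ncol(x$val))
    z[cbind(seq_len(n), j)] <- as.vector(g)
    list(z)
  })
}

tpCbind <- function(nodes, tape) {
  vals <- lapply(nodes, function(nd) nd$val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  .tpNode(tape, do.call(cbind, vals), nodes, function(g)
    lapply(seq_along(nodes), function(i)
      g[, starts[i]:ends[i], drop = FALSE]))
}

# inverse-distance interpolation: out[i, ] = sum_j w[i, j] * x[idx[i, j], ]
tpInterp <- function(x, idx, w, tape) {
  K <- ncol(idx)
  v <- 0
  for (j in seq_len(K)) v <- v + x$val[idx[, j], , drop = FALSE] * w[, j]
  .tpNode(tape, v, list(x), function(g) {
    z <- matrix(0, nrow(x$val), ncol(x$val))
    for (j in seq_len(K)) {
      rs <- rowsum(g * w[, j], idx[, j])
      tgt <- as.integer(rownames(rs))
      z[tgt, ] <- z[tgt, , drop = FALSE] + rs
    }
    list(z)
  })
}

# fused weighted softmax cross-entropy over 2 classes.
# logits: n x 2 node; y: 0/1 vector; w: per-point weights (mean ~ 1).
# Returns list(node = scalar loss node, probs = n x 2 matrix).
tpSoftmaxCE <- function(logits, y, w, tape) {
  L <- logits$val
  m <- pmax(L[, 1], L[, 2])
  lse <- m + log(exp(L[, 1] - m) + exp(L[, 2] - m))
  p <- exp(L - lse)
  n <- length(y)
  picked <- L[cbind(seq_len(n), y + 1L)]
  loss <- sum(w * (lse - picked)) / n
  node <- .tpNode(tape, loss, list(logits), function(g) {
    oneHot <- cbind(1 - y, y)
    list(g * (p - oneHot) * w / n)
  })
  list(node = node, probs = p)
}
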