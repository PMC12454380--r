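# O(n^3) Hungarian algorithm (potentials / shortest augmenting path form)
# for the rectangular linear assignment problem. Written here because no
# assignment solver ships with the installed stack; validated in the test
# suite against exhaustive enumeration on small instances.

#' Solve the linear assignment problem
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns.
#' Rectangular matrices are padded internally with zeros; every row (or
#' every column, whichever is fewer) is assigned.
#'
#' @param cost numeric cost matrix.
#' @return A list with integer vectors `row` and `col` (matched pairs,
#'   real rows/columns only) and the total `cost` over those pairs.
#' @examples
#' solveAssignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3))
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  INF <- sum(abs(a)) + 1

  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  colOf <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) colOf[p[j + 1L]] <- j
  keep <- which(seq_len(n) <= nr & colOf <= nc & colOf > 0L)
  keep <- keep[keep <= nr]
  rows <- keep[colOf[keep] <= nc]
  list(row = rows, col = colOf[rows],
       cost = sum(cost[cbind(rows, colOf[rows])]))
}
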