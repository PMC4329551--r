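# Hungarian (Kuhn-Munkres) assignment via the shortest-augmenting-path
# formulation with row/column potentials; O(n^2 m) for an n x m cost
# matrix with n <= m. Verified against brute-force permutation search in
# the test suite.

#' Minimum-cost injective assignment of rows to columns
#'
#' @param cost numeric matrix, rows <= columns, finite entries.
#' @return list: `assignment` (column index per row), `cost` (total).
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("more rows than columns; assignment must be injective")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n)
  v <- numeric(m + 1L)       # v[1] is the dummy column 0
  p <- integer(m + 1L)       # p[j + 1] = row matched to column j (0 = none)
  way <- integer(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
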