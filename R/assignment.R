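# Linear assignment by the Hungarian algorithm with potentials
# (O(n^3)); used for the optimal split matchings in the generalized
# tree distances.  Kept dependency-free on purpose: the tests compare
# it against a brute-force permutation oracle.

#' Minimum-cost linear assignment
#'
#' @param cost numeric matrix with `nrow(cost) <= ncol(cost)`; entry
#'   `[i, j]` is the cost of assigning row `i` to column `j`.
#' @return list with `assignment` (column chosen for each row) and
#'   `cost` (total).
#' @export
solve_assignment <- function(cost) {
  wc_assert(is.matrix(cost) && all(is.finite(cost)),
            "cost must be a finite numeric matrix")
  n <- nrow(cost)
  m <- ncol(cost)
  wc_assert(n <= m, "need nrow <= ncol (pad the matrix)")
  if (n == 0) return(list(assignment = integer(0), cost = 0))
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j + 1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- !used[jj + 1]
      cur <- cost[i0, ] - u[i0 + 1] - v[jj + 1]
      upd <- free & cur < minv
      minv[upd] <- cur[upd]
      way[jj[upd] + 1] <- j0
      fidx <- jj[free]
      j1 <- fidx[which.min(minv[fidx])]
      delta <- minv[j1]
      usedj <- which(used) - 1                # column ids incl. dummy 0
      u[p[usedj + 1] + 1] <- u[p[usedj + 1] + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[!used[jj + 1]] <- minv[!used[jj + 1]] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

# maximum-score matching of the rows/columns of a (possibly
# rectangular) score matrix, unmatched entries scoring 0
max_score_matching <- function(score) {
  if (length(score) == 0 || nrow(score) == 0 || ncol(score) == 0) return(0)
  n <- max(nrow(score), ncol(score))
  s <- matrix(0, n, n)
  s[seq_len(nrow(score)), seq_len(ncol(score))] <- score
  res <- solve_assignment(max(s) - s)
  n * max(s) - res$cost
}
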