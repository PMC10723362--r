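# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: splits come from phangorn, matchings
# from exhaustive permutation, and test statistics from enumeration.

# all permutations of a vector, recursive list construction (distinct
# from the package's iterative generator)
perm_list <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_list(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# non-trivial splits of a tree as a logical matrix over sorted labels,
# canonical side excluding the first label (via phangorn)
oracle_splits <- function(tree) {
  m <- as.matrix(phangorn::as.splits(ape::unroot(tree)))
  labs <- sort(colnames(m))
  m <- m[, labs, drop = FALSE]
  n <- ncol(m)
  sz <- rowSums(m)
  m <- m[sz >= 2 & sz <= n - 2, , drop = FALSE]
  flip <- m[, 1] == 1
  m[flip, ] <- 1 - m[flip, , drop = FALSE]
  m <- unique(m, MARGIN = 1)
  m == 1
}

oracle_rf <- function(t1, t2) phangorn::RF.dist(t1, t2)

# scalar entropy / mutual clustering information (bits) for two splits
oracle_entropy <- function(x) {
  n <- length(x); a <- sum(x)
  p <- c(a, n - a) / n
  -sum(p * log2(p))
}

oracle_mci <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xv in c(TRUE, FALSE)) for (yv in c(TRUE, FALSE)) {
    nij <- sum(x == xv & y == yv)
    ri <- sum(x == xv); cj <- sum(y == yv)
    if (nij > 0) total <- total + (nij / n) * log2(n * nij / (ri * cj))
  }
  total
}

oracle_jaccard_score <- function(x, y, k) {
  jac <- function(a, b) sum(a & b) / sum(a | b)
  max(min(jac(x, y), jac(!x, !y)), min(jac(x, !y), jac(!x, y)))^k
}

# exhaustive maximum matching of a rectangular score matrix
oracle_max_matching <- function(score) {
  n1 <- nrow(score); n2 <- ncol(score)
  if (n1 == 0 || n2 == 0) return(0)
  if (n1 <= n2) {
    best <- -Inf
    for (p in perm_list(seq_len(n2))) {
      v <- sum(score[cbind(seq_len(n1), p[seq_len(n1)])])
      best <- max(best, v)
    }
    best
  } else oracle_max_matching(t(score))
}

oracle_cid <- function(t1, t2) {
  m1 <- oracle_splits(t1); m2 <- oracle_splits(t2)
  h1 <- sum(apply(m1, 1, oracle_entropy))
  h2 <- sum(apply(m2, 1, oracle_entropy))
  if (nrow(m1) == 0 || nrow(m2) == 0) return(h1 + h2)
  sc <- matrix(0, nrow(m1), nrow(m2))
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2)))
    sc[i, j] <- oracle_mci(m1[i, ], m2[j, ])
  h1 + h2 - 2 * oracle_max_matching(sc)
}

oracle_jrf <- function(t1, t2, k = 1) {
  m1 <- oracle_splits(t1); m2 <- oracle_splits(t2)
  if (nrow(m1) == 0 || nrow(m2) == 0) return(nrow(m1) + nrow(m2))
  sc <- matrix(0, nrow(m1), nrow(m2))
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2)))
    sc[i, j] <- oracle_jaccard_score(m1[i, ], m2[j, ], k)
  nrow(m1) + nrow(m2) - 2 * oracle_max_matching(sc)
}

# exact one-sided rank-sum p-value by full label permutation
oracle_wilcox_less <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  groups <- utils::combn(length(pooled), m)
  mean(apply(groups, 2, u_of) <= u_obs + 1e-9)
}

# exact two-sided Spearman p by enumeration over y-rank permutations
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  rhos <- vapply(perm_list(ry), function(p) cor(rx, p), 0)
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# every labeled unrooted binary topology on the given labels
# (enumerate rooted trees on labels[-1], then attach labels[1])
enumerate_topologies <- function(labels) {
  insert_all <- function(tr, lb) {
    res <- list(list(tr, lb))
    if (is.list(tr)) {
      for (l1 in insert_all(tr[[1]], lb))
        res <- c(res, list(list(l1, tr[[2]])))
      for (r1 in insert_all(tr[[2]], lb))
        res <- c(res, list(list(tr[[1]], r1)))
    }
    res
  }
  to_newick <- function(tr) {
    if (is.character(tr)) return(tr)
    sprintf("(%s,%s)", to_newick(tr[[1]]), to_newick(tr[[2]]))
  }
  trees <- list(labels[2])
  for (lb in labels[-c(1, 2)]) {
    out <- list()
    for (tr in trees) out <- c(out, insert_all(tr, lb))
    trees <- out
  }
  lapply(trees, function(tr)
    ape::unroot(ape::read.tree(
      text = sprintf("(%s,%s);", labels[1], to_newick(tr)))))
}

# tiny codon-alignment fixture builder
make_aln <- function(...) {
  s <- c(...)
  codon_alignment(s)
}
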