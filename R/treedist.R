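# Split-based tree distances (RF, Jaccard-RF, clustering information),
# uniform random topologies, and the random-pair permutation test with
# null-mean normalization.

#' Non-trivial splits of an (un)rooted tree
#'
#' Trees are unrooted before split extraction.  Each split is stored as
#' the logical membership vector of the side *not* containing the
#' alphabetically first leaf, over the sorted leaf labels.
#'
#' @param tree a `phylo`.
#' @return list with `labels` (sorted leaf labels) and `mat` (logical
#'   splits x leaves matrix, zero rows for a star tree).
#' @export
tree_splits <- function(tree) {
  wc_assert(inherits(tree, "phylo"), "not a phylo tree",
            "wolclock_input_error")
  labels <- sort(tree$tip.label)
  n <- length(labels)
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  nt <- length(tr$tip.label)
  tip_id <- match(tr$tip.label, labels)
  po <- ape::reorder.phylo(tr, "postorder")
  below <- matrix(FALSE, nt + tr$Nnode, n)
  below[cbind(seq_len(nt), tip_id)] <- TRUE
  for (k in seq_len(nrow(po$edge)))
    below[po$edge[k, 1], ] <- below[po$edge[k, 1], ] | below[po$edge[k, 2], ]
  internal_children <- po$edge[po$edge[, 2] > nt, 2]
  mat <- below[internal_children, , drop = FALSE]
  sz <- rowSums(mat)
  mat <- mat[sz >= 2 & (n - sz) >= 2, , drop = FALSE]
  # canonical orientation: exclude the first label
  flip <- mat[, 1]
  mat[flip, ] <- !mat[flip, , drop = FALSE]
  mat <- unique(mat)
  list(labels = labels, mat = mat)
}

check_leafsets <- function(t1, t2) {
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  if (!identical(s1$labels, s2$labels))
    wc_stop("trees must share an identical leaf set", "wolclock_input_error")
  list(s1 = s1, s2 = s2, n = length(s1$labels))
}

split_keys <- function(mat) apply(mat, 1, function(r) paste(as.integer(r),
                                                            collapse = ""))

#' Robinson-Foulds distance
#'
#' Number of non-trivial splits present in exactly one of the two trees.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer distance in `[0, 2(n - 3)]`.
#' @export
rf_distance <- function(t1, t2) {
  s <- check_leafsets(t1, t2)
  k1 <- split_keys(s$s1$mat)
  k2 <- split_keys(s$s2$mat)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Jaccard-Robinson-Foulds distance
#'
#' Generalized RF distance: splits of the two trees are matched by
#' solving a linear assignment problem on the pairwise split similarity
#' `J^k`, where `J` is the Jaccard index of the best side
#' correspondence (`max` over the two orientations of the `min` of the
#' two sides' Jaccard indices) and `k` is the concession exponent.  The
#' distance is `m1 + m2 - 2 * max matching score`; identical trees score
#' 0, and as `k -> Inf` the distance approaches RF.
#'
#' @inheritParams rf_distance
#' @param k concession exponent, `> 0`.
#' @return non-negative real distance.
#' @export
jrf_distance <- function(t1, t2, k = 1) {
  wc_assert(k > 0, "k must be > 0")
  s <- check_leafsets(t1, t2)
  m1 <- s$s1$mat; m2 <- s$s2$mat
  if (nrow(m1) == 0 && nrow(m2) == 0) return(0)
  if (nrow(m1) == 0 || nrow(m2) == 0) return(nrow(m1) + nrow(m2))
  n <- s$n
  sc <- jrf_score_matrix(m1, m2, n, k)
  nrow(m1) + nrow(m2) - 2 * max_score_matching(sc)
}

jrf_score_matrix <- function(m1, m2, n, k) {
  inter <- m1 %*% t(m2)
  a <- rowSums(m1); b <- rowSums(m2)
  A <- matrix(a, nrow(m1), nrow(m2))
  B <- matrix(b, nrow(m1), nrow(m2), byrow = TRUE)
  jXY <- inter / (A + B - inter)
  jXcYc <- (n - A - B + inter) / (n - inter)
  jXYc <- (A - inter) / (n - B + inter)
  jXcY <- (B - inter) / (n - A + inter)
  pmax(pmin(jXY, jXcYc), pmin(jXYc, jXcY))^k
}

#' Clustering-information distance (bits)
#'
#' Each split is a two-cluster partition of the leaves; its entropy and
#' the mutual clustering information of split pairs are measured in
#' bits.  Splits are matched by a linear assignment maximizing summed
#' mutual information; the distance is
#' `H(t1) + H(t2) - 2 * MCI_max`, zero for identical split sets.
#'
#' @inheritParams rf_distance
#' @return non-negative real distance in bits.
#' @export
cid_distance <- function(t1, t2) {
  s <- check_leafsets(t1, t2)
  wc_assert(s$n >= 4, "need >= 4 leaves")
  m1 <- s$s1$mat; m2 <- s$s2$mat
  h1 <- sum(split_entropy(m1, s$n))
  h2 <- sum(split_entropy(m2, s$n))
  if (nrow(m1) == 0 || nrow(m2) == 0) return(h1 + h2)
  mci <- mci_matrix(m1, m2, s$n)
  h1 + h2 - 2 * max_score_matching(mci)
}

split_entropy <- function(mat, n) {
  if (nrow(mat) == 0) return(numeric(0))
  a <- rowSums(mat)
  p <- a / n
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

mci_matrix <- function(m1, m2, n) {
  inter <- m1 %*% t(m2)
  a <- rowSums(m1); b <- rowSums(m2)
  A <- matrix(a, nrow(m1), nrow(m2))
  B <- matrix(b, nrow(m1), nrow(m2), byrow = TRUE)
  term <- function(nij, ri, cj) {
    out <- (nij / n) * log2((n * nij) / (ri * cj))
    out[nij == 0] <- 0
    out
  }
  term(inter, A, B) + term(A - inter, A, n - B) +
    term(B - inter, n - A, B) + term(n - A - B + inter, n - A, n - B)
}

#' Uniform random binary tree topology
#'
#' Builds a topology by sequential pair joining with a uniform choice of
#' the pair at each step (coalescent-style), which makes the three
#' 4-leaf unrooted topologies equiprobable.
#'
#' @param n_leaves number of leaves, `>= 4`.
#' @param seed optional integer seed.
#' @param labels leaf labels (default `t1..tn`).
#' @return an unrooted binary `phylo` without branch lengths.
#' @export
random_tree <- function(n_leaves, seed = NULL, labels = NULL) {
  wc_assert(n_leaves >= 4, "need >= 4 leaves")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  wc_assert(length(labels) == n_leaves, "labels length mismatch")
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    ij <- sample.int(length(nodes), 2)
    merged <- paste0("(", nodes[[ij[1]]], ",", nodes[[ij[2]]], ")")
    nodes <- c(nodes[-ij], list(merged))
  }
  ape::unroot(ape::read.tree(text = paste0(nodes[[1]], ";")))
}

#' Topological similarity test against a random-tree null
#'
#' The observed distance is divided by the mean distance of `n_random`
#' independent random tree pairs on the same leaf count, and the
#' p-value is the proportion of null pairs with distance strictly below
#' the observed one (testing whether the two trees are more similar
#' than chance).
#'
#' @inheritParams rf_distance
#' @param metric `"CID"`, `"JRF"` or `"RF"`.
#' @param n_random number of random tree pairs for the null.
#' @param seed optional integer seed.
#' @param k concession exponent for JRF.
#' @param plus_one if `TRUE`, report `(b + 1) / (n_random + 1)` instead
#'   of the raw proportion, avoiding p = 0.
#' @return a `tree_distance_result` list: `metric`, `raw`,
#'   `normalized`, `p_value`, `null_mean`, `n_random`, `seed`.
#' @export
similarity_test <- function(t1, t2, metric = c("CID", "JRF", "RF"),
                            n_random = 10000, seed = NULL, k = 1,
                            plus_one = FALSE) {
  metric <- match.arg(metric)
  wc_assert(n_random >= 1, "n_random must be >= 1")
  fun <- switch(metric, CID = cid_distance,
                JRF = function(a, b) jrf_distance(a, b, k = k),
                RF = rf_distance)
  obs <- fun(t1, t2)
  n <- length(t1$tip.label)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_random), function(i)
    fun(random_tree(n), random_tree(n)), 0)
  nm <- mean(null)
  if (nm == 0)
    wc_stop("degenerate null: mean random-pair distance is 0",
            "wolclock_degenerate_error")
  b <- sum(null < obs)
  structure(list(metric = metric, raw = obs, normalized = obs / nm,
                 p_value = if (plus_one) (b + 1) / (n_random + 1)
                           else b / n_random,
                 null_mean = nm, n_random = n_random, seed = seed),
            class = "tree_distance_result")
}

#' @export
print.tree_distance_result <- function(x, ...) {
  cat(sprintf("%s distance %.4g (normalized %.3f), p = %.4g (%d random pairs)\n",
              x$metric, x$raw, x$normalized, x$p_value, x$n_random))
  invisible(x)
}
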