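# Scaling relative-chronogram posterior samples (root age = 1) to
# absolute time with sampled substitution rates, summarizing node ages,
# and collapsing weakly supported nodes into polytomies.

# node ages of an ultrametric tree (named by internal node number)
node_ages <- function(tree) {
  ape::branching.times(tree)
}

# relative depth of every tip from the root; ultrametry check helper
tip_depths <- function(tree) {
  nt <- length(tree$tip.label)
  dm <- ape::node.depth.edgelength(tree)
  dm[seq_len(nt)]
}

validate_relative_tree <- function(tree, tol = 1e-6) {
  wc_assert(inherits(tree, "phylo"), "not a phylo tree",
            "wolclock_input_error")
  wc_assert(!is.null(tree$edge.length), "tree has no branch lengths",
            "wolclock_input_error")
  d <- tip_depths(tree)
  if (diff(range(d)) > tol * max(d))
    wc_stop("relative tree is not ultrametric within tolerance",
            "wolclock_validation_error")
  if (abs(max(d) - 1) > 1e-3)
    wc_stop("relative tree root age must be 1", "wolclock_validation_error")
  if (any(tree$edge.length < -tol))
    wc_stop("negative branch length: child older than parent",
            "wolclock_validation_error")
  invisible(tree)
}

#' Read relative-chronogram posterior samples
#'
#' @param trees_path Newick file, one relative chronogram per line (root
#'   age 1; node labels, if present, read as posterior supports).
#' @param rates_path TSV with one row per tree and a column `m3`: the
#'   third-position substitutions per site per unit relative time for
#'   that posterior draw.
#' @return list of `chronogram_sample` objects (`tree`, `m3`).
#' @export
read_posterior <- function(trees_path, rates_path) {
  trees <- ape::read.tree(trees_path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  rates <- read.delim(rates_path, stringsAsFactors = FALSE)
  wc_assert("m3" %in% names(rates), "rates table needs an m3 column",
            "wolclock_input_error")
  if (length(trees) != nrow(rates))
    wc_stop(sprintf("%d trees but %d rate rows", length(trees), nrow(rates)),
            "wolclock_input_error")
  wc_assert(all(rates$m3 > 0), "m3 must be > 0", "wolclock_validation_error")
  lv <- sort(trees[[1]]$tip.label)
  out <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    wc_assert(identical(sort(trees[[i]]$tip.label), lv),
              "posterior trees must share one leaf set",
              "wolclock_input_error")
    validate_relative_tree(trees[[i]])
    out[[i]] <- structure(list(tree = trees[[i]], m3 = rates$m3[i]),
                          class = "chronogram_sample")
  }
  out
}

# clade tip-set keys for internal nodes, used to match nodes across
# posterior samples sharing a topology
clade_keys <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(desc[(nt + 1):(nt + nn)],
         function(x) paste(sort(x), collapse = "|"), "")
}

#' Scale relative chronogram samples to absolute time
#'
#' For posterior sample `i` (relative ages and third-position rate
#' multiplier `m3_i`) and rate draw `r_j` from the prior, the absolute
#' age of a node is `relative age x m3_i / r_j`.  Rate draws are crossed
#' with posterior samples; point estimates are posterior medians and
#' credible intervals equal-tailed percentiles over the full grid.
#'
#' @param samples list of `chronogram_sample` from [read_posterior()] or
#'   [sim_posterior()].
#' @param prior a [make_prior()] object, or a single positive number for
#'   a point-mass rate.
#' @param draws_per_sample rate draws crossed with each posterior
#'   sample.
#' @param seed optional integer seed.
#' @param level credible level for the equal-tailed interval.
#' @return an `absolute_chronogram` list: `topology` (first sample's
#'   tree), `nodes` (data frame: node, clade, age, age_low, age_high,
#'   support), `n_samples`, `draws_per_sample`.
#' @export
scale_to_absolute <- function(samples, prior, draws_per_sample = 100,
                              seed = NULL, level = 0.95) {
  wc_assert(length(samples) >= 1, "need >= 1 posterior sample",
            "wolclock_input_error")
  wc_assert(draws_per_sample >= 1, "draws_per_sample must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  point_mass <- is.numeric(prior) && length(prior) == 1
  if (!point_mass)
    wc_assert(inherits(prior, "rate_prior"),
              "prior must be a rate_prior or a single rate",
              "wolclock_config_error")
  ref <- samples[[1]]$tree
  keys <- clade_keys(ref)
  nt <- length(ref$tip.label)
  rel <- matrix(NA_real_, nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, NULL))
  for (i in seq_along(samples)) {
    tr <- samples[[i]]$tree
    ki <- clade_keys(tr)
    if (!setequal(ki, keys))
      wc_stop(paste("posterior samples disagree in topology;",
                    "build a consensus upstream before scaling"),
              "wolclock_input_error")
    ages <- node_ages(tr)
    rel[ki, i] <- ages[as.character(nt + seq_along(ki))]
  }
  m3 <- vapply(samples, function(s) s$m3, 0)
  ages_all <- matrix(NA_real_, nrow = length(keys),
                     ncol = length(samples) * draws_per_sample)
  for (i in seq_along(samples)) {
    r <- if (point_mass) rep(prior, draws_per_sample)
         else sample_prior_unseeded(prior, draws_per_sample)
    cols <- (i - 1) * draws_per_sample + seq_len(draws_per_sample)
    ages_all[, cols] <- outer(rel[, i] * m3[i], 1 / r)
  }
  a <- (1 - level) / 2
  support <- rep(NA_real_, length(keys))
  if (!is.null(ref$node.label)) {
    s <- suppressWarnings(as.numeric(ref$node.label))
    support <- s
  }
  nodes <- data.frame(
    node = nt + seq_along(keys),
    clade = keys,
    age = apply(ages_all, 1, median),
    age_low = apply(ages_all, 1, quantile, probs = a, names = FALSE),
    age_high = apply(ages_all, 1, quantile, probs = 1 - a, names = FALSE),
    support = support)
  structure(list(topology = ref, nodes = nodes,
                 n_samples = length(samples),
                 draws_per_sample = draws_per_sample),
            class = "absolute_chronogram")
}

# draws from a prior without touching the seed (used inside seeded loops)
sample_prior_unseeded <- function(prior, n) sample_prior(prior, n, seed = NULL)

#' @export
print.absolute_chronogram <- function(x, ...) {
  cat(sprintf("absolute_chronogram: %d tips, %d posterior samples x %d rate draws\n",
              length(x$topology$tip.label), x$n_samples, x$draws_per_sample))
  root <- x$nodes[1, ]
  cat(sprintf("  crown age %.4g years (%.4g-%.4g)\n",
              root$age, root$age_low, root$age_high))
  invisible(x)
}

#' Collapse weakly supported nodes into polytomies
#'
#' Contracts every internal edge whose child node carries posterior
#' support below `threshold` (root support is not required).  The leaf
#' set is unchanged.
#'
#' @param tree a `phylo` with numeric node labels holding posterior
#'   supports in `[0, 1]` for all non-root internal nodes.
#' @param threshold support below which a node is collapsed.
#' @return the collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 0.95) {
  wc_assert(inherits(tree, "phylo"), "not a phylo tree",
            "wolclock_input_error")
  nt <- length(tree$tip.label)
  root <- nt + 1L
  supp <- suppressWarnings(as.numeric(tree$node.label))
  internal <- nt + seq_len(tree$Nnode)
  nonroot <- setdiff(internal, root)
  if (length(nonroot) && (is.null(tree$node.label) ||
                          any(is.na(supp[nonroot - nt]))))
    wc_stop("missing numeric support on an internal node",
            "wolclock_validation_error")
  drop <- nonroot[supp[nonroot - nt] < threshold]
  if (!length(drop)) return(tree)
  edge <- tree$edge
  el <- tree$edge.length
  # walk up through dropped ancestors to the nearest kept node,
  # accumulating the contracted edge lengths so node depths are kept
  resolve <- function(v) {
    extra <- 0
    while (v %in% drop) {
      k <- which(edge[, 2] == v)
      if (!is.null(el)) extra <- extra + el[k]
      v <- edge[k, 1]
    }
    list(node = v, extra = extra)
  }
  keep_edge <- !(edge[, 2] %in% drop)
  new_edge <- edge[keep_edge, , drop = FALSE]
  new_el <- if (!is.null(el)) el[keep_edge] else NULL
  for (k in seq_len(nrow(new_edge))) {
    r <- resolve(new_edge[k, 1])
    new_edge[k, 1] <- r$node
    if (!is.null(new_el)) new_el[k] <- new_el[k] + r$extra
  }
  kept_internal <- sort(unique(new_edge[, 1]))
  remap <- setNames(seq_along(kept_internal) + nt, kept_internal)
  out <- tree
  out$edge <- cbind(remap[as.character(new_edge[, 1])],
                    ifelse(new_edge[, 2] <= nt, new_edge[, 2],
                           remap[as.character(new_edge[, 2])]))
  dimnames(out$edge) <- NULL
  storage.mode(out$edge) <- "integer"
  if (!is.null(new_el)) out$edge.length <- new_el
  out$Nnode <- length(kept_internal)
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[kept_internal - nt]
  attr(out, "order") <- NULL
  out
}
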