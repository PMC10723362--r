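# Non-sequence simulators: birth-death trees, ideal-helix structures,
# hatch tables with an incompatibility effect, and fake relative
# chronogram posteriors.

#' Simulate a complete-sampling birth-death tree with n extant tips
#'
#' Forward simulation at per-lineage birth and death rates; the process
#' restarts on extinction and stops the first time `n_tips` lineages
#' are extant, with the present placed just before the next event
#' (memoryless `Exp(n (birth + death))` epoch).  Extinct lineages are
#' pruned.  Under pure birth the expected root age is
#' `sum_{k=2..n} 1 / (birth * k)`.
#'
#' @param n_tips number of extant tips (`>= 2`).
#' @param birth per-lineage speciation rate, `> death`.
#' @param death per-lineage extinction rate, `>= 0`.
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
sim_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  wc_assert(n_tips >= 2, "need >= 2 tips")
  wc_assert(birth > death && death >= 0, "need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    born <- c(0)            # per lineage id: birth time
    parent <- c(NA_integer_)
    kids <- list(NULL)
    endt <- c(NA_real_)     # split or death time
    alive <- 1L
    t <- 0
    ok <- FALSE
    while (TRUE) {
      k <- length(alive)
      if (k == 0) break
      if (k == n_tips) {
        t_present <- t + rexp(1, k * (birth + death))
        ok <- TRUE
        break
      }
      t <- t + rexp(1, k * (birth + death))
      who <- alive[sample.int(k, 1)]
      if (runif(1) < birth / (birth + death)) {
        id1 <- length(born) + 1L; id2 <- id1 + 1L
        born <- c(born, t, t)
        parent <- c(parent, who, who)
        kids[[who]] <- c(id1, id2)
        kids[id1] <- list(NULL); kids[id2] <- list(NULL)
        endt[who] <- t
        endt <- c(endt, NA_real_, NA_real_)
        alive <- c(setdiff(alive, who), id1, id2)
      } else {
        endt[who] <- t
        alive <- setdiff(alive, who)
      }
    }
    if (ok) break
  }
  tip_no <- 0L
  render <- function(id) {
    end <- if (id %in% alive) t_present else endt[id]
    if (is.null(kids[[id]])) {
      if (!(id %in% alive)) return(NULL)            # extinct tip
      tip_no <<- tip_no + 1L
      return(sprintf("t%d:%.10g", tip_no, end - born[id]))
    }
    sub <- Filter(Negate(is.null), lapply(kids[[id]], render))
    if (length(sub) == 0) return(NULL)
    if (length(sub) == 1) {                         # pass-through branch
      # child string carries its own length; extend by this segment
      add_len <- endt[id] - born[id]
      parts <- sub[[1]]
      colon <- regexpr(":[^:]*$", parts)
      len <- as.numeric(substring(parts, colon + 1))
      return(paste0(substring(parts, 1, colon - 1),
                    sprintf(":%.10g", len + add_len)))
    }
    sprintf("(%s):%.10g", paste(unlist(sub), collapse = ","),
            end - born[id])
  }
  txt <- render(1L)
  # strip the root branch length and parse
  txt <- sub(":[0-9.eE+-]*$", "", txt)
  ape::read.tree(text = paste0(txt, ";"))
}

#' Ideal alpha-helix toy structure
#'
#' Residue `i` sits at angle `100 * (i - 1)` degrees on a cylinder of
#' radius 2.3 Angstrom with a rise of 1.5 Angstrom per residue, giving
#' the canonical ~3.8 Angstrom C-alpha spacing.  Window membership has
#' a closed form, which makes it the fixture for the spherical-window
#' code.
#'
#' @param n_residues number of residues (`>= 2`).
#' @param confidence per-residue confidence score stored with the
#'   model (recycled).
#' @return a `structure_model`.
#' @export
sim_helix <- function(n_residues, confidence = 90) {
  wc_assert(n_residues >= 2, "need >= 2 residues")
  i <- seq_len(n_residues) - 1
  theta <- i * 100 * pi / 180
  df <- data.frame(resno = seq_len(n_residues), aa = "A",
                   x = 2.3 * cos(theta), y = 2.3 * sin(theta),
                   z = 1.5 * i,
                   confidence = rep_len(confidence, n_residues))
  class(df) <- c("structure_model", "data.frame")
  df
}

#' Write a C-alpha structure model as a PDB file
#'
#' @param structure a `structure_model`.
#' @param path output file.
#' @param chain chain identifier.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, chain = "A") {
  aa1to3 <- setNames(names(AA3TO1), AA3TO1)
  lines <- vapply(seq_len(nrow(structure)), function(i) {
    r <- structure[i, ]
    res3 <- if (r$aa %in% names(aa1to3)) aa1to3[[r$aa]] else "UNK"
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, res3, chain, r$resno, r$x, r$y, r$z, 1.0, r$confidence)
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Simulate an egg-hatch table with a cytoplasmic-incompatibility effect
#'
#' Each cross runs for 5 days; daily egg counts are uniform integers in
#' `[eggs_low, eggs_high]` and hatch counts are binomial with a
#' cross-level hatch probability drawn from a beta distribution with
#' the group mean and concentration (between-cross overdispersion).
#' The defaults mirror the assay design the package targets: IC mean
#' hatch 0.34 (N = 14) vs CC mean 0.89 (N = 18).
#'
#' @param n_ic,n_cc number of incompatible / compatible crosses.
#' @param p_ic,p_cc group mean hatch probabilities.
#' @param eggs_low,eggs_high daily egg count range.
#' @param seed optional integer seed.
#' @param conc_ic,conc_cc beta concentrations; the defaults match
#'   between-cross SDs of about 0.21 (IC) and 0.11 (CC).
#' @return a hatch table data frame (see [read_hatch_table()]).
#' @export
sim_hatch <- function(n_ic = 14, n_cc = 18, p_ic = 0.34, p_cc = 0.89,
                      eggs_low = 5, eggs_high = 15, seed = NULL,
                      conc_ic = 4.1, conc_cc = 7.1) {
  wc_assert(p_ic >= 0 && p_ic <= 1 && p_cc >= 0 && p_cc <= 1,
            "probabilities must be in [0, 1]")
  wc_assert(eggs_low >= 0 && eggs_high >= eggs_low, "invalid egg range")
  if (!is.null(seed)) set.seed(seed)
  one_group <- function(n, p, conc, type, offset) {
    rows <- lapply(seq_len(n), function(i) {
      pc <- if (p %in% c(0, 1)) p else rbeta(1, p * conc, (1 - p) * conc)
      eggs <- sample(eggs_low:eggs_high, 5, replace = TRUE)
      data.frame(cross_id = sprintf("%s%02d", type, i + offset),
                 type = type, day = 1:5, eggs = eggs,
                 hatched = rbinom(5, eggs, pc))
    })
    do.call(rbind, rows)
  }
  rbind(one_group(n_ic, p_ic, conc_ic, "IC", 0),
        one_group(n_cc, p_cc, conc_cc, "CC", 0))
}

#' Simulate relative-chronogram posterior samples
#'
#' Node ages of the (root-1-normalized) input tree are perturbed
#' multiplicatively by lognormal noise, constrained to stay younger
#' than their parent, and renormalized to root age 1; each sample
#' carries a lognormal third-position rate multiplier with mean
#' `m3_mean`.
#'
#' @param true_tree ultrametric `phylo` (any root age; rescaled to 1).
#' @param n_samples number of posterior draws.
#' @param age_jitter lognormal sigma of the age perturbation
#'   (0 = identical samples).
#' @param m3_mean mean third-position substitutions per site per unit
#'   relative time.
#' @param m3_jitter lognormal sigma of the multiplier.
#' @param seed optional integer seed.
#' @param dir if given, writes `trees.nwk` and `rates.tsv` there and
#'   returns the two paths as an attribute.
#' @return list of `chronogram_sample` objects, as [read_posterior()]
#'   returns.
#' @export
sim_posterior <- function(true_tree, n_samples, age_jitter = 0.1,
                          m3_mean, m3_jitter = 0.1, seed = NULL,
                          dir = NULL) {
  wc_assert(age_jitter >= 0 && m3_mean > 0, "invalid jitter or m3_mean")
  if (!is.null(seed)) set.seed(seed)
  base <- true_tree
  depth <- max(tip_depths(base))
  base$edge.length <- base$edge.length / depth
  nt <- length(base$tip.label)
  ages0 <- node_ages(base)
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    ages <- ages0 * exp(rnorm(length(ages0), 0, age_jitter))
    # enforce parent > child root-down, then renormalize to root 1
    ord <- order(ages0, decreasing = TRUE)
    for (v in names(ages)[ord]) {
      vn <- as.integer(v)
      pe <- base$edge[base$edge[, 2] == vn, 1]
      if (length(pe))
        ages[v] <- min(ages[v], 0.999 * ages[as.character(pe)])
    }
    ages <- ages / ages[as.character(nt + 1)]
    tr <- base
    age_of <- function(v) if (v <= nt) 0 else ages[as.character(v)]
    tr$edge.length <- vapply(seq_len(nrow(tr$edge)), function(k)
      age_of(tr$edge[k, 1]) - age_of(tr$edge[k, 2]), 0)
    m3 <- m3_mean * exp(rnorm(1, -m3_jitter^2 / 2, m3_jitter))
    samples[[s]] <- structure(list(tree = tr, m3 = m3),
                              class = "chronogram_sample")
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tp <- file.path(dir, "trees.nwk")
    rp <- file.path(dir, "rates.tsv")
    trees <- lapply(samples, `[[`, "tree")
    class(trees) <- "multiPhylo"
    ape::write.tree(trees, tp)
    write.table(data.frame(sample = seq_len(n_samples),
                           m3 = vapply(samples, `[[`, 0, "m3")),
                rp, sep = "\t", row.names = FALSE, quote = FALSE)
    attr(samples, "paths") <- c(trees = tp, rates = rp)
  }
  samples
}
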