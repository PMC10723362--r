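# Sequence simulators: GTR + Gamma nucleotide evolution with
# codon-position rate multipliers and relaxed branch rates, the
# three-genome cladogenic system, and a codon-level simulator with
# regional dN/dS.

#' Specify a GTR + Gamma evolution model with codon-position multipliers
#'
#' The rate matrix is scaled to one expected substitution per site per
#' unit branch length; the three codon-position multipliers are
#' normalized to mean 1.
#'
#' @param exchangeabilities six symmetric exchange rates in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs equilibrium base frequencies (A, C, G, T), summing
#'   to 1.
#' @param gamma_shape shape of the among-site rate distribution
#'   (`Inf` = equal rates).
#' @param pos_multipliers three positive codon-position rate
#'   multipliers (rescaled to mean 1).
#' @return an `evolution_model` object.
#' @export
evolution_model <- function(exchangeabilities = rep(1, 6),
                            base_freqs = rep(0.25, 4),
                            gamma_shape = Inf,
                            pos_multipliers = c(1, 1, 1)) {
  wc_assert(length(exchangeabilities) == 6 && all(exchangeabilities > 0),
            "need 6 positive exchangeabilities")
  wc_assert(length(base_freqs) == 4 && all(base_freqs > 0) &&
              abs(sum(base_freqs) - 1) < 1e-9,
            "base frequencies must be 4 positive values summing to 1")
  wc_assert(gamma_shape > 0, "gamma shape must be > 0")
  wc_assert(length(pos_multipliers) == 3 && all(pos_multipliers >= 0) &&
              mean(pos_multipliers) > 0,
            "need 3 non-negative position multipliers")
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- exchangeabilities[k] * base_freqs[j]
    Q[j, i] <- exchangeabilities[k] * base_freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  structure(list(Q = Q, base_freqs = base_freqs,
                 gamma_shape = gamma_shape,
                 pos_multipliers = pos_multipliers * 3 /
                   sum(pos_multipliers)),
            class = "evolution_model")
}

# spectral decomposition of a reversible rate matrix: P(t) = A exp(Lt) B
reversible_eigen <- function(Q, freqs) {
  s <- sqrt(freqs)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(A = diag(1 / s) %*% e$vectors, Binv = t(e$vectors) %*% diag(s),
       lambda = e$values)
}

# vectorized state transitions: states (integers 1..k) evolve for
# per-site times t under the decomposition dec
evolve_states <- function(states, t, dec) {
  E <- exp(outer(t, dec$lambda))            # n x k
  W <- E * dec$A[states, , drop = FALSE]
  P <- W %*% dec$Binv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  cp <- t(apply(P, 1, cumsum))
  u <- runif(length(states))
  max.col(cp >= u, ties.method = "first")
}

#' Simulate a codon alignment on a tree under GTR + Gamma
#'
#' Sites evolve independently given their gamma site rate and
#' codon-position multiplier; the expected number of substitutions on a
#' branch is `branch length x branch rate x site rate x position
#' multiplier`.  Stop codons may arise (nucleotide-level process).
#'
#' @param tree a `phylo` with branch lengths in expected substitutions
#'   per site (at rate 1).
#' @param model an [evolution_model()].
#' @param branch_rates `"fixed"` (all 1), `"gamma"` (Gamma(7,7) draws
#'   normalized to mean 1 across branches), or a numeric vector, one
#'   rate per edge.
#' @param n_codons number of codons to simulate.
#' @param seed optional integer seed.
#' @return a [codon_alignment()] of the tip sequences.
#' @export
sim_alignment <- function(tree, model = evolution_model(),
                          branch_rates = "fixed", n_codons, seed = NULL) {
  wc_assert(inherits(tree, "phylo") && !is.null(tree$edge.length),
            "tree must be a phylo with branch lengths",
            "wolclock_input_error")
  wc_assert(n_codons >= 1, "n_codons must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(tree$edge)
  rates <- if (identical(branch_rates, "fixed")) rep(1, ne)
    else if (identical(branch_rates, "gamma")) {
      r <- rgamma(ne, shape = 7, rate = 7)
      r / mean(r)
    } else {
      wc_assert(is.numeric(branch_rates) && length(branch_rates) == ne,
                "branch_rates vector must have one rate per edge")
      branch_rates
    }
  nsites <- 3 * n_codons
  site_rate <- if (is.finite(model$gamma_shape))
    rgamma(nsites, shape = model$gamma_shape, rate = model$gamma_shape)
    else rep(1, nsites)
  pos_mult <- model$pos_multipliers[rep(1:3, n_codons)]
  site_scale <- site_rate * pos_mult
  dec <- reversible_eigen(model$Q, model$base_freqs)
  nt <- length(tree$tip.label)
  states <- matrix(NA_integer_, nt + tree$Nnode, nsites)
  root <- nt + 1L
  states[root, ] <- sample.int(4, nsites, replace = TRUE,
                               prob = model$base_freqs)
  po <- ape::reorder.phylo(tree, "postorder")
  # map postorder edges back to the input edge order (branch_rates are
  # given in tree$edge order)
  eo <- match(paste(po$edge[, 1], po$edge[, 2]),
              paste(tree$edge[, 1], tree$edge[, 2]))
  ord <- rev(seq_len(ne))  # preorder traversal of postorder edges
  for (k in ord) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    t_site <- po$edge.length[k] * rates[eo[k]] * site_scale
    states[ch, ] <- evolve_states(states[p, ], t_site, dec)
  }
  seqs <- vapply(seq_len(nt), function(i)
    paste(DNA_BASES[states[i, ]], collapse = ""), "")
  names(seqs) <- tree$tip.label
  codon_alignment(seqs)
}

#' Simulate the three-genome cladogenic co-divergence system
#'
#' Three independent two-taxon alignments (symbiont, host nuclear, host
#' mitochondrial) whose expected pairwise third-position divergence is
#' `2 x rate x T` each, under a Jukes-Cantor model with third-position
#' weighting.  Feeds the divergence-ratio and calibration layers
#' end-to-end.
#'
#' @param wol_rate,nuc_rate,mt_rate third-position substitution rates
#'   (per site per year).
#' @param T_years divergence time in years.
#' @param lengths named vector of codon counts,
#'   `c(wol = , nuc = , mt = )`.
#' @param seed optional integer seed.
#' @param pos_multipliers codon-position multipliers shared by the
#'   three genomes.
#' @return named list of three [codon_alignment()] objects (`wol`,
#'   `nuc`, `mt`), each with taxa `A` and `B`.
#' @export
sim_cladogenic_system <- function(wol_rate, nuc_rate, mt_rate, T_years,
                                  lengths = c(wol = 20000, nuc = 5000,
                                              mt = 1500),
                                  seed = NULL,
                                  pos_multipliers = c(0.3, 0.3, 2.4)) {
  rates <- c(wol = wol_rate, nuc = nuc_rate, mt = mt_rate)
  wc_assert(all(rates > 0) && T_years >= 0, "rates must be > 0, T >= 0")
  if (any(2 * rates * T_years >= 0.75))
    wc_stop("expected divergence 2rT >= 0.75: saturated parameters",
            "wolclock_domain_error")
  if (!is.null(seed)) set.seed(seed)
  model <- evolution_model(pos_multipliers = pos_multipliers)
  m3 <- model$pos_multipliers[3]
  out <- lapply(names(rates), function(g) {
    bl <- rates[[g]] * T_years / m3   # per-lineage, third-position scale
    tree <- ape::read.tree(text = sprintf("(A:%.10g,B:%.10g);", bl, bl))
    sim_alignment(tree, model, "fixed", n_codons = lengths[[g]])
  })
  names(out) <- names(rates)
  out
}

# ---- codon-level simulation with regional omega -------------------------

.codon_sim <- new.env(parent = emptyenv())

sense_codons <- function() {
  cods <- all_codons()
  cods[GENETIC_CODE[cods] != "*"]
}

# symmetric Goldman-Yang-style rate matrix over the 61 sense codons:
# single-nucleotide changes only, synonymous rate 1, nonsynonymous
# omega, stop codons unreachable; scaled by the neutral mean rate so
# t is expected substitutions per codon at omega = 1
codon_q <- function(omega) {
  key <- sprintf("omega_%.12g", omega)
  if (!is.null(.codon_sim[[key]])) return(.codon_sim[[key]])
  cods <- sense_codons()
  k <- length(cods)
  if (is.null(.codon_sim$adj)) {
    syn <- matrix(FALSE, k, k)
    nb <- matrix(FALSE, k, k)
    split_c <- strsplit(cods, "")
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (sum(split_c[[i]] != split_c[[j]]) == 1L) {
        nb[i, j] <- TRUE
        syn[i, j] <- GENETIC_CODE[cods[i]] == GENETIC_CODE[cods[j]]
      }
    }
    .codon_sim$adj <- nb
    .codon_sim$syn <- syn
    Q1 <- matrix(0, k, k)
    Q1[nb] <- 1
    diag(Q1) <- -rowSums(Q1)
    .codon_sim$neutral_mean <- -mean(diag(Q1))
  }
  Q <- matrix(0, k, k, dimnames = list(cods, cods))
  Q[.codon_sim$adj & .codon_sim$syn] <- 1
  Q[.codon_sim$adj & !.codon_sim$syn] <- omega
  diag(Q) <- -rowSums(Q)
  Q <- Q / .codon_sim$neutral_mean
  dec <- reversible_eigen(Q, rep(1 / k, k))
  .codon_sim[[key]] <- dec
  dec
}

#' Simulate a two-sequence codon alignment with a regional dN/dS profile
#'
#' Codon-level (Goldman-Yang-style) simulation: synonymous
#' single-nucleotide changes at rate 1, nonsynonymous at rate `omega`
#' (per-codon), no transitions through stop codons.  `t` is the total
#' expected number of nucleotide substitutions per codon between the
#' two sequences at neutrality; each lineage evolves for `t / 2`.
#'
#' @param omega_profile numeric vector of per-codon omega values
#'   (`>= 0`).
#' @param t divergence scale, `> 0`.
#' @param seed optional integer seed.
#' @param taxa two sequence labels.
#' @return a [codon_alignment()] of the two sequences.
#' @export
sim_codon_pair_omega <- function(omega_profile, t, seed = NULL,
                                 taxa = c("A", "B")) {
  wc_assert(all(omega_profile >= 0) && all(is.finite(omega_profile)),
            "omega values must be finite and >= 0")
  wc_assert(t > 0, "t must be > 0")
  if (!is.null(seed)) set.seed(seed)
  cods <- sense_codons()
  L <- length(omega_profile)
  root <- sample.int(length(cods), L, replace = TRUE)
  tip1 <- integer(L); tip2 <- integer(L)
  for (om in unique(omega_profile)) {
    idx <- which(omega_profile == om)
    dec <- codon_q(om)
    tt <- rep(t / 2, length(idx))
    tip1[idx] <- evolve_states(root[idx], tt, dec)
    tip2[idx] <- evolve_states(root[idx], tt, dec)
  }
  seqs <- c(paste(cods[tip1], collapse = ""),
            paste(cods[tip2], collapse = ""))
  names(seqs) <- taxa
  codon_alignment(seqs)
}
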