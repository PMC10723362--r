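# Structure-mapped selection analysis: per-codon NG86 counts indexed on
# a reference sequence, spherical windows on a protein structure,
# windowed dN/dS profiles and their medians across pairwise comparisons.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a protein structure's C-alpha trace from a PDB file
#'
#' One representative (C-alpha) atom per residue; the B-factor column is
#' read as a per-residue confidence score (pLDDT convention for
#' predicted structures).  Duplicate altloc C-alphas keep the first
#' occurrence with a warning.
#'
#' @param path PDB file with `ATOM` records.
#' @param chain chain identifier (default `"A"`).
#' @return a `structure_model`: data frame with columns `resno`, `aa`
#'   (one-letter), `x`, `y`, `z` (Angstrom), `confidence`.
#' @export
read_structure <- function(path, chain = "A") {
  wc_assert(file.exists(path), paste("no such file:", path),
            "wolclock_input_error")
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM")]
  atom <- atom[substring(atom, 22, 22) == chain]
  if (!length(atom))
    wc_stop(sprintf("no ATOM records for chain '%s'", chain),
            "wolclock_input_error")
  ca <- atom[trimws(substring(atom, 13, 16)) == "CA"]
  if (!length(ca))
    wc_stop("no C-alpha atoms in chain", "wolclock_input_error")
  resno <- as.integer(substring(ca, 23, 26))
  if (anyDuplicated(resno)) {
    warning("duplicate C-alpha records (altloc?): keeping first per residue")
    keep <- !duplicated(resno)
    ca <- ca[keep]; resno <- resno[keep]
  }
  res3 <- trimws(substring(ca, 18, 20))
  df <- data.frame(
    resno = resno,
    aa = unname(ifelse(res3 %in% names(AA3TO1), AA3TO1[res3], "X")),
    x = as.numeric(substring(ca, 31, 38)),
    y = as.numeric(substring(ca, 39, 46)),
    z = as.numeric(substring(ca, 47, 54)),
    confidence = as.numeric(substring(ca, 61, 66)))
  wc_assert(all(is.finite(as.matrix(df[, c("x", "y", "z")]))),
            "non-finite coordinates", "wolclock_format_error")
  wc_assert(!is.unsorted(df$resno, strictly = TRUE),
            "residue indices must be strictly increasing",
            "wolclock_format_error")
  class(df) <- c("structure_model", "data.frame")
  df
}

structure_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Per-reference-codon NG86 site and difference counts
#'
#' Nei-Gojobori quantities (`N_sites`, `S_sites`, `N_diff`, `S_diff`)
#' for one pairwise comparison, indexed by the codons of the reference
#' sequence: alignment codons in which the reference carries a gap are
#' dropped, so row `i` corresponds to reference residue `i`.  Codons
#' unresolved in either sequence (gap, `N`) or containing a stop are
#' `NA`.
#'
#' @param aln a [codon_alignment()].
#' @param ref reference taxon label.
#' @param other compared taxon label.
#' @return a `site_counts` data frame with one row per reference
#'   residue; attribute `comparison` holds the pair label.
#' @export
pairwise_site_counts <- function(aln, ref, other) {
  check_pair(aln, ref, other)
  cnt <- ng86_pair_counts(aln, ref, other)
  refseq <- aln$seq[ref, ]
  dim(refseq) <- c(3, aln$n_codons)
  ref_has_gap <- colSums(refseq == "-") > 0
  out <- cnt[!ref_has_gap, , drop = FALSE]
  out$codon <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "comparison") <- paste(ref, other, sep = "|")
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Spherical window membership on a structure
#'
#' Residue `j` belongs to the window of residue `i` iff the Euclidean
#' distance between their representative atoms is `<= radius` (closed
#' ball; the focal residue is always a member).
#'
#' @param structure a `structure_model`.
#' @param radius window radius in Angstrom (default 10).
#' @return list of integer vectors, one per residue.
#' @export
spherical_windows <- function(structure, radius = 10) {
  wc_assert(radius > 0, "radius must be > 0")
  d <- as.matrix(stats::dist(structure_coords(structure)))
  lapply(seq_len(nrow(d)), function(i) which(unname(d[i, ]) <= radius))
}

#' Windowed dN/dS for one pairwise comparison
#'
#' Pools the NG86 counts over each residue's spherical window, computes
#' `pN` and `pS`, Jukes-Cantor corrects both, and returns
#' `omega = dN / dS` per residue.  `omega` is `NA` where `dS = 0` or a
#' proportion saturates (warning, never an error mid-profile); 0 is a
#' valid value when `dN = 0`.
#'
#' @param counts a `site_counts` from [pairwise_site_counts()].
#' @param windows window membership from [spherical_windows()]; must
#'   index the same reference residues as `counts`.
#' @return numeric vector of per-residue omega values.
#' @export
window_omega <- function(counts, windows) {
  wc_assert(nrow(counts) == length(windows),
            "counts and windows index different residue sets",
            "wolclock_input_error")
  L <- nrow(counts)
  omega <- rep(NA_real_, L)
  saturated <- 0L
  for (i in seq_len(L)) {
    idx <- windows[[i]]
    Ns <- sum(counts$N_sites[idx], na.rm = TRUE)
    Ss <- sum(counts$S_sites[idx], na.rm = TRUE)
    if (Ns == 0 || Ss == 0) next
    pN <- sum(counts$N_diff[idx], na.rm = TRUE) / Ns
    pS <- sum(counts$S_diff[idx], na.rm = TRUE) / Ss
    if (pN >= 0.75 || pS >= 0.75) { saturated <- saturated + 1L; next }
    dN <- jc_correct(pN)
    dS <- jc_correct(pS)
    omega[i] <- if (dS == 0) NA_real_ else dN / dS
  }
  if (saturated > 0)
    warning(sprintf("%d window(s) saturated (p >= 0.75): omega set to NA",
                    saturated))
  omega
}

#' Median dN/dS profile across pairwise comparisons
#'
#' @param profiles list (or matrix, rows = comparisons) of per-residue
#'   omega vectors sharing one reference indexing.
#' @return numeric vector of NA-aware per-residue medians; a residue is
#'   `NA` only when all comparisons are `NA` there.
#' @export
median_profile <- function(profiles) {
  if (is.list(profiles)) {
    wc_assert(length(unique(lengths(profiles))) == 1,
              "profiles index different residue sets",
              "wolclock_input_error")
    profiles <- do.call(rbind, profiles)
  }
  apply(profiles, 2, function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
}

#' Full structure-mapped dN/dS profile for a reference taxon
#'
#' Convenience wrapper: NG86 counts of every non-reference taxon against
#' `ref`, windowed omega per comparison, and the per-residue median.
#'
#' @inheritParams pairwise_site_counts
#' @param structure a `structure_model` whose residues 1..L match the
#'   reference's ungapped codons (extra structure residues beyond the
#'   alignment are trimmed, and vice versa, with a warning).
#' @param radius window radius in Angstrom.
#' @param groups optional character vector of per-residue group labels
#'   (e.g. domain or binding-site annotations).
#' @return a `site_omega_profile`: data frame with `residue`,
#'   `median_omega`, `n_comparisons`, `group`; per-comparison profiles
#'   in `attr(, "comparisons")`.
#' @export
structure_omega_profile <- function(aln, ref, structure, radius = 10,
                                    groups = NULL) {
  others <- setdiff(aln$taxa, ref)
  counts <- lapply(others, function(o) pairwise_site_counts(aln, ref, o))
  L_aln <- nrow(counts[[1]])
  L_str <- nrow(structure)
  L <- min(L_aln, L_str)
  if (L_aln != L_str)
    warning(sprintf("alignment codons (%d) and structure residues (%d) differ; using first %d",
                    L_aln, L_str, L))
  windows <- spherical_windows(structure[seq_len(L), , drop = FALSE], radius)
  prof <- lapply(counts, function(cn)
    window_omega(cn[seq_len(L), , drop = FALSE], windows))
  med <- median_profile(prof)
  out <- data.frame(residue = seq_len(L), median_omega = med,
                    n_comparisons = colSums(!is.na(do.call(rbind, prof))),
                    group = if (is.null(groups)) NA_character_
                            else groups[seq_len(L)])
  attr(out, "comparisons") <- setNames(prof, others)
  class(out) <- c("site_omega_profile", "data.frame")
  out
}
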