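# Divergence estimation from in-frame codon alignments:
# Jukes-Cantor third-position divergence, Nei-Gojobori (1986) synonymous
# divergence, and symbiont/nuclear/mtDNA ratio tables.

DNA_BASES <- c("A", "C", "G", "T")

# standard genetic code, one-letter amino acids, "*" = stop
GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

is_stop_codon <- function(codon) GENETIC_CODE[codon] == "*"

#' Jukes-Cantor multiple-hit correction
#'
#' Corrects a raw proportion of differing sites for multiple substitutions
#' at the same site: `d = -(3/4) * log(1 - (4/3) * p)`.
#'
#' @param p numeric vector of raw difference proportions, each in
#'   `[0, 0.75)`.
#' @return corrected substitutions per site, same length as `p`;
#'   always `>= p`.
#' @examples
#' jc_correct(c(0, 0.024))
#' @export
jc_correct <- function(p) {
  wc_assert(is.numeric(p) && all(is.finite(p)), "p must be finite numeric")
  if (any(p < 0)) wc_stop("p must be >= 0", "wolclock_domain_error")
  if (any(p >= 0.75))
    wc_stop("p >= 0.75: Jukes-Cantor correction saturates",
            "wolclock_saturation_error")
  -0.75 * log(1 - 4 * p / 3)
}

# ---- Nei-Gojobori (1986) codon machinery -------------------------------
#
# Site counts: at each codon position the synonymous fraction is the
# number of the 3 possible single-base changes that preserve the amino
# acid, divided by 3.  Changes creating a stop codon count as
# nonsynonymous, so N + S = 3 exactly for every non-stop codon.
#
# Difference counts: for codons differing at d positions, average the
# synonymous/nonsynonymous step classification over all d! substitution
# orders whose intermediates avoid stop codons (equal weights); if every
# order passes through a stop, fall back to all orders.

.ng86 <- new.env(parent = emptyenv())

all_codons <- function() {
  g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

ng86_tables <- function() {
  if (!is.null(.ng86$S)) return(as.list(.ng86))
  codons <- all_codons()
  n <- length(codons)
  syn_sites <- setNames(numeric(n), codons)
  for (cd in codons) {
    if (is_stop_codon(cd)) { syn_sites[cd] <- NA_real_; next }
    s <- 0
    bases <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(DNA_BASES, bases[pos])) {
      mut <- bases
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (!is_stop_codon(mutc) && GENETIC_CODE[mutc] == GENETIC_CODE[cd])
        s <- s + 1 / 3
    }
    syn_sites[cd] <- s
  }
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- Sd
  perms <- list(`1` = matrix(1, 1), `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    c1 <- strsplit(codons[i], "")[[1]]
    c2 <- strsplit(codons[j], "")[[1]]
    if (is_stop_codon(codons[i]) || is_stop_codon(codons[j])) {
      Sd[i, j] <- NA_real_; Nd[i, j] <- NA_real_; next
    }
    diffpos <- which(c1 != c2)
    d <- length(diffpos)
    if (d == 0) next
    ord <- perms[[as.character(d)]]
    paths <- vector("list", nrow(ord))
    ok <- logical(nrow(ord))
    for (k in seq_len(nrow(ord))) {
      cur <- c1
      sd_k <- 0; nd_k <- 0; blocked <- FALSE
      for (pos in diffpos[ord[k, ]]) {
        nxt <- cur
        nxt[pos] <- c2[pos]
        curc <- paste(cur, collapse = ""); nxtc <- paste(nxt, collapse = "")
        if (is_stop_codon(nxtc) && nxtc != codons[j]) blocked <- TRUE
        if (!is_stop_codon(curc) && !is_stop_codon(nxtc) &&
            GENETIC_CODE[curc] == GENETIC_CODE[nxtc]) sd_k <- sd_k + 1
        else nd_k <- nd_k + 1
        cur <- nxt
      }
      paths[[k]] <- c(sd_k, nd_k)
      ok[k] <- !blocked
    }
    use <- if (any(ok)) paths[ok] else paths
    m <- colMeans(do.call(rbind, use))
    Sd[i, j] <- m[1]; Nd[i, j] <- m[2]
  }
  .ng86$S <- syn_sites
  .ng86$Sd <- Sd
  .ng86$Nd <- Nd
  as.list(.ng86)
}

#' Nei-Gojobori synonymous site count of a codon
#'
#' @param codon character vector of codons (e.g. `"TTT"`).
#' @return numeric vector of synonymous site counts in `[0, 3]`;
#'   `NA` for stop codons.  The nonsynonymous count is `3 - S`.
#' @export
ng86_codon_sites <- function(codon) {
  tb <- ng86_tables()
  codon <- toupper(codon)
  wc_assert(all(codon %in% names(tb$S)), "unrecognized codon")
  unname(tb$S[codon])
}

#' Nei-Gojobori pathway-averaged difference counts for a codon pair
#'
#' @param codon1,codon2 codon strings.
#' @return named numeric `c(Sd = , Nd = )`, averaged over minimal
#'   substitution pathways that avoid stop-codon intermediates.
#' @export
ng86_codon_diffs <- function(codon1, codon2) {
  tb <- ng86_tables()
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  wc_assert(codon1 %in% rownames(tb$Sd) && codon2 %in% rownames(tb$Sd),
            "unrecognized codon")
  c(Sd = tb$Sd[codon1, codon2], Nd = tb$Nd[codon1, codon2])
}

# ---- codon alignments ---------------------------------------------------

#' Construct a codon alignment from sequence strings
#'
#' @param sequences named character vector of equal-length nucleotide
#'   strings (alphabet `A`, `C`, `G`, `T`, `N`, `-`).
#' @param frame_offset 0, 1 or 2: number of leading nucleotides to skip
#'   before the first complete codon.
#' @return an object of class `codon_alignment` with fields `taxa`,
#'   `seq` (character matrix, taxa x sites), `length_nt`, `n_codons`,
#'   `frame_offset`.
#' @export
codon_alignment <- function(sequences, frame_offset = 0) {
  wc_assert(length(sequences) >= 2, "need >= 2 sequences",
            "wolclock_input_error")
  wc_assert(frame_offset %in% 0:2, "frame_offset must be 0, 1 or 2")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    wc_stop("sequences differ in length", "wolclock_format_error")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  bad <- setdiff(unique(as.vector(mat)), c(DNA_BASES, "N", "-"))
  if (length(bad))
    wc_stop(paste0("non-IUPAC characters in alignment: ",
                   paste(bad, collapse = " ")), "wolclock_format_error")
  if (frame_offset > 0) mat <- mat[, -(seq_len(frame_offset)), drop = FALSE]
  extra <- ncol(mat) %% 3
  if (extra > 0) {
    warning(sprintf("dropping %d trailing nucleotide(s) of an incomplete codon",
                    extra))
    mat <- mat[, seq_len(ncol(mat) - extra), drop = FALSE]
  }
  wc_assert(ncol(mat) >= 3, "alignment has no complete codon",
            "wolclock_input_error")
  structure(list(taxa = rownames(mat), seq = mat,
                 length_nt = ncol(mat), n_codons = ncol(mat) %/% 3,
                 frame_offset = as.integer(frame_offset)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa, %d nt (%d codons), frame %d\n",
              length(x$taxa), x$length_nt, x$n_codons, x$frame_offset))
  invisible(x)
}

#' Read an in-frame codon alignment from a FASTA file
#'
#' @param path FASTA file (wrapped or single-line records).
#' @param frame_offset leading nucleotides to skip (0-2).
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, frame_offset = 0) {
  wc_assert(file.exists(path), paste("no such file:", path),
            "wolclock_input_error")
  dna <- ape::read.FASTA(path)
  wc_assert(length(dna) >= 2, "FASTA must contain >= 2 records",
            "wolclock_input_error")
  if (length(unique(lengths(dna))) != 1L)
    wc_stop("FASTA records differ in length", "wolclock_format_error")
  chr <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  codon_alignment(chr, frame_offset = frame_offset)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_codon_alignment <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in aln$taxa) {
    s <- paste(aln$seq[tx, ], collapse = "")
    writeLines(paste0(">", tx), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(nchar(s), seq(1, nchar(s), width) + width - 1)),
               con)
  }
  invisible(path)
}

divergence_estimate <- function(pair, sites, p_raw, kind) {
  d <- jc_correct(p_raw)
  structure(list(pair = pair, sites_compared = sites, p_raw = p_raw,
                 d_jc = d, d_percent = 100 * d, kind = kind),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("%s divergence %s vs %s: p = %.5g, d = %.5g (%.4g%%) over %d sites\n",
              x$kind, x$pair[1], x$pair[2], x$p_raw, x$d_jc, x$d_percent,
              x$sites_compared))
  invisible(x)
}

check_pair <- function(aln, a, b) {
  wc_assert(inherits(aln, "codon_alignment"), "not a codon_alignment",
            "wolclock_input_error")
  wc_assert(all(c(a, b) %in% aln$taxa),
            "both labels must be present in the alignment",
            "wolclock_input_error")
}

#' Jukes-Cantor corrected third-position divergence between two sequences
#'
#' Sites with a gap or `N` in either sequence are excluded (pairwise
#' deletion).
#'
#' @param aln a [codon_alignment()].
#' @param a,b taxon labels.
#' @return a `divergence_estimate` with `kind = "third_position"`.
#' @export
third_position_divergence <- function(aln, a, b) {
  check_pair(aln, a, b)
  idx <- seq(3, aln$length_nt, by = 3)
  s1 <- aln$seq[a, idx]; s2 <- aln$seq[b, idx]
  ok <- s1 %in% DNA_BASES & s2 %in% DNA_BASES
  n <- sum(ok)
  if (n == 0)
    wc_stop("no comparable third-position sites", "wolclock_degenerate_error")
  p <- sum(s1[ok] != s2[ok]) / n
  if (p >= 0.75)
    wc_stop(sprintf("third-position divergence saturated (p_raw = %.3f)", p),
            "wolclock_saturation_error")
  divergence_estimate(c(a, b), n, p, "third_position")
}

#' Nei-Gojobori synonymous divergence between two sequences
#'
#' Synonymous sites `S` are averaged between the two sequences; observed
#' synonymous differences `Sd` average over minimal substitution
#' pathways; `pS = Sd / S` is Jukes-Cantor corrected.  Codons containing
#' gaps or `N` in either sequence are skipped; in-frame stop codons are
#' skipped with a warning (truncated pseudogenes are expected inputs).
#'
#' @inheritParams third_position_divergence
#' @return a `divergence_estimate` with `kind = "synonymous"`;
#'   `sites_compared` is the rounded number of synonymous sites.
#' @export
synonymous_divergence <- function(aln, a, b) {
  check_pair(aln, a, b)
  cnt <- ng86_pair_counts(aln, a, b)
  S <- sum(cnt$S_sites, na.rm = TRUE)
  if (S <= 0)
    wc_stop("no synonymous sites comparable", "wolclock_degenerate_error")
  Sd <- sum(cnt$S_diff, na.rm = TRUE)
  p <- Sd / S
  if (p >= 0.75)
    wc_stop(sprintf("synonymous divergence saturated (pS = %.3f)", p),
            "wolclock_saturation_error")
  out <- divergence_estimate(c(a, b), round(S), p, "synonymous")
  out$S_sites <- S
  out$S_diff <- Sd
  out
}

# shared NG86 per-codon engine; reference-indexed variant lives in
# structdnds.R.  Returns one row per alignment codon; NA rows for codons
# skipped (gap/N/stop in either sequence).
ng86_pair_counts <- function(aln, a, b) {
  tb <- ng86_tables()
  n_cod <- aln$n_codons
  s1 <- aln$seq[a, ]; s2 <- aln$seq[b, ]
  dim(s1) <- dim(s2) <- c(3, n_cod)
  cod1 <- apply(s1, 2, paste, collapse = "")
  cod2 <- apply(s2, 2, paste, collapse = "")
  resolved <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2)
  stopf <- resolved & (is_stop_codon(ifelse(resolved, cod1, "AAA")) |
                       is_stop_codon(ifelse(resolved, cod2, "AAA")))
  if (any(stopf))
    warning(sprintf("skipping %d codon(s) containing in-frame stops",
                    sum(stopf)))
  use <- resolved & !stopf
  S_sites <- N_sites <- S_diff <- N_diff <- rep(NA_real_, n_cod)
  if (any(use)) {
    S_sites[use] <- (tb$S[cod1[use]] + tb$S[cod2[use]]) / 2
    N_sites[use] <- 3 - S_sites[use]
    S_diff[use] <- tb$Sd[cbind(cod1[use], cod2[use])]
    N_diff[use] <- tb$Nd[cbind(cod1[use], cod2[use])]
  }
  data.frame(codon = seq_len(n_cod), S_sites = S_sites, N_sites = N_sites,
             S_diff = S_diff, N_diff = N_diff)
}

# ---- ratio tables -------------------------------------------------------

ratio_or_na <- function(num, den) {
  out <- num / den
  zero <- !is.na(den) & den == 0
  if (any(zero & !is.na(num))) {
    warning("zero denominator divergence: ratio set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Divergence ratio table (symbiont vs host nuclear and mitochondrial)
#'
#' Takes per-pair percent divergences (computed by this package or
#' transcribed from printed tables) and derives the three ratios
#' wolbachia/nuclear, mtDNA/wolbachia and mtDNA/nuclear for the
#' third-position and synonymous estimates.  `NA` inputs propagate.
#'
#' @param entries data frame with columns `pair`, `wol_third`,
#'   `wol_syn`, `nuc_third`, `nuc_syn`, `mt_third`, `mt_syn`
#'   (percent divergences; `NA` allowed everywhere except `wol_*`).
#' @return a `ratio_table` data frame adding columns
#'   `ratio_wol_nuc_*`, `ratio_mt_wol_*`, `ratio_mt_nuc_*` for
#'   `third` and `syn`, at full precision (see
#'   [format_ratio_table()] for printed rendering).
#' @export
divergence_ratio_table <- function(entries) {
  need <- c("pair", "wol_third", "wol_syn", "nuc_third", "nuc_syn",
            "mt_third", "mt_syn")
  wc_assert(all(need %in% names(entries)),
            paste("entries must have columns:", paste(need, collapse = ", ")),
            "wolclock_input_error")
  wc_assert(all(!is.na(entries$wol_third) | !is.na(entries$wol_syn)),
            "each row needs at least one Wolbachia divergence",
            "wolclock_input_error")
  out <- entries
  for (kind in c("third", "syn")) {
    w <- entries[[paste0("wol_", kind)]]
    nu <- entries[[paste0("nuc_", kind)]]
    mt <- entries[[paste0("mt_", kind)]]
    out[[paste0("ratio_wol_nuc_", kind)]] <- ratio_or_na(w, nu)
    out[[paste0("ratio_mt_wol_", kind)]] <- ratio_or_na(mt, w)
    out[[paste0("ratio_mt_nuc_", kind)]] <- ratio_or_na(mt, nu)
  }
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Render a ratio value at table precision
#'
#' Values below 1 print with 2 significant figures, values in `[1, 10)`
#' with 2 decimals, and values `>= 10` with 1 decimal.
#'
#' @param x numeric vector.
#' @return character vector (`"NA"` for missing).
#' @export
format_ratio <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    out[i] <- if (is.na(v)) "NA"
      else if (v == 0) "0"
      else if (abs(v) < 1) sprintf("%.*f", 1 - floor(log10(abs(v))),
                                   signif(v, 2))
      else if (abs(v) < 10) sprintf("%.2f", v)
      else sprintf("%.1f", v)
  }
  out
}

#' Render a full ratio table the way the source tables print
#'
#' @param rt a `ratio_table`.
#' @return data frame of formatted strings, one row per pair.
#' @export
format_ratio_table <- function(rt) {
  fmt_div <- function(x) ifelse(is.na(x), "NA",
                                ifelse(abs(x) >= 10, sprintf("%.1f", x),
                                       format_ratio(x)))
  data.frame(
    pair = rt$pair,
    wolbachia = paste(fmt_div(rt$wol_third), fmt_div(rt$wol_syn), sep = ", "),
    nuclear = paste(fmt_div(rt$nuc_third), fmt_div(rt$nuc_syn), sep = ", "),
    mtdna = paste(fmt_div(rt$mt_third), fmt_div(rt$mt_syn), sep = ", "),
    wol_nuc = paste(format_ratio(rt$ratio_wol_nuc_third),
                    format_ratio(rt$ratio_wol_nuc_syn), sep = ", "),
    mt_wol = paste(format_ratio(rt$ratio_mt_wol_third),
                   format_ratio(rt$ratio_mt_wol_syn), sep = ", "),
    mt_nuc = paste(format_ratio(rt$ratio_mt_nuc_third),
                   format_ratio(rt$ratio_mt_nuc_syn), sep = ", "))
}
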