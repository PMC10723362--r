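test_that("jc_correct matches the closed form and its limits", {
  expect_identical(jc_correct(0), 0)
  expect_equal(jc_correct(0.024), 0.0243923, tolerance = 1e-5)
  expect_error(jc_correct(0.75), class = "wolclock_saturation_error")
  expect_error(jc_correct(-0.01), class = "wolclock_domain_error")
  # monotone increasing, d >= p, d/p -> 1 as p -> 0
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_lt(abs(jc_correct(1e-4) - 1e-4), 1e-6)
})

test_that("read_codon_alignment validates and trims to frame", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGGCTAAA", ">b", "ATGGCTAAA"), fa)
  aln <- read_codon_alignment(fa)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_codons, 3)

  writeLines(c(">a", "ATGGCTAAAT", ">b", "ATGGCTAAAC"), fa)
  expect_warning(aln10 <- read_codon_alignment(fa), "trailing")
  expect_equal(aln10$n_codons, 3)
  expect_equal(aln10$length_nt, 9)

  # frame offset shifts the codon grid
  writeLines(c(">a", "TATGGCTAAA", ">b", "TATGGCTAAA"), fa)
  aln_f1 <- read_codon_alignment(fa, frame_offset = 1)
  expect_equal(aln_f1$n_codons, 3)
  expect_equal(paste(aln_f1$seq["a", 1:3], collapse = ""), "ATG")

  writeLines(c(">a", "ATGGCTAAA", ">b", "ATGGCTAAACCC"), fa)
  expect_error(read_codon_alignment(fa), class = "wolclock_format_error")
  writeLines(c(">a", "ATGGCTAAA"), fa)
  expect_error(read_codon_alignment(fa), class = "wolclock_input_error")
  expect_error(codon_alignment(c(a = "ATGXCT", b = "ATGGCT")),
               class = "wolclock_format_error")
})

test_that("third-position divergence counts comparable sites only", {
  aln <- make_aln(a = "ATGGCTAAA", b = "ATGGCTAAA")
  expect_equal(third_position_divergence(aln, "a", "b")$d_percent, 0)

  # 1 difference at 1 of 100 third positions
  s <- strrep("ATG", 100)
  s2 <- paste0(substr(s, 1, 2), "A", substr(s, 4, 300))
  est <- third_position_divergence(make_aln(a = s, b = s2), "a", "b")
  expect_equal(est$p_raw, 0.01)
  expect_equal(est$sites_compared, 100)

  # gap and N third positions excluded in either sequence
  aln2 <- make_aln(a = "ATGAT-ATNATT", b = "ATGATGATAATA")
  est2 <- third_position_divergence(aln2, "a", "b")
  expect_equal(est2$sites_compared, 2)
  expect_equal(est2$p_raw, 0.5)

  expect_error(third_position_divergence(make_aln(a = "AT-", b = "ATG"),
                                         "a", "b"),
               class = "wolclock_degenerate_error")
  sat <- make_aln(a = strrep("ATA", 50), b = strrep("ATG", 50))
  expect_error(third_position_divergence(sat, "a", "b"),
               class = "wolclock_saturation_error")
})

test_that("NG86 site counts follow the genetic code", {
  expect_equal(ng86_codon_sites("TTT"), 1 / 3)
  # N + S = 3 for every non-stop codon; symmetric difference counts
  tb <- wolclock:::ng86_tables()
  non_stop <- names(tb$S)[!is.na(tb$S)]
  expect_true(all(abs((tb$S[non_stop] + (3 - tb$S[non_stop])) - 3) < 1e-12))
  expect_true(all(tb$S[non_stop] >= 0 & tb$S[non_stop] <= 3))
  expect_equal(tb$Sd[non_stop, non_stop], t(tb$Sd[non_stop, non_stop]))
  expect_equal(tb$Nd[non_stop, non_stop], t(tb$Nd[non_stop, non_stop]))
  # Sd + Nd equals the nucleotide difference count
  for (pair in list(c("TTT", "TTC"), c("AAA", "AGG"), c("ATG", "TAC"))) {
    d <- ng86_codon_diffs(pair[1], pair[2])
    nd <- sum(strsplit(pair[1], "")[[1]] != strsplit(pair[2], "")[[1]])
    expect_equal(unname(sum(d)), nd)
  }
  # hand-enumerated cases
  expect_equal(ng86_codon_diffs("TTT", "TTC"), c(Sd = 1, Nd = 0))
  expect_equal(ng86_codon_diffs("TTT", "TTA"), c(Sd = 0, Nd = 1))
  # AAA -> AGG: both orders give one synonymous + one nonsynonymous step
  expect_equal(ng86_codon_diffs("AAA", "AGG"), c(Sd = 1, Nd = 1))
})

test_that("synonymous divergence pools NG86 counts and skips stops", {
  aln <- make_aln(a = strrep("TTTGCA", 200), b = strrep("TTTGCA", 200))
  expect_equal(synonymous_divergence(aln, "a", "b")$d_jc, 0)

  # 10 TTT->TTC codons among 400: Sd = 10, S = 400 * 1/3 + 200 * ...
  a <- paste0(strrep("TTT", 390), strrep("TTC", 10))
  b <- strrep("TTT", 400)
  est <- synonymous_divergence(make_aln(a = a, b = b), "a", "b")
  expect_equal(est$S_diff, 10)
  expect_equal(est$S_sites, 400 / 3)
  expect_equal(est$p_raw, 10 / (400 / 3))

  # in-frame stop codons skipped with a warning, not an error
  with_stop <- make_aln(a = paste0("TAA", strrep("TTT", 50)),
                        b = paste0("TAA", strrep("TTT", 50)))
  expect_warning(est2 <- synonymous_divergence(with_stop, "a", "b"),
                 "stop")
  expect_equal(est2$d_jc, 0)
  expect_equal(est2$S_sites, 50 / 3)
})

test_that("divergence ratio table computes quotients and propagates NA", {
  entries <- data.frame(pair = c("p1", "p2"),
                        wol_third = c(2.4, 1), wol_syn = c(3.7, NA),
                        nuc_third = c(12.3, 1), nuc_syn = c(19.3, NA),
                        mt_third = c(15.7, NA), mt_syn = c(28.0, NA))
  rt <- divergence_ratio_table(entries)
  expect_equal(rt$ratio_mt_wol_third[1], 15.7 / 2.4)
  expect_equal(rt$ratio_wol_nuc_third[2], 1)      # wol = nuc -> 1
  expect_true(is.na(rt$ratio_mt_wol_third[2]))    # NA propagates
  # zero denominator -> NA with warning
  z <- data.frame(pair = "z", wol_third = 0, wol_syn = 0.1,
                  nuc_third = 1, nuc_syn = 1, mt_third = 1, mt_syn = 1)
  expect_warning(rz <- divergence_ratio_table(z), "zero denominator")
  expect_true(is.na(rz$ratio_mt_wol_third[1]))
  # rendering convention
  expect_equal(format_ratio(c(6.541666, 150.75, 0.0135, 0.198)),
               c("6.54", "150.8", "0.014", "0.20"))
})

test_that("simulated pairs recover known third-position divergence", {
  # two-tip tree with total third-position path length 0.024
  set.seed(401)
  model <- evolution_model(pos_multipliers = c(0.3, 0.3, 2.4))
  tree <- ape::read.tree(text = sprintf("(A:%g,B:%g);", 0.012 / 2.4,
                                        0.012 / 2.4))
  reps <- replicate(30, {
    aln <- sim_alignment(tree, model, "fixed", n_codons = 4000)
    third_position_divergence(aln, "A", "B")$d_jc
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.024), 3 * se)
})
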