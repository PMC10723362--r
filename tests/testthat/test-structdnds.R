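test_that("read_structure round-trips C-alpha models", {
  h <- sim_helix(5, confidence = c(90, 80, 70, 60, 50))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, pdb)
  got <- read_structure(pdb, "A")
  expect_equal(nrow(got), 5)
  expect_equal(got$x, h$x, tolerance = 1e-3)   # PDB has 3 decimals
  expect_equal(got$confidence, h$confidence)
  expect_error(read_structure(pdb, "B"), class = "wolclock_input_error")

  # duplicate altloc keeps the first with a warning
  lines <- readLines(pdb)
  dup <- c(lines[1], lines[1], lines[-1])
  writeLines(dup, pdb)
  expect_warning(got2 <- read_structure(pdb, "A"), "altloc")
  expect_equal(nrow(got2), 5)
})

test_that("pairwise_site_counts indexes reference residues", {
  aln <- make_aln(ref = strrep("TTT", 10), other = strrep("TTT", 10))
  cnt <- pairwise_site_counts(aln, "ref", "other")
  expect_equal(sum(cnt$S_diff), 0)
  expect_equal(sum(cnt$N_diff), 0)
  expect_equal(cnt$S_sites + cnt$N_sites, rep(3, 10))

  # single TTT -> TTC at reference codon 5
  other <- paste0(strrep("TTT", 4), "TTC", strrep("TTT", 5))
  cnt5 <- pairwise_site_counts(make_aln(ref = strrep("TTT", 10),
                                        other = other), "ref", "other")
  expect_equal(cnt5$S_diff[5], 1)
  expect_equal(sum(cnt5$S_diff[-5]) + sum(cnt5$N_diff), 0)

  # reference-gapped codons are dropped so counts index residues 1..L
  refg <- paste0("TTT", "---", strrep("TTT", 3))
  othg <- paste0("TTT", "GGG", "TTC", strrep("TTT", 2))
  cg <- pairwise_site_counts(make_aln(ref = refg, other = othg),
                             "ref", "other")
  expect_equal(nrow(cg), 4)
  expect_equal(cg$S_diff[2], 1)   # the TTC now sits at reference codon 2
})

test_that("spherical windows equal the brute-force distance oracle", {
  h <- sim_helix(40)
  xyz <- as.matrix(h[, c("x", "y", "z")])
  for (radius in c(2.3, 5, 10)) {
    w <- spherical_windows(h, radius)
    for (i in c(1, 7, 20, 40)) {
      direct <- which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) <= radius)
      expect_equal(w[[i]], direct)
    }
    expect_true(all(vapply(seq_len(40), function(i) i %in% w[[i]], TRUE)))
  }
  # limits: tiny radius -> singleton; huge radius -> everything
  expect_true(all(lengths(spherical_windows(h, 1e-6)) == 1))
  expect_true(all(lengths(spherical_windows(h, 1e6)) == 40))
})

test_that("window_omega pools counts and handles degenerate windows", {
  # dS = 0 with dN > 0 gives NA; dN = 0 gives 0
  counts <- data.frame(codon = 1:2,
                       S_sites = c(1, 2), N_sites = c(2, 1),
                       S_diff = c(0, 1), N_diff = c(1, 0))
  w <- list(1L, 2L)
  om <- window_omega(counts, w)
  expect_true(is.na(om[1]))
  expect_equal(om[2], 0)
  expect_error(window_omega(counts, list(1L)),
               class = "wolclock_input_error")
})

test_that("median_profile is NA-aware and order-invariant", {
  p1 <- c(0.2, NA, 1); p2 <- c(0.4, NA, 2); p3 <- c(NA, NA, 3)
  med <- median_profile(list(p1, p2, p3))
  expect_equal(med, c(0.3, NA, 2))
  expect_equal(median_profile(list(p3, p1, p2)), med)
  expect_equal(median_profile(list(p1)), p1)
  expect_error(median_profile(list(1:3, 1:4)),
               class = "wolclock_input_error")
})

test_that("bca_interval implements the BCa adjustment", {
  expect_warning(ci <- bca_interval(rep(2, 10), mean, n_boot = 500),
                 "degenerate")
  expect_equal(ci, c(2, 2))
  # z0 = a = 0 reduces exactly to the percentile interval
  bs <- rnorm(2000)
  expect_equal(wolclock:::bca_endpoints(bs, 0, 0),
               quantile(bs, c(0.025, 0.975), names = FALSE))
  # interval contains the point estimate and shifts with skewness
  set.seed(42)
  x <- rexp(40)
  ci2 <- bca_interval(x, mean, n_boot = 999, seed = 1)
  expect_true(ci2[1] < mean(x) && mean(x) < ci2[2])
})

test_that("group_compare runs MWU for 2 groups and KW+Dunn for more", {
  # identical values in both groups: p = 1
  gc0 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gc0$p_value, 1)
  expect_equal(unname(gc0$letters["a"]), unname(gc0$letters["b"]))
  # {1,2,3} vs {10,11,12}: exact two-sided p = 1/10
  gc1 <- group_compare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(gc1$p_value, 0.1)
  # three identical groups share one letter
  gc2 <- group_compare(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(length(unique(gc2$letters)) == 1)
  # clearly separated groups get distinct letters
  set.seed(43)
  v <- c(rnorm(12), rnorm(12) + 10, rnorm(12) + 20)
  gc3 <- group_compare(v, rep(c("a", "b", "c"), each = 12))
  expect_equal(length(unique(gc3$letters)), 3)
  expect_equal(gc3$pairwise$p_adjusted,
               p.adjust(gc3$pairwise$p, "holm"))
  # small groups are excluded with a warning
  expect_warning(gc4 <- group_compare(c(1, 2, 3, 4, 9),
                                      c("a", "a", "b", "b", "c")),
                 "excluding")
  expect_error(suppressWarnings(
    group_compare(c(1, 2, 9), c("a", "a", "c"))),
    class = "wolclock_input_error")
})

test_that("kabsch_tm scores superpositions the way the formula says", {
  h <- sim_helix(30)
  self <- kabsch_tm(h, h)
  expect_equal(self$score, 1)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  # displaced residue: score equals the direct formula under the
  # superposition fitted on the unmoved residues
  moved <- h
  moved$x[15] <- moved$x[15] + 20
  tm <- kabsch_tm(h, moved)
  d0 <- wolclock:::tm_d0(30)
  oracle <- (29 + 1 / (1 + (20 / d0)^2)) / 30
  expect_equal(tm$score, oracle, tolerance = 1e-4)

  # asymmetric under swapping when lengths differ
  short <- sim_helix(20)
  corr <- cbind(1:20, 1:20)
  ab <- kabsch_tm(h, short, corr)
  ba <- kabsch_tm(short, h, corr[, 2:1])
  expect_false(isTRUE(all.equal(ab$score, ba$score)))
  expect_equal(ab$score * ab$L_norm, ba$score * ba$L_norm,
               tolerance = 1e-6)  # same summed term, different norms

  # the reported transform reproduces the score
  x <- wolclock:::structure_coords(h)
  y <- wolclock:::structure_coords(moved)
  d <- sqrt(rowSums((sweep(x %*% tm$rotation, 2, tm$translation, `+`) -
                     y)^2))
  expect_equal(sum(1 / (1 + (d / d0)^2)) / 30, tm$score, tolerance = 1e-9)

  expect_error(kabsch_tm(h, moved, cbind(1:2, 1:2)),
               class = "wolclock_input_error")
})

test_that("spearman_test matches enumeration and the t approximation", {
  expect_equal(spearman_test(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_test(1:6, -(1:6))$rho, -1)
  # n = 5 with a tie equals the exhaustive-permutation oracle
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2, 5, 1, 4)
  got <- spearman_test(x, y)
  orc <- oracle_spearman(x, y)
  expect_equal(got$rho, orc$rho)
  expect_equal(got$p_value, orc$p)
  expect_warning(z <- spearman_test(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(z$rho))
  # large-n branch agrees with cor.test's t approximation
  set.seed(44)
  a <- rnorm(30); b <- a + rnorm(30)
  got2 <- spearman_test(a, b)
  ct <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(got2$rho, unname(ct$estimate))
  expect_equal(got2$p_value, ct$p.value, tolerance = 1e-6)
})

test_that("structure_omega_profile ties the pieces together", {
  set.seed(45)
  L <- 60
  aln3 <- sim_codon_pair_omega(rep(0.5, L), t = 0.4, seed = 46,
                               taxa = c("wRef", "wA"))
  third <- sim_codon_pair_omega(rep(0.5, L), t = 0.4, seed = 47,
                                taxa = c("wRef", "wB"))
  merged <- codon_alignment(c(
    wRef = paste(aln3$seq["wRef", ], collapse = ""),
    wA = paste(aln3$seq["wA", ], collapse = ""),
    wB = paste(third$seq["wB", ], collapse = "")))
  prof <- structure_omega_profile(merged, "wRef", sim_helix(L), radius = 10)
  expect_s3_class(prof, "site_omega_profile")
  expect_equal(nrow(prof), L)
  comps <- attr(prof, "comparisons")
  expect_named(comps, c("wA", "wB"))
  expect_equal(prof$median_omega,
               median_profile(comps))
})
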