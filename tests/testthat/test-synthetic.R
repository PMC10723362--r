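test_that("sim_tree produces seeded ultrametric trees", {
  t2 <- sim_tree(2, seed = 61)
  expect_equal(length(t2$tip.label), 2)
  expect_gt(max(ape::branching.times(t2)), 0)
  expect_identical(ape::write.tree(sim_tree(12, 1, 0.3, seed = 62)),
                   ape::write.tree(sim_tree(12, 1, 0.3, seed = 62)))
  td <- sim_tree(15, birth = 1, death = 0.5, seed = 63)
  expect_equal(length(td$tip.label), 15)
  expect_true(ape::is.ultrametric(td, tol = 1e-6))
  expect_error(sim_tree(5, birth = 1, death = 2),
               class = "wolclock_domain_error")
})

test_that("pure-birth root ages match the Yule expectation", {
  set.seed(64)
  n <- 40
  ages <- replicate(150, max(ape::branching.times(sim_tree(n, birth = 2))))
  expected <- sum(1 / (2 * (2:n)))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("sim_alignment respects branch lengths and multipliers", {
  zero <- ape::read.tree(text = "(A:0,B:0);")
  a0 <- sim_alignment(zero, evolution_model(), "fixed", 200, seed = 65)
  expect_identical(a0$seq["A", ], a0$seq["B", ])

  # JC analytic p-distance: E[p] = 3/4 (1 - exp(-4 d / 3))
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  set.seed(66)
  ps <- replicate(25, {
    a <- sim_alignment(tr, evolution_model(), "fixed", 3000)
    mean(a$seq["A", ] != a$seq["B", ])
  })
  expected_p <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(mean(ps) - expected_p), 3 * sd(ps) / sqrt(length(ps)))

  # multipliers (0.5, 0.5, 2): position-3 divergence ~ 4x position-1
  m <- evolution_model(pos_multipliers = c(0.5, 0.5, 2))
  set.seed(67)
  aln <- sim_alignment(ape::read.tree(text = "(A:0.15,B:0.15);"), m,
                       "fixed", 30000)
  i1 <- seq(1, aln$length_nt, 3); i3 <- seq(3, aln$length_nt, 3)
  d1 <- jc_correct(mean(aln$seq["A", i1] != aln$seq["B", i1]))
  d3 <- jc_correct(mean(aln$seq["A", i3] != aln$seq["B", i3]))
  expect_equal(d3 / d1, 4, tolerance = 0.2)

  # gamma branch rates are normalized to mean 1, so expectation holds
  set.seed(68)
  pg <- replicate(20, {
    a <- sim_alignment(tr, evolution_model(), "gamma", 2000)
    mean(a$seq["A", ] != a$seq["B", ])
  })
  expect_lt(abs(mean(pg) - expected_p), 4 * sd(pg) / sqrt(length(pg)))
})

test_that("sim_cladogenic_system hits its divergence targets", {
  expect_error(sim_cladogenic_system(1e-7, 1e-7, 1e-6, 5e6),
               class = "wolclock_domain_error")
  zero <- sim_cladogenic_system(1e-9, 1e-9, 1e-9, 0,
                                lengths = c(wol = 100, nuc = 100, mt = 100),
                                seed = 69)
  expect_identical(zero$wol$seq["A", ], zero$wol$seq["B", ])

  set.seed(70)
  ds <- replicate(15, {
    sys <- sim_cladogenic_system(2.2e-9, 1.1e-8, 2.2e-8, 5.5e6,
                                 lengths = c(wol = 6000, nuc = 3000,
                                             mt = 3000))
    c(third_position_divergence(sys$wol, "A", "B")$d_percent,
      third_position_divergence(sys$nuc, "A", "B")$d_percent,
      third_position_divergence(sys$mt, "A", "B")$d_percent)
  })
  means <- rowMeans(ds)
  ses <- apply(ds, 1, sd) / sqrt(ncol(ds))
  expect_lt(abs(means[1] - 2.42), 3 * ses[1])
  expect_lt(abs(means[2] - 12.1), 3 * ses[2])
  expect_lt(abs(means[3] - 24.2), 3 * ses[3])
})

test_that("codon-level simulation honors regional omega", {
  expect_error(sim_codon_pair_omega(c(1, -1), 0.5),
               class = "wolclock_domain_error")
  # omega = 0 region: zero nonsynonymous differences, forced
  aln <- sim_codon_pair_omega(rep(c(0, 1), each = 150), t = 0.8, seed = 71)
  cnt <- pairwise_site_counts(aln, "A", "B")
  expect_equal(sum(cnt$N_diff[1:150]), 0)
  expect_gt(sum(cnt$N_diff[151:300]), 0)
  expect_identical(sim_codon_pair_omega(rep(1, 50), 0.5, seed = 72)$seq,
                   sim_codon_pair_omega(rep(1, 50), 0.5, seed = 72)$seq)
})

test_that("sim_helix has the canonical geometry", {
  h <- sim_helix(25)
  gaps <- sqrt(diff(h$x)^2 + diff(h$y)^2 + diff(h$z)^2)
  expect_equal(unique(round(gaps, 6)), round(gaps[1], 6))
  expect_equal(gaps[1], 3.8, tolerance = 0.02)
  h2 <- sim_helix(2)
  w <- spherical_windows(h2, 10)
  expect_equal(w[[1]], c(1L, 2L))
})

test_that("sim_hatch matches its stated group structure", {
  tab <- sim_hatch(seed = 73)
  expect_equal(length(unique(tab$cross_id[tab$type == "IC"])), 14)
  expect_equal(length(unique(tab$cross_id[tab$type == "CC"])), 18)
  expect_true(all(tab$hatched <= tab$eggs))
  zero <- sim_hatch(n_ic = 5, n_cc = 5, p_ic = 0, p_cc = 1,
                    eggs_low = 3, eggs_high = 5, seed = 74)
  agg <- pooled_hatch(zero)
  expect_true(all(agg$proportion[agg$type == "IC"] == 0))
  expect_true(all(agg$proportion[agg$type == "CC"] == 1))
  # group means near the design targets over repeated simulation
  set.seed(75)
  mm <- replicate(60, {
    p <- pooled_hatch(sim_hatch())
    c(mean(p$proportion[p$type == "IC"]), mean(p$proportion[p$type == "CC"]))
  })
  expect_lt(abs(mean(mm[1, ]) - 0.34), 0.1)
  expect_lt(abs(mean(mm[2, ]) - 0.89), 0.1)
})

test_that("sim_posterior perturbs ages and stays relative", {
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,(c:0.7,d:0.7):0.3);")
  fixed <- sim_posterior(tr, 5, age_jitter = 0, m3_mean = 0.01, seed = 76)
  nwk <- vapply(fixed, function(s) ape::write.tree(s$tree), "")
  expect_equal(length(unique(nwk)), 1)
  jit <- sim_posterior(tr, 30, age_jitter = 0.1, m3_mean = 0.01, seed = 77)
  for (s in jit[1:5]) {
    expect_true(ape::is.ultrametric(s$tree, tol = 1e-8))
    expect_equal(max(ape::branching.times(s$tree)), 1, tolerance = 1e-9)
  }
  # m3 scaling scales recovered ages linearly (point-mass prior)
  s1 <- sim_posterior(tr, 4, age_jitter = 0, m3_mean = 0.01, seed = 78)
  s2 <- sim_posterior(tr, 4, age_jitter = 0, m3_mean = 0.02, seed = 78)
  a1 <- scale_to_absolute(s1, 2e-9, draws_per_sample = 2)
  a2 <- scale_to_absolute(s2, 2e-9, draws_per_sample = 2)
  expect_equal(a2$nodes$age, 2 * a1$nodes$age)
})
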