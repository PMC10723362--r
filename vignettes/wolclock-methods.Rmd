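---
title: "Models and numerical conventions in wolclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in wolclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wolclock implements the computation chain behind a co-divergence
calibrated chronology for maternally inherited endosymbionts: pairwise
divergence estimation on codon alignments, substitution-rate
calibration from host-symbiont co-divergence, scaling of relative
chronogram posteriors to absolute time, split-based tree comparison
with a random-tree null, structure-mapped windowed dN/dS with
resampling and rank statistics, and an egg-hatch incompatibility test.
This vignette records the models, the parameters that matter, and the
numerical decisions taken where the design was genuinely open.  It
states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Divergence estimation

**Jukes-Cantor correction.** All raw difference proportions `p` are
corrected for multiple hits with `d = -(3/4) ln(1 - 4p/3)`.  The
correction is undefined at `p >= 0.75`; `jc_correct()` treats that as a
saturation error everywhere except inside windowed profiles, where a
saturated window becomes `NA` with a warning so one hot window cannot
abort a whole profile.

**Third-position divergence** uses pairwise deletion per site: a third
position enters the comparison only when both sequences carry an
unambiguous base there.  This maximizes comparable sites without
imputation and matches the usual pairwise-distance convention.

**Synonymous divergence** follows Nei-Gojobori (1986).  Site counts:
at each codon position the synonymous fraction is the number of the
three possible single-base changes that preserve the amino acid,
divided by three; changes that create a stop codon count as
nonsynonymous, so `N + S = 3` exactly for every resolved codon (a
testable invariant).  Difference counts for codons differing at 2-3
positions average over all minimal substitution orders whose
intermediates avoid stop codons, with equal weights; if every order
passes through a stop, all orders are used.  Codons containing gaps or
`N` in either sequence are skipped per codon (pairwise deletion at the
codon level); in-frame stop codons are skipped with a warning rather
than an error because truncated, putatively pseudogenized genes are
expected inputs.

**Ratio tables** keep full precision internally; rendering to the
printed convention (2 significant figures below 1, 2 decimals in
[1, 10), 1 decimal above) is a formatting layer only.  A zero
denominator yields `NA` with a warning; `NA` inputs propagate.

## Rate calibration and priors

A cladogenic co-divergence example converts a percent divergence `d`
and host divergence time `T` (years) into
`r = (d/100) / (2T)` substitutions/site/year — the factor 2 because
pairwise divergence accrues along both lineages.  Credible bounds
invert monotonically: `rate_low` from `T_high` and vice versa.  Rates
are carried in substitutions/site/year everywhere; "x 10^-9" and
"KY/MY" formatting is presentation-layer only, which avoids unit
drift.

The four calibration priors share a mean near 1.65e-9/site/year
(two-thirds weight on the concordant 2.2e-9 examples, one-third on the
0.56e-9 example):

| name | definition |
|------|------------|
| N1 | N(1, 0.34) x 1.65e-9 |
| U1 | U(0.33, 1.67) x 1.65e-9 |
| N2 | N(1, 0.36) x 0.56e-9 w.p. 1/3; N(1, 0.08) x 2.2e-9 w.p. 2/3 |
| U2 | U(0.3, 1.7) x 0.56e-9 w.p. 1/3; U(0.84, 1.16) x 2.2e-9 w.p. 2/3 |
| legacy | Gamma(shape 7, rate 7) x 6.87e-9 (mutation-rate based) |

**Truncation of normal components.** A substitution rate must be
positive, so normal draws are truncated at zero by rejection.  Plain
truncation shifts the N1 mean up by ~0.18%, which is larger than the
Monte-Carlo error of a 10^6-draw calibration run; we therefore divide
the truncated draws by the analytic truncated-normal mean factor
`1 + (sigma/mu) phi(mu/sigma) / Phi(mu/sigma)`, keeping each component
mean at its nominal value while preserving positivity.  The bimodal
mixtures' analytic mean is exactly (1/3)0.56 + (2/3)2.2 = 1.6533e-9,
i.e. 1.65e-9 at the three printed significant figures; sampler
correctness is therefore asserted against the analytic means.

## Chronogram scaling

Inputs are posterior samples of a relative chronogram (ultrametric,
root age 1, validated to 1e-6) each carrying a third-position rate
multiplier `m3` (substitutions per site per unit relative time for
that draw).  For sample `i` and rate draw `r_j` from a prior, the
absolute age of a node is `relative age x m3_i / r_j`.  Decisions:

* **Rate draws are crossed with posterior samples** (an i x j grid,
  default 100 draws per sample, configurable) rather than paired 1:1 —
  this approximates integrating the rate prior independently of the
  relative-time posterior.  How many draws the original analysis
  combined per sample is not recorded anywhere we can consult; 100 is
  enough that the grid, not the draw count, dominates.
* **Point estimate = posterior median.**  The point convention is not
  stated by the source analyses; the median is robust to the heavy
  right tail that `1/r` induces.
* **Equal-tailed percentile intervals**, not HPD: simpler, and
  monotone-transform-consistent under `1/r`.  HPD could be added
  beside it without changing the interface.
* Scaling requires all samples to share one topology and errors
  otherwise, pointing the user to build a consensus upstream — summary
  across topologies is a different (and lossier) operation.

`collapse_low_support()` contracts exactly the internal edges whose
child node has posterior support below 0.95 (threshold configurable),
adding the contracted edge lengths to the reattached children so node
depths are preserved.

## Tree distances and the random null

Trees are unrooted before split extraction; splits are stored
canonically as the side excluding the alphabetically first leaf, and
only non-trivial splits (both sides >= 2) count.

* **RF** is the symmetric difference of split sets.
* **JRF** solves a linear assignment on per-pair split scores `J^k`.
  The per-pair Jaccard `J` is the max over the two side
  correspondences of the min of the two sides' Jaccard indices — a
  symmetric choice that is 1 exactly for identical splits and
  approaches the RF behaviour as `k -> Inf` (spot-checked at k = 64).
  The concession exponent defaults to `k = 1`.
* **CID** scores pairs by mutual clustering information in bits and
  returns `H(t1) + H(t2) - 2 MCI_max`.

The assignment step uses an in-package Hungarian solver
(`solve_assignment()`), tested against exhaustive permutation oracles.

`random_tree()` draws topologies by sequential pair joining with a
uniform pair choice at each step (coalescent-style), which makes the
three 4-leaf unrooted topologies equiprobable.  `similarity_test()`
draws `n_random` *pairs* of random trees — the null is two random
trees, not one fixed — normalizes the observed distance by the null
mean, and reports `p` as the proportion of null pairs with distance
strictly below the observed one (strict "below" matches the stated
test of "more similar than chance"); a `plus_one` option gives
`(b+1)/(N+1)` for users who dislike p = 0.

## Structure-mapped dN/dS

The representative atom is the C-alpha (the windowing predates
full-atom conventions; configurable by supplying other coordinates),
and the per-residue confidence (pLDDT) from the B-factor column is
carried as metadata only — no confidence-based masking is applied
because none is stated by the protocols this mirrors.

NG86 counts are indexed by *reference* residues: alignment codons
where the reference is gapped are dropped so counts line up with
structure residues 1..L.  Windows are closed balls of radius 10
Angstrom (focal residue always included).  Per residue, counts are
pooled over the window, `pN` and `pS` are Jukes-Cantor corrected, and
`omega = dN/dS` with these conventions: `dS = 0` gives `NA` (capping
would distort the downstream rank tests; all statistics are NA-aware),
`dN = 0` with `dS > 0` gives a true 0, saturation gives `NA` with a
warning.  Medians across pairwise comparisons are NA-aware; a residue
is `NA` only if every comparison is.

**BCa intervals** use the standard bias correction (normal quantile of
the bootstrap fraction below the observed statistic, clamped away from
0/1 by half a bootstrap unit) and jackknife acceleration.  With
`z0 = a = 0` the endpoints reduce exactly to the percentile interval
on the same draws — a formula-reduction test.  Degenerate bootstrap
distributions yield a zero-width interval with a warning.

**Group comparisons**: two groups use a two-sided Mann-Whitney U
(exact via the null CDF when tie-free and `m + n <= 20`, else normal
approximation with tie and continuity correction); more use
Kruskal-Wallis followed by all-pairs Dunn z tests.  Dunn multiplicity
adjustment defaults to Holm (Bonferroni/BH selectable) — the original
figure captions do not state one, and Holm dominates Bonferroni
uniformly.  The compact letter display uses insert-and-absorb.

**TM-scores** normalize by the *target* length
(`d0 = 1.24 (L_t - 15)^{1/3} - 1.8`, floored at 0.5 Angstrom), so the
score is asymmetric when lengths differ — run both directions, as the
two-direction protocol does.  Superposition is Kabsch (SVD) on the
correspondence, refined iteratively on pairs closer than `d0` until
the score moves less than 1e-6 (max 20 iterations), keeping the best
score seen.  Truncated proteins are analyzed over their aligned extent
for omega profiles but excluded from TM comparisons.

**Spearman** uses average ranks; `p` is exact by enumeration for
`n <= 9` and a t approximation above.

## Incompatibility assay

"Hatch proportions across the 5-day period" is read as pooled totals
per cross (total hatched / total laid), not the mean of daily
proportions — pooling weights days by eggs laid and is robust to
zero-egg days.  Crosses with fewer than 10 total eggs are removed (an
insemination control); exactly 10 is retained.  The one-sided rank-sum
test (IC stochastically smaller than CC) is exact when tie-free and
`m + n <= 20`, else a tie-corrected normal approximation — both
routes are provided because the original analysis does not say which
it used.

## What the simulators emulate — and what they do not

Every simulator is deterministic given a seed.

* `sim_tree()` runs a forward birth-death process conditioned on `n`
  extant tips; the present is placed a memoryless exponential epoch
  after the tip count first reaches `n`, which makes the pure-birth
  expected root age exactly `sum_{k=2..n} 1/(birth k)`.
* `sim_alignment()` implements GTR+Gamma with *deterministic*
  codon-position rate multipliers (normalized to mean 1) and
  Gamma(7,7) branch rates normalized to mean 1 across branches.  This
  inverts the inference assumptions well enough to test the divergence
  and scaling layers, but it is *not* the full partitioned model a
  Bayesian reanalysis would fit (no per-partition frequencies or
  exchangeabilities).  Stop codons may arise: the process is
  nucleotide-level.
* `sim_codon_pair_omega()` is codon-level (Goldman-Yang-style):
  synonymous single-nucleotide changes at rate 1, nonsynonymous at
  rate omega, stop codons unreachable, uniform codon frequencies.  `t`
  is calibrated so that at neutrality it equals the expected number of
  nucleotide substitutions per codon along the whole path; regions
  with omega < 1 evolve correspondingly slower, as purifying selection
  does.
* `sim_cladogenic_system()` produces three independent two-taxon
  alignments with expected third-position divergence `2 r T` each.  It
  refuses parameters with `2 r T >= 0.75` (beyond Jukes-Cantor
  saturation) — note this caps how extreme a symbiont:mtDNA rate ratio
  can be simulated at realistic divergences.
* `sim_hatch()` draws cross-level hatch probabilities from beta
  distributions whose concentrations (4.1 IC / 7.1 CC) were chosen
  once to reproduce the published between-cross SDs (0.21 and 0.11)
  at the published means (0.34, 0.89) and sample sizes (14, 18);
  daily egg counts (uniform 5-15) are a realistic invention, as the
  originals are unpublished.
* `sim_posterior()` jitters node ages lognormally and renormalizes —
  it emulates posterior spread, not MCMC autocorrelation or
  topological uncertainty.

A green test against these generators establishes that the analysis
layer recovers what the generator encoded under the stated model; it
does not validate the upstream biology (no recombination, phage
gain/loss, assembly artifacts, or model misspecification are
simulated).

## Known limitations

* Only Jukes-Cantor distances: no K80/GTR pairwise distances and no
  ML codon models; the windowed NG86 omega is a counting estimate with
  a mild upward bias near saturation.
* The published synonymous-divergence columns may have used a counting
  scheme other than NG86 (unstated); only the ratio cells — pure
  arithmetic — are golden-tested against the printed table.
* The random-tree null treats both trees as random; if the intended
  null fixed one observed tree, p-values would differ slightly.
* Crown-age numbers for the real symbiont clades are not
  reproducible without the deposited genomes and an MCMC run; the
  package's recovery suite substitutes synthetic posteriors with known
  truth.
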