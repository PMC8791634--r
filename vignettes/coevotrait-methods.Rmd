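---
title: "Models and methods behind coevotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coevotrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coevotrait` studies how two regulatory sequence features of the epithelial
sodium channel (ENaC) evolved across vertebrates: the paired polybasic
cleavage tracts in the extracellular GRIP domain that proteases (furin,
prostasin) must cut to activate the channel, and the intracellular C-terminal
PY motif through which Nedd4-2 controls channel turnover.  The package covers
the complete chain of analysis: motif detection in a protein alignment,
binary trait matrices, correlated-evolution likelihood models on a fixed gene
tree, likelihood-ratio tests, and Bayesian ancestral reconstruction with
stepping-stone marginal likelihoods and Bayes factors.

## Motif scanning

Cleavage-site detection is anchored: the P1 residue (the residue immediately
N-terminal to the scissile bond) of each reference site — the human α
subunit's proximal and distal furin sites and the human γ subunit's furin and
prostasin sites — is mapped from ungapped reference coordinates to an
alignment column, and every sequence is scanned for candidate P4–P1 4-mers
whose P1 residue falls within ±5 alignment columns of that anchor.

*Why columns?*  The alignment is the only coordinate system shared across
sequences, and "nearby" in homology terms means nearby columns.  The
half-width of 5 is a tunable argument (`window`).

A candidate 4-mer is read from the sequence's own ungapped residues (so a
tract interrupted by alignment gaps is still read as its contiguous
residues).  It is a hit when its P1 residue satisfies the protease rule — Arg
for furin-style scans, Arg or Lys for prostasin-style scans — and the 4-mer
is either an ideal furin site (R-X-R/K-R) or a polybasic tract with at least
two basic residues among the four.  The two-basic threshold is the weakest
operationalization consistent with the tracts reported for this family (the
weakest published tracts, RGVR and VKQR, have exactly two).  When several
candidates fall in one window the scanner keeps the one whose P1 column is
nearest the anchor, breaking ties toward the C-terminus; this makes output
deterministic and single-valued per sequence and site.  A window that
contains no residues at all marks the site *ambiguous* rather than absent —
the region is missing from the available sequence, not motif-free.

PY motifs are searched as `L/P-P-X-Y` within the last 25 ungapped residues of
each sequence, reporting the match nearest the C-terminus.  The 25-residue
bound keeps the search in the C-terminal tail where every published PY motif
of this family sits, and prevents spurious internal matches.  A sequence that
is all gaps over the trailing alignment columns is flagged as C-terminally
truncated and its PY trait coded ambiguous.

ASIC and other non-ENaC outgroup sequences carry the study's explicit trait
assignment rather than scan results: all marine, sites absent except the
coelacanth ASIC2 site-2 tract, and no PY motif (ASIC C-termini lack PY
motifs).

## Trait models

All evolutionary models are continuous-time Markov chains over joint states
of two binary characters, with *dual transitions* (both characters changing
in the same instant) fixed to rate zero — the standard structure for
correlated evolution of discrete characters, and the only structure
consistent with the parameter counts of the fitted models (2 vs 4 and 3 vs
5).

* **Pair family** (two cleavage sites).  The independent model has one gain
  and one loss rate shared by both sites.  The dependent model splits each
  into rates conditional on the other site's presence, adding two free
  parameters.
* **Habitat family** (a trait against terrestrial status or lungs).  The
  independent model has trait gain, trait loss, and a marine→terrestrial (or
  lungs-appearance) rate; the reverse habitat transition is a structural
  zero, since the model families only balance with no reversal parameter and
  the conditioning characters never revert in this dataset.  The dependent
  model splits the trait's gain and loss rates between the two habitat
  states.

Tips observe states through indicator vectors: present and absent tips pin
the character, ambiguous tips (missing sequence regions) allow both values.
The likelihood is computed by Felsenstein pruning with per-node rescaling
(53 tips with small rates can underflow double precision), in compiled code.
Transition probabilities use the closed-form two-state solution where
applicable and otherwise an eigendecomposition of the rate matrix verified by
reconstruction, with scaling-and-squaring as fallback; the R-level
`transition_matrix()` uses the conventional scaling-and-squaring Padé route
and serves as the independent reference in the tests.

**Root prior.**  Uniform over states.  The choice is logged in run metadata;
a stationary-distribution prior is a plausible alternative and can shift
log-likelihoods by up to `log(#states)`, which is one reason exact numerical
agreement with other implementations is not guaranteed.

## Maximum likelihood and the LRT

Rates are optimized in log space (they span orders of magnitude) under box
bounds `[1e-8, 100]`, from 25 restarts drawn log-uniformly; the best restart
is kept and estimates at the lower bound are reported as zero in summaries.
Nested models are compared with the likelihood-ratio statistic
`2 (lnL_dep − lnL_indep)` against a chi-square with df equal to the
difference in parameter counts (2 for every comparison here).  Because null
rates can sit on the boundary of the parameter space, the chi-square
reference is conservative; the calibration helper (`lrt_calibration()`)
measures the realized type-I error by simulation, and the test suite checks
that it is at or below the nominal level.

## MCMC, fossilization, stepping stones

The posterior over rates is sampled by Metropolis–Hastings with a mixture of
proposals: multiplicative lognormal random walks on single rates (step sizes
auto-tuned during burn-in toward 20–40% acceptance), independence draws from
the parameter's prior, log-uniform independence draws across all rate
scales, and a global rate-scaling move.  The latter two address a real
feature of these posteriors: at intermediate stepping-stone temperatures the
tempered posterior separates into a low-rate mode and a saturated-rate mode
with similar rate *ratios*, and a pure random walk mixes between them too
slowly for stable marginal-likelihood estimates.  Chain defaults follow the
study's reported settings: 1,010,000 iterations, with the first 10,000
discarded and every 100th retained.

Priors follow the study's qualitative rule, made concrete: a parameter whose
ML estimate is below 0.01 receives an exponential prior with mean 0.001,
otherwise a uniform(0, 100) prior.  The 0.01 threshold is recorded in run
metadata and adjustable.

Ancestral hypotheses are imposed by *fossilization*: at a named internal
node (the four gene-duplication nodes of the ENaC tree), the partial
likelihoods of disallowed states are zeroed, so the model only integrates
over histories consistent with the hypothesis.  Each retained MCMC sample
also draws a joint realization of all internal-node states (root from its
conditional, then children given parents), from which node posteriors are
simple sample fractions.

Marginal likelihoods use the stepping-stone estimator with 100 powers placed
at quantiles of a Beta(0.4, 1) distribution — the standard placement that
concentrates stones near the prior — and 10,000 iterations per stone, the
first 10% of each stone discarded, each stone's chain continuing from the
previous one.  Log Bayes factors are twice the difference of log marginal
likelihoods, read against the conventional bands (<2 weak, >2 positive, 5–10
strong, >10 very strong).  Because the estimator is stochastic, analyses
default to reporting the mean of 3 independent replicate runs with the
spread as Monte Carlo uncertainty; on two-parameter problems of this size a
single run is accurate to roughly ±0.2 log units and the tests hold it to
within 0.1 log units of deterministic quadrature on toy problems.

## The packaged dataset and its stand-ins

The published trait tables are printed in full and are encoded verbatim
(`enac_site_motifs()`, `enac_py_motifs()`, `enac_trait_table()`): every
cleavage-site 4-mer, dash, and missing-region mark, the species' terrestrial
status and lungs, and the explicit outgroup assignments.

The published 53-sequence maximum-likelihood tree and the underlying
alignment are supplementary files that cannot be redistributed, so the
package ships clearly-labelled synthetic stand-ins:

* `enac_tree_synthetic()` — a 53-tip tree with the described topology (six
  clades; duplication nodes `node1`–`node4`; jawless fishes basal within
  each subunit clade; the α/δ duplication placed before the
  coelacanth–tetrapod divergence) and branch lengths set once from rough
  divergence-time differences (in Myr) times per-clade amino-acid
  substitution rates of about 0.001–0.0017 substitutions/site/Myr, giving a
  root-to-tip depth near 0.8 substitutions/site — typical for a deep
  protein-family tree.
* `enac_alignment_synthetic()` — an 80-column alignment in which the
  published 4-mers sit at the anchored proximal (column 20) and distal
  (column 45) sites, published C-terminal sequences end at the final
  column, missing regions are gap runs, and the background alphabet contains
  no basic residues and no tyrosine, so scanner hits on it are exactly the
  published motifs.

Consequences: analyses driven by the trait coding and tree *shape*
(which model is preferred, which rates hit boundaries, evidence directions)
reproduce the published picture, and indeed every significance call and
Bayes-factor direction matches.  Quantities that depend on the exact
published branch lengths — individual p-values at two significant figures,
Bayes-factor magnitudes, node posterior percentages — differ numerically on
the stand-in tree, and the package makes no attempt to tune the stand-in
toward them.

## The synthetic-data module

`simulate_tree()` draws complete-sampling birth–death trees conditioned on
tip count (optionally rescaled to a fixed total length, since trait
information content is governed by tree length); `simulate_traits()` runs
exact CTMC simulation down the tree; `make_alignment_fixture()` implants
motifs into a basic-residue-free background so scanner truth tables are
exact; `lrt_calibration()` measures test size and power.  Everything is
seed-deterministic.

What the simulations do *not* emulate: sequence evolution (alignments are
fixtures, not substitution-model output), rate heterogeneity across
branches and lineages, alignment error, and tree estimation uncertainty.
Passing tests therefore demonstrate correctness of the inference machinery
under the model, not robustness of the biological conclusions to
misalignment or tree error.

## Numerical choices and limitations

* Optimizer: `L-BFGS-B` on log rates, convergence `factr = 1e4`; nesting
  violations beyond 1e-6 log units raise an error rather than being clipped.
* Pruning rescales whenever a node's partials drop below 1e-100, and the
  matrix-exponential eigenroute verifies its factorization to 1e-9 before
  use.
* Problem sizes in the tests: brute-force oracles enumerate trees of up to 6
  tips; calibration uses 500 null replicates with 4 optimizer restarts per
  fit; recovery checks use 150–200-tip simulated trees.
* State spaces are limited to at most 8 states; more than two jointly
  modelled characters, branch-specific rates, and tree uncertainty are out
  of scope.
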