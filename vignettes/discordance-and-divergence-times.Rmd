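---
title: "Gene-tree discordance and divergence-time estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-tree discordance and divergence-time estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discordtime)
```

## The problem

Phylogenomic divergence-time estimation usually concatenates hundreds of
loci and dates a single, fixed species-tree topology. Individual loci,
however, have their own genealogies, and processes such as incomplete
lineage sorting make a fraction of gene trees topologically incongruent
with the species tree. For a branch of the species tree, the number of
substitutions `n`, the temporal duration `t`, and the substitution rate `r`
are linked by `n = r * t`. When loci whose gene trees lack a species-tree
clade are forced onto the species-tree topology, the substitutions they
contribute to that branch are misassigned, `n` for the branch is
underestimated, and every quantity derived from it — `t` under a clock, `r`
under a relaxed clock — inherits the bias. Branches untouched by the
incongruence (terminal branches in particular, which by construction cannot
be incongruent) absorb the displaced signal and are overestimated.

`discordtime` reproduces this phenomenon and evaluates two mitigation
strategies entirely from simulation:

* **congruent-locus filtering** — keep only loci whose gene trees have at
  most a chosen number of incongruent branches, then concatenate;
* **equivalent-branch averaging** — date every gene tree individually and
  estimate each species branch as the mean over gene-tree branches that are
  *equivalent* to it.

## Study designs generated by the package

`canonical_trees()` builds the species trees and, for the fixed-topology
designs, the alternative gene-tree topology:

* **four_taxon** — `((A,B),(C,D))`, root age 1.0, both internal divergences
  at 0.5. The alternative topology is `((A,C),(B,D))` with identical node
  ages, so incongruence is the *only* difference between loci.
  `simulate_fixed_scheme()` assigns an exact share of the 400 loci
  (0–50%) to the alternative topology.
* **balanced16_swap2 … swap8** — a perfectly balanced 16-taxon tree with
  every branch duration 0.2 (depth 0.8). The alternative topologies swap
  1–4 pairs of terminals reciprocally across the two halves of the tree
  (A↔I, then B↔J, C↔K, D↔L), producing graded incongruence.
* **imbalanced16** — a 16-taxon caterpillar with internal branches 0.2 and
  node ages 0.2, 0.4, …, 3.0. Published descriptions of this design give a
  root age (3.2) that cannot be reconciled with equal 0.2 internal
  branches on an ultrametric caterpillar; the package uses the
  depth-consistent ladder ending at 3.0. Percentage errors are invariant
  to the overall scale, so this choice does not affect any reported
  quantity. The alternative topology swaps terminals A and I, mirroring
  the balanced swap2 design.
* **four_taxon_msc** — `((A,B),(C,D))` with every branch duration 0.2
  (root age 0.4), used for the coalescent design below.

`simulate_msc()` draws gene trees from a multispecies coalescent on any of
these species trees: one haploid lineage per species, exponential waiting
times at rate `k(k-1)/(2 Ne)` for `k` lineages inside each species-tree
branch (time measured in species-tree units), with uncoalesced lineages
passed rootward. With `Ne = 0.12` and internal branches of duration 0.2,
an isolated internal branch is congruent in a fraction
`1 - (2/3) exp(-0.2/0.12) = 87.4%` of gene trees, and the balanced
16-taxon tree averages close to 87% across its internal branches — the
calibration the whole coalescent design rests on. This convention for the
coalescent rate is the only one that reproduces that calibration.

`simulate_jc_alignment()` evolves 800 bp of DNA per locus along each gene
tree under Jukes–Cantor at rate 0.05 substitutions/site/time: uniform root
states, per-site survival probability `1/4 + 3/4 exp(-4/3 r t)` per branch.
No rate heterogeneity, indels, or other substitution models are simulated.

## Estimation

All estimators run on a compiled Jukes–Cantor pruning likelihood with
site-pattern compression.

**Strict-clock dating** (`estimate_t_strict_clock()`) maximises the
likelihood over internal node ages with the root age fixed to the species
tree's root age and tips at 0. The search works on substitution-scale node
heights (`h = rate * age`), where branch lengths are plain height
differences; coordinate-wise Brent updates then converge quickly because
the strong trade-off between the rate and all node ages disappears — a free
clock rate is nothing but a free root height. Convergence is declared when
a full sweep improves the log-likelihood by less than 1e-8 (capped at 500
sweeps), and by default two jittered restarts guard against local optima.
With `rate = "free"` the rate is box-constrained to `[1e-6, 1]`, standing
in for a uniform rate prior; the fixed-rate mode (0.05) is used for the
fixed-topology designs where the simulation rate is the natural calibration,
and the free rate for coalescent data, whose gene trees are genuinely
deeper than the species tree that supplies the root calibration.

**Unrooted branch lengths** (`estimate_n_unrooted()`) estimate `n` per
branch on the unrooted topology. Under a reversible model the root position
carries no information, so the two root-adjacent branches are estimated as
one merged branch and reported jointly; their error is assessed against the
sum of the two true values.

**Fixed-time rates** (`estimate_r_fixed_times()`) compute
maximum-a-posteriori per-branch rates with all node ages pinned to the true
chronogram, under independent lognormal priors with real-scale mean `m` and
log-scale standard deviation `v`. This parameterisation is the one under
which the two published regimes separate cleanly: `v = 0.001` pins rates to
within a fraction of a percent of `m` even against genome-scale data, while
`v = 0.1` is weak enough that rate errors track the substitution-count
errors almost exactly. Interpreting `v` as a real-scale variance instead
makes even the "low variance" prior too weak to matter against several
hundred thousand sites, which contradicts the reported behaviour, so that
reading was rejected.

## Congruence and equivalence

All topology comparison is clade-based and rooted. A species branch is
identified by its descendant clade (the tip set below its child node);
a gene tree is *congruent* for that branch when it contains the same clade.
`branch_incongruence()` reports the per-branch percentage of gene trees
lacking the clade — terminal branches are never incongruent.
`filter_gene_trees()` retains loci whose gene trees have at most a chosen
number of incongruent branches.

A gene-tree branch is *equivalent* to a species branch
(`is_equivalent_branch()`) only when the clades below both its child node
and its parent node match the species branch's descendant and ancestral
clades — strictly stronger than congruence, because a branch that subtends
the right clade but arises from a different parent split is not the same
branch. With incomplete taxon sampling the species clades are first
intersected with the gene tree's taxa; a branch whose restricted descendant
clade becomes empty or collapses onto the restricted ancestral clade is
untestable and excluded from denominators. For a child of the root the
ancestral clade is the full taxon set, so an equivalent gene branch must
itself hang off the gene tree's root.

`run_congruent_branches()` dates every gene tree on its own topology with
the root fixed to the species root age, then averages durations over
equivalent branches. Per-locus datings default to zero restarts: the
coordinate fits are smooth in practice and the estimator averages across
hundreds of loci. No confidence intervals are produced for this method and
the per-branch means are deliberately not reassembled into a single
chronogram — different branches are informed by different gene-tree
subsets, so the implied tip times need not align, which the package treats
as an accepted property rather than an error.

## Experiment drivers and summaries

`fixed_scheme_experiment()` runs one fixed-topology data set end to end;
`msc_experiment()` runs replicated coalescent data sets (fresh gene trees
and sequences per replicate) and collects, per method: class-mean
percentage errors (`100 (estimate - truth)/truth`, averaged without
weights over branches within the internal/terminal class and then over
replicates), node-age errors (root excluded, since its age is fixed by the
calibration; nodes are classed as subtending internal branches when at
least one child branch is internal), per-replicate mean internal-branch
congruence, and pooled per-branch errors for incongruence-binned curves
(`incongruence_error_curve()`, 5-point bins).

The canonical problem sizes used throughout the package's own checks are
400 loci of 800 bp for every design, with 10 independent replicates for the
balanced 16-taxon coalescent experiment; fixed-topology designs are single
runs, as their only randomness is the sequence simulation.

## Numerical choices and degenerate inputs

* Log-likelihood convergence tolerance 1e-8; per-coordinate Brent with
  relative tolerance 1e-7; branch lengths bracketed in `[0, 10]`
  substitutions/site; free rates in `[1e-6, 1]`.
* Node ages maintain `child < parent` with a margin of `1e-9 * root_age`.
* Ultrametricity is validated to 1e-9 absolute; newick round-trips
  preserve ages to better than 1e-10.
* Gaps/unknown states carry a flat partial likelihood; a two-taxon
  alignment is estimated by the closed-form JC distance, and a saturated
  two-taxon alignment (mismatch at or above 3/4) is an error.
* Species branches with zero equivalent gene-tree branches yield `NA` plus
  a warning — never a silent fallback to another estimator.

## What the simulations do and do not show

The generators emulate exactly the processes whose consequences are under
study: topological incongruence with identical node ages (fixed schemes)
and coalescent incongruence with genuinely older gene divergences (MSC
schemes). They do not emulate gene-tree estimation error, alignment error,
substitution-model misspecification, rate variation among sites or
lineages, gene flow, or fossil-calibration uncertainty. Passing checks
therefore demonstrate the *logic* of the bias and its mitigations, not the
magnitude of any of these additional effects in empirical data.

Two reported quantities from the original study are not reproducible under
its stated design, and the package makes no attempt to force them: the
equivalent-branch class errors for the balanced coalescent design (the
idealized estimator applied to the true gene trees — no sequence noise at
all — already yields roughly -12% internal / +24% terminal, because a few
percent of equivalent cherries coalesce far above the species divergence
yet retain their clade), and the concatenated internal error for the
four-taxon coalescent design, where joint maximum likelihood on the
constrained clock surface settles near -21% rather than -50%. The package
reports what the stated model actually produces.
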