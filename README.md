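# discordtime

Simulation and inference tools for a question that sits under every
phylogenomic timetree: **what does gene-tree/species-tree topological
incongruence do to branch-wise estimates of substitutions (n), times (t),
and rates (r)?** The three are welded together by `n = r * t` on every
branch, so substitutions misassigned by forcing discordant loci onto a
single species-tree topology propagate into divergence times under a clock
and into branch rates under a relaxed clock.

The package is aimed at molecular evolutionists and method developers who
want a fully scripted, fully synthetic testbed: it generates the data
(fixed-topology gene-tree mixtures, multispecies-coalescent gene trees,
Jukes–Cantor alignments), estimates the parameters (maximum-likelihood
strict-clock dating with a fixed root calibration, unrooted branch
lengths, fixed-time MAP branch rates under a lognormal prior), and
implements two mitigation strategies:

* **congruent-locus filtering** — concatenate only loci whose gene trees
  are (nearly) congruent with the species tree;
* **equivalent-branch averaging** — date every gene tree separately and
  estimate each species branch as the mean over gene-tree branches whose
  descendant *and* ancestral clades both match that branch.

Core quantities, in the field's usual notation: for a species-tree branch
with duration `t` and clock rate `r`, the expected substitutions per site
are `n = r t`; the per-branch incongruence of a gene-tree set is the
percentage of gene trees lacking a branch with the same descendant clade;
under the multispecies coalescent with population size `Ne`, `k` lineages
coalesce at rate `k(k-1)/(2 Ne)`, and an isolated internal branch of
duration `t` is congruent with probability `1 - (2/3) e^{-t/Ne}` (87.4%
for the canonical `t = 0.2`, `Ne = 0.12`).

## A worked example

Four taxa, 400 loci of 800 bp, half the loci simulated on the alternative
topology `((A,C),(B,D))` with the same node ages as the species tree:

```r
library(discordtime)

dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0.5,
                        n_loci = 400, seq_length = 800, seed = 1)

# all loci concatenated, strict clock (rate 0.05), root fixed at 1.0
concat <- run_concatenated(dat$alignments, dat$species, param = "t",
                           rate = 0.05)
round(class_mean_errors(concat$table), 1)
#> internal terminal
#>    -50.4     50.4

# keep only the 200 congruent loci
filt <- run_congruent_loci(dat$alignments, dat$genes, dat$species, 0,
                           param = "t", rate = 0.05)
round(class_mean_errors(filt$table), 1)
#> internal terminal
#>      0.2     -0.2

# equivalent-branch averaging across individually dated gene trees
br <- run_congruent_branches(dat$alignments, dat$genes, dat$species,
                             param = "t", rate = 0.05)
round(class_mean_errors(br$table), 1)
#> internal terminal
#>      0.2     -0.2
```

Read: concatenating 50% discordant loci halves the internal branch
durations (≈ −51%) and pushes the lost time onto the terminals (+51%),
while either mitigation collapses the error to well under a percent.
Replicated multispecies-coalescent experiments on a balanced 16-taxon tree
(`msc_experiment("balanced16", ...)`) show the same structure with
coalescent-generated discordance, plus the additional distortion caused by
gene divergences predating species divergences.

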