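test_that("incongruent branch counts match hand enumeration", {
  ct <- canonical_trees("four_taxon")
  expect_identical(count_incongruent_branches(ct$species, ct$incongruent), 2L)
  expect_identical(count_incongruent_branches(ct$species, ct$species), 0L)

  sw <- canonical_trees("balanced16_swap2")
  # A<->I displaces clades AB, IJ, ABCD, IJKL, and both root halves
  expect_identical(count_incongruent_branches(sw$species, sw$incongruent), 6L)
})

test_that("per-branch incongruence counts over a constructed set", {
  ct <- canonical_trees("four_taxon")
  genes <- simulate_fixed_scheme(ct$species, ct$incongruent, 0.3,
                                 n_loci = 400, seed = 41)
  inc <- branch_incongruence(ct$species, genes)
  expect_equal(inc$percent_incongruent[!inc$terminal], c(30, 30))
  expect_equal(inc$percent_incongruent[inc$terminal], rep(0, 4))
  expect_equal(inc$n_considered, rep(400L, 6))
  expect_error(branch_incongruence(ct$species, list()), "empty")
})

test_that("filtering retains exactly the near-congruent gene trees", {
  ct <- canonical_trees("four_taxon")
  genes <- simulate_fixed_scheme(ct$species, ct$incongruent, 0.5,
                                 n_loci = 400, seed = 42)
  kept <- filter_gene_trees(genes, ct$species, max_incongruent = 0)
  expect_length(kept, 200)
  expect_identical(attr(kept, "retained"), !attr(genes, "incongruent"))
  inc_after <- branch_incongruence(ct$species, kept)
  expect_true(all(inc_after$percent_incongruent == 0))

  all_kept <- filter_gene_trees(genes, ct$species, max_incongruent = 99)
  expect_length(all_kept, 400)
  expect_warning(filter_gene_trees(genes[attr(genes, "incongruent")],
                                   ct$species, 0), "no gene tree")
})

test_that("equivalence requires both descendant and ancestral clades", {
  sp <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  # species branch above the AB clade: ancestral clade is the full taxon set
  cp <- clade_pair(c("A", "B"), c("A", "B", "C", "D"))
  keyed <- function(g) {
    ck <- clade_keys(g)
    as.integer(names(ck)[ck == "A|B"])
  }
  ident <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  expect_true(is_equivalent_branch(cp, ident, keyed(ident)))

  # same descendant clade but a different parent split: congruent, not
  # equivalent
  ladder <- read_newick("(((A:0.3,B:0.3):0.3,C:0.6):0.4,D:1);")
  expect_true("A|B" %in% clade_keys(ladder))
  expect_false(is_equivalent_branch(cp, ladder, keyed(ladder)))

  # incomplete sampling: the induced clades decide
  part_ok <- read_newick("((A:0.5,B:0.5):0.5,C:1);")
  expect_true(is_equivalent_branch(cp, part_ok, keyed(part_ok)))
  part_bad <- read_newick("((A:0.5,C:0.5):0.5,B:1);")
  ckb <- clade_keys(part_bad)
  expect_false(any(vapply(as.integer(names(ckb)), function(nd)
    is_equivalent_branch(cp, part_bad, nd), TRUE)))
})

test_that("equivalence maps cover congruent trees and only them", {
  ct <- canonical_trees("four_taxon")
  genes <- simulate_fixed_scheme(ct$species, ct$incongruent, 0.5,
                                 n_loci = 80, seed = 43)
  emap <- build_equivalence_map(ct$species, genes)
  congruent <- which(!attr(genes, "incongruent"))
  for (key in c("A|B", "C|D", "A", "B", "C", "D")) {
    expect_setequal(emap[[key]]$gene, congruent)
  }
})

test_that("equivalence implies descendant-clade congruence", {
  set.seed(44)
  labs <- paste0("t", 1:8)
  for (i in 1:25) {
    sp <- random_timetree(8, labs)
    gt <- random_timetree(8, labs)
    emap <- build_equivalence_map(sp, list(gt))
    gkeys <- clade_keys(gt)
    for (key in names(emap)) {
      if (nrow(emap[[key]]) == 0) next
      expect_true(key %in% gkeys)
    }
  }
})

test_that("clade pairs validate their subset structure", {
  expect_error(clade_pair(c("A", "B"), c("A", "B")))
  expect_error(clade_pair(character(0), c("A", "B")))
  expect_silent(clade_pair("A", c("A", "B")))
})
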