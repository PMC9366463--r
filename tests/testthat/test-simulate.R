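test_that("canonical trees match the study designs", {
  ft <- canonical_trees("four_taxon")
  expect_equal(root_age(ft$species), 1.0)
  expect_identical(sort(unname(clade_keys(ft$incongruent))),
                   sort(c("A", "B", "C", "D", "A|C", "B|D")))
  inc_bt <- branch_table(ft$incongruent)
  expect_equal(inc_bt$duration[inc_bt$clade == "A|C"], 0.5)

  fm <- canonical_trees("four_taxon_msc")
  expect_equal(root_age(fm$species), 0.4)

  b16 <- canonical_trees("balanced16")$species
  bt <- branch_table(b16)
  expect_equal(bt$duration, rep(0.2, 30), tolerance = 1e-12)
  depths <- ape::node.depth.edgelength(b16$phy)[1:16]
  expect_equal(depths, rep(0.8, 16), tolerance = 1e-12)

  im <- canonical_trees("imbalanced16")$species
  expect_equal(root_age(im), 3.0)
  ibt <- branch_table(im)
  expect_equal(sort(ibt$duration[!ibt$terminal]), rep(0.2, 14))
  expect_equal(sort(ibt$duration[ibt$terminal]),
               c(0.2, seq(0.2, 3.0, by = 0.2)), tolerance = 1e-12)

  expect_error(canonical_trees("nope"), "unknown scheme")
})

test_that("tip-swap schemes share ages with the species tree", {
  for (scheme in paste0("balanced16_swap", c(2, 4, 6, 8))) {
    ct <- canonical_trees(scheme)
    expect_setequal(ct$species$phy$tip.label, ct$incongruent$phy$tip.label)
    expect_equal(sort(ct$incongruent$ages), sort(ct$species$ages))
  }
  # the swap2 gene tree displaces exactly two terminals (A and I)
  ct <- canonical_trees("balanced16_swap2")
  expect_true("B|I" %in% clade_keys(ct$incongruent))
  expect_true("A|J" %in% clade_keys(ct$incongruent))
})

test_that("fixed-scheme sets hit configured incongruent counts exactly", {
  ct <- canonical_trees("four_taxon")
  genes <- simulate_fixed_scheme(ct$species, ct$incongruent, 0.3,
                                 n_loci = 400, seed = 5)
  expect_length(genes, 400)
  expect_identical(sum(attr(genes, "incongruent")), 120L)
  inc <- branch_incongruence(ct$species, genes)
  expect_equal(inc$percent_incongruent[inc$clade %in% c("A|B", "C|D")],
               c(30, 30))
  expect_equal(inc$percent_incongruent[inc$terminal], rep(0, 4))

  all_cong <- simulate_fixed_scheme(ct$species, ct$incongruent, 0,
                                    n_loci = 10, seed = 1)
  expect_true(all(vapply(all_cong, function(g)
    setequal(clade_keys(g), clade_keys(ct$species)), TRUE)))
})

test_that("JC sequence simulation obeys the closed forms", {
  # zero duration: child identical to parent
  tt0 <- as_timetree(ape::read.tree(text = "(A:0,B:0);"))
  a0 <- simulate_jc_alignment(tt0, 500, 0.05, seed = 1)
  expect_identical(a0$states["A", ], a0$states["B", ])

  # pairwise mismatch at distance 2*r*t within 3 Monte-Carlo SEs
  tt <- read_newick("(A:0.5,B:0.5);")
  L <- 1e5
  a <- simulate_jc_alignment(tt, L, 0.05, seed = 2)
  p_obs <- mean(a$states["A", ] != a$states["B", ])
  p_exp <- jc_mismatch(2 * 0.5 * 0.05)
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # stationary base composition
  freq <- tabulate(a$states, 4) / (2 * L)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("the coalescent simulator matches the two-lineage closed form", {
  # species tree with one isolated internal branch of duration 0.2:
  # P(congruent clade AB) = 1 - (2/3) exp(-t/Ne)
  tt <- read_newick("((A:0.2,B:0.2):0.2,C:0.4);")
  n <- 3000
  g <- simulate_msc(tt, ne = 0.12, n_loci = n, seed = 9)
  inc <- branch_incongruence(tt, g)
  p_obs <- (100 - inc$percent_incongruent[inc$clade == "A|B"]) / 100
  p_exp <- 1 - (2 / 3) * exp(-0.2 / 0.12)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("gene-tree divergences predate species divergences", {
  sp <- canonical_trees("balanced16")$species
  sp_ages <- pair_mrca_ages(sp)
  g <- simulate_msc(sp, ne = 0.12, n_loci = 25, seed = 13)
  labs <- sp$phy$tip.label
  for (gt in g) {
    ga <- pair_mrca_ages(gt)[labs, labs]
    expect_true(all(ga - sp_ages[labs, labs] >= -1e-9))
  }
  # Ne -> 0 limit: gene root age collapses onto the species divergence
  two <- read_newick("(A:1,B:1);")
  g2 <- simulate_msc(two, ne = 1e-8, n_loci = 5, seed = 3)
  expect_true(all(vapply(g2, root_age, 0) - 1 < 1e-6))
})

test_that("simulation is reproducible under a seed", {
  sp <- canonical_trees("balanced16")$species
  a <- write_newick(simulate_msc(sp, 0.12, 5, seed = 77))
  b <- write_newick(simulate_msc(sp, 0.12, 5, seed = 77))
  expect_identical(a, b)
  s1 <- simulate_jc_alignment(sp, 100, 0.05, seed = 7)
  s2 <- simulate_jc_alignment(sp, 100, 0.05, seed = 7)
  expect_identical(s1$states, s2$states)
})
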