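test_that("concatenation appends columns and pads missing taxa", {
  tt <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  a1 <- simulate_jc_alignment(tt, 30, 0.05, seed = 51)
  a2 <- simulate_jc_alignment(tt, 50, 0.05, seed = 52)
  cc <- concatenate_alignments(list(a1, a2))
  expect_equal(n_sites(cc), 80)
  expect_equal(attr(cc, "locus_boundaries"), c(30L, 80L))
  expect_identical(concatenate_alignments(list(a1)), a1)

  # a taxon absent from one locus becomes gaps there
  sub <- new_jc_alignment(a2$states[c("A", "B", "C"), ])
  cc2 <- concatenate_alignments(list(a1, sub))
  expect_true(all(cc2$states["D", 31:80] == 0L))

  # locus order cannot change the concatenated likelihood
  ll1 <- jc_log_likelihood(tt, concatenate_alignments(list(a1, a2)),
                           rate = 0.05)
  ll2 <- jc_log_likelihood(tt, concatenate_alignments(list(a2, a1)),
                           rate = 0.05)
  expect_equal(ll1, ll2)
})

test_that("an infinite filter threshold reduces to the concatenated run", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0.5,
                          n_loci = 30, seq_length = 300, seed = 53)
  a <- run_concatenated(dat$alignments, dat$species, param = "t",
                        rate = 0.05)
  b <- run_congruent_loci(dat$alignments, dat$genes, dat$species,
                          max_incongruent = 99, param = "t", rate = 0.05)
  expect_equal(b$table$estimate, a$table$estimate, tolerance = 1e-9)
  expect_equal(b$retained_fraction, 1)
})

test_that("congruent-branch averaging recovers clock-true data", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0,
                          n_loci = 30, seq_length = 800, seed = 54)
  res <- run_congruent_branches(dat$alignments, dat$genes, dat$species,
                                param = "t", rate = 0.05)
  expect_true(all(res$table$n_used == 30))
  pe <- percent_error(res$table)
  expect_true(all(abs(pe$percent_error) < 3))
})

test_that("both mitigation methods remove the concatenation bias", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0.5,
                          n_loci = 100, seq_length = 800, seed = 55)
  concat <- class_mean_errors(
    run_concatenated(dat$alignments, dat$species, param = "t",
                     rate = 0.05)$table)
  filt <- class_mean_errors(
    run_congruent_loci(dat$alignments, dat$genes, dat$species, 0,
                       param = "t", rate = 0.05)$table)
  branch <- class_mean_errors(
    run_congruent_branches(dat$alignments, dat$genes, dat$species,
                           param = "t", rate = 0.05)$table)
  expect_lt(concat[["internal"]], -40)
  expect_lt(abs(filt[["internal"]]), abs(concat[["internal"]]) / 10)
  expect_lt(abs(branch[["internal"]]), abs(concat[["internal"]]) / 10)
})

test_that("species branches without equivalents stay missing", {
  ct <- canonical_trees("four_taxon")
  genes <- simulate_fixed_scheme(ct$species, ct$incongruent, 1,
                                 n_loci = 10, seed = 56)
  alns <- lapply(genes, simulate_jc_alignment, seq_length = 100,
                 rate = 0.05)
  expect_warning(
    res <- run_congruent_branches(alns, genes, ct$species, param = "t",
                                  rate = 0.05),
    "no equivalent")
  expect_true(all(is.na(res$table$estimate)))
  expect_true(all(res$table$n_used == 0))
})

test_that("congruent-branch estimation of n averages unrooted lengths", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0,
                          n_loci = 40, seq_length = 800, seed = 57)
  expect_warning(
    res <- run_congruent_branches(dat$alignments, dat$genes, dat$species,
                                  param = "n", rate = 0.05),
    "no equivalent")
  tab <- res$table
  # root-adjacent branches are unidentifiable per locus and stay missing
  expect_true(all(is.na(tab$estimate[tab$class == "internal"])))
  pe <- percent_error(tab[tab$class == "terminal", ])
  expect_true(all(abs(pe$percent_error) < 10))
})
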