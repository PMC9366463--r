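test_that("two-taxon branch length equals the closed-form JC distance", {
  tt <- read_newick("(A:0.5,B:0.5);")
  aln <- simulate_jc_alignment(tt, 2e4, 0.05, seed = 31)
  est <- estimate_n_unrooted(aln, tt)
  p <- mean(aln$states["A", ] != aln$states["B", ])
  expect_equal(est$n_hat, -0.75 * log(1 - 4 / 3 * p), tolerance = 1e-10)
  expect_true(est$root_sum)
})

test_that("parameters are recovered without incongruence", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0,
                          n_loci = 50, seq_length = 800, seed = 32)
  # t: strict clock, fixed true rate
  rt <- run_concatenated(dat$alignments, dat$species, param = "t",
                         rate = 0.05)
  pe <- percent_error(rt$table)
  expect_true(all(abs(pe$percent_error) < 2))
  # n: unrooted branch lengths around r * t
  rn <- run_concatenated(dat$alignments, dat$species, param = "n",
                         rate = 0.05)
  pen <- percent_error(rn$table)
  expect_true(all(abs(pen$percent_error[!is.na(pen$estimate)]) < 5))
  # free rate recovers the simulation rate
  rf <- estimate_t_strict_clock(concatenate_alignments(dat$alignments),
                                dat$species, root_age = 1, rate = "free")
  expect_equal(attr(rf, "rate"), 0.05, tolerance = 0.05)
})

test_that("strict-clock output is ultrametric with the root pinned", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0.5,
                          n_loci = 20, seq_length = 400, seed = 33)
  fit <- estimate_t_strict_clock(concatenate_alignments(dat$alignments),
                                 dat$species, root_age = 1, rate = 0.05)
  expect_equal(root_age(fit), 1.0)
  expect_true(validate_timetree(fit, ultrametric = TRUE, tol = 1e-8))
  # sister terminals share their parent's age, hence identical durations
  bt <- branch_table(fit)
  expect_equal(bt$duration[bt$clade == "A"], bt$duration[bt$clade == "B"])
  expect_equal(bt$duration[bt$clade == "C"], bt$duration[bt$clade == "D"])
})

test_that("time-estimate error shrinks with alignment length", {
  rmse <- vapply(c(200, 1600, 12800), function(L) {
    dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0,
                            n_loci = 1, seq_length = L, seed = 34)
    fit <- run_concatenated(dat$alignments, dat$species, param = "t",
                            rate = 0.05)
    pe <- percent_error(fit$table)
    sqrt(mean(pe$percent_error^2))
  }, 0)
  expect_true(rmse[2] < rmse[1] && rmse[3] < rmse[2])
})

test_that("rate estimation responds to the UCLN prior as designed", {
  dat <- simulate_dataset("four_taxon", process = "fixed", fraction = 0.5,
                          n_loci = 30, seq_length = 800, seed = 35)
  aln <- concatenate_alignments(dat$alignments)
  # degenerate prior: strict clock at m
  r0 <- estimate_r_fixed_times(aln, dat$species, m = 0.05, v = 0)
  expect_true(all(r0$r_hat == 0.05))
  # tight prior pins rates near m despite 50% incongruence
  r1 <- estimate_r_fixed_times(aln, dat$species, m = 0.05, v = 0.001)
  expect_true(all(abs(r1$r_hat / 0.05 - 1) < 0.02))
  # diffuse prior lets rates track the (biased) substitution signal
  r2 <- estimate_r_fixed_times(aln, dat$species, m = 0.05, v = 0.1)
  internal <- r2$clade %in% c("A|B", "C|D")
  expect_true(all(r2$r_hat[internal] < 0.04))
  # zero-duration branches are rejected
  degen <- as_timetree(ape::read.tree(text = "((A:0,B:0):1,C:1);"))
  a3 <- simulate_jc_alignment(random_timetree(3, c("A", "B", "C")), 50,
                              0.05, seed = 2)
  expect_error(estimate_r_fixed_times(a3, degen, m = 0.05, v = 0.1),
               "zero-duration")
})
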