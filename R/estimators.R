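# The three species-tree estimation strategies: concatenated analysis,
# congruent-loci filtering, and the congruent-branch (equivalent-branch
# averaging) estimator.

# Branch-estimate table skeleton from a species tree: truth per branch.
truth_table <- function(species, param, true_rate = 0.05) {
  bt <- branch_table(species)
  truth <- switch(param,
    t = bt$duration,
    n = true_rate * bt$duration,
    r = rep(true_rate, nrow(bt)))
  data.frame(node = bt$node, clade = bt$clade,
             class = ifelse(bt$terminal, "terminal", "internal"),
             truth = truth, stringsAsFactors = FALSE)
}

#' Concatenated estimation on the fixed species topology
#'
#' Concatenates all loci and estimates the requested parameter on the fixed
#' species-tree topology: `t` by strict-clock dating ([estimate_t_strict_clock]),
#' `n` by unrooted ML branch lengths ([estimate_n_unrooted]; the two
#' root-adjacent branches are reported as their identifiable sum), `r` by
#' fixed-time MAP rates ([estimate_r_fixed_times]).
#'
#' @param alignments list of `jc_alignment`s (or one already-concatenated
#'   alignment).
#' @param species a `timetree` (also supplies the truth for error columns).
#' @param param `"t"`, `"n"` or `"r"`.
#' @param rate clock rate for dating: numeric (fixed) or `"free"`.
#' @param root_age root calibration; defaults to the species-tree root age.
#' @param true_rate simulation rate used to fill the truth for `n`/`r`.
#' @param m,v UCLN prior moments (for `param = "r"`).
#' @param ... passed to the underlying estimator.
#' @return list with `table` (one row per species branch: `node`, `clade`,
#'   `class`, `truth`, `estimate`, `method`) and `fit` (the estimator's
#'   native output, e.g. the fitted `timetree` for `param = "t"`).
#' @export
run_concatenated <- function(alignments, species, param = "t", rate = 0.05,
                             root_age = NULL, true_rate = 0.05, m = 0.05,
                             v = 0.1, ...) {
  param <- match.arg(param, c("t", "n", "r"))
  aln <- concatenate_alignments(alignments)
  if (is.null(root_age)) root_age <- root_age(species)
  tab <- truth_table(species, param, true_rate)
  if (param == "t") {
    fit <- estimate_t_strict_clock(aln, species, root_age = root_age,
                                   rate = rate, ...)
    est_bt <- branch_table(fit)
    tab$estimate <- est_bt$duration[match(tab$node, est_bt$node)]
  } else if (param == "n") {
    fit <- estimate_n_unrooted(aln, species, ...)
    tab$estimate <- fit$n_hat[match(tab$clade, fit$clade)]
    rs_clade <- fit$clade[fit$root_sum]
    if (length(rs_clade) == 1L) {
      # the merged branch carries the sum of the two root-adjacent truths
      root <- ape::Ntip(species$phy) + 1L
      kids <- species$phy$edge[species$phy$edge[, 1] == root, 2]
      pair <- tab$node %in% kids
      tab$truth[tab$clade == rs_clade] <- sum(tab$truth[pair])
      tab$estimate[pair & tab$clade != rs_clade] <- NA_real_
    }
  } else {
    fit <- estimate_r_fixed_times(aln, species, m = m, v = v, ...)
    tab$estimate <- fit$r_hat[match(tab$node, fit$node)]
  }
  tab$method <- "concatenated"
  list(table = tab, fit = fit)
}

#' Concatenated estimation restricted to near-congruent loci
#'
#' Filters loci whose gene trees have at most `max_incongruent` incongruent
#' branches with the species tree, then runs [run_concatenated] on the
#' retained loci.
#'
#' @inheritParams run_concatenated
#' @param genes list of gene `timetree`s, aligned with `alignments`.
#' @param max_incongruent retention threshold (0 = fully congruent loci).
#' @return as [run_concatenated], plus `retained_fraction`.
#' @export
run_congruent_loci <- function(alignments, genes, species,
                               max_incongruent = 0, param = "t",
                               rate = 0.05, root_age = NULL,
                               true_rate = 0.05, ...) {
  kept <- filter_gene_trees(genes, species, max_incongruent)
  keep <- attr(kept, "retained")
  if (!any(keep)) stop("no loci retained by the congruence filter")
  res <- run_concatenated(alignments[keep], species, param = param,
                          rate = rate, root_age = root_age,
                          true_rate = true_rate, ...)
  res$table$method <- sprintf("congruent_loci<=%d", max_incongruent)
  res$retained_fraction <- mean(keep)
  res
}

#' Congruent-branch (equivalent-branch averaging) estimation
#'
#' Each gene tree is analysed individually on its own topology — dated by
#' strict clock with the root fixed to the species-tree root age for
#' `param = "t"`, or given unrooted ML branch lengths for `param = "n"` —
#' and the species-tree estimate for a branch is the arithmetic mean over
#' the gene-tree branches that are equivalent to it (descendant and
#' ancestral clades both matching; see [is_equivalent_branch]). Species
#' branches with no equivalent branch in any gene tree yield `NA` and a
#' warning. No re-ultrametricisation is performed: sister terminal estimates
#' need not agree, mirroring the method's conceptual caveats.
#'
#' @inheritParams run_congruent_loci
#' @param param `"t"` or `"n"`.
#' @param restarts jittered restarts for each per-locus dating (default 0:
#'   the per-locus coordinate fits are smooth, and averaging across hundreds
#'   of loci makes restart insurance redundant).
#' @return list with `table` (columns as [run_concatenated] plus `n_used`,
#'   the number of gene trees contributing to each branch).
#' @export
run_congruent_branches <- function(alignments, genes, species, param = "t",
                                   rate = 0.05, root_age = NULL,
                                   true_rate = 0.05, restarts = 0, ...) {
  param <- match.arg(param, c("t", "n"))
  if (is.null(root_age)) root_age <- root_age(species)
  emap <- build_equivalence_map(species, genes)
  # per-locus branch estimates keyed by gene child node
  per_locus <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    needed <- any(vapply(emap, function(df) any(df$gene == j), TRUE))
    if (!needed) next
    if (param == "t") {
      fit <- estimate_t_strict_clock(alignments[[j]], genes[[j]],
                                     root_age = root_age, rate = rate,
                                     restarts = restarts, ...)
      bt <- branch_table(fit)
      per_locus[[j]] <- setNames(bt$duration, bt$node)
    } else {
      fit <- estimate_n_unrooted(alignments[[j]], genes[[j]], ...)
      bt <- branch_table(genes[[j]])
      vals <- fit$n_hat[match(bt$clade, fit$clade)]
      vals[bt$clade %in% fit$clade[fit$root_sum]] <- NA_real_
      per_locus[[j]] <- setNames(vals, bt$node)
    }
  }
  tab <- truth_table(species, param, true_rate)
  tab$estimate <- NA_real_
  tab$n_used <- 0L
  for (i in seq_len(nrow(tab))) {
    df <- emap[[tab$clade[i]]]
    if (nrow(df) == 0L) next
    vals <- vapply(seq_len(nrow(df)), function(k)
      per_locus[[df$gene[k]]][[as.character(df$gene_node[k])]], 0)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) next
    tab$estimate[i] <- mean(vals)
    tab$n_used[i] <- length(vals)
  }
  if (anyNA(tab$estimate))
    warning("species branches with no equivalent gene-tree branch: ",
            paste(tab$clade[is.na(tab$estimate)], collapse = ", "))
  tab$method <- "congruent_branches"
  list(table = tab)
}
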