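# Replicated experiment drivers and percentage-error summaries.

#' Percentage errors of a branch-estimate table
#'
#' Adds `percent_error = 100 * (estimate - truth) / truth` and returns the
#' table; class means are available via [class_mean_errors()].
#'
#' @param table a branch-estimate table from one of the `run_*` estimators.
#' @export
percent_error <- function(table) {
  if (any(table$truth == 0, na.rm = TRUE))
    stop("zero truth: percentage error undefined")
  table$percent_error <- 100 * (table$estimate - table$truth) / table$truth
  table
}

#' Class-mean percentage errors
#'
#' Unweighted mean of per-branch percentage errors within each branch class
#' (internal / terminal). `NA` estimates (e.g. unresolved root-adjacent
#' branches of an unrooted analysis, or species branches with no equivalent
#' gene-tree branch) are dropped.
#'
#' @param table a branch-estimate table.
#' @return named numeric vector with elements `internal` and `terminal`.
#' @export
class_mean_errors <- function(table) {
  pe <- percent_error(table)
  vapply(c(internal = "internal", terminal = "terminal"), function(cl) {
    v <- pe$percent_error[pe$class == cl & !is.na(pe$estimate)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, 0)
}

#' Node-age percentage errors
#'
#' Compares estimated against true internal node ages. The root is excluded
#' (its age is fixed by the calibration). Nodes are classed by the branches
#' they subtend: `subtending_internal` when at least one child branch is
#' internal, `subtending_terminal` when all child branches are terminal.
#'
#' @param fit the estimated `timetree`.
#' @param truth the true `timetree` (same topology).
#' @return data.frame with `node`, `class`, `truth`, `estimate`,
#'   `percent_error`.
#' @export
node_age_errors <- function(fit, truth) {
  phy <- truth$phy
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  nodes <- setdiff(ntip + seq_len(phy$Nnode), root)
  cls <- vapply(nodes, function(v) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    if (any(kids > ntip)) "subtending_internal" else "subtending_terminal"
  }, "")
  df <- data.frame(node = nodes, class = cls,
                   truth = truth$ages[nodes], estimate = fit$ages[nodes],
                   stringsAsFactors = FALSE)
  df$percent_error <- 100 * (df$estimate - df$truth) / df$truth
  df
}

#' Mean error by incongruence bin
#'
#' Bins per-branch percentage errors by the branch's gene-tree incongruence
#' percentage (default 5-point bins; terminal branches, with 0%
#' incongruence, fall in the first bin) and averages within bins.
#'
#' @param errors numeric vector of per-branch percentage errors.
#' @param incongruence matching vector of per-branch incongruence
#'   percentages (0-100).
#' @param bin_width bin width in percentage points.
#' @return data.frame with `bin_low`, `bin_mid`, `mean_error`, `n`.
#' @export
incongruence_error_curve <- function(errors, incongruence, bin_width = 5) {
  stopifnot(length(errors) == length(incongruence), bin_width > 0)
  lo <- bin_width * (floor(incongruence / bin_width))
  lo[incongruence >= 100] <- 100 - bin_width
  agg <- tapply(errors, lo, mean)
  n <- tapply(errors, lo, length)
  data.frame(bin_low = as.numeric(names(agg)),
             bin_mid = as.numeric(names(agg)) + bin_width / 2,
             mean_error = as.numeric(agg), n = as.integer(n))
}

#' Fixed-scheme experiment (four-taxon or 16-taxon tip-swap designs)
#'
#' Simulates one gene-tree + alignment data set under a fixed-topology
#' scheme and applies the requested estimation strategies for `t`.
#'
#' @param scheme scheme id, e.g. `"four_taxon"` or `"balanced16_swap2"`.
#' @param fraction incongruent gene-tree fraction.
#' @param methods subset of `c("concat", "congruent_loci",
#'   "congruent_branches")`.
#' @param max_incongruent filter threshold for `congruent_loci`.
#' @param n_loci,seq_length,rate simulation settings (rate is also the fixed
#'   clock rate at analysis time for these schemes).
#' @param param parameter to estimate (`"t"` or `"n"`).
#' @param seed integer seed.
#' @return list with per-method branch tables, class-mean errors, and the
#'   per-branch incongruence report.
#' @export
fixed_scheme_experiment <- function(scheme = "four_taxon", fraction = 0.5,
                                    methods = c("concat", "congruent_loci",
                                                "congruent_branches"),
                                    max_incongruent = 0, n_loci = 400,
                                    seq_length = 800, rate = 0.05,
                                    param = "t", seed = NULL) {
  dat <- simulate_dataset(scheme, process = "fixed", fraction = fraction,
                          n_loci = n_loci, seq_length = seq_length,
                          rate = rate, seed = seed)
  out <- list(incongruence = branch_incongruence(dat$species, dat$genes),
              tables = list(), errors = list())
  for (m in methods) {
    res <- switch(m,
      concat = run_concatenated(dat$alignments, dat$species, param = param,
                                rate = rate),
      congruent_loci = run_congruent_loci(dat$alignments, dat$genes,
                                          dat$species,
                                          max_incongruent = max_incongruent,
                                          param = param, rate = rate),
      congruent_branches = run_congruent_branches(dat$alignments, dat$genes,
                                                  dat$species, param = param,
                                                  rate = rate),
      stop("unknown method: ", m))
    out$tables[[m]] <- res$table
    out$errors[[m]] <- class_mean_errors(res$table)
    if (m == "concat" && param == "t") out$fit <- res$fit
  }
  out
}

#' Replicated multispecies-coalescent experiment
#'
#' For each replicate: simulate `n_loci` MSC gene trees and JC alignments on
#' the scheme's species tree, then estimate `t` by the requested strategies
#' and summarise percentage errors by branch class, node-age errors by node
#' class, and per-branch incongruence.
#'
#' @param scheme `"balanced16"`, `"imbalanced16"` or `"four_taxon_msc"`.
#' @param n_replicates number of independent replicates.
#' @param methods subset of `c("concat", "congruent_loci",
#'   "congruent_branches")`.
#' @param clock_rate analysis clock: `"free"` (rate estimated inside
#'   `c(1e-6, 1)`) or a fixed numeric rate.
#' @param max_incongruent filter threshold for `congruent_loci`.
#' @param n_loci,seq_length,rate,ne simulation settings.
#' @param seed integer master seed; replicate seeds are derived from it.
#' @return list with `summary` (data.frame of per-replicate class-mean
#'   errors per method), `node_summary`, `mean_internal_congruence`
#'   (per-replicate mean congruent percentage over internal branches), and
#'   `per_branch` (pooled per-branch errors with incongruence, for error
#'   curves).
#' @export
msc_experiment <- function(scheme = "balanced16", n_replicates = 10,
                           methods = c("concat", "congruent_loci",
                                       "congruent_branches"),
                           clock_rate = "free", max_incongruent = 0,
                           n_loci = 400, seq_length = 800, rate = 0.05,
                           ne = 0.12, seed = 1) {
  species <- canonical_trees(scheme)$species
  rows <- list(); node_rows <- list(); pb_rows <- list()
  cong <- numeric(n_replicates)
  for (rep in seq_len(n_replicates)) {
    set.seed((seed * 1000L + rep) %% .Machine$integer.max)
    genes <- simulate_msc(species, ne = ne, n_loci = n_loci)
    alns <- lapply(genes, simulate_jc_alignment, seq_length = seq_length,
                   rate = rate)
    inc <- branch_incongruence(species, genes)
    cong[rep] <- mean(100 - inc$percent_incongruent[!inc$terminal])
    for (m in methods) {
      res <- switch(m,
        concat = run_concatenated(alns, species, param = "t",
                                  rate = clock_rate),
        congruent_loci = run_congruent_loci(alns, genes, species,
                                            max_incongruent = max_incongruent,
                                            param = "t", rate = clock_rate),
        congruent_branches = run_congruent_branches(alns, genes, species,
                                                    param = "t",
                                                    rate = clock_rate))
      ce <- class_mean_errors(res$table)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = rep, method = m,
                   internal = ce[["internal"]], terminal = ce[["terminal"]])
      if (m %in% c("concat", "congruent_loci")) {
        na <- node_age_errors(res$fit, species)
        for (cl in unique(na$class)) {
          node_rows[[length(node_rows) + 1L]] <-
            data.frame(replicate = rep, method = m, class = cl,
                       mean_error = mean(na$percent_error[na$class == cl]))
        }
      }
      if (m == "concat") {
        pe <- percent_error(res$table)
        pb_rows[[length(pb_rows) + 1L]] <-
          data.frame(replicate = rep, clade = pe$clade,
                     percent_error = pe$percent_error,
                     incongruence = inc$percent_incongruent[
                       match(pe$clade, inc$clade)])
      }
    }
  }
  list(summary = do.call(rbind, rows),
       node_summary = do.call(rbind, node_rows),
       mean_internal_congruence = cong,
       per_branch = do.call(rbind, pb_rows))
}

#' Aggregate a replicated experiment summary
#'
#' Mean internal/terminal class errors per method across replicates.
#'
#' @param experiment result of [msc_experiment()].
#' @return data.frame with one row per method.
#' @export
summarise_msc_experiment <- function(experiment) {
  s <- experiment$summary
  out <- do.call(rbind, lapply(split(s, s$method), function(d)
    data.frame(method = d$method[1], internal = mean(d$internal),
               terminal = mean(d$terminal), n_replicates = nrow(d))))
  rownames(out) <- NULL
  ns <- experiment$node_summary
  if (!is.null(ns) && nrow(ns)) {
    agg <- do.call(rbind, lapply(split(ns, list(ns$method, ns$class),
                                       drop = TRUE), function(d)
      data.frame(method = d$method[1], class = d$class[1],
                 mean_error = mean(d$mean_error))))
    rownames(agg) <- NULL
    attr(out, "node_ages") <- agg
  }
  attr(out, "mean_internal_congruence") <-
    mean(experiment$mean_internal_congruence)
  out
}

#' Run a configured experiment and optionally write TSV outputs
#'
#' Thin driver around [fixed_scheme_experiment()] and [msc_experiment()].
#' `config` is a list with at least `scheme`; fixed schemes accept
#' `fraction`, MSC schemes accept `n_replicates`, `clock_rate`, `ne`; both
#' accept `methods`, `max_incongruent`, `n_loci`, `seq_length`, `rate`,
#' `seed`. Identical config + seed reproduces identical outputs.
#'
#' @param config named list, see above.
#' @param out_dir optional directory; when given, `summary.tsv` (class-mean
#'   errors) and `per_branch.tsv`/`curve.tsv` (MSC schemes) are written.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(!is.null(config$scheme))
  msc <- config$scheme %in% c("balanced16", "imbalanced16",
                              "four_taxon_msc") &&
         is.null(config$fraction)
  args <- config[setdiff(names(config), "scheme")]
  res <- if (msc) {
    do.call(msc_experiment, c(list(scheme = config$scheme),
                              args[names(args) %in%
                                   names(formals(msc_experiment))]))
  } else {
    do.call(fixed_scheme_experiment,
            c(list(scheme = config$scheme),
              args[names(args) %in% names(formals(fixed_scheme_experiment))]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (msc) {
      summ <- summarise_msc_experiment(res)
      utils::write.table(summ, file.path(out_dir, "summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(res$per_branch, file.path(out_dir, "per_branch.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      curve <- incongruence_error_curve(res$per_branch$percent_error,
                                        res$per_branch$incongruence)
      utils::write.table(curve, file.path(out_dir, "curve.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      err <- do.call(rbind, lapply(names(res$errors), function(m)
        data.frame(method = m, internal = res$errors[[m]][["internal"]],
                   terminal = res$errors[[m]][["terminal"]])))
      utils::write.table(err, file.path(out_dir, "summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  res
}
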