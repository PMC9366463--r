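# Likelihood-based estimation of n (unrooted branch lengths), t
# (strict-clock chronograms with a fixed root age) and r (per-branch rates
# with fixed times). Point estimates are maximum-likelihood, or maximum a
# posteriori for the rates, computed with the compiled Jukes-Cantor pruning
# engine and coordinate-wise Brent updates.

# Postorder edge matrix + compressed patterns for a phylo.
likelihood_inputs <- function(phy, aln) {
  po <- ape::reorder.phylo(phy, "postorder")
  pd <- pattern_data(aln, phy$tip.label)
  list(edge = po$edge, tip = pd$tip, w = pd$w, po = po)
}

#' Jukes-Cantor log-likelihood of a tree
#'
#' Exact pruning likelihood with uniform 1/4 root frequencies. Branch
#' lengths are expected substitutions per site: supply either a `phylo`
#' whose `edge.length` are substitutions, or a `timetree` plus the clock
#' `rate` converting durations to substitutions.
#'
#' @param tree a `phylo` (edge lengths in substitutions/site) or `timetree`.
#' @param alignment a `jc_alignment` containing all of the tree's tips.
#' @param rate clock rate, required when `tree` is a `timetree`.
#' @return the log-likelihood (numeric scalar).
#' @export
jc_log_likelihood <- function(tree, alignment, rate = NULL) {
  if (inherits(tree, "timetree")) {
    if (is.null(rate)) stop("supply `rate` to convert durations to n")
    phy <- tree$phy
    en_ages <- tree$ages
    li <- likelihood_inputs(phy, alignment)
    en <- rate * (en_ages[li$edge[, 1]] - en_ages[li$edge[, 2]])
  } else {
    phy <- tree
    li <- likelihood_inputs(phy, alignment)
    idx <- match(paste(li$edge[, 1], li$edge[, 2]),
                 paste(phy$edge[, 1], phy$edge[, 2]))
    en <- phy$edge.length[idx]
  }
  if (any(en < -1e-12)) stop("negative branch length")
  cpp_jc_loglik(li$edge, pmax(en, 0), li$tip, li$w)
}

# Random feasible perturbation of internal node ages (root kept fixed):
# multiply by a jitter, then repair parent>child ordering root-to-tip.
perturb_ages <- function(phy, ages, root) {
  ntip <- ape::Ntip(phy)
  internal <- setdiff(ntip + seq_len(phy$Nnode), root)
  ages[internal] <- ages[internal] * runif(length(internal), 0.4, 1.2)
  pr <- ape::reorder.phylo(phy, "postorder")
  E <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE] # preorder
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    if (ch > ntip && ages[ch] >= ages[p])
      ages[ch] <- ages[p] * runif(1, 0.5, 0.98)
  }
  ages
}

#' Strict-clock divergence-time estimation
#'
#' Maximises the JC likelihood over internal node ages on a fixed rooted
#' topology, subject to `child age < parent age`, the root fixed at
#' `root_age` and tips at 0. With `rate = "free"` the single clock rate is
#' estimated jointly inside `rate_interval` (the box constraint standing in
#' for a uniform rate prior); a numeric `rate` is held fixed. Optimisation
#' is by repeated coordinate Brent updates until the log-likelihood improves
#' by less than `tol`, with `restarts` jittered re-initialisations keeping
#' the best solution.
#'
#' @param alignment a `jc_alignment`.
#' @param topology a `timetree` giving the fixed topology (its ages, scaled
#'   to `root_age`, seed the search).
#' @param root_age fixed age of the root.
#' @param rate numeric fixed clock rate, or `"free"`.
#' @param rate_interval search bounds for the free rate.
#' @param restarts number of additional jittered starts (default 2, i.e.
#'   three starts in total).
#' @param tol log-likelihood convergence tolerance.
#' @param max_sweeps cap on coordinate sweeps.
#' @return a `timetree` with estimated ages; attributes `rate`, `logLik`.
#' @export
estimate_t_strict_clock <- function(alignment, topology, root_age,
                                    rate = 0.05,
                                    rate_interval = c(1e-6, 1),
                                    restarts = 2, tol = 1e-8,
                                    max_sweeps = 500) {
  stopifnot(root_age > 0)
  free <- identical(rate, "free")
  if (!free) stopifnot(is.numeric(rate), rate > 0)
  phy <- topology$phy
  li <- likelihood_inputs(phy, alignment)
  root <- ape::Ntip(phy) + 1L
  ages0 <- topology$ages / topology$ages[root] * root_age
  starts <- list(ages0)
  if (restarts > 0) {
    for (i in seq_len(restarts))
      starts[[i + 1L]] <- perturb_ages(phy, ages0, root)
  }
  # crude data-driven starting rate for the free-rate search: mean pairwise
  # JC distance between adjacent taxa, converted to rate over 2 * root_age
  r_init <- rate
  if (free) {
    m <- alignment$states[match(phy$tip.label, alignment$taxa), ,
                          drop = FALSE]
    nt <- nrow(m)
    pairs <- cbind(seq_len(min(nt - 1L, 8L)), seq_len(min(nt - 1L, 8L)) + 1L)
    d <- apply(pairs, 1L, function(ij) {
      a <- m[ij[1], ]; b <- m[ij[2], ]
      ok <- a > 0L & b > 0L
      p <- min(mean(a[ok] != b[ok]), 0.70)
      -0.75 * log(1 - 4 / 3 * p)
    })
    r_init <- min(max(mean(d) / (2 * root_age), rate_interval[1] * 2),
                  rate_interval[2] / 2)
  }
  best <- NULL
  for (st in starts) {
    r0 <- r_init
    fit <- cpp_fit_clock(li$edge, st, root, li$tip, li$w, r0, free,
                         rate_interval[1], rate_interval[2], tol,
                         max_sweeps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  out <- topology
  out$ages <- best$ages
  out$phy$edge.length <- best$ages[phy$edge[, 1]] - best$ages[phy$edge[, 2]]
  attr(out, "rate") <- best$rate
  attr(out, "logLik") <- best$loglik
  out
}

#' Maximum-likelihood branch lengths on the unrooted topology
#'
#' Estimates expected substitutions per site for every branch of the
#' unrooted version of a fixed topology. Because JC is reversible the root
#' position is unidentifiable, so the two branches adjacent to the original
#' root are estimated as a single merged branch and reported jointly
#' (`root_sum = TRUE`).
#'
#' @param alignment a `jc_alignment`.
#' @param topology a rooted `timetree` fixing the topology.
#' @param n_max upper bracket for any single branch length.
#' @param tol log-likelihood convergence tolerance.
#' @return data.frame with one row per unrooted branch: `clade` (descendant
#'   clade key in the rooted orientation), `n_hat`, `root_sum`.
#' @export
estimate_n_unrooted <- function(alignment, topology, n_max = 10,
                                tol = 1e-8) {
  phy <- topology$phy
  rooted_keys <- clade_keys(topology)
  if (ape::Ntip(phy) == 2L) {
    # only the tip-to-tip path is identifiable: closed-form ML JC distance
    m <- alignment$states[match(phy$tip.label, alignment$taxa), ,
                          drop = FALSE]
    ok <- m[1, ] > 0L & m[2, ] > 0L
    p <- mean(m[1, ok] != m[2, ok])
    if (p >= 0.75) stop("saturated 2-taxon alignment: JC distance infinite")
    return(data.frame(clade = clade_key(phy$tip.label[1]),
                      n_hat = -0.75 * log(1 - 4 / 3 * p),
                      root_sum = TRUE, stringsAsFactors = FALSE))
  }
  uphy <- ape::unroot(phy)
  li <- likelihood_inputs(uphy, alignment)
  idx <- match(paste(li$edge[, 1], li$edge[, 2]),
               paste(uphy$edge[, 1], uphy$edge[, 2]))
  en0 <- pmax(uphy$edge.length[idx], 1e-4) * 0.05
  fit <- cpp_fit_edges(li$edge, en0, li$tip, li$w, n_max, tol, 1000L)
  # tip set on the child side of each unrooted edge
  ntip <- ape::Ntip(uphy)
  sets <- vector("list", ntip + uphy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- uphy$tip.label[i]
  for (e in seq_len(nrow(li$edge))) {
    p <- li$edge[e, 1]; ch <- li$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  all_tips <- uphy$tip.label
  clade <- character(nrow(li$edge))
  root_sum <- logical(nrow(li$edge))
  for (e in seq_len(nrow(li$edge))) {
    s <- sets[[li$edge[e, 2]]]
    k1 <- clade_key(s); k2 <- clade_key(setdiff(all_tips, s))
    in1 <- k1 %in% rooted_keys; in2 <- k2 %in% rooted_keys
    if (in1 && in2) { # the merged root branch: both sides are root children
      clade[e] <- min(k1, k2)
      root_sum[e] <- TRUE
    } else {
      clade[e] <- if (in1) k1 else k2
    }
  }
  data.frame(clade = clade, n_hat = fit$en[seq_len(nrow(li$edge))],
             root_sum = root_sum, stringsAsFactors = FALSE)
}

#' Per-branch substitution rates with fixed divergence times
#'
#' Maximum a posteriori rates under an uncorrelated lognormal (UCLN) prior
#' with all node ages fixed to the supplied chronogram. The prior's
#' real-scale mean is `m` and `v` sets the spread of the underlying normal
#' (`sigma = v`, `mu = log(m) - sigma^2/2`): a low `v` such as 0.001 pins
#' branch rates to within a fraction of a percent of `m`, while `v = 0.1`
#' leaves them nearly free against genome-scale data. `v = 0` collapses to
#' a strict clock at rate `m`.
#'
#' @param alignment a `jc_alignment`.
#' @param chronogram a `timetree` with the (true) node ages.
#' @param m,v real-scale mean of the branch-rate distribution and standard
#'   deviation of its underlying normal (log-scale).
#' @param r_interval search bounds for each branch rate.
#' @param tol objective convergence tolerance.
#' @return data.frame with one row per branch: `node`, `clade`, `t`,
#'   `r_hat`, `n_hat`.
#' @export
estimate_r_fixed_times <- function(alignment, chronogram, m = 0.05,
                                   v = 0.1, r_interval = c(1e-8, 10),
                                   tol = 1e-8) {
  stopifnot(m > 0, v >= 0)
  phy <- chronogram$phy
  li <- likelihood_inputs(phy, alignment)
  tdur <- chronogram$ages[li$edge[, 1]] - chronogram$ages[li$edge[, 2]]
  if (any(tdur <= 0))
    stop("zero-duration branch: rate prior undefined")
  bt <- branch_table(chronogram)
  node <- li$edge[, 2]
  if (v == 0) {
    r <- rep(m, length(tdur))
  } else {
    s2 <- v^2
    mu <- log(m) - s2 / 2
    fit <- cpp_fit_rates(li$edge, tdur, rep(m, length(tdur)), li$tip, li$w,
                         mu, sqrt(s2), r_interval[1], r_interval[2], tol,
                         500L)
    r <- fit$rates
  }
  data.frame(node = node,
             clade = bt$clade[match(node, bt$node)],
             t = tdur, r_hat = r, n_hat = r * tdur,
             stringsAsFactors = FALSE)
}
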