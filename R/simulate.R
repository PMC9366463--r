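#' Canonical simulation trees
#'
#' Returns the species tree, and where the scheme is a fixed-topology one,
#' the matching incongruent gene tree (identical node ages, different
#' topology). Schemes:
#'
#' * `four_taxon`: `((A,B),(C,D))`, root age 1.0, internal nodes at 0.5;
#'   incongruent tree `((A,C),(B,D))` with the same ages.
#' * `balanced16_swap2` .. `swap8`: perfectly balanced 16-taxon tree with
#'   every branch duration 0.2 (depth 0.8); the incongruent tree swaps
#'   1/2/3/4 terminals reciprocally across the two halves (A<->I, then B<->J,
#'   C<->K, D<->L).
#' * `balanced16`: the balanced species tree with no incongruent partner.
#' * `imbalanced16`: 16-taxon caterpillar, internal branches 0.2, node ages
#'   0.2, 0.4, ..., 3.0, terminal durations growing toward the root; the
#'   incongruent partner swaps A<->I.
#' * `four_taxon_msc`: `((A,B),(C,D))` with every branch duration 0.2
#'   (root age 0.4), used for multispecies-coalescent simulation.
#'
#' @param scheme one of the ids above.
#' @return list with elements `species` and `incongruent` (a `timetree` or
#'   `NULL`).
#' @export
canonical_trees <- function(scheme) {
  bal16 <- function() {
    g <- function(labs) {
      if (length(labs) == 1L) return(paste0(labs, ":0.2"))
      h <- length(labs) / 2
      paste0("(", g(labs[1:h]), ",", g(labs[(h + 1):length(labs)]),
             "):0.2")
    }
    labs <- LETTERS[1:16]
    paste0("(", g(labs[1:8]), ",", g(labs[9:16]), ");")
  }
  swap_tips <- function(tt, from, to) {
    lab <- tt$phy$tip.label
    i <- match(from, lab); j <- match(to, lab)
    lab[i] <- to; lab[j] <- from
    tt$phy$tip.label <- lab
    tt
  }
  cater16 <- function() {
    nwk <- "(A:0.2,B:0.2)"
    age <- 0.2
    for (tipl in LETTERS[3:16]) {
      age <- age + 0.2
      nwk <- paste0("(", nwk, ":0.2,", tipl, ":", age, ")")
    }
    paste0(nwk, ";")
  }
  sw <- function(k) LETTERS[seq_len(k)]
  swto <- function(k) LETTERS[8 + seq_len(k)]
  switch(scheme,
    four_taxon = list(
      species = read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);"),
      incongruent = read_newick("((A:0.5,C:0.5):0.5,(B:0.5,D:0.5):0.5);")),
    four_taxon_msc = list(
      species = read_newick("((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);"),
      incongruent = NULL),
    balanced16 = list(species = read_newick(bal16()), incongruent = NULL),
    balanced16_swap2 = ,
    balanced16_swap4 = ,
    balanced16_swap6 = ,
    balanced16_swap8 = {
      k <- as.integer(sub("balanced16_swap", "", scheme)) / 2L
      sp <- read_newick(bal16())
      inc <- sp
      for (i in seq_len(k)) inc <- swap_tips(inc, sw(k)[i], swto(k)[i])
      list(species = sp, incongruent = inc)
    },
    imbalanced16 = {
      sp <- read_newick(cater16())
      list(species = sp, incongruent = swap_tips(sp, "A", "I"))
    },
    stop("unknown scheme id: ", scheme)
  )
}

#' Simulate a fixed-topology gene-tree set
#'
#' Exactly `round(fraction * n_loci)` gene trees are copies of the
#' incongruent tree, the remainder copies of the species tree; node ages are
#' carried over verbatim and the order is shuffled.
#'
#' @param species,incongruent `timetree`s with identical tip sets.
#' @param fraction proportion of incongruent gene trees in `[0, 1]`.
#' @param n_loci number of gene trees (default 400).
#' @param seed optional integer seed.
#' @return list of `timetree`s with logical attribute `incongruent`.
#' @export
simulate_fixed_scheme <- function(species, incongruent, fraction,
                                  n_loci = 400, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, n_loci >= 1)
  if (fraction > 0) {
    if (is.null(incongruent)) stop("incongruent tree required")
    if (!setequal(species$phy$tip.label, incongruent$phy$tip.label))
      stop("species and incongruent trees must share tip sets")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * n_loci)
  flags <- c(rep(FALSE, n_loci - k), rep(TRUE, k))
  flags <- sample(flags)
  genes <- lapply(flags, function(f) if (f) incongruent else species)
  attr(genes, "incongruent") <- flags
  attr(genes, "scheme") <- "fixed"
  genes
}

# Coalesce lineages within one population interval [t0, t1); rate for k
# lineages is k(k-1)/(2 Ne). Each lineage is list(nwk = newick fragment,
# age = height of its current node).
coalesce_interval <- function(lineages, t0, t1, ne) {
  t <- t0
  while (length(lineages) >= 2L) {
    k <- length(lineages)
    t <- t + rexp(1L, rate = k * (k - 1) / (2 * ne))
    if (t >= t1) break
    pair <- sample.int(k, 2L)
    a <- lineages[[pair[1L]]]; b <- lineages[[pair[2L]]]
    merged <- list(
      nwk = paste0("(", a$nwk, ":", format(t - a$age, digits = 17), ",",
                   b$nwk, ":", format(t - b$age, digits = 17), ")"),
      age = t)
    lineages <- c(lineages[-pair], list(merged))
  }
  lineages
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per species tip. Within each species-tree
#' branch, lineages coalesce with exponential waiting times at rate
#' `k(k-1)/(2 Ne)` for `k` lineages (time measured in the species tree's
#' units); lineages that fail to coalesce are passed to the parent branch,
#' and all remaining lineages coalesce above the root. Every gene-tree
#' divergence therefore predates (or equals, in the zero-`Ne` limit) the
#' corresponding species divergence.
#'
#' @param species a `timetree`.
#' @param ne effective population size in species-tree time units
#'   (0.12 for the canonical simulations here).
#' @param n_loci number of gene trees.
#' @param seed optional integer seed.
#' @return list of ultrametric `timetree`s.
#' @export
simulate_msc <- function(species, ne = 0.12, n_loci = 400, seed = NULL) {
  stopifnot(ne > 0, n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  phy <- species$phy
  ntip <- ape::Ntip(phy)
  ages <- species$ages
  po <- ape::reorder.phylo(phy, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  ord <- order(ages[ntip + seq_len(phy$Nnode)]) + ntip # internal, young first
  one_tree <- function() {
    pool <- vector("list", ntip + phy$Nnode)
    for (i in seq_len(ntip))
      pool[[i]] <- list(list(nwk = phy$tip.label[i], age = 0))
    for (v in ord) {
      lin <- list()
      for (ch in children[[as.character(v)]]) {
        lin <- c(lin, coalesce_interval(pool[[ch]], ages[ch], ages[v], ne))
      }
      pool[[v]] <- lin
    }
    root <- ntip + 1L
    lin <- coalesce_interval(pool[[root]], ages[root], Inf, ne)
    read_newick(paste0(lin[[1L]]$nwk, ";"))
  }
  genes <- lapply(seq_len(n_loci), function(i) one_tree())
  attr(genes, "scheme") <- "msc"
  attr(genes, "ne") <- ne
  genes
}

#' Simulate a DNA alignment under Jukes-Cantor along a tree
#'
#' The root state is uniform over `{A, C, G, T}` per site; along a branch of
#' duration `t` each site keeps its state with probability
#' `1/4 + 3/4 exp(-4/3 r t)`, otherwise moves uniformly to one of the other
#' three states; sites are independent.
#'
#' @param tree a `timetree` (gene tree with node ages).
#' @param seq_length number of sites (default 800).
#' @param rate substitutions per site per time unit (default 0.05).
#' @param seed optional integer seed.
#' @return a `jc_alignment`: list with integer matrix `states`
#'   (taxa x sites, values 1..4 for A,C,G,T) and `taxa`.
#' @export
simulate_jc_alignment <- function(tree, seq_length = 800, rate = 0.05,
                                  seed = NULL) {
  stopifnot(seq_length >= 1, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  pr <- ape::reorder.phylo(phy, "postorder")
  E <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE] # preorder
  dur <- tree$ages[E[, 1]] - tree$ages[E[, 2]]
  seqs <- matrix(0L, nn, seq_length)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  for (e in seq_len(nrow(E))) {
    n <- rate * dur[e]
    p_same <- 0.25 + 0.75 * exp(-4 / 3 * n)
    parent <- seqs[E[e, 1], ]
    child <- parent
    flip <- runif(seq_length) > p_same
    nf <- sum(flip)
    if (nf > 0) {
      child[flip] <- ((parent[flip] - 1L +
                       sample.int(3L, nf, replace = TRUE)) %% 4L) + 1L
    }
    seqs[E[e, 2], ] <- child
  }
  states <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(states) <- phy$tip.label
  new_jc_alignment(states)
}

#' Simulate a full gene-tree + alignment data set
#'
#' Convenience wrapper producing the gene trees of a scheme and one JC
#' alignment per locus.
#'
#' @param scheme a scheme id accepted by [canonical_trees()].
#' @param process `"fixed"` copies the canonical species/incongruent trees
#'   in the configured proportions; `"msc"` draws gene trees from the
#'   multispecies coalescent on the species tree. The default picks `"msc"`
#'   for the `*_msc`/plain `balanced16`/`imbalanced16` schemes and `"fixed"`
#'   otherwise.
#' @param fraction incongruent fraction (fixed process only).
#' @param n_loci,seq_length,rate,ne simulation settings.
#' @param seed integer master seed; per-locus sequences use the R RNG stream
#'   sequentially, so a given seed reproduces the data set exactly.
#' @return list with `species`, `genes`, `alignments`.
#' @export
simulate_dataset <- function(scheme, process = NULL, fraction = 0,
                             n_loci = 400, seq_length = 800, rate = 0.05,
                             ne = 0.12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(process)) {
    process <- if (scheme %in% c("four_taxon_msc", "balanced16",
                                 "imbalanced16")) "msc" else "fixed"
  }
  ct <- canonical_trees(scheme)
  genes <- if (process == "msc") {
    simulate_msc(ct$species, ne = ne, n_loci = n_loci)
  } else {
    simulate_fixed_scheme(ct$species, ct$incongruent, fraction, n_loci)
  }
  alns <- lapply(genes, simulate_jc_alignment, seq_length = seq_length,
                 rate = rate)
  list(species = ct$species, genes = genes, alignments = alns)
}
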