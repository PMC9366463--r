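# Topology-comparison machinery: per-branch incongruence percentages,
# gene-tree filtering, and the equivalent-branch rule.
#
# Congruence is clade-based and rooted throughout: a species-tree branch is
# identified by its descendant clade (tip set below its child node), and a
# gene tree is congruent for that branch when it contains a branch with the
# identical (taxon-restricted) descendant clade. Equivalence is stricter:
# the ancestral-node clade must match too.

#' Branch identity as a descendant/ancestral clade pair
#'
#' @param descendant tip labels below the branch's child node.
#' @param ancestral tip labels below the branch's parent node; for a child
#'   of the root this is the full taxon set. `descendant` must be a proper,
#'   non-empty subset of `ancestral`.
#' @export
clade_pair <- function(descendant, ancestral) {
  stopifnot(length(descendant) >= 1,
            all(descendant %in% ancestral),
            length(descendant) < length(ancestral))
  structure(list(descendant = sort(descendant), ancestral = sort(ancestral)),
            class = "clade_pair")
}

# All clade pairs of a rooted tree, one per non-root branch (child node id).
tree_clade_pairs <- function(tree) {
  cl <- descendant_clades(tree)
  phy <- tree$phy
  pmap <- integer(ape::Ntip(phy) + phy$Nnode)
  pmap[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ape::Ntip(phy) + 1L
  all_tips <- phy$tip.label
  lapply(setNames(names(cl), names(cl)), function(nd) {
    p <- pmap[as.integer(nd)]
    anc <- if (p == root) all_tips else cl[[as.character(p)]]
    clade_pair(cl[[nd]], anc)
  })
}

# Clade keys of a gene tree after restriction to `taxa` (NULL = no
# restriction). Restriction is by intersection semantics: the induced
# subtree's clades.
restricted_clade_keys <- function(gene, taxa = NULL) {
  if (!is.null(taxa) && !setequal(gene$phy$tip.label, taxa))
    gene <- restrict_to_taxa(gene, taxa)
  unname(clade_keys(gene))
}

#' Per-branch topological incongruence of a gene-tree set
#'
#' For each species-tree branch, the percentage of gene trees that lack a
#' branch with the same descendant clade (after restricting the species
#' clades to each gene tree's sampled taxa). A gene tree whose taxon set
#' makes a branch untestable (restricted descendant clade empty, or equal to
#' the restricted ancestral clade) is excluded from that branch's
#' denominator. Terminal branches are never incongruent.
#'
#' @param species a `timetree`.
#' @param genes list of gene `timetree`s (tips within the species taxa).
#' @return data.frame with one row per non-root species branch: `node`,
#'   `clade`, `terminal`, `percent_incongruent`, `n_considered`.
#' @export
branch_incongruence <- function(species, genes) {
  if (length(genes) == 0L) stop("empty gene-tree set")
  bt <- branch_table(species)
  pairs <- tree_clade_pairs(species)
  miss <- integer(nrow(bt))
  denom <- integer(nrow(bt))
  for (g in genes) {
    taxa <- g$phy$tip.label
    keys <- restricted_clade_keys(g)
    full <- setequal(taxa, species$phy$tip.label)
    for (i in seq_len(nrow(bt))) {
      cp <- pairs[[as.character(bt$node[i])]]
      d <- if (full) cp$descendant else intersect(cp$descendant, taxa)
      if (length(d) == 0L) next
      if (!full) {
        a <- intersect(cp$ancestral, taxa)
        if (length(d) == length(a)) next # untestable restriction
      }
      denom[i] <- denom[i] + 1L
      if (!(clade_key(d) %in% keys) && length(d) > 1L)
        miss[i] <- miss[i] + 1L
    }
  }
  data.frame(node = bt$node, clade = bt$clade, terminal = bt$terminal,
             percent_incongruent = 100 * miss / pmax(denom, 1L),
             n_considered = denom, stringsAsFactors = FALSE)
}

#' Number of species-tree branches a gene tree is incongruent for
#'
#' Counts the internal species-tree branches whose (taxon-restricted)
#' descendant clade is absent from the gene tree.
#'
#' @param species a `timetree`.
#' @param gene a gene `timetree`.
#' @return integer count.
#' @export
count_incongruent_branches <- function(species, gene) {
  bt <- branch_table(species)
  pairs <- tree_clade_pairs(species)
  taxa <- gene$phy$tip.label
  keys <- restricted_clade_keys(gene)
  full <- setequal(taxa, species$phy$tip.label)
  n <- 0L
  for (i in which(!bt$terminal)) {
    cp <- pairs[[as.character(bt$node[i])]]
    d <- if (full) cp$descendant else intersect(cp$descendant, taxa)
    if (length(d) <= 1L) next
    if (!full) {
      a <- intersect(cp$ancestral, taxa)
      if (length(d) == length(a)) next
    }
    if (!(clade_key(d) %in% keys)) n <- n + 1L
  }
  n
}

#' Filter gene trees by incongruence level
#'
#' Retains gene trees with at most `max_incongruent` topologically
#' incongruent branches relative to the species tree, preserving order.
#'
#' @param genes list of gene `timetree`s.
#' @param species a `timetree`.
#' @param max_incongruent retention threshold (0 keeps only fully congruent
#'   gene trees).
#' @return the retained sublist, with attributes `retained` (logical vector
#'   over the input) and `retained_fraction`.
#' @export
filter_gene_trees <- function(genes, species, max_incongruent = 0) {
  stopifnot(max_incongruent >= 0)
  counts <- vapply(genes, count_incongruent_branches, 0L,
                   species = species)
  keep <- counts <= max_incongruent
  if (!any(keep))
    warning("no gene tree passes the incongruence threshold")
  out <- genes[keep]
  attr(out, "retained") <- keep
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Test whether a gene-tree branch is equivalent to a species-tree branch
#'
#' A gene-tree branch is equivalent when the clades descending from both its
#' child node and its parent node match the species branch's descendant and
#' ancestral clades exactly, after restricting the species clades to the
#' gene tree's sampled taxa. This is strictly stronger than descendant-clade
#' congruence, and it is directional: equivalence is defined from a species
#' branch to a gene branch only.
#'
#' @param species_branch a [clade_pair()].
#' @param gene a gene `timetree`.
#' @param gene_node child node id of the gene-tree branch.
#' @return logical.
#' @export
is_equivalent_branch <- function(species_branch, gene, gene_node) {
  taxa <- gene$phy$tip.label
  d <- intersect(species_branch$descendant, taxa)
  a <- intersect(species_branch$ancestral, taxa)
  if (length(d) == 0L || length(d) == length(a)) return(FALSE)
  gp <- tree_clade_pairs(gene)
  cp <- gp[[as.character(gene_node)]]
  if (is.null(cp)) return(FALSE)
  setequal(cp$descendant, d) && setequal(cp$ancestral, a)
}

#' Equivalent branches of every species-tree branch across gene trees
#'
#' For each non-root species branch, finds in each gene tree the branch (if
#' any) whose descendant and ancestral clades both match after taxon
#' restriction. At most one gene-tree branch can match per species branch on
#' a bifurcating gene tree; were several to match (polytomies), the one with
#' the smallest ancestral clade is kept.
#'
#' @param species a `timetree`.
#' @param genes list of gene `timetree`s.
#' @return list keyed by species branch clade key; each element is a
#'   data.frame with columns `gene` (index into `genes`) and `gene_node`.
#' @export
build_equivalence_map <- function(species, genes) {
  sp_pairs <- tree_clade_pairs(species)
  sp_bt <- branch_table(species)
  # per gene tree: lookup from "desc_key;anc_key" to child node
  gene_lookup <- lapply(genes, function(g) {
    gp <- tree_clade_pairs(g)
    keys <- vapply(gp, function(cp)
      paste(clade_key(cp$descendant), clade_key(cp$ancestral), sep = ";"),
      "")
    anc_size <- vapply(gp, function(cp) length(cp$ancestral), 0L)
    node <- as.integer(names(gp))
    o <- order(anc_size) # smallest ancestral clade wins on duplicates
    setNames(node[o][!duplicated(keys[o])], keys[o][!duplicated(keys[o])])
  })
  out <- vector("list", nrow(sp_bt))
  names(out) <- sp_bt$clade
  for (i in seq_len(nrow(sp_bt))) {
    cp <- sp_pairs[[as.character(sp_bt$node[i])]]
    hits_gene <- integer(0); hits_node <- integer(0)
    for (j in seq_along(genes)) {
      taxa <- genes[[j]]$phy$tip.label
      d <- intersect(cp$descendant, taxa)
      a <- intersect(cp$ancestral, taxa)
      if (length(d) == 0L || length(d) == length(a)) next
      key <- paste(clade_key(d), clade_key(a), sep = ";")
      nd <- gene_lookup[[j]][key]
      if (!is.na(nd)) {
        hits_gene <- c(hits_gene, j)
        hits_node <- c(hits_node, unname(nd))
      }
    }
    out[[i]] <- data.frame(gene = hits_gene, gene_node = hits_node)
  }
  out
}
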