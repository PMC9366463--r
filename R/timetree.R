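#' Time trees
#'
#' A `timetree` couples an [ape::phylo] topology with node ages (time before
#' present; tips of an ultrametric tree sit at 0). Branch durations are
#' `parent age - child age` and always agree with the stored `edge.length`.
#'
#' @param phy an `ape::phylo` with branch lengths.
#' @return an object of class `timetree` with elements `phy` (the phylo,
#'   edge lengths = durations) and `ages` (numeric, indexed by node id).
#' @export
as_timetree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label: ",
         phy$tip.label[duplicated(phy$tip.label)][1])
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  structure(list(phy = phy, ages = ages), class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  cat("<timetree> ", ape::Ntip(x$phy), " tips, root age ",
      format(root_age(x)), "\n", sep = "")
  invisible(x)
}

#' Read a tree (or trees) from newick
#'
#' @param text newick string(s); alternatively supply `file`.
#' @param file path to a newick file, one tree per line for gene-tree sets.
#' @return a `timetree`, or a list of them when the input holds several
#'   trees.
#' @examples
#' tt <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
#' root_age(tt) # 1.0
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file = file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed newick input")
  if (inherits(tr, "multiPhylo")) lapply(tr, as_timetree)
  else as_timetree(tr)
}

#' Write a timetree (or list of timetrees) as newick
#'
#' Branch lengths are always written; tip labels are emitted as-is.
#'
#' @param tree a `timetree` or list of them.
#' @param file optional path; when `NULL` the newick string(s) are returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  phys <- if (inherits(tree, "timetree")) list(tree$phy)
          else lapply(tree, function(t) t$phy)
  txt <- vapply(phys, function(p) ape::write.tree(p, digits = digits), "")
  if (is.null(file)) return(if (length(txt) == 1L) txt[[1L]] else txt)
  writeLines(txt, file)
  invisible(file)
}

#' @rdname as_timetree
#' @param tree a `timetree`.
#' @export
root_age <- function(tree) {
  tree$ages[ape::Ntip(tree$phy) + 1L]
}

#' Node ages of a timetree
#'
#' @param tree a `timetree`.
#' @return numeric vector indexed by node id (1..Ntip are tips, root is
#'   Ntip + 1).
#' @export
node_ages <- function(tree) tree$ages

#' Canonical clade identifier
#'
#' Clades are identified across trees by their sorted tip labels joined with
#' `"|"`; this string is the branch identity used throughout the package.
#'
#' @param tips character vector of tip labels.
#' @export
clade_key <- function(tips) paste(sort(tips), collapse = "|")

#' Descendant clades of every non-root branch
#'
#' Each branch of a rooted tree is identified by its child node; this returns
#' the set of tip labels descending from that node. A fully bifurcating
#' rooted tree yields `2 * Ntip - 2` entries.
#'
#' @param tree a `timetree`.
#' @return named list of character vectors; names are child node ids.
#' @export
descendant_clades <- function(tree) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  root <- ntip + 1L
  keep <- setdiff(seq_len(nn), root)
  setNames(sets[keep], keep)
}

#' Clade keys present in a tree
#'
#' @param tree a `timetree`.
#' @return character vector of [clade_key()] strings, named by child node id.
#' @export
clade_keys <- function(tree) {
  cl <- descendant_clades(tree)
  vapply(cl, clade_key, "", USE.NAMES = TRUE)
}

#' Branch table of a timetree
#'
#' One row per non-root branch with its identity, duration, and class.
#'
#' @param tree a `timetree`.
#' @return data.frame with columns `node` (child node id), `clade`
#'   (clade key), `duration`, `terminal`.
#' @export
branch_table <- function(tree) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  keys <- clade_keys(tree)
  node <- as.integer(names(keys))
  parent <- integer(length(node))
  pmap <- integer(ntip + phy$Nnode)
  pmap[phy$edge[, 2]] <- phy$edge[, 1]
  parent <- pmap[node]
  data.frame(node = node, clade = unname(keys),
             duration = tree$ages[parent] - tree$ages[node],
             terminal = node <= ntip,
             stringsAsFactors = FALSE)
}

#' Restrict a tree to a subset of taxa
#'
#' Drops all other tips and suppresses the resulting unary nodes; ages of
#' retained nodes are unchanged.
#'
#' @param tree a `timetree`.
#' @param taxa tip labels to keep (at least two must be present).
#' @export
restrict_to_taxa <- function(tree, taxa) {
  keep <- intersect(tree$phy$tip.label, taxa)
  if (length(keep) == 0L) stop("no requested taxa present in tree")
  if (length(keep) == 1L)
    stop("cannot build an induced tree with a single taxon")
  if (length(keep) == ape::Ntip(tree$phy)) return(tree)
  as_timetree(ape::keep.tip(tree$phy, keep))
}

#' Validate timetree invariants
#'
#' Checks that ages decrease strictly from parent to child, that edge lengths
#' match age differences, and (optionally) ultrametricity: all tips at age 0
#' and equal root-to-tip path sums.
#'
#' @param tree a `timetree`.
#' @param ultrametric also check the ultrametric invariants.
#' @param tol absolute tolerance for the ultrametricity checks.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_timetree <- function(tree, ultrametric = TRUE, tol = 1e-9) {
  phy <- tree$phy
  dur <- tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]
  if (any(dur < -1e-12)) stop("a node is older than its parent")
  if (max(abs(dur - phy$edge.length)) > tol)
    stop("edge lengths disagree with node ages")
  if (ultrametric) {
    ntip <- ape::Ntip(phy)
    if (max(abs(tree$ages[seq_len(ntip)])) > tol)
      stop("tips of an ultrametric tree must sit at age 0")
    depth <- ape::node.depth.edgelength(phy)[seq_len(ntip)]
    if (diff(range(depth)) > tol)
      stop("root-to-tip path sums differ by more than tol")
  }
  invisible(TRUE)
}
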