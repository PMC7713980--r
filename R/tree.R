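# Tree utilities.  Trees are ape "phylo" objects: rooted, with unique tip
# labels and (possibly assigned) internal-node labels.  Internally the
# likelihood machinery uses a flat graph representation (parent pointers,
# children lists, postorder) built by .tree_graph().

#' Read a rooted tree from a Newick file or string
#'
#' Internal node labels are preserved; unlabeled internal nodes are assigned
#' labels N1, N2, ... in ape node order.
#'
#' @param x path to a Newick file, or a Newick string
#' @return an ape `phylo` object with complete node labels
#' @export
read_newick <- function(x) {
  phy <- if (length(x) == 1L && !grepl("[();]", x) && file.exists(x))
    ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(phy)) stop("could not parse Newick input")
  ensure_node_labels(phy)
}

#' Write a tree to Newick
#' @param phy an ape `phylo`
#' @param path output path (or "" for stdout)
#' @export
write_newick <- function(phy, path = "") {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Assign labels to unlabeled internal nodes
#'
#' @param phy an ape `phylo`
#' @param prefix label prefix (default "N"; nodes become N1..Nk in ape order)
#' @return the tree with every internal node labeled
#' @export
ensure_node_labels <- function(phy, prefix = "N") {
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0(prefix, which(empty))
  if (anyDuplicated(lab)) stop("internal node labels are not unique")
  if (anyDuplicated(phy$tip.label)) stop("tip labels are not unique")
  phy$node.label <- lab
  phy
}

# Flat representation used by the likelihood engine.
# Node ids follow ape: tips 1..ntip, internals ntip+1..nnode, root = ntip+1.
.tree_graph <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  parent <- integer(nnode)
  blen <- rep(NA_real_, nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; set or estimate them first")
  blen[phy$edge[, 2]] <- phy$edge.length
  if (anyNA(blen[-root])) stop("tree has missing branch lengths")
  if (any(blen[-root] < 0)) stop("tree has negative branch lengths")
  children <- vector("list", nnode)
  sp <- split(phy$edge[, 2], phy$edge[, 1])
  children[as.integer(names(sp))] <- sp
  po <- ape::reorder.phylo(phy, "postorder")
  postorder <- c(unique(po$edge[, 2]), root)   # children before parents
  labels <- c(phy$tip.label, phy$node.label)
  list(phy = phy, ntip = ntip, nnode = nnode, root = root, parent = parent,
       children = children, blen = blen, postorder = postorder,
       labels = labels)
}

# Set branch lengths on a phylo from a per-node vector (indexed by node id).
.set_blen <- function(phy, blen) {
  phy$edge.length <- blen[phy$edge[, 2]]
  phy
}

#' Remove one species from a tree, preserving labels
#'
#' @param phy an ape `phylo` with node labels
#' @param species tip label to remove
#' @return the pruned tree
#' @export
prune_species <- function(phy, species) {
  if (!species %in% phy$tip.label) stop("no tip named ", species)
  ape::drop.tip(phy, species)
}

#' Find the sister species of a tip
#'
#' The tip(s) forming the smallest clade containing `species`'s sibling
#' lineage; if the sibling lineage contains several tips, the one at minimal
#' patristic distance is returned.
#'
#' @param phy an ape `phylo`
#' @param species a tip label
#' @return a single tip label
#' @export
sister_species <- function(phy, species) {
  i <- match(species, phy$tip.label)
  if (is.na(i)) stop("no tip named ", species)
  g <- .tree_graph(phy)
  p <- g$parent[i]
  sibs <- setdiff(g$children[[p]], i)
  tips <- unlist(lapply(sibs, function(v) .subtree_tips(g, v)))
  if (length(tips) == 1L) return(g$labels[tips])
  d <- ape::cophenetic.phylo(phy)[species, g$labels[tips]]
  g$labels[tips][which.min(d)]
}

.subtree_tips <- function(g, v) {
  if (v <= g$ntip) return(v)
  unlist(lapply(g$children[[v]], .subtree_tips, g = g))
}
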