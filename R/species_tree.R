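#' Species tree with a focal lineage
#'
#' Wraps a rooted `ape::phylo` tree together with a focal species and
#' indexes the branches on the root-to-focal path. Gene ages are expressed
#' as an index on this path: branch 0 is the root itself (genes at least as
#' old as the root divergence, pooled), branch `K` is the terminal branch of
#' the focal species. Every other species in the tree is mapped to its
#' attachment point on the path (the most recent common ancestor it shares
#' with the focal species), so presence of a gene in any member of a sister
#' clade pushes the inferred origin back to that clade's join point.
#'
#' @param tree A rooted `ape::phylo` object, or a path to a newick file, or
#'   a newick string.
#' @param focal Name of the focal species; must be a leaf label.
#' @param node_ages Optional numeric vector of ages (Mya) for the path
#'   nodes, length `K + 1`, ordered root first. Purely annotational.
#' @return An object of class `species_tree` with elements `phylo`, `focal`,
#'   `K` (number of branches on the root-to-focal path), `path_nodes`
#'   (node ids, root first, ending at the focal tip), `attachment` (named
#'   integer vector: for each leaf, the path index of its MRCA with the
#'   focal species) and `branch_labels`.
#' @examples
#' tr <- species_tree(default_drosophila_tree(), "D_melanogaster")
#' tr$K
#' @export
species_tree <- function(tree, focal, node_ages = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  abort_if(!inherits(tree, "phylo"), "tree must be a phylo object or newick input")
  abort_if(!ape::is.rooted(tree), "tree must be rooted")
  abort_if(anyDuplicated(tree$tip.label) > 0, "leaf labels must be unique")
  abort_if(!(focal %in% tree$tip.label), "focal species '%s' is not a leaf of the tree", focal)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  focal_tip <- match(focal, tree$tip.label)

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # root-to-focal path
  path <- focal_tip
  node <- focal_tip
  while (node != root) {
    node <- parent[node]
    path <- c(node, path)
  }
  K <- length(path) - 1L

  path_index <- integer(ntip + tree$Nnode)
  path_index[] <- NA_integer_
  path_index[path] <- seq_along(path) - 1L

  # attachment branch per leaf: deepest path node among its ancestors
  attachment <- integer(ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    while (is.na(path_index[node])) node <- parent[node]
    attachment[tip] <- path_index[node]
  }
  names(attachment) <- tree$tip.label

  if (!is.null(node_ages)) {
    abort_if(length(node_ages) != K + 1L,
             "node_ages must have length K + 1 = %d", K + 1L)
  }

  labels <- paste0("b", 0:K)
  structure(
    list(phylo = tree, focal = focal, K = K, path_nodes = path,
         path_index = path_index, parent = parent,
         attachment = attachment, node_ages = node_ages,
         branch_labels = labels),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$phylo$tip.label), "leaves, focal =", x$focal,
      ", K =", x$K, "branches on root-to-focal path\n")
  invisible(x)
}

#' Default 12-species Drosophila tree
#'
#' A rooted, approximately ultrametric 12-species Drosophila phylogeny in
#' newick form, with *D. melanogaster* as the intended focal species. The
#' root (genus divergence, ~40 Mya) to *D. melanogaster* path carries six
#' internal stages, so origination branches run 0 (pre-genus) through 6
#' (terminal *D. melanogaster* branch). Branch lengths are rough divergence
#' times in Mya and are annotational only; parsimony dating uses topology.
#'
#' @return A newick string.
#' @export
default_drosophila_tree <- function() {
  paste0(
    "((((((D_melanogaster:5.4,(D_simulans:2.5,D_sechellia:2.5):2.9):7.2,",
    "(D_yakuba:6.1,D_erecta:6.1):6.5):12.4,D_ananassae:25):5.5,",
    "(D_pseudoobscura:15,D_persimilis:15):15.5):5.1,D_willistoni:35.6):4.4,",
    "(D_grimshawi:36,(D_virilis:25,D_mojavensis:25):11):4);"
  )
}

# leaves (tip indices) descending from a node, by iterative traversal
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (n <= ntip) tips <- c(tips, n) else stack <- c(stack, kids[[as.character(n)]])
  }
  sort(tips)
}
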