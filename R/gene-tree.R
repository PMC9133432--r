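#' Gene tree with leaf metadata
#'
#' Wraps an [ape::phylo] tree together with per-leaf annotations: species,
#' whether the leaf is a human protein, and (optionally) the ordered taxonomic
#' lineage of the species. The tree is the unit of ortholog/paralog decisions:
#' rooting on an outgroup, extracting the ortholog clade of the human target,
#' and trimming diverged paralogous clades.
#'
#' More than one leaf may be human (the outgroup is itself a human paralog);
#' the single human *target* is designated separately via `target`.
#'
#' @param phy An [ape::phylo] object. Polytomies are allowed at construction
#'   and resolved by [root_by_outgroup()].
#' @param leaves Tibble with columns `seq_id`, `species`, `is_human` and
#'   optionally `lineage` (list-column of ordered rank character vectors,
#'   root-most first). Must cover every tip label of `phy`.
#' @param target Optional `seq_id` of the human target leaf.
#' @return An object of class `gene_tree`.
#' @export
gene_tree <- function(phy, leaves, target = NULL) {
  stopifnot(inherits(phy, "phylo"))
  leaves <- as_tibble(leaves)
  required <- c("seq_id", "species", "is_human")
  missing_cols <- setdiff(required, names(leaves))
  if (length(missing_cols) > 0) {
    abort(paste0("leaves is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  unresolved <- setdiff(phy$tip.label, leaves$seq_id)
  if (length(unresolved) > 0) {
    abort(paste0("tree leaf name(s) without metadata: ",
                 paste(unresolved, collapse = ", ")))
  }
  if (!"lineage" %in% names(leaves)) {
    leaves$lineage <- replicate(nrow(leaves), character(0), simplify = FALSE)
  }
  if (!is.null(target)) {
    if (!target %in% phy$tip.label) {
      abort(paste0("target '", target, "' is not a leaf of the tree"))
    }
  }
  structure(
    list(phy = phy, leaves = leaves, target = target),
    class = "gene_tree"
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree> ", length(x$phy$tip.label), " leaves, ",
      sum(x$leaves$is_human), " human; target: ",
      x$target %||% "<unset>", "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.gene_tree <- function(x, ...) x$leaves

leaf_meta <- function(gt, seq_ids) {
  gt$leaves[match(seq_ids, gt$leaves$seq_id), ]
}

tree_target <- function(gt, target = NULL) {
  target <- target %||% gt$target
  if (is.null(target)) abort("no target leaf designated for this gene tree")
  if (!target %in% gt$phy$tip.label) {
    abort(paste0("target '", target, "' is not a leaf of the tree"))
  }
  target
}

# children of every node: list indexed by node number
node_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  kids
}

# tip indices under a node (the node itself if it is a tip)
clade_tip_indices <- function(phy, node, kids = node_children(phy)) {
  ntip <- ape::Ntip(phy)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (cur <= ntip) out <- c(out, cur) else stack <- c(stack, kids[[cur]])
  }
  sort(out)
}

clade_tip_labels <- function(phy, node, kids = node_children(phy)) {
  phy$tip.label[clade_tip_indices(phy, node, kids)]
}
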