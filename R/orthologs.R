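#' Root a gene tree on an outgroup leaf
#'
#' Roots the tree so that the outgroup (conventionally the third human
#' protein of the homolog retrieval) sits on one side of the root, and
#' resolves any polytomies deterministically so downstream internode
#' assessments see a binary tree. Rooting an already correctly rooted tree
#' leaves the topology unchanged.
#'
#' @param gt A [gene_tree()].
#' @param outgroup_leaf `seq_id` of the outgroup leaf.
#' @return A rooted, binary [gene_tree()].
#' @export
root_by_outgroup <- function(gt, outgroup_leaf) {
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$phy
  if (!outgroup_leaf %in% phy$tip.label) {
    abort(paste0("outgroup '", outgroup_leaf, "' is not a leaf of the tree"))
  }
  phy <- ape::root(phy, outgroup = outgroup_leaf, resolve.root = TRUE)
  if (!ape::is.binary(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
  }
  gene_tree(phy, gt$leaves, target = gt$target)
}

#' Extract the ortholog clade of the human target
#'
#' Walks from the human target leaf toward the root. At each step the newly
#' joined sibling subtree is inspected: if it contains a human protein other
#' than the target, the traversal stops (the duplication node is the
#' boundary and that subtree is neither included nor traversed). Otherwise
#' the subtree is included when its species set is disjoint from every
#' species observed so far, and excluded (reason `reseen_species`) when it
#' re-introduces a previously seen species -- re-seeing a species at a lower
#' phylogenetic level signals a differential gene-loss event, not
#' orthology. Species observed so far accumulate from the target and from
#' included subtrees only.
#'
#' @param gt A rooted, binary [gene_tree()] (see [root_by_outgroup()]).
#' @param target_leaf `seq_id` of the human target; defaults to the tree's
#'   designated target.
#' @return An `ortholog_set`: list with `kept_leaves` (character),
#'   `excluded_clades` (tibble of node id, reason and leaf list) and
#'   `stop_node` (internal node number where another human protein was
#'   reached, or `NA`).
#' @export
extract_ortholog_clade <- function(gt, target_leaf = NULL) {
  stopifnot(inherits(gt, "gene_tree"))
  target_leaf <- tree_target(gt, target_leaf)
  phy <- gt$phy
  if (!ape::is.rooted(phy)) abort("tree must be rooted (see root_by_outgroup)")
  ntip <- ape::Ntip(phy)
  kids <- node_children(phy)
  parent_of <- integer(ntip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L

  target_idx <- match(target_leaf, phy$tip.label)
  meta <- gt$leaves
  species_of <- function(ids) {
    tolower(meta$species[match(ids, meta$seq_id)])
  }
  is_human_of <- function(ids) meta$is_human[match(ids, meta$seq_id)]

  kept <- target_leaf
  seen <- unique(species_of(target_leaf))
  excluded <- list()
  stop_node <- NA_integer_

  node <- target_idx
  while (node != root) {
    par <- parent_of[node]
    sibs <- setdiff(kids[[par]], node)
    stopped <- FALSE
    for (sib in sibs) {
      sib_ids <- clade_tip_labels(phy, sib, kids)
      others_human <- is_human_of(sib_ids) & sib_ids != target_leaf
      if (any(others_human)) {
        stop_node <- par
        stopped <- TRUE
        break
      }
      sp <- unique(species_of(sib_ids))
      if (any(sp %in% seen)) {
        excluded[[length(excluded) + 1]] <- tibble(
          node_id = as.integer(sib),
          reason = "reseen_species",
          leaves = list(sib_ids)
        )
      } else {
        kept <- c(kept, sib_ids)
        seen <- union(seen, sp)
      }
    }
    if (stopped) break
    node <- par
  }

  structure(
    list(
      kept_leaves = kept,
      excluded_clades = if (length(excluded) > 0) bind_rows(excluded) else
        tibble(node_id = integer(0), reason = character(0),
               leaves = list()),
      stop_node = stop_node
    ),
    class = "ortholog_set"
  )
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("<ortholog_set> ", length(x$kept_leaves), " leaves kept, ",
      nrow(x$excluded_clades), " clade(s) excluded",
      if (!is.na(x$stop_node)) paste0("; stopped at node ", x$stop_node),
      "\n", sep = "")
  invisible(x)
}
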