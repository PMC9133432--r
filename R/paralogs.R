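#' Global alignment score of two protein sequences
#'
#' Needleman-Wunsch optimal global alignment score under BLOSUM62 with
#' affine gap penalties (open 11, extend 1 -- EMBOSS/BLAST-like defaults;
#' only the matrix is prescribed by the method, the penalties are a
#' documented convention). Gaps must be stripped from MSA rows before
#' scoring.
#'
#' @param seq_a,seq_b Ungapped amino-acid strings.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Numeric scalar score; symmetric in its arguments.
#' @export
#' @examples
#' global_alignment_score("MKLV", "MKIV")
global_alignment_score <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                   gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("empty sequence")
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  ))
}

#' Global alignment scores of every family member against the target
#'
#' @param family An [aligned_family()].
#' @param target Target `seq_id`; defaults to the family target.
#' @param ... Passed to [global_alignment_score()].
#' @return Tibble with `seq_id` and `score`.
#' @export
alignment_score_table <- function(family, target = NULL, ...) {
  stopifnot(inherits(family, "aligned_family"))
  target <- target %||% family_target(family)
  target_seq <- ungapped_sequence(family, target)
  scores <- vapply(family$sequences$seq_id, function(id) {
    global_alignment_score(ungapped_sequence(family, id), target_seq, ...)
  }, numeric(1))
  tibble(seq_id = family$sequences$seq_id, score = unname(scores))
}

# two-sample t-test that tolerates zero-variance samples (noise-free
# synthetic fixtures are exactly constant): both constant and equal -> 1,
# constant and different -> 0, otherwise stats::t.test
safe_t_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  sx <- sd(x)
  sy <- sd(y)
  if (isTRUE(all.equal(sx, 0)) && isTRUE(all.equal(sy, 0))) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  p <- tryCatch(
    t.test(x, y, var.equal = var_equal)$p.value,
    error = function(e) NA_real_
  )
  if (is.na(p) || is.nan(p)) 1 else p
}

lineage_shared_counts <- function(species, lineages, human_lineage) {
  idx <- match(tolower(species), tolower(lineages$species))
  if (anyNA(idx)) {
    abort(paste0("no lineage for species: ",
                 paste(unique(species[is.na(idx)]), collapse = ", ")))
  }
  vapply(lineages$lineage[idx],
         function(l) length(intersect(l, human_lineage)), numeric(1))
}

#' Assess one internode for a diverged paralogous clade
#'
#' Implements the internode decision rule of paralog trimming. The two
#' child clades are compared only when they share at least one species.
#' With both clades holding at least three leaves, the clades must first be
#' evolutionarily comparable -- a two-sample t-test on each leaf's count of
#' lineage ranks shared with the human lineage must NOT be significant
#' (p > alpha). If comparable and the global-alignment-score t-test is
#' significant (p <= alpha), the clade with the lower mean score is removed.
#' With both clades below three leaves the lower-average clade is removed
#' outright; mixed sizes remove nothing.
#'
#' @param node_id Internal node number (bookkeeping only).
#' @param left_ids,right_ids Leaf `seq_id`s of the two child clades.
#' @param scores Named numeric vector of global alignment scores vs the
#'   human target, covering every leaf.
#' @param species Named character vector of leaf species.
#' @param lineage_counts Named numeric vector of per-leaf shared-rank counts
#'   with the human lineage.
#' @param alpha Significance level for both tests (default 0.1).
#' @param var_equal Use the classic equal-variance Student t-test (default);
#'   `FALSE` gives Welch.
#' @return One-row tibble verdict (`removed_clade` in left/right/none,
#'   `rule_used` in ttest/small_clade_average/none).
#' @export
assess_internode <- function(node_id, left_ids, right_ids, scores, species,
                             lineage_counts, alpha = 0.1, var_equal = TRUE) {
  for (ids in list(left_ids, right_ids)) {
    missing_s <- setdiff(ids, names(scores))
    if (length(missing_s) > 0) {
      abort(paste0("missing alignment score for leaf: ", missing_s[1]))
    }
    missing_l <- setdiff(ids, names(lineage_counts))
    if (length(missing_l) > 0) {
      abort(paste0("missing lineage for leaf: ", missing_l[1]))
    }
  }
  verdict <- tibble(
    node_id = as.integer(node_id),
    species_overlap = FALSE,
    comparable = NA,
    p_score = NA_real_,
    p_lineage = NA_real_,
    removed_clade = "none",
    rule_used = "none",
    mean_left = mean(scores[left_ids]),
    mean_right = mean(scores[right_ids])
  )
  sp_l <- unique(tolower(species[left_ids]))
  sp_r <- unique(tolower(species[right_ids]))
  verdict$species_overlap <- length(intersect(sp_l, sp_r)) > 0
  if (!verdict$species_overlap) return(verdict)

  nl <- length(left_ids)
  nr <- length(right_ids)
  lower <- if (verdict$mean_left < verdict$mean_right) "left" else "right"

  if (nl >= 3 && nr >= 3) {
    verdict$p_lineage <- safe_t_test(lineage_counts[left_ids],
                                     lineage_counts[right_ids],
                                     var_equal = var_equal)
    verdict$comparable <- verdict$p_lineage > alpha
    if (isTRUE(verdict$comparable)) {
      verdict$p_score <- safe_t_test(scores[left_ids], scores[right_ids],
                                     var_equal = var_equal)
      if (verdict$p_score <= alpha &&
          verdict$mean_left != verdict$mean_right) {
        verdict$removed_clade <- lower
        verdict$rule_used <- "ttest"
      }
    }
  } else if (nl < 3 && nr < 3) {
    if (verdict$mean_left != verdict$mean_right) {
      verdict$removed_clade <- lower
      verdict$rule_used <- "small_clade_average"
    }
  }
  verdict
}

#' Trim diverged paralogous clades from a gene tree
#'
#' Scores every leaf against the human target (BLOSUM62 global alignment),
#' then assesses internodes leaves-up (post-order), removing a clade
#' whenever [assess_internode()] says so. Once removed, a clade's leaves are
#' excluded from all later assessments. Attempting to remove the clade that
#' contains the target raises a diagnostic error rather than silently
#' removing it.
#'
#' @param gt A rooted, binary [gene_tree()].
#' @param family [aligned_family()] covering the tree leaves (used for
#'   alignment scores).
#' @param lineages Lineage table (see [read_lineages()]).
#' @param alpha Significance level (default 0.1).
#' @param target Target `seq_id`; defaults to the tree's designated target.
#' @param var_equal Student (default) vs Welch t-tests.
#' @param scores Optional precomputed named score vector (as produced from
#'   [alignment_score_table()]), to avoid re-aligning.
#' @return List with `kept` (character vector of surviving leaf ids) and
#'   `verdicts` (tibble of internode verdicts).
#' @export
trim_paralogs <- function(gt, family, lineages, alpha = 0.1, target = NULL,
                          var_equal = TRUE, scores = NULL) {
  stopifnot(inherits(gt, "gene_tree"), inherits(family, "aligned_family"))
  target <- tree_target(gt, target)
  phy <- gt$phy
  leaves <- phy$tip.label
  missing_seq <- setdiff(leaves, family$sequences$seq_id)
  if (length(missing_seq) > 0) {
    abort(paste0("missing sequence for leaf: ", missing_seq[1]))
  }
  if (is.null(scores)) {
    tab <- alignment_score_table(subset_family(family, leaves),
                                 target = target)
    scores <- setNames(tab$score, tab$seq_id)
  }
  meta <- leaf_meta(gt, leaves)
  species <- setNames(meta$species, leaves)
  human_species <- meta$species[match(target, meta$seq_id)]
  hidx <- match(tolower(human_species), tolower(lineages$species))
  if (is.na(hidx)) {
    abort(paste0("no lineage for target species: ", human_species))
  }
  human_lineage <- lineages$lineage[[hidx]]
  lineage_counts <- setNames(
    lineage_shared_counts(species, lineages, human_lineage), leaves)

  kids <- node_children(phy)
  ntip <- ape::Ntip(phy)
  edge <- stats::reorder(phy, "postorder")$edge
  internal_postorder <- unique(edge[, 1])
  removed <- character(0)
  verdicts <- list()
  for (node in internal_postorder) {
    ch <- kids[[node]]
    if (length(ch) != 2) next
    left_ids <- setdiff(clade_tip_labels(phy, ch[1], kids), removed)
    right_ids <- setdiff(clade_tip_labels(phy, ch[2], kids), removed)
    if (length(left_ids) == 0 || length(right_ids) == 0) next
    v <- assess_internode(node, left_ids, right_ids, scores, species,
                          lineage_counts, alpha = alpha,
                          var_equal = var_equal)
    verdicts[[length(verdicts) + 1]] <- v
    if (v$removed_clade != "none") {
      gone <- if (v$removed_clade == "left") left_ids else right_ids
      if (target %in% gone) {
        abort(paste0(
          "diagnostic: the clade containing the target '", target,
          "' scored significantly lower at node ", node,
          "; refusing to remove it"))
      }
      removed <- c(removed, gone)
    }
  }
  list(
    kept = setdiff(leaves, removed),
    verdicts = if (length(verdicts) > 0) bind_rows(verdicts) else
      tibble()
  )
}
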