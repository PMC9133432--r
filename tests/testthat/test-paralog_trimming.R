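test_that("global alignment scores match self-alignment and single cells", {
  b62 <- blosum_matrix("BLOSUM62")
  s <- "MKWLVF"
  self <- sum(vapply(strsplit(s, "")[[1]], function(a) b62[a, a], numeric(1)))
  expect_equal(global_alignment_score(s, s), self)
  expect_equal(global_alignment_score("A", "A"), b62["A", "A"])
  expect_equal(global_alignment_score("A", "A"), 4)
  expect_error(global_alignment_score("", "A"), "empty")
})

test_that("alignment scores are symmetric", {
  set.seed(9)
  for (i in 1:25) {
    a <- paste(sample(AA_ALPHABET, sample(5:30, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(AA_ALPHABET, sample(5:30, 1), replace = TRUE),
               collapse = "")
    expect_equal(global_alignment_score(a, b), global_alignment_score(b, a))
  }
})

test_that("score tables strip gaps and cover every member", {
  fam <- aligned_family(tibble::tibble(
    seq_id = c("t_HUMAN", "m_MOUSE"),
    species = c("HUMAN", "MOUSE"),
    residues = c("MK-LV", "MKQLV")
  ))
  tab <- alignment_score_table(fam)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$score[1], global_alignment_score("MKLV", "MKLV"))
})

make_verdict_inputs <- function(left_scores, right_scores,
                                left_species = NULL, right_species = NULL,
                                left_lineage = NULL, right_lineage = NULL) {
  nl <- length(left_scores)
  nr <- length(right_scores)
  left_ids <- paste0("l", seq_len(nl))
  right_ids <- paste0("r", seq_len(nr))
  list(
    left = left_ids, right = right_ids,
    scores = setNames(c(left_scores, right_scores), c(left_ids, right_ids)),
    species = setNames(
      c(left_species %||% paste0("sp", seq_len(nl)),
        right_species %||% paste0("sp", seq_len(nr))),
      c(left_ids, right_ids)),
    lineage = setNames(
      c(left_lineage %||% rep(4, nl), right_lineage %||% rep(4, nr)),
      c(left_ids, right_ids))
  )
}

test_that("disjoint species sets preclude any removal", {
  z <- make_verdict_inputs(c(100, 101, 102), c(60, 61, 62),
                           left_species = c("a", "b", "c"),
                           right_species = c("d", "e", "f"))
  v <- assess_internode(1, z$left, z$right, z$scores, z$species, z$lineage)
  expect_false(v$species_overlap)
  expect_equal(v$removed_clade, "none")
})

test_that("a significantly lower-scoring comparable clade is removed", {
  z <- make_verdict_inputs(c(100, 101, 102), c(60, 61, 62))
  v <- assess_internode(1, z$left, z$right, z$scores, z$species, z$lineage)
  expect_true(v$species_overlap)
  expect_true(v$comparable)
  # independent check of the score t-test p-value
  p_ref <- t.test(c(100, 101, 102), c(60, 61, 62), var.equal = TRUE)$p.value
  expect_equal(v$p_score, p_ref)
  expect_lt(v$p_score, 0.1)
  expect_equal(v$removed_clade, "right")
  expect_equal(v$rule_used, "ttest")
})

test_that("lineage incomparability blocks the score test", {
  z <- make_verdict_inputs(c(100, 101, 102), c(60, 61, 62),
                           left_lineage = c(8, 8, 8),
                           right_lineage = c(2, 2, 2))
  v <- assess_internode(1, z$left, z$right, z$scores, z$species, z$lineage)
  expect_false(v$comparable)
  expect_equal(v$removed_clade, "none")
})

test_that("small clades fall back to the average rule", {
  z <- make_verdict_inputs(c(80, 80), c(70, 70))
  v <- assess_internode(1, z$left, z$right, z$scores, z$species, z$lineage)
  expect_equal(v$removed_clade, "right")
  expect_equal(v$rule_used, "small_clade_average")
  # mixed sizes (one small, one large): no removal
  z2 <- make_verdict_inputs(c(80, 81), c(60, 61, 62, 63))
  v2 <- assess_internode(1, z2$left, z2$right, z2$scores, z2$species,
                         z2$lineage)
  expect_equal(v2$removed_clade, "none")
  expect_equal(v2$rule_used, "none")
})

test_that("missing scores or lineages name the offending leaf", {
  z <- make_verdict_inputs(c(100, 101), c(60, 61))
  expect_error(
    assess_internode(1, c(z$left, "ghost"), z$right, z$scores, z$species,
                     z$lineage),
    "ghost")
})

test_that("a planted diverged clade is trimmed and the truth matches", {
  sim <- simulate_paralog_tree(6, 6, divergence = 1.0, seed = 101)
  res <- trim_paralogs(sim$tree, sim$family, sim$lineages)
  expect_setequal(setdiff(sim$tree$phy$tip.label, res$kept),
                  sim$truth$paralog_ids)
  expect_true(sim$truth$ortholog_ids[1] %in% res$kept)
})

test_that("no species overlap anywhere keeps all leaves", {
  sim <- simulate_paralog_tree(4, 4, divergence = 1.0, shared_species = 0,
                               seed = 55)
  res <- trim_paralogs(sim$tree, sim$family, sim$lineages)
  expect_setequal(res$kept, sim$tree$phy$tip.label)
  expect_true(all(res$verdicts$removed_clade == "none"))
})

test_that("verdicts are stable under leaf relabeling", {
  sim <- simulate_paralog_tree(5, 5, divergence = 0.8, seed = 77)
  res1 <- trim_paralogs(sim$tree, sim$family, sim$lineages)
  relabel <- setNames(paste0("x_", sim$tree$phy$tip.label),
                      sim$tree$phy$tip.label)
  phy2 <- sim$tree$phy
  phy2$tip.label <- unname(relabel[phy2$tip.label])
  leaves2 <- sim$tree$leaves
  leaves2$seq_id <- unname(relabel[leaves2$seq_id])
  seqs2 <- sim$family$sequences
  seqs2$seq_id <- unname(relabel[seqs2$seq_id])
  gt2 <- gene_tree(phy2, leaves2, target = unname(relabel[sim$tree$target]))
  fam2 <- aligned_family(seqs2, target = gt2$target)
  res2 <- trim_paralogs(gt2, fam2, sim$lineages)
  expect_setequal(unname(relabel[res1$kept]), res2$kept)
})

test_that("removing the target clade raises the diagnostic error", {
  # plant the divergence on the ortholog (target) side by swapping roles:
  # build a fixture where the target sits among low scorers
  sim <- simulate_paralog_tree(6, 6, divergence = 0, seed = 1)
  leaves <- sim$tree$phy$tip.label
  target <- sim$tree$target
  scores <- setNames(rep(100, length(leaves)), leaves)
  scores[sim$truth$ortholog_ids] <- c(60, 61, 62, 60, 61, 62)
  expect_error(
    trim_paralogs(sim$tree, sim$family, sim$lineages, scores = scores),
    "diagnostic")
})
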