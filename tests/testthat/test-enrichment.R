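# builders for small hand-countable cohorts: each family is one informative
# column (column 3 of width 6) with everything else conserved background
det_family <- function(id, residues) {
  column_family(id, residues, width = 6, at_column = 3)
}

test_that("a noise-free planted cohort is recovered exactly", {
  ch <- simulate_cohort(cohort_spec(seed = 21))
  res <- specific_approach(ch$couplers, ch$noncouplers)
  expect_setequal(res$positions, ch$truth$planted_columns)
  # frequencies: specific in every cross pair, in no within pair
  det <- res$table[res$table$column %in% ch$truth$planted_columns, ]
  expect_true(all(det$coupler_frequency == 1))
  expect_true(all(det$within_coupler_frequency == 0))
})

test_that("cross and within frequencies match explicit pair enumeration", {
  # 2 couplers x 3 non-couplers; one non-coupler carries the coupler
  # residue L, so only 2 of the 3 cross partners yield a specific call:
  # cross frequency 4/6, within 0/2
  c1 <- det_family("c1", rep("L", 10))
  c2 <- det_family("c2", rep("L", 10))
  n1 <- det_family("n1", rep("T", 10))
  n2 <- det_family("n2", rep("D", 10))
  n3 <- det_family("n3", rep("L", 10))
  res <- specific_approach(list(c1, c2), list(n1, n2, n3))
  row <- res$table[res$table$column == 3, ]
  expect_equal(row$coupler_frequency, 4 / 6)
  expect_equal(row$within_coupler_frequency, 0)
  expect_true(3 %in% res$positions)
  # denominators against an explicit enumeration
  n <- 2; m <- 3
  expect_equal(nrow(expand.grid(seq_len(n), seq_len(m))), n * m)
  ordered_pairs <- expand.grid(i = seq_len(n), k = seq_len(n))
  expect_equal(sum(ordered_pairs$i != ordered_pairs$k), n * (n - 1))
})

test_that("within-coupler variation excludes a column", {
  # couplers disagree (D vs K, dissimilar): specific_both within
  c1 <- det_family("c1", rep("D", 10))
  c2 <- det_family("c2", rep("K", 10))
  n1 <- det_family("n1", rep("T", 10))
  res <- specific_approach(list(c1, c2), list(n1))
  row <- res$table[res$table$column == 3, ]
  expect_gt(row$within_coupler_frequency, 0)
  expect_false(3 %in% res$positions)
})

test_that("fewer than two couplers is an error", {
  c1 <- det_family("c1", rep("L", 10))
  n1 <- det_family("n1", rep("T", 10))
  expect_error(specific_approach(list(c1), list(n1)), ">= 2 couplers")
})

test_that("the sensitive approach recovers a tolerated-variant determinant", {
  # coupler c2 carries the BLOSUM80-boundary variant M (score(L, M) = 2:
  # similar for the classifier, NOT credited as an allowed substitution),
  # so c2's own conservation drops to 0.6 < 0.7 and c1-vs-c2 becomes a
  # within-coupler specific call -> the specific approach drops the column.
  # Pooling c1 + c2 keeps modal L above 90%, and the pooled alignment vs
  # the non-coupler (T, dissimilar) is specific -> recovered.
  c1 <- det_family("c1", rep("L", 19))
  c2 <- det_family("c2", c("L", "L", "L", "M", "M"))
  nc <- det_family("nc", rep("T", 10))

  spec_res <- specific_approach(list(c1, c2), list(nc))
  expect_false(3 %in% spec_res$positions)
  expect_gt(spec_res$table$within_coupler_frequency[
    spec_res$table$column == 3], 0)

  sens_res <- sensitive_approach(combine_families(list(c1, c2)), list(nc))
  expect_true(3 %in% sens_res$positions)
})

test_that("non-couplers sharing the coupler residue are not reported", {
  comb <- combine_families(list(det_family("c1", rep("L", 10)),
                                det_family("c2", rep("L", 8))))
  nc <- det_family("nc", rep("L", 10))
  res <- sensitive_approach(comb, list(nc))
  expect_false(3 %in% res$positions)
  row <- res$table[res$table$column == 3, ]
  expect_equal(row$coupler_frequency, 0)
})

test_that("raising min_frequency only shrinks the sensitive set", {
  comb <- combine_families(list(det_family("c1", rep("L", 10))),
                           family_id = "comb")
  ncs <- list(det_family("n1", rep("T", 10)),
              det_family("n2", rep("L", 10)))
  loose <- sensitive_approach(comb, ncs, min_frequency = 0)
  strict <- sensitive_approach(comb, ncs, min_frequency = 0.99)
  expect_true(all(strict$positions %in% loose$positions))
  expect_true(3 %in% loose$positions)   # frequency 1/2 > 0
  expect_false(3 %in% strict$positions)
})

test_that("results are invariant to receptor order within groups", {
  ch <- simulate_cohort(cohort_spec(seed = 33))
  r1 <- specific_approach(ch$couplers, ch$noncouplers)
  r2 <- specific_approach(rev(ch$couplers), rev(ch$noncouplers))
  expect_equal(r1$table, r2$table)
})

test_that("pooled residue sets merge with provenance", {
  pool <- merge_residue_sets(specific = c(3L, 7L, 9L),
                             sensitive = c(7L, 12L),
                             consensus = NULL)
  expect_equal(nrow(pool), 4)
  expect_equal(pool$sources[pool$position == 7], "specific,sensitive")
  pool2 <- merge_residue_sets(specific = c(3L, 7L, 9L),
                              sensitive = NULL, consensus = c(1L, 2L))
  expect_equal(nrow(pool2), 5)
  map <- generic_number_map(tibble::tibble(
    residue_index = c(1L, 2L, 3L, 7L, 9L),
    generic_number = c("1x50", "2x50", "3x50", "7x41", "6x48")))
  pool3 <- merge_residue_sets(specific = c(3L, 7L), consensus = c(1L),
                              generic_map = map)
  expect_setequal(pool3$position, c("1x50", "3x50", "7x41"))
  expect_error(merge_residue_sets(specific = c(99L), generic_map = map),
               "no generic number")
})

test_that("tidy and glance expose the enrichment tables", {
  ch <- simulate_cohort(cohort_spec(seed = 2))
  res <- specific_approach(ch$couplers, ch$noncouplers, g_protein = "Gs")
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$g_protein, "Gs")
  expect_equal(g$n_couplers, 3)
})
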