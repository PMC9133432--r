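POSITION_LABELS <- c("specific_A", "specific_B", "specific_both",
                     "consensus", "none", "gap")

# vectorised classification over paired column profiles; the single-column
# and family-level wrappers both call this
classify_profiles <- function(profA, profB, spec_thr = 0.9, cons_thr = 0.9,
                              lower_thr = 0.7, matrix = "BLOSUM80",
                              consensus_min = 1, dissimilar_max = 2) {
  stopifnot(nrow(profA) == nrow(profB))
  consA <- profA$conservation
  consB <- profB$conservation
  mA <- profA$most_frequent
  mB <- profB$most_frequent
  s <- blosum_score(mA, mB, matrix)
  label <- rep("none", nrow(profA))

  gap <- profA$gap_flag | profB$gap_flag
  degenerate <- !gap & (is.na(mA) | is.na(mB))
  ok <- !gap & !degenerate

  consensus <- ok & consA > cons_thr & consB > cons_thr & s > consensus_min
  dis <- ok & !consensus & s < dissimilar_max
  sim <- ok & !consensus & !dis

  spec_a <- (dis & consA > spec_thr) |
    (sim & consA > spec_thr & consB < lower_thr)
  spec_b <- (dis & consB > spec_thr) |
    (sim & consB > spec_thr & consA < lower_thr)

  label[gap] <- "gap"
  label[consensus] <- "consensus"
  label[spec_a & !spec_b] <- "specific_A"
  label[!spec_a & spec_b] <- "specific_B"
  label[spec_a & spec_b] <- "specific_both"

  tibble(
    column_a = profA$column,
    column_b = profB$column,
    label = factor(label, levels = POSITION_LABELS),
    conservation_A = consA,
    conservation_B = consB,
    modal_A = mA,
    modal_B = mB,
    modal_similarity_score = s
  )
}

#' Classify one shared alignment column between two families
#'
#' Assigns a specificity verdict to a column shared by two receptor
#' families, from their per-column conservation profiles:
#'
#' * `gap` if either side is gap-flagged;
#' * `consensus` if both conservations exceed `cons_thr` and the modal
#'   residues are similar (BLOSUM80 score strictly greater than
#'   `consensus_min`);
#' * with dissimilar modals (score strictly below `dissimilar_max`), each
#'   side whose conservation exceeds `spec_thr` earns its specific label
#'   (possibly both sides);
#' * with similar modals, a side is specific only if it exceeds `spec_thr`
#'   while the other side falls below `lower_thr`;
#' * otherwise `none`.
#'
#' A BLOSUM80 score of exactly 2 is treated as "similar" in both the
#' consensus and the specificity branch; this is the only reading consistent
#' with the three stated cutoffs (more than 1 for consensus similarity,
#' lower than 2 for dissimilarity).
#'
#' @param colA,colB One-row profiles from [column_conservation()] for the
#'   same shared column.
#' @param spec_thr Specificity threshold (strict, default 0.9).
#' @param cons_thr Consensus threshold (strict, default 0.9).
#' @param lower_thr Lower threshold on the opposing family (strict,
#'   default 0.7).
#' @param matrix Substitution matrix name.
#' @param consensus_min Modal similarity must exceed this for `consensus`.
#' @param dissimilar_max Modal similarity below this counts as dissimilar.
#' @return One-row tibble with the label and the quantities it was derived
#'   from.
#' @export
classify_position <- function(colA, colB, spec_thr = 0.9, cons_thr = 0.9,
                              lower_thr = 0.7, matrix = "BLOSUM80",
                              consensus_min = 1, dissimilar_max = 2) {
  stopifnot(nrow(colA) == 1, nrow(colB) == 1)
  classify_profiles(colA, colB, spec_thr = spec_thr, cons_thr = cons_thr,
                    lower_thr = lower_thr, matrix = matrix,
                    consensus_min = consensus_min,
                    dissimilar_max = dissimilar_max)
}

#' Compare two families column by column
#'
#' Computes conservation profiles for both families and classifies every
#' mapped column pair. With the default identity map the families must have
#' equal width (the usual case where both derive from one combined MSA that
#' was split in two).
#'
#' @param familyA,familyB [aligned_family()] objects.
#' @param column_map Optional tibble with integer columns `column_a`,
#'   `column_b` pairing alignment columns; default pairs column i with
#'   column i.
#' @param ... Thresholds passed on to [classify_position()].
#' @param allowed_min,gap_max Conservation parameters (see
#'   [column_conservation()]).
#' @return Tibble of class `position_labels`, one row per mapped column.
#' @export
compare_families <- function(familyA, familyB, column_map = NULL, ...,
                             allowed_min = 2, gap_max = 0.5) {
  profA <- msa_conservation_profile(familyA, allowed_min = allowed_min,
                                    gap_max = gap_max)
  profB <- msa_conservation_profile(familyB, allowed_min = allowed_min,
                                    gap_max = gap_max)
  compare_profiles(profA, profB, column_map = column_map, ...,
                   families = c(familyA$family_id, familyB$family_id))
}

compare_profiles <- function(profA, profB, column_map = NULL, ...,
                             families = c("A", "B")) {
  if (is.null(column_map)) {
    if (nrow(profA) != nrow(profB)) {
      abort("families differ in width; supply an explicit column_map")
    }
    column_map <- tibble(column_a = profA$column, column_b = profB$column)
  }
  bad_a <- setdiff(column_map$column_a, profA$column)
  bad_b <- setdiff(column_map$column_b, profB$column)
  if (length(bad_a) + length(bad_b) > 0) {
    abort(paste0("column map references unmapped column(s): ",
                 paste(c(bad_a, bad_b), collapse = ", ")))
  }
  out <- classify_profiles(
    profA[match(column_map$column_a, profA$column), ],
    profB[match(column_map$column_b, profB$column), ],
    ...
  )
  structure(out, families = families,
            class = c("position_labels", class(out)))
}

#' @export
print.position_labels <- function(x, ...) {
  fams <- attr(x, "families")
  cat("<position_labels> ", fams[1], " vs ", fams[2], ": ", nrow(x),
      " columns\n", sep = "")
  NextMethod()
}

#' Positions conserved across a whole set of families
#'
#' A column is a consensus position when it is labelled `consensus` in at
#' least `min_fraction` of all pairwise family comparisons (default: all of
#' them). Used to link specifically conserved residues to the shared
#' activation machinery of the receptor family.
#'
#' @param families List of equal-width [aligned_family()] objects
#'   (length >= 2).
#' @param min_fraction Required fraction of pairwise comparisons labelled
#'   consensus (default 1).
#' @param ... Passed to [compare_families()].
#' @return Tibble with `column`, `n_pairs`, `consensus_fraction` for columns
#'   meeting the fraction.
#' @export
consensus_positions <- function(families, min_fraction = 1, ...) {
  stopifnot(length(families) >= 2)
  profiles <- lapply(families, msa_conservation_profile)
  pairs <- utils::combn(length(families), 2, simplify = FALSE)
  hits <- lapply(pairs, function(p) {
    labs <- compare_profiles(profiles[[p[1]]], profiles[[p[2]]], ...)
    tibble(column = labs$column_a, consensus = labs$label == "consensus")
  })
  bind_rows(hits) |>
    group_by(.data$column) |>
    summarise(n_pairs = n(),
              consensus_fraction = mean(.data$consensus),
              .groups = "drop") |>
    filter(.data$consensus_fraction >= min_fraction)
}
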