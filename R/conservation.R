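#' Conservation of one alignment column
#'
#' Implements the ortholog-conservation score with substitution tolerance:
#' the most frequent residue of the column is found, every other residue
#' whose BLOSUM80 score against it is strictly greater than `allowed_min`
#' counts as an "allowed" substitution, and the conservation score is the
#' fraction of non-gap rows holding either the modal residue or an allowed
#' substitute. Columns with more than `gap_max` gaps are flagged as gap
#' positions and receive no score.
#'
#' Ties for the modal residue are broken by alphabetical amino-acid order.
#' `X` counts in the non-gap denominator but can be neither modal nor
#' allowed.
#'
#' @param column_residues Character vector of single residues (with `-` for
#'   gaps) making up one alignment column.
#' @param matrix Substitution matrix name (see [blosum_matrix()]).
#' @param allowed_min Substitutions scoring strictly above this value are
#'   "allowed" (default 2, i.e. integer scores >= 3 qualify).
#' @param gap_max Maximum tolerated gap fraction (default 0.5; strictly more
#'   gaps flags the column).
#' @param column 1-based column index recorded in the profile.
#' @return One-row tibble with `column`, `n`, `gap_fraction`, `gap_flag`,
#'   `most_frequent`, `conservation` and a `counts` list-column.
#' @export
#' @examples
#' column_conservation(c("L", "L", "L", "I", "-"))
column_conservation <- function(column_residues, matrix = "BLOSUM80",
                                allowed_min = 2, gap_max = 0.5,
                                column = 1L) {
  if (length(column_residues) == 0) abort("empty alignment column")
  bad <- setdiff(unique(column_residues), c(AA_ALPHABET, MSA_EXTRA_SYMBOLS))
  if (length(bad) > 0) {
    abort(paste0("unknown residue symbol(s): ", paste(bad, collapse = ", ")))
  }
  n <- length(column_residues)
  n_gap <- sum(column_residues == "-")
  gap_fraction <- n_gap / n
  res <- column_residues[column_residues != "-"]
  counts <- table(factor(res, levels = c(AA_ALPHABET, "X")))
  counts <- counts[counts > 0]
  profile <- tibble(
    column = as.integer(column),
    n = n,
    gap_fraction = gap_fraction,
    gap_flag = gap_fraction > gap_max,
    most_frequent = NA_character_,
    conservation = NA_real_,
    counts = list(counts)
  )
  if (profile$gap_flag) return(profile)
  candidates <- counts[names(counts) != "X"]
  if (length(candidates) == 0) return(profile)
  # modal residue; ties resolved by the alphabetical order of the levels
  modal <- names(candidates)[which.max(candidates)]
  others <- setdiff(names(candidates), modal)
  allowed <- if (length(others) > 0) {
    others[blosum_score(modal, others, matrix) > allowed_min]
  } else {
    character(0)
  }
  profile$most_frequent <- modal
  profile$conservation <-
    (candidates[[modal]] + sum(counts[allowed])) / (n - n_gap)
  profile
}

#' Column-wise conservation profile of a family
#'
#' Applies [column_conservation()] to every column of the alignment,
#' preserving column order.
#'
#' @param family An [aligned_family()].
#' @inheritParams column_conservation
#' @return Tibble of class `conservation_profile`, one row per column.
#' @export
msa_conservation_profile <- function(family, matrix = "BLOSUM80",
                                     allowed_min = 2, gap_max = 0.5) {
  stopifnot(inherits(family, "aligned_family"))
  m <- family_matrix(family)
  profiles <- lapply(seq_len(ncol(m)), function(j) {
    column_conservation(m[, j], matrix = matrix, allowed_min = allowed_min,
                        gap_max = gap_max, column = j)
  })
  out <- bind_rows(profiles)
  structure(out,
            family_id = family$family_id,
            class = c("conservation_profile", class(out)))
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", attr(x, "family_id"), ": ", nrow(x),
      " columns, ", sum(x$gap_flag), " gap-flagged\n", sep = "")
  NextMethod()
}
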