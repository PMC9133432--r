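#' Aligned ortholog family
#'
#' Container for one receptor's ortholog multiple sequence alignment: a tibble
#' of aligned sequences with species annotations plus the index of the human
#' target sequence. This is the unit of conservation analysis.
#'
#' @param sequences Tibble (or data frame) with columns `seq_id`, `species`
#'   and `residues` (aligned amino-acid strings using `-` for gaps).
#' @param family_id Identifier for the family.
#' @param target `seq_id` of the human target sequence. Defaults to the single
#'   sequence whose species is `HUMAN`/`Homo sapiens` when unambiguous,
#'   otherwise the first sequence.
#' @return An object of class `aligned_family`.
#' @export
#' @examples
#' fam <- aligned_family(
#'   tibble::tibble(
#'     seq_id = c("r1_HUMAN", "r1_MOUSE"),
#'     species = c("HUMAN", "MOUSE"),
#'     residues = c("MLKV", "MLRV")
#'   ),
#'   family_id = "r1"
#' )
#' fam
aligned_family <- function(sequences, family_id = "family", target = NULL) {
  sequences <- as_tibble(sequences)
  required <- c("seq_id", "species", "residues")
  missing_cols <- setdiff(required, names(sequences))
  if (length(missing_cols) > 0) {
    abort(paste0("sequences is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(sequences) == 0) abort("family must contain at least one sequence")
  if (anyDuplicated(sequences$seq_id)) {
    abort(paste0("duplicate seq_id: ",
                 sequences$seq_id[duplicated(sequences$seq_id)][1]))
  }
  widths <- nchar(sequences$residues)
  if (any(widths < 1)) abort("aligned sequences must have length >= 1")
  if (length(unique(widths)) != 1) {
    bad <- sequences$seq_id[widths != widths[1]][1]
    abort(paste0("ragged alignment: sequence '", bad, "' has length ",
                 widths[widths != widths[1]][1], ", expected ", widths[1]))
  }
  chars <- unique(unlist(strsplit(sequences$residues, "", fixed = TRUE)))
  bad <- setdiff(chars, c(AA_ALPHABET, MSA_EXTRA_SYMBOLS))
  if (length(bad) > 0) {
    abort(paste0("unknown residue symbol(s): ", paste(bad, collapse = ", ")))
  }
  target_index <- resolve_target(sequences, target)
  structure(
    list(
      family_id = family_id,
      sequences = sequences,
      target_index = target_index
    ),
    class = "aligned_family"
  )
}

resolve_target <- function(sequences, target) {
  if (!is.null(target)) {
    idx <- match(target, sequences$seq_id)
    if (is.na(idx)) abort(paste0("target '", target, "' not found in family"))
    return(idx)
  }
  human <- which(tolower(sequences$species) %in% c("human", "homo sapiens"))
  if (length(human) == 1) human else 1L
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("<aligned_family> ", x$family_id, ": ", nrow(x$sequences),
      " sequences x ", family_width(x), " columns (target: ",
      x$sequences$seq_id[x$target_index], ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.aligned_family <- function(x, ...) x$sequences

#' Alignment width (number of columns)
#' @param family An [aligned_family()].
#' @return Integer number of alignment columns.
#' @export
family_width <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  nchar(family$sequences$residues[1])
}

#' Alignment as a character matrix
#'
#' Rows are sequences (named by `seq_id`), columns are 1-based alignment
#' columns.
#' @param family An [aligned_family()].
#' @return Character matrix of single residues.
#' @export
family_matrix <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  m <- do.call(rbind, strsplit(family$sequences$residues, "", fixed = TRUE))
  rownames(m) <- family$sequences$seq_id
  m
}

#' Target sequence id of a family
#' @param family An [aligned_family()].
#' @return The `seq_id` of the human target sequence.
#' @export
family_target <- function(family) {
  family$sequences$seq_id[family$target_index]
}

#' Ungapped sequence of one family member
#' @param family An [aligned_family()].
#' @param seq_id Sequence identifier.
#' @return Character scalar with gap characters removed.
#' @export
ungapped_sequence <- function(family, seq_id) {
  idx <- match(seq_id, family$sequences$seq_id)
  if (is.na(idx)) abort(paste0("sequence '", seq_id, "' not in family"))
  gsub("-", "", family$sequences$residues[idx], fixed = TRUE)
}

#' Subset a family to a set of sequences
#'
#' Keeps the given sequences (in their original order). The target is
#' retained automatically.
#' @param family An [aligned_family()].
#' @param seq_ids Character vector of sequence ids to keep.
#' @return An [aligned_family()].
#' @export
subset_family <- function(family, seq_ids) {
  keep <- union(family_target(family), seq_ids)
  rows <- family$sequences[family$sequences$seq_id %in% keep, ]
  aligned_family(rows, family_id = family$family_id,
                 target = family_target(family))
}

#' Combine several families into one alignment
#'
#' Row-binds the member sequences of equal-width families (used by the
#' sensitive enrichment approach to pool coupler receptors with their
#' orthologs). Sequence ids must be unique across families.
#'
#' @param families List of [aligned_family()] objects of identical width.
#' @param family_id Identifier for the combined family.
#' @param target Optional target `seq_id`; defaults to the first family's
#'   target.
#' @return An [aligned_family()].
#' @export
combine_families <- function(families, family_id = "combined", target = NULL) {
  stopifnot(length(families) >= 1)
  widths <- vapply(families, family_width, integer(1))
  if (length(unique(widths)) != 1) {
    abort("families must share a common alignment width to be combined")
  }
  seqs <- bind_rows(lapply(families, function(f) f$sequences))
  aligned_family(seqs, family_id = family_id,
                 target = target %||% family_target(families[[1]]))
}
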