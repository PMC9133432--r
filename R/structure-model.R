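#' Heavy-atom structure model
#'
#' A structure is represented as a tibble of heavy atoms (one row per atom)
#' carrying residue bookkeeping and, where a generic-number map provides one,
#' the GPCRdb generic number of the residue. Coordinates are in Angstrom and
#' residue indexing follows the author (PDB) numbering.
#'
#' @param atoms Tibble with columns `chain`, `residue_index`, `residue_name`,
#'   `atom_name`, `element`, `x`, `y`, `z` and optionally `generic_number`.
#' @param structure_id Identifier (e.g. a PDB id).
#' @param state Activation state, `"active"` or `"inactive"`.
#' @return An object of class `structure_model` (a tibble subclass).
#' @export
structure_model <- function(atoms, structure_id = "structure",
                            state = c("active", "inactive")) {
  state <- match.arg(state)
  atoms <- as_tibble(atoms)
  required <- c("chain", "residue_index", "residue_name", "atom_name",
                "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"generic_number" %in% names(atoms)) {
    atoms$generic_number <- NA_character_
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) abort("non-finite atom coordinates")
  # a generic number, when present, must belong to a single residue
  gn <- distinct(atoms[!is.na(atoms$generic_number),
                       c("chain", "residue_index", "generic_number")])
  if (anyDuplicated(gn$generic_number)) {
    abort(paste0("generic number assigned to more than one residue: ",
                 gn$generic_number[duplicated(gn$generic_number)][1]))
  }
  structure(
    atoms,
    structure_id = structure_id,
    state = state,
    class = c("structure_model", class(atoms))
  )
}

#' @export
print.structure_model <- function(x, ...) {
  res <- distinct(as_tibble(x)[, c("chain", "residue_index")])
  cat("<structure_model> ", attr(x, "structure_id"), " (",
      attr(x, "state"), "): ", nrow(res), " residues, ", nrow(x),
      " heavy atoms\n", sep = "")
  NextMethod()
}

structure_id <- function(x) attr(x, "structure_id")
structure_state <- function(x) attr(x, "state")

# residue label used as contact-network node key: the generic number when
# annotated, otherwise chain:index
residue_labels <- function(atoms) {
  ifelse(is.na(atoms$generic_number),
         paste0(atoms$chain, ":", atoms$residue_index),
         atoms$generic_number)
}

#' Validate a GPCRdb generic-number map
#'
#' A generic-number map relates author residue indices to GPCRdb generic
#' numbers of the form `TMxYY` (e.g. `7x41`). The map must be injective.
#'
#' @param map Tibble (or data frame) with columns `residue_index` and
#'   `generic_number`.
#' @return The validated map as a tibble.
#' @export
generic_number_map <- function(map) {
  map <- as_tibble(map)
  missing_cols <- setdiff(c("residue_index", "generic_number"), names(map))
  if (length(missing_cols) > 0) {
    abort(paste0("map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- !grepl("^[0-9]+x[0-9]+$", map$generic_number)
  if (any(bad)) {
    abort(paste0("malformed generic number: ", map$generic_number[bad][1]))
  }
  if (anyDuplicated(map$generic_number) || anyDuplicated(map$residue_index)) {
    abort("generic-number map must be one-to-one")
  }
  map
}
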