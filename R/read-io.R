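#' Read an aligned FASTA file into an aligned family
#'
#' Species are parsed from record headers with a configurable regular
#' expression whose first capture group is the species token; the default
#' matches UniProt `..._SPECIES` mnemonics (e.g. `sp|P07550|ADRB2_HUMAN`
#' gives `HUMAN`).
#'
#' @param path Path to a FASTA file with equal-length (aligned) records.
#' @param species_pattern Regular expression with one capture group applied
#'   to each header to extract the species token. Headers that do not match
#'   get species `NA`.
#' @param family_id Family identifier; defaults to the file name.
#' @param target Optional target `seq_id` (see [aligned_family()]).
#' @return An [aligned_family()].
#' @export
read_fasta_msa <- function(path, species_pattern = "_([A-Za-z0-9]+)\\s*$",
                           family_id = NULL, target = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  species <- stringr::str_match(names(set), species_pattern)[, 2]
  fam <- aligned_family(
    tibble(seq_id = ids, species = species,
           residues = toupper(as.character(set))),
    family_id = family_id %||% sub("\\.[^.]*$", "", basename(path)),
    target = target
  )
  fam
}

#' Write an aligned family to FASTA
#'
#' @param family An [aligned_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_msa <- function(family, path) {
  stopifnot(inherits(family, "aligned_family"))
  set <- Biostrings::AAStringSet(
    setNames(family$sequences$residues, family$sequences$seq_id)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Newick gene tree
#'
#' Leaf names are resolved to (seq_id, species) with the same configurable
#' species pattern used for FASTA headers. Polytomies are accepted at load
#' time; they are resolved only by [root_by_outgroup()]. Human leaves are
#' recognised by species token `HUMAN` or `Homo sapiens` (case-insensitive).
#'
#' @inheritParams read_fasta_msa
#' @param path Path to a Newick file.
#' @param lineages Optional lineage table (see [read_lineages()]) used to
#'   annotate leaves with taxonomic lineages.
#' @param target Optional target leaf `seq_id`.
#' @return A [gene_tree()].
#' @export
read_newick <- function(path, species_pattern = "_([A-Za-z0-9]+)\\s*$",
                        lineages = NULL, target = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) abort(paste0("Newick parse error in ",
                                                   path, ": ", conditionMessage(e))))
  if (is.null(phy)) abort(paste0("Newick parse error in ", path))
  species <- stringr::str_match(phy$tip.label, species_pattern)[, 2]
  if (anyNA(species)) {
    abort(paste0("leaf name(s) not resolvable to a species: ",
                 paste(phy$tip.label[is.na(species)], collapse = ", ")))
  }
  leaves <- tibble(
    seq_id = phy$tip.label,
    species = species,
    is_human = tolower(species) %in% c("human", "homo sapiens")
  )
  if (!is.null(lineages)) {
    leaves$lineage <- lineages$lineage[match(tolower(leaves$species),
                                             tolower(lineages$species))]
  }
  gene_tree(phy, leaves, target = target)
}

#' Read a coupling-profile table
#'
#' Tab-separated table with columns `receptor`, `g_protein`, `source` and
#' `couples` (0/1). Each (receptor, g_protein, source) combination must be
#' present exactly once, and `g_protein` names must come from a fixed
#' vocabulary of the 11 Galpha subtypes.
#'
#' @param path Path to the TSV file.
#' @param g_proteins Controlled vocabulary of Galpha subtype names.
#' @return A tibble with `couples` as logical.
#' @export
read_coupling_table <- function(path, g_proteins = G_PROTEIN_SUBTYPES) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  coupling_table(tab, g_proteins = g_proteins)
}

#' Validate a coupling table held in memory
#'
#' @param tab Tibble with columns `receptor`, `g_protein`, `source`,
#'   `couples`.
#' @inheritParams read_coupling_table
#' @return A validated tibble with `couples` as logical.
#' @export
coupling_table <- function(tab, g_proteins = G_PROTEIN_SUBTYPES) {
  tab <- as_tibble(tab)
  required <- c("receptor", "g_protein", "source", "couples")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("coupling table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$g_protein), g_proteins)
  if (length(bad) > 0) {
    abort(paste0("unknown G protein subtype(s): ",
                 paste(bad, collapse = ", ")))
  }
  key <- paste(tab$receptor, tab$g_protein, tab$source, sep = "\r")
  if (anyDuplicated(key)) {
    abort("each (receptor, g_protein, source) must appear exactly once")
  }
  tab$couples <- as.logical(as.integer(tab$couples))
  tab
}

#' The 11 Galpha subtypes
#'
#' Controlled vocabulary for coupling-profile tables, covering the chimeric
#' Galpha panel used by the underlying coupling datasets.
#' @format Character vector of length 11.
#' @export
G_PROTEIN_SUBTYPES <- c("Gs", "Gi1", "Gi3", "Go", "Gz", "Gq",
                        "G11", "G14", "G15", "G12", "G13")

#' Read a GPCRdb generic-number map
#'
#' Tab-separated columns `residue_index`, `generic_number`.
#' @param path Path to the TSV file.
#' @return A validated map tibble (see [generic_number_map()]).
#' @export
read_generic_map <- function(path) {
  map <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  generic_number_map(map)
}

#' Read a species lineage table
#'
#' Tab-separated columns `species` and `lineage`, the latter a
#' semicolon-separated list of taxonomic ranks ordered root-most first.
#' @param path Path to the TSV file.
#' @return Tibble with `species` and a `lineage` list-column.
#' @export
read_lineages <- function(path) {
  tab <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(c("species", "lineage"), names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("lineage table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(
    species = tab$species,
    lineage = strsplit(tab$lineage, ";", fixed = TRUE)
  )
}

#' Read a PDB structure into a heavy-atom model
#'
#' Hydrogen (and deuterium) atoms are dropped. When alternate locations are
#' present, the highest-occupancy altloc of each atom is kept (ties go to the
#' first record). Duplicated atom serial numbers produce a warning and the
#' first record wins. Residues listed in the generic-number map are annotated;
#' all others are retained unannotated.
#'
#' @param path Path to a PDB file.
#' @param generic_map Optional map from [generic_number_map()] /
#'   [read_generic_map()].
#' @param state Activation state of the structure.
#' @param structure_id Identifier; defaults to the file name.
#' @param chain Optional chain to restrict to (e.g. the receptor chain of a
#'   complex).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, generic_map = NULL,
                           state = c("active", "inactive"),
                           structure_id = NULL, chain = NULL) {
  state <- match.arg(state)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # rm.alt = FALSE: all altlocs are read so the highest-occupancy rule
  # below can pick one; bio3d's own altloc/serial notes are superseded by
  # the explicit handling here
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- as_tibble(pdb$atom)
  at <- at[at$type %in% c("ATOM", "HETATM"), ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  if (anyDuplicated(at$eleno)) {
    warn(paste0("duplicate atom serial number(s) in ", path,
                "; keeping first occurrence"))
    at <- at[!duplicated(at$eleno), ]
  }
  element <- toupper(trimws(at$elesy))
  fallback <- is.na(element) | element == ""
  if (any(fallback)) {
    # derive the element from the atom name: strip digits, take first letter
    element[fallback] <-
      substr(gsub("[0-9']", "", toupper(trimws(at$elety[fallback]))), 1, 1)
  }
  heavy <- !(element %in% c("H", "D"))
  at <- at[heavy, ]
  element <- element[heavy]
  if (nrow(at) == 0 || !any(trimws(at$elety) == "CA" & at$resid != "CA")) {
    abort(paste0("not a protein structure (no CA atoms): ", path))
  }
  # altloc rule: keep the highest-occupancy alternate of each named atom
  alt <- trimws(at$alt)
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  atom_key <- paste(at$chain, at$resno, trimws(at$elety), sep = "\r")
  ord <- order(atom_key, -occ, alt, seq_len(nrow(at)))
  at <- at[ord, ][!duplicated(atom_key[ord]), ]
  element <- element[ord][!duplicated(atom_key[ord])]
  ord2 <- order(at$eleno)
  at <- at[ord2, ]
  element <- element[ord2]
  atoms <- tibble(
    chain = at$chain,
    residue_index = at$resno,
    residue_name = trimws(at$resid),
    atom_name = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    generic_number = NA_character_
  )
  if (!is.null(generic_map)) {
    generic_map <- generic_number_map(generic_map)
    atoms$generic_number <-
      generic_map$generic_number[match(atoms$residue_index,
                                       generic_map$residue_index)]
  }
  structure_model(
    atoms,
    structure_id = structure_id %||% sub("\\.[^.]*$", "", basename(path)),
    state = state
  )
}

#' Write a contact network as a Cytoscape-compatible edge table
#'
#' Tab-separated columns `source_generic`, `target_generic`, `score` and,
#' when present, `p_value`. Edges are written in canonical lexicographic
#' order, so a given network always produces byte-identical output.
#'
#' @param network A [contact_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(network, path) {
  if (is.null(network)) abort("network must not be NULL")
  stopifnot(inherits(network, "contact_network"))
  score_col <- intersect(c("score", "delta", "delta_delta", "count"),
                         names(network))
  score <- if (length(score_col) > 0) network[[score_col[1]]] else
    rep(NA_real_, nrow(network))
  out <- data.frame(
    source_generic = network$source,
    target_generic = network$target,
    score = score,
    stringsAsFactors = FALSE
  )
  if ("p_value" %in% names(network)) out$p_value <- network$p_value
  out <- out[order(out$source_generic, out$target_generic), , drop = FALSE]
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(paste0("cannot write to ", path)))
  on.exit(close(con))
  write.table(format(out, trim = TRUE, digits = 15, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
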