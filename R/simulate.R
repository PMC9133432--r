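#' Specification for a synthetic ortholog family
#'
#' Describes the statistical structure of a simulated ortholog MSA: which
#' columns are conserved (one planted residue, possibly noised), which are
#' "specific" (a fixed planted residue, typically coordinated across
#' families by [simulate_cohort()]), and which are variable (uniform
#' residue draws per row). Remaining columns behave like conserved
#' background. Substitution noise flips a cell to a uniformly random other
#' residue; gaps are introduced independently.
#'
#' @param n_orthologs Number of sequences.
#' @param length Number of alignment columns.
#' @param conserved_columns,specific_columns,variable_columns Disjoint
#'   1-based column index sets within `[1, length]`.
#' @param substitution_noise Per-cell flip probability in non-variable
#'   columns.
#' @param gap_rate Per-cell gap probability.
#' @param seed Integer seed; generators are pure functions of spec + seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_orthologs, length, conserved_columns = integer(),
                        specific_columns = integer(),
                        variable_columns = integer(),
                        substitution_noise = 0, gap_rate = 0, seed = 1L) {
  stopifnot(is_count(n_orthologs, min = 1), is_count(length, min = 1),
            is_probability(substitution_noise), is_probability(gap_rate))
  sets <- list(conserved = as.integer(conserved_columns),
               specific = as.integer(specific_columns),
               variable = as.integer(variable_columns))
  all_cols <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_cols)) {
    abort("conserved/specific/variable column sets must be disjoint")
  }
  if (length(all_cols) > 0 && (min(all_cols) < 1 || max(all_cols) > length)) {
    abort("column indices must lie in [1, length]")
  }
  structure(
    list(n_orthologs = as.integer(n_orthologs), length = as.integer(length),
         conserved_columns = sets$conserved,
         specific_columns = sets$specific,
         variable_columns = sets$variable,
         substitution_noise = substitution_noise, gap_rate = gap_rate,
         seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' Simulate an ortholog family with planted column structure
#'
#' @param spec A [family_spec()].
#' @param family_id Family identifier.
#' @param base_sequence Optional reference residue per column (character
#'   vector of length `spec$length`); drawn uniformly when absent.
#' @param specific_residues Optional named character vector giving the
#'   planted residue of each specific column (names are column indices).
#' @return An [aligned_family()]; the planted truth (base sequence and
#'   column sets) is attached as attribute `"truth"`.
#' @export
simulate_family <- function(spec, family_id = "fam", base_sequence = NULL,
                            specific_residues = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    n <- spec$n_orthologs
    base <- base_sequence %||% sample(AA_ALPHABET, L, replace = TRUE)
    stopifnot(length(base) == L)
    if (!is.null(specific_residues)) {
      base[as.integer(names(specific_residues))] <- specific_residues
    }
    m <- matrix(rep(base, each = n), nrow = n)
    for (j in spec$variable_columns) {
      m[, j] <- sample(AA_ALPHABET, n, replace = TRUE)
    }
    if (spec$substitution_noise > 0) {
      fixed_cols <- setdiff(seq_len(L), spec$variable_columns)
      for (j in fixed_cols) {
        flip <- runif(n) < spec$substitution_noise
        if (any(flip)) {
          m[flip, j] <- vapply(which(flip), function(i) {
            sample(setdiff(AA_ALPHABET, m[i, j]), 1)
          }, character(1))
        }
      }
    }
    if (spec$gap_rate > 0) {
      gap <- matrix(runif(n * L) < spec$gap_rate, nrow = n)
      m[gap] <- "-"
    }
    species <- c("HUMAN", sprintf("SP%03d", seq_len(max(n - 1, 0))))[seq_len(n)]
    fam <- aligned_family(
      tibble(
        seq_id = paste0(family_id, "_", species),
        species = species,
        residues = apply(m, 1, paste0, collapse = "")
      ),
      family_id = family_id,
      target = paste0(family_id, "_HUMAN")
    )
    attr(fam, "truth") <- list(
      base_sequence = base,
      conserved_columns = spec$conserved_columns,
      specific_columns = spec$specific_columns,
      variable_columns = spec$variable_columns
    )
    fam
  })
}

#' Specification for a coupler / non-coupler receptor cohort
#'
#' Defines a synthetic cohort mimicking the determinant structure the
#' enrichment step looks for: at each planted determinant column, every
#' coupler family conserves one residue while every non-coupler family
#' conserves a BLOSUM80-dissimilar residue. All families additionally share
#' conserved background columns (which become consensus positions) and a
#' common set of variable columns.
#'
#' @param n_couplers,n_noncouplers Family counts (couplers >= 2).
#' @param planted_determinants Column indices of the planted determinants.
#' @param length Alignment width.
#' @param n_orthologs Sequences per family.
#' @param variable_columns Column indices drawn uniformly at random per row
#'   in every family; by default every fourth column not holding a planted
#'   determinant.
#' @param substitution_noise,gap_rate Per-family noise (see
#'   [family_spec()]).
#' @param determinant_residue Residue conserved by couplers at determinant
#'   columns.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_couplers = 3, n_noncouplers = 3,
                        planted_determinants = c(5L, 20L, 35L),
                        length = 60, n_orthologs = 12,
                        variable_columns = NULL,
                        substitution_noise = 0, gap_rate = 0,
                        determinant_residue = "L", seed = 1L) {
  stopifnot(is_count(n_couplers, 2), is_count(n_noncouplers, 1))
  if (is.null(variable_columns)) {
    variable_columns <- setdiff(seq(3L, length, by = 4L),
                                planted_determinants)
  }
  if (base::length(variable_columns) > 0 && max(variable_columns) > length) {
    abort("variable columns must lie within the alignment")
  }
  if (length(intersect(planted_determinants, variable_columns)) > 0) {
    abort("planted determinants must not be variable columns")
  }
  if (length(planted_determinants) > 0 &&
      max(planted_determinants) > length) {
    abort("planted determinants must lie within the alignment")
  }
  structure(
    list(n_couplers = as.integer(n_couplers),
         n_noncouplers = as.integer(n_noncouplers),
         planted_determinants = as.integer(planted_determinants),
         length = as.integer(length),
         n_orthologs = as.integer(n_orthologs),
         variable_columns = as.integer(variable_columns),
         substitution_noise = substitution_noise, gap_rate = gap_rate,
         determinant_residue = determinant_residue,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a coupler / non-coupler cohort with planted determinants
#'
#' @param spec A [cohort_spec()].
#' @return List with `couplers` and `noncouplers` (lists of
#'   [aligned_family()]) and `truth` (planted columns and residues) --
#'   the ground-truth sidecar tests score recovery against.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    det <- spec$planted_determinants
    base <- sample(AA_ALPHABET, L, replace = TRUE)
    r1 <- spec$determinant_residue
    # residues clearly dissimilar to the coupler determinant (BLOSUM80 < 2
    # keeps the classifier in its dissimilar branch)
    dissim <- AA_ALPHABET[blosum_score(r1, AA_ALPHABET) < 2]
    noncoupler_res <- matrix(
      sample(dissim, spec$n_noncouplers * length(det), replace = TRUE),
      nrow = spec$n_noncouplers
    )
    seeds <- sample.int(.Machine$integer.max,
                        spec$n_couplers + spec$n_noncouplers)
    make <- function(idx, id, residues_at_det) {
      fs <- family_spec(
        n_orthologs = spec$n_orthologs, length = L,
        specific_columns = det,
        variable_columns = spec$variable_columns,
        substitution_noise = spec$substitution_noise,
        gap_rate = spec$gap_rate, seed = seeds[idx]
      )
      simulate_family(
        fs, family_id = id, base_sequence = base,
        specific_residues = setNames(residues_at_det, as.character(det))
      )
    }
    couplers <- lapply(seq_len(spec$n_couplers), function(i) {
      make(i, sprintf("coupler%02d", i), rep(r1, length(det)))
    })
    noncouplers <- lapply(seq_len(spec$n_noncouplers), function(i) {
      make(spec$n_couplers + i, sprintf("noncoupler%02d", i),
           noncoupler_res[i, ])
    })
    list(
      couplers = couplers,
      noncouplers = noncouplers,
      truth = list(
        planted_columns = det,
        determinant_residue = r1,
        noncoupler_residues = noncoupler_res
      )
    )
  })
}

mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  flip <- runif(length(seq)) < p
  if (any(flip)) {
    seq[flip] <- vapply(which(flip), function(i) {
      sample(setdiff(AA_ALPHABET, seq[i]), 1)
    }, character(1))
  }
  seq
}

ladder_newick <- function(ids) {
  Reduce(function(a, b) paste0("(", a, ",", b, ")"), ids)
}

#' Simulate a gene tree with a diverged paralogous clade
#'
#' Builds a rooted tree `(outgroup, (orthologs, paralogs))` whose two inner
#' sibling clades share species content, with paralog sequences evolved
#' under extra divergence so their BLOSUM62 global-alignment scores against
#' the human target are stochastically lower. At `divergence = 0` the two
#' clades are statistically indistinguishable (the type-I calibration
#' condition); at high divergence the paralog clade should be removed by
#' [trim_paralogs()].
#'
#' @param n_ortho,n_paralog Clade sizes (each >= 3 for the t-test path).
#' @param divergence Extra expected substitutions/site on the paralog
#'   branch; converted to a per-site substitution probability
#'   `1 - exp(-divergence)`.
#' @param shared_species Number of species present in both clades
#'   (`<= min(n_ortho - 1, n_paralog)`).
#' @param seed Integer seed.
#' @param length Sequence length.
#' @param base_noise Per-site substitution probability applied to every
#'   non-target leaf.
#' @param outgroup_divergence Extra divergence of the human outgroup
#'   paralog.
#' @return List with `tree` ([gene_tree()]), `family`
#'   ([aligned_family()]), `lineages` (uniform lineage table) and `truth`
#'   (paralog leaf ids).
#' @export
simulate_paralog_tree <- function(n_ortho, n_paralog, divergence = 0,
                                  shared_species = min(n_ortho - 1, n_paralog),
                                  seed = 1L, length = 120,
                                  base_noise = 0.05,
                                  outgroup_divergence = 0.8) {
  stopifnot(n_ortho >= 3, n_paralog >= 3, divergence >= 0)
  if (shared_species > min(n_ortho - 1, n_paralog)) {
    abort("shared_species exceeds the available species overlap")
  }
  with_seed(seed, {
    target <- sample(AA_ALPHABET, length, replace = TRUE)
    p_div <- 1 - exp(-divergence)
    p_out <- 1 - exp(-outgroup_divergence)

    ortho_species <- c("HUMAN", sprintf("SP%02d", seq_len(n_ortho - 1)))
    par_species <- c(
      sprintf("SP%02d", seq_len(shared_species)),
      if (n_paralog > shared_species)
        sprintf("PSP%02d", seq_len(n_paralog - shared_species))
    )
    ortho_ids <- paste0("ortho", seq_len(n_ortho), "_", ortho_species)
    par_ids <- paste0("para", seq_len(n_paralog), "_", par_species)
    out_id <- "outgroup_HUMAN"

    seqs <- c(
      list(target),
      lapply(seq_len(n_ortho - 1), function(i) mutate_sequence(target, base_noise)),
      lapply(seq_len(n_paralog), function(i) {
        mutate_sequence(mutate_sequence(target, p_div), base_noise)
      }),
      list(mutate_sequence(target, p_out))
    )
    ids <- c(ortho_ids, par_ids, out_id)
    species <- c(ortho_species, par_species, "HUMAN")
    fam <- aligned_family(
      tibble(
        seq_id = ids,
        species = species,
        residues = vapply(seqs, paste0, character(1), collapse = "")
      ),
      family_id = "paralog_sim",
      target = ortho_ids[1]
    )
    nwk <- paste0("(", out_id, ",(", ladder_newick(ortho_ids), ",",
                  ladder_newick(par_ids), "));")
    phy <- ape::read.tree(text = nwk)
    lineages <- tibble(
      species = unique(species),
      lineage = replicate(length(unique(species)),
                          c("Eukaryota", "Metazoa", "Chordata", "Mammalia"),
                          simplify = FALSE)
    )
    leaves <- tibble(
      seq_id = ids,
      species = species,
      is_human = species == "HUMAN",
      lineage = lineages$lineage[match(species, lineages$species)]
    )
    list(
      tree = gene_tree(phy, leaves, target = ortho_ids[1]),
      family = fam,
      lineages = lineages,
      truth = list(paralog_ids = par_ids, ortholog_ids = ortho_ids,
                   outgroup = out_id)
    )
  })
}

#' Specification for a planted active/inactive structure pair
#'
#' @param n_residues Number of residues (one side-chain pseudo-atom each,
#'   at most 80).
#' @param planted_gain_pairs,planted_loss_pairs Lists of residue index
#'   pairs `c(i, j)`; gains are in contact in the active state only, losses
#'   in the inactive state only. A residue may take part in at most one
#'   planted pair.
#' @param displacement Extra separation (Angstrom, > 0) breaking a
#'   contact; broken pairs sit at `contact_distance + displacement` which
#'   must reach the zero-contact distance 4.63 A.
#' @param jitter_sd Gaussian coordinate noise (Angstrom).
#' @param contact_distance Distance of a formed contact (default 3.0 A,
#'   inside the full-score range).
#' @param seed Integer seed.
#' @return A `structure_pair_spec` list.
#' @export
structure_pair_spec <- function(n_residues, planted_gain_pairs = list(),
                                planted_loss_pairs = list(),
                                displacement = 2.5, jitter_sd = 0,
                                contact_distance = 3.0, seed = 1L) {
  stopifnot(is_count(n_residues, 2), displacement > 0, jitter_sd >= 0)
  if (n_residues > 80) abort("n_residues must be at most 80")
  pairs <- c(planted_gain_pairs, planted_loss_pairs)
  for (p in pairs) {
    if (length(p) != 2 || any(p < 1) || any(p > n_residues) || p[1] == p[2]) {
      abort("planted pairs must be two distinct residue indices in range")
    }
  }
  members <- unlist(pairs)
  if (anyDuplicated(members)) {
    abort(paste0("geometric infeasibility: residue ",
                 members[duplicated(members)][1],
                 " takes part in more than one planted pair; ",
                 "use smaller pair sets"))
  }
  if (contact_distance + displacement < 4.63) {
    abort("contact_distance + displacement must reach 4.63 A to break a contact")
  }
  structure(
    list(n_residues = as.integer(n_residues),
         planted_gain_pairs = planted_gain_pairs,
         planted_loss_pairs = planted_loss_pairs,
         displacement = displacement, jitter_sd = jitter_sd,
         contact_distance = contact_distance, seed = as.integer(seed)),
    class = "structure_pair_spec"
  )
}

pseudo_structure <- function(coords, structure_id, state) {
  n <- nrow(coords)
  structure_model(
    tibble(
      chain = "A",
      residue_index = seq_len(n),
      residue_name = "ALA",
      atom_name = "CB",
      element = "C",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      generic_number = sprintf("%dx%02d", (seq_len(n) - 1) %/% 10 + 1,
                               30 + (seq_len(n) - 1) %% 10)
    ),
    structure_id = structure_id, state = state
  )
}

#' Simulate an active/inactive structure pair with planted contact changes
#'
#' Residues are single side-chain pseudo-atoms on a 12-Angstrom lattice, so
#' unplanted residue pairs are far outside contact range. Planted gain
#' pairs sit at `contact_distance` in the active structure and at
#' `contact_distance + displacement` in the inactive one; loss pairs are
#' reversed. Gaussian jitter, when requested, is applied to all
#' coordinates of both structures independently.
#'
#' @param spec A [structure_pair_spec()].
#' @return List with `active` and `inactive` [structure_model()]s and
#'   `truth` (the planted pairs expressed as generic-number edges).
#' @export
simulate_structure_pair <- function(spec) {
  stopifnot(inherits(spec, "structure_pair_spec"))
  with_seed(spec$seed, {
    n <- spec$n_residues
    m <- ceiling(n^(1 / 3))
    k <- seq_len(n) - 1
    base <- cbind(k %% m, (k %/% m) %% m, k %/% (m * m)) * 12
    place <- function(in_contact_pairs, out_pairs) {
      coords <- base
      adjust <- function(p, dist) {
        u <- base[p[2], ] - base[p[1], ]
        u <- u / sqrt(sum(u^2))
        coords[p[2], ] <<- base[p[1], ] + u * dist
      }
      for (p in in_contact_pairs) adjust(p, spec$contact_distance)
      for (p in out_pairs) adjust(p, spec$contact_distance + spec$displacement)
      if (spec$jitter_sd > 0) {
        coords <- coords + matrix(rnorm(length(coords), sd = spec$jitter_sd),
                                  ncol = 3)
      }
      coords
    }
    active_coords <- place(spec$planted_gain_pairs, spec$planted_loss_pairs)
    inactive_coords <- place(spec$planted_loss_pairs, spec$planted_gain_pairs)
    active <- pseudo_structure(active_coords, "sim_active", "active")
    inactive <- pseudo_structure(inactive_coords, "sim_inactive", "inactive")
    gn <- active$generic_number[!duplicated(active$residue_index)]
    as_edge <- function(p) sort(gn[p])
    list(
      active = active,
      inactive = inactive,
      truth = list(
        gain_edges = lapply(spec$planted_gain_pairs, as_edge),
        loss_edges = lapply(spec$planted_loss_pairs, as_edge)
      )
    )
  })
}

#' Synthetic receptor templates with controllable activation metric
#'
#' Builds an active/inactive template pair whose four GPCRdb marker
#' residues (2x41, 6x38, 3x44, 7x52) are placed so that the activation
#' metric d(2x41, 6x38) - d(3x44, 7x52) equals a requested value in each
#' state. Every residue carries a single CA atom; non-marker residues sit
#' on a distant lattice, with two of them placed at a mid-range contact
#' distance so trajectories derived from the templates have
#' distance-sensitive contacts to test.
#'
#' @param n_residues Total residues (>= 10).
#' @param active_metric,inactive_metric Desired metric (Angstrom) of each
#'   template; active conformations exceed 7.15, inactive fall below 2.
#' @param contact_pair_distance CA-CA distance of the built-in contact pair
#'   (default 3.9 A, mid-range of the RRCS ramp).
#' @return List with `active` and `inactive` [structure_model()]s sharing
#'   one atom roster.
#' @export
simulate_receptor_templates <- function(n_residues = 10, active_metric = 10,
                                        inactive_metric = 0.5,
                                        contact_pair_distance = 3.9) {
  stopifnot(n_residues >= 10)
  markers <- c("2x41", "6x38", "3x44", "7x52")
  build <- function(metric, state, id) {
    d12 <- 5 + metric
    coords <- matrix(0, nrow = n_residues, ncol = 3)
    coords[1, ] <- c(0, 0, 0)        # 2x41
    coords[2, ] <- c(d12, 0, 0)      # 6x38
    coords[3, ] <- c(0, 40, 0)       # 3x44
    coords[4, ] <- c(5, 40, 0)       # 7x52
    rest <- seq(5, n_residues)
    coords[rest, ] <- cbind(12 * (rest - 5), 0, 80)
    # a contact pair among the lattice residues, in range in both states;
    # the partners are >= 5 apart in sequence so the CA atoms are not
    # subject to the near-sequence backbone exclusion
    coords[n_residues, ] <- coords[5, ] + c(contact_pair_distance, 0, 0)
    gn <- c(markers, sprintf("5x%02d", 10 + seq_len(n_residues - 4)))
    structure_model(
      tibble(
        chain = "A", residue_index = seq_len(n_residues),
        residue_name = "ALA", atom_name = "CA", element = "C",
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        generic_number = gn
      ),
      structure_id = id, state = state
    )
  }
  list(
    active = build(active_metric, "active", "template_active"),
    inactive = build(inactive_metric, "inactive", "template_inactive")
  )
}
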