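#' Split receptors into couplers and non-couplers for one Galpha
#'
#' Applies a source policy to a coupling table: a receptor is a coupler
#' under `"union"` if any source reports coupling, under `"intersection"`
#' if every source does, or per a single named source.
#'
#' @param coupling A validated coupling table (see [coupling_table()]).
#' @param g_protein One Galpha subtype name.
#' @param source_policy `"union"`, `"intersection"`, or the name of a source
#'   present in the table.
#' @return List with character vectors `couplers` and `noncouplers`.
#' @export
coupling_groups <- function(coupling, g_protein,
                            source_policy = "union") {
  rows <- coupling[coupling$g_protein == g_protein, ]
  if (nrow(rows) == 0) {
    abort(paste0("no coupling data for ", g_protein))
  }
  by_receptor <- split(rows$couples, rows$receptor)
  couples <- switch(
    source_policy,
    union = vapply(by_receptor, any, logical(1)),
    intersection = vapply(by_receptor, all, logical(1)),
    {
      sub <- rows[rows$source == source_policy, ]
      if (nrow(sub) == 0) {
        abort(paste0("unknown coupling source: ", source_policy))
      }
      setNames(sub$couples, sub$receptor)
    }
  )
  list(
    couplers = sort(names(couples)[couples]),
    noncouplers = sort(names(couples)[!couples])
  )
}

count_specific_a <- function(profA, profB, column_map, ...) {
  labs <- compare_profiles(profA, profB, column_map = column_map, ...)
  tibble(column = labs$column_a,
         specific = labs$label %in% c("specific_A", "specific_both"))
}

#' Specific enrichment approach
#'
#' The high-confidence two-condition identification of specifically
#' conserved residues for a coupler group. Every coupler family is compared
#' with every non-coupler family (n x m ordered comparisons) and, per
#' column, the fraction of comparisons in which the column is specific for
#' the coupler side is recorded (`coupler_frequency`). The same
#' classification over all n x (n - 1) ordered coupler-coupler comparisons
#' gives `within_coupler_frequency`. A column is reported only when the
#' cross frequency is positive and the within frequency is exactly zero (no
#' inside variation tolerated).
#'
#' @param couplers List of >= 2 [aligned_family()] objects (the coupler
#'   receptors with their orthologs).
#' @param noncouplers List of >= 1 [aligned_family()] objects.
#' @param column_map Optional shared-column map (see [compare_families()]);
#'   default identity over a common width.
#' @param g_protein Galpha label recorded in the result.
#' @param ... Classification thresholds passed to [classify_position()].
#' @return An `enrichment_result` object.
#' @export
specific_approach <- function(couplers, noncouplers, column_map = NULL,
                              g_protein = NA_character_, ...) {
  n <- length(couplers)
  m <- length(noncouplers)
  if (n < 2) {
    abort("specific approach requires >= 2 couplers (within-coupler frequency undefined)")
  }
  if (m < 1) abort("specific approach requires >= 1 non-coupler")
  prof_c <- lapply(couplers, msa_conservation_profile)
  prof_n <- lapply(noncouplers, msa_conservation_profile)

  cross <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cross[[length(cross) + 1]] <-
        count_specific_a(prof_c[[i]], prof_n[[j]], column_map, ...)
    }
  }
  within <- list()
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      within[[length(within) + 1]] <-
        count_specific_a(prof_c[[i]], prof_c[[k]], column_map, ...)
    }
  }
  cross_freq <- bind_rows(cross) |>
    group_by(.data$column) |>
    summarise(coupler_frequency = sum(.data$specific) / (n * m),
              .groups = "drop")
  within_freq <- bind_rows(within) |>
    group_by(.data$column) |>
    summarise(within_coupler_frequency = sum(.data$specific) / (n * (n - 1)),
              .groups = "drop")
  table <- full_join(cross_freq, within_freq, by = "column") |>
    arrange(.data$column)
  table$reported <- table$coupler_frequency > 0 &
    table$within_coupler_frequency == 0
  enrichment_result(g_protein, "specific", table,
                    n_couplers = n, n_noncouplers = m)
}

#' Sensitive enrichment approach
#'
#' Tolerates minor variation (including false-positive couplings in the
#' profile datasets) by pooling all coupler receptors and their orthologs
#' into one comprehensive alignment, which is then compared against each
#' non-coupler family. Columns specific for the pooled coupler side in more
#' than `min_frequency` of the m comparisons are reported.
#'
#' @param combined A single [aligned_family()] pooling the coupler receptors
#'   with their orthologs (see [combine_families()]).
#' @param noncouplers List of >= 1 [aligned_family()] objects.
#' @param column_map Optional shared-column map.
#' @param min_frequency Strict lower bound on the reporting frequency
#'   (default 0, mirroring the specific approach's positive-count rule).
#' @param g_protein Galpha label recorded in the result.
#' @param ... Classification thresholds.
#' @return An `enrichment_result` object.
#' @export
sensitive_approach <- function(combined, noncouplers, column_map = NULL,
                               min_frequency = 0,
                               g_protein = NA_character_, ...) {
  stopifnot(inherits(combined, "aligned_family"))
  if (nrow(combined$sequences) == 0) abort("empty combined family")
  m <- length(noncouplers)
  if (m < 1) abort("sensitive approach requires >= 1 non-coupler")
  prof_c <- msa_conservation_profile(combined)
  hits <- lapply(noncouplers, function(f) {
    count_specific_a(prof_c, msa_conservation_profile(f), column_map, ...)
  })
  table <- bind_rows(hits) |>
    group_by(.data$column) |>
    summarise(coupler_frequency = sum(.data$specific) / m,
              .groups = "drop") |>
    arrange(.data$column)
  table$within_coupler_frequency <- NA_real_
  table$reported <- table$coupler_frequency > min_frequency
  enrichment_result(g_protein, "sensitive", table,
                    n_couplers = 1L, n_noncouplers = m)
}

enrichment_result <- function(g_protein, approach, table, n_couplers,
                              n_noncouplers) {
  structure(
    list(
      g_protein = g_protein,
      approach = approach,
      table = table,
      positions = table$column[table$reported],
      n_couplers = n_couplers,
      n_noncouplers = n_noncouplers
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$approach, " approach",
      if (!is.na(x$g_protein)) paste0(" for ", x$g_protein), ": ",
      length(x$positions), " specifically conserved position(s)\n", sep = "")
  if (length(x$positions) > 0) {
    cat("  columns: ", paste(x$positions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) x$table

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    g_protein = x$g_protein,
    approach = x$approach,
    n_couplers = x$n_couplers,
    n_noncouplers = x$n_noncouplers,
    n_reported = length(x$positions)
  )
}

#' Pool specific, sensitive and consensus position sets
#'
#' Union with provenance tags, deterministically ordered. Positions may be
#' alignment columns (integers) or generic numbers (characters); a
#' `generic_map` (column -> generic number) may be supplied to express the
#' pooled set in generic numbers, and conflicting mappings raise an error.
#'
#' @param specific An `enrichment_result` from [specific_approach()], or a
#'   bare vector of positions, or `NULL`.
#' @param sensitive Likewise for the sensitive approach.
#' @param consensus Vector of consensus positions (or the tibble from
#'   [consensus_positions()]), or `NULL`.
#' @param generic_map Optional [generic_number_map()] with `residue_index`
#'   interpreted as alignment column.
#' @return Tibble with `position`, logical provenance flags and a
#'   comma-separated `sources` tag.
#' @export
merge_residue_sets <- function(specific = NULL, sensitive = NULL,
                               consensus = NULL, generic_map = NULL) {
  pull_positions <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "enrichment_result")) return(x$positions)
    if (is.data.frame(x)) return(x$column %||% x$position)
    x
  }
  sets <- list(
    specific = pull_positions(specific),
    sensitive = pull_positions(sensitive),
    consensus = pull_positions(consensus)
  )
  all_pos <- sort(unique(unlist(sets, use.names = FALSE)))
  out <- tibble(
    position = all_pos,
    specific = all_pos %in% sets$specific,
    sensitive = all_pos %in% sets$sensitive,
    consensus = all_pos %in% sets$consensus
  )
  out$sources <- apply(out[, c("specific", "sensitive", "consensus")], 1,
                       function(fl) paste(names(fl)[fl], collapse = ","))
  if (!is.null(generic_map)) {
    generic_map <- generic_number_map(generic_map)
    idx <- match(out$position, generic_map$residue_index)
    if (anyNA(idx)) {
      abort(paste0("no generic number mapped for position(s): ",
                   paste(out$position[is.na(idx)], collapse = ", ")))
    }
    out$position <- generic_map$generic_number[idx]
  }
  out
}
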