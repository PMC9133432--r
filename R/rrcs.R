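#' Residue-residue contact scores of a structure
#'
#' For every residue pair (i, j) the RRCS is the sum over qualifying
#' heavy-atom pairs of a piecewise-linear distance weight: 1 at or below
#' `d_min`, 0 at or beyond `d_max`, and `(d_max - d) / (d_max - d_min)`
#' in between. For sequence-adjacent residue pairs of the same chain
#' (|index difference| < `near_seq_cutoff`) atom pairs involving a backbone
#' atom (N, CA, C, O) are excluded, so trivially bonded neighbours do not
#' register as contacts. Residue pairs with zero score are omitted from the
#' edge map. Constants follow the published RRCS method.
#'
#' @param structure A [structure_model()] (heavy atoms; any stray H/D atoms
#'   are dropped defensively).
#' @param d_min,d_max Full-contact and zero-contact distances in Angstrom.
#' @param near_seq_cutoff Residue pairs closer in sequence than this exclude
#'   backbone atoms.
#' @param backbone_atoms Atom names treated as backbone.
#' @return A [contact_network()] with a `score` column, keyed by generic
#'   numbers where annotated (else `chain:index`).
#' @export
compute_rrcs <- function(structure, d_min = 3.23, d_max = 4.63,
                         near_seq_cutoff = 5,
                         backbone_atoms = c("N", "CA", "C", "O")) {
  stopifnot(inherits(structure, "structure_model"))
  atoms <- as_tibble(structure)
  all_res <- unique(paste(atoms$chain, atoms$residue_index, sep = "\r"))
  atoms <- atoms[!(atoms$element %in% c("H", "D")), ]
  res_key <- paste(atoms$chain, atoms$residue_index, sep = "\r")
  lost <- setdiff(all_res, unique(res_key))
  if (length(lost) > 0) {
    warn(paste0(length(lost), " residue(s) lacking heavy atoms skipped"))
  }
  labels <- residue_labels(atoms)
  prov <- structure_id(structure)
  if (nrow(atoms) < 2) {
    return(empty_network(kind = "rrcs", provenance = prov))
  }

  d <- as.matrix(dist(as.matrix(atoms[, c("x", "y", "z")])))
  f <- (d_max - d) / (d_max - d_min)
  f[f > 1] <- 1
  f[f < 0] <- 0

  near <- outer(atoms$residue_index, atoms$residue_index,
                function(a, b) abs(a - b) < near_seq_cutoff) &
    outer(atoms$chain, atoms$chain, "==")
  is_bb <- atoms$atom_name %in% backbone_atoms
  excl <- near & (outer(is_bb, rep(TRUE, length(is_bb)), "&") |
                    outer(rep(TRUE, length(is_bb)), is_bb, "&"))
  f[excl] <- 0

  # aggregate atom-pair weights into residue-pair sums
  rf <- factor(res_key, levels = unique(res_key))
  by_row <- rowsum(f, rf, reorder = FALSE)
  per_res <- rowsum(t(by_row), rf, reorder = FALSE)
  res_label <- labels[!duplicated(res_key)]
  dimnames(per_res) <- list(res_label, res_label)

  idx <- which(upper.tri(per_res) & per_res > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(empty_network(kind = "rrcs", provenance = prov))
  }
  contact_network(
    tibble(
      source = res_label[idx[, 1]],
      target = res_label[idx[, 2]],
      score = per_res[idx]
    ),
    kind = "rrcs",
    provenance = prov
  )
}

#' Contact-score change between activation states
#'
#' Subtracts per-pair contact scores to obtain delta RRCS = RRCS(active) -
#' RRCS(inactive); a pair absent from one side contributes zero there
#' (no contact has zero score by construction). Positive values mean a
#' contact formed upon activation. Pairs with |delta| <= `delta_min` are
#' filtered out, and pairs are restricted to the pool of conserved
#' residues -- by default both endpoints must be in the pool.
#'
#' @param active,inactive [contact_network()]s of RRCS scores keyed in the
#'   same generic-number space.
#' @param pool Character vector of residue labels (generic numbers) forming
#'   the conserved-residue pool; must be non-empty.
#' @param delta_min Magnitude filter (default 0.2; pairs at exactly the
#'   threshold are dropped).
#' @param endpoints `"both"` (default) requires both pair members in the
#'   pool, `"either"` only one.
#' @return A [contact_network()] with a `delta` column.
#' @export
delta_rrcs <- function(active, inactive, pool, delta_min = 0.2,
                       endpoints = c("both", "either")) {
  endpoints <- match.arg(endpoints)
  stopifnot(inherits(active, "contact_network"),
            inherits(inactive, "contact_network"))
  if (missing(pool) || length(pool) == 0) {
    abort("empty conserved-residue pool")
  }
  a <- tibble(source = active$source, target = active$target,
              score_active = active$score)
  i <- tibble(source = inactive$source, target = inactive$target,
              score_inactive = inactive$score)
  merged <- full_join(a, i, by = c("source", "target"))
  merged$score_active[is.na(merged$score_active)] <- 0
  merged$score_inactive[is.na(merged$score_inactive)] <- 0
  merged$delta <- merged$score_active - merged$score_inactive
  # small tolerance so scores that differ by exactly the threshold are
  # dropped even when the subtraction carries floating-point error
  keep <- abs(merged$delta) > delta_min + 1e-9
  in_pool_s <- merged$source %in% pool
  in_pool_t <- merged$target %in% pool
  keep <- keep & if (endpoints == "both") in_pool_s & in_pool_t else
    in_pool_s | in_pool_t
  contact_network(
    merged[keep, c("source", "target", "delta")],
    kind = "delta_rrcs",
    provenance = c(structure_id(active) %||% attr(active, "provenance"),
                   structure_id(inactive) %||% attr(inactive, "provenance"))
  )
}

#' Edges shared across many activation networks
#'
#' Keeps an edge when it occurs (after the per-pair delta filter) in at
#' least `min_count` of the input networks, regardless of the sign of the
#' change; the edge value is its occurrence count. This summarises the
#' per-receptor-pair activation networks into the common activation
#' mechanism.
#'
#' @param networks List of [contact_network()]s (length >= 1).
#' @param min_count Minimum occurrence count (default 36, out of the 41
#'   active/inactive structure pairs of the original analysis).
#' @return A [contact_network()] with a `count` column.
#' @export
common_network <- function(networks, min_count = 36) {
  stopifnot(length(networks) >= 1)
  if (min_count > length(networks)) {
    warn(paste0("min_count (", min_count, ") exceeds the number of networks (",
                length(networks), "); result is empty"))
    return(empty_network(kind = "common", value_cols = "count"))
  }
  edges <- bind_rows(lapply(networks, function(n) {
    distinct(tibble(source = n$source, target = n$target))
  }))
  counted <- edges |>
    count(.data$source, .data$target, name = "count") |>
    filter(.data$count >= min_count)
  contact_network(counted, kind = "common")
}

#' Active/inactive structure pairing plan
#'
#' Builds the per-receptor Cartesian product of active and inactive
#' structure ids, or validates an explicit pair table (useful when the
#' published pair list cannot be reproduced from the structure roster).
#'
#' @param sets Tibble with columns `receptor`, `active` and `inactive`
#'   (list-columns of structure ids), or `NULL` when `pairs` is given.
#' @param pairs Explicit tibble with columns `receptor`, `active_id`,
#'   `inactive_id` overriding the Cartesian expansion.
#' @return Tibble of class `pairing_plan` with one row per structure pair.
#' @export
pairing_plan <- function(sets = NULL, pairs = NULL) {
  if (is.null(pairs)) {
    if (is.null(sets)) abort("provide either sets or pairs")
    sets <- as_tibble(sets)
    pairs <- sets |>
      tidyr::unnest_longer("active", values_to = "active_id") |>
      tidyr::unnest_longer("inactive", values_to = "inactive_id") |>
      select("receptor", "active_id", "inactive_id")
  }
  pairs <- as_tibble(pairs)
  missing_cols <- setdiff(c("receptor", "active_id", "inactive_id"),
                          names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("pairing plan is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  structure(pairs, class = c("pairing_plan", class(pairs)))
}

#' Galpha-specific activation network
#'
#' Compares the per-pair delta RRCS values of the receptors coupled to one
#' Galpha against all remaining pairs, edge by edge, with a two-sample
#' t-test; an edge absent from a pair's network contributes zero. Edges
#' significant at `alpha` are retained, annotated with the group-minus-rest
#' mean difference (delta-delta RRCS) and its sign. An exclusion list
#' allows re-testing with outlier receptors or structures removed.
#'
#' @param pair_networks A [pairing_plan()]-shaped tibble with an added
#'   `network` list-column holding each pair's delta-RRCS
#'   [contact_network()].
#' @param group Character vector of receptor names forming the Galpha
#'   group.
#' @param alpha Significance level (0.01 for most subtypes, 0.1 for Gi1 in
#'   the original analysis).
#' @param exclude Receptor names or structure ids whose pairs are dropped
#'   before testing.
#' @param var_equal Student (default) vs Welch t-test.
#' @return A [contact_network()] with `delta_delta`, `p_value` and `sign`
#'   columns.
#' @export
gprotein_specific_network <- function(pair_networks, group, alpha = 0.01,
                                      exclude = character(),
                                      var_equal = TRUE) {
  pair_networks <- as_tibble(pair_networks)
  required <- c("receptor", "active_id", "inactive_id", "network")
  missing_cols <- setdiff(required, names(pair_networks))
  if (length(missing_cols) > 0) {
    abort(paste0("pair_networks is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  drop <- pair_networks$receptor %in% exclude |
    pair_networks$active_id %in% exclude |
    pair_networks$inactive_id %in% exclude
  pair_networks <- pair_networks[!drop, ]
  in_group <- pair_networks$receptor %in% group
  if (sum(in_group) < 2 || sum(!in_group) < 2) {
    warn("fewer than 2 pairs in group or rest; all edges skipped")
    return(empty_network(kind = "ddrrcs",
                         value_cols = c("delta_delta", "p_value", "sign")))
  }
  all_edges <- distinct(bind_rows(lapply(pair_networks$network, function(n) {
    tibble(source = n$source, target = n$target)
  })))
  if (nrow(all_edges) == 0) {
    return(empty_network(kind = "ddrrcs",
                         value_cols = c("delta_delta", "p_value", "sign")))
  }
  keys <- paste(all_edges$source, all_edges$target, sep = "|")
  # edge x pair matrix of delta values, absent edges as zero
  vals <- vapply(pair_networks$network, function(n) {
    v <- setNames(rep(0, length(keys)), keys)
    v[edge_keys(n)] <- n$delta
    v
  }, numeric(length(keys)))
  vals <- matrix(vals, nrow = length(keys))
  res <- lapply(seq_along(keys), function(e) {
    x <- vals[e, in_group]
    y <- vals[e, !in_group]
    p <- safe_t_test(x, y, var_equal = var_equal)
    tibble(source = all_edges$source[e], target = all_edges$target[e],
           delta_delta = mean(x) - mean(y), p_value = p)
  })
  res <- bind_rows(res)
  res <- res[!is.na(res$p_value) & res$p_value <= alpha, ]
  res$sign <- sign(res$delta_delta)
  contact_network(res, kind = "ddrrcs",
                  provenance = paste0("group: ",
                                      paste(group, collapse = ",")))
}
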