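#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain with the
#' defaults used throughout: specificity/consensus thresholds 0.9, lower
#' threshold 0.7, allowed-substitution cutoff 2 (strict), gap cutoff 0.5,
#' paralog-trimming alpha 0.1, delta-RRCS magnitude filter 0.2, common-edge
#' minimum count 36, per-Galpha network alphas (0.01, with 0.1 for Gi1)
#' and the MD contact-change alpha 0.05.
#'
#' @param receptors Named list describing each receptor: elements may hold
#'   `family` (an [aligned_family()] or FASTA path), optionally `tree`
#'   (a [gene_tree()] or Newick path) and `outgroup` (leaf id). When a tree
#'   is present, ortholog extraction and paralog trimming are applied
#'   before conservation analysis.
#' @param coupling Coupling table (tibble or TSV path).
#' @param lineages Lineage table (tibble or TSV path); required when any
#'   receptor has a tree.
#' @param g_proteins Galpha subtypes to analyse.
#' @param source_policy Coupling source policy (see [coupling_groups()]).
#' @param sensitive_mask Galpha subtypes for which the sensitive approach
#'   is NOT applied (few couplers inflate false positives; G12/G13 by
#'   default).
#' @param spec_thr,cons_thr,lower_thr,allowed_min,gap_max,paralog_alpha
#'   Evolution-stage thresholds.
#' @param delta_min,common_min_count,galpha_alpha,md_alpha Structure- and
#'   trajectory-stage thresholds; `galpha_alpha` is a named vector of
#'   per-subtype significance levels (subtypes missing from it fall back
#'   to 0.01).
#' @param seed Integer seed recorded in the config.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(receptors = list(), coupling = NULL,
                            lineages = NULL,
                            g_proteins = c("Gs", "Gi1", "Go", "Gq"),
                            source_policy = "union",
                            sensitive_mask = c("G12", "G13"),
                            spec_thr = 0.9, cons_thr = 0.9, lower_thr = 0.7,
                            allowed_min = 2, gap_max = 0.5,
                            paralog_alpha = 0.1, delta_min = 0.2,
                            common_min_count = 36,
                            galpha_alpha = c(Gs = 0.01, Gq = 0.01,
                                             Go = 0.01, Gi1 = 0.1),
                            md_alpha = 0.05, seed = 1L) {
  for (thr in list(spec_thr, cons_thr, lower_thr, gap_max, paralog_alpha,
                   md_alpha)) {
    if (!is_probability(thr)) abort("thresholds must lie in [0, 1]")
  }
  if (delta_min < 0) abort("delta_min must be non-negative")
  structure(
    list(receptors = receptors, coupling = coupling, lineages = lineages,
         g_proteins = g_proteins, source_policy = source_policy,
         sensitive_mask = sensitive_mask, spec_thr = spec_thr,
         cons_thr = cons_thr, lower_thr = lower_thr,
         allowed_min = allowed_min, gap_max = gap_max,
         paralog_alpha = paralog_alpha, delta_min = delta_min,
         common_min_count = common_min_count, galpha_alpha = galpha_alpha,
         md_alpha = md_alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", name, ": ", conditionMessage(e)))
  })
}

load_family <- function(x) {
  if (inherits(x, "aligned_family")) x else read_fasta_msa(x)
}

load_tree <- function(x, lineages = NULL) {
  if (inherits(x, "gene_tree")) x else read_newick(x, lineages = lineages)
}

#' Run the evolution stage: orthologs to enrichment
#'
#' Per receptor: (optionally) root the gene tree on its outgroup, extract
#' the ortholog clade of the human target, trim diverged paralogs, and
#' restrict the family alignment to the surviving orthologs. Then, per
#' Galpha subtype, split receptors into couplers and non-couplers and run
#' the specific (and, where allowed, sensitive) enrichment, finishing with
#' the cross-receptor consensus set and the pooled residue sets.
#'
#' @param config A [pipeline_config()].
#' @return List with `families` (post-selection), `ortholog_reports`,
#'   `trim_reports`, `enrichment` (per Galpha: specific, sensitive, merged),
#'   `consensus` and a `provenance` tibble of per-stage record counts.
#' @export
run_evolution_stage <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$receptors) == 0) abort("stage input: no receptors configured")
  lineages <- stage("input", {
    if (is.null(config$lineages) || is_tibble(config$lineages) ||
        is.data.frame(config$lineages)) config$lineages else
          read_lineages(config$lineages)
  })
  coupling <- stage("input", {
    if (is.null(config$coupling)) abort("coupling table required")
    if (is.character(config$coupling)) read_coupling_table(config$coupling)
    else coupling_table(config$coupling)
  })

  families <- list()
  ortholog_reports <- list()
  trim_reports <- list()
  for (name in names(config$receptors)) {
    entry <- config$receptors[[name]]
    fam <- stage("input", load_family(entry$family))
    if (!is.null(entry$tree)) {
      gt <- stage("ortholog_selection", {
        gt <- load_tree(entry$tree, lineages)
        gt$target <- gt$target %||% family_target(fam)
        if (!is.null(entry$outgroup)) root_by_outgroup(gt, entry$outgroup)
        else gt
      })
      orth <- stage("ortholog_selection", extract_ortholog_clade(gt))
      ortholog_reports[[name]] <- orth
      pruned <- stage("paralog_trimming", {
        keep_idx <- match(orth$kept_leaves, gt$phy$tip.label)
        sub_phy <- ape::keep.tip(gt$phy, orth$kept_leaves)
        sub_gt <- gene_tree(sub_phy, gt$leaves, target = gt$target)
        if (length(orth$kept_leaves) >= 3) {
          trim_paralogs(sub_gt, fam, lineages, alpha = config$paralog_alpha)
        } else {
          list(kept = orth$kept_leaves, verdicts = tibble())
        }
      })
      trim_reports[[name]] <- pruned$verdicts
      fam <- stage("ortholog_selection", subset_family(fam, pruned$kept))
    }
    families[[name]] <- fam
  }

  thr <- list(spec_thr = config$spec_thr, cons_thr = config$cons_thr,
              lower_thr = config$lower_thr)
  enrichment <- list()
  for (gp in config$g_proteins) {
    groups <- stage("enrichment", coupling_groups(coupling, gp,
                                                  config$source_policy))
    cf <- families[intersect(groups$couplers, names(families))]
    nf <- families[intersect(groups$noncouplers, names(families))]
    spec_res <- stage("enrichment", do.call(specific_approach, c(
      list(couplers = unname(cf), noncouplers = unname(nf),
           g_protein = gp), thr)))
    sens_res <- NULL
    if (!gp %in% config$sensitive_mask) {
      sens_res <- stage("enrichment", do.call(sensitive_approach, c(
        list(combined = combine_families(unname(cf),
                                         family_id = paste0(gp, "_couplers")),
             noncouplers = unname(nf), g_protein = gp), thr)))
    }
    enrichment[[gp]] <- list(specific = spec_res, sensitive = sens_res)
  }

  consensus <- if (length(families) >= 2) {
    stage("conservation", do.call(consensus_positions, c(
      list(families = unname(families)), thr)))
  } else {
    tibble(column = integer(0), n_pairs = integer(0),
           consensus_fraction = numeric(0))
  }

  for (gp in names(enrichment)) {
    enrichment[[gp]]$merged <- merge_residue_sets(
      specific = enrichment[[gp]]$specific,
      sensitive = enrichment[[gp]]$sensitive,
      consensus = consensus$column
    )
  }

  provenance <- tibble(
    stage = c("families", "g_proteins", "consensus_positions"),
    records = c(length(families), length(enrichment), nrow(consensus))
  )
  list(families = families, ortholog_reports = ortholog_reports,
       trim_reports = trim_reports, enrichment = enrichment,
       consensus = consensus, provenance = provenance)
}

#' Run the structure stage: RRCS to Galpha-specific networks
#'
#' Computes RRCS for every structure, delta-RRCS networks for every
#' active/inactive pair of the pairing plan (restricted to the conserved
#' pool and filtered at `delta_min`), the cross-pair common activation
#' network, and one Galpha-specific delta-delta network per configured
#' subtype.
#'
#' @param config A [pipeline_config()].
#' @param structures Named list of [structure_model()]s keyed by structure
#'   id (or paths, read with [read_structure()]).
#' @param plan A [pairing_plan()].
#' @param pool Conserved-residue pool (generic numbers); must be
#'   non-empty.
#' @param groups Named list mapping each Galpha subtype to its coupler
#'   receptor names.
#' @param exclude Structure ids / receptors excluded from the
#'   group-difference tests.
#' @return List with `pair_networks` (plan plus a `network` list-column),
#'   `common` and `specific` (named list of per-Galpha networks).
#' @export
run_structure_stage <- function(config, structures, plan, pool,
                                groups = list(), exclude = character()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(plan) == 0) abort("stage pairing: empty pairing plan")
  if (length(pool) == 0) abort("stage delta_rrcs: empty conserved-residue pool")
  structures <- lapply(structures, function(s) {
    if (inherits(s, "structure_model")) s else read_structure(s)
  })
  rrcs <- stage("rrcs", lapply(structures, compute_rrcs))
  missing_ids <- setdiff(unique(c(plan$active_id, plan$inactive_id)),
                         names(rrcs))
  if (length(missing_ids) > 0) {
    abort(paste0("stage pairing: structure(s) missing from roster: ",
                 paste(missing_ids, collapse = ", ")))
  }
  pair_networks <- as_tibble(plan)
  pair_networks$network <- stage("delta_rrcs", {
    lapply(seq_len(nrow(plan)), function(i) {
      delta_rrcs(rrcs[[plan$active_id[i]]], rrcs[[plan$inactive_id[i]]],
                 pool = pool, delta_min = config$delta_min)
    })
  })
  common <- stage("common_network",
                  common_network(pair_networks$network,
                                 min_count = config$common_min_count))
  specific <- list()
  for (gp in names(groups)) {
    alpha <- unname(config$galpha_alpha[gp])
    if (is.na(alpha)) alpha <- 0.01
    specific[[gp]] <- stage("specific_network",
                            gprotein_specific_network(
                              pair_networks, group = groups[[gp]],
                              alpha = alpha, exclude = exclude))
  }
  list(pair_networks = pair_networks, common = common, specific = specific)
}
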