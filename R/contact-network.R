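#' Residue-residue contact network
#'
#' An edge list over residue pairs keyed by GPCRdb generic numbers (or
#' `chain:index` labels for unannotated residues). Edge values may be raw
#' contact scores (RRCS), activation-state differences (delta RRCS), common
#' edge occurrence counts, or group-difference statistics with p-values.
#' Pair keys are stored canonically (`source < target` lexicographically) and
#' rows are sorted, so identical networks are byte-identical on export.
#'
#' @param edges Tibble with character columns `source` and `target` plus any
#'   value columns (`score`, `delta`, `p_value`, ...).
#' @param kind Label describing what the values are.
#' @param provenance Free-form provenance (structure ids, group label).
#' @return An object of class `contact_network` (a tibble subclass).
#' @export
contact_network <- function(edges, kind = "rrcs", provenance = NULL) {
  edges <- as_tibble(edges)
  missing_cols <- setdiff(c("source", "target"), names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("edges is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(edges$source == edges$target)) {
    abort("self-edges are not allowed in a contact network")
  }
  swap <- edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
    abort("duplicate residue pair in contact network")
  }
  num <- vapply(edges, is.numeric, logical(1))
  if (any(num)) {
    vals <- as.matrix(edges[num])
    if (!all(is.finite(vals))) abort("contact network values must be finite")
  }
  edges <- arrange(edges, .data$source, .data$target)
  structure(
    edges,
    kind = kind,
    provenance = provenance,
    class = c("contact_network", class(edges))
  )
}

#' @export
print.contact_network <- function(x, ...) {
  cat("<contact_network> kind=", attr(x, "kind"), ", ", nrow(x),
      " edges\n", sep = "")
  NextMethod()
}

network_kind <- function(x) attr(x, "kind")

edge_keys <- function(net) paste(net$source, net$target, sep = "|")

# re-attach contact_network attributes after dplyr operations strip them
as_network <- function(edges, template = NULL, kind = NULL,
                       provenance = NULL) {
  contact_network(
    edges,
    kind = kind %||% (if (!is.null(template)) attr(template, "kind") else "rrcs"),
    provenance = provenance %||%
      (if (!is.null(template)) attr(template, "provenance") else NULL)
  )
}

empty_network <- function(kind = "rrcs", value_cols = "score",
                          provenance = NULL) {
  edges <- tibble(source = character(0), target = character(0))
  for (col in value_cols) edges[[col]] <- numeric(0)
  contact_network(edges, kind = kind, provenance = provenance)
}

#' @export
tidy.contact_network <- function(x, ...) {
  as_tibble(unclass_network(x))
}

unclass_network <- function(x) {
  class(x) <- setdiff(class(x), "contact_network")
  attr(x, "kind") <- NULL
  attr(x, "provenance") <- NULL
  x
}
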