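# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, direct matrix indexing, no shared helpers.

.b80 <- local({
  env <- new.env()
  utils::data("BLOSUM80", package = "Biostrings", envir = env)
  env$BLOSUM80
})

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# conservation of one column by explicit recount (exact integer ratio)
oracle_conservation <- function(col) {
  n <- length(col)
  n_gap <- 0L
  for (r in col) if (r == "-") n_gap <- n_gap + 1L
  if (n_gap / n > 0.5) {
    return(list(gap = TRUE, modal = NA_character_, conservation = NA_real_))
  }
  best <- NA_character_
  best_count <- -1L
  for (aa in AA20) {  # alphabetical scan makes ties resolve alphabetically
    cnt <- sum(col == aa)
    if (cnt > best_count) {
      best <- aa
      best_count <- cnt
    }
  }
  if (best_count <= 0) {
    return(list(gap = FALSE, modal = NA_character_,
                conservation = NA_real_))
  }
  num <- 0L
  for (r in col) {
    if (r == "-" || r == "X") next
    if (r == best || .b80[best, r] > 2) num <- num + 1L
  }
  list(gap = FALSE, modal = best, conservation = num / (n - n_gap))
}

# RRCS by explicit double loop over residues and heavy-atom pairs
oracle_rrcs <- function(structure, d_min = 3.23, d_max = 4.63,
                        near_seq_cutoff = 5,
                        backbone = c("N", "CA", "C", "O")) {
  at <- as.data.frame(structure)
  at <- at[!(at$element %in% c("H", "D")), ]
  res <- unique(at[, c("chain", "residue_index")])
  out <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      ai <- at[at$chain == res$chain[i] &
                 at$residue_index == res$residue_index[i], ]
      aj <- at[at$chain == res$chain[j] &
                 at$residue_index == res$residue_index[j], ]
      near <- res$chain[i] == res$chain[j] &&
        abs(res$residue_index[i] - res$residue_index[j]) < near_seq_cutoff
      s <- 0
      for (a in seq_len(nrow(ai))) {
        for (b in seq_len(nrow(aj))) {
          if (near && (ai$atom_name[a] %in% backbone ||
                       aj$atom_name[b] %in% backbone)) next
          d <- sqrt((ai$x[a] - aj$x[b])^2 + (ai$y[a] - aj$y[b])^2 +
                      (ai$z[a] - aj$z[b])^2)
          if (d <= d_min) {
            s <- s + 1
          } else if (d < d_max) {
            s <- s + (d_max - d) / (d_max - d_min)
          }
        }
      }
      if (s > 0) {
        lab_i <- if (is.na(ai$generic_number[1]))
          paste0(res$chain[i], ":", res$residue_index[i]) else
            ai$generic_number[1]
        lab_j <- if (is.na(aj$generic_number[1]))
          paste0(res$chain[j], ":", res$residue_index[j]) else
            aj$generic_number[1]
        key <- paste(sort(c(lab_i, lab_j)), collapse = "|")
        out[[key]] <- s
      }
    }
  }
  out
}

# random heavy-atom structure for oracle comparison: n residues with 1-3
# atoms each (mix of backbone and side-chain names), coordinates compact
# enough to produce many mid-range contacts
random_structure <- function(n_residues = 20, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_residues)) {
    centre <- runif(3, 0, 12)
    n_at <- sample(1:3, 1)
    names_i <- sample(c("N", "CA", "C", "O", "CB", "CG", "CD"), n_at)
    for (k in seq_len(n_at)) {
      xyz <- centre + rnorm(3, sd = 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", residue_index = i, residue_name = "ALA",
        atom_name = names_i[k], element = substr(names_i[k], 1, 1),
        x = xyz[1], y = xyz[2], z = xyz[3],
        generic_number = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  structure_model(do.call(rbind, rows), structure_id = paste0("rnd", seed),
                  state = "active")
}

# minimal structure builder used across structural tests
toy_structure <- function(coords, atom_name = "CB", generic = NULL,
                          id = "toy", state = "active") {
  n <- nrow(coords)
  structure_model(
    tibble::tibble(
      chain = "A", residue_index = seq_len(n), residue_name = "ALA",
      atom_name = rep_len(atom_name, n), element = "C",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      generic_number = generic %||% paste0("1x", 10 + seq_len(n))
    ),
    structure_id = id, state = state
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

edge_keys <- function(net) paste(net$source, net$target, sep = "|")

# conserved single-column family builder: one aligned column per residue
# vector given; rows are species-annotated sequences
column_family <- function(id, column_residues, width = 1,
                          at_column = 1) {
  n <- length(column_residues)
  species <- c("HUMAN", sprintf("SP%02d", seq_len(max(n - 1, 0))))[seq_len(n)]
  residues <- vapply(column_residues, function(r) {
    s <- rep("G", width)
    s[at_column] <- r
    paste(s, collapse = "")
  }, character(1))
  aligned_family(
    tibble::tibble(seq_id = paste0(id, "_", species), species = species,
                   residues = residues),
    family_id = id
  )
}
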