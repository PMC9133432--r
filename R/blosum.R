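#' Amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order. This
#' fixed order is also the deterministic tie-break used when two residues are
#' equally frequent in an alignment column.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# symbols tolerated in alignment columns beyond the 20 amino acids
MSA_EXTRA_SYMBOLS <- c("-", "X")

.blosum_cache <- new.env(parent = emptyenv())

#' Substitution matrices
#'
#' Returns the standard integer (half-bit) BLOSUM matrices shipped with
#' Biostrings. BLOSUM80 drives the "allowed substitution" credit in
#' conservation scoring and the modal-residue similarity branches of the
#' specificity classifier; BLOSUM62 drives global alignment scores used for
#' paralog trimming.
#'
#' @param name Matrix name, `"BLOSUM80"` or `"BLOSUM62"`.
#' @return Integer matrix with amino-acid row/column names.
#' @export
#' @examples
#' blosum_matrix("BLOSUM80")["L", "M"]
blosum_matrix <- function(name = c("BLOSUM80", "BLOSUM62")) {
  name <- match.arg(name)
  if (is.null(.blosum_cache[[name]])) {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    .blosum_cache[[name]] <- env[[name]]
  }
  .blosum_cache[[name]]
}

#' Pairwise substitution score
#'
#' Vectorised lookup of the substitution score for residue pairs. `NA` is
#' returned where either residue is missing or not in the matrix.
#'
#' @param a,b Character vectors of single-letter residues (recycled).
#' @param matrix Matrix name passed to [blosum_matrix()].
#' @return Numeric vector of scores.
#' @export
blosum_score <- function(a, b, matrix = "BLOSUM80") {
  m <- blosum_matrix(matrix)
  if (length(a) == 0 || length(b) == 0) return(numeric(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(a) & !is.na(b) & a %in% rownames(m) & b %in% colnames(m)
  if (any(ok)) out[ok] <- m[cbind(a[ok], b[ok])]
  out
}

# run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in their seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == trunc(x)
}
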