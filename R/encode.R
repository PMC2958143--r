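#' @keywords internal
"_PACKAGE"

## Nucleotides are held as 4-bit sets so that intersection/union in the
## Fitch pass and wildcard handling in the likelihood pass are plain
## bitwAnd/bitwOr on integer vectors.
NUC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L, `-` = 15L, `?` = 15L
)

#' Encode an aligned character matrix as 4-bit state sets
#'
#' @param aln character matrix (rows = taxa, possibly named), single
#'   upper- or lower-case nucleotide characters from `A,C,G,T,-,?,N`
#'   (IUPAC ambiguity codes also accepted).
#' @return integer matrix of the same shape; gaps/missing become 15
#'   (wildcard over all four bases).
#' @keywords internal
encode_nuc <- function(aln) {
  stopifnot(is.matrix(aln))
  codes <- NUC_BITS[toupper(aln)]
  if (anyNA(codes)) {
    bad <- unique(aln[is.na(codes)])
    stop("unrecognised alignment characters: ", paste(bad, collapse = " "))
  }
  m <- matrix(as.integer(codes), nrow = nrow(aln))
  dimnames(m) <- dimnames(aln)
  m
}

#' Compress alignment columns into unique site patterns
#'
#' Identical columns are collapsed and weighted; an optional partition id
#' per column is folded into the pattern key so patterns never straddle
#' partitions (needed for per-partition parsimony lengths).
#'
#' @param codes integer matrix from [encode_nuc()] (taxa x sites).
#' @param part optional integer/character vector, one id per column.
#' @return list with `codes` (taxa x n_patterns), `weights` (numeric),
#'   `index` (pattern id per original column), `part` (partition id per
#'   pattern, or NULL).
#' @keywords internal
compress_patterns <- function(codes, part = NULL) {
  key <- apply(codes, 2, paste, collapse = ",")
  if (!is.null(part)) {
    stopifnot(length(part) == ncol(codes))
    key <- paste(part, key, sep = "|")
  }
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  list(
    codes   = codes[, first, drop = FALSE],
    weights = as.numeric(tabulate(idx, nbins = sum(first))),
    index   = idx,
    part    = if (is.null(part)) NULL else part[first]
  )
}

## Is each code an unambiguous single base?
is_single_base <- function(code) code %in% c(1L, 2L, 4L, 8L)

## Map single-base bit codes to 1..4 (A,C,G,T); others NA.
base_index <- function(code) {
  out <- rep(NA_integer_, length(code))
  out[code == 1L] <- 1L
  out[code == 2L] <- 2L
  out[code == 4L] <- 3L
  out[code == 8L] <- 4L
  out
}
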