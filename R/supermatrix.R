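## Supermatrix assembly and descriptive statistics: concatenation with
## partition schemes, site classification, base composition and its
## chi-square homogeneity test, K2P distances and Ti/Tv.

#' A single-locus alignment with exon/intron site annotation
#'
#' @param id gene identifier.
#' @param aln character matrix over `A,C,G,T,-,?,N` (rows named by taxa).
#' @param annotation per-column class, one of `"exon1"`, `"exon2"`,
#'   `"exon3"`, `"intron"`.
#' @return object of class `gene_alignment`.
#' @export
gene_alignment <- function(id, aln, annotation) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)),
            !anyDuplicated(rownames(aln)),
            length(annotation) == ncol(aln))
  bad <- setdiff(unique(annotation), c("exon1", "exon2", "exon3", "intron"))
  if (length(bad)) stop("unknown site annotation: ", paste(bad, collapse = " "))
  structure(list(id = id, aln = aln, annotation = annotation),
            class = "gene_alignment")
}

## contiguous blocks of sizes differing by <= 1 that sum to n
balanced_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Genes are laid end-to-end in input order; taxa absent from a gene are
#' filled with `?`. Five partition schemes are materialised: by gene,
#' exon vs intron, codon positions + intron, seven equal-length blocks,
#' and a single partition.
#'
#' @param genes list of [gene_alignment()] objects with unique ids.
#' @param taxa master taxon list; default is the union over genes in
#'   order of first appearance.
#' @return object of class `supermatrix`: `taxa`, `matrix` (character),
#'   `annotation`, `schemes` (named list of named lists of column
#'   indices), `genes` (data.frame id/start/end).
#' @export
concatenate <- function(genes, taxa = NULL) {
  stopifnot(length(genes) >= 1)
  ids <- vapply(genes, function(g) g$id, "")
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(genes, function(g) rownames(g$aln))))
  for (g in genes) {
    extra <- setdiff(rownames(g$aln), taxa)
    if (length(extra)) stop("gene ", g$id, " has taxa outside master list: ",
                            paste(extra, collapse = " "))
  }
  lens <- vapply(genes, function(g) ncol(g$aln), 0L)
  total <- sum(lens)
  m <- matrix("?", length(taxa), total, dimnames = list(taxa, NULL))
  anno <- character(total)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    cols <- starts[i]:ends[i]
    m[rownames(g$aln), cols] <- g$aln
    anno[cols] <- g$annotation
  }
  exon_cols <- which(anno != "intron")
  intron_cols <- which(anno == "intron")
  drop_empty <- function(l) l[lengths(l) > 0]
  schemes <- list(
    by_gene = stats::setNames(
      mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE), ids),
    exon_intron = drop_empty(list(exon = exon_cols, intron = intron_cols)),
    codon_intron = drop_empty(list(
      codon1 = which(anno == "exon1"), codon2 = which(anno == "exon2"),
      codon3 = which(anno == "exon3"), intron = intron_cols)),
    equal7 = stats::setNames(balanced_blocks(total, 7),
                             paste0("block", 1:7)),
    single = list(all = seq_len(total))
  )
  structure(list(taxa = taxa, matrix = m, annotation = anno,
                 schemes = schemes,
                 genes = data.frame(id = ids, start = starts, end = ends,
                                    stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$taxa), "taxa x", ncol(x$matrix), "sites,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

as_aln <- function(x) {
  if (inherits(x, "supermatrix")) x$matrix
  else if (inherits(x, "gene_alignment")) x$aln
  else x
}

## per-column counts of unambiguous bases (4 x L)
base_counts_by_col <- function(aln) {
  up <- toupper(aln)
  rbind(A = colSums(up == "A"), C = colSums(up == "C"),
        G = colSums(up == "G"), T = colSums(up == "T"))
}

#' Classify alignment columns
#'
#' A column is *variable* if at least two distinct unambiguous bases
#' occur among its non-missing rows, and *parsimony-informative* if at
#' least two bases are each present in at least two rows. Gaps, `?` and
#' `N` are ignored. Percentages use the total column count as
#' denominator.
#'
#' @param x supermatrix, gene alignment or character matrix (>= 2 rows).
#' @return list: `class` (per column), `counts`, `percent`.
#' @export
site_classes <- function(x) {
  aln <- as_aln(x)
  stopifnot(nrow(aln) >= 2)
  if (ncol(aln) == 0) stop("zero-length matrix")
  bc <- base_counts_by_col(aln)
  n_states <- colSums(bc > 0)
  n_doubles <- colSums(bc >= 2)
  cls <- rep("constant", ncol(aln))
  cls[n_states >= 2] <- "variable"
  cls[n_states >= 2 & n_doubles >= 2] <- "parsimony_informative"
  counts <- c(constant = sum(cls == "constant"),
              variable = sum(cls != "constant"),
              parsimony_informative = sum(cls == "parsimony_informative"))
  list(class = cls, counts = counts,
       percent = 100 * counts / ncol(aln))
}

#' Percentage of a site count over a total, alignment-column convention
#'
#' The reporting convention used throughout: percentage = 100 * count /
#' total alignment columns, rounded to `digits`.
#'
#' @param count,total site counts.
#' @param digits decimal places retained.
#' @return numeric percentage.
#' @export
site_percent <- function(count, total, digits = 2) {
  round(100 * count / total, digits)
}

## transition pairs: A<->G, C<->T
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

single_base <- function(v) v %in% c("A", "C", "G", "T")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Over pairwise-complete sites (both rows an unambiguous base), with
#' transition proportion P and transversion proportion Q:
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). Saturated pairs (either
#' logarithm's argument <= 0) return `NA` with `saturated = TRUE`.
#'
#' @param a,b equal-length character vectors.
#' @return list: `d`, `P`, `Q`, `n` (comparable sites), `saturated`.
#' @export
k2p_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- toupper(a); b <- toupper(b)
  ok <- single_base(a) & single_base(b)
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  diff <- ok & (a != b)
  ti <- sum(diff & is_transition(a, b))
  tv <- sum(diff) - ti
  P <- ti / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, n = n, saturated = TRUE))
  }
  list(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, n = n,
       saturated = FALSE)
}

#' Pairwise distance matrix (K2P or p-distance)
#'
#' Pairwise deletion: each pair uses its own comparable sites.
#'
#' @param x supermatrix or character matrix.
#' @param estimator `"K2P"` or `"p"`.
#' @return object of class `phylo_dist`: symmetric `matrix` with zero
#'   diagonal (`NA` marks saturated pairs), `estimator`, `saturated`
#'   (logical matrix).
#' @export
distance_matrix <- function(x, estimator = c("K2P", "p")) {
  estimator <- match.arg(estimator)
  aln <- as_aln(x)
  taxa <- rownames(aln)
  nt <- nrow(aln)
  d <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, nt, nt, dimnames = list(taxa, taxa))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    a <- aln[i, ]; b <- aln[j, ]
    if (estimator == "K2P") {
      k <- k2p_distance(a, b)
      d[i, j] <- d[j, i] <- k$d
      sat[i, j] <- sat[j, i] <- k$saturated
    } else {
      ok <- single_base(a) & single_base(b)
      if (!sum(ok)) stop("no comparable sites for pair ", taxa[i], "/", taxa[j])
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  structure(list(matrix = d, estimator = estimator, saturated = sat),
            class = "phylo_dist")
}

#' Base composition, overall and per taxon
#'
#' @param x supermatrix or character matrix.
#' @param per_taxon include per-taxon rows.
#' @return data.frame of A/C/G/T proportions (rows sum to 1); missing
#'   and gap characters excluded.
#' @export
base_composition <- function(x, per_taxon = TRUE) {
  aln <- toupper(as_aln(x))
  count_row <- function(v) {
    n <- c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
           T = sum(v == "T"))
    if (sum(n) == 0) stop("taxon with zero unambiguous sites")
    n / sum(n)
  }
  rows <- list(overall = count_row(as.vector(aln)))
  if (per_taxon) {
    for (tx in rownames(aln)) rows[[tx]] <- count_row(aln[tx, ])
  }
  out <- do.call(rbind, rows)
  as.data.frame(out)
}

#' Chi-square test of base-composition homogeneity across taxa
#'
#' Standard chi-square on the taxa x 4 base-count table with expected
#' counts from the pooled frequencies; df = (n_taxa - 1) * 3. With a
#' partition scheme the test is run per site set and overall.
#'
#' @param x supermatrix or character matrix.
#' @param scheme optional name of a partition scheme of the supermatrix
#'   (e.g. `"exon_intron"`), or a named list of column index vectors.
#' @return data.frame: partition, statistic, df, p.
#' @export
chi_square_homogeneity <- function(x, scheme = NULL) {
  aln <- toupper(as_aln(x))
  if (nrow(aln) < 2) stop("need at least 2 taxa")
  sets <- list(overall = seq_len(ncol(aln)))
  if (!is.null(scheme)) {
    if (is.character(scheme) && inherits(x, "supermatrix"))
      scheme <- x$schemes[[scheme]]
    stopifnot(is.list(scheme))
    sets <- c(sets, scheme)
  }
  one <- function(cols, name) {
    sub <- aln[, cols, drop = FALSE]
    O <- t(apply(sub, 1, function(v)
      c(sum(v == "A"), sum(v == "C"), sum(v == "G"), sum(v == "T"))))
    keep <- rowSums(O) > 0
    O <- O[keep, , drop = FALSE]
    if (nrow(O) < 2) stop("chi-square needs >= 2 taxa with unambiguous sites")
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    cells <- E > 0
    stat <- sum((O[cells] - E[cells])^2 / E[cells])
    df <- (nrow(O) - 1) * 3
    data.frame(partition = name, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, Map(one, sets, names(sets)))
}

#' Pooled transition/transversion ratio
#'
#' Transitions and transversions are counted over all taxon pairs and
#' their pairwise-comparable sites; a zero transversion count yields an
#' undefined (`NA`) ratio rather than infinity.
#'
#' @param x supermatrix or character matrix.
#' @return list: `ratio` (`NA` if undefined), `transitions`,
#'   `transversions`.
#' @export
ti_tv_ratio <- function(x) {
  aln <- toupper(as_aln(x))
  stopifnot(nrow(aln) >= 2)
  ti <- 0; tv <- 0
  for (i in seq_len(nrow(aln) - 1)) for (j in (i + 1):nrow(aln)) {
    a <- aln[i, ]; b <- aln[j, ]
    ok <- single_base(a) & single_base(b) & (a != b)
    t1 <- sum(is_transition(a[ok], b[ok]))
    ti <- ti + t1
    tv <- tv + sum(ok) - t1
  }
  list(ratio = if (tv == 0) NA_real_ else ti / tv,
       transitions = ti, transversions = tv)
}

#' Per-gene descriptive report
#'
#' One row per gene (length, % exon, variable and parsimony-informative
#' counts, mean within-group p-distance, base composition) plus an
#' aggregate row for the concatenation.
#'
#' @param genes list of [gene_alignment()] objects.
#' @param group optional taxon subset for the within-group p-distance
#'   (default: all taxa present in the gene).
#' @return data.frame, TSV-writable.
#' @export
per_gene_report <- function(genes, group = NULL) {
  stopifnot(length(genes) >= 1)
  one <- function(g) {
    aln <- g$aln
    sc <- site_classes(aln)
    sub <- if (is.null(group)) aln else
      aln[intersect(rownames(aln), group), , drop = FALSE]
    pd <- NA_real_
    if (nrow(sub) >= 2) {
      dm <- tryCatch(distance_matrix(sub, "p")$matrix, error = function(e) NULL)
      if (!is.null(dm)) pd <- mean(dm[upper.tri(dm)])
    }
    bc <- base_composition(aln, per_taxon = FALSE)
    data.frame(gene = g$id, length = ncol(aln),
               pct_exon = 100 * mean(g$annotation != "intron"),
               variable = unname(sc$counts["variable"]),
               parsimony_informative =
                 unname(sc$counts["parsimony_informative"]),
               mean_p_distance = pd,
               A = bc$A, C = bc$C, G = bc$G, T = bc$T,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(genes, one))
  sm <- concatenate(genes)
  agg <- one(gene_alignment("ALL", sm$matrix, sm$annotation))
  rbind(tab, agg)
}
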