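## Single-copy marker mining: all-vs-all protein self-comparison with
## similarity (S) and coverage (C) thresholds, single-significant-hit
## orthology confirmation, and exon-length binning of candidates.

#' All-vs-all local-alignment search over a protein set
#'
#' Every ordered query-subject pair whose Smith-Waterman local alignment
#' (BLOSUM62, affine gaps) reaches `significance_cutoff` is reported
#' with percent identity over the aligned region (S), percent of the
#' query covered by the aligned region (C) and the raw score. Self-hits
#' are always reported with S = C = 100. The cutoff is a raw-score
#' threshold: unlike an e-value it does not depend on database size.
#'
#' @param records named character vector of amino-acid sequences, or a
#'   `genome_fixture` from [simulate_genome()].
#' @param significance_cutoff minimum local-alignment score (> 0). The
#'   default 150 sits far above the score ceiling of unrelated random
#'   proteins of a few hundred residues (< 100) while homologues at 40%+
#'   identity score in the many hundreds.
#' @return object of class `hit_table`: data.frame query, subject, S, C,
#'   score; attribute `"cutoff"`.
#' @export
all_vs_all_search <- function(records, significance_cutoff = 150) {
  if (inherits(records, "genome_fixture")) records <- records$records
  stopifnot(length(records) >= 1, significance_cutoff > 0)
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must have unique names")
  ids <- names(records)
  xs <- Biostrings::AAStringSet(records)
  lens <- Biostrings::width(xs)
  names(lens) <- ids
  rows <- list()
  add <- function(q, s, S, C, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query = q, subject = s, S = S, C = C, score = score,
      stringsAsFactors = FALSE)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  for (i in seq_along(ids)) {
    self <- Biostrings::pairwiseAlignment(
      xs[[i]], xs[[i]], type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 10, gapExtension = 0.5)
    add(ids[i], ids[i], 100, 100, Biostrings::score(self))
  }
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      pa <- Biostrings::pairwiseAlignment(
        xs[[i]], xs[[j]], type = "local", substitutionMatrix = BLOSUM62,
        gapOpening = 10, gapExtension = 0.5)
      sc <- Biostrings::score(pa)
      if (sc < significance_cutoff) next
      S <- Biostrings::pid(pa, type = "PID1")
      span_q <- Biostrings::nchar(pa) -
        Biostrings::nindel(pa)@insertion[, "WidthSum"]
      span_s <- Biostrings::nchar(pa) -
        Biostrings::nindel(pa)@deletion[, "WidthSum"]
      add(ids[i], ids[j], S, 100 * span_q / lens[i], sc)
      add(ids[j], ids[i], S, 100 * span_s / lens[j], sc)
    }
  }
  tab <- do.call(rbind, rows)
  structure(tab, class = c("hit_table", "data.frame"),
            cutoff = significance_cutoff)
}

#' Filter a hit table down to single-copy genes
#'
#' A gene is retained iff *every* non-self hit involving it (as query or
#' subject) has similarity below `s_max` *and* coverage below `c_max`
#' (the strict reading; `rule = "either"` disqualifies only hits
#' breaching both thresholds). Self-hits are ignored.
#'
#' @param table a `hit_table` (self-hits present).
#' @param s_max,c_max percent thresholds in (0, 100].
#' @param rule `"all_below"` (default, strict) or `"either"`.
#' @return list: `retained` (character ids), `excluded`, `diagnostics`
#'   (worst offending hit per gene).
#' @export
filter_single_copy <- function(table, s_max = 30, c_max = 30,
                               rule = c("all_below", "either")) {
  rule <- match.arg(rule)
  if (s_max <= 0 || s_max > 100 || c_max <= 0 || c_max > 100)
    stop("thresholds must lie in (0, 100]")
  genes <- unique(table$query)
  nonself <- table[table$query != table$subject, , drop = FALSE]
  offending <- function(h) {
    if (rule == "all_below") !(h$S < s_max & h$C < c_max)
    else h$S >= s_max & h$C >= c_max
  }
  retained <- character(0); excluded <- character(0)
  diags <- list()
  for (g in genes) {
    hits <- nonself[nonself$query == g | nonself$subject == g, , drop = FALSE]
    bad <- if (nrow(hits)) offending(hits) else logical(0)
    if (any(bad)) {
      excluded <- c(excluded, g)
      worst <- hits[bad, , drop = FALSE]
      worst <- worst[which.max(pmax(worst$S, worst$C)), , drop = FALSE]
      diags[[g]] <- cbind(gene = g, worst)
    } else {
      retained <- c(retained, g)
    }
  }
  list(retained = retained, excluded = excluded,
       diagnostics = if (length(diags)) do.call(rbind, diags) else NULL)
}

#' Confirm that a marker has exactly one significant database hit
#'
#' @param query gene id (must be present in the table).
#' @param table a `hit_table` built against the reference database.
#' @return TRUE iff exactly one distinct non-self subject is hit.
#' @export
confirm_single_hit <- function(query, table) {
  if (!query %in% table$query) stop("query absent from hit table: ", query)
  subjects <- unique(table$subject[table$query == query &
                                     table$subject != query])
  length(subjects) == 1L
}

#' Bin candidate genes by exon length
#'
#' Histogram over `(b1,b2], (b2,b3], ..., (b_last, Inf)`; genes shorter
#' than the first boundary are reported separately.
#'
#' @param exon_lengths non-negative numeric vector (names = gene ids).
#' @param boundaries strictly increasing bin boundaries.
#' @return named integer vector: `below_<b1>`, one count per bin, and
#'   `gt_<b_last>`.
#' @export
bin_by_exon_length <- function(exon_lengths, boundaries = c(500, 600, 700, 800)) {
  stopifnot(all(exon_lengths >= 0))
  if (is.unsorted(boundaries, strictly = TRUE)) stop("unsorted boundaries")
  k <- length(boundaries)
  labs <- c(paste0("below_", boundaries[1]),
            paste0(boundaries[-k], "_", boundaries[-1]),
            paste0("gt_", boundaries[k]))
  idx <- findInterval(exon_lengths, boundaries, left.open = TRUE) + 1L
  ## findInterval with left.open: length == boundary falls in lower bin
  counts <- tabulate(idx, nbins = k + 1L)
  stats::setNames(as.integer(counts), labs)
}
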