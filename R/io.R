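## Readers and writers for the standard formats: per-gene FASTA plus
## annotation TSV, NEXUS supermatrix with a SETS block, Newick trees,
## NEXUS discrete-trait matrices, and plain TSV tables.

#' Write a gene alignment as FASTA plus an annotation TSV
#'
#' @param gene a [gene_alignment()].
#' @param fasta,annotation_tsv output paths (annotation file optional).
#' @export
write_gene_fasta <- function(gene, fasta, annotation_tsv = NULL) {
  seqs <- apply(gene$aln, 1, paste, collapse = "")
  xs <- Biostrings::BStringSet(seqs)
  names(xs) <- rownames(gene$aln)
  Biostrings::writeXStringSet(xs, fasta)
  if (!is.null(annotation_tsv)) {
    utils::write.table(
      data.frame(site = seq_along(gene$annotation), class = gene$annotation),
      annotation_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a gene alignment from FASTA (+ optional annotation TSV)
#'
#' Without an annotation file all sites are treated as `exon` with codon
#' positions cycling 1,2,3.
#'
#' @param fasta path to an aligned FASTA file.
#' @param annotation_tsv optional TSV with columns `site`, `class`.
#' @param id gene id (default: file name without extension).
#' @return a [gene_alignment()].
#' @export
read_gene_fasta <- function(fasta, annotation_tsv = NULL, id = NULL) {
  xs <- Biostrings::readBStringSet(fasta)
  aln <- do.call(rbind, strsplit(toupper(as.character(xs)), ""))
  rownames(aln) <- names(xs)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(fasta))
  anno <- if (is.null(annotation_tsv)) {
    paste0("exon", rep_len(1:3, ncol(aln)))
  } else {
    tab <- utils::read.table(annotation_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    tab$class[order(tab$site)]
  }
  gene_alignment(id, aln, anno)
}

## run-length encode integer site sets as NEXUS range strings
nexus_ranges <- function(cols) {
  cols <- sort(cols)
  breaks <- c(0, which(diff(cols) != 1), length(cols))
  parts <- character(0)
  for (i in seq_len(length(breaks) - 1)) {
    s <- cols[breaks[i] + 1]; e <- cols[breaks[i + 1]]
    parts <- c(parts, if (s == e) as.character(s) else paste0(s, "-", e))
  }
  paste(parts, collapse = " ")
}

#' Write a supermatrix as NEXUS with a SETS block
#'
#' All partition schemes are emitted as CHARSET lines plus one
#' CHARPARTITION per scheme.
#'
#' @param sm a [concatenate()] supermatrix.
#' @param path output path.
#' @export
write_supermatrix_nexus <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nt <- length(sm$taxa); nc <- ncol(sm$matrix)
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
               "  MATRIX"), con)
  for (tx in sm$taxa) {
    writeLines(sprintf("    %s  %s", gsub("[^A-Za-z0-9_.]", "_", tx),
                       paste(sm$matrix[tx, ], collapse = "")), con)
  }
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  for (scheme in names(sm$schemes)) {
    sets <- sm$schemes[[scheme]]
    for (nm in names(sets)) {
      writeLines(sprintf("  CHARSET %s_%s = %s;", scheme, nm,
                         nexus_ranges(sets[[nm]])), con)
    }
    writeLines(sprintf("  CHARPARTITION %s = %s;", scheme,
                       paste(sprintf("%s:%s_%s", names(sets), scheme,
                                     names(sets)), collapse = ", ")), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' Read a NEXUS data matrix (sequences or discrete traits)
#'
#' Thin wrapper over `ape::read.nexus.data` returning a character
#' matrix; CHARSET lines, when present, are parsed into a list of site
#' sets attached as attribute `"charsets"`.
#'
#' @param path NEXUS file path.
#' @return character matrix (rows = taxa).
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(dat, toupper))
  rownames(m) <- names(dat)
  txt <- readLines(path, warn = FALSE)
  cs_lines <- grep("^\\s*charset", txt, ignore.case = TRUE, value = TRUE)
  if (length(cs_lines)) {
    charsets <- list()
    for (l in cs_lines) {
      nm <- trimws(sub("^[[:space:]]*charset[[:space:]]+([^=]+)=.*$", "\\1",
                       l, ignore.case = TRUE))
      body <- sub("^.*=\\s*(.*);\\s*$", "\\1", l)
      cols <- integer(0)
      for (tok in strsplit(trimws(body), "\\s+")[[1]]) {
        if (grepl("-", tok)) {
          se <- as.integer(strsplit(tok, "-")[[1]])
          cols <- c(cols, se[1]:se[2])
        } else cols <- c(cols, as.integer(tok))
      }
      charsets[[nm]] <- cols
    }
    attr(m, "charsets") <- charsets
  }
  m
}

#' Read a discrete-trait matrix from TSV
#'
#' First column taxa, remaining columns characters; states coded as
#' strings, `?`/`-`/`NA` treated as missing.
#'
#' @param path TSV file path.
#' @return character matrix (rows = taxa).
#' @export
read_trait_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "character"
  rownames(m) <- tab[[1]]
  m[m %in% c("?", "-", "NA", "")] <- NA_character_
  m
}

#' Write a data.frame as TSV
#' @param tab data.frame; @param path output path.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
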