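## Maximum parsimony: vectorised Fitch scoring over site patterns, exact
## (exhaustive / branch-and-bound) and heuristic (random addition + TBR)
## searches, nonparametric and variable-length bootstrap, and
## Bremer / partitioned Bremer support via anti-constraint searches.

## ---- scoring -----------------------------------------------------------

## Fitch pass on an internal edge-list tree.  `codes` rows are indexed by
## tip id.  Returns total weighted score and per-pattern step counts.
fitch_el <- function(el, codes, weights, per_site = FALSE) {
  po <- el_postorder(el$parent, el$child)
  P <- ncol(codes)
  maxid <- max(el$parent, el$child)
  S <- matrix(0L, maxid, P)
  tips <- unique(c(el$parent, el$child))
  tips <- tips[tips <= el$ntip]
  S[tips, ] <- codes[tips, , drop = FALSE]
  steps <- integer(P)
  for (v in po$order) {
    ks <- po$kids[[v]]
    A <- S[ks[1L], ]
    for (w in ks[-1L]) {
      B <- S[w, ]
      I <- bitwAnd(A, B)
      z <- I == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        I[z] <- bitwOr(A[z], B[z])
      }
      A <- I
    }
    S[v, ] <- A
  }
  total <- sum(steps * weights)
  if (per_site) list(total = total, steps = steps) else total
}

## encode + compress a character alignment matrix (rows = taxa)
prepare_codes <- function(aln, part = NULL) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  cp <- compress_patterns(encode_nuc(aln), part = part)
  cp$labels <- rownames(aln)
  cp
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of unordered state changes required by `aln` on the
#' topology `phy`, summed over columns. Gaps, `?` and `N` act as
#' wildcards and never force a change on their own.
#'
#' @param phy a binary tree (`phylo`); branch lengths ignored.
#' @param aln character matrix, rows named by the tree's taxa.
#' @param site_steps logical; also return per-column step counts.
#' @return integer score, or a list with `score` and `site_steps`.
#' @export
fitch_score <- function(phy, aln, site_steps = FALSE) {
  if (!setequal(phy$tip.label, rownames(aln)))
    stop("tree leaves and alignment taxa differ")
  aln <- aln[phy$tip.label, , drop = FALSE]
  cp <- prepare_codes(aln)
  el <- phylo_to_el(phy)
  fs <- fitch_el(el, cp$codes, cp$weights, per_site = TRUE)
  if (site_steps) {
    list(score = fs$total, site_steps = fs$steps[cp$index])
  } else {
    as.integer(fs$total)
  }
}

## ---- search ------------------------------------------------------------

## greedy stepwise addition in the order `ord` (tip ids); random tie-break
greedy_addition <- function(cp, ord) {
  ntip <- length(cp$labels)
  iid <- ntip + 1L
  el <- el_triplet(ord[1:3], ntip, iid)
  iid <- iid + 1L
  for (t in ord[-(1:3)]) {
    best <- Inf; best_el <- NULL
    idx <- seq_along(el$parent)
    for (i in idx) {
      cand <- el_insert_tip(el, t, i, iid)
      sc <- fitch_el(cand, cp$codes, cp$weights)
      if (sc < best || (sc == best && stats::runif(1) < 0.5)) {
        best <- sc; best_el <- cand
      }
    }
    el <- best_el
    iid <- iid + 1L
  }
  list(el = el, score = best)
}

## hill-climb until no improvement: cheap NNI passes first, then (when
## `use_tbr`) one full TBR neighbourhood scan, looping back to NNI after
## any TBR improvement.  `admit` optionally rejects candidate trees
## (anti-constraint searches).
swap_climb <- function(el, cp, use_tbr = TRUE, admit = NULL) {
  cur <- el
  cur_score <- fitch_el(cur, cp$codes, cp$weights)
  pass <- function(neighbors) {
    improved <- FALSE
    for (nb in neighbors(cur)) {
      if (!is.null(admit) && !admit(nb)) next
      sc <- fitch_el(nb, cp$codes, cp$weights)
      if (sc < cur_score) {
        cur <<- nb; cur_score <<- sc; improved <- TRUE
        break
      }
    }
    improved
  }
  repeat {
    while (pass(el_nni_neighbors)) {}
    if (!use_tbr || !pass(el_tbr_neighbors)) break
  }
  list(el = cur, score = cur_score)
}

## exact search by stepwise addition with pruning at `bound`;
## `admit` filters completed trees (anti-constraint searches)
addition_search <- function(cp, bound = Inf, collect = TRUE, admit = NULL) {
  ntip <- length(cp$labels)
  best <- bound
  best_els <- list()
  rec <- function(el, nxt, iid) {
    sc <- fitch_el(el, cp$codes, cp$weights)
    if (sc > best) return(invisible())
    if (nxt > ntip) {
      if (!is.null(admit) && !admit(el)) return(invisible())
      if (sc < best) {
        best <<- sc
        best_els <<- list(el)
      } else if (collect && sc == best) {
        best_els <<- c(best_els, list(el))
      }
      return(invisible())
    }
    for (i in seq_along(el$parent)) {
      rec(el_insert_tip(el, nxt, i, iid), nxt + 1L, iid + 1L)
    }
  }
  rec(el_triplet(1:3, ntip, ntip + 1L), 4L, ntip + 2L)
  list(els = best_els, score = best)
}

#' Maximum-parsimony tree search
#'
#' Exact search (exhaustive enumeration or branch-and-bound) for small
#' taxon sets, or a heuristic of random-addition starting trees refined
#' by TBR branch swapping. All equally parsimonious trees are retained
#' (deduplicated by topology).
#'
#' @param aln character matrix, rows named by taxa (>= 4).
#' @param strategy `"auto"` picks branch-and-bound for <= 10 taxa, TBR
#'   otherwise.
#' @param n_addition_replicates random addition-sequence replicates for
#'   the heuristic.
#' @param seed optional integer seed.
#' @param allow_large permit exhaustive enumeration beyond 10 taxa.
#' @return list with `trees` (list of `phylo`), `score`, `strategy`.
#' @export
mp_search <- function(aln,
                      strategy = c("auto", "exhaustive", "branch_and_bound",
                                   "tbr_heuristic"),
                      n_addition_replicates = 10, seed = NULL,
                      allow_large = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(nrow(aln) >= 4)
  if (!is.null(seed)) set.seed(seed)
  cp <- prepare_codes(aln)
  ntip <- nrow(aln)
  if (strategy == "auto")
    strategy <- if (ntip <= 10) "branch_and_bound" else "tbr_heuristic"
  if (strategy == "exhaustive" && ntip > 10 && !allow_large)
    stop("exhaustive search refused for more than 10 taxa; ",
         "set allow_large = TRUE to override")

  if (strategy %in% c("exhaustive", "branch_and_bound")) {
    bound <- Inf
    if (strategy == "branch_and_bound") {
      bound <- greedy_addition(cp, seq_len(ntip))$score
    }
    res <- addition_search(cp, bound = bound)
    els <- res$els
    score <- res$score
  } else {
    best <- Inf
    els <- list()
    keys <- character(0)
    for (r in seq_len(n_addition_replicates)) {
      start <- greedy_addition(cp, sample.int(ntip))
      hc <- swap_climb(start$el, cp)
      if (hc$score < best) {
        best <- hc$score
        els <- list(hc$el)
        keys <- el_topo_key(hc$el, cp$labels)
      } else if (hc$score == best) {
        k <- el_topo_key(hc$el, cp$labels)
        if (!k %in% keys) {
          els <- c(els, list(hc$el))
          keys <- c(keys, k)
        }
      }
    }
    score <- best
  }
  ## dedupe by topology
  keys <- vapply(els, el_topo_key, "", labels = cp$labels)
  els <- els[!duplicated(keys)]
  list(trees = lapply(els, el_to_phylo, labels = cp$labels),
       score = as.integer(score), strategy = strategy)
}

## ---- bootstrap ---------------------------------------------------------

## one bootstrap/VLB replicate: resample `size` columns by pattern index,
## search, return split keys of the (first) best tree
boot_replicate <- function(cp, size, strategy, n_addition) {
  w <- tabulate(sample(cp$index, size, replace = TRUE),
                nbins = ncol(cp$codes))
  keep <- w > 0
  sub <- list(codes = cp$codes[, keep, drop = FALSE],
              weights = as.numeric(w[keep]), labels = cp$labels)
  ntip <- length(cp$labels)
  best <- Inf; best_el <- NULL
  for (r in seq_len(n_addition)) {
    start <- greedy_addition(sub, sample.int(ntip))
    hc <- swap_climb(start$el, sub, use_tbr = strategy == "tbr_heuristic")
    if (hc$score < best) { best <- hc$score; best_el <- hc$el }
  }
  best_el
}

#' Nonparametric bootstrap support under parsimony
#'
#' Columns are resampled with replacement to the original length; each
#' pseudo-replicate is analysed by a parsimony search and split
#' frequencies are tabulated over replicates.
#'
#' @param aln character matrix, rows named by taxa.
#' @param n_reps number of pseudo-replicates.
#' @param seed optional integer seed.
#' @param strategy replicate-level search: `"greedy_nni"` (random
#'   addition + NNI refinement, the desk-scale default) or
#'   `"tbr_heuristic"`.
#' @param n_addition addition-sequence replicates per pseudo-replicate.
#' @param reference tree whose splits are reported (default: MP tree of
#'   `aln`).
#' @return list with `table` (split, support %), `freqs` (all observed
#'   splits), `consensus` (majority-rule consensus `phylo`), `reference`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = NULL,
                              strategy = c("greedy_nni", "tbr_heuristic"),
                              n_addition = 1, reference = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- mp_search(aln)$trees[[1]]
  cp <- prepare_codes(aln)
  counts <- new.env(parent = emptyenv())
  rep_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    el <- boot_replicate(cp, ncol(aln), strategy, n_addition)
    for (k in el_split_keys(el$parent, el$child, el$ntip, cp$labels)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
    rep_trees[[b]] <- el_to_phylo(el, cp$labels)
  }
  freqs <- unlist(as.list(counts)) / n_reps * 100
  if (is.null(freqs)) freqs <- numeric(0)
  ref_keys <- tree_splits(reference)
  sup <- ifelse(ref_keys %in% names(freqs), freqs[ref_keys], 0)
  cons <- ape::consensus(rep_trees, p = 0.5)
  list(table = data.frame(split = ref_keys, bootstrap = as.numeric(sup),
                          stringsAsFactors = FALSE),
       freqs = freqs, consensus = cons, reference = reference)
}

#' Variable-length bootstrap support curves
#'
#' Bootstrap pseudo-matrices of a range of lengths (resampling with
#' replacement, so lengths may exceed the original matrix) chart how
#' split support grows with the quantity of data.
#'
#' @inheritParams bootstrap_support
#' @param sizes integer vector of resample lengths.
#' @return data.frame (size, split, support) over the reference splits.
#' @export
variable_length_bootstrap <- function(aln, sizes, n_reps = 100, seed = NULL,
                                      strategy = c("greedy_nni",
                                                   "tbr_heuristic"),
                                      n_addition = 1, reference = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- mp_search(aln)$trees[[1]]
  cp <- prepare_codes(aln)
  ref_keys <- tree_splits(reference)
  out <- list()
  for (m in sizes) {
    hits <- stats::setNames(numeric(length(ref_keys)), ref_keys)
    for (b in seq_len(n_reps)) {
      el <- boot_replicate(cp, m, strategy, n_addition)
      ks <- el_split_keys(el$parent, el$child, el$ntip, cp$labels)
      hits[ref_keys %in% ks] <- hits[ref_keys %in% ks] + 1
    }
    out[[length(out) + 1L]] <- data.frame(
      size = m, split = ref_keys, support = as.numeric(hits) / n_reps * 100,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- Bremer / partitioned Bremer --------------------------------------

## best score among trees NOT containing `split_key`; exact for small
## taxon sets, constrained TBR otherwise.  Returns score and co-optimal
## anti-constraint trees.
anti_constraint_search <- function(cp, split_key, best_el, exact,
                                   n_restarts = 3) {
  labels <- cp$labels
  lacks <- function(el)
    !split_key %in% el_split_keys(el$parent, el$child, el$ntip, labels)
  if (exact) {
    res <- addition_search(cp, bound = Inf, admit = lacks)
    ## keep co-optimal anti trees, deduplicated
    keys <- vapply(res$els, el_topo_key, "", labels = labels)
    list(score = res$score, els = res$els[!duplicated(keys)])
  } else {
    ## start from NNI perturbations of the best tree that break the split
    starts <- Filter(lacks, el_nni_neighbors(best_el))
    if (!length(starts)) starts <- list(best_el)
    best <- Inf; els <- list(); keys <- character(0)
    for (s in starts[seq_len(min(length(starts), n_restarts))]) {
      hc <- swap_climb(s, cp, admit = lacks)
      if (hc$score < best) {
        best <- hc$score; els <- list(hc$el)
        keys <- el_topo_key(hc$el, labels)
      } else if (hc$score == best) {
        k <- el_topo_key(hc$el, labels)
        if (!k %in% keys) { els <- c(els, list(hc$el)); keys <- c(keys, k) }
      }
    }
    list(score = best, els = els)
  }
}

## per-partition Fitch lengths of a tree (named numeric by partition)
partition_lengths <- function(el, cp) {
  fs <- fitch_el(el, cp$codes, cp$weights, per_site = TRUE)
  contrib <- fs$steps * cp$weights
  tapply(contrib, cp$part, sum)
}

#' Bremer (decay) and partitioned Bremer support
#'
#' For each internal split of the most-parsimonious tree, the decay
#' index is the extra length of the best tree that does not contain the
#' split, found by an anti-constraint search (exact enumeration with
#' pruning for small taxon sets, constrained TBR otherwise). With a
#' partition, the decay decomposes into per-partition contributions
#' (PBS), which may be negative and always sum to the decay index.
#'
#' @param aln character matrix, rows named by taxa.
#' @param best_tree an MP tree for `aln` (verified by rescoring).
#' @param part optional partition id per column; when given, PBS columns
#'   are added.
#' @param exact_max use exact anti-constraint search up to this many taxa.
#' @param tie_break `"average"` per-partition lengths across co-optimal
#'   anti-constraint trees, or `"first"`.
#' @param seed optional integer seed (heuristic search path).
#' @return data.frame: split, decay, and one `pbs.<partition>` column per
#'   partition when `part` is given.
#' @export
bremer_support <- function(aln, best_tree, part = NULL, exact_max = 9,
                           tie_break = c("average", "first"), seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(setequal(rownames(aln), best_tree$tip.label))
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  cp <- prepare_codes(aln, part = part)
  best_el <- phylo_to_el_relabel(best_tree, cp$labels)
  best_score <- fitch_el(best_el, cp$codes, cp$weights)
  ## optimality check: any NNI neighbour strictly better => not an MP tree
  for (nb in el_nni_neighbors(best_el)) {
    if (fitch_el(nb, cp$codes, cp$weights) < best_score)
      stop("best_tree is not optimal for this matrix (an NNI neighbour is shorter)")
  }
  exact <- length(cp$labels) <= exact_max
  keys <- el_split_keys(best_el$parent, best_el$child, best_el$ntip, cp$labels)
  base_len <- if (!is.null(part)) partition_lengths(best_el, cp)
  rows <- lapply(keys, function(k) {
    res <- anti_constraint_search(cp, k, best_el, exact)
    decay <- res$score - best_score
    row <- data.frame(split = k, decay = as.numeric(decay),
                      stringsAsFactors = FALSE)
    if (!is.null(part)) {
      lens <- lapply(res$els, partition_lengths, cp = cp)
      if (tie_break == "first") lens <- lens[1]
      anti_len <- Reduce(`+`, lens) / length(lens)
      pbs <- anti_len - base_len
      names(pbs) <- paste0("pbs.", names(pbs))
      row <- cbind(row, as.data.frame(as.list(pbs)))
    }
    row
  })
  do.call(rbind, rows)
}

#' @rdname bremer_support
#' @export
partitioned_bremer <- function(aln, part, best_tree, exact_max = 9,
                               tie_break = c("average", "first"),
                               seed = NULL) {
  stopifnot(length(part) == ncol(aln))
  bremer_support(aln, best_tree, part = part, exact_max = exact_max,
                 tie_break = tie_break, seed = seed)
}

## map an ape tree onto internal ids given a fixed label order
phylo_to_el_relabel <- function(phy, labels) {
  phy <- ape::unroot(phy)
  ids <- match(phy$tip.label, labels)
  ntip <- length(labels)
  e <- phy$edge
  remap <- function(x) ifelse(x <= length(phy$tip.label), ids[x],
                              x - length(phy$tip.label) + ntip)
  list(parent = remap(e[, 1]), child = remap(e[, 2]), ntip = ntip,
       labels = labels)
}
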