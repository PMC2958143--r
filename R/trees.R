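## Internal unrooted-tree machinery used by the parsimony search engine.
##
## Trees are held as directed edge lists (`parent`, `child` integer
## vectors): tips are 1..ntip, internal nodes any id > ntip, and edges
## point away from an arbitrary internal "root" (a trifurcation for a
## binary unrooted tree).  Conversion to/from ape's `phylo` happens only
## at API boundaries; the search inner loops stay on plain vectors.

el_root <- function(parent, child) {
  r <- setdiff(unique(parent), child)
  stopifnot(length(r) == 1L)
  r
}

## children-of list indexed by node id
el_children <- function(parent, child, maxid) {
  kids <- vector("list", maxid)
  for (i in seq_along(parent)) kids[[parent[i]]] <- c(kids[[parent[i]]], child[i])
  kids
}

## internal nodes in postorder (children before parents)
el_postorder <- function(parent, child) {
  root <- el_root(parent, child)
  maxid <- max(parent, child)
  kids <- el_children(parent, child, maxid)
  ## preorder by stack, then reverse
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, kids[[v]])
  }
  internal <- pre[lengths(kids[pre]) > 0L]
  list(order = rev(internal), kids = kids, root = root)
}

## Direct an undirected edge set (a,b) into (parent,child), rooted at an
## internal node (or a given node id).
direct_tree <- function(a, b, ntip, root = NULL) {
  nodes <- unique(c(a, b))
  if (is.null(root)) {
    internal <- nodes[nodes > ntip]
    root <- if (length(internal)) min(internal) else nodes[1]
  }
  maxid <- max(nodes)
  adj <- vector("list", maxid)
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  parent <- integer(length(a))
  child <- integer(length(a))
  k <- 0L
  stack <- root
  from <- rep(0L, maxid)
  from[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (w == from[v]) next
      k <- k + 1L
      parent[k] <- v
      child[k] <- w
      from[w] <- v
      stack <- c(stack, w)
    }
  }
  list(parent = parent, child = child, ntip = ntip)
}

## tip sets (logical over 1..ntip) below each node
el_tipsets <- function(parent, child, ntip) {
  po <- el_postorder(parent, child)
  maxid <- max(parent, child)
  sets <- matrix(FALSE, maxid, ntip)
  tips <- unique(c(parent, child))
  tips <- tips[tips <= ntip]
  sets[cbind(tips, tips)] <- TRUE
  for (v in po$order) {
    for (w in po$kids[[v]]) sets[v, ] <- sets[v, ] | sets[w, ]
  }
  sets
}

## Canonical keys for the non-trivial splits of a tree over `labels`
## (labels indexed by tip id).  The key is the sorted side that does NOT
## contain the lexicographically smallest label, joined by "|".
el_split_keys <- function(parent, child, ntip, labels) {
  sets <- el_tipsets(parent, child, ntip)
  root <- el_root(parent, child)
  anchor <- which(labels == min(labels, na.rm = TRUE))[1]
  keys <- character(0)
  for (i in seq_along(child)) {
    v <- child[i]
    if (v <= ntip) next        # trivial split
    side <- sets[v, ]
    if (!side[anchor]) side <- !side
    if (sum(side) < 2L || sum(!side) < 2L) next
    keys <- c(keys, paste(sort(labels[side]), collapse = "|"))
  }
  unique(keys)
}

## canonical topology identifier (independent of rooting/edge order)
el_topo_key <- function(el, labels) {
  paste(sort(el_split_keys(el$parent, el$child, el$ntip, labels)), collapse = ";")
}

#' Non-trivial splits (bipartitions) of a tree
#'
#' Each internal edge of an unrooted tree induces a bipartition of the
#' taxa. Splits are keyed canonically by the lexicographically smaller
#' side (the one containing the alphabetically first taxon), sorted and
#' joined with `"|"`, so support values from different methods can be
#' merged on the key.
#'
#' @param phy an object of class `phylo`.
#' @return character vector of split keys.
#' @export
tree_splits <- function(phy) {
  phy <- ape::unroot(phy)
  el <- phylo_to_el(phy)
  el_split_keys(el$parent, el$child, el$ntip, phy$tip.label)
}

#' Test whether two trees have the same unrooted topology
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  stopifnot(setequal(t1$tip.label, t2$tip.label))
  setequal(tree_splits(t1), tree_splits(t2))
}

## ---- conversions -------------------------------------------------------

phylo_to_el <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  list(parent = phy$edge[, 1], child = phy$edge[, 2], ntip = ntip,
       labels = phy$tip.label)
}

el_to_phylo <- function(el, labels) {
  parent <- el$parent; child <- el$child; ntip <- el$ntip
  tips <- sort(unique(c(parent, child)[c(parent, child) <= ntip]))
  internals <- unique(c(parent, child)[c(parent, child) > ntip])
  ## ape wants tips 1..k, internals k+1.., root first
  root <- el_root(parent, child)
  internals <- c(root, setdiff(internals, root))
  map <- integer(max(parent, child))
  map[tips] <- seq_along(tips)
  map[internals] <- length(tips) + seq_along(internals)
  phy <- list(edge = cbind(map[parent], map[child]),
              tip.label = labels[tips],
              Nnode = length(internals))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::read.tree(text = ape::write.tree(phy))
}

## ---- elementary tree surgery ------------------------------------------

## star triplet on tip ids t (length 3); internal node gets id `iid`
el_triplet <- function(t, ntip, iid) {
  list(parent = rep(iid, 3L), child = t, ntip = ntip)
}

## attach tip `tip` onto edge i of `el`; new internal node id `iid`
el_insert_tip <- function(el, tip, i, iid) {
  p <- el$parent; ch <- el$child
  pe <- p[i]; ce <- ch[i]
  p <- p[-i]; ch <- ch[-i]
  list(parent = c(p, pe, iid, iid), child = c(ch, iid, ce, tip), ntip = el$ntip)
}

## undirected edge pairs of an el
el_undirected <- function(el) cbind(el$parent, el$child)

## suppress a degree-2 node in an undirected edge matrix
suppress_deg2 <- function(ed, v) {
  hit <- which(ed[, 1] == v | ed[, 2] == v)
  if (length(hit) != 2L) return(ed)
  nb <- c(ed[hit, ][ed[hit, ] != v])
  ed <- ed[-hit, , drop = FALSE]
  rbind(ed, nb)
}

## All NNI rearrangements around internal edges (undirected logic).
el_nni_neighbors <- function(el) {
  ed <- el_undirected(el)
  ntip <- el$ntip
  out <- list()
  for (i in seq_len(nrow(ed))) {
    u <- ed[i, 1]; v <- ed[i, 2]
    if (u <= ntip || v <= ntip) next
    nb_u <- setdiff(c(ed[ed[, 1] == u, 2], ed[ed[, 2] == u, 1]), v)
    nb_v <- setdiff(c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1]), u)
    if (length(nb_u) < 2L || length(nb_v) < 2L) next
    b <- nb_u[2]
    for (c_ in nb_v) {
      ed2 <- ed
      swap_edge <- function(m, x, y, nx, ny) {
        j <- which((m[, 1] == x & m[, 2] == y) | (m[, 1] == y & m[, 2] == x))[1]
        m[j, ] <- c(nx, ny)
        m
      }
      ed2 <- swap_edge(ed2, u, b, v, b)
      ed2 <- swap_edge(ed2, v, c_, u, c_)
      out[[length(out) + 1L]] <-
        direct_tree(ed2[, 1], ed2[, 2], ntip)
    }
  }
  out
}

## All TBR rearrangements: bisect every edge, reattach every edge pair.
el_tbr_neighbors <- function(el) {
  ed <- el_undirected(el)
  ntip <- el$ntip
  maxid <- max(ed)
  out <- list()
  for (i in seq_len(nrow(ed))) {
    u <- ed[i, 1]; v <- ed[i, 2]
    rest <- ed[-i, , drop = FALSE]
    comp_u <- reachable(rest, u)
    e_u <- rest[rest[, 1] %in% comp_u, , drop = FALSE]
    e_v <- rest[!(rest[, 1] %in% comp_u), , drop = FALSE]
    e_u <- fixup_component(e_u, u)
    e_v <- fixup_component(e_v, v)
    att_u <- attachment_points(e_u, u)
    att_v <- attachment_points(e_v, v)
    for (au in att_u) for (av in att_v) {
      ne <- maxid
      join <- function(comp, att) {
        if (is.null(att$edge)) return(list(edges = comp$edges, node = att$node))
        ne <<- ne + 1L
        x <- ne
        m <- comp$edges
        j <- att$edge
        e1 <- m[j, ]
        m <- m[-j, , drop = FALSE]
        m <- rbind(m, c(e1[1], x), c(x, e1[2]))
        list(edges = m, node = x)
      }
      ju <- join(au$comp, au)
      jv <- join(av$comp, av)
      ed2 <- rbind(ju$edges, jv$edges, c(ju$node, jv$node))
      out[[length(out) + 1L]] <- direct_tree(ed2[, 1], ed2[, 2], ntip)
    }
  }
  out
}

## nodes reachable from x in an undirected edge matrix
reachable <- function(ed, x) {
  seen <- x
  repeat {
    nb <- c(ed[ed[, 1] %in% seen, 2], ed[ed[, 2] %in% seen, 1])
    new <- setdiff(nb, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  seen
}

## after bisection, the cut endpoint may have degree 2: suppress it
fixup_component <- function(edges, endpoint) {
  if (nrow(edges) == 0L) return(list(edges = edges, single = endpoint))
  deg <- sum(edges[, 1] == endpoint | edges[, 2] == endpoint)
  if (deg == 2L) edges <- suppress_deg2(edges, endpoint)
  list(edges = edges, single = NULL)
}

## candidate reattachment loci of a component: each edge, or the lone node
attachment_points <- function(comp, endpoint) {
  if (nrow(comp$edges) == 0L) {
    return(list(list(comp = comp, edge = NULL, node = endpoint)))
  }
  lapply(seq_len(nrow(comp$edges)),
         function(j) list(comp = comp, edge = j, node = NULL))
}

## All NNI neighbours of a phylo, preserving branch lengths (each swap
## exchanges a child subtree of an internal edge's lower node with a
## child subtree of its upper node; lengths travel with the subtrees).
nni_neighbors_phylo <- function(phy) {
  e <- phy$edge
  ntip <- length(phy$tip.label)
  out <- list()
  for (i in which(e[, 2] > ntip)) {
    u <- e[i, 1]; v <- e[i, 2]
    ch_v <- which(e[, 1] == v)
    ch_u <- setdiff(which(e[, 1] == u), i)
    for (a in ch_v) for (w in ch_u) {
      p2 <- phy
      tmp <- p2$edge[a, 2]
      p2$edge[a, 2] <- p2$edge[w, 2]
      p2$edge[w, 2] <- tmp
      out[[length(out) + 1L]] <- p2
    }
  }
  out
}

#' Enumerate all unrooted binary topologies on a set of taxa
#'
#' Recursive stepwise addition without pruning; (2n-5)!! trees, so
#' intended for n at most 8 or so.
#'
#' @param labels character vector of taxon names (length >= 3).
#' @return list of `phylo` objects.
#' @export
enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  if (n > 9) stop("refusing to enumerate more than 9 taxa (", n, " given)")
  out <- list()
  rec <- function(el, nxt, iid) {
    if (nxt > n) {
      out[[length(out) + 1L]] <<- el
      return(invisible())
    }
    for (i in seq_along(el$parent)) {
      rec(el_insert_tip(el, nxt, i, iid), nxt + 1L, iid + 1L)
    }
  }
  rec(el_triplet(1:3, n, n + 1L), 4L, n + 2L)
  lapply(out, el_to_phylo, labels = labels)
}
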