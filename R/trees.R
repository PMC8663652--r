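## Tree topology utilities.
##
## Public trees are ape "phylo" objects without branch lengths (parsimony
## only).  Internally, search and scoring work on plain integer edge
## matrices: two columns (undirected endpoints), tips 1..n in a fixed taxon
## order, internal nodes numbered above n.  The C++ scorer consumes a
## postorder orientation of these edges.

## ---- internal edge-list machinery ------------------------------------

## adjacency list over 1..max(E)
edge_adj <- function(E) {
  mx <- max(E)
  adj <- rep(list(integer()), mx)
  for (i in seq_len(nrow(E))) {
    adj[[E[i, 1]]] <- c(adj[[E[i, 1]]], E[i, 2])
    adj[[E[i, 2]]] <- c(adj[[E[i, 2]]], E[i, 1])
  }
  adj
}

## postorder parent/child orientation of an undirected edge matrix,
## rooted at the lowest-numbered internal node
postorder_from_edges <- function(E, n) {
  adj <- edge_adj(E)
  root <- min(setdiff(unique(as.vector(E)), seq_len(n)))
  pe <- integer(nrow(E)); ce <- integer(nrow(E)); k <- 0L
  visit <- function(node, parent) {
    for (nb in adj[[node]]) {
      if (nb != parent) {
        visit(nb, node)
        k <<- k + 1L
        pe[k] <<- node; ce[k] <<- nb
      }
    }
  }
  visit(root, 0L)
  cbind(pe, ce, deparse.level = 0)
}

## build an ape phylo from an undirected edge matrix (tips 1..n)
phylo_from_edges <- function(E, tip_labels) {
  n <- length(tip_labels)
  adj <- edge_adj(E)
  internal <- setdiff(unique(as.vector(E)), seq_len(n))
  if (!length(internal)) stop("edge list has no internal node")
  root <- min(internal)
  newid <- integer(max(E)); newid[seq_len(n)] <- seq_len(n)
  cnt <- n
  pe <- integer(nrow(E)); ce <- integer(nrow(E)); k <- 0L
  visit <- function(node, parent) {
    if (node > n) { cnt <<- cnt + 1L; newid[node] <<- cnt }
    if (parent > 0L) {
      k <<- k + 1L
      pe[k] <<- newid[parent]; ce[k] <<- newid[node]
    }
    for (nb in adj[[node]]) if (nb != parent) visit(nb, node)
  }
  visit(root, 0L)
  phy <- structure(list(edge = cbind(pe, ce, deparse.level = 0),
                        tip.label = tip_labels,
                        Nnode = cnt - n),
                   class = "phylo", order = "cladewise")
  phy
}

## undirected edge matrix + tip labels from a phylo (drops root dichotomy
## bookkeeping; tips keep ape numbering 1..n)
edges_from_phylo <- function(phy) {
  E <- phy$edge
  storage.mode(E) <- "integer"
  E
}

## postorder edge encoding for the scorer: tips renumbered to positions in
## `taxa`; internal node ids left as is (always > ntip).
encode_postorder <- function(phy, taxa) {
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx))
    stop("tree tip '", phy$tip.label[which(is.na(idx))[1]],
         "' is not a matrix taxon")
  phy <- ape::reorder.phylo(phy, "postorder")
  e <- phy$edge
  n <- length(phy$tip.label)
  sel <- e[, 2] <= n
  e[sel, 2] <- idx[e[sel, 2]]
  storage.mode(e) <- "integer"
  e
}

## ---- bipartitions -----------------------------------------------------

## canonical split keys from a postorder edge matrix over tips 1..n.
## A key lists the tip indices of the block NOT containing tip 1,
## comma-joined; with include_trivial, pendant splits are included too.
split_keys_post <- function(po, n, include_trivial = FALSE) {
  mx <- max(po)
  memb <- vector("list", mx)
  for (i in seq_len(n)) memb[[i]] <- i
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    memb[[p]] <- c(memb[[p]], memb[[ch]])
  }
  keys <- character(0)
  all_tips <- seq_len(n)
  for (i in seq_len(nrow(po))) {
    ch <- po[i, 2]
    if (ch <= n && !include_trivial) next
    blk <- sort(memb[[ch]])
    if (length(blk) %in% c(0L, n)) next
    if (1L %in% blk) blk <- setdiff(all_tips, blk)
    if (length(blk) == 0L || length(blk) == n) next
    ## splits with a single taxon on either side are trivial; they arise
    ## from pendant edges and from the root edges of a rooted tree
    if (!include_trivial && (length(blk) < 2L || length(blk) > n - 2L)) next
    keys <- c(keys, paste(blk, collapse = ","))
  }
  unique(keys)
}

## split keys of a phylo, on the label level (canonical block = the one not
## containing the alphabetically first label)
split_keys_phylo <- function(phy, include_trivial = FALSE) {
  taxa <- sort(phy$tip.label)
  po <- encode_postorder(phy, taxa)
  keys <- split_keys_post(po, length(taxa), include_trivial)
  vapply(keys, function(k) {
    idx <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    paste(taxa[idx], collapse = ",")
  }, "", USE.NAMES = FALSE)
}

#' Bipartitions of a tree
#'
#' Removing an edge splits the leaf set in two; each non-trivial split is
#' returned in a canonical orientation (the block not containing the
#' alphabetically first taxon), so two trees are topologically equal iff
#' their bipartition sets are equal.
#'
#' @param tree a `phylo` object.
#' @param include_trivial also return pendant-edge (single-taxon) splits.
#' @return a list of character vectors, each one block of a split, sorted.
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  keys <- split_keys_phylo(tree, include_trivial)
  lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
}

#' Test topological equality of two trees
#'
#' Trees are equal iff they have the same leaf set and the same set of
#' bipartitions; child order and internal node numbering are irrelevant.
#'
#' @param t1,t2 `phylo` objects.
#' @return logical.
#' @export
tree_equal <- function(t1, t2) {
  setequal(t1$tip.label, t2$tip.label) &&
    setequal(split_keys_phylo(t1), split_keys_phylo(t2))
}

## canonical identity string (used for dedup and tie-breaking)
tree_key <- function(phy) paste(sort(split_keys_phylo(phy)), collapse = ";")

## ---- enumeration ------------------------------------------------------

## all unrooted binary topologies over tips 1..n, as raw edge matrices;
## internal nodes numbered n+1, n+2, ...
all_topology_edges <- function(n) {
  if (n < 3) stop("need at least 3 taxa to enumerate topologies")
  base <- list(cbind(c(n + 1L, n + 1L, n + 1L), 1:3))
  if (n == 3) return(base)
  for (k in 4:n) {
    out <- vector("list", length(base) * (2L * (k - 1L) - 3L))
    j <- 0L
    for (E in base) {
      x <- max(E) + 1L
      for (e in seq_len(nrow(E))) {
        E2 <- E
        v <- E[e, 2]
        E2[e, 2] <- x
        E2 <- rbind(E2, c(x, v), c(x, k))
        j <- j + 1L
        out[[j]] <- E2
      }
    }
    base <- out
  }
  base
}

#' Enumerate all unrooted binary topologies
#'
#' Yields every distinct unrooted binary tree on the given taxa exactly
#' once; there are (2n-5)!! of them, so this is only feasible for small n
#' (945 trees at n = 7, 2,027,025 at n = 10).
#'
#' @param taxa character vector of at least 3 taxon labels.
#' @return a list of `phylo` objects.
#' @export
enumerate_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa to enumerate topologies")
  lapply(all_topology_edges(n), phylo_from_edges, tip_labels = taxa)
}

## ---- rooting ----------------------------------------------------------

#' Root a tree on an outgroup taxon
#'
#' Places the root on the pendant edge of the outgroup, so the ingroup
#' (all remaining taxa) forms a clade.  Rooting is idempotent and does not
#' change the unrooted topology.
#'
#' @param tree a `phylo` object.
#' @param outgroup a tip label of `tree`.
#' @return a rooted `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("unknown taxon label: '", outgroup, "'")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

## ---- TBR --------------------------------------------------------------

## suppress a degree-2 node w in an edge matrix (after bisection)
suppress_node <- function(Ec, w) {
  idx <- which(Ec[, 1] == w | Ec[, 2] == w)
  if (length(idx) == 2) {
    a <- setdiff(Ec[idx[1], ], w)
    b <- setdiff(Ec[idx[2], ], w)
    Ec <- rbind(Ec[-idx, , drop = FALSE], c(a, b))
  }
  Ec
}

#' Tree-bisection-reconnection neighborhood
#'
#' Yields every distinct topology reachable from `tree` by one TBR move:
#' remove an edge, suppress the resulting degree-2 nodes, then reconnect
#' any edge (or lone tip) of one fragment to any edge (or lone tip) of the
#' other.  The input topology itself is excluded.  TBR generalizes NNI and
#' SPR, so its neighborhood contains theirs.
#'
#' @param tree an unrooted binary `phylo` with at least 4 tips.
#' @return a list of `phylo` objects.
#' @export
tbr_neighbors <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) stop("TBR needs at least 4 tips")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!ape::is.binary(tree)) stop("TBR requires a binary tree")
  E <- edges_from_phylo(tree)
  self_key <- tree_key(tree)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1]; v <- E[i, 2]
    Er <- E[-i, , drop = FALSE]
    ## component containing u
    adj <- edge_adj(rbind(Er, c(u, u)))  # guard: keep u in range
    compu <- logical(max(E))
    stack <- u
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (compu[x]) next
      compu[x] <- TRUE
      stack <- c(stack, adj[[x]])
    }
    in1 <- compu[Er[, 1]]
    E1 <- Er[in1, , drop = FALSE]
    E2 <- Er[!in1, , drop = FALSE]
    E1 <- suppress_node(E1, u)
    E2 <- suppress_node(E2, v)
    ## attachment points: each edge, or the lone tip if the fragment is one
    att1 <- if (nrow(E1) == 0) list(u) else
      lapply(seq_len(nrow(E1)), function(j) E1[j, ])
    att2 <- if (nrow(E2) == 0) list(v) else
      lapply(seq_len(nrow(E2)), function(j) E2[j, ])
    nxt <- max(E) + 1L
    for (a1 in att1) {
      for (a2 in att2) {
        F1 <- E1; F2 <- E2
        if (length(a1) == 1) p1 <- a1 else {
          p1 <- nxt
          j <- which((F1[, 1] == a1[1] & F1[, 2] == a1[2]) |
                     (F1[, 1] == a1[2] & F1[, 2] == a1[1]))[1]
          F1 <- rbind(F1[-j, , drop = FALSE], c(a1[1], p1), c(p1, a1[2]))
        }
        if (length(a2) == 1) p2 <- a2 else {
          p2 <- nxt + 1L
          j <- which((F2[, 1] == a2[1] & F2[, 2] == a2[2]) |
                     (F2[, 1] == a2[2] & F2[, 2] == a2[1]))[1]
          F2 <- rbind(F2[-j, , drop = FALSE], c(a2[1], p2), c(p2, a2[2]))
        }
        cand <- phylo_from_edges(rbind(F1, F2, c(p1, p2)), tree$tip.label)
        k <- tree_key(cand)
        if (k == self_key || !is.null(seen[[k]])) next
        seen[[k]] <- TRUE
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

## ---- consensus --------------------------------------------------------

#' Strict consensus of a set of trees
#'
#' Returns the tree whose bipartition set is the intersection of the
#' inputs' bipartition sets; conflicting resolutions collapse to
#' polytomies.
#'
#' @param trees a non-empty list of `phylo` objects on one leaf set.
#' @return a `phylo` object (possibly with polytomies).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, taxa))
      stop("all trees must share one leaf set")
  common <- Reduce(intersect, lapply(trees, split_keys_phylo))
  tree_from_splits(common, taxa)
}

## build a (possibly multifurcating) unrooted phylo from compatible splits;
## each split key is a comma-joined label block not containing taxa[1]
tree_from_splits <- function(keys, taxa) {
  n <- length(taxa)
  blocks <- lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  ## view rooted next to taxa[1]: every block is a clade
  blocks <- blocks[order(-lengths(blocks))]
  E <- matrix(0L, 0, 2)
  node_of <- function(i) n + 1L + i     # block i -> node id
  parent_node <- integer(length(blocks))
  ## parent of a block = its smallest proper container (basal node if none)
  for (i in seq_along(blocks)) {
    cont <- which(vapply(seq_along(blocks), function(j)
      j != i && all(blocks[[i]] %in% blocks[[j]]), TRUE))
    if (length(cont)) {
      sz <- lengths(blocks)[cont]
      parent_node[i] <- node_of(cont[which.min(sz)])
    } else parent_node[i] <- n + 1L
  }
  for (i in seq_along(blocks))
    E <- rbind(E, c(parent_node[i], node_of(i)))
  for (t in seq_len(n)) {
    cont <- which(vapply(blocks, function(b) taxa[t] %in% b, TRUE))
    p <- if (length(cont)) node_of(cont[which.min(lengths(blocks)[cont])])
         else n + 1L
    E <- rbind(E, c(p, t))
  }
  phylo_from_edges(E, taxa)
}

## ---- Newick I/O -------------------------------------------------------

#' Write trees as Newick
#'
#' @param trees a `phylo` or list of `phylo` objects; node labels (e.g.
#'   bootstrap supports) are preserved.
#' @param file optional output path; if `NULL`, the Newick strings are
#'   returned.
#' @return a character vector of Newick strings (invisibly when writing to
#'   a file).
#' @export
write_newick <- function(trees, file = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  s <- vapply(trees, ape::write.tree, "")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read Newick trees
#'
#' @param text Newick string(s), or `NULL` to read from `file`.
#' @param file optional path.
#' @return a single `phylo` if the input holds one tree, else a list.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file)
        else ape::read.tree(text = paste(text, collapse = "\n"))
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "phylo")) tr else unclass(tr)
}
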