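## Ancestral-state reconstruction and unambiguous change mapping.
##
## For one character on a rooted binary tree, the dynamic program below
## computes, for every node, the cost of its subtree under each state
## ("down" pass) and the cost of the rest of the tree under each state of
## its parent ("out" pass).  Together these give, exactly:
##   - the MPR state set of every node (states assigned in at least one
##     most-parsimonious reconstruction), and
##   - for every branch, the set of (parent state, child state) pairs
##     realized across all MPRs.
## A change is "unambiguous" on a branch when every MPR changes state there
## with the same from/to pair - the reading under which a derived state can
## be called a synapomorphy of the clade below the branch without
## qualification.  The outgroup's states are ordinary data (reversals
## toward the outgroup condition are allowed and do occur).

INF_COST <- 1e9

mode_cost <- function(nst, mode) {
  s <- 0:(nst - 1)
  switch(mode,
         unordered = matrix(1, nst, nst) - diag(nst),
         ordered = abs(outer(s, s, "-")),
         stop("change mapping supports unordered and ordered characters"))
}

## children lookup for a rooted phylo
children_of <- function(phy) {
  n <- length(phy$tip.label)
  kids <- rep(list(integer(0)), n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

## core DP; column aligned to phy$tip.label
mpr_engine <- function(phy, column, mode) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  root <- n + 1L
  obs <- column[!is.na(column)]
  nst <- max(obs) + 1L
  cost <- mode_cost(nst, mode)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  down <- matrix(0, nn, nst)
  for (i in seq_len(n)) {
    if (!is.na(column[i])) {
      down[i, ] <- INF_COST
      down[i, column[i] + 1L] <- 0
    }
  }
  ## C[v, t]: cost of v's subtree plus the edge into v, given parent state t
  C <- matrix(0, nn, nst)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; v <- po[i, 2]
    C[v, ] <- vapply(seq_len(nst), function(t)
      min(down[v, ] + cost[t, ]), 0)
    down[p, ] <- down[p, ] + C[v, ]
  }
  minlen <- min(down[root, ])
  ## The root subdivides the outgroup's pendant edge, so its state is often
  ## ambiguous between the outgroup and ingroup conditions.  It is fixed to
  ## the LOWEST cost-optimal state: in matrices coded with low states
  ## presumed plesiomorphic this reads the basal condition as plesiomorphic
  ## wherever the data allow, without ever changing the tree length.
  root_state <- min(which(down[root, ] <= minlen + 1e-6)) - 1L
  root_base <- rep(INF_COST, nst)
  root_base[root_state + 1L] <- 0
  ## out[v, s]: cost of everything outside v's subtree, including the edge
  ## into v, given v = s
  kids <- children_of(phy)
  out <- matrix(0, nn, nst)
  R <- matrix(0, nn, nst)   # R[v, t]: cost outside v given parent(v) = t
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  out[root, ] <- root_base
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1]; v <- pre[i, 2]
    base <- if (p == root) root_base else out[p, ]
    sibs <- setdiff(kids[[p]], v)
    Rv <- base
    for (w in sibs) Rv <- Rv + C[w, ]
    R[v, ] <- Rv
    out[v, ] <- vapply(seq_len(nst), function(s)
      min(Rv + cost[, s]), 0)
  }
  list(down = down, out = out, R = R, C = C, cost = cost, minlen = minlen,
       nst = nst, root = root, root_state = root_state, n = n, po = po,
       kids = kids)
}

#' MPR state sets of every node
#'
#' For one character on a rooted binary tree, returns for each node the set
#' of states it takes in at least one most-parsimonious reconstruction
#' (the union of all optimal assignments, covering both accelerated and
#' delayed transformation).  Missing tips carry the full state alphabet.
#' The root node, which subdivides the outgroup's pendant edge, is fixed to
#' the lowest cost-optimal state, reflecting the coding convention that low
#' states are presumed plesiomorphic; this never changes the tree length.
#'
#' @param tree a rooted binary `phylo` (see [root_on_outgroup()]).
#' @param column integer state vector (named by taxon or in tip order).
#' @param mode `"unordered"` or `"ordered"`.
#' @return a list, indexed by node number (tips `1..n`, then internal
#'   nodes), of sorted integer state sets.
#' @export
mpr_state_sets <- function(tree, column, mode = c("unordered", "ordered")) {
  mode <- match.arg(mode)
  col <- align_column(column, tree$tip.label)
  eng <- mpr_engine(tree, col, mode)
  nn <- eng$n + tree$Nnode
  lapply(seq_len(nn), function(v) {
    tot <- eng$down[v, ] + eng$out[v, ]
    sort(which(tot <= eng$minlen + 1e-6) - 1L)
  })
}

#' Unambiguous state changes on a tree
#'
#' Maps, branch by branch, every character-state transition that occurs in
#' all most-parsimonious reconstructions with the same from/to states.
#' Changes on pendant branches are autapomorphies and on internal branches
#' synapomorphies; characters whose observed steps exceed their minimum on
#' this tree (per-character ci < 1) are flagged as homoplasies instead,
#' whichever branch carries them.  The outgroup's states are ordinary data
#' (reversals toward the outgroup condition are allowed), but where the
#' basal state is ambiguous it resolves to the lowest optimal state (see
#' [mpr_state_sets()]), so a derived condition unique to the outgroup maps
#' to the outgroup's own branch rather than to the ingroup.
#'
#' @param tree a rooted binary `phylo` (root it with [root_on_outgroup()]).
#' @param m a [char_matrix()].
#' @param spec a [char_type_spec()]; irreversible characters are not
#'   supported by the mapping.
#' @return a data frame of class `change_table` with columns `character`
#'   (0-based index), `clade` (comma-joined sorted labels below the
#'   branch), `from`, `to`, `branch` (`"internal"`/`"pendant"`) and
#'   `classification` (`"synapomorphy"`, `"autapomorphy"` or
#'   `"homoplasy"`).
#' @export
unambiguous_changes <- function(tree, m, spec = NULL) {
  spec <- spec_for(m, spec)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree tips and matrix taxa differ")
  if (!ape::is.rooted(tree))
    stop("change mapping needs a rooted tree; see root_on_outgroup()")
  n <- length(tree$tip.label)
  root <- n + 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  below <- rep(list(character(0)), n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po)))
    below[[po[i, 1]]] <- c(below[[po[i, 1]]], below[[po[i, 2]]])
  col_of <- function(j) m$states[match(tree$tip.label, m$taxa), j]

  rows <- list()
  for (j in which(spec$active)) {
    col <- col_of(j)
    if (all(is.na(col))) next
    eng <- mpr_engine(tree, col, spec$mode[j])
    s_obs <- eng$minlen
    m_min <- min_steps(m$states[, j], spec$mode[j])
    homoplastic <- s_obs > m_min + 1e-6
    nst <- eng$nst
    for (i in seq_len(nrow(eng$po))) {
      v <- eng$po[i, 2]
      ## tot[a, b] = best tree length with parent(v) = a and v = b;
      ## eng$R[v, a] already covers everything outside v's subtree
      tot <- eng$R[v, ] + eng$cost +
        matrix(eng$down[v, ], nst, nst, byrow = TRUE)
      opt <- which(tot <= eng$minlen + 1e-6, arr.ind = TRUE)
      if (nrow(opt) == 1 && opt[1, 1] != opt[1, 2]) {
        rows[[length(rows) + 1L]] <- data.frame(
          character = j - 1L,
          clade = paste(sort(below[[v]]), collapse = ","),
          from = opt[1, 1] - 1L, to = opt[1, 2] - 1L,
          branch = if (v <= n) "pendant" else "internal",
          classification = if (homoplastic) "homoplasy"
                           else if (v <= n) "autapomorphy"
                           else "synapomorphy")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = integer(0), clade = character(0),
               from = integer(0), to = integer(0), branch = character(0),
               classification = character(0))
  out <- out[order(out$character, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("change_table", "data.frame")
  out
}

#' Changes shared by every most parsimonious tree
#'
#' Intersects the per-tree unambiguous change lists, keyed by the clade's
#' leaf set and the (character, from, to) triple, so a change counts as
#' shared when the same clade acquires the same state in every MPT even
#' though the trees differ elsewhere.
#'
#' @param trees non-empty list of trees on one leaf set (rooted, or rooted
#'   on `outgroup` when given).
#' @param m a [char_matrix()].
#' @param spec a [char_type_spec()].
#' @param outgroup optional taxon to root unrooted input trees.
#' @return a `change_table` (see [unambiguous_changes()]) restricted to
#'   records present for every tree.
#' @export
shared_changes_across_mpts <- function(trees, m, spec = NULL,
                                       outgroup = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  tabs <- lapply(trees, function(t) {
    if (!is.null(outgroup)) t <- root_on_outgroup(t, outgroup)
    unambiguous_changes(t, m, spec)
  })
  key <- function(tab) paste(tab$clade, tab$character, tab$from, tab$to,
                             sep = "|")
  common <- Reduce(intersect, lapply(tabs, key))
  out <- tabs[[1]][key(tabs[[1]]) %in% common, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("change_table", "data.frame")
  out
}

#' Write a change table as TSV
#'
#' @param x a `change_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_changes_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
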