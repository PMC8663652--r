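## Nonparametric bootstrap clade support.
##
## Each replicate resamples the characters with replacement, finds that
## replicate's most parsimonious trees (exactly, for small matrices; by a
## multi-start TBR hill climb otherwise), and counts a clade only when it
## appears in the replicate's strict consensus - i.e. only when the
## replicate supports it unambiguously.  Clades are expressed in the
## outgroup-rooted view: each bipartition is reported as the taxon block
## not containing the outgroup.

#' Bootstrap clade support
#'
#' @param m a [char_matrix()].
#' @param spec a [char_type_spec()]; default all-unordered, weight 1.
#' @param outgroup taxon used to orient splits as clades (and to root the
#'   scoring when irreversible characters are present).
#' @param replications number of bootstrap replicates.
#' @param searches_per_replicate random-addition starts per replicate
#'   (heuristic mode only).
#' @param max_trees cap on trees held per replicate (heuristic mode only).
#' @param seed integer seed; the whole run is reproducible from it.
#' @param search_mode `"exact"` scores all topologies per replicate,
#'   `"tbr"` runs the heuristic, `"auto"` picks exact when `n_taxa <=
#'   exact_cap`.
#' @param exact_cap largest taxon count for which `"auto"` uses exact
#'   per-replicate searches.
#' @param count_any_mpt count a clade when it occurs in *any* replicate MPT
#'   instead of requiring it in the replicate's strict consensus (a more
#'   liberal convention, off by default).
#' @return an object of class `clade_support`: a data frame with columns
#'   `clade` (comma-joined sorted taxon labels), `size`, `count` and
#'   `support` (percent, full precision), ordered by decreasing support.
#'   The ingroup clade (everything but the outgroup) is present in every
#'   binary rooted tree by construction and is reported at 100%; the
#'   trivial all-taxa clade and single-taxon clades are omitted.
#' @export
bootstrap_support <- function(m, spec = NULL, outgroup,
                              replications = 500,
                              searches_per_replicate = 10,
                              max_trees = 100,
                              seed = 0,
                              search_mode = c("auto", "exact", "tbr"),
                              exact_cap = 9,
                              count_any_mpt = FALSE) {
  spec <- spec_for(m, spec)
  search_mode <- match.arg(search_mode)
  if (!outgroup %in% m$taxa) stop("outgroup '", outgroup, "' not in matrix")
  stopifnot(replications >= 1)
  exact <- switch(search_mode, exact = TRUE, tbr = FALSE,
                  auto = m$n_taxa <= exact_cap)
  n <- m$n_taxa
  counts <- new.env(parent = emptyenv())
  tally <- function(keys) for (k in keys)
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L

  rooted <- needs_rooting(spec)
  og_idx <- match(outgroup, m$taxa)

  if (exact) {
    edge_list <- all_topology_edges(n)
    enc <- if (rooted) {
      lapply(edge_list, function(E) {
        phy <- phylo_from_edges(E, m$taxa)
        encode_postorder(root_on_outgroup(phy, outgroup), m$taxa)
      })
    } else lapply(edge_list, postorder_from_edges, n = n)
    topo_keys <- lapply(edge_list, function(E)
      split_keys_post(postorder_from_edges(E, n), n))
  }

  with_seed(seed, {
    for (r in seq_len(replications)) {
      cols <- sample.int(m$n_chars, m$n_chars, replace = TRUE)
      states_r <- m$states[, cols, drop = FALSE]
      modes_r <- spec$mode[cols]
      w_r <- ifelse(spec$active[cols], spec$weight[cols], 0)
      if (exact) {
        lens <- as.numeric(score_encoded(enc, n, states_r, modes_r, w_r))
        idx <- which(lens == min(lens))
        keysets <- topo_keys[idx]
      } else {
        m_r <- char_matrix(states_r, m$taxa)
        spec_r <- char_type_spec(ncol(states_r), mode = modes_r,
                                 weight = pmax(1L, as.integer(w_r)),
                                 active = spec$active[cols])
        pool <- list(); pool_keys <- character(0); best <- Inf
        for (s in seq_len(searches_per_replicate)) {
          start <- stepwise_addition_tree(m_r, spec_r, sample.int(n),
                                          outgroup)
          hc <- tbr_hill_climb(start, m_r, spec_r, max_trees, outgroup)
          if (hc$length < best) {
            best <- hc$length; pool <- list(); pool_keys <- character(0)
          }
          if (hc$length == best) for (t in hc$trees) {
            k <- tree_key(t)
            if (!k %in% pool_keys && length(pool) < max_trees) {
              pool_keys <- c(pool_keys, k)
              pool[[length(pool) + 1L]] <- t
            }
          }
        }
        keysets <- lapply(pool, function(t)
          split_keys_post(encode_postorder(t, m$taxa), n))
      }
      common <- if (count_any_mpt) unique(unlist(keysets))
                else Reduce(intersect, keysets)
      tally(common)
    }
  })

  keys <- ls(counts)
  to_clade <- function(k) {
    idx <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    if (og_idx %in% idx) idx <- setdiff(seq_len(n), idx)
    sort(m$taxa[idx])
  }
  clades <- lapply(keys, to_clade)
  cnt <- vapply(keys, function(k) counts[[k]], 0L)
  ## ingroup clade: the outgroup's pendant split, present in every rooted
  ## binary tree, hence 100% by construction
  clades <- c(clades, list(sort(setdiff(m$taxa, outgroup))))
  cnt <- c(cnt, replications)
  keep <- lengths(clades) > 1 & lengths(clades) < n
  tab <- data.frame(clade = vapply(clades[keep], paste, "", collapse = ","),
                    size = lengths(clades[keep]),
                    count = cnt[keep],
                    support = 100 * cnt[keep] / replications)
  tab <- tab[order(-tab$support, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("clade_support", "data.frame"),
            replications = replications, seed = seed, outgroup = outgroup,
            settings = list(search_mode = if (exact) "exact" else "tbr",
                            searches_per_replicate = searches_per_replicate,
                            max_trees = max_trees,
                            count_any_mpt = count_any_mpt))
}

#' @export
print.clade_support <- function(x, ...) {
  cat("Bootstrap clade support: ", attr(x, "replications"),
      " replicates, seed ", attr(x, "seed"),
      ", outgroup ", attr(x, "outgroup"), "\n", sep = "")
  y <- as.data.frame(x)
  y$support <- round(y$support)
  print(y, ...)
  invisible(x)
}

#' Look up the support of one clade
#'
#' @param table a `clade_support` object.
#' @param taxa the clade's taxon labels.
#' @return support in percent (0 if the clade never occurred).
#' @export
support_for <- function(table, taxa) {
  key <- paste(sort(taxa), collapse = ",")
  hit <- match(key, table$clade)
  if (is.na(hit)) 0 else table$support[hit]
}

#' Annotate a tree with bootstrap supports
#'
#' Sets the node labels of the outgroup-rooted view of `tree` to the
#' (rounded) bootstrap percentage of each internal clade.
#'
#' @param tree a `phylo` on the support table's taxa.
#' @param table a `clade_support` object.
#' @return a rooted `phylo` with node labels.
#' @export
annotate_support <- function(tree, table) {
  outgroup <- attr(table, "outgroup")
  phy <- root_on_outgroup(tree, outgroup)
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  below <- rep(list(character(0)), n + phy$Nnode)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  for (i in seq_len(nrow(po)))
    below[[po[i, 1]]] <- c(below[[po[i, 1]]], below[[po[i, 2]]])
  lab <- vapply((n + 1):(n + phy$Nnode), function(node) {
    cl <- below[[node]]
    if (length(cl) %in% c(1L, n)) return("")
    as.character(round(support_for(table, cl)))
  }, "")
  phy$node.label <- lab
  phy
}
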