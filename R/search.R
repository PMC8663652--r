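## Tree search under the parsimony criterion.
##
## Exact methods (exhaustive scoring of every topology, and stepwise
## branch-and-bound) return the complete set of minimum-length binary
## topologies.  The parsimony ratchet is a seedable heuristic for matrices
## too large for exact search: it alternates TBR hill climbing on the
## original matrix and on a perturbed matrix in which a random character
## subset is upweighted, accumulating distinct optimal trees across
## iterations.

## evaluate RNG-dependent code under a local, restorable seed
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

new_search_result <- function(best_length, trees, method, evaluations,
                              seed = NA, settings = list()) {
  ## canonical order for reproducible output
  keys <- vapply(trees, tree_key, "")
  trees <- trees[order(keys)]
  structure(list(best_length = best_length, trees = trees, method = method,
                 evaluations = evaluations, seed = seed,
                 settings = settings),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Parsimony search (", x$method, "): best length ", x$best_length,
      ", ", length(x$trees), " tree(s), ", x$evaluations,
      " evaluations\n", sep = "")
  invisible(x)
}

## rooted scoring encodings when irreversible characters are present
needs_rooting <- function(spec) any(spec$mode == "irreversible" & spec$active)

score_topologies <- function(edge_list, m, spec, outgroup = NULL) {
  if (needs_rooting(spec)) {
    if (is.null(outgroup))
      stop("irreversible characters require an outgroup for rooted scoring")
    enc <- lapply(edge_list, function(E) {
      phy <- phylo_from_edges(E, m$taxa)
      encode_postorder(root_on_outgroup(phy, outgroup), m$taxa)
    })
  } else {
    enc <- lapply(edge_list, postorder_from_edges, n = m$n_taxa)
  }
  active <- spec$active
  w <- ifelse(active, spec$weight, 0L)
  as.numeric(score_encoded(enc, m$n_taxa, m$states, spec$mode, w))
}

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology and returns the complete set of
#' minimum-length trees.  Feasible only for small matrices; the default cap
#' of 9 taxa corresponds to 135,135 topologies.
#'
#' @param m a [char_matrix()].
#' @param spec a [char_type_spec()] (default: all unordered, weight 1).
#' @param outgroup required only when `spec` contains irreversible
#'   characters (their length depends on the rooting).
#' @param cap refuse matrices with more taxa than this.
#' @return a `search_result`: best length, complete list of most
#'   parsimonious trees (`phylo`), method tag and evaluation count.
#' @export
exhaustive_search <- function(m, spec = NULL, outgroup = NULL, cap = 9) {
  spec <- spec_for(m, spec)
  if (m$n_taxa > cap)
    stop("exhaustive search capped at ", cap, " taxa (",
         m$n_taxa, " supplied); use branch_and_bound_search() or ",
         "ratchet_search()")
  if (m$n_taxa < 3) stop("need at least 3 taxa")
  edge_list <- all_topology_edges(m$n_taxa)
  lens <- score_topologies(edge_list, m, spec, outgroup)
  best <- min(lens)
  mpts <- lapply(edge_list[lens == best], phylo_from_edges,
                 tip_labels = m$taxa)
  new_search_result(best, mpts, "exhaustive", length(edge_list))
}

#' Branch-and-bound parsimony search
#'
#' Exact search by stepwise taxon addition: taxa are added in input order
#' to every edge of every partial topology, and a partial tree is pruned
#' when a lower bound on its completions (its own length, raised per
#' character to the minimum conceivable steps on the full taxon set)
#' exceeds the best complete length found so far.  Returns the same
#' complete tie set as [exhaustive_search()].
#'
#' @inheritParams exhaustive_search
#' @return a `search_result`.
#' @export
branch_and_bound_search <- function(m, spec = NULL, outgroup = NULL) {
  spec <- spec_for(m, spec)
  n <- m$n_taxa
  if (n < 4) return(exhaustive_search(m, spec, outgroup, cap = 9))
  rooted <- needs_rooting(spec)
  if (rooted && is.null(outgroup))
    stop("irreversible characters require an outgroup for rooted scoring")
  w <- ifelse(spec$active, spec$weight, 0)
  m_full <- vapply(seq_len(m$n_chars), function(j)
    as.numeric(min_steps(m$states[, j], spec$mode[j])), 0)
  floor_len <- sum(w * m_full)

  best <- Inf
  best_edges <- list()
  eval_count <- 0L

  ## partial-tree bound scoring: irreversible characters are bounded from
  ## below by their ordered (Wagner) length, which is rooting-invariant and
  ## never exceeds the increase-only length of any completion
  bound_modes <- ifelse(spec$mode == "irreversible", "ordered", spec$mode)
  per_char_len <- function(E, k) {
    po <- postorder_from_edges(E, k)
    score_encoded(list(po), k, m$states[seq_len(k), , drop = FALSE],
                  bound_modes, rep(1, m$n_chars), per_char = TRUE)[1, ]
  }

  grow <- function(E, k) {
    per <- per_char_len(E, k)
    eval_count <<- eval_count + 1L
    bound <- sum(w * pmax(per, m_full))
    if (bound > best) return()
    if (k == n) {
      len <- if (rooted) score_topologies(list(E), m, spec, outgroup)
             else sum(w * per)
      if (len < best) { best <<- len; best_edges <<- list(E) }
      else if (len == best) best_edges[[length(best_edges) + 1L]] <<- E
      return()
    }
    x <- max(E) + 1L
    for (e in seq_len(nrow(E))) {
      E2 <- E
      v <- E[e, 2]
      E2[e, 2] <- x
      E2 <- rbind(E2, c(x, v), c(x, k + 1L))
      grow(E2, k + 1L)
    }
  }
  grow(cbind(rep(n + 1L, 3), 1:3), 3L)
  mpts <- lapply(best_edges, phylo_from_edges, tip_labels = m$taxa)
  new_search_result(best, mpts, "branch_and_bound", eval_count)
}

## greedy stepwise-addition tree for a given taxon addition order
stepwise_addition_tree <- function(m, spec, order_idx, outgroup = NULL) {
  n <- m$n_taxa
  ## build over renamed tip ids = original taxa indices
  E <- cbind(rep(2L * n, 3), order_idx[1:3])
  nxt <- 2L * n + 1L
  if (n >= 4) for (k in 4:n) {
    cand <- vector("list", nrow(E))
    for (e in seq_len(nrow(E))) {
      E2 <- E
      v <- E[e, 2]
      E2[e, 2] <- nxt
      E2 <- rbind(E2, c(nxt, v), c(nxt, order_idx[k]))
      cand[[e]] <- E2
    }
    ## score partial trees on the full state matrix restricted to placed taxa
    placed <- sort(order_idx[1:k])
    remap <- integer(n); remap[placed] <- seq_len(k)
    enc <- lapply(cand, function(Ec) {
      Ec2 <- Ec
      tipsel <- Ec2 <= n
      Ec2[tipsel] <- remap[Ec2[tipsel]]
      Ec2[!tipsel] <- Ec2[!tipsel] - n + k  # keep internals above k
      postorder_from_edges(Ec2, k)
    })
    w <- ifelse(spec$active, spec$weight, 0)
    lens <- as.numeric(score_encoded(enc, k,
                                     m$states[placed, , drop = FALSE],
                                     spec$mode, w))
    E <- cand[[which.min(lens)]]
    nxt <- nxt + 1L
  }
  phylo_from_edges(E, tip_labels = m$taxa[seq_len(n)])
}

## hill climb by TBR from one tree; returns list(trees, length)
## holding up to `hold` tied trees at the current best
tbr_hill_climb <- function(tree, m, spec, hold, outgroup = NULL) {
  score1 <- function(phy) {
    if (needs_rooting(spec))
      score_topologies(list(edges_from_phylo(ape::unroot(phy))), m, spec,
                       outgroup)
    else {
      po <- encode_postorder(phy, m$taxa)
      w <- ifelse(spec$active, spec$weight, 0)
      as.numeric(score_encoded(list(po), m$n_taxa, m$states, spec$mode, w))
    }
  }
  pool <- list(tree)
  best <- score1(tree)
  repeat {
    nb <- list()
    seen <- new.env(parent = emptyenv())
    for (t in pool) for (x in tbr_neighbors(t)) {
      k <- tree_key(x)
      if (is.null(seen[[k]])) { seen[[k]] <- TRUE; nb[[length(nb) + 1L]] <- x }
    }
    if (!length(nb)) break
    lens <- vapply(nb, score1, 0)
    if (min(lens) < best) {
      best <- min(lens)
      tied <- nb[lens == best]
      tied <- tied[order(vapply(tied, tree_key, ""))]
      pool <- tied[seq_len(min(hold, length(tied)))]
    } else {
      tied <- c(pool, nb[lens == best])
      keys <- vapply(tied, tree_key, "")
      tied <- tied[!duplicated(keys)]
      tied <- tied[order(vapply(tied, tree_key, ""))]
      pool <- tied[seq_len(min(hold, length(tied)))]
      break
    }
  }
  list(trees = pool, length = best)
}

#' Parsimony ratchet search
#'
#' A seeded heuristic in the spirit of Nixon's ratchet: each iteration
#' (i) upweights a random sample of characters by one, (ii) TBR
#' hill-climbs under the perturbed weights, (iii) hill-climbs the result
#' again under the original weights, and (iv) pools any new minimum-length
#' trees.  The starting tree is the best of `random_constraint_level`
#' greedy stepwise-addition trees built with random taxon addition orders.
#' With `iterations = 0` the starting tree alone is returned.
#'
#' Results never beat the exact optimum; on small matrices they are checked
#' against [exhaustive_search()] in the package tests.
#'
#' @inheritParams exhaustive_search
#' @param iterations number of ratchet iterations.
#' @param trees_to_hold maximum trees held per hill climb.
#' @param characters_to_sample characters upweighted per iteration.
#' @param random_constraint_level number of random-addition starting trees.
#' @param seed integer seed; identical inputs and seed give identical
#'   results.
#' @return a `search_result` (accumulated distinct best trees).
#' @export
ratchet_search <- function(m, spec = NULL, iterations = 1000,
                           trees_to_hold = 5, characters_to_sample = 10,
                           random_constraint_level = 10, seed = 0,
                           outgroup = NULL) {
  spec <- spec_for(m, spec)
  stopifnot(iterations >= 0, trees_to_hold >= 1,
            characters_to_sample >= 1,
            characters_to_sample <= m$n_chars)
  with_seed(seed, {
    n <- m$n_taxa
    starts <- lapply(seq_len(max(1, random_constraint_level)), function(i) {
      ord <- if (i == 1) seq_len(n) else sample.int(n)
      stepwise_addition_tree(m, spec, ord, outgroup)
    })
    slen <- vapply(starts, function(t) tree_length(t, m, spec)$total, 0)
    current <- starts[[which.min(slen)]]
    eval_count <- length(starts)
    if (iterations == 0)
      return(new_search_result(min(slen), list(current), "ratchet",
                               eval_count, seed,
                               list(iterations = iterations)))
    best_len <- Inf
    best_pool <- list()
    keys <- character(0)
    take <- function(trees, len) {
      if (len < best_len) {
        best_len <<- len; best_pool <<- list(); keys <<- character(0)
      }
      if (len == best_len) for (t in trees) {
        k <- tree_key(t)
        if (!k %in% keys) {
          keys <<- c(keys, k)
          best_pool[[length(best_pool) + 1L]] <<- t
        }
      }
    }
    base_w <- spec$weight
    for (it in seq_len(iterations)) {
      pert <- spec
      idx <- sample(which(spec$active), characters_to_sample)
      pert$weight[idx] <- pert$weight[idx] + 1L
      r1 <- tbr_hill_climb(current, m, pert, trees_to_hold, outgroup)
      r2 <- tbr_hill_climb(r1$trees[[1]], m, spec, trees_to_hold, outgroup)
      eval_count <- eval_count + 1L
      take(r2$trees, r2$length)
      current <- best_pool[[1L + (it %% length(best_pool))]]
    }
    new_search_result(best_len, best_pool, "ratchet", eval_count, seed,
                      list(iterations = iterations,
                           trees_to_hold = trees_to_hold,
                           characters_to_sample = characters_to_sample,
                           random_constraint_level = random_constraint_level))
  })
}
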