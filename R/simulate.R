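## Synthetic character matrices with known generating trees.
##
## Characters evolve independently on a random topology.  The rate is
## parameterized as the expected number of change events per character on
## the whole tree (a Poisson draw), because parsimony behavior is governed
## by the total change count rather than by per-branch rates.  Two models:
##   mk_unordered     - an event replaces the current state by a uniformly
##                      chosen different state
##   irreversible_gain - an event increments the state by one (0 -> 1 -> 2);
##                      events at the top state are lost, so states are
##                      non-decreasing along every root-to-tip path
## After simulation a configured fraction of entries is masked to missing;
## if masking ever blanks out a whole character, one random entry of that
## character is restored so the matrix stays valid.

#' Simulation settings
#'
#' @param n_taxa number of taxa (>= 3).
#' @param n_chars number of characters.
#' @param n_states states per character (2 or 3).
#' @param model `"mk_unordered"` or `"irreversible_gain"`.
#' @param rate expected number of change events per character on the whole
#'   tree (> 0).
#' @param missing_fraction fraction of entries masked to `"?"`, in
#'   \[0, 0.5\].
#' @param seed integer seed; a fixed seed fixes the output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_taxa, n_chars, n_states = 2,
                              model = c("mk_unordered", "irreversible_gain"),
                              rate = 1, missing_fraction = 0, seed = 0) {
  model <- match.arg(model)
  stopifnot(n_taxa >= 3, n_chars >= 1, n_states %in% c(2, 3), rate > 0,
            missing_fraction >= 0, missing_fraction <= 0.5)
  structure(list(n_taxa = n_taxa, n_chars = n_chars, n_states = n_states,
                 model = model, rate = rate,
                 missing_fraction = missing_fraction, seed = seed),
            class = "simulation_config")
}

#' Simulate a random unrooted binary topology
#'
#' Sequential attachment: starting from the three-taxon tree, each further
#' taxon is attached to an edge chosen uniformly at random.  This yields
#' the uniform distribution over the (2n-5)!! unrooted binary topologies.
#'
#' @param n_taxa number of taxa (>= 3); tips are labelled `t1..tn`.
#' @param seed optional integer seed.
#' @return an unrooted binary `phylo`.
#' @export
simulate_topology <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 3)
  with_seed(seed, {
    n <- n_taxa
    E <- cbind(rep(n + 1L, 3), 1:3)
    nxt <- n + 2L
    if (n >= 4) for (k in 4:n) {
      e <- sample.int(nrow(E), 1)
      x <- nxt
      v <- E[e, 2]
      E[e, 2] <- x
      E <- rbind(E, c(x, v), c(x, k))
      nxt <- nxt + 1L
    }
    phylo_from_edges(E, paste0("t", seq_len(n)))
  })
}

#' Simulate characters on a tree
#'
#' @param tree a binary `phylo` (the generating topology); evolution runs
#'   from the basal node outward, starting every character in state 0.
#' @param config a [simulation_config()]; its `seed` drives all randomness.
#' @param drop_constant drop characters that end up constant (the matrix
#'   then has fewer than `n_chars` columns).
#' @return a [char_matrix()]; the unmasked generative states are attached
#'   as the integer matrix attribute `"generating_states"`.
#' @export
simulate_characters <- function(tree, config, drop_constant = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(tree$tip.label)
  phy <- ape::reorder.phylo(if (ape::is.rooted(tree)) tree else tree,
                            "postorder")
  pre <- phy$edge[rev(seq_len(nrow(phy$edge))), , drop = FALSE]
  nn <- n + phy$Nnode
  root <- pre[1, 1]
  nE <- nrow(pre)
  with_seed(config$seed, {
    full <- matrix(0L, n, config$n_chars)
    for (j in seq_len(config$n_chars)) {
      k <- stats::rpois(1, config$rate)
      hits <- tabulate(sample.int(nE, k, replace = TRUE), nbins = nE)
      st <- integer(nn)
      st[root] <- 0L
      for (i in seq_len(nE)) {
        p <- pre[i, 1]; v <- pre[i, 2]
        s <- st[p]
        if (hits[i] > 0) for (h in seq_len(hits[i])) {
          if (config$model == "mk_unordered") {
            others <- setdiff(0:(config$n_states - 1L), s)
            s <- if (length(others) == 1) others else sample(others, 1)
          } else {
            if (s < config$n_states - 1L) s <- s + 1L
          }
        }
        st[v] <- s
      }
      full[, j] <- st[seq_len(n)]
    }
    states <- full
    n_mask <- round(config$missing_fraction * length(states))
    if (n_mask > 0) {
      idx <- sample.int(length(states), n_mask)
      states[idx] <- NA_integer_
      blank <- which(colSums(!is.na(states)) == 0L)
      for (j in blank) {
        i <- sample.int(n, 1)
        states[i, j] <- full[i, j]
      }
    }
    if (drop_constant) {
      keep <- apply(states, 2, function(col)
        length(unique(col[!is.na(col)])) > 1)
      states <- states[, keep, drop = FALSE]
      full <- full[, keep, drop = FALSE]
    }
    m <- char_matrix(states, taxa = tree$tip.label)
    attr(m, "generating_states") <- full
    m
  })
}

#' Simulate a full dataset (tree plus matrix)
#'
#' @param config a [simulation_config()]; the topology uses `seed` and the
#'   characters `seed + 1`.
#' @return a list with `tree`, `matrix`, a default all-unordered `spec`,
#'   and the `config`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_topology(config$n_taxa, seed = config$seed)
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  m <- simulate_characters(tree, cfg2)
  list(tree = tree, matrix = m, spec = char_type_spec(m$n_chars),
       config = config)
}
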