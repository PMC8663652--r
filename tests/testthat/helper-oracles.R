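# Brute-force oracles: exhaustive enumeration over ancestral-state
# assignments.  Deliberately naive and independent of the package's dynamic
# programs; only usable for small trees and state counts.

oracle_cost <- function(nst, mode) {
  s <- 0:(nst - 1)
  switch(mode,
         unordered = matrix(1, nst, nst) - diag(nst),
         ordered = abs(outer(s, s, "-")),
         irreversible = ifelse(outer(s, s, "<="), outer(s, s, function(a, b) b - a), Inf))
}

# minimum steps by enumerating every assignment of internal-node states;
# missing tips contribute no cost (their state can always copy the parent).
# root_policy "free" minimizes over root states; "fixed" uses root_state.
oracle_length <- function(phy, column, mode = "unordered",
                          root_policy = "free", root_state = NULL) {
  n <- length(phy$tip.label)
  stopifnot(length(column) == n)
  nst <- max(column, na.rm = TRUE) + 1L
  cost <- oracle_cost(nst, mode)
  E <- phy$edge
  internals <- sort(unique(E[E > n]))
  grids <- rep(list(0:(nst - 1)), length(internals))
  best <- Inf
  assign_all <- as.matrix(expand.grid(grids))
  root <- internals[1]
  for (r in seq_len(nrow(assign_all))) {
    st <- integer(n + length(internals))
    st[seq_len(n)] <- ifelse(is.na(column), -1L, column)
    st[internals] <- assign_all[r, ]
    if (root_policy == "fixed" && st[root] != root_state) next
    tot <- 0
    for (i in seq_len(nrow(E))) {
      a <- st[E[i, 1]]; b <- st[E[i, 2]]
      if (b < 0) next                      # missing tip: free
      tot <- tot + cost[a + 1, b + 1]
      if (!is.finite(tot)) break
    }
    if (tot < best) best <- tot
  }
  best
}

# union of states over all optimal assignments, per node; mirrors the
# package convention that the root resolves to its lowest optimal state
oracle_mpr_sets <- function(phy, column, mode = "unordered") {
  n <- length(phy$tip.label)
  nst <- max(column, na.rm = TRUE) + 1L
  cost <- oracle_cost(nst, mode)
  E <- phy$edge
  internals <- sort(unique(E[E > n]))
  root <- n + 1L
  assign_all <- as.matrix(expand.grid(rep(list(0:(nst - 1)),
                                          length(internals))))
  score_one <- function(st) {
    tot <- 0
    for (i in seq_len(nrow(E))) {
      a <- st[E[i, 1]]; b <- st[E[i, 2]]
      if (b < 0) next
      tot <- tot + cost[a + 1, b + 1]
    }
    tot
  }
  lens <- apply(assign_all, 1, function(as) {
    st <- integer(n + length(internals))
    st[seq_len(n)] <- ifelse(is.na(column), -1L, column)
    st[internals] <- as
    score_one(st)
  })
  minlen <- min(lens)
  opt <- assign_all[lens <= minlen + 1e-9, , drop = FALSE]
  root_col <- match(root, internals)
  s0 <- min(opt[, root_col])
  opt <- opt[opt[, root_col] == s0, , drop = FALSE]
  sets <- vector("list", n + length(internals))
  for (i in seq_len(n))
    sets[[i]] <- if (is.na(column[i])) NA else column[i]
  for (k in seq_along(internals))
    sets[[internals[k]]] <- sort(unique(opt[, k]))
  list(sets = sets, minlen = minlen, opt = opt, internals = internals,
       root_state = s0)
}

# small random matrix for round-trip and property tests
random_matrix <- function(n_taxa, n_chars, nst = 2, missing_p = 0.1) {
  states <- matrix(sample(0:(nst - 1), n_taxa * n_chars, replace = TRUE),
                   n_taxa, n_chars)
  states[stats::runif(length(states)) < missing_p] <- NA_integer_
  blank <- which(colSums(!is.na(states)) == 0L)
  for (j in blank) states[sample.int(n_taxa, 1), j] <- 0L
  char_matrix(states, taxa = paste0("t", seq_len(n_taxa)))
}

# study clade label sets, used across test files
study_clades <- function() {
  trio <- c("Bicorniphontodes_lacuna", "Bicorniphontodes_comptus",
            "Bicorniphontodes_huysi")
  list(
    outgroup = "Laophontodes_typicus",
    ingroup = sort(c("Bicorniphontodes_bicornis", "Bicorniphontodes_clarae",
                     "Bicorniphontodes_horstgeorgei", trio)),
    trio = sort(trio),
    four = sort(c(trio, "Bicorniphontodes_horstgeorgei")),
    pair = sort(c("Bicorniphontodes_lacuna", "Bicorniphontodes_comptus")))
}

clade_key <- function(taxa) paste(sort(taxa), collapse = ",")
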