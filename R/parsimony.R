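## Parsimony scoring and homoplasy indices.
##
## Three optimization modes are supported per character:
##   unordered    - Fitch: any state-to-state change costs one step
##   ordered      - Wagner/additive: a change of k units on the linear
##                  state scale costs k steps
##   irreversible - states may only increase along the scale; the root
##                  state is fixed (by default to the smallest observed
##                  state).  Lengths under this mode depend on the rooting,
##                  so score a tree rooted on the outgroup.
## Missing ("?") tips are free: they contribute the whole state alphabet in
## Fitch and an unconstrained state in the Wagner/irreversible dynamic
## program, at no cost.

MODE_CODE <- c(unordered = 0L, ordered = 1L, irreversible = 2L)

## shared entry to the C++ kernel
score_encoded <- function(encodings, ntip, states, modes, weights,
                          root_states = NULL, per_char = FALSE) {
  if (is.null(root_states)) {
    root_states <- apply(states, 2, function(col) {
      v <- col[!is.na(col)]
      if (length(v)) min(v) else 0L
    })
  }
  score_trees_cpp(encodings, ntip, states, MODE_CODE[modes],
                  as.numeric(weights), as.integer(root_states), per_char)
}

## align a column (possibly named) to a taxon order
align_column <- function(column, taxa) {
  if (!is.null(names(column))) {
    if (!setequal(names(column), taxa))
      stop("column names do not match the tree's taxa")
    column <- column[taxa]
  } else if (length(column) != length(taxa)) {
    stop("column length must equal the number of tips")
  }
  as.integer(column)
}

#' Parsimony length of one character on a tree
#'
#' @param tree a `phylo` object; for `mode = "irreversible"` it should be
#'   rooted (see [root_on_outgroup()]), since increase-only costs are not
#'   rooting-invariant.
#' @param column integer state vector (0-9, `NA` = missing), named by taxon
#'   or ordered as `tree$tip.label`.
#' @param mode optimization mode.
#' @param root_state for `"irreversible"`, the fixed root state; default is
#'   the smallest observed state.  `Inf` is returned when no assignment is
#'   feasible (e.g. a tip state below the fixed root state).
#' @return number of steps (possibly `Inf` for infeasible irreversible
#'   columns).
#' @export
character_length <- function(tree, column,
                             mode = c("unordered", "ordered", "irreversible"),
                             root_state = NULL) {
  mode <- match.arg(mode)
  taxa <- tree$tip.label
  col <- align_column(column, taxa)
  if (all(is.na(col))) stop("column has no observed states")
  states <- matrix(col, ncol = 1)
  rs <- if (is.null(root_state)) min(col, na.rm = TRUE) else as.integer(root_state)
  po <- encode_postorder(tree, taxa)
  as.numeric(score_encoded(list(po), length(taxa), states, mode, 1,
                           root_states = rs))
}

#' Parsimony length of a whole matrix on a tree
#'
#' The total is the weighted sum of per-character lengths over active
#' characters.  For unordered and ordered characters the result does not
#' depend on taxon input order or rooting.
#'
#' @param tree a `phylo` whose tips are exactly the matrix taxa.
#' @param m a [char_matrix()].
#' @param spec a [char_type_spec()]; defaults to all characters unordered,
#'   weight 1, active.
#' @return a list with `total` (weighted steps) and `per_character`
#'   (unweighted steps for every character, including inactive ones).
#' @export
tree_length <- function(tree, m, spec = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  spec <- spec_for(m, spec)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree tips and matrix taxa differ")
  po <- encode_postorder(tree, m$taxa)
  per <- score_encoded(list(po), m$n_taxa, m$states, spec$mode, spec$weight,
                       per_char = TRUE)[1, ]
  total <- sum(per[spec$active] * spec$weight[spec$active])
  list(total = total, per_character = per)
}

#' Minimum conceivable steps of a character
#'
#' The smallest number of steps the character can require on any tree:
#' (number of distinct observed states - 1) for unordered characters, the
#' observed state range for ordered and irreversible ones.
#'
#' @param column integer state vector with `NA` for missing.
#' @param mode optimization mode.
#' @return integer.
#' @export
min_steps <- function(column,
                      mode = c("unordered", "ordered", "irreversible")) {
  mode <- match.arg(mode)
  v <- column[!is.na(column)]
  if (!length(v)) stop("column has no observed states")
  if (mode == "unordered") length(unique(v)) - 1L
  else diff(range(v))
}

#' Maximum conceivable steps of a character
#'
#' The length of the character on the completely unresolved (star) tree:
#' the number of observed entries minus the count of the most frequent
#' state for unordered characters; for ordered characters the star center
#' is the cost-minimizing state (a median); for irreversible characters the
#' center is the fixed root state (smallest observed).
#'
#' @inheritParams min_steps
#' @return integer.
#' @export
max_steps <- function(column,
                      mode = c("unordered", "ordered", "irreversible")) {
  mode <- match.arg(mode)
  v <- column[!is.na(column)]
  if (!length(v)) stop("column has no observed states")
  switch(mode,
         unordered = length(v) - max(tabulate(v + 1L)),
         ordered = min(vapply(min(v):max(v),
                              function(c) sum(abs(v - c)), 0)),
         irreversible = sum(v - min(v)))
}

## display rounding: half away from zero, as printed cladistic summaries use
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Ensemble consistency and retention indices
#'
#' For each active character, the observed steps `s` on `tree`, the
#' minimum `m` and maximum `g` conceivable steps give the per-character
#' consistency index `ci = m/s` and retention index `ri = (g-s)/(g-m)`.
#' The ensemble indices sum the (weighted) quantities over characters:
#' `Ci = sum(m)/sum(s)` and `Ri = (sum(g)-sum(s))/(sum(g)-sum(m))`.
#' Parsimony-uninformative characters are included by default, matching
#' the convention of the usual cladistic software summaries.
#'
#' @inheritParams tree_length
#' @param informative_only drop characters with `g == m` (which can never
#'   show homoplasy) from the ensemble sums.
#' @return an object of class `homoplasy_indices`: a list with full
#'   precision `ci` and `ri`, two-decimal `ci_2dp` and `ri_2dp` (rounded
#'   half up), the ensemble sums, the tree length, and a per-character
#'   `table` (data frame with columns `character` (0-based), `mode`,
#'   `weight`, `s`, `m`, `g`, `ci`, `ri`).
#' @export
homoplasy_indices <- function(tree, m, spec = NULL,
                              informative_only = FALSE) {
  spec <- spec_for(m, spec)
  tl <- tree_length(tree, m, spec)
  s <- tl$per_character
  mm <- vapply(seq_len(m$n_chars), function(j)
    as.numeric(min_steps(m$states[, j], spec$mode[j])), 0)
  gg <- vapply(seq_len(m$n_chars), function(j)
    as.numeric(max_steps(m$states[, j], spec$mode[j])), 0)
  ci_c <- ifelse(s > 0, mm / s, 1)
  ri_c <- ifelse(gg > mm, (gg - s) / (gg - mm), 1)
  keep <- spec$active
  if (informative_only) keep <- keep & (gg > mm)
  w <- spec$weight
  S <- sum(w[keep] * s[keep]); M <- sum(w[keep] * mm[keep])
  G <- sum(w[keep] * gg[keep])
  Ci <- if (S > 0) M / S else 1
  Ri <- if (G > M) (G - S) / (G - M) else 1
  structure(list(
    ci = Ci, ri = Ri,
    ci_2dp = round_half_up(Ci), ri_2dp = round_half_up(Ri),
    length = S, sum_min = M, sum_max = G,
    table = data.frame(character = seq_len(m$n_chars) - 1L,
                       mode = spec$mode, weight = w, active = spec$active,
                       s = s, m = mm, g = gg, ci = ci_c, ri = ri_c)),
    class = "homoplasy_indices")
}

#' @export
print.homoplasy_indices <- function(x, ...) {
  cat("Tree length ", x$length, " steps; Ci = ", format(x$ci_2dp, nsmall = 2),
      ", Ri = ", format(x$ri_2dp, nsmall = 2), "\n", sep = "")
  cat("  (sum min = ", x$sum_min, ", sum max = ", x$sum_max,
      "; full precision Ci = ", signif(x$ci, 6),
      ", Ri = ", signif(x$ri, 6), ")\n", sep = "")
  invisible(x)
}

#' Export a per-character score table as TSV
#'
#' @param x a `homoplasy_indices` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_indices_tsv <- function(x, file) {
  utils::write.table(x$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
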