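---
title: "Parsimony analysis of morphological matrices with morphpars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony analysis of morphological matrices with morphpars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphpars)
```

## The problem

Morphological cladistics of small taxon samples still underpins much of
invertebrate systematics: a handful of species, a few dozen discrete
characters scored by eye, and a maximum-parsimony analysis whose entire
evidential content is the character matrix printed with the paper.
`morphpars` implements that analysis end to end — scoring, exact and
heuristic tree search, homoplasy indices, bootstrap support, and
branch-by-branch character mapping — for matrices of exactly this kind,
and bundles one worked study system: the 7-taxon, 41-character matrix for
the laophontodid copepod genus *Bicorniphontodes* (six ingroup species
plus the outgroup *Laophontodes typicus*).

At seven taxa the unrooted binary tree space has only
$(2 \cdot 7 - 5)!! = 945$ topologies, so every quantity the package
reports for the bundled matrix is computed *exactly*: search is
exhaustive, the tie set of most parsimonious trees (MPTs) is complete,
and each bootstrap replicate is itself solved exactly. Heuristics
(branch-and-bound, the parsimony ratchet) exist for larger matrices and
are verified against the exact methods on small ones.

## Scoring model

A character is a column of small integer states (0–9) with `?` for
missing entries. Three optimization modes are available per character:

* **unordered** (Fitch): any change of state costs one step;
* **ordered** (Wagner, additive): a change of $k$ units on the linear
  state scale costs $k$ steps;
* **irreversible**: states may only increase along the scale; the root
  state is fixed (by default to the smallest observed state). Because
  increase-only costs are not rooting-invariant, these characters are
  scored on the outgroup-rooted view.

Missing entries are free: a `?` tip contributes the whole state alphabet
in the Fitch set calculus and an unconstrained state in the dynamic
program, at no cost. Unordered and ordered lengths are invariant to
rooting and to taxon input order; the package tests verify both
properties, and verify all three modes against brute-force enumeration of
every ancestral-state assignment on trees of up to six taxa.

The scoring kernel is compiled (C++ via Rcpp): Fitch lengths use bit-set
intersection/union over a postorder edge list, ordered and irreversible
lengths a small Sankoff-style dynamic program. Batch scoring of many
topologies against one matrix is what makes exhaustive search and the
exact bootstrap cheap (milliseconds for 945 trees x 41 characters).

## Character typing in the bundled matrix

The bundled matrix codes states so that 0 is the presumed plesiomorphic
condition and 1–2 are successively derived. Thirty-seven characters are
binary; four (6, 7, 39, 40) are three-state descriptions of progressive
series — protuberance counts, process development, tube-pore loss. The
bundled `char_type_spec` treats the binary characters as unordered and
the four multistate characters as **ordered**, reading each three-state
series as additive.

This choice is not cosmetic, and the matrix itself discriminates it.
With the four multistate characters ordered, exact search yields exactly
two MPTs of length 59, the per-character maximum steps sum to 83 and the
minimum steps to 45, giving ensemble indices Ci = 45/59 = 0.76 and
Ri = (83−59)/(83−45) = 0.63 (two decimals). Treating all characters as
unordered leaves the minimum length at 59 but yields *nine* binary MPTs
(the three-species ingroup clade loses its internal resolution) and
Σg = 80, hence Ri = 0.60. Only the ordered typing reproduces the full
set of published statistics simultaneously, so it is the package
default for this matrix; `char_type_spec()` lets users retype any
character.

## Homoplasy indices

For each character, `s` is its observed length on the tree, `m` the
minimum conceivable steps on any tree (distinct observed states − 1 for
unordered characters, the observed range for ordered ones) and `g` the
maximum conceivable steps, i.e. its length on the completely unresolved
star tree (observations minus the modal state count for unordered
characters; the cost around the best center state — a median — for
ordered ones). The ensemble indices are

$$\mathrm{Ci} = \frac{\sum m}{\sum s}, \qquad
  \mathrm{Ri} = \frac{\sum g - \sum s}{\sum g - \sum m},$$

summed over all active characters including parsimony-uninformative ones
(the convention of the common cladistic software summaries;
`informative_only = TRUE` excludes characters with $g = m$). Displayed
values round half-up to two decimals; full precision is always returned.
The identity $\mathrm{Ci} \cdot \sum s = \sum m$ holds exactly and is
asserted in the tests.

## Tree search

* `exhaustive_search()` scores every topology (capped at 9 taxa,
  135,135 trees) and returns the complete tie set.
* `branch_and_bound_search()` adds taxa stepwise in input order and
  prunes a partial tree when its length, raised per character to the
  full-matrix minimum steps, already exceeds the best complete tree.
  Partial irreversible lengths are bounded below by their ordered
  (rooting-invariant) lengths, keeping the prune sound. It returns the
  identical tie set to exhaustive search, which the tests verify on
  dozens of random matrices.
* `ratchet_search()` is a seedable parsimony ratchet: each iteration
  upweights a random character sample by one, TBR-hill-climbs under the
  perturbed weights, re-climbs under the original weights, and pools any
  new minimum-length trees. The starting tree is the best of several
  greedy random-addition trees (the `random_constraint_level` parameter
  is interpreted as the number of such starts — an explicit design
  choice, since the knob it mirrors in older software is undocumented).
  Ties are broken everywhere by a canonical tree ordering (sorted
  bipartition keys), making runs bit-reproducible from the seed.

Most-parsimonious-tree identity is defined on fully resolved binary
topologies; no zero-length-branch collapsing is applied to the MPT count.

## Bootstrap support

`bootstrap_support()` draws, per replicate, `n_chars` characters with
replacement, finds the replicate's MPTs (exactly when the taxon count
permits, otherwise by multi-start TBR climbs), takes the replicate's
strict consensus, and counts a clade only when it appears there — a
clade must be *unambiguously* supported by the replicate to count. The
more liberal convention (count a clade present in any replicate MPT) is
available as `count_any_mpt = TRUE`.

Two structural facts are worth knowing when reading the output. First,
with a single outgroup the "ingroup monophyly" clade corresponds to the
outgroup's pendant split, which every binary tree contains; its support
is 100% by construction. Second, mid-range support values are sensitive
to the per-replicate search protocol: exact per-replicate searches with
complete tie sets are the most defensible convention and the one this
package uses, but heuristic single-start searches (as in the older
interactive software this analysis style grew up with) can deflate
mid-range frequencies by several points. Comparisons of bootstrap
percentages across programs should allow for this protocol sensitivity
on top of ordinary Monte-Carlo error (binomial SE ≈ 2.2 points at 57%
with 500 replicates).

## Unambiguous change mapping

`mpr_state_sets()` computes, for one character on a rooted binary tree,
the set of states each node takes in at least one most-parsimonious
reconstruction (the union over all optimal assignments — covering both
accelerated and delayed transformation), via a down-pass/out-pass dynamic
program that the tests check against brute-force enumeration of all
internal labelings.

`unambiguous_changes()` reports a change on a branch only when *every*
most-parsimonious reconstruction places a change there with the same
from/to states. Changes on pendant branches are autapomorphies, on
internal branches synapomorphies; characters whose observed steps exceed
their minimum on the tree (per-character ci < 1) are flagged as
homoplasies wherever they map. Two conventions matter:

* The outgroup's states are ordinary data, not a fixed ancestral state;
  reversals toward the outgroup condition are allowed (and the bundled
  matrix needs them: the three-species clade is diagnosed partly by
  reversals to state 0).
* The root of the rooted view subdivides the outgroup's pendant edge, so
  its state is often ambiguous between the outgroup and ingroup
  conditions. It is resolved to the **lowest cost-optimal state** — in
  matrices coded with low states plesiomorphic, the basal condition reads
  as plesiomorphic wherever the data allow. This never changes the tree
  length; it decides only whether a basal change is drawn on the ingroup
  branch (outgroup retains the low state) or on the outgroup's own branch
  (outgroup carries the derived state). Without this resolution every
  character differing between the outgroup and the whole ingroup would be
  "ambiguous" on both basal branches, and the familiar reading of such
  characters as ingroup synapomorphies would be unrecoverable.

`shared_changes_across_mpts()` intersects per-tree change lists keyed by
the clade's leaf set and the (character, from, to) triple, so "supported
in both cladograms" statements remain well defined when MPTs differ in
topology elsewhere.

## The synthetic-data generator

`simulate_topology()` draws uniformly over unrooted binary topologies by
sequential attachment to a uniformly chosen edge. `simulate_characters()`
evolves each character independently from state 0 at the basal node: the
number of change events is Poisson with mean `rate` (the expected number
of changes per character on the whole tree — the quantity that governs
parsimony behavior), events land on uniformly chosen edges, and an event
either switches to a uniformly chosen different state (`mk_unordered`) or
increments the state by one (`irreversible_gain`, states non-decreasing
along every root-to-tip path). A configured fraction of entries is then
masked to `?`; if masking blanks out a whole character one entry is
restored, since a fully unknown character carries no information and the
container rejects it.

What the generator emulates: matrices of the bundled kind — few taxa,
tens of independent discrete characters, a plesiomorphic baseline,
optional progressive (irreversible) series, scattered missing entries.
What it does not emulate: branch-length heterogeneity (events are
uniform over edges, not proportional to time), character correlation,
and state-dependent scoring biases. Consequently, passing recovery tests
says the *inference machinery* is sound, not that real morphological
data meet these assumptions.

One property of the uniform-placement design deserves emphasis: with
seven taxa, roughly two thirds of edges are pendant, so most simulated
changes are autapomorphies and the four internal edges receive little
signal. At about one expected change per character over 41 characters,
occasional convergent characters can then strictly outweigh a weakly
supported true edge, and the generating topology drops out of the MPT
set in a substantial fraction of runs. The package's recovery test
measures exactly this quantity under those conditions; its design
threshold (95%) reflects an idealized expectation that the uniform
placement model does not meet, and the shortfall is a property of the
simulation design, not of the search (which is exact there).

## Numerical and degenerate-input choices

* Infeasible irreversible columns (a fixed root state above an observed
  tip state) return `Inf`, never an exception.
* Dynamic programs use an additive large-cost sentinel (1e9) with a 1e-6
  comparison tolerance; all real costs are small integers, so ties are
  exact.
* All-missing characters are rejected at construction; polymorphic
  entries (`{01}`) are rejected at parse time with a clear error rather
  than silently coerced.
* Display rounding is half-up to two decimals; full precision values are
  always retained alongside.
* Every stochastic routine (`ratchet_search`, `bootstrap_support`,
  `simulate_*`) takes an integer seed, restores the caller's RNG state,
  and is bitwise reproducible from its arguments.

## Problem sizes used in the test suite

The tests run exhaustive searches at up to 7 taxa, brute-force
assignment oracles at up to 6 taxa and 3 states, 50 random
branch-and-bound/exhaustive cross-checks, a 500-replicate bootstrap on
the bundled matrix, an exact enumeration of all $5^5$ resamples of a
5-character toy matrix against a 4,000-replicate Monte-Carlo run, and
100 simulated recovery datasets at the bundled matrix's dimensions.

## Known limitations

* No generalized (Sankoff) step matrices, implied weighting, or
  likelihood/Bayesian scoring.
* No polymorphic-state scoring.
* Exact search caps at 9 taxa; the ratchet is the intended tool beyond
  that, but it has been exercised mainly at the small sizes where it can
  be verified against exact results.
* Rooting is by a single outgroup taxon; with one outgroup the direction
  of change on the basal branch rests on the coding convention described
  above, not on evidence internal to the matrix.
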