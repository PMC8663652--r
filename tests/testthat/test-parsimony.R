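test_that("single-character lengths match trivial cases", {
  tr <- simulate_topology(7, seed = 1)
  expect_equal(character_length(tr, rep(0L, 7)), 0)
  ## outgroup 0, all six ingroup taxa 1: one step on any topology
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  col2 <- b$matrix$states[, 3]
  names(col2) <- b$matrix$taxa
  expect_equal(character_length(res$trees[[1]], col2), 1)
  expect_equal(character_length(res$trees[[2]], col2), 1)
})

test_that("Fitch and Wagner lengths equal brute-force assignment minima", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tr <- simulate_topology(n, seed = 500 + rep)
    nst <- sample(2:4, 1)
    col <- sample(0:(nst - 1), n, replace = TRUE)
    if (rep %% 3 == 0) col[sample.int(n, 1)] <- NA
    if (all(is.na(col))) col[1] <- 0L
    for (mode in c("unordered", "ordered")) {
      expect_equal(character_length(tr, col, mode),
                   oracle_length(tr, col, mode),
                   info = paste(mode, "rep", rep))
    }
  }
})

test_that("irreversible lengths respect the fixed root and signal infeasibility", {
  tr <- root_on_outgroup(simulate_topology(5, seed = 3), "t1")
  col <- c(0L, 1L, 1L, 0L, 1L)
  expect_equal(character_length(tr, col, "irreversible"),
               oracle_length(tr, col, "irreversible",
                             root_policy = "fixed", root_state = 0))
  ## a root state above an observed tip state admits no assignment
  expect_equal(character_length(tr, col, "irreversible", root_state = 1),
               Inf)
  ## increase-only costs dominate ordered costs which dominate unordered
  set.seed(31)
  for (rep in 1:10) {
    tr <- root_on_outgroup(simulate_topology(6, seed = 700 + rep), "t1")
    col <- sample(0:2, 6, replace = TRUE)
    lu <- character_length(tr, col, "unordered")
    lo <- character_length(tr, col, "ordered")
    li <- character_length(tr, col, "irreversible")
    expect_true(lu <= lo && lo <= li)
  }
})

test_that("tree length is additive, weight-linear and rooting-invariant", {
  set.seed(17)
  m <- random_matrix(6, 12, nst = 3)
  tr <- simulate_topology(6, seed = 9)
  spec <- char_type_spec(12, mode = sample(c("unordered", "ordered"), 12,
                                           replace = TRUE))
  tl <- tree_length(tr, m, spec)
  expect_equal(tl$total, sum(tl$per_character))
  ## single-character matrix
  m1 <- char_matrix(m$states[, 1, drop = FALSE], m$taxa)
  expect_equal(tree_length(tr, m1)$total, tl$per_character[1])
  ## doubling weights doubles the total
  spec2 <- spec; spec2$weight <- spec2$weight * 2L
  expect_equal(tree_length(tr, m, spec2)$total, 2 * tl$total)
  ## rooting invariance for unordered/ordered modes
  for (og in m$taxa[1:3]) {
    rooted <- root_on_outgroup(tr, og)
    expect_equal(tree_length(rooted, m, spec)$total, tl$total)
  }
  ## taxon input order invariance
  perm <- sample(m$n_taxa)
  m_perm <- char_matrix(m$states[perm, , drop = FALSE], m$taxa[perm])
  expect_equal(tree_length(tr, m_perm, spec)$total, tl$total)
})

test_that("Fitch lengths agree with phangorn on random unordered matrices", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    m <- random_matrix(n, 15, nst = 2, missing_p = 0.05)
    tr <- simulate_topology(n, seed = 900 + rep)
    dat <- phangorn::phyDat(ifelse(is.na(m$states), "?",
                                   as.character(m$states)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(tree_length(tr, m)$total,
                 as.numeric(phangorn::parsimony(tr, dat)))
  }
})

test_that("min and max conceivable steps follow their definitions", {
  col <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L)
  expect_equal(min_steps(col), 1)
  expect_equal(max_steps(col), 3)
  expect_equal(min_steps(c(0L, 2L, NA), "ordered"), 2)
  expect_equal(max_steps(c(0L, 1L, 2L, 2L), "ordered"), 3)  # center 2
  expect_equal(max_steps(c(0L, 1L, 2L, 2L), "irreversible"), 5)
  ## star-tree length bounds the length on every binary tree (n = 6)
  set.seed(19)
  trees <- enumerate_unrooted_topologies(paste0("t", 1:6))
  for (rep in 1:5) {
    col <- sample(0:2, 6, replace = TRUE)
    g <- max_steps(col)
    lens <- vapply(trees, character_length, 0, column = col)
    expect_true(all(lens <= g))
    expect_true(all(lens >= min_steps(col)))
  }
})

test_that("ensemble indices reproduce the study values and their identities", {
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  for (tr in res$trees) {
    ind <- homoplasy_indices(tr, b$matrix, b$spec)
    expect_equal(ind$length, 59)
    expect_equal(ind$sum_min, 45)
    expect_equal(ind$sum_max, 83)
    expect_equal(ind$ci_2dp, 0.76)
    expect_equal(ind$ri_2dp, 0.63)
    ## exact ensemble identity Ci * sum(s) = sum(m)
    expect_equal(ind$ci * ind$length, ind$sum_min)
  }
})

test_that("indices are 1 without homoplasy and bounded on random data", {
  ## one clean change per character
  states <- cbind(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  m <- char_matrix(states, paste0("t", 1:4))
  tr <- read_newick("((t1,t2),(t3,t4));")
  ind <- homoplasy_indices(tr, m)
  expect_equal(ind$ci, 1)
  expect_equal(ind$ri, 1)
  set.seed(29)
  for (rep in 1:10) {
    m <- random_matrix(6, 20, nst = sample(2:3, 1))
    tr <- simulate_topology(6, seed = 300 + rep)
    ind <- homoplasy_indices(tr, m)
    expect_true(ind$ci > 0 && ind$ci <= 1)
    expect_true(ind$ri >= 0 && ind$ri <= 1)
    ok <- with(ind$table, ci > 0 & ci <= 1 & ri >= 0 & ri <= 1)
    expect_true(all(ok))
  }
})
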