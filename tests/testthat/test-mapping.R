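test_that("MPR state sets are exact on trivial cases", {
  tr <- root_on_outgroup(simulate_topology(6, seed = 2), "t1")
  sets <- mpr_state_sets(tr, rep(1L, 6))
  for (s in sets) expect_equal(s, 1L)
  ## study character 2 (outgroup 0, ingroup 1): ingroup ancestor fixed at 1,
  ## basal node resolves to the plesiomorphic 0
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  r1 <- root_on_outgroup(res$trees[[1]], b$outgroup)
  col <- b$matrix$states[, 3]
  names(col) <- b$matrix$taxa
  sets <- mpr_state_sets(r1, col)
  n <- 7
  root <- n + 1L
  expect_equal(sets[[root]], 0L)
  ## the ingroup ancestor is the root child that is not the outgroup tip
  kids <- morphpars:::children_of(r1)[[root]]
  ing_node <- kids[kids > n]
  expect_equal(sets[[ing_node]], 1L)
})

test_that("MPR sets equal brute-force optimal-assignment unions", {
  set.seed(43)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tr <- root_on_outgroup(simulate_topology(n, seed = 40 + rep), "t1")
    nst <- sample(2:3, 1)
    col <- sample(0:(nst - 1), n, replace = TRUE)
    if (rep %% 4 == 0) col[n] <- NA
    if (all(is.na(col))) col[1] <- 0L
    mode <- sample(c("unordered", "ordered"), 1)
    got <- mpr_state_sets(tr, col, mode)
    oracle <- oracle_mpr_sets(tr, col, mode)
    for (v in oracle$internals)
      expect_equal(got[[v]], oracle$sets[[v]],
                   info = paste("rep", rep, "node", v, mode))
  }
})

test_that("every reported unambiguous change holds in all optimal reconstructions", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    tr <- root_on_outgroup(simulate_topology(n, seed = 80 + rep), "t1")
    m <- random_matrix(n, 8, nst = sample(2:3, 1), missing_p = 0.05)
    ## align matrix rows to this tree's labels
    tab <- unambiguous_changes(tr, m)
    if (!nrow(tab)) next
    po <- ape::reorder.phylo(tr, "postorder")$edge
    below <- rep(list(character(0)), n + tr$Nnode)
    for (i in seq_len(n)) below[[i]] <- tr$tip.label[i]
    for (i in seq_len(nrow(po)))
      below[[po[i, 1]]] <- c(below[[po[i, 1]]], below[[po[i, 2]]])
    for (k in seq_len(nrow(tab))) {
      j <- tab$character[k] + 1L
      col <- m$states[match(tr$tip.label, m$taxa), j]
      oracle <- oracle_mpr_sets(tr, col, "unordered")
      ## locate the edge whose child subtends the recorded clade
      v <- which(vapply(seq_along(below), function(x)
        identical(clade_key(below[[x]]), tab$clade[k]), TRUE))[1]
      p <- po[po[, 2] == v, 1]
      ## in every optimal assignment (root resolved low), parent carries
      ## `from` and child carries `to`
      st_tips <- ifelse(is.na(col), -1L, col)
      for (r in seq_len(nrow(oracle$opt))) {
        st <- c(st_tips, oracle$opt[r, ])
        pv <- st[p]
        cv <- if (v <= n) st[v] else st[v]
        if (cv < 0) next
        expect_equal(unname(pv), tab$from[k])
        expect_equal(unname(cv), tab$to[k])
      }
    }
  }
})

test_that("a constant matrix maps no changes", {
  m <- char_matrix(matrix(1L, 5, 4), paste0("t", 1:5))
  tr <- root_on_outgroup(simulate_topology(5, seed = 6), "t1")
  expect_equal(nrow(unambiguous_changes(tr, m)), 0)
})

test_that("characters with ci = 1 are never classified as homoplasies", {
  set.seed(53)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    m <- random_matrix(n, 10, nst = 2, missing_p = 0)
    res <- exhaustive_search(m)
    tr <- root_on_outgroup(res$trees[[1]], m$taxa[1])
    ind <- homoplasy_indices(res$trees[[1]], m)
    tab <- unambiguous_changes(tr, m)
    if (!nrow(tab)) next
    clean <- ind$table$character[ind$table$ci >= 1 - 1e-9]
    expect_false(any(tab$classification[tab$character %in% clean] ==
                       "homoplasy"))
    homop <- ind$table$character[ind$table$ci < 1 - 1e-9]
    expect_true(all(tab$classification[tab$character %in% homop] ==
                      "homoplasy"))
  }
})

test_that("shared changes intersect per-tree lists and ignore tree order", {
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  one <- shared_changes_across_mpts(res$trees[1], b$matrix, b$spec,
                                    outgroup = b$outgroup)
  direct <- unambiguous_changes(root_on_outgroup(res$trees[[1]], b$outgroup),
                                b$matrix, b$spec)
  expect_equal(as.data.frame(one), as.data.frame(direct))
  fwd <- shared_changes_across_mpts(res$trees, b$matrix, b$spec,
                                    outgroup = b$outgroup)
  rev_ <- shared_changes_across_mpts(rev(res$trees), b$matrix, b$spec,
                                     outgroup = b$outgroup)
  key <- function(d) paste(d$clade, d$character, d$from, d$to)
  expect_setequal(key(fwd), key(rev_))
  ## shared records are a subset of each per-tree list
  expect_true(all(key(fwd) %in% key(direct)))
})

test_that("the study's published change lists are reproduced", {
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  cl <- study_clades()
  for (tr in res$trees) {
    tab <- unambiguous_changes(root_on_outgroup(tr, b$outgroup),
                               b$matrix, b$spec)
    syn <- tab[tab$classification == "synapomorphy", ]
    expect_setequal(syn$character[syn$clade == clade_key(cl$ingroup)],
                    c(2, 3, 4, 17, 32))
    trio_rows <- syn[syn$clade == clade_key(cl$trio), ]
    expect_setequal(trio_rows$character, c(25, 30, 33, 38, 40))
    expect_equal(trio_rows$to[order(trio_rows$character)],
                 c(0, 0, 0, 0, 1))
    ## the sister pair is defined by the single homoplastic change 7 -> 2
    pair_rows <- tab[tab$clade == clade_key(cl$pair), ]
    expect_true(any(pair_rows$character == 7 & pair_rows$to == 2 &
                      pair_rows$classification == "homoplasy"))
  }
  sh <- shared_changes_across_mpts(res$trees, b$matrix, b$spec,
                                   outgroup = b$outgroup)
  expect_setequal(sh$character[sh$clade == clade_key(cl$four)],
                  c(0, 6, 12, 14))
})
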