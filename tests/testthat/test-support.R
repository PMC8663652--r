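test_that("bootstrap runs are reproducible from the seed", {
  b <- bundled_study_matrix()
  s1 <- bootstrap_support(b$matrix, b$spec, b$outgroup, replications = 40,
                          seed = 7)
  s2 <- bootstrap_support(b$matrix, b$spec, b$outgroup, replications = 40,
                          seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- bootstrap_support(b$matrix, b$spec, b$outgroup, replications = 40,
                          seed = 8)
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
})

test_that("a single repeated signal yields deterministic 100% support", {
  ## one informative character replicated 20 times, nothing else varies
  col <- c(0L, 0L, 0L, 1L, 1L, 1L)
  states <- matrix(rep(col, 20), ncol = 20)
  m <- char_matrix(states, paste0("t", 1:6))
  bs <- bootstrap_support(m, outgroup = "t1", replications = 60, seed = 1)
  expect_equal(support_for(bs, c("t4", "t5", "t6")), 100)
  ## the ingroup clade is reported at 100 and the full set never appears
  expect_equal(support_for(bs, paste0("t", 2:6)), 100)
  expect_false(clade_key(paste0("t", 1:6)) %in% bs$clade)
  expect_true(all(bs$size > 1 & bs$size < 6))
  expect_true(all(bs$support >= 0 & bs$support <= 100))
})

test_that("Monte-Carlo frequencies match exact resample enumeration", {
  ## 5-character toy: every one of the 5^5 equally likely resamples is
  ## enumerated and searched exactly, giving the exact bootstrap
  ## probability that the (t4, t5) clade survives the strict consensus
  taxa <- paste0("t", 1:5)
  states <- cbind(c(0L, 0L, 0L, 1L, 1L),
                  c(0L, 0L, 0L, 1L, 1L),
                  c(0L, 0L, 1L, 1L, 0L),
                  c(0L, 1L, 1L, 0L, 0L),
                  c(0L, 1L, 0L, 1L, 0L))
  m <- char_matrix(states, taxa)
  edge_list <- morphpars:::all_topology_edges(5)
  enc <- lapply(edge_list, morphpars:::postorder_from_edges, n = 5)
  topo_keys <- lapply(edge_list, function(E)
    morphpars:::split_keys_post(morphpars:::postorder_from_edges(E, 5), 5))
  target <- paste(4:5, collapse = ",")   # t4,t5 block (canonical: no t1)
  tuples <- as.matrix(expand.grid(rep(list(1:5), 5)))
  hit <- 0L
  for (r in seq_len(nrow(tuples))) {
    cols <- tuples[r, ]
    lens <- as.numeric(morphpars:::score_encoded(
      enc, 5, m$states[, cols, drop = FALSE],
      rep("unordered", 5), rep(1, 5)))
    common <- Reduce(intersect, topo_keys[lens == min(lens)])
    if (target %in% common) hit <- hit + 1L
  }
  p_exact <- 100 * hit / nrow(tuples)
  R <- 4000
  bs <- bootstrap_support(m, outgroup = "t1", replications = R, seed = 2)
  p_mc <- support_for(bs, c("t4", "t5"))
  se <- 100 * sqrt(p_exact / 100 * (1 - p_exact / 100) / R)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1e-9)
})

test_that("the heuristic search mode agrees with exact on a small matrix", {
  set.seed(3)
  m <- random_matrix(6, 14, nst = 2, missing_p = 0)
  e1 <- bootstrap_support(m, outgroup = "t1", replications = 30, seed = 5,
                          search_mode = "exact")
  e2 <- bootstrap_support(m, outgroup = "t1", replications = 30, seed = 5,
                          search_mode = "tbr", searches_per_replicate = 4)
  ## identical resamples (same seed consumption order is not guaranteed,
  ## so compare support levels loosely): the dominant clades must agree
  top1 <- e1$clade[e1$support >= 90]
  for (cl in top1)
    expect_gt(support_for(e2, strsplit(cl, ",")[[1]]), 50)
})

test_that("support annotation labels internal nodes of the rooted view", {
  b <- bundled_study_matrix()
  res <- exhaustive_search(b$matrix, b$spec)
  bs <- bootstrap_support(b$matrix, b$spec, b$outgroup, replications = 50,
                          seed = 4)
  ann <- annotate_support(res$trees[[1]], bs)
  expect_true(ape::is.rooted(ann))
  expect_length(ann$node.label, ann$Nnode)
  lab <- suppressWarnings(as.numeric(ann$node.label))
  expect_true(all(is.na(lab) | (lab >= 0 & lab <= 100)))
})
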