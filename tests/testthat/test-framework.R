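test_that("skeleton learning handles the trivial and the V-structure case", {
  one <- discrete_dataset(matrix(sample(0:1, 50, TRUE), ncol = 1L,
                                 dimnames = list(NULL, "A")))
  cfg <- framework_config(bso = bso_config(pop_size = 2L, n_clusters = 1L,
                                           max_iteration = 2L), seed = 1)
  res <- learn_skeleton(one, cfg)
  expect_equal(nrow(res$skeleton$undirected), 0L)

  hits <- 0L
  for (s in 1:10) {
    d <- forward_sample(example_network("collider3"), 2000, seed = s)
    cfg <- framework_config(bso = bso_config(pop_size = 10L, n_clusters = 2L,
                                             max_iteration = 15L), seed = s)
    sk <- learn_skeleton(d, cfg)$skeleton
    keys <- apply(sk$undirected, 1L, paste, collapse = "-")
    if (setequal(keys, c("A-C", "B-C"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("skeleton edge count respects the in-degree cap", {
  d <- forward_sample(random_dag(6, 3, 0.6, seed = 2), 500, seed = 3)
  cfg <- framework_config(bso = bso_config(pop_size = 8L, n_clusters = 2L,
                                           max_iteration = 5L),
                          max_parents = 2L, seed = 4)
  sk <- learn_skeleton(d, cfg)$skeleton
  expect_lte(nrow(sk$undirected), 6L * 2L)
})

test_that("PDAG merging follows the direction-preservation and conflict rules", {
  nodes <- c("A", "B", "C")
  p_dir <- pdag(nodes, directed = rbind(c("A", "C")))
  p_und <- pdag(nodes, undirected = rbind(c("A", "C")))
  p_rev <- pdag(nodes, directed = rbind(c("C", "A")))

  m1 <- merge_pdags(list(p_dir), nodes)             # identity
  expect_equal(nrow(m1$directed), 1L)
  expect_equal(nrow(m1$undirected), 0L)

  m2 <- merge_pdags(list(p_dir, p_und), nodes)      # directed wins
  expect_equal(unname(m2$directed[1L, ]), c("A", "C"))
  expect_equal(nrow(m2$undirected), 0L)

  m3 <- merge_pdags(list(p_dir, p_rev), nodes)      # conflict demotes
  expect_equal(nrow(m3$directed), 0L)
  expect_equal(nrow(m3$undirected), 1L)
  expect_length(attr(m3, "conflicts"), 1L)
})

test_that("merging repairs directed cycles by demoting recent edges", {
  nodes <- c("A", "B", "C")
  parts <- list(pdag(nodes, directed = rbind(c("A", "B"))),
                pdag(nodes, directed = rbind(c("B", "C"))),
                pdag(nodes, directed = rbind(c("C", "A"))))
  m <- merge_pdags(parts, nodes)
  expect_true(k2bso:::edges_acyclic(nodes, m$directed))
  expect_equal(nrow(m$directed) + nrow(m$undirected), 3L)
  expect_gte(length(attr(m, "conflicts")), 1L)
})

test_that("the continuous pipeline orients a V-structure end to end", {
  d <- collider_continuous(300, seed = 80)
  cfg <- framework_config(bso = bso_config(pop_size = 10L, n_clusters = 2L,
                                           max_iteration = 15L),
                          n_permutations = 100L, seed = 81)
  g <- k2bso_run(d, cfg)
  got <- apply(g$directed, 1L, paste, collapse = ">")
  expect_true(all(c("A>C", "B>C") %in% got))
})

test_that("the pipeline is deterministic under a fixed seed", {
  d <- forward_sample(example_network("tree5"), 800, seed = 82)
  cfg <- framework_config(bso = bso_config(pop_size = 10L, n_clusters = 2L,
                                           max_iteration = 10L), seed = 83)
  a <- k2bso_run(d, cfg)
  b <- k2bso_run(d, cfg)
  expect_identical(a$directed, b$directed)
  expect_identical(a$undirected, b$undirected)
})

test_that("discrete data below the threshold returns the K2 directions", {
  d <- forward_sample(example_network("tree5"), 800, seed = 84)
  cfg <- framework_config(threshold_k = 50L,
                          bso = bso_config(pop_size = 10L, n_clusters = 2L,
                                           max_iteration = 10L), seed = 85)
  g <- k2bso_run(d, cfg)
  expect_equal(nrow(g$undirected), 0L)       # all edges carry K2 directions
  expect_true(k2bso:::edges_acyclic(g$nodes, g$directed))
})

test_that("the split path covers the node set and stays inside the whole-data skeleton", {
  truth <- example_network("tree5")
  ok <- 0L
  for (s in 1:5) {
    d <- forward_sample(truth, 1500, seed = 90 + s)
    base_cfg <- framework_config(
      bso = bso_config(pop_size = 12L, n_clusters = 2L, max_iteration = 15L),
      seed = 90 + s)
    whole <- k2bso_run(d, base_cfg)
    split_cfg <- base_cfg
    split_cfg$threshold_k <- 2L                     # force the split path
    parts <- k2bso_run(d, split_cfg)
    expect_identical(parts$nodes, d$columns)
    whole_keys <- c(apply(whole$directed, 1L, function(e)
                      paste(sort(e), collapse = "-")),
                    apply(whole$undirected, 1L, function(e)
                      paste(sort(e), collapse = "-")))
    part_keys <- c(apply(parts$directed, 1L, function(e)
                     paste(sort(e), collapse = "-")),
                   apply(parts$undirected, 1L, function(e)
                     paste(sort(e), collapse = "-")))
    if (all(part_keys %in% whole_keys)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
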