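test_that("prefix-overlap distance matches hand enumeration", {
  expect_equal(order_distance(c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_equal(order_distance(c("A", "B", "C"), c("C", "B", "A")), 3L)
  expect_equal(order_distance(c("A", "B", "C"), c("A", "C", "B")), 1L)
  expect_error(order_distance(c("A", "B"), c("A", "C")), "same name set")
})

test_that("distance equals the Kendall-tau pair-disagreement oracle", {
  # exhaustive for n <= 4
  for (n in 2:4) {
    perms <- all_permutations(paste0("v", seq_len(n)))
    for (p1 in perms) {
      for (p2 in perms) {
        expect_identical(order_distance(p1, p2), kendall_oracle(p1, p2))
      }
    }
  }
  # random pairs for larger n
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(5:15, 1L)
    p1 <- sample(paste0("v", seq_len(n)))
    p2 <- sample(paste0("v", seq_len(n)))
    expect_identical(order_distance(p1, p2), kendall_oracle(p1, p2))
  }
})

test_that("distance satisfies the metric axioms on random permutations", {
  set.seed(15)
  for (rep in 1:50) {
    n <- sample(3:12, 1L)
    v <- paste0("v", seq_len(n))
    a <- sample(v); b <- sample(v); cc <- sample(v)
    dab <- order_distance(a, b)
    expect_identical(dab, order_distance(b, a))         # symmetry
    expect_gte(dab, 0L)
    expect_lte(dab, n * (n - 1L) / 2L)
    expect_identical(order_distance(a, a), 0L)
    if (dab == 0L) expect_identical(a, b)
    expect_lte(dab, order_distance(a, cc) + order_distance(cc, b))
  }
})

test_that("k-medoids clustering separates planted bundles and handles edge cases", {
  v <- paste0("v", 1:10)
  # m = pop size: singleton clusters, every member its own center
  orders <- replicate(4, sample(v), simplify = FALSE)
  cl <- cluster_orders(orders, scores = 1:4, m = 4L, seed = 1)
  expect_equal(sort(unique(cl$cluster_of)), 1:4)
  expect_setequal(cl$centers, 1:4)

  expect_error(cluster_orders(orders, 1:4, m = 0L), "at least 1")

  # two tight bundles of perturbed seed orders should split cleanly
  seed1 <- v
  seed2 <- rev(v)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    bundle <- c(lapply(1:5, function(i) perturb_order(seed1, 0.1)),
                lapply(1:5, function(i) perturb_order(seed2, 0.1)))
    cl <- cluster_orders(bundle, scores = rep(0, 10), m = 2L, seed = s)
    lab <- cl$cluster_of
    if (length(unique(lab[1:5])) == 1L && length(unique(lab[6:10])) == 1L &&
        lab[[1L]] != lab[[6L]]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("clustering of separated bundles is shuffle-equivariant up to relabeling", {
  v <- paste0("v", 1:10)
  set.seed(22)
  bundle <- c(lapply(1:5, function(i) perturb_order(v, 0.1)),
              lapply(1:5, function(i) perturb_order(rev(v), 0.1)))
  scores <- runif(10)
  cl <- cluster_orders(bundle, scores, m = 2L, seed = 3)
  shuffle <- sample(10)
  cl2 <- cluster_orders(bundle[shuffle], scores[shuffle], m = 2L, seed = 4)
  # partitions agree as set partitions
  part1 <- split(seq_len(10L), cl$cluster_of)
  part2 <- split(shuffle, cl2$cluster_of)
  norm <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","), ""))
  expect_identical(norm(part1), norm(part2))
})

test_that("the logistic step-size schedule has the stated shape", {
  set.seed(30)
  # at the midpoint the logistic factor is exactly 1/2
  xs <- replicate(2000, step_size(100, 50, 10))
  expect_true(all(xs > 0 & xs < 0.5))
  expect_equal(mean(xs), 0.25, tolerance = 0.02)
  # late iterations with a small slope give a vanishing factor
  expect_lt(step_size(100, 100, 1), 1e-15)
  # Monte-Carlo mean at iteration 0 vs closed form logsig(5)/2
  xs0 <- replicate(1e5, step_size(100, 0, 10))
  expect_equal(mean(xs0), plogis(5) / 2, tolerance = 0.01)
  expect_error(step_size(100, 10, 0), "nonzero")
})

test_that("perturbation always yields a permutation and scales with step size", {
  v <- paste0("v", 1:10)
  set.seed(31)
  for (rep in 1:500) {
    out <- perturb_order(v, runif(1))
    expect_identical(sort(out), sort(v))
  }
  # xi -> 0 means exactly one insertion move: distance <= n - 1
  d1 <- replicate(200, order_distance(v, perturb_order(v, 0)))
  expect_true(all(d1 <= length(v) - 1L))
  expect_true(any(d1 > 0L))
  # expected displacement grows with xi (Spearman over a grid)
  v20 <- paste0("v", 1:20)
  grid <- seq(0.05, 0.95, by = 0.15)
  mean_d <- vapply(grid, function(xi) {
    mean(replicate(100, order_distance(v20, perturb_order(v20, xi))))
  }, 0)
  expect_gt(cor(grid, mean_d, method = "spearman"), 0.9)
})

test_that("rank-average fusion is idempotent and sits between its parents", {
  v <- paste0("v", 1:7)
  set.seed(32)
  r <- sample(v)
  expect_identical(merge_orders(r, r), r)

  # fully tied keys: jitter picks among all orderings
  outs <- replicate(200,
    paste(merge_orders(c("A", "B", "C"), c("C", "B", "A")), collapse = ""))
  expect_gte(length(unique(outs)), 5L)      # nearly all 3! orders appear

  v10 <- paste0("v", 1:10)
  between <- 0L
  for (rep in 1:100) {
    a <- sample(v10); b <- sample(v10)
    m <- merge_orders(a, b)
    dab <- order_distance(a, b)
    if (order_distance(m, a) <= dab && order_distance(m, b) <= dab) {
      between <- between + 1L
    }
  }
  expect_gte(between, 95L)
})

test_that("BSO finds the exhaustive-best order on a small chain problem", {
  d <- forward_sample(example_network("chain5"), 2000, seed = 40)
  cache <- score_cache()
  exhaustive <- max(vapply(all_permutations(d$columns), function(ord) {
    score_order(d, ord, cache = cache)
  }, 0))
  hits <- 0L
  for (s in 1:5) {
    cfg <- bso_config(pop_size = 20L, n_clusters = 3L, max_iteration = 50L,
                      seed = s)
    res <- bso_search(d, cfg, cache = cache)
    if (abs(res$score - exhaustive) < 1e-9) hits <- hits + 1L
    # returned score always matches recomputation on the returned order
    expect_equal(res$score, score_order(d, res$order), tolerance = 1e-12)
    expect_true(all(diff(res$trace$best_score) >= 0))
  }
  expect_gte(hits, 4L)
})

test_that("BSO is deterministic under a fixed seed", {
  d <- forward_sample(example_network("collider3"), 500, seed = 41)
  cfg <- bso_config(pop_size = 10L, n_clusters = 2L, max_iteration = 10L,
                    seed = 77)
  a <- bso_search(d, cfg)
  b <- bso_search(d, cfg)
  expect_identical(a$order, b$order)
  expect_identical(a$score, b$score)
  expect_identical(a$trace, b$trace)
})

test_that("random search stops after ten stale batches and respects its seed", {
  one <- discrete_dataset(matrix(sample(0:1, 30, TRUE), ncol = 1L,
                                 dimnames = list(NULL, "A")))
  res <- random_search(one, batch = 3L, seed = 1)
  expect_identical(res$order, "A")
  expect_equal(nrow(res$trace), 11L)        # 1 improving + 10 stale batches

  d <- forward_sample(example_network("collider3"), 300, seed = 42)
  a <- random_search(d, batch = 10L, seed = 5)
  b <- random_search(d, batch = 10L, seed = 5)
  expect_identical(a, b)
  expect_equal(a$score, score_order(d, a$order), tolerance = 1e-12)
})

test_that("GA search degenerates to the initial population at zero generations", {
  d <- forward_sample(example_network("collider3"), 300, seed = 43)
  res0 <- ga_search(d, pop_size = 10L, generations = 0L, seed = 9)
  # generations = 0: exactly pop_size evaluations, best of the random start
  expect_equal(res0$evaluations, 10L)
  expect_equal(res0$score, score_order(d, res0$order), tolerance = 1e-12)

  res <- ga_search(d, pop_size = 10L, generations = 15L, seed = 9)
  expect_true(all(diff(res$trace$best_score) >= 0))   # elitism
  expect_gte(res$score, res0$score)
})

test_that("order crossover produces valid permutations", {
  set.seed(44)
  v <- paste0("v", 1:12)
  for (rep in 1:200) {
    child <- k2bso:::ox_crossover(sample(v), sample(v))
    expect_identical(sort(child), sort(v))
  }
})
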