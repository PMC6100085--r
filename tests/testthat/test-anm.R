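test_that("skeleton splitting reads off adjacency and drops isolated nodes", {
  star <- pdag(c("A", "B", "C", "D"),
               undirected = rbind(c("C", "A"), c("C", "B")))
  subs <- split_skeleton(star)
  tab <- setNames(lapply(subs, `[[`, "neighbors"),
                  vapply(subs, `[[`, "", "target"))
  expect_named(tab, c("A", "B", "C"), ignore.order = TRUE)   # D isolated
  expect_identical(tab$C, c("A", "B"))
  expect_identical(tab$A, "C")
  # handshake identity
  expect_equal(sum(lengths(tab)), 2L * nrow(star$undirected))

  expect_error(split_skeleton(pdag(c("A", "B"),
                                   directed = rbind(c("A", "B")))),
               "undirected")
})

test_that("HSIC permutation test is calibrated under the null and powerful under copy", {
  # null: independent uniforms; mean p over repeats near 1/2
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    test_independence(runif(60), runif(60), n_permutations = 100, seed = s)
  }, 0)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)

  # maximal dependence: b is a copy of a
  set.seed(7)
  a <- runif(200)
  expect_lte(test_independence(a, a, n_permutations = 200, seed = 1), 0.01)

  # kernel centering: adding a constant to b leaves the p-value unchanged
  b <- runif(60); x <- runif(60)
  expect_identical(test_independence(x, b, n_permutations = 100, seed = 2),
                   test_independence(x, b + 5, n_permutations = 100, seed = 2))

  expect_error(test_independence(runif(30), runif(30), n_permutations = 10),
               "at least 50")
  expect_error(test_independence(runif(10), runif(10)), "at least 20")
})

test_that("type-I error of the permutation test stays near the nominal level", {
  rejections <- 0L
  for (s in 1:200) {
    set.seed(s + 1000)
    p <- test_independence(runif(40), runif(40), n_permutations = 60,
                           seed = s)
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("ANM fits accept the causal and reject the anti-causal direction", {
  # perfect function: residuals vanish, fit accepted
  set.seed(50)
  x <- runif(100, -1, 1)
  d <- continuous_dataset(cbind(X = x, Y = x^3))
  fit <- fit_anm(d, "Y", "X", seed = 1)
  expect_true(fit$accepted)
  expect_lt(max(abs(fit$residuals)), 0.05)

  causal <- 0L; anti <- 0L
  for (s in 1:3) {
    set.seed(s)
    x <- runif(300, -1, 1)
    y <- x^3 + x + runif(300, -1, 1)
    d <- continuous_dataset(cbind(X = x, Y = y))
    if (fit_anm(d, "Y", "X", seed = s)$accepted) causal <- causal + 1L
    if (!fit_anm(d, "X", "Y", seed = s)$accepted) anti <- anti + 1L
  }
  expect_gte(causal, 2L)
  expect_gte(anti, 2L)

  expect_error(fit_anm(d, "Y", character(0)), "non-empty")
  dbad <- continuous_dataset(cbind(X = rep(1, 50) + 0 * x[1:50],
                                   Y = runif(50)))
  expect_error(fit_anm(dbad, "Y", "X"), "constant")
})

test_that("sub-skeleton orientation recovers a collider and leaves anti-causal edges alone", {
  d <- collider_continuous(300, seed = 60)
  sub_c <- list(target = "C", neighbors = c("A", "B"))
  g <- orient_subskeleton(d, sub_c, n_permutations = 100, seed = 61)
  got <- apply(g$directed, 1L, paste, collapse = ">")
  expect_setequal(got, c("A>C", "B>C"))

  # anti-causal side: A's only neighbor is its child C; nothing accepted
  sub_a <- list(target = "A", neighbors = "C")
  g2 <- orient_subskeleton(d, sub_a, n_permutations = 100, seed = 62)
  expect_equal(nrow(g2$directed), 0L)
  expect_equal(nrow(g2$undirected), 1L)

  # alpha = 0 disables all acceptance
  g3 <- orient_subskeleton(d, sub_c, alpha = 0, n_permutations = 100,
                           seed = 63)
  expect_equal(nrow(g3$directed), 0L)
  expect_equal(nrow(g3$undirected), 2L)
})

test_that("orientation never invents edges nor emits both directions", {
  d <- collider_continuous(150, seed = 70)
  for (target in c("A", "B", "C")) {
    nbs <- setdiff(c("A", "B", "C"), target)
    g <- orient_subskeleton(d, list(target = target, neighbors = nbs),
                            n_permutations = 60, seed = 71)
    all_pairs <- rbind(g$directed, g$undirected)
    expect_true(all(apply(all_pairs, 1L, function(e) target %in% e)))
    keys <- apply(g$directed, 1L, function(e) paste(sort(e), collapse = "-"))
    expect_false(anyDuplicated(keys) > 0L)
  }
})
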