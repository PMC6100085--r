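# Direction learning: fit additive-noise models on the sub-skeletons of a
# causal skeleton and accept an orientation when the regression residual is
# statistically independent of the candidate parents.  Regression is kernel
# ridge (RBF, median-heuristic bandwidth, leave-one-out choice of the ridge
# penalty); independence is a permutation HSIC test.

#' Split a skeleton into per-node sub-skeletons
#'
#' One sub-skeleton per node with at least one neighbor: the target node
#' plus its adjacency set.  Sub-skeletons are low-dimensional even when the
#' full graph is not, which is what makes ANM orientation tractable.
#'
#' @param skel a \code{pdag} with only undirected edges.
#' @return list of sub-skeletons, each \code{list(target, neighbors)}.
#' @export
split_skeleton <- function(skel) {
  if (nrow(skel$directed)) stop("skeleton must be fully undirected")
  e <- skel$undirected
  subs <- list()
  for (v in skel$nodes) {
    nb <- unname(c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L]))
    if (length(nb)) {
      subs[[length(subs) + 1L]] <- list(target = v, neighbors = sort(nb))
    }
  }
  subs
}

rbf_kernel <- function(x) {
  x <- as.matrix(x)
  d2 <- as.matrix(stats::dist(x))^2
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  exp(-d2 / (2 * med^2))
}

center_kernel <- function(K) {
  K <- sweep(K, 1L, rowMeans(K))
  sweep(K, 2L, colMeans(K))
}

#' Permutation HSIC independence test
#'
#' Hilbert-Schmidt independence criterion with RBF kernels
#' (median-heuristic bandwidths) between a matrix of predictors and a
#' vector; the null distribution is obtained by permuting \code{b}, so the
#' p-value is distribution-free under independence.
#'
#' @param a numeric matrix (or vector) of predictors.
#' @param b numeric vector.
#' @param n_permutations number of permutations (at least 50).
#' @param seed integer seed for the permutation draw.
#' @return p-value in (0, 1]: \code{(1 + #{perm >= observed}) /
#'   (1 + n_permutations)}.
#' @export
test_independence <- function(a, b, n_permutations = 200L, seed = NULL) {
  a <- as.matrix(a)
  b <- as.numeric(b)
  n <- nrow(a)
  if (length(b) != n) stop("row counts differ")
  if (n < 20L) stop("need at least 20 samples")
  if (n_permutations < 50L) stop("need at least 50 permutations")
  Kc <- center_kernel(rbf_kernel(a))
  Lc <- center_kernel(rbf_kernel(b))
  stat <- sum(Kc * Lc) / n^2
  with_seed_(seed, {
    exceed <- 0L
    for (dummy in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (sum(Kc * Lc[p, p]) / n^2 >= stat) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_permutations)
  })
}

# kernel ridge regression of y on X with LOO-chosen ridge penalty;
# returns the residual vector.  Eigendecomposition makes the LOO curve
# cheap across the whole penalty grid.
krr_residuals <- function(X, y, lambdas = 10^seq(-8, 0)) {
  X <- scale(as.matrix(X))
  n <- nrow(X)
  K <- rbf_kernel(X)
  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  uy <- crossprod(U, y)
  best <- NULL
  best_err <- Inf
  for (lam in lambdas) {
    shrink <- d / (d + lam * n)
    fitted <- U %*% (shrink * uy)
    hdiag <- rowSums(sweep(U^2, 2L, shrink, `*`))
    loo <- (y - fitted) / pmax(1 - hdiag, 1e-10)
    err <- mean(loo^2)
    if (err < best_err) {
      best_err <- err
      best <- as.numeric(y - fitted)
    }
  }
  best
}

#' Fit an additive-noise model and test residual independence
#'
#' Regresses \code{target} on \code{parents} by kernel ridge regression and
#' tests whether the residual is independent of the parents; under a correct
#' causal orientation the additive-noise assumption makes the residual
#' independent, while the anti-causal fit generally leaves dependence the
#' test detects.
#'
#' @param data a \code{continuous_dataset}.
#' @param target name of the response column.
#' @param parents non-empty character vector of candidate parent columns.
#' @param alpha significance level for acceptance.
#' @param n_permutations permutations for the HSIC test.
#' @param seed integer seed.
#' @return list with \code{candidate_parents}, \code{residuals},
#'   \code{p_value} and \code{accepted} (\code{p_value > alpha}).  A fit
#'   whose residual standard deviation falls below 1e-3 of the response's is
#'   an exact functional relationship: it is accepted with \code{p_value}
#'   1, since the leftover is regression shrinkage, not noise, and testing
#'   its independence would be meaningless.
#' @export
fit_anm <- function(data, target, parents, alpha = 0.05,
                    n_permutations = 200L, seed = NULL) {
  if (!length(parents)) stop("parents must be non-empty")
  cols <- c(target, parents)
  bad <- setdiff(cols, data$columns)
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  X <- data$values[, parents, drop = FALSE]
  y <- data$values[, target]
  if (nrow(X) < 20L) stop("need at least 20 samples")
  if (any(apply(cbind(X, y), 2L, stats::sd) == 0)) {
    stop("degenerate (constant) column")
  }
  with_seed_(seed, {
    res <- krr_residuals(X, y)
    p <- if (stats::sd(res) <= 1e-3 * stats::sd(y)) 1
         else test_independence(X, res, n_permutations)
    list(candidate_parents = parents, residuals = res, p_value = p,
         accepted = p > alpha)
  })
}

#' Orient one sub-skeleton by additive-noise-model fits
#'
#' Enumerates candidate parent sets (subsets of the neighbors, smallest
#' first, lexicographic within a size) and accepts every set whose ANM fit
#' passes the independence test at level \code{alpha}; the union of the
#' accepted sets is oriented towards the target and the remaining target
#' edges stay undirected.  Accepting all passing sets (rather than stopping
#' at the first) is what lets a collider orient both its parents: each
#' parent alone already yields an independent residual there.
#'
#' @param data a \code{continuous_dataset} covering the sub-skeleton.
#' @param sub sub-skeleton, \code{list(target, neighbors)}.
#' @param alpha significance level (0 disables all acceptance).
#' @param max_set largest candidate parent-set size tried.
#' @param n_permutations permutations for the HSIC test.
#' @param seed integer seed.
#' @return a \code{pdag} over \code{c(target, neighbors)}; its
#'   \code{"report"} attribute is a data frame of every candidate set tried
#'   with its p-value.
#' @export
orient_subskeleton <- function(data, sub, alpha = 0.05, max_set = 3L,
                               n_permutations = 200L, seed = NULL) {
  target <- sub$target
  nbs <- sort(sub$neighbors)
  report <- data.frame(target = character(0), candidate_set = character(0),
                       p_value = numeric(0), accepted = logical(0))
  accepted_set <- character(0)
  with_seed_(seed, {
    for (k in seq_len(min(max_set, length(nbs)))) {
      sets <- utils::combn(nbs, k, simplify = FALSE)
      for (cs in sets) {
        fit <- fit_anm(data, target, cs, alpha = alpha,
                       n_permutations = n_permutations)
        ok <- alpha > 0 && fit$accepted
        report <- rbind(report, data.frame(
          target = target, candidate_set = paste(cs, collapse = ","),
          p_value = fit$p_value, accepted = ok))
        if (ok) accepted_set <- union(accepted_set, cs)
      }
    }
  })
  directed <- NULL
  undirected <- NULL
  if (length(accepted_set)) {
    directed <- cbind(accepted_set, rep(target, length(accepted_set)))
  }
  rest <- setdiff(nbs, accepted_set)
  if (length(rest)) {
    undirected <- cbind(rest, rep(target, length(rest)))
  }
  out <- pdag(c(target, nbs), directed = directed, undirected = undirected)
  attr(out, "report") <- report
  out
}
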