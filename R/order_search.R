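# Search over topological orders.  The BSO searcher clusters a population of
# orders under a prefix-overlap distance (equal to the Kendall-tau pair
# disagreement count), keeps each cluster's best-scoring member as its
# center, and generates candidates by perturbing or fusing members/centers
# with a logistic-scheduled step size.  Random-restart and genetic-algorithm
# searchers provide matched-budget baselines.

#' Prefix-overlap distance between two orders
#'
#' For every variable \eqn{v}, count how many variables precede \eqn{v} in
#' both orders; the distance is \eqn{n(n-1)/2} minus the summed overlap, so
#' identical orders are at distance 0 and reversed orders at the maximum
#' \eqn{n(n-1)/2}.  This equals the Kendall-tau disagreement count: the
#' number of unordered pairs on whose relative order the two permutations
#' disagree.
#'
#' @param r1,r2 character vectors: permutations of the same name set.
#' @return integer distance in \code{[0, n(n-1)/2]}.
#' @export
order_distance <- function(r1, r2) {
  n <- length(r1)
  if (length(r2) != n || !setequal(r1, r2) ||
      anyDuplicated(r1) || anyDuplicated(r2)) {
    stop("orders must be permutations of the same name set")
  }
  if (n < 2L) return(0L)
  p2 <- match(r1, r2)          # position in r2 of the i-th element of r1
  overlap <- 0L
  for (j in 2:n) overlap <- overlap + sum(p2[seq_len(j - 1L)] < p2[[j]])
  as.integer(n * (n - 1L) / 2L - overlap)
}

order_distance_matrix <- function(orders) {
  k <- length(orders)
  d <- matrix(0L, k, k)
  if (k < 2L) return(d)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- order_distance(orders[[i]], orders[[j]])
    }
  }
  d
}

#' Cluster a population of orders by k-medoids
#'
#' PAM-style alternation (seeded medoid initialisation, at most 50 sweeps)
#' under \code{\link{order_distance}}; permutations admit no mean, so
#' medoids stand in for k-means centroids.  After partitioning, each
#' cluster's best-scoring member is marked as its center, matching the rule
#' that the optimal individual represents the cluster.
#'
#' @param orders list of orders (character permutations).
#' @param scores numeric vector of fitness values parallel to \code{orders}.
#' @param m number of clusters, \code{1 <= m <= length(orders)}.
#' @param seed integer seed for medoid initialisation.
#' @return list with \code{cluster_of} (integer cluster id per member) and
#'   \code{centers} (member index of each cluster's best scorer).
#' @export
cluster_orders <- function(orders, scores, m, seed = NULL) {
  k <- length(orders)
  if (m < 1L) stop("m must be at least 1")
  if (m > k) stop("more clusters than members")
  with_seed_(seed, {
    d <- order_distance_matrix(orders)
    assign_to <- function(medoids) {
      apply(d[, medoids, drop = FALSE], 1L, which.min)  # tie -> lowest id
    }
    # every cluster keeps at least one member: repopulate an empty cluster
    # with the member farthest from its current medoid (never emptying
    # another cluster in the process)
    fix_empty <- function(cl, medoids) {
      repeat {
        empty <- setdiff(seq_len(m), unique(cl))
        if (!length(empty)) return(cl)
        counts <- tabulate(cl, m)
        movable <- which(counts[cl] > 1L)
        far <- movable[[which.max(d[cbind(movable, medoids[cl[movable]])])]]
        cl[[far]] <- empty[[1L]]
      }
    }
    medoids <- sort(sample.int(k, m))
    cl <- fix_empty(assign_to(medoids), medoids)
    for (sweep in seq_len(50L)) {
      new_medoids <- vapply(seq_len(m), function(c) {
        idx <- which(cl == c)
        idx[[which.min(colSums(d[idx, idx, drop = FALSE]))]]
      }, 1L)
      new_cl <- fix_empty(assign_to(new_medoids), new_medoids)
      if (identical(new_medoids, medoids) && identical(new_cl, cl)) break
      medoids <- new_medoids
      cl <- new_cl
    }
    centers <- vapply(seq_len(m), function(c) {
      idx <- which(cl == c)
      idx[[which.max(scores[idx])]]
    }, 1L)
    list(cluster_of = cl, centers = centers)
  })
}

#' Logistic step-size schedule
#'
#' \eqn{\xi = \mathrm{logsig}((0.5\,T - t)/k) \cdot u}, \eqn{u \sim U(0,1)}:
#' large early (exploration), decaying to 0 late (exploitation); \code{k}
#' controls the slope of the transition.
#'
#' @param max_iteration total iteration budget \eqn{T}.
#' @param current_iteration current iteration \eqn{t}.
#' @param k slope of the logistic; must be nonzero.
#' @return a step size in (0, 1); consumes one uniform draw from the current
#'   RNG stream.
#' @export
step_size <- function(max_iteration, current_iteration, k = 20) {
  if (k == 0) stop("slope k must be nonzero")
  stopifnot(current_iteration >= 0, current_iteration <= max_iteration)
  stats::plogis((0.5 * max_iteration - current_iteration) / k) *
    stats::runif(1L)
}

#' Perturb an order by random insertion moves
#'
#' Applies \code{max(1, round(xi * n))} insertion moves (remove one element,
#' reinsert at a random position), the permutation-space analogue of adding
#' scheduled noise to a real-valued candidate: the step size controls how
#' far the candidate moves in order space.
#'
#' @param base an order.
#' @param xi step size in (0, 1), e.g. from \code{\link{step_size}}.
#' @return a new order over the same names.
#' @export
perturb_order <- function(base, xi) {
  n <- length(base)
  s <- max(1L, as.integer(round(xi * n)))
  out <- base
  for (dummy in seq_len(s)) {
    i <- sample.int(n, 1L)
    el <- out[[i]]
    out <- out[-i]
    j <- sample.int(n, 1L)
    out <- append(out, el, after = j - 1L)
  }
  out
}

#' Fuse two orders by rank averaging
#'
#' Each variable's key is the mean of its positions in the two parents plus
#' a tiny uniform jitter (which breaks ties uniformly at random); the fused
#' order sorts variables by key.  Fusing an order with itself returns it
#' unchanged.
#'
#' @param r1,r2 orders over the same name set.
#' @return a fused order.
#' @export
merge_orders <- function(r1, r2) {
  if (!setequal(r1, r2)) stop("orders must share the same name set")
  key <- (seq_along(r1) + match(r1, r2)) / 2 +
    stats::runif(length(r1)) * 1e-9
  r1[order(key)]
}

#' BSO search configuration
#'
#' @param pop_size population size.
#' @param n_clusters number of clusters \eqn{m}.
#' @param max_iteration iteration budget.
#' @param slope_k slope of the logistic step-size schedule.
#' @param p_replace_center probability (per iteration) of replacing a random
#'   cluster's center with a fresh random order.
#' @param p_one_cluster probability a candidate is generated from one
#'   cluster (vs fused from two).
#' @param p_use_center probability the one-cluster candidate starts from the
#'   cluster center (vs a random member).
#' @param p_use_center_pair probability the two-cluster candidate fuses the
#'   two centers (vs two random members).
#' @param stall_limit stop after this many iterations without improvement.
#' @param max_evals optional cap on score evaluations (matched-budget
#'   comparisons); \code{Inf} to disable.
#' @param seed integer seed.
#' @return list of class \code{bso_config}.
#' @export
bso_config <- function(pop_size = 50L, n_clusters = 5L, max_iteration = 100L,
                       slope_k = 20, p_replace_center = 0.2,
                       p_one_cluster = 0.8, p_use_center = 0.4,
                       p_use_center_pair = 0.5, stall_limit = 20L,
                       max_evals = Inf, seed = NULL) {
  probs <- c(p_replace_center, p_one_cluster, p_use_center, p_use_center_pair)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (pop_size < n_clusters || n_clusters < 1L) {
    stop("need pop_size >= n_clusters >= 1")
  }
  if (slope_k == 0) stop("slope_k must be nonzero")
  structure(list(pop_size = as.integer(pop_size),
                 n_clusters = as.integer(n_clusters),
                 max_iteration = as.integer(max_iteration),
                 slope_k = slope_k,
                 p_replace_center = p_replace_center,
                 p_one_cluster = p_one_cluster,
                 p_use_center = p_use_center,
                 p_use_center_pair = p_use_center_pair,
                 stall_limit = as.integer(stall_limit),
                 max_evals = max_evals,
                 seed = seed),
            class = "bso_config")
}

new_trace_row <- function(iteration, evaluations, best, scores, nonempty) {
  data.frame(iteration = iteration, evaluations = evaluations,
             best_score = best, mean_score = mean(scores),
             n_clusters_nonempty = nonempty)
}

#' Brain-storm optimization over topological orders
#'
#' Maintains a population of orders scored by \code{\link{score_order}},
#' re-clustered every iteration by \code{\link{cluster_orders}}.  Each
#' iteration optionally re-seeds a random cluster center, then generates one
#' candidate per member by one of four routes (one-cluster center,
#' one-cluster random member, fused centers of two clusters, fused random
#' members of two clusters; cluster choice weighted by cluster size),
#' perturbs it with the scheduled step size, and keeps the candidate only if
#' strictly better.  Stops at \code{max_iteration}, after
#' \code{stall_limit} non-improving iterations, or when the evaluation
#' budget runs out.
#'
#' @param data a \code{discrete_dataset}.
#' @param config a \code{\link{bso_config}}.
#' @param max_parents in-degree cap passed to the K2 scorer.
#' @param cache optional shared \code{\link{score_cache}}.
#' @return list with \code{order}, \code{score} (best ever), \code{trace}
#'   (per-iteration data frame) and \code{evaluations}.
#' @export
bso_search <- function(data, config = bso_config(), max_parents = 4L,
                       cache = score_cache()) {
  if (length(data$columns) < 1L) stop("empty data")
  cfg <- config
  with_seed_(cfg$seed, {
    nodes <- data$columns
    evals <- 0L
    score1 <- function(ord) {
      evals <<- evals + 1L
      score_order(data, ord, max_parents, cache)
    }
    members <- replicate(cfg$pop_size, sample(nodes), simplify = FALSE)
    scores <- vapply(members, score1, 0)
    m <- cfg$n_clusters
    cl <- cluster_orders(members, scores, m)
    best_i <- which.max(scores)
    best_order <- members[[best_i]]
    best_score <- scores[[best_i]]
    trace <- new_trace_row(0L, evals, best_score, scores,
                           length(unique(cl$cluster_of)))
    stall <- 0L
    for (it in seq_len(cfg$max_iteration)) {
      if (evals >= cfg$max_evals) break
      if (stats::runif(1L) < cfg$p_replace_center) {
        c_pick <- sample.int(m, 1L)
        idx <- cl$centers[[c_pick]]
        members[[idx]] <- sample(nodes)
        scores[[idx]] <- score1(members[[idx]])
      }
      sizes <- tabulate(cl$cluster_of, nbins = m)
      for (i in seq_len(cfg$pop_size)) {
        if (evals >= cfg$max_evals) break
        if (m == 1L || stats::runif(1L) < cfg$p_one_cluster) {
          c1 <- sample.int(m, 1L, prob = sizes)
          base <- if (stats::runif(1L) < cfg$p_use_center) {
            members[[cl$centers[[c1]]]]
          } else {
            members[[resample(which(cl$cluster_of == c1), 1L)]]
          }
        } else {
          cs <- sample.int(m, 2L, prob = sizes)
          base <- if (stats::runif(1L) < cfg$p_use_center_pair) {
            merge_orders(members[[cl$centers[[cs[[1L]]]]]],
                         members[[cl$centers[[cs[[2L]]]]]])
          } else {
            merge_orders(members[[resample(which(cl$cluster_of == cs[[1L]]), 1L)]],
                         members[[resample(which(cl$cluster_of == cs[[2L]]), 1L)]])
          }
        }
        cand <- perturb_order(base, step_size(cfg$max_iteration, it,
                                              cfg$slope_k))
        s <- score1(cand)
        if (s > scores[[i]]) {
          members[[i]] <- cand
          scores[[i]] <- s
        }
      }
      cl <- cluster_orders(members, scores, m)
      it_best <- which.max(scores)
      if (scores[[it_best]] > best_score) {
        best_score <- scores[[it_best]]
        best_order <- members[[it_best]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      trace <- rbind(trace, new_trace_row(it, evals, best_score, scores,
                                          length(unique(cl$cluster_of))))
      if (stall >= cfg$stall_limit) break
    }
    list(order = best_order, score = best_score, trace = trace,
         evaluations = evals)
  })
}

# sample() treats a length-1 numeric x as 1:x; this never does
resample <- function(x, size) x[sample.int(length(x), size)]

#' Random-restart order search
#'
#' Scores batches of uniformly random orders, tracking the best; terminates
#' once 10 consecutive batches fail to improve it (or the evaluation budget
#' runs out).
#'
#' @param data a \code{discrete_dataset}.
#' @param batch orders per batch.
#' @param max_parents in-degree cap.
#' @param seed integer seed.
#' @param max_evals optional evaluation cap.
#' @param cache optional shared \code{\link{score_cache}}.
#' @return list with \code{order}, \code{score}, \code{trace},
#'   \code{evaluations}.
#' @export
random_search <- function(data, batch = 20L, max_parents = 4L, seed = NULL,
                          max_evals = Inf, cache = score_cache()) {
  stopifnot(batch >= 1L)
  with_seed_(seed, {
    nodes <- data$columns
    evals <- 0L
    best_order <- NULL
    best_score <- -Inf
    no_improve <- 0L
    trace <- NULL
    it <- 0L
    while (no_improve < 10L && evals < max_evals) {
      it <- it + 1L
      improved <- FALSE
      for (dummy in seq_len(batch)) {
        if (evals >= max_evals) break
        ord <- sample(nodes)
        evals <- evals + 1L
        s <- score_order(data, ord, max_parents, cache)
        if (s > best_score) {
          best_score <- s
          best_order <- ord
          improved <- TRUE
        }
      }
      no_improve <- if (improved) 0L else no_improve + 1L
      row <- new_trace_row(it, evals, best_score, best_score, 1L)
      trace <- if (is.null(trace)) row else rbind(trace, row)
    }
    list(order = best_order, score = best_score, trace = trace,
         evaluations = evals)
  })
}

#' Genetic-algorithm order search
#'
#' Permutation GA baseline: tournament selection, order crossover (OX),
#' insertion mutation, and one-elite survival, so the best-so-far trace is
#' non-decreasing.
#'
#' @param data a \code{discrete_dataset}.
#' @param pop_size population size (>= 2).
#' @param generations number of generations (0 returns the best of the
#'   random initial population).
#' @param max_parents in-degree cap.
#' @param p_mutate per-child insertion-mutation probability.
#' @param seed integer seed.
#' @param max_evals optional evaluation cap.
#' @param cache optional shared \code{\link{score_cache}}.
#' @return list with \code{order}, \code{score}, \code{trace},
#'   \code{evaluations}.
#' @export
ga_search <- function(data, pop_size = 50L, generations = 100L,
                      max_parents = 4L, p_mutate = 0.2, seed = NULL,
                      max_evals = Inf, cache = score_cache()) {
  stopifnot(pop_size >= 2L, generations >= 0L)
  with_seed_(seed, {
    nodes <- data$columns
    evals <- 0L
    score1 <- function(ord) {
      evals <<- evals + 1L
      score_order(data, ord, max_parents, cache)
    }
    pop <- replicate(pop_size, sample(nodes), simplify = FALSE)
    scores <- vapply(pop, score1, 0)
    best_i <- which.max(scores)
    best_order <- pop[[best_i]]
    best_score <- scores[[best_i]]
    trace <- new_trace_row(0L, evals, best_score, scores, 1L)
    tournament <- function() {
      ij <- sample.int(pop_size, 2L)
      ij[[which.max(scores[ij])]]
    }
    for (g in seq_len(generations)) {
      if (evals >= max_evals) break
      new_pop <- list(best_order)        # elitism
      new_scores <- best_score
      while (length(new_pop) < pop_size && evals < max_evals) {
        p1 <- pop[[tournament()]]
        p2 <- pop[[tournament()]]
        child <- ox_crossover(p1, p2)
        if (stats::runif(1L) < p_mutate) child <- perturb_order(child, 0)
        new_pop[[length(new_pop) + 1L]] <- child
        new_scores <- c(new_scores, score1(child))
      }
      pop <- new_pop
      scores <- new_scores
      pop_size_eff <- length(pop)
      if (pop_size_eff < 2L) break
      pop_size <- pop_size_eff
      gi <- which.max(scores)
      if (scores[[gi]] > best_score) {
        best_score <- scores[[gi]]
        best_order <- pop[[gi]]
      }
      trace <- rbind(trace, new_trace_row(g, evals, best_score, scores, 1L))
      if (evals >= max_evals) break
    }
    list(order = best_order, score = best_score, trace = trace,
         evaluations = evals)
  })
}

# order crossover: keep a random slice of p1, fill the rest in p2's order
ox_crossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample.int(n, 2L))
  slice <- p1[cut[[1L]]:cut[[2L]]]
  rest <- p2[!p2 %in% slice]
  out <- character(n)
  out[cut[[1L]]:cut[[2L]]] <- slice
  out[-(cut[[1L]]:cut[[2L]])] <- rest
  out
}
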