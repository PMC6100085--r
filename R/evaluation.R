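# Structure-recovery metrics: recall, precision and F1 of an inferred graph
# against a ground-truth network, in directed or skeleton mode.

#' Recall / precision / F1 of structure recovery
#'
#' In \code{directed} mode edges are compared as ordered pairs and inferred
#' undirected edges earn no credit (strict reading of "inferred
#' directions"); in \code{skeleton} mode all edges are compared as unordered
#' pairs.  Recall is correct/actual, precision correct/inferred and
#' \eqn{F1 = 2RP/(R+P)}; empty denominators yield 0 with a warning.
#'
#' @param inferred a \code{pdag} (or \code{bn_network}).
#' @param truth a \code{bn_network} over the same node set.
#' @param mode \code{"directed"} or \code{"skeleton"}.
#' @return list with \code{recall}, \code{precision}, \code{f1},
#'   \code{n_inferred}, \code{n_actual}, \code{n_correct}, \code{mode}.
#' @export
score_structure <- function(inferred, truth, mode = c("directed", "skeleton")) {
  mode <- match.arg(mode)
  if (inherits(inferred, "bn_network")) inferred <- dag_to_pdag(inferred)
  if (!setequal(inferred$nodes, truth$nodes)) stop("node sets differ")
  true_edges <- network_edges(truth)
  if (mode == "directed") {
    inf_keys <- edge_key(inferred$directed, ordered = TRUE)
    true_keys <- edge_key(true_edges, ordered = TRUE)
  } else {
    inf_keys <- unique(c(edge_key(inferred$directed, ordered = FALSE),
                         edge_key(inferred$undirected, ordered = FALSE)))
    true_keys <- unique(edge_key(true_edges, ordered = FALSE))
  }
  n_inferred <- length(inf_keys)
  n_actual <- length(true_keys)
  n_correct <- length(intersect(inf_keys, true_keys))
  recall <- if (n_actual > 0L) n_correct / n_actual else {
    warning("no actual edges; recall set to 0"); 0
  }
  precision <- if (n_inferred > 0L) n_correct / n_inferred else {
    warning("no inferred edges; precision set to 0"); 0
  }
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  list(recall = recall, precision = precision, f1 = f1,
       n_inferred = n_inferred, n_actual = n_actual, n_correct = n_correct,
       mode = mode)
}

edge_key <- function(m, ordered) {
  if (is.null(m) || !nrow(m)) return(character(0))
  if (ordered) apply(m, 1L, paste, collapse = "\r") else pair_key(m)
}
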