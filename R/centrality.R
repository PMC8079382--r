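# Centrality measures computed from scratch: eigenvector centrality by power
# iteration on the weighted adjacency, Brandes node and edge betweenness (C++
# kernel), and degree/strength. Conventions follow the figures the measures
# feed: eigenvector and strength are max-scaled to 1; node betweenness is
# normalized by (n-1)(n-2)/2 and edge betweenness by n(n-1)/2, per connected
# component.

new_centrality_scores <- function(measure, node_scores = NULL,
                                  edge_scores = NULL, normalized = TRUE,
                                  params = list()) {
  structure(list(measure = measure, node_scores = node_scores,
                 edge_scores = edge_scores, normalized = normalized,
                 params = params),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("<centrality_scores> %s (%s)\n", x$measure,
              if (x$normalized) "normalized" else "raw"))
  sc <- x$node_scores %||% x$edge_scores
  if (!is.null(sc)) {
    top <- head(sort(sc, decreasing = TRUE), 5L)
    cat("  top:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

graph_components <- function(graph) {
  n <- graph_n_nodes(graph)
  ix <- edge_indices(graph)
  components_int(n, ix$i, ix$j)
}

#' Eigenvector centrality via power iteration
#'
#' Computes the leading eigenvector of the weighted adjacency matrix with a
#' strictly positive start vector, max-scaled so the top score is exactly 1.
#' The iteration runs on `A + cI` with a small diagonal shift
#' (`c = 0.1 * max strength`), which leaves the Perron vector unchanged but
#' guarantees convergence on bipartite components, whose extreme eigenvalues
#' come in +/- pairs. On disconnected graphs the measure is computed on the
#' largest connected component (ties broken by summed edge weight) and all
#' other nodes score 0, with a warning.
#'
#' @param graph a `hashtag_graph` with non-negative weights.
#' @param tolerance convergence threshold on the max absolute change of the
#'   max-scaled iterate.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param start optional positive start vector (named by hashtag or in node
#'   order); the converged scores do not depend on it.
#' @return a `centrality_scores` with `node_scores` named by hashtag.
#' @export
eigenvector_centrality <- function(graph, tolerance = 1e-10, max_iter = 1000L,
                                   start = NULL) {
  n <- graph_n_nodes(graph)
  if (n == 0L) stop_data("empty graph")
  if (any(graph$edges$weight < 0)) stop_data("negative edge weights")
  tags <- graph$nodes$hashtag
  if (nrow(graph$edges) == 0L) {
    warning("graph has no edges; eigenvector centrality undefined, returning 0s")
    return(new_centrality_scores("eigenvector",
                                 setNames(numeric(n), tags), normalized = TRUE,
                                 params = list(tolerance = tolerance)))
  }
  comp <- graph_components(graph)
  ix <- edge_indices(graph)
  comp_sizes <- tabulate(comp)
  if (max(comp) > 1L) {
    cand <- which(comp_sizes == max(comp_sizes))
    if (length(cand) > 1L) {
      wsum <- vapply(cand, function(cc)
        sum(graph$edges$weight[comp[ix$i] == cc]), numeric(1))
      cand <- cand[which.max(wsum)]
    }
    giant <- cand[[1L]]
    warning(sprintf(
      "graph is disconnected (%d components); eigenvector computed on the largest (%d nodes), others scored 0",
      max(comp), comp_sizes[[giant]]))
  } else giant <- 1L

  in_g <- comp == giant
  sub_id <- cumsum(in_g)
  keep_e <- in_g[ix$i]
  A <- Matrix::sparseMatrix(
    i = c(sub_id[ix$i[keep_e]], sub_id[ix$j[keep_e]]),
    j = c(sub_id[ix$j[keep_e]], sub_id[ix$i[keep_e]]),
    x = rep(graph$edges$weight[keep_e], 2L),
    dims = c(sum(in_g), sum(in_g))
  )
  ng <- sum(in_g)
  if (is.null(start)) {
    x <- rep(1, ng)
  } else {
    x <- if (!is.null(names(start))) unname(start[tags[in_g]]) else start[in_g]
    if (length(x) != ng || any(is.na(x)) || any(x <= 0))
      stop_config("start vector must be strictly positive over the giant component")
  }
  x <- x / max(x)
  shift <- 0.1 * max(Matrix::rowSums(A))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x) + shift * x
    x_new <- x_new / max(x_new)
    resid <- max(abs(x_new - x))
    x <- x_new
    if (resid < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    stop_data("power iteration did not converge in %d iterations (residual %.3g)",
              max_iter, resid)
  scores <- setNames(numeric(n), tags)
  scores[in_g] <- x
  new_centrality_scores("eigenvector", scores, normalized = TRUE,
                        params = list(tolerance = tolerance, max_iter = max_iter,
                                      iterations = it, shift = shift))
}

# shared driver for node/edge betweenness
run_brandes <- function(graph, mode) {
  n <- graph_n_nodes(graph)
  m <- nrow(graph$edges)
  ix <- edge_indices(graph)
  weighted <- mode == "inverse_weight"
  if (weighted && m > 0L && any(graph$edges$weight <= 0))
    stop_data("inverse_weight mode requires strictly positive edge weights")
  len <- if (weighted && m > 0L) 1 / graph$edges$weight else numeric(m)
  res <- brandes_cpp(n, ix$i - 1L, ix$j - 1L, as.numeric(len), weighted)
  res
}

#' Node betweenness centrality (Brandes)
#'
#' Counts, for every node, the (fractional) number of all-pairs shortest paths
#' passing through it, each unordered pair counted once and dependencies split
#' equally among multiple shortest paths. In `inverse_weight` mode (the
#' default) edge length is `1/weight`, so heavily co-occurring hashtag pairs
#' are close. Disconnected graphs are handled per component; normalization
#' divides by `(nc-1)(nc-2)/2` with `nc` the node's component size.
#'
#' @param graph a `hashtag_graph`.
#' @param mode `"inverse_weight"` or `"unweighted"`.
#' @param normalized return normalized scores (raw scores are kept in
#'   `params$raw`).
#' @return a `centrality_scores` with `node_scores` named by hashtag.
#' @export
betweenness_centrality <- function(graph, mode = c("inverse_weight", "unweighted"),
                                   normalized = TRUE) {
  mode <- match.arg(mode)
  n <- graph_n_nodes(graph)
  if (n == 0L) stop_data("empty graph")
  raw <- setNames(run_brandes(graph, mode)$node, graph$nodes$hashtag)
  comp <- graph_components(graph)
  nc <- tabulate(comp)[comp]
  denom <- ifelse(nc >= 3L, (nc - 1) * (nc - 2) / 2, 1)
  norm <- raw / denom
  new_centrality_scores("betweenness",
                        if (normalized) norm else raw,
                        normalized = normalized,
                        params = list(mode = mode, raw = raw,
                                      distance = if (mode == "inverse_weight")
                                        "1/weight" else "hops"))
}

#' Edge betweenness centrality (Brandes)
#'
#' Per-edge count of shortest paths over all unordered node pairs, endpoints
#' included, split equally among multiple shortest paths. Normalization
#' divides by `nc(nc-1)/2` pairs of the edge's component.
#'
#' @inheritParams betweenness_centrality
#' @return a `centrality_scores` with `edge_scores` named `"from|to"`.
#' @export
edge_betweenness <- function(graph, mode = c("inverse_weight", "unweighted"),
                             normalized = FALSE) {
  mode <- match.arg(mode)
  if (graph_n_nodes(graph) == 0L) stop_data("empty graph")
  raw <- run_brandes(graph, mode)$edge
  names(raw) <- paste(graph$edges$from, graph$edges$to, sep = "|")
  comp <- graph_components(graph)
  ix <- edge_indices(graph)
  nc <- tabulate(comp)[comp[ix$i]]
  denom <- ifelse(nc >= 2L, nc * (nc - 1) / 2, 1)
  norm <- raw / denom
  new_centrality_scores("edge_betweenness", edge_scores =
                          if (normalized) norm else raw,
                        normalized = normalized,
                        params = list(mode = mode, raw = raw))
}

#' Degree and strength (weighted degree)
#'
#' @param graph a `hashtag_graph`.
#' @return list of two `centrality_scores`: `degree` (incident edge count) and
#'   `strength` (incident weight sum), each with raw scores in `params$raw`
#'   and max-normalized `node_scores` (all 0 when the maximum is 0).
#' @export
degree_and_strength <- function(graph) {
  n <- graph_n_nodes(graph)
  tags <- graph$nodes$hashtag
  deg <- setNames(numeric(n), tags)
  str <- setNames(numeric(n), tags)
  if (nrow(graph$edges)) {
    ix <- edge_indices(graph)
    for (e in seq_len(nrow(graph$edges))) {
      deg[[ix$i[e]]] <- deg[[ix$i[e]]] + 1
      deg[[ix$j[e]]] <- deg[[ix$j[e]]] + 1
      str[[ix$i[e]]] <- str[[ix$i[e]]] + graph$edges$weight[[e]]
      str[[ix$j[e]]] <- str[[ix$j[e]]] + graph$edges$weight[[e]]
    }
  }
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  list(
    degree = new_centrality_scores("degree", norm(deg), normalized = TRUE,
                                   params = list(raw = deg)),
    strength = new_centrality_scores("strength", norm(str), normalized = TRUE,
                                     params = list(raw = str))
  )
}

#' Write centrality scores to CSV
#' @param scores a `centrality_scores` or list of them.
#' @param path output CSV (columns: name, measure, score, raw).
#' @return `path`, invisibly.
#' @export
write_centrality_csv <- function(scores, path) {
  if (inherits(scores, "centrality_scores")) scores <- list(scores)
  rows <- lapply(scores, function(sc) {
    v <- sc$node_scores %||% sc$edge_scores
    raw <- sc$params$raw %||% v
    data.frame(name = names(v), measure = sc$measure,
               score = unname(v), raw = unname(raw[names(v)]),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
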