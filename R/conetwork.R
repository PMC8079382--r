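# Per-area hashtag co-occurrence graphs.
#
# Nodes are hashtags weighted by post frequency; an edge's weight counts the
# retained posts containing both endpoint tags (binary per post, since posts
# carry hashtag *sets*). The analysis graph is restricted to the area's most
# frequent hashtags (150 by default, the count at which the selected tags
# co-occur with one another in >90% of the posts that contain any of them),
# with the ubiquitous query tag excluded.

new_hashtag_graph <- function(nodes, edges, area_name = "") {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, area_name = area_name),
            class = "hashtag_graph")
}

#' @export
print.hashtag_graph <- function(x, ...) {
  cat(sprintf("<hashtag_graph> '%s': %d nodes, %d edges\n",
              x$area_name, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_n_nodes <- function(g) nrow(g$nodes)

# edge endpoints as integer indices into g$nodes$hashtag
edge_indices <- function(g) {
  list(i = match(g$edges$from, g$nodes$hashtag),
       j = match(g$edges$to, g$nodes$hashtag))
}

#' Hashtag post-frequencies
#'
#' @param corpus a `corpus`.
#' @return named integer vector: number of posts whose hashtag set contains
#'   each tag (a tag counts once per post), sorted by tag.
#' @export
hashtag_frequencies <- function(corpus) {
  tags <- unlist(corpus$hashtags, use.names = FALSE)
  if (!length(tags)) return(setNames(integer(0), character(0)))
  tab <- table(tags)
  f <- setNames(as.integer(tab), names(tab))
  f[sort_c(names(f))]
}

#' Select the most frequent hashtags
#'
#' @param freqs named frequency vector from [hashtag_frequencies()].
#' @param n how many tags to keep (all if fewer exist).
#' @param exclude tags removed before ranking -- by default the query/area tag
#'   should be passed here, as it occurs in every post.
#' @return character vector of up to `n` tags, frequency-descending, ties
#'   broken lexicographically ascending.
#' @export
select_top_hashtags <- function(freqs, n = 150L, exclude = character(0)) {
  if (n < 1) stop_config("n must be >= 1")
  freqs <- freqs[!(names(freqs) %in% exclude)]
  if (!length(freqs)) return(character(0))
  ord <- order_c(-as.numeric(freqs), names(freqs))
  head(names(freqs)[ord], n)
}

#' Build the co-occurrence graph over selected hashtags
#'
#' For every post, every unordered pair of selected tags it contains
#' increments that pair's edge weight by exactly one. Zero-weight pairs are
#' absent; selected tags that never co-occur remain as degree-0 nodes.
#'
#' @param corpus a `corpus`.
#' @param selected non-empty character vector of hashtags.
#' @return a `hashtag_graph` with `nodes` (hashtag, frequency) and `edges`
#'   (from, to, weight; `from < to` lexicographically).
#' @export
build_cooccurrence_graph <- function(corpus, selected) {
  if (!length(selected)) stop_config("'selected' must be non-empty")
  selected <- unique(selected)
  freqs <- hashtag_frequencies(corpus)
  nodes <- data.frame(hashtag = sort_c(selected), stringsAsFactors = FALSE)
  nodes$frequency <- as.integer(freqs[nodes$hashtag])
  nodes$frequency[is.na(nodes$frequency)] <- 0L

  pair_from <- character(0); pair_to <- character(0)
  per_post <- lapply(corpus$hashtags, function(h) {
    h <- h[h %in% selected]
    if (length(h) < 2L) return(NULL)
    h <- sort_c(h)
    k <- length(h)
    # unordered pairs of the post's selected tags
    i <- rep.int(seq_len(k - 1L), rev(seq_len(k - 1L)))
    j <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k), use.names = FALSE)
    cbind(h[i], h[j])
  })
  per_post <- per_post[!vapply(per_post, is.null, logical(1))]
  if (length(per_post)) {
    mat <- do.call(rbind, per_post)
    key <- paste(mat[, 1], mat[, 2], sep = "\x1f")
    tab <- table(key)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      weight = as.numeric(tab),
      stringsAsFactors = FALSE
    )
    edges <- edges[order_c(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  new_hashtag_graph(nodes, edges, area_name(corpus) %||% "")
}

#' Add node strengths and max-normalized weights to a graph
#'
#' Node strength is the summed weight of incident edges (weighted degree);
#' normalized strength divides by the maximum strength and normalized edge
#' weight by the maximum weight, so each maximum is exactly 1. On an edgeless
#' graph all normalized values are 0 and a warning is emitted.
#'
#' @param graph a `hashtag_graph`.
#' @return the graph with `strength`/`normalized_strength` node columns and a
#'   `normalized_weight` edge column.
#' @export
normalize_strength <- function(graph) {
  n <- graph_n_nodes(graph)
  s <- numeric(n)
  if (nrow(graph$edges)) {
    ix <- edge_indices(graph)
    for (e in seq_len(nrow(graph$edges))) {
      w <- graph$edges$weight[[e]]
      s[[ix$i[e]]] <- s[[ix$i[e]]] + w
      s[[ix$j[e]]] <- s[[ix$j[e]]] + w
    }
    graph$nodes$strength <- s
    graph$nodes$normalized_strength <- s / max(s)
    graph$edges$normalized_weight <- graph$edges$weight / max(graph$edges$weight)
  } else {
    warning("graph has no edges; normalized strengths set to 0")
    graph$nodes$strength <- s
    graph$nodes$normalized_strength <- s
    graph$edges$normalized_weight <- numeric(0)
  }
  graph
}

#' Co-occurrence coverage of a hashtag selection
#'
#' The fraction of posts containing at least one selected tag that contain at
#' least two -- i.e. how often a selected tag occurs together with another
#' selected tag in the same post. The top-150 selection is motivated by this
#' fraction exceeding 0.9.
#'
#' @param corpus a `corpus`.
#' @param selected character vector of selected hashtags.
#' @return a proportion in \[0, 1\].
#' @export
cooccurrence_coverage <- function(corpus, selected) {
  if (!length(selected)) stop_config("'selected' must be non-empty")
  k <- vapply(corpus$hashtags, function(h) sum(h %in% selected), integer(1))
  denom <- sum(k >= 1L)
  if (denom == 0L)
    stop_data("no post contains any selected hashtag; coverage undefined")
  sum(k >= 2L) / denom
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Export a hashtag graph as GraphML
#'
#' Writes every node column (besides `hashtag`) as a node attribute and every
#' edge column (besides endpoints) as an edge attribute.
#'
#' @param graph a `hashtag_graph`.
#' @param path output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  node_attrs <- setdiff(names(graph$nodes), "hashtag")
  edge_attrs <- setdiff(names(graph$edges), c("from", "to"))
  attr_type <- function(v) if (is.numeric(v)) "double" else "string"
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, useBytes = TRUE)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  for (a in node_attrs)
    w('  <key id="n_%s" for="node" attr.name="%s" attr.type="%s"/>',
      a, a, attr_type(graph$nodes[[a]]))
  for (a in edge_attrs)
    w('  <key id="e_%s" for="edge" attr.name="%s" attr.type="%s"/>',
      a, a, attr_type(graph$edges[[a]]))
  w('  <graph id="%s" edgedefault="undirected">', xml_escape(graph$area_name))
  for (i in seq_len(nrow(graph$nodes))) {
    w('    <node id="%s">', xml_escape(graph$nodes$hashtag[[i]]))
    for (a in node_attrs)
      w('      <data key="n_%s">%s</data>', a,
        xml_escape(format(graph$nodes[[a]][[i]], scientific = FALSE, digits = 15)))
    w('    </node>')
  }
  for (e in seq_len(nrow(graph$edges))) {
    w('    <edge source="%s" target="%s">',
      xml_escape(graph$edges$from[[e]]), xml_escape(graph$edges$to[[e]]))
    for (a in edge_attrs)
      w('      <data key="e_%s">%s</data>', a,
        xml_escape(format(graph$edges[[a]][[e]], scientific = FALSE, digits = 15)))
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#' @param path a `.graphml` file.
#' @return a `hashtag_graph`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  key_map <- setNames(
    xml2::xml_attr(keys, "attr.name"),
    xml2::xml_attr(keys, "id")
  )
  key_type <- setNames(xml2::xml_attr(keys, "attr.type"),
                       xml2::xml_attr(keys, "id"))
  gnode <- xml2::xml_find_first(doc, ".//g:graph", ns)
  area <- xml2::xml_attr(gnode, "id") %||% ""

  read_data <- function(el) {
    d <- xml2::xml_find_all(el, "./g:data", ns)
    setNames(xml2::xml_text(d), xml2::xml_attr(d, "key"))
  }
  nodes_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(hashtag = xml2::xml_attr(nodes_xml, "id"),
                      stringsAsFactors = FALSE)
  edges_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(from = xml2::xml_attr(edges_xml, "source"),
                      to = xml2::xml_attr(edges_xml, "target"),
                      stringsAsFactors = FALSE)
  fill <- function(df, xml_list) {
    if (!length(xml_list)) return(df)
    datas <- lapply(xml_list, read_data)
    for (k in unique(unlist(lapply(datas, names)))) {
      vals <- vapply(datas, function(d) d[[k]] %||% NA_character_, character(1))
      nm <- key_map[[k]] %||% k
      df[[nm]] <- if (identical(key_type[[k]], "double")) as.numeric(vals) else vals
    }
    df
  }
  nodes <- fill(nodes, nodes_xml)
  edges <- fill(edges, edges_xml)
  if (!is.null(nodes$frequency)) nodes$frequency <- as.integer(nodes$frequency)
  if (is.null(edges$weight) && nrow(edges)) edges$weight <- 1
  if (!nrow(edges)) edges$weight <- numeric(0)
  # canonical edge orientation and order
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges <- edges[order_c(edges$from, edges$to), , drop = FALSE]
  }
  nodes <- nodes[order_c(nodes$hashtag), , drop = FALSE]
  new_hashtag_graph(nodes, edges, area)
}

#' Write a plain edge-list CSV (source, target, weight)
#' @param graph a `hashtag_graph`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  df <- data.frame(source = graph$edges$from, target = graph$edges$to,
                   weight = graph$edges$weight, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# construct a hashtag_graph directly from an edge table (test fixtures, merged
# networks); node frequencies default to strengths
graph_from_edges <- function(from, to, weight = 1, area_name = "",
                             frequency = NULL) {
  stopifnot(length(from) == length(to))
  weight <- rep_len(weight, length(from))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  if (any(from == to)) stop_data("self-loops are not allowed")
  key <- paste(from, to, sep = "\x1f")
  if (anyDuplicated(key)) stop_data("duplicate edges")
  ord <- order_c(from, to)
  edges <- data.frame(from = from[ord], to = to[ord], weight = weight[ord],
                      stringsAsFactors = FALSE)
  tags <- sort_c(unique(c(from, to)))
  nodes <- data.frame(hashtag = tags, stringsAsFactors = FALSE)
  if (is.null(frequency)) {
    s <- setNames(numeric(length(tags)), tags)
    for (e in seq_len(nrow(edges))) {
      s[[edges$from[[e]]]] <- s[[edges$from[[e]]]] + edges$weight[[e]]
      s[[edges$to[[e]]]] <- s[[edges$to[[e]]]] + edges$weight[[e]]
    }
    nodes$frequency <- as.integer(round(s))
  } else {
    nodes$frequency <- as.integer(frequency[tags])
  }
  new_hashtag_graph(nodes, edges, area_name)
}
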