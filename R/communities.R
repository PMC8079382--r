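# Fast-greedy (Clauset-Newman-Moore) modularity communities on the weighted
# co-occurrence graph, plus a lexicon layer that *suggests* cultural-
# ecosystem-services labels for each community. Label suggestion is advisory:
# the CES class names attached to real corpora come from human interpretation,
# and the shipped lexicon is an editable starting point, not a ground truth.

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c [ W_c/W - (S_c / 2W)^2 ]` with `W` the total edge weight, `W_c`
#' the intra-community weight and `S_c` the summed strength of community `c`.
#'
#' @param graph a `hashtag_graph` with at least one edge.
#' @param membership named vector (hashtag -> community id) covering every
#'   node of the graph.
#' @return the modularity, a real number `<= 1`.
#' @export
modularity_q <- function(graph, membership) {
  tags <- graph$nodes$hashtag
  if (!all(tags %in% names(membership)))
    stop_data("membership is missing %d node(s)",
              sum(!(tags %in% names(membership))))
  W <- sum(graph$edges$weight)
  if (W == 0) stop_data("graph has no edge weight; modularity undefined")
  mem <- membership[tags]
  comms <- unique(mem)
  ix <- edge_indices(graph)
  mi <- mem[ix$i]; mj <- mem[ix$j]
  s <- setNames(numeric(length(tags)), tags)
  for (e in seq_along(ix$i)) {
    s[[ix$i[e]]] <- s[[ix$i[e]]] + graph$edges$weight[[e]]
    s[[ix$j[e]]] <- s[[ix$j[e]]] + graph$edges$weight[[e]]
  }
  q <- 0
  for (cc in comms) {
    wc <- sum(graph$edges$weight[mi == cc & mj == cc])
    sc <- sum(s[mem == cc])
    q <- q + wc / W - (sc / (2 * W))^2
  }
  unname(q)
}

#' Fast-greedy (CNM) community detection
#'
#' Agglomerative modularity maximization on the weighted graph: start from
#' singleton communities and repeatedly merge the connected pair of
#' communities with the largest modularity increase, recording the merge
#' dendrogram and the modularity trace; the returned partition is the cut
#' maximizing Q. Ties between candidate merges are broken deterministically by
#' the lexicographically least hashtag of the would-be merged pair (then the
#' other side), so results are platform-independent. Disconnected graphs are
#' handled naturally (only connected pairs merge), yielding one dendrogram per
#' component; community indices are contiguous from 0, ordered by each
#' community's smallest hashtag.
#'
#' @param graph a `hashtag_graph` with at least one edge.
#' @param weighted use edge weights (default) or treat all edges as weight 1.
#' @param force_k optionally cut the dendrogram at `k` communities per run
#'   instead of at the modularity maximum (only reachable `k` are honoured).
#' @return a `community_partition`: `membership` (hashtag -> index from 0),
#'   `n_communities`, `modularity`, `dendrogram` (data.frame of merges with
#'   the modularity after each), `cut_index`.
#' @export
fast_greedy_communities <- function(graph, weighted = TRUE, force_k = NULL) {
  n <- graph_n_nodes(graph)
  if (n == 0L) stop_data("empty graph")
  tags <- graph$nodes$hashtag
  m <- nrow(graph$edges)
  if (m == 0L) stop_data("graph has no edges; communities undefined")
  wts <- if (weighted) graph$edges$weight else rep(1, m)
  ix <- edge_indices(graph)
  W <- sum(wts)

  # community state: B[i,j] = weight between communities i and j (i != j),
  # diag = intra weight; S = community strengths; min_tag for tie-breaks
  B <- matrix(0, n, n)
  for (e in seq_len(m)) {
    B[ix$i[e], ix$j[e]] <- B[ix$i[e], ix$j[e]] + wts[[e]]
    B[ix$j[e], ix$i[e]] <- B[ix$j[e], ix$i[e]] + wts[[e]]
  }
  S <- rowSums(B)
  active <- rep(TRUE, n)
  min_tag <- tags
  owner <- seq_len(n)            # node -> community slot
  q <- -sum((S / (2 * W))^2)     # singleton-partition modularity
  trace_q <- q
  best_q <- q
  best_step <- 0L
  merges <- list()

  snapshots <- list()            # owner vectors after each merge (for cuts)
  step <- 0L
  repeat {
    act <- which(active)
    if (length(act) <= 1L) break
    sub <- B[act, act, drop = FALSE]
    diag(sub) <- 0
    cand <- which(sub > 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (!nrow(cand)) break       # only disconnected communities remain
    ci <- act[cand[, 1]]; cj <- act[cand[, 2]]
    dq <- B[cbind(ci, cj)] / W - S[ci] * S[cj] / (2 * W^2)
    best <- which(dq >= max(dq) - 1e-14)
    if (length(best) > 1L) {
      lo <- pmin(min_tag[ci[best]], min_tag[cj[best]])
      hi <- pmax(min_tag[ci[best]], min_tag[cj[best]])
      pick <- best[order_c(lo, hi)[1L]]
    } else pick <- best
    a <- ci[[pick]]; b <- cj[[pick]]
    # merge b into a
    q <- q + dq[[pick]]
    step <- step + 1L
    merges[[step]] <- data.frame(a = min_tag[[a]], b = min_tag[[b]],
                                 modularity = q, stringsAsFactors = FALSE)
    B[a, ] <- B[a, ] + B[b, ]
    B[, a] <- B[, a] + B[, b]
    B[b, ] <- 0; B[, b] <- 0
    S[[a]] <- S[[a]] + S[[b]]
    active[[b]] <- FALSE
    min_tag[[a]] <- min(min_tag[[a]], min_tag[[b]])
    owner[owner == b] <- a
    snapshots[[step]] <- owner
    trace_q <- c(trace_q, q)
    if (q > best_q + 1e-14) { best_q <- q; best_step <- step }
  }

  cut <- best_step
  if (!is.null(force_k)) {
    ks <- c(n, n - seq_len(step))  # communities remaining after each merge
    hit <- which(ks == force_k)
    if (!length(hit))
      stop_config("force_k = %d is not reachable (graph yields %d..%d communities)",
                  force_k, min(ks), max(ks))
    cut <- hit[[1L]] - 1L
  }
  owner_cut <- if (cut == 0L) seq_len(n) else snapshots[[cut]]

  # contiguous indices from 0, ordered by each community's smallest hashtag
  reps <- vapply(unique(owner_cut), function(o) min(tags[owner_cut == o]),
                 character(1))
  ord <- unique(owner_cut)[order_c(reps)]
  membership <- setNames(match(owner_cut, ord) - 1L, tags)

  structure(list(
    membership = membership,
    n_communities = length(ord),
    modularity = if (cut == 0L) trace_q[[1L]] else merges[[cut]]$modularity,
    dendrogram = if (step) do.call(rbind, merges) else
      data.frame(a = character(0), b = character(0), modularity = numeric(0)),
    cut_index = cut,
    modularity_trace = trace_q
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f (cut %d of %d merges)\n",
              x$n_communities, x$modularity, x$cut_index, nrow(x$dendrogram)))
  invisible(x)
}

#' CES lexicon: class name -> cue hashtags
#' @param classes named list of character vectors; cue sets may overlap.
#' @return a `ces_lexicon`.
#' @export
ces_lexicon <- function(classes) {
  if (!length(classes) || is.null(names(classes)))
    stop_config("lexicon needs at least one named class")
  structure(lapply(classes, function(x) unique(normalize_one(x))),
            class = "ces_lexicon")
}

#' Read a CES lexicon from CSV (columns: class, tag)
#' @param path CSV file; defaults to the lexicon shipped with the package.
#' @return a `ces_lexicon`.
#' @export
read_ces_lexicon <- function(path = system.file("extdata", "ces_lexicon.csv",
                                                package = "tagnet")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "tag") %in% names(df)))
    stop_config("lexicon CSV must have columns 'class' and 'tag'")
  ces_lexicon(split(df$tag, df$class))
}

#' Suggest CES labels for communities
#'
#' Scores every community against every lexicon class by the fraction of its
#' member hashtags appearing in the class's cue set; classes are ranked by
#' score (ties alphabetically). Communities hitting no class are labelled
#' `"Other"`.
#'
#' @param partition a `community_partition`.
#' @param lexicon a [ces_lexicon()].
#' @return data.frame (community, label, score, rank) with all non-zero
#'   classes per community plus the `"Other"` fallback rows.
#' @export
suggest_ces_labels <- function(partition, lexicon) {
  if (!inherits(lexicon, "ces_lexicon")) lexicon <- ces_lexicon(lexicon)
  out <- list()
  for (cc in sort(unique(partition$membership))) {
    members <- names(partition$membership)[partition$membership == cc]
    sc <- vapply(lexicon, function(cues)
      sum(members %in% cues) / length(members), numeric(1))
    sc <- sc[sc > 0]
    if (!length(sc)) {
      out[[length(out) + 1L]] <- data.frame(
        community = cc, label = "Other", score = 0, rank = 1L,
        stringsAsFactors = FALSE)
    } else {
      ord <- order_c(-sc, names(sc))
      out[[length(out) + 1L]] <- data.frame(
        community = cc, label = names(sc)[ord], score = unname(sc[ord]),
        rank = seq_along(sc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
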