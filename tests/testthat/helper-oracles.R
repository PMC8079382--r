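# Independent oracles and fixtures for the test suite. Everything here is
# deliberately naive (Floyd-Warshall, explicit path counting, exact rational
# accumulation, dense eigendecomposition, exhaustive partition enumeration)
# and shares no code path with the package implementation.

# ---- tiny exact rational arithmetic ----------------------------------------
gcd2 <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }

frac <- function(num = 0, den = 1) c(num = num, den = den)

frac_add <- function(f, num, den) {
  n <- f[["num"]] * den + num * f[["den"]]
  d <- f[["den"]] * den
  g <- gcd2(abs(n), d)
  if (g > 1) { n <- n / g; d <- d / g }
  frac(n, d)
}

frac_value <- function(f) f[["num"]] / f[["den"]]

# ---- brute-force betweenness oracle ----------------------------------------
# graph: list(n, ei, ej, len) with 1-based endpoints; len in "distance" units
# (all 1 for unweighted). Returns exact node and edge betweenness (each
# unordered pair once; node scores exclude endpoints, edge scores include
# them), computed with rational arithmetic over integer path counts.
oracle_betweenness <- function(n, ei, ej, len) {
  tol_eq <- function(a, b) is.finite(a) & is.finite(b) &
    abs(a - b) <= 1e-12 * pmax(1, abs(b))
  D <- matrix(Inf, n, n); diag(D) <- 0
  L <- matrix(Inf, n, n)
  for (e in seq_along(ei)) {
    L[ei[e], ej[e]] <- L[ej[e], ei[e]] <- len[e]
    D[ei[e], ej[e]] <- D[ej[e], ei[e]] <- min(D[ei[e], ej[e]], len[e])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]

  # sigma[s, t]: number of shortest s-t paths, by DP over increasing distance
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(is.finite(L[, t]) & tol_eq(D[s, ] + L[, t], D[s, t]))
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }

  node <- numeric(n)
  for (v in seq_len(n)) {
    acc <- frac()
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (v == s || v == t || !is.finite(D[s, t])) next
      if (tol_eq(D[s, v] + D[v, t], D[s, t]) && sigma[s, v] * sigma[v, t] > 0)
        acc <- frac_add(acc, sigma[s, v] * sigma[v, t], sigma[s, t])
    }
    node[v] <- frac_value(acc)
  }
  edge <- numeric(length(ei))
  for (e in seq_along(ei)) {
    u <- ei[e]; v <- ej[e]; l <- len[e]
    acc <- frac()
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      through <- 0
      if (tol_eq(D[s, u] + l + D[v, t], D[s, t])) through <- through + sigma[s, u] * sigma[v, t]
      if (tol_eq(D[s, v] + l + D[u, t], D[s, t])) through <- through + sigma[s, v] * sigma[u, t]
      if (through > 0) acc <- frac_add(acc, through, sigma[s, t])
    }
    edge[e] <- frac_value(acc)
  }
  list(node = node, edge = edge)
}

# ---- dense eigenvector oracle ----------------------------------------------
oracle_eigenvector <- function(graph) {
  tags <- graph$nodes$hashtag
  n <- length(tags)
  A <- matrix(0, n, n, dimnames = list(tags, tags))
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[e]; j <- graph$edges$to[e]
    A[i, j] <- A[j, i] <- graph$edges$weight[e]
  }
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  setNames(v / max(v), tags)
}

# ---- exhaustive modularity maximum (set partitions via restricted growth) --
all_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    k <- length(rgs)
    if (k == n) { out[[length(out) + 1L]] <<- rgs; return(invisible()) }
    for (v in 0:(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(integer(0), -1L)
  out
}

oracle_best_modularity <- function(graph) {
  n <- nrow(graph$nodes)
  stopifnot(n <= 8)
  tags <- graph$nodes$hashtag
  best <- -Inf; best_p <- NULL
  for (p in all_partitions(n)) {
    q <- modularity_q(graph, setNames(p, tags))
    if (q > best + 1e-12) { best <- q; best_p <- p }
  }
  list(q = best, membership = setNames(best_p, tags))
}

# ---- graph fixtures ---------------------------------------------------------
path_graph <- function(tags, weights = 1) {
  tagnet:::graph_from_edges(tags[-length(tags)], tags[-1], weights)
}

star_graph <- function() tagnet:::graph_from_edges(rep("c", 3), c("l1", "l2", "l3"))

# two unit-weight K3 cliques joined by one unit bridge (a1a2a3 | b1b2b3)
two_clique_bridge <- function() {
  tagnet:::graph_from_edges(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    weight = 1
  )
}

# Erdos-Renyi G(n, p), resampled until connected; deterministic in seed
random_connected_er <- function(n, p, seed, weights = FALSE) {
  for (attempt in 1:200) {
    set.seed(seed * 1000 + attempt)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    ei <- pairs[keep, 1]; ej <- pairs[keep, 2]
    if (max(tagnet:::components_int(n, ei, ej)) != 1L) next
    w <- if (weights) sample(1:5, length(ei), TRUE) else rep(1, length(ei))
    tags <- sprintf("v%02d", seq_len(n))
    return(tagnet:::graph_from_edges(tags[ei], tags[ej], w))
  }
  stop("could not generate a connected ER graph")
}

# planted topic of a generated topic-vocabulary tag, NA for shared tags
planted_topic <- function(tags) {
  m <- regmatches(tags, regexec("^area[0-9]+_topic([0-9]+)_w[0-9]+$", tags))
  vapply(m, function(x) if (length(x) == 2) as.integer(x[2]) else NA_integer_,
         integer(1))
}

# tiny deterministic corpus from explicit hashtag sets
corpus_from_sets <- function(sets, users = NULL, times = NULL) {
  n <- length(sets)
  df <- data.frame(
    post_id = sprintf("p%03d", seq_len(n)),
    user_id = users %||% sprintf("u%03d", seq_len(n)),
    timestamp = times %||% format(
      as.POSIXct("2019-06-01", tz = "UTC") + 3600 * seq_len(n),
      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  df$hashtags <- lapply(sets, function(s) sort(unique(tolower(s))))
  df$truth_label <- rep(NA_character_, n)
  df$truth_topic <- rep(NA_integer_, n)
  tagnet:::new_corpus(df, "testarea", list(kind = "file", path = "<memory>"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# checksums of every file under a directory, keyed by relative path
dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(unname(tools::md5sum(files)),
           sub(paste0("^", dir, "/"), "", files))
}
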