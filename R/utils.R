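#' @useDynLib tagnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent sort: byte order, so output files reproduce across machines
sort_c <- function(x, decreasing = FALSE) {
  if (length(x) == 0L) return(x)
  sort(x, decreasing = decreasing, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

stop_config <- function(fmt, ...) {
  stop(structure(
    class = c("tagnet_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_data <- function(fmt, ...) {
  stop(structure(
    class = c("tagnet_data_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# connected components of an undirected graph given as an edge list over
# nodes 1..n; returns an integer membership vector (components numbered from 1
# in order of their smallest node index)
components_int <- function(n, ei, ej) {
  adj <- vector("list", n)
  if (length(ei)) {
    adj_from <- split(c(ej, ei), c(ei, ej))
    idx <- as.integer(names(adj_from))
    adj[idx] <- adj_from
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Normalized mutual information between two partitions
#'
#' Compares two labelings of the same items, e.g. detected communities against
#' a planted ground truth. Uses the standard `2 I(X;Y) / (H(X) + H(Y))`
#' normalization; two identical partitions score 1, independent ones 0. When
#' both partitions are trivial (a single block each) the score is defined as 1.
#'
#' @param a,b vectors of equal length giving the two labelings.
#' @return a number in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop_data("partitions differ in length")
  n <- length(a)
  if (n == 0L) stop_data("empty partitions")
  tab <- table(a, b)
  joint <- tab / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}
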