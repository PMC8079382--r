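# Corpus cleaning: bot detection, blocklist discards, synonym/misspelling
# merging, and the discard accounting report.
#
# Three detector families target automated posts. The graph-based detector
# (near-duplicate hashtag sets, Jaccard similarity join, connected-component
# clustering) is the workhorse and runs by default; the anomaly (per-user
# volume) and time-series (per-user burstiness) detectors are optional
# complements. Posts containing blocklisted hashtags or authored by
# blocklisted users are discarded, spelling variants are merged onto canonical
# tags, and the report warns when more than 25% of the input is discarded --
# the ceiling observed for real corpora of this kind.

#' Synonym map: variant spelling -> canonical hashtag
#'
#' @param entries named character vector, `names(entries)` are the variant
#'   spellings and the values their canonical tags. The map must be idempotent:
#'   no canonical tag may itself appear as a variant key.
#' @return a `synonym_map`.
#' @export
synonym_map <- function(entries = character(0)) {
  entries <- unlist(entries)
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop_config("synonym map entries must be named (variant -> canonical)")
    bad <- intersect(unname(entries), names(entries))
    if (length(bad))
      stop_config("synonym map is not idempotent: canonical tag(s) %s are also variant keys",
                  paste(bad, collapse = ", "))
  }
  structure(as.character(entries) |> setNames(names(entries)),
            class = "synonym_map")
}

#' Read a synonym map from a two-column CSV (variant, canonical)
#' @param path CSV file with columns `variant`, `canonical`.
#' @return a `synonym_map`.
#' @export
read_synonym_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "canonical") %in% names(df)))
    stop_config("synonym CSV must have columns 'variant' and 'canonical'")
  synonym_map(setNames(normalize_one(df$canonical), normalize_one(df$variant)))
}

normalize_one <- function(x) sub("^#+", "", tolower(trimws(as.character(x))))

#' Blocklist of banned hashtags and users
#' @param hashtags banned hashtags (posts containing any are discarded).
#' @param users banned user ids (all their posts are discarded).
#' @return a `blocklist`.
#' @export
blocklist <- function(hashtags = character(0), users = character(0)) {
  hashtags <- normalize_one(hashtags)
  users <- trimws(as.character(users))
  if (any(!nzchar(hashtags)) || any(!nzchar(users)))
    stop_config("blocklist entries must be non-empty strings")
  structure(list(banned_hashtags = unique(hashtags),
                 banned_users = unique(users)),
            class = "blocklist")
}

#' Read a blocklist from plain text (one entry per line, `user:` prefix for users)
#' @param path text file; lines starting `user:` ban a user id, others a hashtag.
#' @return a `blocklist`.
#' @export
read_blocklist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#!")]
  is_user <- startsWith(lines, "user:")
  blocklist(hashtags = lines[!is_user],
            users = sub("^user:", "", lines[is_user]))
}

#' Detect automated (bot) posts
#'
#' Runs up to three detectors and returns the union of their flags:
#' \describe{
#'   \item{graph}{links posts whose hashtag-set Jaccard similarity is at least
#'     `jaccard_threshold`; connected components with at least `min_cluster`
#'     posts are flagged. Sufficient alone for template-replicating bots.}
#'   \item{anomaly}{flags wholesale every user whose total post count exceeds
#'     `mean + rate_zscore * sd` over users.}
#'   \item{timeseries}{flags users with any `rate_window`-second window
#'     containing more posts than `mean + rate_zscore * sd` of their own
#'     windowed counts.}
#' }
#'
#' @param corpus a `corpus`.
#' @param jaccard_threshold similarity threshold in (0, 1].
#' @param min_cluster minimum near-duplicate cluster size to flag (>= 2).
#' @param detectors subset of `c("graph", "anomaly", "timeseries")`.
#' @param rate_window window length in seconds for the time-series detector.
#' @param rate_zscore z-score threshold for the anomaly/time-series detectors.
#' @return list with `flagged` (post ids) and `per_detector_counts`.
#' @export
detect_automated_posts <- function(corpus,
                                   jaccard_threshold = 0.65,
                                   min_cluster = 3L,
                                   detectors = "graph",
                                   rate_window = 3600,
                                   rate_zscore = 3) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1)
    stop_config("jaccard_threshold must be in (0, 1]")
  if (min_cluster < 2) stop_config("min_cluster must be >= 2")
  detectors <- match.arg(detectors, c("graph", "anomaly", "timeseries"),
                         several.ok = TRUE)
  counts <- setNames(integer(3), c("graph", "anomaly", "timeseries"))
  if (nrow(corpus) == 0L)
    return(list(flagged = character(0), per_detector_counts = as.list(counts)))

  flagged <- character(0)
  if ("graph" %in% detectors) {
    f <- flag_near_duplicates(corpus$hashtags, jaccard_threshold, min_cluster)
    counts[["graph"]] <- sum(f)
    flagged <- union(flagged, corpus$post_id[f])
  }
  if ("anomaly" %in% detectors) {
    per_user <- table(corpus$user_id)
    if (length(per_user) >= 2L) {
      thr <- mean(per_user) + rate_zscore * sd(per_user)
      bad_users <- names(per_user)[per_user > thr]
      f <- corpus$user_id %in% bad_users
      counts[["anomaly"]] <- sum(f)
      flagged <- union(flagged, corpus$post_id[f])
    }
  }
  if ("timeseries" %in% detectors) {
    ts <- as.numeric(as.POSIXct(corpus$timestamp, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"))
    ok <- !is.na(ts)
    if (any(ok)) {
      lo <- min(ts[ok]); hi <- max(ts[ok])
      nbin <- max(2L, ceiling((hi - lo + 1) / rate_window))
      bin <- pmin(nbin, 1L + floor((ts - lo) / rate_window))
      bad_users <- character(0)
      for (u in unique(corpus$user_id[ok])) {
        b <- bin[ok & corpus$user_id == u]
        cnt <- tabulate(b, nbins = nbin)
        if (sd(cnt) > 0 && max(cnt) > mean(cnt) + rate_zscore * sd(cnt))
          bad_users <- c(bad_users, u)
      }
      f <- corpus$user_id %in% bad_users
      counts[["timeseries"]] <- sum(f)
      flagged <- union(flagged, corpus$post_id[f])
    }
  }
  list(flagged = sort_c(flagged), per_detector_counts = as.list(counts))
}

# Exact Jaccard similarity join with near-duplicate clustering.
#
# Identical hashtag sets are collapsed first (bot posts are mostly verbatim
# template copies), then candidate pairs among the unique sets come from
# prefix filtering: with tags ordered by ascending document frequency, a set A
# with J(A,B) >= t must share >= ceil(t*|A|) tags with B, so A's first
# |A| - ceil(t*|A|) + 1 rarest tags must hit B. This keeps the join linear in
# practice (the ubiquitous query tag never enters a prefix) while remaining
# exact. Components of the >= threshold similarity graph whose total post
# multiplicity reaches min_cluster are flagged.
flag_near_duplicates <- function(hashtag_sets, threshold, min_cluster) {
  n <- length(hashtag_sets)
  if (n == 0L) return(logical(0))
  sig <- vapply(hashtag_sets, paste, character(1), collapse = "\x1f")
  uid <- match(sig, unique(sig))
  usets <- hashtag_sets[!duplicated(sig)]
  u <- length(usets)
  mult <- tabulate(uid, u)
  sizes <- lengths(usets)

  all_tags <- unlist(usets, use.names = FALSE)
  if (!length(all_tags)) return(logical(n))
  vocab <- unique(all_tags)
  tid <- match(all_tags, vocab)
  dfreq <- tabulate(tid, length(vocab))
  # global tag order: rarest first, ties by tag name, for the prefix theorem
  tag_rank <- integer(length(vocab))
  tag_rank[order_c(dfreq, vocab)] <- seq_along(vocab)

  row_id <- rep.int(seq_len(u), sizes)
  prefix_len <- pmax(1L, sizes - ceiling(threshold * sizes) + 1L)
  # mark, within each set, the prefix_len lowest-ranked tags
  ord <- order_c(row_id, tag_rank[tid])
  pos_in_set <- sequence(sizes)
  in_prefix <- logical(length(tid))
  in_prefix[ord] <- pos_in_set <= prefix_len[row_id[ord]]

  M <- Matrix::sparseMatrix(i = row_id, j = tid, x = 1,
                            dims = c(u, length(vocab)))
  P <- Matrix::sparseMatrix(i = row_id[in_prefix], j = tid[in_prefix], x = 1,
                            dims = c(u, length(vocab)))
  cand <- Matrix::tcrossprod(P, M)        # prefix-of-i hits full set of j
  cand <- cand + Matrix::t(cand)
  idx <- Matrix::summary(Matrix::triu(cand, k = 1))
  edges_i <- integer(0); edges_j <- integer(0)
  if (nrow(idx)) {
    inter <- mapply(function(a, b)
      length(intersect(usets[[a]], usets[[b]])), idx$i, idx$j)
    jac <- inter / (sizes[idx$i] + sizes[idx$j] - inter)
    keep <- jac >= threshold
    edges_i <- idx$i[keep]; edges_j <- idx$j[keep]
  }
  comp <- components_int(u, edges_i, edges_j)
  comp_weight <- vapply(seq_len(max(comp)), function(cc)
    sum(mult[comp == cc]), numeric(1))
  # a component is a bot cluster when it holds >= min_cluster posts in total;
  # a single unique set repeated min_cluster times qualifies (Jaccard 1)
  flagged_u <- comp_weight[comp] >= min_cluster &
    (mult > 1L | tabulate(c(edges_i, edges_j), u) > 0L)
  flagged_u[uid]
}

#' Remove blocklisted posts
#' @param corpus a `corpus`.
#' @param bl a [blocklist()].
#' @return list with the filtered `corpus` and `n_removed`.
#' @export
apply_blocklist <- function(corpus, bl) {
  stopifnot(inherits(bl, "blocklist"))
  hit_tag <- vapply(corpus$hashtags, function(h)
    any(h %in% bl$banned_hashtags), logical(1))
  hit_user <- corpus$user_id %in% bl$banned_users
  keep <- !(hit_tag | hit_user)
  out <- new_corpus(corpus[keep, , drop = FALSE], attr(corpus, "area_name"),
                    attr(corpus, "provenance"))
  list(corpus = out, n_removed = sum(!keep))
}

#' Merge synonym and misspelling variants onto canonical hashtags
#' @param corpus a `corpus`.
#' @param map a [synonym_map()].
#' @return the corpus with every variant replaced by its canonical tag and
#'   post hashtag sets re-deduplicated.
#' @export
apply_synonym_map <- function(corpus, map) {
  if (!inherits(map, "synonym_map")) map <- synonym_map(map)
  if (!length(map)) return(corpus)
  corpus$hashtags <- lapply(corpus$hashtags, function(h) {
    m <- match(h, names(map))
    h[!is.na(m)] <- unname(map)[m[!is.na(m)]]
    sort_c(unique(h))
  })
  corpus
}

#' Clean a corpus end to end
#'
#' Pipeline order: normalize hashtags, detect automated posts, apply the
#' blocklist, merge synonyms. The report conserves counts
#' (`n_retained + n_flagged_bot + n_flagged_blocklist = n_input`) and appends
#' a warning when the discard fraction exceeds 0.25, the ceiling observed on
#' real corpora of this kind.
#'
#' @param corpus a `corpus`.
#' @param bl a [blocklist()] (default: empty).
#' @param map a [synonym_map()] (default: empty).
#' @param jaccard_threshold,min_cluster,detectors,rate_window,rate_zscore
#'   passed to [detect_automated_posts()].
#' @param discard_warn_fraction warning threshold on the discard fraction.
#' @return list with the cleaned `corpus` and a `report` list
#'   (`n_input`, `n_flagged_bot`, `n_flagged_blocklist`, `n_retained`,
#'   `discard_fraction`, `per_detector_counts`, `warnings`).
#' @export
clean_corpus <- function(corpus, bl = blocklist(), map = synonym_map(),
                         jaccard_threshold = 0.65, min_cluster = 3L,
                         detectors = "graph", rate_window = 3600,
                         rate_zscore = 3, discard_warn_fraction = 0.25) {
  corpus$hashtags <- lapply(corpus$hashtags, normalize_tags)
  n_input <- nrow(corpus)

  det <- detect_automated_posts(corpus, jaccard_threshold, min_cluster,
                                detectors, rate_window, rate_zscore)
  keep <- !(corpus$post_id %in% det$flagged)
  corpus2 <- new_corpus(corpus[keep, , drop = FALSE],
                        attr(corpus, "area_name"), attr(corpus, "provenance"))
  blres <- apply_blocklist(corpus2, bl)
  cleaned <- apply_synonym_map(blres$corpus, map)

  n_bot <- length(det$flagged)
  n_block <- blres$n_removed
  n_retained <- nrow(cleaned)
  discard_fraction <- if (n_input > 0) 1 - n_retained / n_input else 0
  warnings <- character(0)
  if (discard_fraction > discard_warn_fraction)
    warnings <- sprintf(
      "discard fraction %.3f exceeds %.2f, above the ceiling observed for corpora of this kind",
      discard_fraction, discard_warn_fraction)
  report <- list(
    n_input = n_input, n_flagged_bot = n_bot, n_flagged_blocklist = n_block,
    n_retained = n_retained, discard_fraction = discard_fraction,
    per_detector_counts = det$per_detector_counts, warnings = warnings
  )
  stopifnot(n_retained + n_bot + n_block == n_input)
  list(corpus = cleaned, report = report)
}
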