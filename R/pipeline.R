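# End-to-end orchestration: simulate/load -> clean -> network -> centrality
# -> communities -> merge, from a single configuration, with a manifest that
# makes every run reproducible byte for byte.

#' Pipeline configuration
#'
#' @param areas list of area sources: each either a [generator_config()]
#'   (synthetic; the area index is its position) or a list
#'   `list(path = ..., format = ...)` for a corpus file.
#' @param top_hashtags hashtags retained per area (default 150).
#' @param top_pairs pairs retained in the merged network (default 1400).
#' @param blocklist_path,synonym_path optional cleaning input files.
#' @param lexicon_path CES lexicon CSV; defaults to the shipped lexicon.
#' @param jaccard_threshold,min_cluster,detectors bot-detector parameters,
#'   see [detect_automated_posts()].
#' @param eigen_tolerance,eigen_max_iter eigenvector iteration controls.
#' @param betweenness_mode shortest-path convention for betweenness.
#' @param out_dir output directory.
#' @param seed integer seed overriding any generator seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(areas,
                            top_hashtags = 150L,
                            top_pairs = 1400L,
                            blocklist_path = NULL,
                            synonym_path = NULL,
                            lexicon_path = NULL,
                            jaccard_threshold = 0.65,
                            min_cluster = 3L,
                            detectors = "graph",
                            eigen_tolerance = 1e-10,
                            eigen_max_iter = 2000L,
                            betweenness_mode = "inverse_weight",
                            out_dir = NULL,
                            seed = 1L) {
  if (!length(areas)) stop_config("at least one area is required")
  if (top_hashtags < 1 || top_pairs < 1)
    stop_config("top_hashtags and top_pairs must be >= 1")
  for (p in c(blocklist_path, synonym_path))
    if (!is.null(p) && !file.exists(p))
      stop_config("configured path does not exist: %s", p)
  lexicon_path <- lexicon_path %||%
    system.file("extdata", "ces_lexicon.csv", package = "tagnet")
  if (!file.exists(lexicon_path))
    stop_config("lexicon path does not exist: %s", lexicon_path)
  structure(list(
    areas = areas, top_hashtags = as.integer(top_hashtags),
    top_pairs = as.integer(top_pairs),
    blocklist_path = blocklist_path, synonym_path = synonym_path,
    lexicon_path = lexicon_path,
    jaccard_threshold = jaccard_threshold, min_cluster = as.integer(min_cluster),
    detectors = detectors, eigen_tolerance = eigen_tolerance,
    eigen_max_iter = as.integer(eigen_max_iter),
    betweenness_mode = betweenness_mode,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# canonical JSON of the analysis parameters; out_dir is where a run lands,
# not what it computes, so it stays out of the manifest
config_json <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  as.character(jsonlite::toJSON(strip(cfg), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

load_area_corpus <- function(config, idx) {
  src <- config$areas[[idx]]
  if (inherits(src, "generator_config")) {
    src$seed <- config$seed
    generate_corpus(src, idx)
  } else if (is.list(src) && !is.null(src$path)) {
    read_corpus(src$path, format = src$format %||% "jsonl",
                area_name = src$area_name %||% NULL)
  } else stop_config("area %d is neither a generator_config nor a file source", idx)
}

#' Run the full per-area analysis
#'
#' Stage order: load/simulate, clean, select top hashtags, build and
#' normalize the co-occurrence graph, centralities (eigenvector, betweenness,
#' edge betweenness, degree/strength), fast-greedy communities, CES label
#' suggestions. All artefacts are written under `out_dir/<area>/` together
#' with a manifest carrying the full configuration and seed; identical
#' configurations reproduce identical files.
#'
#' @param config a [pipeline_config()].
#' @param idx area position in `config$areas`.
#' @param write write artefacts to disk (set `FALSE` to only return them).
#' @return list: `corpus`, `report`, `graph`, `centrality` (list of 4),
#'   `partition`, `ces_labels`, `coverage`, `selected`.
#' @export
run_area <- function(config, idx, write = !is.null(config$out_dir)) {
  stopifnot(inherits(config, "pipeline_config"))
  bl <- if (!is.null(config$blocklist_path)) read_blocklist(config$blocklist_path)
        else blocklist()
  sm <- if (!is.null(config$synonym_path)) read_synonym_map(config$synonym_path)
        else synonym_map()
  lex <- read_ces_lexicon(config$lexicon_path)

  corpus <- load_area_corpus(config, idx)
  if (nrow(corpus) < 1000)
    warning(sprintf("area '%s' has %d posts, below the 1000-post floor real corpora respected",
                    area_name(corpus), nrow(corpus)))
  cl <- clean_corpus(corpus, bl, sm,
                     jaccard_threshold = config$jaccard_threshold,
                     min_cluster = config$min_cluster,
                     detectors = config$detectors)
  cleaned <- cl$corpus
  freqs <- hashtag_frequencies(cleaned)
  selected <- select_top_hashtags(freqs, config$top_hashtags,
                                  exclude = area_name(cleaned))
  if (!length(selected)) stop_data("area '%s': no hashtags to select", area_name(cleaned))
  graph <- build_cooccurrence_graph(cleaned, selected)
  graph <- normalize_strength(graph)
  coverage <- cooccurrence_coverage(cleaned, selected)

  eig <- eigenvector_centrality(graph, tolerance = config$eigen_tolerance,
                                max_iter = config$eigen_max_iter)
  btw <- betweenness_centrality(graph, mode = config$betweenness_mode)
  ebtw <- edge_betweenness(graph, mode = config$betweenness_mode)
  ds <- degree_and_strength(graph)
  partition <- fast_greedy_communities(graph)
  labels <- suggest_ces_labels(partition, lex)

  out <- list(corpus = cleaned, report = cl$report, graph = graph,
              centrality = list(eigenvector = eig, betweenness = btw,
                                edge_betweenness = ebtw, strength = ds$strength),
              partition = partition, ces_labels = labels,
              coverage = coverage, selected = selected)
  if (write) write_area_outputs(config, idx, out)
  out
}

write_area_outputs <- function(config, idx, out) {
  area <- area_name(out$corpus)
  dir <- file.path(config$out_dir, area)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(out$corpus, file.path(dir, "corpus_clean.jsonl"))
  jsonlite::write_json(out$report, file.path(dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA)
  # merge centrality and community attributes into the exported graph
  g <- out$graph
  g$nodes$eigenvector <- unname(out$centrality$eigenvector$node_scores[g$nodes$hashtag])
  g$nodes$betweenness <- unname(out$centrality$betweenness$node_scores[g$nodes$hashtag])
  g$nodes$community <- unname(out$partition$membership[g$nodes$hashtag])
  ekey <- paste(g$edges$from, g$edges$to, sep = "|")
  g$edges$edge_betweenness <- unname(out$centrality$edge_betweenness$edge_scores[ekey])
  write_graphml(g, file.path(dir, "network.graphml"))
  write_edgelist(g, file.path(dir, "edges.csv"))
  write_centrality_csv(out$centrality, file.path(dir, "centrality.csv"))
  mem <- out$partition$membership
  top_label <- vapply(unname(mem), function(cc) {
    rows <- out$ces_labels[out$ces_labels$community == cc, ]
    rows$label[[1L]]
  }, character(1))
  top_score <- vapply(unname(mem), function(cc) {
    rows <- out$ces_labels[out$ces_labels$community == cc, ]
    rows$score[[1L]]
  }, numeric(1))
  write.csv(data.frame(hashtag = names(mem), community = unname(mem),
                       ces_label = top_label, ces_score = top_score,
                       stringsAsFactors = FALSE),
            file.path(dir, "communities.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(merges = out$partition$dendrogram,
         modularity = out$partition$modularity,
         cut_index = out$partition$cut_index),
    file.path(dir, "dendrogram.json"), digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tagnet")),
    area = area, area_index = idx, seed = config$seed,
    config = config_json(config),
    stages = c("load", "clean", "select", "network", "centrality",
               "communities", "labels")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run every area and the merged-network analysis
#'
#' @param config a [pipeline_config()].
#' @param bridge_k bridge hashtags to report for the merged network.
#' @return list: `areas` (per-area outputs of [run_area()]), `merged`
#'   (a `merged_graph`), `merged_eigenvector`, `bridges`, `summary`
#'   (one row per area: posts retained, discard fraction, nodes, edges,
#'   coverage, communities, modularity, top-5 eigenvector hashtags).
#' @export
run_all <- function(config, bridge_k = 20L) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- lapply(seq_along(config$areas), function(i) run_area(config, i))
  graphs <- lapply(res, `[[`, "graph")
  merged <- select_top_pairs(merge_pair_counts(graphs), config$top_pairs)
  meig <- merged_eigenvector(merged, tolerance = config$eigen_tolerance,
                             max_iter = config$eigen_max_iter)
  bridges <- bridge_hashtags(merged, k = bridge_k,
                             mode = config$betweenness_mode)
  summary <- do.call(rbind, lapply(res, function(r) {
    top5 <- names(sort(r$centrality$eigenvector$node_scores, decreasing = TRUE))[1:5]
    data.frame(
      area = area_name(r$corpus),
      n_retained = r$report$n_retained,
      discard_fraction = r$report$discard_fraction,
      n_nodes = nrow(r$graph$nodes), n_edges = nrow(r$graph$edges),
      coverage = r$coverage,
      n_communities = r$partition$n_communities,
      modularity = r$partition$modularity,
      top_eigenvector = paste(top5, collapse = "|"),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    mg <- merged$graph
    mg$nodes$eigenvector <- unname(meig$node_scores[mg$nodes$hashtag])
    mg$nodes$areas <- vapply(merged$area_tags[mg$nodes$hashtag],
                             paste, character(1), collapse = "|")
    write_graphml(mg, file.path(config$out_dir, "merged.graphml"))
    write.csv(bridges, file.path(config$out_dir, "bridges.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(coverage = merged$coverage,
                              n_pairs = merged$n_pairs),
                         file.path(config$out_dir, "merged_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(areas = res, merged = merged, merged_eigenvector = meig,
       bridges = bridges, summary = summary)
}
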