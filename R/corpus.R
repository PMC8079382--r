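# Corpus container and the synthetic corpus generator.
#
# A corpus is a data.frame with one row per post (post_id, user_id, timestamp,
# hashtags list-column, truth_label, truth_topic) plus area_name / provenance
# attributes. Synthetic corpora carry planted ground truth (topic structure,
# bot/ad labels) so that downstream detectors and community recovery can be
# scored; file-loaded corpora have NA truth columns.

new_corpus <- function(df, area_name, provenance) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  structure(df, area_name = area_name, provenance = provenance,
            class = c("corpus", "data.frame"))
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> area '%s': %d posts, %d distinct hashtags\n",
              attr(x, "area_name"), nrow(x),
              length(unique(unlist(x$hashtags)))))
  if (!all(is.na(x$truth_label))) {
    tab <- table(x$truth_label)
    cat("  truth labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

area_name <- function(corpus) attr(corpus, "area_name")

# curated shared vocabulary head: the global travel/nature/photo tags that
# recur across areas; padded with generic tags up to the configured size
shared_vocab_base <- c(
  "travel", "nature", "photo", "travelphotography", "wanderlust", "adventure",
  "instatravel", "travelgram", "igtravel", "photography", "wildlife",
  "landscape", "sunset", "beach", "ocean", "island", "sea", "summer", "sun",
  "holiday", "vacation", "explore", "hiking", "trekking", "diving",
  "underwater", "coral", "reef", "birds", "whale", "penguin", "naturelovers",
  "wildlifephotography", "landscapephotography", "paradise", "relax", "happy",
  "beautiful", "amazing", "sky", "clouds", "water", "trip", "tourism",
  "outdoors", "conservation", "science", "sustainability", "culture",
  "heritage", "history", "art", "food", "sunrise", "mountains", "forest",
  "camping", "sailing", "surf", "snorkeling"
)

default_synonym_groups <- list(
  travel = c("travell", "travle"),
  nature = c("naturee"),
  photography = c("photografy", "fotography"),
  beautiful = c("beautifull")
)

#' Configuration for the synthetic post-corpus generator
#'
#' Fully parameterises the simulated Instagram-style corpora: per-area planted
#' topic vocabularies with Zipf-ranked tag frequencies, a shared global
#' vocabulary of travel/nature/photo tags, template-replicating bot users
#' posting in short bursts, advertising posts carrying blocklisted tags, and
#' misspelling variants of canonical tags.
#'
#' @param n_areas number of areas (case studies) the configuration describes.
#' @param posts_per_area posts to generate per area.
#' @param n_topics planted topic (CES-theme) count per area.
#' @param vocab_size_per_topic tags in each area-specific topic vocabulary.
#' @param shared_vocab_size size of the global shared vocabulary.
#' @param zipf_exponent exponent `s > 0` of the rank-frequency law
#'   `p(r) ~ r^-s` used within every vocabulary.
#' @param tags_min,tags_lambda post length is `tags_min + Poisson(tags_lambda)`
#'   hashtags (before set-deduplication and the always-present query tag).
#' @param p_topic probability an organic tag is drawn from the post's topic
#'   vocabulary rather than the shared vocabulary.
#' @param bot_fraction,ad_fraction expected fractions of bot / advertising
#'   posts; their sum must not exceed 1.
#' @param bot_template_size tags in each bot user's fixed template.
#' @param bot_jitter per-tag probability a bot post perturbs its template.
#' @param n_bot_users number of bot accounts (each holds one template and one
#'   one-hour burst window).
#' @param ad_tags blocklisted hashtags, at least one of which every ad carries.
#' @param misspelling_rate probability a drawn canonical tag is replaced by one
#'   of its registered variant spellings.
#' @param synonym_groups named list, canonical tag -> character vector of
#'   variant spellings.
#' @param organic_user_pool number of distinct organic user ids.
#' @param time_span_days organic timestamps are uniform over this many days.
#' @param seed integer seed; corpora are a pure function of (config, area).
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_areas = 14L,
                             posts_per_area = 2000L,
                             n_topics = 5L,
                             vocab_size_per_topic = 120L,
                             shared_vocab_size = 100L,
                             zipf_exponent = 1.0,
                             tags_min = 3L,
                             tags_lambda = 5,
                             p_topic = 0.7,
                             bot_fraction = 0.1,
                             bot_template_size = 10L,
                             bot_jitter = 0.05,
                             n_bot_users = 5L,
                             ad_fraction = 0.05,
                             ad_tags = c("advert", "sale", "discount", "promo"),
                             misspelling_rate = 0.02,
                             synonym_groups = default_synonym_groups,
                             organic_user_pool = 800L,
                             time_span_days = 365L,
                             seed = 1L) {
  cfg <- list(
    n_areas = as.integer(n_areas), posts_per_area = as.integer(posts_per_area),
    n_topics = as.integer(n_topics),
    vocab_size_per_topic = as.integer(vocab_size_per_topic),
    shared_vocab_size = as.integer(shared_vocab_size),
    zipf_exponent = zipf_exponent, tags_min = as.integer(tags_min),
    tags_lambda = tags_lambda, p_topic = p_topic,
    bot_fraction = bot_fraction, bot_template_size = as.integer(bot_template_size),
    bot_jitter = bot_jitter, n_bot_users = as.integer(n_bot_users),
    ad_fraction = ad_fraction, ad_tags = as.character(ad_tags),
    misspelling_rate = misspelling_rate, synonym_groups = synonym_groups,
    organic_user_pool = as.integer(organic_user_pool),
    time_span_days = as.integer(time_span_days), seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c("p_topic", "bot_fraction", "bot_jitter", "ad_fraction",
             "misspelling_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_config("generator_config field '%s' must be a probability in [0,1]", p)
  }
  if (cfg$bot_fraction + cfg$ad_fraction > 1)
    stop_config("bot_fraction + ad_fraction must be <= 1")
  if (!is.numeric(cfg$zipf_exponent) || cfg$zipf_exponent <= 0)
    stop_config("zipf_exponent must be > 0")
  counts1 <- c("posts_per_area", "n_topics", "n_areas", "vocab_size_per_topic",
               "shared_vocab_size", "bot_template_size", "n_bot_users",
               "organic_user_pool", "time_span_days")
  for (p in counts1) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop_config("generator_config field '%s' must be a count >= 1", p)
  }
  if (cfg$tags_min < 0) stop_config("tags_min must be >= 0")
  if (cfg$tags_lambda < 0) stop_config("tags_lambda must be >= 0")
  if (length(cfg$synonym_groups)) {
    if (is.null(names(cfg$synonym_groups)) || any(names(cfg$synonym_groups) == ""))
      stop_config("synonym_groups must be a named list (canonical -> variants)")
  }
  invisible(cfg)
}

# deterministic per-(config, area) seed, kept under 2^31
area_seed <- function(seed, area_index) {
  (as.numeric(seed) * 48271 + area_index * 16807) %% 2147483647
}

zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

area_tag <- function(area_index) sprintf("area%02d", area_index)

topic_vocab <- function(area_index, topic, size) {
  sprintf("area%02d_topic%d_w%03d", area_index, topic, seq_len(size))
}

shared_vocab <- function(size) {
  base <- shared_vocab_base
  if (size <= length(base)) return(base[seq_len(size)])
  c(base, sprintf("shared_w%03d", seq_len(size - length(base))))
}

#' Generate one synthetic per-area corpus
#'
#' Organic posts pick a topic uniformly and draw `tags_min + Poisson(lambda)`
#' tags, each from the area's topic vocabulary with probability `p_topic`
#' (Zipf-ranked within the vocabulary) and from the shared vocabulary
#' otherwise. Bot posts replicate one of `n_bot_users` fixed templates with
#' per-tag jitter and are emitted in that user's one-hour burst window. Ad
#' posts carry at least one blocklisted `ad_tag`. A per-tag misspelling step
#' replaces canonical tags by registered variants. The area's query tag
#' (`area01`, ...) is inserted into every post, mirroring that every
#' downloaded post contained the search term. Identical `(config, area_index)`
#' yields an identical corpus.
#'
#' @param config a [generator_config()].
#' @param area_index which area to generate, in `1..n_areas`.
#' @return a `corpus` object with ground-truth `truth_label` / `truth_topic`.
#' @export
generate_corpus <- function(config, area_index = 1L) {
  if (!inherits(config, "generator_config")) validate_generator_config(config)
  if (area_index < 1 || area_index > config$n_areas)
    stop_config("area_index must be in 1..n_areas (= %d)", config$n_areas)
  with_seed(area_seed(config$seed, area_index), {
    n <- config$posts_per_area
    qtag <- area_tag(area_index)
    shared <- shared_vocab(config$shared_vocab_size)
    p_shared <- zipf_probs(length(shared), config$zipf_exponent)
    topics <- lapply(seq_len(config$n_topics), function(t)
      topic_vocab(area_index, t, config$vocab_size_per_topic))
    p_topic_vocab <- zipf_probs(config$vocab_size_per_topic, config$zipf_exponent)

    labels <- sample(c("organic", "bot", "ad"), n, replace = TRUE,
                     prob = c(1 - config$bot_fraction - config$ad_fraction,
                              config$bot_fraction, config$ad_fraction))

    # bot users: fixed template (mostly shared vocabulary, bots chase reach)
    # and a one-hour burst window
    bot_users <- sprintf("bot%03d", seq_len(config$n_bot_users))
    templates <- lapply(seq_len(config$n_bot_users), function(i) {
      unique(sample(shared, config$bot_template_size, replace = FALSE,
                    prob = p_shared[seq_along(shared)]))
    })
    span_sec <- config$time_span_days * 86400
    burst_start <- runif(config$n_bot_users, 0, span_sec - 3600)

    variants <- config$synonym_groups
    misspell <- function(tags) {
      if (config$misspelling_rate == 0 || !length(variants)) return(tags)
      hit <- tags %in% names(variants) &
        runif(length(tags)) < config$misspelling_rate
      if (any(hit)) {
        tags[hit] <- vapply(tags[hit], function(tg) {
          v <- variants[[tg]]
          v[[sample.int(length(v), 1L)]]
        }, character(1))
      }
      tags
    }

    origin <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
    hashtags <- vector("list", n)
    user_id <- character(n)
    tstamp <- numeric(n)
    truth_topic <- rep(NA_integer_, n)

    for (i in seq_len(n)) {
      lab <- labels[[i]]
      if (lab == "bot") {
        b <- sample.int(config$n_bot_users, 1L)
        tags <- templates[[b]]
        jit <- runif(length(tags)) < config$bot_jitter
        if (any(jit))
          tags[jit] <- sample(shared, sum(jit), replace = TRUE, prob = p_shared)
        user_id[[i]] <- bot_users[[b]]
        tstamp[[i]] <- burst_start[[b]] + runif(1, 0, 3600)
      } else {
        k <- config$tags_min + rpois(1L, config$tags_lambda)
        from_topic <- runif(k) < config$p_topic
        t_idx <- sample.int(config$n_topics, 1L)
        tags <- character(k)
        if (any(from_topic))
          tags[from_topic] <- sample(topics[[t_idx]], sum(from_topic),
                                     replace = TRUE, prob = p_topic_vocab)
        if (any(!from_topic))
          tags[!from_topic] <- sample(shared, sum(!from_topic),
                                      replace = TRUE, prob = p_shared)
        if (lab == "ad") {
          n_ad <- sample.int(min(2L, length(config$ad_tags)), 1L)
          tags <- c(tags, sample(config$ad_tags, n_ad))
          user_id[[i]] <- sprintf("adv%03d", sample.int(20L, 1L))
        } else {
          truth_topic[[i]] <- t_idx
          user_id[[i]] <- sprintf("u%05d", sample.int(config$organic_user_pool, 1L))
        }
        tstamp[[i]] <- runif(1, 0, span_sec)
      }
      tags <- misspell(tags)
      hashtags[[i]] <- sort_c(unique(c(qtag, tags)))
    }

    df <- data.frame(
      post_id = sprintf("%s_p%05d", qtag, seq_len(n)),
      user_id = user_id,
      timestamp = format(origin + tstamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      stringsAsFactors = FALSE
    )
    df$hashtags <- hashtags
    df$truth_label <- labels
    df$truth_topic <- truth_topic
    new_corpus(df, qtag,
               provenance = list(kind = "synthetic", seed = config$seed,
                                 area_index = area_index))
  })
}

#' Summarise a corpus
#'
#' @param corpus a `corpus`.
#' @return list with `n_posts`, per-truth-label counts (zero-filled), and the
#'   hashtag frequency table (posts containing each tag).
#' @export
corpus_summary <- function(corpus) {
  labs <- c("organic", "bot", "ad")
  lc <- setNames(integer(3), labs)
  if (nrow(corpus)) {
    tab <- table(factor(corpus$truth_label, levels = labs))
    lc[labs] <- as.integer(tab)
  }
  freqs <- hashtag_frequencies(corpus)
  list(n_posts = nrow(corpus), label_counts = as.list(lc),
       n_distinct_hashtags = length(freqs), hashtag_frequencies = freqs)
}
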