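test_that("read_corpus normalizes hashtags and round-trips both formats", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"post_id":"p1","user_id":"u1","timestamp":"2019-06-01T10:00:00Z","hashtags":["#Travel","travel","TRAVEL "]}',
    '{"post_id":"p2","user_id":"u2","timestamp":"2019-06-01T11:00:00Z","hashtags":["#Beach","","  "]}'
  ), f)
  corp <- read_corpus(f, "jsonl")
  expect_equal(corp$hashtags[[1]], "travel")
  expect_equal(corp$hashtags[[2]], "beach")

  # JSONL and CSV serializations parse to the identical corpus value
  cfg <- generator_config(posts_per_area = 100, seed = 2)
  corp <- generate_corpus(cfg, 1)
  fj <- withr::local_tempfile(fileext = ".jsonl")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, fj, "jsonl"); write_corpus(corp, fc, "csv")
  a <- read_corpus(fj, "jsonl", area_name = "x")
  b <- read_corpus(fc, "csv", area_name = "x")
  for (col in c("post_id", "user_id", "timestamp", "hashtags",
                "truth_label", "truth_topic"))
    expect_identical(a[[col]], b[[col]])

  # empty file is an empty corpus, not an error
  fe <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), fe)
  expect_equal(nrow(read_corpus(fe, "jsonl")), 0)

  # malformed record names the line
  fm <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"post_id":"p1","hashtags":["a"]}', "not json"), fm)
  expect_error(read_corpus(fm, "jsonl"), "line 2")
})

test_that("graph-based detector flags identical-template clusters and nothing else", {
  tmpl <- sprintf("tag%02d", 1:8)
  corp <- corpus_from_sets(list(tmpl, tmpl, tmpl, c("x"), c("y")),
                           users = c("b", "b", "b", "u1", "u2"))
  det <- detect_automated_posts(corp, jaccard_threshold = 0.9, min_cluster = 3)
  expect_setequal(det$flagged, c("p001", "p002", "p003"))
  expect_equal(det$per_detector_counts$graph, 3)

  # all-distinct single-tag posts: nothing to flag
  corp2 <- corpus_from_sets(lapply(letters[1:6], identity))
  expect_length(detect_automated_posts(corp2)$flagged, 0)
})

test_that("anomaly and time-series detectors flag high-volume and bursty users", {
  sets <- c(lapply(1:40, function(i) c(sprintf("u%d", i), "common")),
            lapply(1:20, function(i) sprintf("bot_post_%d", i)))
  users <- c(sprintf("u%03d", 1:40), rep("flood", 20))
  t0 <- as.POSIXct("2019-06-01", tz = "UTC")
  times <- format(c(t0 + 86400 * (1:40), t0 + 1:20),
                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  corp <- corpus_from_sets(sets, users = users, times = times)
  det_a <- detect_automated_posts(corp, detectors = "anomaly")
  expect_setequal(det_a$flagged, corp$post_id[corp$user_id == "flood"])
  det_t <- detect_automated_posts(corp, detectors = "timeseries")
  expect_true(all(corp$post_id[corp$user_id == "flood"] %in% det_t$flagged))
})

test_that("blocklist removes posts by banned tag or banned user", {
  corp <- corpus_from_sets(list(c("rapanui", "chocolate"), c("rapanui", "moai")))
  res <- apply_blocklist(corp, blocklist(hashtags = "chocolate"))
  expect_equal(res$n_removed, 1)
  expect_equal(res$corpus$post_id, "p002")

  # empty blocklist is the identity
  res0 <- apply_blocklist(corp, blocklist())
  expect_identical(as.data.frame(res0$corpus), as.data.frame(corp))
  expect_equal(res0$n_removed, 0)

  sets <- c(rep(list(c("spam", "z")), 4), rep(list(c("ok")), 6))
  corp10 <- corpus_from_sets(sets)
  res4 <- apply_blocklist(corp10, blocklist(hashtags = "spam"))
  expect_equal(res4$n_removed, 4)
  expect_equal(nrow(res4$corpus), 6)
})

test_that("synonym merging replaces variants and re-deduplicates", {
  map <- synonym_map(c(travelgram = "travel", instatravel = "travel"))
  corp <- corpus_from_sets(list(c("travelgram", "instatravel", "beach")))
  out <- apply_synonym_map(corp, map)
  expect_equal(out$hashtags[[1]], c("beach", "travel"))

  # set collapse after merge
  out2 <- apply_synonym_map(corpus_from_sets(list(c("travell", "travel"))),
                            synonym_map(c(travell = "travel")))
  expect_equal(out2$hashtags[[1]], "travel")

  # empty map is the identity
  expect_identical(as.data.frame(apply_synonym_map(corp, synonym_map())),
                   as.data.frame(corp))

  # non-idempotent map is a configuration error
  expect_error(synonym_map(c(a = "b", b = "c")), "idempotent")
})

test_that("file readers parse synonym maps and blocklists", {
  fs <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant,canonical", "travelgram,travel", "#IGtravel,travel"), fs)
  sm <- read_synonym_map(fs)
  expect_equal(unname(sm[["igtravel"]]), "travel")

  fb <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chocolate", "user:spammer1", ""), fb)
  bl <- read_blocklist(fb)
  expect_equal(bl$banned_hashtags, "chocolate")
  expect_equal(bl$banned_users, "spammer1")
})

test_that("clean_corpus conserves counts, is idempotent, and warns past 25%", {
  cfg <- generator_config(posts_per_area = 1500, seed = 8)
  corp <- generate_corpus(cfg, 1)
  res <- clean_corpus(corp, blocklist(hashtags = cfg$ad_tags))
  r <- res$report
  expect_equal(r$n_retained + r$n_flagged_bot + r$n_flagged_blocklist, r$n_input)
  expect_equal(r$discard_fraction, 1 - r$n_retained / r$n_input)

  # idempotence: cleaning a cleaned corpus removes nothing further
  res2 <- clean_corpus(res$corpus, blocklist(hashtags = cfg$ad_tags))
  expect_identical(as.data.frame(res2$corpus), as.data.frame(res$corpus))
  expect_equal(res2$report$discard_fraction, 0)

  # a corpus with no bots or ads keeps everything
  clean_only <- corpus_from_sets(lapply(1:20, function(i) c(sprintf("t%d", i), "x")))
  r0 <- clean_corpus(clean_only)$report
  expect_equal(r0$discard_fraction, 0)
  expect_length(r0$warnings, 0)

  # warning fires exactly above 0.25: 26/100 yes, 25/100 no
  mk <- function(n_bad) corpus_from_sets(c(
    rep(list(c("spam")), n_bad),
    lapply(1:(100 - n_bad), function(i) c(sprintf("ok%d", i)))))
  r26 <- clean_corpus(mk(26), blocklist(hashtags = "spam"))$report
  expect_length(r26$warnings, 1)
  r25 <- clean_corpus(mk(25), blocklist(hashtags = "spam"))$report
  expect_length(r25$warnings, 0)
})

test_that("synonym application never increases the number of distinct hashtags", {
  cfg <- generator_config(posts_per_area = 400, misspelling_rate = 0.2, seed = 12)
  corp <- generate_corpus(cfg, 1)
  map <- synonym_map(unlist(lapply(names(cfg$synonym_groups), function(cn)
    setNames(rep(cn, length(cfg$synonym_groups[[cn]])), cfg$synonym_groups[[cn]]))))
  before <- length(hashtag_frequencies(corp))
  after <- length(hashtag_frequencies(apply_synonym_map(corp, map)))
  expect_lte(after, before)
  expect_lt(after, before)  # misspellings were present at this rate
})
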