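# Corpus serialization: JSONL (one post object per line) and flat CSV
# (hashtags pipe-delimited). Ground truth travels in the same record when
# present; readers normalize hashtags so both formats round-trip to the same
# corpus value.

#' Write a corpus to disk
#'
#' @param corpus a `corpus`.
#' @param path output file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`
#'   (pipe-delimited hashtags).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(
        post_id = corpus$post_id[[i]],
        user_id = corpus$user_id[[i]],
        timestamp = corpus$timestamp[[i]],
        hashtags = as.list(corpus$hashtags[[i]])
      )
      if (!is.na(corpus$truth_label[[i]])) {
        rec$truth_label <- corpus$truth_label[[i]]
        if (!is.na(corpus$truth_topic[[i]]))
          rec$truth_topic <- corpus$truth_topic[[i]]
      }
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(
      post_id = corpus$post_id, user_id = corpus$user_id,
      timestamp = corpus$timestamp,
      hashtags = vapply(corpus$hashtags, paste, character(1), collapse = "|"),
      truth_label = corpus$truth_label, truth_topic = corpus$truth_topic,
      stringsAsFactors = FALSE
    )
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

# hashtag normalization: lower-case, strip leading '#', NFKC, trim, drop
# empties, dedup within the post
normalize_tags <- function(tags) {
  tags <- as.character(tags)
  tags <- stringi::stri_trans_nfkc(enc2utf8(tags))
  tags <- tolower(trimws(tags))
  tags <- sub("^#+", "", tags)
  tags <- tags[!is.na(tags) & nzchar(tags)]
  sort_c(unique(tags))
}

#' Read a corpus from JSONL or CSV
#'
#' Hashtags are normalized on read: lower-cased, leading `#` stripped,
#' whitespace trimmed, empty tags dropped and duplicates within a post
#' collapsed, so the JSONL and CSV serializations of a corpus parse to the
#' same value.
#'
#' @param path input file.
#' @param format `"jsonl"` or `"csv"`.
#' @param area_name area label for the corpus; defaults to the file stem.
#' @return a `corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"), area_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("corpus file not found: %s", path)
  area_name <- area_name %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$post_id))
        stop_data("malformed JSONL record at line %d of %s", i, path)
      rec
    })
    df <- data.frame(
      post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
      user_id = vapply(recs, function(r) as.character(r$user_id %||% ""), character(1)),
      timestamp = vapply(recs, function(r) as.character(r$timestamp %||% ""), character(1)),
      stringsAsFactors = FALSE
    )
    df$hashtags <- lapply(recs, function(r) normalize_tags(unlist(r$hashtags)))
    df$truth_label <- vapply(recs, function(r)
      if (is.null(r$truth_label)) NA_character_ else as.character(r$truth_label),
      character(1))
    df$truth_topic <- vapply(recs, function(r)
      if (is.null(r$truth_topic)) NA_integer_ else as.integer(r$truth_topic),
      integer(1))
  } else {
    raw <- tryCatch(
      read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop_data("malformed CSV in %s: %s", path, conditionMessage(e)))
    if (nrow(raw) && is.null(raw$post_id))
      stop_data("CSV %s lacks a post_id column", path)
    df <- data.frame(
      post_id = as.character(raw$post_id %||% character(0)),
      user_id = as.character(raw$user_id %||% character(0)),
      timestamp = as.character(raw$timestamp %||% character(0)),
      stringsAsFactors = FALSE
    )
    df$hashtags <- lapply(raw$hashtags %||% character(0), function(s)
      normalize_tags(strsplit(s, "|", fixed = TRUE)[[1]]))
    tl <- as.character(raw$truth_label %||% rep("", nrow(df)))
    df$truth_label <- ifelse(nzchar(tl), tl, NA_character_)
    tt <- as.character(raw$truth_topic %||% rep("", nrow(df)))
    df$truth_topic <- suppressWarnings(as.integer(ifelse(nzchar(tt), tt, NA)))
  }
  if (anyDuplicated(df$post_id))
    stop_data("duplicate post_id values in %s", path)
  new_corpus(df, area_name, provenance = list(kind = "file", path = path))
}
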