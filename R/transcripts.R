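#' Default speaker alias table
#'
#' Maps the labels found in transcript files onto the two canonical
#' speakers, `"patient"` and `"interviewer"`. Matching is case-insensitive.
#'
#' @return Named character vector: names are accepted aliases, values are
#'   canonical speaker labels.
#' @export
#' @examples
#' default_speaker_aliases()
default_speaker_aliases <- function() {
  c(
    patient = "patient", p = "patient", participant = "patient",
    pt = "patient", subject = "patient",
    interviewer = "interviewer", i = "interviewer", int = "interviewer",
    examiner = "interviewer", coordinator = "interviewer"
  )
}

canonical_speaker <- function(labels, aliases = default_speaker_aliases()) {
  key <- tolower(trimws(labels))
  out <- unname(aliases[key])
  if (anyNA(out)) {
    bad <- unique(labels[is.na(out)])
    abort(sprintf(
      "Unknown speaker label(s): %s. Accepted aliases: %s.",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(names(aliases)), collapse = ", ")
    ))
  }
  out
}

new_utterance_tbl <- function(interview_id, speaker, text, start_s, end_s) {
  out <- tibble(
    interview_id = as.character(interview_id),
    speaker = speaker,
    text = stringr::str_squish(text),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s)
  )
  out <- dplyr::filter(out, nchar(.data$text) > 0)
  if (nrow(out) == 0) abort("no utterances")
  bad <- !is.na(out$start_s) & !is.na(out$end_s) & out$end_s < out$start_s
  if (any(bad)) abort("utterance end_s earlier than start_s")
  if (any(out$start_s < 0, na.rm = TRUE)) abort("negative start_s")
  out
}

#' Read an interview transcript
#'
#' Reads one two-speaker interview in one of three plain-text dialects and
#' returns a tidy utterance table, one row per utterance in file order.
#'
#' Dialects:
#' * `"jsonl"`: one JSON object per line with keys `speaker`, `text` and
#'   optional `start_s`/`end_s` (seconds).
#' * `"vtt"`: WebVTT captions; cue timings provide `start_s`/`end_s` and the
#'   speaker is taken from `<v Name>` voice tags.
#' * `"tagged_txt"`: lines of the form `SPEAKER<TAB>text`.
#'
#' @param path Path to the transcript file.
#' @param dialect One of `"jsonl"`, `"vtt"`, `"tagged_txt"`.
#' @param interview_id Identifier for the interview; defaults to the file
#'   name without extension.
#' @param aliases Speaker alias table, see [default_speaker_aliases()].
#' @return A tibble with columns `interview_id`, `speaker`
#'   (`"patient"`/`"interviewer"`), `text`, `start_s`, `end_s` (`NA` when
#'   the dialect carries no timing).
#' @export
read_transcript <- function(path,
                            dialect = c("jsonl", "vtt", "tagged_txt"),
                            interview_id = NULL,
                            aliases = default_speaker_aliases()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("transcript file not found: %s", path))
  interview_id <- interview_id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  switch(dialect,
    jsonl = read_jsonl_transcript(lines, interview_id, aliases, path),
    vtt = read_vtt_transcript(lines, interview_id, aliases, path),
    tagged_txt = read_tagged_transcript(lines, interview_id, aliases, path)
  )
}

read_jsonl_transcript <- function(lines, interview_id, aliases, path) {
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort(sprintf("no utterances in %s", path))
  recs <- lapply(keep, function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("%s: line %d is not valid JSON (%s)",
                      path, i, conditionMessage(e)))
      }
    )
    if (is.null(rec$speaker) || is.null(rec$text)) {
      abort(sprintf("%s: line %d lacks required keys 'speaker'/'text'", path, i))
    }
    tibble(
      speaker = as.character(rec$speaker),
      text = as.character(rec$text),
      start_s = if (is.null(rec$start_s)) NA_real_ else as.numeric(rec$start_s),
      end_s = if (is.null(rec$end_s)) NA_real_ else as.numeric(rec$end_s)
    )
  })
  recs <- bind_rows(recs)
  new_utterance_tbl(interview_id, canonical_speaker(recs$speaker, aliases),
                    recs$text, recs$start_s, recs$end_s)
}

vtt_time_to_seconds <- function(x) {
  parts <- stringr::str_match(x, "^(?:(\\d+):)?(\\d{1,2}):(\\d{2})[.,](\\d{3})$")
  if (anyNA(parts[, 1])) abort(sprintf("malformed WebVTT timestamp: %s", x[is.na(parts[, 1])][1]))
  h <- ifelse(is.na(parts[, 2]), 0, as.numeric(parts[, 2]))
  h * 3600 + as.numeric(parts[, 3]) * 60 + as.numeric(parts[, 4]) +
    as.numeric(parts[, 5]) / 1000
}

read_vtt_transcript <- function(lines, interview_id, aliases, path) {
  if (!any(stringr::str_detect(lines, "-->"))) {
    abort(sprintf("no WebVTT cues found in %s", path))
  }
  # cue text runs from the timing line to the next blank line
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(blank)
  blocks <- split(lines[!blank], block_id[!blank])
  cues <- lapply(blocks, function(bl) {
    i <- which(stringr::str_detect(bl, "-->"))
    if (length(i) == 0) return(NULL) # header or NOTE block
    i <- i[[1]]
    tm <- stringr::str_match(bl[[i]], "([0-9:.,]+)\\s+-->\\s+([0-9:.,]+)")
    if (is.na(tm[1, 1])) abort(sprintf("%s: malformed cue timing line '%s'", path, bl[[i]]))
    if (i == length(bl)) return(NULL)
    text <- paste(bl[seq(i + 1L, length(bl))], collapse = " ")
    voice <- stringr::str_match(text, "<v\\s+([^>]+)>")
    speaker <- if (is.na(voice[1, 2])) "patient" else voice[1, 2]
    text <- stringr::str_remove_all(text, "</?v[^>]*>")
    tibble(
      speaker = speaker, text = text,
      start_s = vtt_time_to_seconds(trimws(tm[1, 2])),
      end_s = vtt_time_to_seconds(trimws(tm[1, 3]))
    )
  })
  cues <- bind_rows(cues)
  if (nrow(cues) == 0) abort(sprintf("no utterances in %s", path))
  new_utterance_tbl(interview_id, canonical_speaker(cues$speaker, aliases),
                    cues$text, cues$start_s, cues$end_s)
}

read_tagged_transcript <- function(lines, interview_id, aliases, path) {
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort(sprintf("no utterances in %s", path))
  m <- stringr::str_match(lines[keep], "^([^\t]+)\t(.*)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("%s: line %d is not of the form SPEAKER<TAB>text",
                  path, keep[which(is.na(m[, 1]))[1]]))
  }
  new_utterance_tbl(interview_id, canonical_speaker(m[, 2], aliases),
                    m[, 3], NA_real_, NA_real_)
}

#' Write utterances to a JSON-lines transcript
#'
#' Inverse of [read_transcript()] for the `jsonl` dialect; round-trips
#' speakers, text and timestamps exactly.
#'
#' @param utterances Utterance tibble as returned by [read_transcript()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_jsonl <- function(utterances, path) {
  stopifnot(is.data.frame(utterances))
  lines <- vapply(seq_len(nrow(utterances)), function(i) {
    rec <- list(speaker = utterances$speaker[[i]], text = utterances$text[[i]])
    if (!is.na(utterances$start_s[[i]])) rec$start_s <- utterances$start_s[[i]]
    if (!is.na(utterances$end_s[[i]])) rec$end_s <- utterances$end_s[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Abbreviations whose trailing period does not end a sentence.
sentence_abbreviations <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "vs", "etc",
  "e.g", "i.e", "approx", "dept", "inc"
)

#' Segment utterances into sentences
#'
#' Splits the selected speakers' utterances into sentences with a
#' punctuation-aware rule: boundaries are `.`, `!` or `?` followed by
#' whitespace, except after a known abbreviation (e.g. "Dr.") or inside a
#' decimal number. Empty fragments are dropped and sentence indices are
#' assigned 0-based, per interview, after filtering.
#'
#' @param utterances Utterance tibble (one or more interviews).
#' @param speakers Character vector of speakers to keep; default
#'   `"patient"`, matching an analysis of the patient channel only.
#' @param min_tokens Minimum whitespace-token count for a sentence to be
#'   kept (default 1, i.e. keep everything non-empty).
#' @return Tibble with columns `interview_id`, `index`, `speaker`, `text`;
#'   empty (zero-row) when the selected speakers said nothing, with a
#'   message noting it.
#' @export
#' @examples
#' utt <- tibble::tibble(
#'   interview_id = "a", speaker = "patient",
#'   text = "It burns. I can't sleep.", start_s = NA_real_, end_s = NA_real_
#' )
#' segment_sentences(utt)
segment_sentences <- function(utterances, speakers = "patient", min_tokens = 1L) {
  stopifnot(is.data.frame(utterances), nrow(utterances) > 0)
  sel <- dplyr::filter(utterances, .data$speaker %in% speakers)
  if (nrow(sel) == 0) {
    inform("segment_sentences: no utterances from the selected speaker(s)")
    return(tibble(interview_id = character(), index = integer(),
                  speaker = character(), text = character()))
  }
  pieces <- split_sentences(sel$text)
  out <- tibble(
    interview_id = rep(sel$interview_id, lengths(pieces)),
    speaker = rep(sel$speaker, lengths(pieces)),
    text = unlist(pieces, use.names = FALSE)
  )
  out <- dplyr::filter(
    out,
    stringr::str_count(.data$text, "\\S+") >= min_tokens
  )
  out |>
    group_by(.data$interview_id) |>
    mutate(index = row_number() - 1L) |>
    ungroup() |>
    select("interview_id", "index", "speaker", "text")
}

split_sentences <- function(texts) {
  prot <- "‸" # caret placeholder for protected periods
  x <- stringr::str_squish(texts)
  # protect known abbreviations (case-insensitive) and decimal numbers
  abbr <- paste0(
    "(?i)\\b(", paste(gsub("\\.", "\\\\.", sentence_abbreviations), collapse = "|"),
    ")\\."
  )
  x <- stringr::str_replace_all(x, abbr, paste0("\\1", prot))
  x <- stringr::str_replace_all(x, "(\\d)\\.(\\d)", paste0("\\1", prot, "\\2"))
  parts <- stringr::str_split(x, "(?<=[.!?])\\s+")
  lapply(parts, function(p) {
    p <- stringr::str_replace_all(p, prot, ".")
    p <- stringr::str_squish(p)
    p[nzchar(p)]
  })
}

normalize_words <- function(texts) {
  toks <- unlist(stringr::str_split(tolower(texts), "\\s+"), use.names = FALSE)
  toks <- stringr::str_remove_all(toks, "^[[:punct:]]+|[[:punct:]]+$")
  toks[nzchar(toks)]
}

#' Per-interview and cohort corpus metrics
#'
#' Word counts, vocabulary richness (type-token ratio), speech rate and
#' percentage of time spoken by the patient. Words are counted over the
#' selected speakers after lowercasing, stripping leading/trailing
#' punctuation and splitting on whitespace; the unique vocabulary is
#' counted after the same normalization. Speech rate is
#' `total_words / duration_min`, where `duration_min` sums the selected
#' speakers' utterance durations. When timestamps are absent the
#' duration-based metrics are `NA` rather than estimated.
#'
#' @param utterances Utterance tibble covering one or more interviews.
#' @param speakers Speakers whose words are counted (default `"patient"`).
#' @return Tibble with one row per interview plus a final `"cohort"` row
#'   of totals (cohort `unique_words` counts distinct words across the
#'   whole corpus, not a sum). Columns: `interview_id`, `total_words`,
#'   `unique_words`, `richness_ratio`, `duration_min`, `words_per_minute`,
#'   `pct_time_patient`.
#' @export
compute_interview_metrics <- function(utterances, speakers = "patient") {
  stopifnot(is.data.frame(utterances), nrow(utterances) > 0)
  ids <- unique(utterances$interview_id)
  per <- lapply(ids, function(id) {
    u <- dplyr::filter(utterances, .data$interview_id == id)
    interview_metrics_row(u, id, speakers)
  })
  per <- bind_rows(per)
  # cohort row: totals, corpus-wide vocabulary
  sel <- dplyr::filter(utterances, .data$speaker %in% speakers)
  words <- normalize_words(sel$text)
  tot_min <- if (all(!is.na(per$duration_min))) sum(per$duration_min) else NA_real_
  all_dur <- utterance_minutes(utterances)
  pat_dur <- utterance_minutes(dplyr::filter(utterances, .data$speaker == "patient"))
  cohort <- tibble(
    interview_id = "cohort",
    total_words = length(words),
    unique_words = length(unique(words)),
    richness_ratio = if (length(words) > 0) length(unique(words)) / length(words) else NA_real_,
    duration_min = tot_min,
    words_per_minute = safe_rate(length(words), tot_min),
    pct_time_patient = if (!is.na(all_dur) && all_dur > 0) 100 * pat_dur / all_dur else NA_real_
  )
  bind_rows(per, cohort)
}

utterance_minutes <- function(u) {
  if (nrow(u) == 0) return(0)
  if (anyNA(u$start_s) || anyNA(u$end_s)) return(NA_real_)
  sum(u$end_s - u$start_s) / 60
}

safe_rate <- function(words, minutes) {
  if (is.na(minutes) || minutes <= 0) NA_real_ else words / minutes
}

interview_metrics_row <- function(u, id, speakers) {
  sel <- dplyr::filter(u, .data$speaker %in% speakers)
  words <- normalize_words(sel$text)
  dur <- utterance_minutes(sel)
  all_dur <- utterance_minutes(u)
  pat_dur <- utterance_minutes(dplyr::filter(u, .data$speaker == "patient"))
  tibble(
    interview_id = id,
    total_words = length(words),
    unique_words = length(unique(words)),
    richness_ratio = if (length(words) > 0) length(unique(words)) / length(words) else NA_real_,
    duration_min = dur,
    words_per_minute = safe_rate(length(words), dur),
    pct_time_patient = if (!is.na(all_dur) && all_dur > 0) 100 * pat_dur / all_dur else NA_real_
  )
}

#' Read a per-patient clinical score table
#'
#' @param path CSV file with columns `interview_id`, `nrs` (integer 0-10),
#'   `vas` (0-100) and optional numeric covariates.
#' @return Validated tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(sprintf("clinical table not found: %s", path))
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_clinical(x)
}

validate_clinical <- function(x) {
  need <- c("interview_id", "nrs", "vas")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("clinical table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  x$interview_id <- as.character(x$interview_id)
  ok_nrs <- is.na(x$nrs) | (x$nrs >= 0 & x$nrs <= 10)
  ok_vas <- is.na(x$vas) | (x$vas >= 0 & x$vas <= 100)
  if (!all(ok_nrs)) abort("NRS values outside [0, 10]")
  if (!all(ok_vas)) abort("VAS values outside [0, 100]")
  as_tibble(x)
}
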