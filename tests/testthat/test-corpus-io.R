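test_that("jsonl transcripts round-trip utterances, speakers and timestamps", {
  path <- write_jsonl_fixture(c(
    '{"speaker":"patient","text":"I hurt.","start_s":0.5,"end_s":2.25}',
    '{"speaker":"interviewer","text":"Tell me more."}'
  ))
  iv <- read_transcript(path, "jsonl")
  expect_equal(iv$speaker, c("patient", "interviewer"))
  expect_equal(iv$text, c("I hurt.", "Tell me more."))
  expect_equal(iv$start_s, c(0.5, NA))
  out <- tempfile(fileext = ".jsonl")
  write_transcript_jsonl(iv, out)
  expect_equal(read_transcript(out, "jsonl", interview_id = iv$interview_id[[1]]), iv)
})

test_that("speaker aliases are mapped and unknown labels rejected", {
  path <- write_jsonl_fixture(c(
    '{"speaker":"P","text":"It aches."}',
    '{"speaker":"Examiner","text":"Where?"}'
  ))
  iv <- read_transcript(path, "jsonl")
  expect_equal(iv$speaker, c("patient", "interviewer"))
  bad <- write_jsonl_fixture('{"speaker":"nurse","text":"hello"}')
  expect_error(read_transcript(bad, "jsonl"), "aliases")
})

test_that("degenerate transcript files raise informative errors", {
  empty <- write_jsonl_fixture(character(0))
  expect_error(read_transcript(empty, "jsonl"), "no utterances")
  badjson <- write_jsonl_fixture('{"speaker": "patient", "text": ')
  expect_error(read_transcript(badjson, "jsonl"), "line 1")
  nokeys <- write_jsonl_fixture('{"who":"patient"}')
  expect_error(read_transcript(nokeys, "jsonl"), "speaker")
})

test_that("WebVTT cues carry timings and voice-tag speakers", {
  path <- tempfile(fileext = ".vtt")
  writeLines(c(
    "WEBVTT", "",
    "1", "00:00:01.000 --> 00:00:04.500",
    "<v Participant>My back hurts today.", "",
    "2", "00:01:00.000 --> 00:01:02.000",
    "<v Interviewer>How badly?"
  ), path)
  iv <- read_transcript(path, "vtt")
  expect_equal(iv$start_s, c(1, 60))
  expect_equal(iv$end_s, c(4.5, 62))
  expect_equal(iv$speaker, c("patient", "interviewer"))
  expect_equal(iv$text[[1]], "My back hurts today.")
})

test_that("tagged text dialect parses SPEAKER<TAB>text lines", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("patient\tIt burns at night.", "interviewer\tSince when?"), path)
  iv <- read_transcript(path, "tagged_txt")
  expect_equal(iv$speaker, c("patient", "interviewer"))
  expect_true(all(is.na(iv$start_s)))
  bad <- tempfile(fileext = ".txt")
  writeLines("no tab here", bad)
  expect_error(read_transcript(bad, "tagged_txt"), "SPEAKER")
})

test_that("sentence segmentation splits on terminal punctuation, keeps abbreviations", {
  u <- utt_tbl("patient", "It burns. I can't sleep.")
  s <- segment_sentences(u)
  expect_equal(s$text, c("It burns.", "I can't sleep."))
  expect_equal(s$index, c(0L, 1L))
  abbr <- segment_sentences(utt_tbl("patient", "Dr. Smith saw me today."))
  expect_equal(nrow(abbr), 1L)
  dec <- segment_sentences(utt_tbl("patient", "I walked 2.5 miles! Then I rested."))
  expect_equal(nrow(dec), 2L)
})

test_that("segmentation filters speakers and is deterministic", {
  u <- dplyr::bind_rows(
    utt_tbl("interviewer", "Tell me about your day. Anything else?"),
    utt_tbl("patient", "I rested. I cooked.")
  )
  expect_message(
    none <- segment_sentences(utt_tbl("interviewer", "Only me talking.")),
    "no utterances"
  )
  expect_equal(nrow(none), 0L)
  s1 <- segment_sentences(u)
  expect_equal(unique(s1$speaker), "patient")
  expect_identical(s1, segment_sentences(u))
  both <- segment_sentences(u, speakers = c("patient", "interviewer"))
  expect_equal(nrow(both), 4L)
})

test_that("interview metrics follow the documented word convention", {
  u <- utt_tbl("patient", "a a a b", start_s = 0, end_s = 60)
  m <- compute_interview_metrics(u)
  row <- m[m$interview_id == "iv1", ]
  expect_equal(row$total_words, 4L)
  expect_equal(row$unique_words, 2L)
  expect_equal(row$richness_ratio, 0.5)
  expect_equal(row$words_per_minute, 4)
  # punctuation stripped, case folded
  u2 <- utt_tbl("patient", "Pain, pain... PAIN!")
  m2 <- compute_interview_metrics(u2)
  expect_equal(m2$unique_words[m2$interview_id == "iv1"], 1L)
})

test_that("cohort metrics are additive in total words and undefined rates stay NA", {
  u <- dplyr::bind_rows(
    utt_tbl("patient", "one two three", interview_id = "a"),
    utt_tbl("patient", "four five", interview_id = "b")
  )
  m <- compute_interview_metrics(u)
  per <- m[m$interview_id != "cohort", ]
  expect_equal(sum(per$total_words), m$total_words[m$interview_id == "cohort"])
  expect_true(all(is.na(m$words_per_minute))) # no timestamps
  expect_true(all(is.na(m$duration_min)))
})

test_that("percent time spoken by patient uses both channels", {
  u <- dplyr::bind_rows(
    utt_tbl("patient", "long answer here", start_s = 0, end_s = 90),
    utt_tbl("interviewer", "short question", start_s = 90, end_s = 100)
  )
  m <- compute_interview_metrics(u)
  expect_equal(m$pct_time_patient[m$interview_id == "iv1"], 90)
})

test_that("clinical tables validate score ranges", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(interview_id = "a", nrs = 4, vas = 35.1), path,
            row.names = FALSE)
  expect_equal(read_clinical(path)$vas, 35.1)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(interview_id = "a", nrs = 12, vas = 35), bad,
            row.names = FALSE)
  expect_error(read_clinical(bad), "NRS")
})
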