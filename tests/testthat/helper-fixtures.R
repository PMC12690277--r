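# Small in-code fixtures shared across tests.

utt_tbl <- function(speaker, text, start_s = NA_real_, end_s = NA_real_,
                    interview_id = "iv1") {
  tibble::tibble(
    interview_id = interview_id, speaker = speaker, text = text,
    start_s = as.numeric(start_s), end_s = as.numeric(end_s)
  )
}

write_jsonl_fixture <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

# shared embedder: warm cache across tests within a run
shared_embedder <- local({
  emb <- NULL
  function() {
    if (is.null(emb)) emb <<- hashed_embedder()
    emb
  }
})

whoqol_pair <- function() {
  anchor_registry(tibble::tibble(
    pair_id = "whoqol_work",
    anchor_text = "I am satisfied with my capacity for work",
    antithesis_text = "I am dissatisfied with my capacity for work",
    source = "WHOQOL",
    domain_tag = "quality_of_life"
  ))
}

painvar_pair <- function() {
  anchor_registry(tibble::tibble(
    pair_id = "painvar",
    anchor_text = "I am in pain",
    antithesis_text = "I have no pain",
    source = "pain_variability",
    domain_tag = "intensity"
  ))
}

# brute-force two-sample KS null: enumerate all interleavings of n x's and
# m y's, return the exact distribution of D as a sorted table
enumerate_ks_null <- function(n, m) {
  pos <- utils::combn(n + m, n)
  d_vals <- apply(pos, 2, function(px) {
    is_x <- logical(n + m)
    is_x[px] <- TRUE
    i <- cumsum(is_x); j <- cumsum(!is_x)
    max(abs(i / n - j / m))
  })
  d_vals
}
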