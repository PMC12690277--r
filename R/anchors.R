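anchor_sources <- c("MPQ", "PCS", "PROMIS", "WHOQOL", "pain_variability", "other")

#' Construct an anchor/antithesis pair registry
#'
#' An anchor registry is a tibble with one row per probe pair: an anchor
#' sentence drawn from a validated questionnaire and its antithetical
#' counterpart, phrased to avoid surface negation where possible. The
#' attribute `m_total` holds the number of tests used for multiple-testing
#' correction (defaults to the number of pairs; set it higher when the
#' registry is a printed subset of a larger tested family).
#'
#' @param pairs Data frame with columns `pair_id`, `anchor_text`,
#'   `antithesis_text`, `source` (one of `r paste(anchor_sources, collapse = ", ")`),
#'   `domain_tag`.
#' @param m_total Total number of pairs assumed for FDR correction;
#'   default `nrow(pairs)`.
#' @return A validated tibble of class `anchor_registry`.
#' @export
anchor_registry <- function(pairs, m_total = nrow(pairs)) {
  x <- as_tibble(pairs)
  need <- c("pair_id", "anchor_text", "antithesis_text", "source", "domain_tag")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("registry lacks required column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("registry must contain at least one pair")
  x <- dplyr::mutate(x, across(dplyr::all_of(need), as.character))
  if (anyDuplicated(x$pair_id)) {
    abort(sprintf("duplicate pair_id(s): %s",
                  paste(unique(x$pair_id[duplicated(x$pair_id)]), collapse = ", ")))
  }
  if (any(!nzchar(trimws(x$anchor_text))) || any(!nzchar(trimws(x$antithesis_text)))) {
    abort("anchor and antithesis texts must be non-empty")
  }
  if (any(x$anchor_text == x$antithesis_text)) {
    abort("anchor_text must differ from antithesis_text")
  }
  bad <- setdiff(unique(x$source), anchor_sources)
  if (length(bad) > 0) {
    abort(sprintf("unknown source(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(anchor_sources, collapse = ", ")))
  }
  if (!is.numeric(m_total) || length(m_total) != 1 || m_total < nrow(x)) {
    abort("m_total must be a single number >= the number of pairs")
  }
  x <- x[, need]
  attr(x, "m_total") <- as.integer(m_total)
  class(x) <- c("anchor_registry", class(x))
  x
}

#' @rdname anchor_registry
#' @param registry An `anchor_registry`.
#' @export
m_total <- function(registry) {
  attr(registry, "m_total") %||% nrow(registry)
}

#' Built-in anchor pairs
#'
#' The seven anchor/antithesis pairs that showed significant
#' anchor-vs-antithesis differences in the reference cohort: five McGill
#' Pain Questionnaire sensory/affective descriptors, one pain-variability
#' pair and one PROMIS pain-interference pair. `m_total` defaults to 7;
#' the original analysis corrected over 33 pairs, so pass `m_total = 33`
#' to reproduce its q-values.
#'
#' @param m_total Total test count for FDR correction (default 7).
#' @return An [anchor_registry()] of 7 pairs.
#' @export
#' @examples
#' builtin_anchor_pairs()
builtin_anchor_pairs <- function(m_total = 7L) {
  anchor_registry(tibble(
    pair_id = c("mpq_cramping", "mpq_splitting", "mpq_throbbing",
                "mpq_stabbing", "mpq_tiring", "painvar_in_pain",
                "promis_focus"),
    anchor_text = c(
      "My pain is cramping",
      "My pain is splitting",
      "My pain is throbbing",
      "My pain is stabbing",
      "My pain is tiring-exhausting",
      "I am in pain",
      "I am unable to focus"
    ),
    antithesis_text = c(
      "My pain is relaxing",
      "My pain is light and dull",
      "My pain is steady",
      "My pain is dull and aching",
      "My pain is bearable",
      "I have no pain",
      "I am able to focus"
    ),
    source = c("MPQ", "MPQ", "MPQ", "MPQ", "MPQ", "pain_variability", "PROMIS"),
    domain_tag = c("sensory", "sensory", "sensory", "sensory", "affective",
                   "intensity", "pain_interference")
  ), m_total = m_total)
}

#' Load an anchor registry from file
#'
#' Accepts UTF-8 TSV (header `pair_id anchor_text antithesis_text source
#' domain_tag`) or an equivalent YAML list of records, chosen by file
#' extension.
#'
#' @param path Registry file (`.tsv`/`.txt` or `.yaml`/`.yml`).
#' @param m_total Optional total test count; defaults to the number of
#'   pairs in the file.
#' @return An [anchor_registry()].
#' @export
load_anchor_registry <- function(path, m_total = NULL) {
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    recs <- yaml::read_yaml(path)
    if (length(recs) == 0) abort("registry must contain at least one pair")
    x <- bind_rows(lapply(recs, as_tibble))
  } else {
    x <- tryCatch(
      as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", fileEncoding = "UTF-8")),
      error = function(e) abort(sprintf("cannot parse registry %s: %s",
                                        path, conditionMessage(e)))
    )
    if (nrow(x) == 0) abort("registry must contain at least one pair")
  }
  anchor_registry(x, m_total = m_total %||% nrow(x))
}

#' Write an anchor registry to TSV
#'
#' @param registry An [anchor_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_registry <- function(registry, path) {
  utils::write.table(as.data.frame(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Surface negation tokens checked by the lint; morphological negation
# ("unable", "dissatisfied") is deliberately not flagged.
negation_tokens <- c("no", "not", "never", "n't", "none", "nothing")

#' Lint anchor pairs for surface negation
#'
#' Sentence encoders can misread negation, so probe sentences are best
#' phrased without it. This lint flags any anchor or antithesis containing
#' a surface negation token (`r paste(negation_tokens, collapse = ", ")`);
#' it warns only and never blocks an analysis.
#'
#' @param registry An [anchor_registry()].
#' @return Tibble of warnings with columns `pair_id`, `side`, `text`,
#'   `token`; zero rows when the registry is clean.
#' @export
#' @examples
#' lint_negation(builtin_anchor_pairs())
lint_negation <- function(registry) {
  long <- tidyr::pivot_longer(
    as_tibble(registry)[, c("pair_id", "anchor_text", "antithesis_text")],
    cols = c("anchor_text", "antithesis_text"),
    names_to = "side", values_to = "text"
  ) |>
    mutate(side = sub("_text$", "", .data$side))
  hits <- purrr::map_dfr(negation_tokens, function(tok) {
    pat <- if (tok == "n't") "n't\\b" else paste0("\\b", tok, "\\b")
    dplyr::filter(long, stringr::str_detect(tolower(.data$text), pat)) |>
      mutate(token = tok)
  })
  hits <- dplyr::arrange(hits, .data$pair_id, .data$side, .data$token)
  if (nrow(hits) > 0) {
    warn(sprintf("%d probe sentence(s) contain surface negation tokens", nrow(hits)))
  }
  hits
}
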