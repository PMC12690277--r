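#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`, clamped to `[-1, 1]` against floating-point
#' overshoot.
#'
#' @param u,v Numeric vectors of equal dimension, both nonzero.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("cosine_similarity: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine_similarity: zero vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Per-sentence similarity distribution against one probe
#'
#' Cosine similarity of every patient sentence in one interview against a
#' single probe sentence, in sentence order, with no filtering or
#' de-duplication.
#'
#' @param sentences Sentence tibble for one interview (as from
#'   [segment_sentences()]).
#' @param probe Probe sentence (character) or a precomputed embedding
#'   vector.
#' @param emb A [embedder()]; required when `probe` or the sentences still
#'   need embedding.
#' @param probe_id Identifier recorded on the output.
#' @return Tibble with columns `interview_id`, `probe_id`, `index`,
#'   `similarity`; one row per sentence.
#' @export
similarity_distribution <- function(sentences, probe, emb, probe_id = "probe") {
  stopifnot(is.data.frame(sentences))
  if (nrow(sentences) == 0) abort("no patient sentences to score")
  if (length(unique(sentences$interview_id)) != 1) {
    abort("similarity_distribution expects sentences from a single interview")
  }
  pv <- if (is.character(probe)) drop(embed_sentences(probe, emb)) else as.numeric(probe)
  sv <- embed_sentences(sentences$text, emb)
  sims <- vapply(seq_len(nrow(sv)), function(i) cosine_similarity(sv[i, ], pv),
                 numeric(1))
  tibble(
    interview_id = sentences$interview_id[[1]],
    probe_id = probe_id,
    index = sentences$index,
    similarity = sims
  )
}

#' Robust maximum of a similarity distribution
#'
#' The interview-level score: a high percentile (default the 95th) of the
#' per-sentence similarities. Compared with the absolute maximum it is
#' resistant to a single outlying sentence, and it is insensitive to
#' interview length for samples from a stable distribution. Percentiles
#' use linear interpolation between closest order statistics
#' (`h = (n - 1) p / 100`, quantile type 7); with a single value it equals
#' that value.
#'
#' @param values Numeric vector of similarities (or a tibble from
#'   [similarity_distribution()], whose `similarity` column is used).
#' @param percentile Percentile in `(0, 100]`; default 95.
#' @return The robust-maximum score (single number).
#' @export
#' @examples
#' robust_max(c(0.1, 0.2, 0.9, 0.4))
robust_max <- function(values, percentile = 95) {
  if (is.data.frame(values)) values <- values$similarity
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    abort("robust_max requires non-empty, non-missing values")
  }
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile > 100) {
    abort("percentile must lie in (0, 100]")
  }
  unname(quantile(values, probs = percentile / 100, type = 7, names = FALSE))
}

#' Build the cohort score table
#'
#' Scores every interview against every probe (anchor and antithesis of
#' each registry pair) and joins the clinical scores. Interviews with no
#' patient sentences are excluded with a warning; interviews missing from
#' the clinical table keep `NA` clinical columns and are flagged with a
#' warning, never silently dropped.
#'
#' @param sentences Sentence tibble covering the cohort (from
#'   [segment_sentences()]).
#' @param registry An [anchor_registry()].
#' @param emb A [embedder()].
#' @param clinical Optional clinical tibble (`interview_id`, `nrs`, `vas`).
#' @param percentile Robust-maximum percentile (default 95).
#' @return A tibble of class `cohort_scores`: one row per interview,
#'   columns `<pair_id>__anchor` / `<pair_id>__antithesis`, then `nrs`,
#'   `vas` if clinical data were given. Attributes: `percentile`,
#'   `registry`, `n_sentences` (named count per interview).
#' @export
build_cohort_table <- function(sentences, registry, emb, clinical = NULL,
                               percentile = 95) {
  stopifnot(is.data.frame(sentences), inherits(registry, "anchor_registry"))
  if (nrow(sentences) == 0) abort("no patient sentences to score")
  probes <- embed_registry(registry, emb)
  svec <- embed_sentences(sentences$text, emb)
  pmat <- probes$vector # n_probes x D
  # unit rows (normalize on) make this a plain inner product; renormalize
  # defensively so the contract holds for any backend
  row_norm <- function(m) m / sqrt(rowSums(m^2))
  sims <- row_norm(svec) %*% t(row_norm(pmat)) # n_sentences x n_probes
  sims <- pmin(pmax(sims, -1), 1)
  ids <- unique(sentences$interview_id)
  by_iv <- split(seq_len(nrow(sentences)), sentences$interview_id)[ids]
  score_rows <- lapply(ids, function(id) {
    idx <- by_iv[[id]]
    scores <- apply(sims[idx, , drop = FALSE], 2, robust_max,
                    percentile = percentile)
    tibble(interview_id = id, !!!setNames(as.list(scores), probes$probe_id))
  })
  out <- bind_rows(score_rows)
  n_sent <- vapply(by_iv, length, integer(1))
  if (!is.null(clinical)) {
    clinical <- validate_clinical(clinical)
    out <- left_join(out, clinical, by = "interview_id")
    missing_clin <- out$interview_id[is.na(out$nrs) & is.na(out$vas)]
    if (length(missing_clin) > 0) {
      warn(sprintf("no clinical scores for interview(s): %s",
                   paste(missing_clin, collapse = ", ")))
    }
  }
  attr(out, "percentile") <- percentile
  attr(out, "registry") <- registry
  attr(out, "n_sentences") <- n_sent
  class(out) <- c("cohort_scores", class(out))
  out
}

probe_columns <- function(scores, side = c("anchor", "antithesis")) {
  side <- match.arg(side)
  grep(paste0("__", side, "$"), names(scores), value = TRUE)
}

get_probe_scores <- function(scores, probe_id) {
  if (!probe_id %in% names(scores)) {
    abort(sprintf("probe column not found: %s", probe_id))
  }
  scores[[probe_id]]
}

#' Export per-sentence similarity distributions
#'
#' Long-format table of the similarity of every sentence to every probe;
#' the per-interview empirical CDF of these values underlies the
#' distribution plots.
#'
#' @inheritParams build_cohort_table
#' @return Tibble `interview_id`, `probe_id`, `index`, `similarity`.
#' @export
similarity_long <- function(sentences, registry, emb) {
  probes <- embed_registry(registry, emb)
  purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    purrr::map_dfr(split(sentences, sentences$interview_id), function(s) {
      similarity_distribution(s, probes$vector[i, ], emb,
                              probe_id = probes$probe_id[[i]])
    })
  })
}
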