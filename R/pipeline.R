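#' Configure an end-to-end pipeline run
#'
#' Bundles everything [run_pipeline()] needs: where the transcripts come
#' from (files on disk or a seeded synthetic cohort), the anchor registry,
#' the embedding backend, the robust-maximum percentile, the FDR test
#' count and the pain-group rule.
#'
#' @param transcripts Character vector of transcript paths, or `NULL` to
#'   generate a synthetic cohort.
#' @param dialect Transcript dialect, see [read_transcript()].
#' @param clinical Path to a clinical CSV, or a tibble, or `NULL`.
#' @param registry An [anchor_registry()], a path to a registry file, or
#'   `NULL` for [builtin_anchor_pairs()].
#' @param emb A [embedder()]; default [hashed_embedder()].
#' @param percentile Robust-maximum percentile (default 95).
#' @param m_total Total test count for FDR; default the registry's.
#' @param vas_threshold,nrs_threshold,combine Pain-group rule, see
#'   [group_split_pain()].
#' @param out_dir Output directory.
#' @param synthetic `NULL`, or a [synthetic_config()] used when
#'   `transcripts` is `NULL`.
#' @param cdf_probe Probe id used for the grouped CDF export; default the
#'   first registry pair's anchor.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(transcripts = NULL, dialect = "jsonl",
                            clinical = NULL, registry = NULL,
                            emb = hashed_embedder(), percentile = 95,
                            m_total = NULL, vas_threshold = 30,
                            nrs_threshold = 3, combine = "or",
                            out_dir = tempfile("painlang_run_"),
                            synthetic = NULL, cdf_probe = NULL) {
  reg <- if (is.null(registry)) {
    builtin_anchor_pairs()
  } else if (is.character(registry)) {
    load_anchor_registry(registry)
  } else {
    registry
  }
  stopifnot(inherits(reg, "anchor_registry"), inherits(emb, "pain_embedder"))
  if (is.null(transcripts) && is.null(synthetic)) {
    synthetic <- synthetic_config()
  }
  if (!is.null(transcripts)) {
    missing_files <- transcripts[!file.exists(transcripts)]
    if (length(missing_files) > 0) {
      abort(sprintf("transcript file(s) not found: %s",
                    paste(missing_files, collapse = ", ")))
    }
  }
  structure(
    list(
      transcripts = transcripts, dialect = dialect, clinical = clinical,
      registry = reg, emb = emb, percentile = percentile,
      m_total = m_total, vas_threshold = vas_threshold,
      nrs_threshold = nrs_threshold, combine = combine,
      out_dir = out_dir, synthetic = synthetic,
      cdf_probe = cdf_probe %||% paste0(reg$pair_id[[1]], "__anchor")
    ),
    class = "pipeline_config"
  )
}

atomic_write <- function(writer, path) {
  tmp <- file.path(dirname(path), paste0(".tmp_", basename(path)))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_atomic <- function(x, path) {
  atomic_write(function(p) {
    utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }, path)
}

write_csv_atomic <- function(x, path) {
  atomic_write(function(p) write.csv(as.data.frame(x), p, row.names = FALSE),
               path)
}

#' Run the full narrative-scoring pipeline
#'
#' Executes transcript reading, sentence segmentation, embedding, scoring
#' and the statistical layer in order, writing each result atomically to
#' `config$out_dir`:
#'
#' * `score_table.csv` — robust-maximum score per interview x probe plus
#'   clinical columns;
#' * `anchor_tests.tsv` — anchor-vs-antithesis KS table with q-values
#'   (sorted by p);
#' * `correlations.tsv` — Spearman rho of each probe against NRS and VAS;
#' * `metrics.csv` — per-interview and cohort corpus metrics;
#' * `cdf_export.csv` — grouped empirical CDF of one probe's scores;
#' * `manifest.json` — configuration, package version and input hashes.
#'
#' With fewer than 2 interviews the statistical tables are skipped with a
#' warning (the KS layer needs at least 2 scores per side) but scores and
#' metrics are still emitted.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`scores`,
#'   `anchor_tests`, `correlations`, `metrics`, `cdf`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  input_files <- character(0)
  if (is.null(config$transcripts)) {
    cohort <- stage("simulate", generate_cohort(config$synthetic))
    tdir <- file.path(config$out_dir, "transcripts")
    stage("simulate", write_cohort(cohort, tdir))
    input_files <- sort(list.files(tdir, full.names = TRUE))
    loaded <- stage("read", read_cohort(tdir))
    utterances <- loaded$utterances
    clinical <- loaded$clinical
  } else {
    input_files <- config$transcripts
    utterances <- stage("read", purrr::map_dfr(
      config$transcripts, read_transcript, dialect = config$dialect))
    clinical <- stage("read", if (is.character(config$clinical)) {
      read_clinical(config$clinical)
    } else if (is.data.frame(config$clinical)) {
      validate_clinical(config$clinical)
    } else NULL)
  }
  metrics <- stage("metrics", compute_interview_metrics(utterances))
  sentences <- stage("segment", segment_sentences(utterances))
  scores <- stage("score", build_cohort_table(
    sentences, config$registry, config$emb, clinical = clinical,
    percentile = config$percentile))
  results <- list(scores = scores, metrics = metrics,
                  anchor_tests = NULL, correlations = NULL, cdf = NULL)
  write_csv_atomic(scores, file.path(config$out_dir, "score_table.csv"))
  write_csv_atomic(metrics, file.path(config$out_dir, "metrics.csv"))
  if (nrow(scores) < 2) {
    warn("fewer than 2 scored interviews: statistical tables skipped")
  } else {
    results$anchor_tests <- stage("stats", anchor_antithesis_tests(
      scores, m_total = config$m_total))
    write_tsv_atomic(results$anchor_tests,
                     file.path(config$out_dir, "anchor_tests.tsv"))
    if (!is.null(clinical)) {
      results$correlations <- stage("stats", bind_rows(
        correlate_scores(scores, "nrs"), correlate_scores(scores, "vas")))
      write_tsv_atomic(results$correlations,
                       file.path(config$out_dir, "correlations.tsv"))
      labels <- stage("stats", group_split_pain(
        scores, config$vas_threshold, config$nrs_threshold, config$combine))
      grouping <- setNames(as.character(labels$group), labels$interview_id)
      results$cdf <- stage("stats", export_cdf(scores, config$cdf_probe,
                                               grouping = grouping))
      write_csv_atomic(results$cdf, file.path(config$out_dir, "cdf_export.csv"))
    }
  }
  manifest <- list(
    package = "painlang",
    version = as.character(utils::packageVersion("painlang")),
    percentile = config$percentile,
    m_total = config$m_total %||% m_total(config$registry),
    embedder = list(backend = config$emb$backend,
                    dimension = config$emb$dimension,
                    normalize = config$emb$normalize),
    group_rule = list(vas_threshold = config$vas_threshold,
                      nrs_threshold = config$nrs_threshold,
                      combine = config$combine),
    synthetic_seed = if (is.null(config$transcripts)) config$synthetic$seed else NULL,
    registry_pairs = config$registry$pair_id,
    input_hashes = as.list(setNames(unname(tools::md5sum(input_files)),
                                    basename(input_files)))
  )
  atomic_write(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }, file.path(config$out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

#' Empirical CDF export for one probe
#'
#' Sorted score values with empirical CDF ordinates per group, mirroring
#' the grouped cumulative-distribution figures; each group also carries
#' its 95th-percentile marker.
#'
#' @param scores A `cohort_scores` table.
#' @param probe_id Probe column name.
#' @param grouping Optional named character vector mapping `interview_id`
#'   to a group label; default puts everything in one group `"all"`.
#' @return Tibble of class `pain_cdf` with columns `group`, `value`,
#'   `ecdf`, `p95` (the group's 95th-percentile score).
#' @export
export_cdf <- function(scores, probe_id, grouping = NULL) {
  vals <- get_probe_scores(scores, probe_id)
  grp <- if (is.null(grouping)) {
    rep("all", length(vals))
  } else {
    g <- grouping[scores$interview_id]
    if (anyNA(g)) abort("grouping lacks labels for some interviews")
    as.character(g)
  }
  out <- purrr::map_dfr(split(vals, grp), function(v) {
    v <- sort(v)
    tibble(value = v, ecdf = seq_along(v) / length(v),
           p95 = robust_max(v, 95))
  }, .id = "group")
  attr(out, "probe_id") <- probe_id
  class(out) <- c("pain_cdf", class(out))
  out
}

#' Plot a grouped empirical CDF
#'
#' Step plot of the [export_cdf()] table with dashed vertical lines at
#' each group's 95th-percentile robust maximum.
#'
#' @param object A `pain_cdf` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pain_cdf <- function(object, ...) {
  markers <- distinct(as_tibble(object)[, c("group", "p95")])
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data$ecdf,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(data = markers,
                        ggplot2::aes(xintercept = .data$p95,
                                     colour = .data$group),
                        linetype = "dashed") +
    ggplot2::labs(x = "semantic similarity", y = "cumulative probability",
                  colour = NULL,
                  title = attr(object, "probe_id") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of probe scores against a pain measure
#'
#' @param scores A `cohort_scores` table with clinical columns.
#' @param probe_id Probe column name.
#' @param measure `"nrs"` or `"vas"`.
#' @return A ggplot object.
#' @export
plot_score_correlation <- function(scores, probe_id, measure = c("nrs", "vas")) {
  measure <- match.arg(measure)
  df <- tibble(score = get_probe_scores(scores, probe_id),
               pain = scores[[measure]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pain, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = toupper(measure), y = paste(probe_id, "robust maximum")) +
    ggplot2::theme_minimal()
}
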