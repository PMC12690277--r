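#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up adjustment, `q(i) = min_{j >= i} p(j) * m_total / j`
#' over the ascending-ordered p-values, clipped at 1; tied p-values share
#' the adjusted value of their largest tied rank. When `m_total` exceeds
#' the list length the listed p-values are treated as the smallest
#' `length(p)` of `m_total` tests (the remaining tests' p-values are
#' unknown but larger, and cannot lower any listed q-value in the step-up
#' minimum).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m_total Total number of tests corrected over; defaults to
#'   `length(p_values)`.
#' @return Tibble in input order with columns `p_value`, `rank`
#'   (ascending, ties by first occurrence), `q_value`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p_values, m_total = length(p_values)) {
  p <- as.numeric(p_values)
  if (length(p) == 0) abort("no p-values supplied")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (m_total < length(p)) abort("m_total must be >= the number of p-values")
  o <- order(p)
  ranks <- seq_along(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m_total / ranks))))
  q <- numeric(length(p)); q[o] <- q_sorted
  rk <- integer(length(p)); rk[o] <- ranks
  tibble(p_value = p, rank = rk, q_value = q)
}

#' Anchor-versus-antithesis tests across the cohort
#'
#' For each registry pair, compares the distribution of robust-maximum
#' scores for the anchor against that of its antithesis across patients
#' with the two-sample KS test, then applies BH-FDR over the pairs using
#' the registry's `m_total`.
#'
#' @param scores A `cohort_scores` table from [build_cohort_table()].
#' @param m_total Total test count for FDR; defaults to the registry's
#'   `m_total` attribute.
#' @param method KS p-value method passed to [ks_two_sample()].
#' @return Tibble sorted by p-value with columns `pair_id`, `anchor`,
#'   `antithesis`, `source`, `ks_stat`, `p_value`, `q_value`, `method`.
#' @export
anchor_antithesis_tests <- function(scores, m_total = NULL,
                                    method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  registry <- attr(scores, "registry")
  if (is.null(registry)) abort("scores table carries no registry attribute")
  if (nrow(scores) < 2) abort("need scores from at least 2 interviews")
  mt <- m_total %||% m_total(registry)
  rows <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    pid <- registry$pair_id[[i]]
    ks <- anchor_antithesis_test(scores, pid, method = method)
    tibble(
      pair_id = pid,
      anchor = registry$anchor_text[[i]],
      antithesis = registry$antithesis_text[[i]],
      source = registry$source[[i]],
      ks_stat = ks$statistic,
      p_value = ks$p_value,
      method = ks$method
    )
  })
  fdr <- bh_fdr(rows$p_value, m_total = mt)
  rows$q_value <- fdr$q_value
  rows |>
    select("pair_id", "anchor", "antithesis", "source", "ks_stat",
           "p_value", "q_value", "method") |>
    arrange(.data$p_value, .data$pair_id)
}

#' @rdname anchor_antithesis_tests
#' @param pair_id A single registry pair id.
#' @return `anchor_antithesis_test()`: a `pain_ks` object.
#' @export
anchor_antithesis_test <- function(scores, pair_id,
                                   method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  x <- get_probe_scores(scores, paste0(pair_id, "__anchor"))
  y <- get_probe_scores(scores, paste0(pair_id, "__antithesis"))
  ks_two_sample(x, y, method = method)
}

#' Spearman correlation of probe scores with pain intensity
#'
#' Spearman's rank correlation (average ranks for ties) between the
#' robust-maximum scores of each probe and a reported pain-intensity
#' measure, with a companion BH-FDR correction over the probes tested.
#' P-values use the exact small-sample null for `n <= 10` (no ties) and
#' the t approximation otherwise.
#'
#' @param scores A `cohort_scores` table including clinical columns.
#' @param measure `"nrs"` or `"vas"`.
#' @param sides Which probe columns to test (default both anchors and
#'   antitheses).
#' @return Tibble with `probe_id`, `measure`, `rho`, `p_value`, `n`,
#'   `q_value`. Probes with a constant score column get `NA` rho with a
#'   warning.
#' @export
correlate_scores <- function(scores, measure = c("nrs", "vas"),
                             sides = c("anchor", "antithesis")) {
  measure <- match.arg(measure)
  if (!measure %in% names(scores)) {
    abort(sprintf("clinical measure '%s' not present in the score table", measure))
  }
  cols <- unlist(lapply(sides, probe_columns, scores = scores))
  if (length(cols) == 0) abort("no probe columns in score table")
  rows <- purrr::map_dfr(cols, function(cn) {
    ok <- !is.na(scores[[cn]]) & !is.na(scores[[measure]])
    x <- scores[[cn]][ok]; y <- scores[[measure]][ok]
    res <- spearman_test(x, y)
    tibble(probe_id = cn, measure = measure, rho = res$rho,
           p_value = res$p_value, n = res$n)
  })
  usable <- !is.na(rows$p_value)
  rows$q_value <- NA_real_
  if (any(usable)) {
    rows$q_value[usable] <- bh_fdr(rows$p_value[usable])$q_value
  }
  rows
}

spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant column: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 10 && !ties))
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Split a cohort into low- and high-pain groups
#'
#' Classifies each interview as low pain when `vas <= vas_threshold` OR
#' `nrs <= nrs_threshold` (under `combine = "or"`, the default), otherwise
#' high pain; `"vas_only"`/`"nrs_only"` use a single scale.
#'
#' @param scores A `cohort_scores` table (or any tibble) with
#'   `interview_id` plus the clinical columns the rule requires.
#' @param vas_threshold VAS cut point (default 30).
#' @param nrs_threshold NRS cut point (default 3).
#' @param combine `"or"`, `"vas_only"`, or `"nrs_only"`.
#' @return Tibble `interview_id`, `group` (factor `low`/`high`).
#' @export
group_split_pain <- function(scores, vas_threshold = 30, nrs_threshold = 3,
                             combine = c("or", "vas_only", "nrs_only")) {
  combine <- match.arg(combine)
  if (vas_threshold < 0 || vas_threshold > 100) abort("vas_threshold outside [0, 100]")
  if (nrs_threshold < 0 || nrs_threshold > 10) abort("nrs_threshold outside [0, 10]")
  need <- switch(combine, or = c("nrs", "vas"), vas_only = "vas", nrs_only = "nrs")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0) {
    abort(sprintf("group rule requires column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- scores$interview_id[rowSums(is.na(scores[, need, drop = FALSE])) > 0]
  if (length(bad) > 0) {
    abort(sprintf("missing clinical scores for interview(s): %s",
                  paste(bad, collapse = ", ")))
  }
  low <- switch(combine,
    or = scores$vas <= vas_threshold | scores$nrs <= nrs_threshold,
    vas_only = scores$vas <= vas_threshold,
    nrs_only = scores$nrs <= nrs_threshold
  )
  tibble(
    interview_id = scores$interview_id,
    group = factor(ifelse(low, "low", "high"), levels = c("low", "high"))
  )
}

#' Compare probe scores between pain groups
#'
#' Two-sample KS test of one probe's robust-maximum scores between the
#' low- and high-pain groups.
#'
#' @param scores A `cohort_scores` table.
#' @param probe_id Probe column, e.g. `"mpq_cramping__anchor"`.
#' @param labels Tibble from [group_split_pain()].
#' @param method KS method, see [ks_two_sample()].
#' @return A `pain_ks` object.
#' @export
group_comparison <- function(scores, probe_id, labels,
                             method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  vals <- get_probe_scores(scores, probe_id)
  grp <- labels$group[match(scores$interview_id, labels$interview_id)]
  if (anyNA(grp)) abort("labels missing for some interviews")
  for (g in c("low", "high")) {
    if (!any(grp == g)) abort(sprintf("empty group: %s", g))
  }
  if (any(table(grp) < 5)) {
    warn("fewer than 5 interviews in a pain group; test is underpowered")
  }
  ks_two_sample(vals[grp == "low"], vals[grp == "high"], method = method)
}
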