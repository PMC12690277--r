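test_that("exact KS p-values match small closed-form cases", {
  expect_equal(ks_p_from_statistic(0, 5, 7), 1)
  # n = m = 2, D = 1: 2 of the 6 interleavings fully separate
  expect_equal(ks_p_from_statistic(1, 2, 2, "exact"), 1 / 3)
  # full separation generally: p = 2 / C(n+m, n)
  expect_equal(ks_p_from_statistic(1, 3, 3, "exact"), 2 / choose(6, 3))
  expect_equal(ks_p_from_statistic(1, 20, 20, "exact"), 2 / choose(40, 20))
  expect_error(ks_p_from_statistic(1.2, 3, 3), "\\[0, 1\\]")
  expect_error(ks_p_from_statistic(0.5, 0, 3), "sizes")
})

test_that("exact KS p agrees with complete interleaving enumeration (n+m <= 10)", {
  for (n in 1:5) {
    for (m in n:(10 - n)) {
      d_null <- enumerate_ks_null(n, m)
      for (d in sort(unique(d_null))) {
        expect_equal(
          ks_p_from_statistic(d, n, m, "exact"),
          mean(d_null >= d - 1e-12),
          tolerance = 1e-12,
          label = sprintf("exact p at n=%d m=%d d=%.4f", n, m, d)
        )
      }
    }
  }
})

test_that("exact KS matches the reference distribution function at n = m = 20", {
  for (d in seq(0.05, 1, by = 0.05)) {
    expect_equal(
      ks_p_from_statistic(d, 20, 20, "exact"),
      stats::psmirnov(d, sizes = c(20, 20), two.sided = TRUE,
                      lower.tail = FALSE, exact = TRUE),
      tolerance = 1e-6
    )
  }
  # unequal sizes too
  expect_equal(ks_p_from_statistic(0.5, 12, 7, "exact"),
               stats::psmirnov(0.5, sizes = c(12, 7), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("asymptotic KS approaches the exact value for moderate samples", {
  p_exact <- ks_p_from_statistic(0.2, 80, 80, "exact")
  p_asym <- ks_p_from_statistic(0.2, 80, 80, "asymptotic")
  expect_lt(abs(p_exact - p_asym) / p_exact, 0.2)
})

test_that("two-sample KS computes the ECDF supremum and routes methods", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3), method = "asymptotic")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 1)
  expect_equal(sep$p_value, 1 / 3)
  expect_equal(sep$method, "exact")
  # 19 of 20 x below all y forces D = 0.95
  x <- c(seq_len(19) / 100, 10)
  y <- seq(1, 20) + 100
  y[1] <- 0.5 # interleave one
  ks <- ks_two_sample(x, jitter(y, amount = 1e-3))
  expect_equal(ks$statistic, 0.95)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  td <- tidy(sep)
  expect_equal(td$statistic, 1)
  expect_equal(td$p_value, 1 / 3)
})

test_that("BH step-up reproduces brute-force adjustment and handles partial lists", {
  expect_equal(bh_fdr(0.04, m_total = 1)$q_value, 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03))$q_value, rep(0.03, 3))
  # brute-force oracle on random lists
  brute_bh <- function(p, M) {
    o <- order(p)
    q <- vapply(seq_along(p), function(i) {
      min(1, min(p[o][seq_along(p) >= i] * M / which(seq_along(p) >= i)))
    }, numeric(1))
    out <- numeric(length(p)); out[o] <- q; out
  }
  set.seed(3)
  for (rep in 1:25) {
    p <- runif(sample(2:15, 1))
    expect_equal(bh_fdr(p)$q_value, brute_bh(p, length(p)), tolerance = 1e-12)
    M <- length(p) + sample(0:20, 1)
    expect_equal(bh_fdr(p, M)$q_value, brute_bh(p, M), tolerance = 1e-12)
  }
  p <- runif(10)
  expect_true(all(bh_fdr(p)$q_value >= p))
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m_total = 1), "m_total")
})

test_that("Spearman correlation handles monotone, tied and constant inputs", {
  s1 <- painlang:::spearman_test(1:10, (1:10)^3)
  expect_equal(s1$rho, 1)
  s2 <- painlang:::spearman_test(1:10, -(1:10))
  expect_equal(s2$rho, -1)
  s3 <- painlang:::spearman_test(c(1, 2, 3), c(2, 1, 3))
  expect_equal(s3$rho, 0.5)
  expect_warning(s4 <- painlang:::spearman_test(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s4$rho))
  # invariant under strictly monotone transforms
  set.seed(9)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(painlang:::spearman_test(x, y)$rho,
               painlang:::spearman_test(exp(x), rank(y))$rho)
})

test_that("pain group split applies the VAS<=30 OR NRS<=3 rule at its boundaries", {
  tb <- tibble::tibble(
    interview_id = c("a", "b", "c", "d"),
    nrs = c(5, 3, 7, 2), vas = c(30, 50, 60, 10)
  )
  lab <- group_split_pain(tb)
  expect_equal(as.character(lab$group), c("low", "low", "high", "low"))
  expect_equal(as.character(group_split_pain(tb, combine = "vas_only")$group),
               c("low", "high", "high", "low"))
  expect_equal(as.character(group_split_pain(tb, combine = "nrs_only")$group),
               c("high", "low", "high", "low"))
  tb$nrs[[2]] <- NA
  expect_error(group_split_pain(tb), "missing clinical")
  expect_error(group_split_pain(tb, vas_threshold = 120), "vas_threshold")
})

test_that("group comparison tests low vs high scores with exact small-sample p", {
  tb <- tibble::tibble(
    interview_id = sprintf("p%d", 1:6),
    pair__anchor = c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15),
    nrs = c(1, 2, 3, 8, 9, 7), vas = c(10, 20, 15, 80, 90, 70)
  )
  lab <- group_split_pain(tb)
  expect_warning(ks <- group_comparison(tb, "pair__anchor", lab), "underpowered")
  expect_equal(ks$statistic, 1)
  expect_equal(ks$p_value, 2 / choose(6, 3)) # = 0.1, fully separated 3 vs 3
  one_group <- tibble::tibble(
    interview_id = c("a", "b"), pair__anchor = c(0.5, 0.6),
    nrs = c(1, 2), vas = c(5, 10)
  )
  lab2 <- group_split_pain(one_group)
  expect_error(suppressWarnings(group_comparison(one_group, "pair__anchor", lab2)),
               "empty group: high")
})

test_that("anchor-antithesis table mirrors per-pair KS tests with FDR", {
  emb <- shared_embedder()
  co <- generate_cohort(synthetic_config(n_patients = 8, seed = 21,
                                         sentences_per_interview = c(30, 60)))
  s <- segment_sentences(co$utterances)
  tb <- build_cohort_table(s, builtin_anchor_pairs(), emb,
                           clinical = co$clinical)
  at <- suppressWarnings(anchor_antithesis_tests(tb))
  expect_equal(nrow(at), 7L)
  expect_false(is.unsorted(at$p_value))
  expect_true(all(at$q_value >= at$p_value))
  one <- suppressWarnings(anchor_antithesis_test(tb, "mpq_cramping"))
  expect_equal(at$p_value[at$pair_id == "mpq_cramping"], one$p_value)
  expect_error(anchor_antithesis_test(tb, "nonexistent"), "probe column")
  # identical anchor/antithesis scores give D = 0, p = 1
  fake <- tb
  fake$mpq_cramping__antithesis <- fake$mpq_cramping__anchor
  same <- suppressWarnings(anchor_antithesis_test(fake, "mpq_cramping"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("correlate_scores reports rho per probe with companion FDR", {
  emb <- shared_embedder()
  co <- generate_cohort(synthetic_config(n_patients = 10, seed = 22,
                                         sentences_per_interview = c(30, 60)))
  s <- segment_sentences(co$utterances)
  tb <- build_cohort_table(s, painvar_pair(), emb, clinical = co$clinical)
  cs <- correlate_scores(tb, "nrs")
  expect_equal(nrow(cs), 2L)
  expect_true(all(abs(cs$rho) <= 1, na.rm = TRUE))
  expect_true(all(cs$q_value >= cs$p_value, na.rm = TRUE))
  expect_error(correlate_scores(dplyr::select(tb, -"nrs"), "nrs"), "nrs")
})
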