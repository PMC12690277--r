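test_that("cohort generation is byte-identical given a seed", {
  cfg <- synthetic_config(n_patients = 3, seed = 99,
                          sentences_per_interview = c(10, 30))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(synthetic_config(n_patients = 3, seed = 100,
                                         sentences_per_interview = c(10, 30)))
  expect_false(identical(c1$utterances$text, c3$utterances$text))
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_cohort(synthetic_config(n_patients = 2,
    seed = 1, sentences_per_interview = c(5, 10)))); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate configurations behave as documented", {
  empty <- generate_cohort(synthetic_config(n_patients = 0))
  expect_equal(nrow(empty$utterances), 0L)
  expect_equal(nrow(empty$clinical), 0L)
  bank <- default_template_bank()
  bank$neutral <- character(0)
  expect_error(synthetic_config(template_bank = bank), "empty template bank")
  expect_error(synthetic_config(template_bank = bank[c(1, 2, 4)]), "lacks bank")
})

test_that("mixture weights are a valid severity-monotone simplex", {
  cfg <- synthetic_config()
  w <- mixture_weights(seq(0, 10, by = 0.5), cfg)
  expect_equal(rowSums(w), rep(1, nrow(w)))
  expect_true(all(w >= 0))
  expect_false(is.unsorted(w[, "pain_descriptor"]))
  expect_false(is.unsorted(w[, "dissatisfaction"]))
  expect_false(is.unsorted(rev(w[, "positive"])))
  expect_false(is.unsorted(rev(w[, "neutral"])))
  # severity 0 at very steep slope: pain weight numerically zero, and no
  # pain-descriptor sentences are ever sampled
  steep <- synthetic_config(mix_slope = 200, severity_range = c(0, 0),
                            n_patients = 2, seed = 4,
                            sentences_per_interview = c(50, 80))
  expect_equal(mixture_weights(0, steep)[1, "pain_descriptor"],
               c(pain_descriptor = 0))
  co <- generate_cohort(steep)
  pain_texts <- unlist(default_template_bank()$pain_descriptor)
  hit <- vapply(pain_texts, function(tpl) {
    any(stringr::str_detect(co$utterances$text, stringr::fixed(
      sub("[.]$", "", tpl))))
  }, logical(1))
  expect_false(any(hit))
  # null configuration: constant weights across severity
  null_w <- mixture_weights(c(0, 5, 10), synthetic_config(mix_slope = 0))
  expect_equal(null_w[1, ], null_w[3, ])
})

test_that("clinical scores derive from severity with clamping and noise", {
  cfg <- synthetic_config(n_patients = 30, seed = 17, nrs_noise_sd = 0,
                          vas_noise_sd = 0, sentences_per_interview = c(1, 2))
  co <- generate_cohort(cfg)
  sev <- co$true_severity$severity
  expect_equal(co$clinical$nrs, as.integer(round(sev)))
  expect_equal(co$clinical$vas, 10 * sev)
  expect_true(all(co$clinical$nrs >= 0 & co$clinical$nrs <= 10))
  expect_true(all(co$clinical$vas >= 0 & co$clinical$vas <= 100))
})

test_that("expected effects describe the generator's ground truth", {
  eff <- expected_effects(synthetic_config())
  expect_equal(eff$expected_sign[eff$quantity == "similarity_positive"], -1)
  expect_equal(eff$expected_sign[eff$quantity == "similarity_pain_descriptor"], 1)
  null_eff <- expected_effects(synthetic_config(mix_slope = 0))
  sim_rows <- grepl("^similarity", null_eff$quantity)
  expect_true(all(null_eff$expected_sign[sim_rows] == 0))
  expect_true(all(null_eff$expected_sign[null_eff$quantity %in% c("nrs", "vas")] == 1))
})

test_that("interview lengths span the configured range and speech rate is near target", {
  cfg <- synthetic_config(n_patients = 12, seed = 31,
                          sentences_per_interview = c(20, 200))
  co <- generate_cohort(cfg)
  m <- compute_interview_metrics(co$utterances)
  per <- m[m$interview_id != "cohort", ]
  expect_gt(max(per$duration_min) / min(per$duration_min), 2)
  expect_true(all(abs(per$words_per_minute - 116) < 15))
  expect_true(all(per$pct_time_patient > 60 & per$pct_time_patient <= 100))
})

test_that("written cohorts are read back through the standard transcript readers", {
  co <- generate_cohort(synthetic_config(n_patients = 2, seed = 8,
                                         sentences_per_interview = c(5, 15)))
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$utterances, co$utterances)
  expect_equal(back$clinical$nrs, co$clinical$nrs)
})

test_that("a strong severity-content link separates pain groups in most replicates", {
  emb <- shared_embedder()
  reg <- whoqol_pair()
  rejected <- vapply(1:100, function(r) {
    co <- generate_cohort(synthetic_config(
      n_patients = 20, seed = 2000 + r, mix_slope = 6,
      sentences_per_interview = c(40, 80)
    ))
    s <- segment_sentences(co$utterances)
    tb <- suppressWarnings(build_cohort_table(s, reg, emb,
                                              clinical = co$clinical))
    lab <- group_split_pain(tb)
    ks <- suppressWarnings(
      tryCatch(group_comparison(tb, "whoqol_work__anchor", lab),
               error = function(e) NULL)
    )
    !is.null(ks) && ks$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})
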