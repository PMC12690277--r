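#' Default sentence template banks for synthetic interviews
#'
#' Four banks of short first-person sentences: pain descriptors and
#' dissatisfaction statements (sampled more often at high latent
#' severity), and neutral and positive/satisfaction statements (sampled
#' more often at low severity). The wording is thematically aligned with
#' the built-in questionnaire anchors (throbbing/cramping descriptors,
#' work- and daily-activity satisfaction), so even a purely lexical
#' embedding backend recovers the designed severity structure.
#'
#' @return Named list of character vectors: `pain_descriptor`,
#'   `dissatisfaction`, `neutral`, `positive`.
#' @export
default_template_bank <- function() {
  list(
    pain_descriptor = c(
      "My back pain is throbbing all day long.",
      "The pain in my lower back is cramping and sharp.",
      "It feels like a stabbing pain shooting down my leg.",
      "My pain is splitting whenever I bend over.",
      "The pain is tiring and exhausting by the evening.",
      "I am in pain from the moment I wake up.",
      "My lower back aches constantly and never lets go.",
      "Some days the pain in my back is unbearable.",
      "The burning in my back keeps me awake at night.",
      "My pain flares up badly when I stand too long."
    ),
    dissatisfaction = c(
      "I cannot work the way I used to anymore.",
      "I had to give up my job because of my back.",
      "I am unable to do my daily activities without help.",
      "I struggle to perform my daily living activities.",
      "My work suffers badly because of the pain.",
      "I cannot focus on anything when the pain starts.",
      "I am unhappy with how little I can get done.",
      "Housework has become almost impossible for me.",
      "I feel useless around the house these days.",
      "I am dissatisfied with my capacity for work."
    ),
    neutral = c(
      "I live with my family in a small house near town.",
      "I usually wake up around seven in the morning.",
      "We watch television together in the evening.",
      "My daughter visits us on the weekends.",
      "I drive to the grocery store once a week.",
      "The weather has been cold this winter.",
      "I worked as a teacher for many years.",
      "We moved to this neighborhood a long time ago.",
      "I like to cook dinner for my family.",
      "My neighbor helps me with the garden sometimes."
    ),
    positive = c(
      "I am satisfied with my capacity for work.",
      "I am satisfied with my ability to perform my daily living activities.",
      "I am able to focus on my work without trouble.",
      "I feel rested and fresh when I wake up.",
      "I have no pain on most days now.",
      "My back feels fine most of the time.",
      "I can walk for an hour without any trouble.",
      "I enjoy my work and my hobbies a great deal.",
      "I am happy with my quality of life.",
      "I sleep well through the whole night."
    )
  )
}

# Disfluency fillers: spontaneous speech is lexically varied, so each
# template is realised with optional prefix/suffix fillers. This also
# spreads the per-sentence similarity values over many distinct levels,
# as continuous-valued embeddings of real speech would be.
filler_prefixes <- c("", "You know,", "I mean,", "Honestly,", "Well,",
                     "To be honest,", "I guess")
filler_suffixes <- c("", "these days", "most of the time", "lately",
                     "as I said", "more or less")

apply_fillers <- function(texts) {
  pre <- sample(filler_prefixes, length(texts), replace = TRUE)
  suf <- sample(filler_suffixes, length(texts), replace = TRUE)
  out <- ifelse(nzchar(pre), paste(pre, texts), texts)
  has_suf <- nzchar(suf)
  out[has_suf] <- paste0(sub("[.]$", "", out[has_suf]), ", ", suf[has_suf], ".")
  out
}

interviewer_prompts <- c(
  "Can you tell me more about that?",
  "How does that affect your day?",
  "What happened next?",
  "How long has that been going on?",
  "What does a typical morning look like for you?",
  "How do you feel about that?"
)

#' Configuration for the synthetic cohort generator
#'
#' Encodes the study conditions the generator emulates: a cohort of 20
#' patients, interviews from under 10 minutes to over half an hour at a
#' natural speech rate near 116 words per minute with the patient speaking
#' most of the time, and a latent pain-severity variable driving both the
#' reported NRS/VAS scores and the mixture of pain-related versus
#' neutral/positive utterances.
#'
#' The content mixture uses a logistic link: with
#' `g = plogis(mix_slope * (severity - mix_midpoint))`, the sampling
#' weights are `0.35 g` (pain descriptors), `0.25 g` (dissatisfaction),
#' `0.35 (1 - g)` (positive) and `0.65 - 0.25 g` (neutral); they sum to 1
#' at every severity, pain-related weights increase with severity, and
#' positive/neutral weights decrease. `mix_slope` is the single
#' effect-size knob: 0 gives a null cohort whose language carries no
#' severity signal.
#'
#' @param n_patients Number of patients (default 20).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param severity_range Latent severity is uniform on this range
#'   (default `c(0, 10)`).
#' @param sentences_per_interview Inclusive integer range of patient
#'   sentence counts (default `c(60, 400)`).
#' @param template_bank Named list of sentence banks, see
#'   [default_template_bank()].
#' @param mix_slope Logistic slope of the severity-to-content link
#'   (default 0.8).
#' @param mix_midpoint Severity at which pain-related and positive content
#'   balance (default 4, the usual moderate-pain NRS cut point).
#' @param nrs_noise_sd,vas_noise_sd Reporting noise SDs on
#'   `NRS = clamp(round(severity + noise), 0, 10)` and
#'   `VAS = clamp(10 severity + noise, 0, 100)` (defaults 0.8 and 7).
#' @param words_per_minute Target speech rate used to synthesize
#'   timestamps (default 116).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20L, seed = 1L,
                             severity_range = c(0, 10),
                             sentences_per_interview = c(60L, 400L),
                             template_bank = default_template_bank(),
                             mix_slope = 0.8, mix_midpoint = 4,
                             nrs_noise_sd = 0.8, vas_noise_sd = 7,
                             words_per_minute = 116) {
  stopifnot(n_patients >= 0, length(severity_range) == 2,
            length(sentences_per_interview) == 2,
            sentences_per_interview[1] >= 1,
            sentences_per_interview[1] <= sentences_per_interview[2],
            nrs_noise_sd >= 0, vas_noise_sd >= 0, words_per_minute > 0)
  need <- c("pain_descriptor", "dissatisfaction", "neutral", "positive")
  miss <- setdiff(need, names(template_bank))
  if (length(miss) > 0) {
    abort(sprintf("template_bank lacks bank(s): %s", paste(miss, collapse = ", ")))
  }
  empty <- need[vapply(template_bank[need], length, integer(1)) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty template bank(s): %s", paste(empty, collapse = ", ")))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      severity_range = as.numeric(severity_range),
      sentences_per_interview = as.integer(sentences_per_interview),
      template_bank = template_bank,
      mix_slope = mix_slope, mix_midpoint = mix_midpoint,
      nrs_noise_sd = nrs_noise_sd, vas_noise_sd = vas_noise_sd,
      words_per_minute = words_per_minute
    ),
    class = "synthetic_config"
  )
}

#' Mixture weights of the template banks at a given severity
#'
#' @param severity Numeric vector of latent severities.
#' @param config A [synthetic_config()].
#' @return Matrix with one row per severity and columns
#'   `pain_descriptor`, `dissatisfaction`, `neutral`, `positive`; rows sum
#'   to 1.
#' @export
mixture_weights <- function(severity, config) {
  g <- stats::plogis(config$mix_slope * (severity - config$mix_midpoint))
  w <- cbind(
    pain_descriptor = 0.35 * g,
    dissatisfaction = 0.25 * g,
    neutral = 0.65 - 0.25 * g,
    positive = 0.35 * (1 - g)
  )
  w
}

#' Generate a synthetic interview cohort
#'
#' Draws a latent severity per patient, samples each interview's sentences
#' from the template banks with severity-tilted mixture weights, groups
#' sentences into utterances interleaved with short interviewer prompts,
#' synthesizes timestamps at the configured speech rate, and derives noisy
#' NRS/VAS scores from the severity. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `utterances`
#'   (tidy utterance tibble for the whole cohort), `clinical`
#'   (`interview_id`, `nrs`, `vas`) and `true_severity` (`interview_id`,
#'   `severity`).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 2, seed = 7,
#'   sentences_per_interview = c(20, 40)))
#' head(cohort$utterances)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_patients == 0) {
    return(structure(
      list(
        utterances = tibble(interview_id = character(), speaker = character(),
                            text = character(), start_s = numeric(),
                            end_s = numeric()),
        clinical = tibble(interview_id = character(), nrs = integer(),
                          vas = numeric()),
        true_severity = tibble(interview_id = character(), severity = numeric())
      ),
      class = "synthetic_cohort"
    ))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  ids <- sprintf("synth_%02d", seq_len(config$n_patients))
  severity <- runif(config$n_patients, config$severity_range[1],
                    config$severity_range[2])
  utts <- purrr::map_dfr(seq_len(config$n_patients), function(i) {
    generate_interview(ids[[i]], severity[[i]], config)
  })
  nrs <- pmin(10, pmax(0, round(severity + rnorm(length(severity), 0, config$nrs_noise_sd))))
  vas <- pmin(100, pmax(0, 10 * severity + rnorm(length(severity), 0, config$vas_noise_sd)))
  structure(
    list(
      utterances = utts,
      clinical = tibble(interview_id = ids, nrs = as.integer(nrs), vas = vas),
      true_severity = tibble(interview_id = ids, severity = severity)
    ),
    class = "synthetic_cohort"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

generate_interview <- function(id, severity, config) {
  lo <- config$sentences_per_interview[1]
  hi <- config$sentences_per_interview[2]
  n_sent <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  w <- mixture_weights(severity, config)[1, ]
  banks <- names(w)[w > 0]
  cat_draw <- sample(banks, n_sent, replace = TRUE, prob = w[banks])
  texts <- vapply(cat_draw, function(b) {
    bank <- config$template_bank[[b]]
    bank[[sample.int(length(bank), 1L)]]
  }, character(1), USE.NAMES = FALSE)
  texts <- apply_fillers(texts)
  # group consecutive sentences into utterances of 1-3, with an
  # interviewer prompt every few patient utterances
  sizes <- integer(0)
  remaining <- n_sent
  while (remaining > 0) {
    s <- min(remaining, sample.int(3L, 1L))
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  patient_text <- vapply(split(texts, rep(seq_along(sizes), sizes)),
                         paste, character(1), collapse = " ")
  prompt_every <- sample(2:8, 1L)
  speakers <- character(0); all_text <- character(0)
  for (k in seq_along(patient_text)) {
    all_text <- c(all_text, patient_text[[k]]); speakers <- c(speakers, "patient")
    if (k %% prompt_every == 0 && k < length(patient_text)) {
      all_text <- c(all_text,
                    interviewer_prompts[[sample.int(length(interviewer_prompts), 1L)]])
      speakers <- c(speakers, "interviewer")
    }
  }
  words <- stringr::str_count(all_text, "\\S+")
  rate <- pmax(60, rnorm(length(words), config$words_per_minute, 8)) # wpm
  dur_s <- words / rate * 60
  gap_s <- runif(length(words), 0.2, 1.5)
  end_s <- cumsum(dur_s + gap_s)
  start_s <- end_s - dur_s
  tibble(interview_id = id, speaker = speakers, text = all_text,
         start_s = round(start_s, 3), end_s = round(end_s, 3))
}

#' Ground-truth relationships built into a synthetic configuration
#'
#' States the signed, monotone relationships the generator guarantees so
#' recovery tests can check the pipeline against them: similarity of
#' patient speech to pain-descriptor and dissatisfaction probes increases
#' with latent severity, similarity to positive/satisfaction probes
#' decreases, neutral content carries no signal, and NRS/VAS increase
#' with severity. All content effects are scaled by the sign of
#' `mix_slope`; a slope of 0 is the null configuration in which every
#' expected content correlation is 0.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `quantity`, `versus`, `expected_sign`
#'   (-1, 0 or +1).
#' @export
expected_effects <- function(config) {
  s <- sign(config$mix_slope)
  tibble(
    quantity = c("similarity_pain_descriptor", "similarity_dissatisfaction",
                 "similarity_neutral", "similarity_positive", "nrs", "vas"),
    versus = "latent_severity",
    expected_sign = c(s, s, 0, -s, 1, 1)
  )
}

#' Write a synthetic cohort to disk
#'
#' One JSON-lines transcript per interview plus `clinical.csv` and
#' `true_severity.csv`, so the synthetic path exercises the same readers
#' as real data.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in unique(cohort$utterances$interview_id)) {
    u <- dplyr::filter(cohort$utterances, .data$interview_id == id)
    write_transcript_jsonl(u, file.path(dir, paste0(id, ".jsonl")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$true_severity, file.path(dir, "true_severity.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `*.jsonl` transcripts and
#'   `clinical.csv`.
#' @return List with `utterances` and `clinical` tibbles.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no .jsonl transcripts in %s", dir))
  utts <- purrr::map_dfr(files, read_transcript, dialect = "jsonl")
  clin_path <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clin_path)) read_clinical(clin_path) else NULL
  list(utterances = utts, clinical = clinical)
}
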