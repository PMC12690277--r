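# painlang

Quantitative semantic analysis of chronic pain narratives.

Subjective report is the gold standard for assessing chronic pain, and the
richest form of that report is the patient's own open-ended "pain story".
`painlang` turns recorded two-speaker interview transcripts into
quantitative, questionnaire-anchored measures of the pain experience, for
researchers in pain phenotyping and patient-reported outcomes who want
language-derived markers next to the usual rating scales (NRS 0–10,
VAS 0–100).

## Method

For every sentence *s* uttered by the patient, and every probe sentence
*a* (an **anchor** drawn from a validated questionnaire such as the McGill
Pain Questionnaire — e.g. *"My pain is throbbing"* — or its **antithesis**
— *"My pain is steady"*), the package computes the cosine similarity of
their sentence embeddings,

    sim(s, a) = ⟨v(s), v(a)⟩ / (‖v(s)‖ ‖v(a)‖).

The per-interview distribution of similarities to one probe is reduced to
its **robust maximum**: the 95th percentile, an outlier-resistant proxy
for "how close did this patient ever get to saying this", insensitive to
interview length. The cohort-level analysis then asks:

* **Anchor vs antithesis** — across patients, do the robust maxima for an
  anchor and its antithesis differ? Tested with the *exact* two-sample
  Kolmogorov–Smirnov test (lattice-path null distribution, required at
  n = 20 per side where asymptotics fail badly), with Benjamini–Hochberg
  FDR correction across pairs.
* **Relation to reported pain** — Spearman correlation of probe scores
  with NRS/VAS, and an exact KS comparison between low-pain
  (VAS ≤ 30 or NRS ≤ 3) and high-pain groups.

Embeddings go through a pluggable backend: a deterministic hashed
character n-gram encoder ships with the package (no downloads, used by
all tests), and any pretrained sentence encoder can be plugged in via
`embedder(backend = "transformer", embed_fun = ...)`.

Because real interview corpora of this kind are confidential, the package
includes a seeded synthetic-cohort generator (`generate_cohort()`) whose
latent pain-severity variable drives both the reported NRS/VAS scores and
the mixture of pain-related versus neutral/positive speech, giving every
pipeline stage a testable ground truth.

## Worked example

```r
library(painlang)

cohort    <- generate_cohort(synthetic_config(n_patients = 20, seed = 42))
sentences <- segment_sentences(cohort$utterances)   # patient channel only
emb       <- hashed_embedder()                      # 1024-dim, deterministic

scores <- build_cohort_table(sentences, builtin_anchor_pairs(), emb,
                             clinical = cohort$clinical)
anchor_antithesis_tests(scores)
#> # A tibble: 7 × 8   (pair_id, ks_stat, p_value, q_value, method shown)
#>   pair_id         ks_stat    p_value    q_value method
#> 1 mpq_throbbing      0.8  0.00000133 0.00000928 exact
#> 2 mpq_stabbing       0.75 0.00000955 0.0000334  exact
#> 3 mpq_splitting      0.7  0.0000557  0.000130   exact
#> 4 mpq_cramping       0.6  0.00112    0.00195    exact
#> 5 painvar_in_pain    0.55 0.00397    0.00555    exact
#> 6 promis_focus       0.5  0.0123     0.0143     exact
#> 7 mpq_tiring         0.35 0.175      0.175      exact
```

Each row compares the 20 per-patient robust maxima for an anchor with
those for its antithesis: `ks_stat` is the ECDF separation D, `p_value`
the exact two-sided KS p, `q_value` the FDR-adjusted value. Six of seven
pairs separate cleanly because high-severity synthetic patients use
pain-descriptor language that low-severity patients do not.

Scores track reported pain intensity in the expected direction:

```r
dplyr::arrange(correlate_scores(scores, "nrs", sides = "anchor"), p_value)
#> 1 painvar_in_pain__anchor nrs  0.816 0.0000114  20 0.0000798
#> 2 mpq_tiring__anchor      nrs  0.684 0.000874   20 0.00306
```

The exact KS machinery is available directly; for example the p-value of
a separation of D = 0.95 between two groups of 20:

```r
ks_p_from_statistic(0.95, 20, 20, "exact")
#> [1] 5.803555e-10
```

`run_pipeline(pipeline_config(...))` executes the whole chain
(read → segment → embed → score → test) and writes the score table,
anchor-test and correlation tables, corpus metrics, a grouped CDF export
and a JSON run manifest; `inst/cli/painlang.R` wraps it for shell use.

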