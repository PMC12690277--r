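---
title: "Anchored semantic scoring of pain narratives: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored semantic scoring of pain narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painlang)
```

## The measurement model

`painlang` quantifies how close a patient's spontaneous speech comes to
the standardized assertions of validated pain questionnaires. The
measurement chain is:

1. **Transcripts** are two-speaker utterance sequences. Only the patient
   channel is scored (the interviewer channel is kept for the
   percentage-of-time-spoken metric); transcripts are consumed verbatim,
   with no spell correction or disfluency removal, because edits would
   inject the analyst's language into the patient's.
2. **Sentences** are the unit of analysis. Sentence embeddings represent
   a whole sentence as one vector; no pooling choices are exposed.
3. **Similarity**: cosine similarity between each patient sentence and a
   probe sentence. With vectors L2-normalized at embedding time (the
   package's convention, tolerance 1e-6) cosine is a plain dot product;
   cosine is scale-invariant, so normalization is an internal convenience
   with no effect on results.
4. **Robust maximum**: each interview-by-probe similarity distribution is
   reduced to its 95th percentile. The maximum itself would be driven by
   a single best-matching sentence; the 95th percentile asks that roughly
   the top 5% of sentences approach the probe, which resists outliers and
   — because it is a quantile — is invariant to interview length for
   speech drawn from a stable distribution. The percentile is a tunable
   parameter (`percentile`, default 95, range (0, 100]).
5. **Statistics**: exact two-sample Kolmogorov–Smirnov tests across
   patients (anchor vs antithesis; low- vs high-pain groups),
   Benjamini–Hochberg FDR correction, and Spearman correlations against
   NRS (0–10) and VAS (0–100) pain intensity.

The key modelling assumption is that semantic proximity of spontaneous
speech to a questionnaire assertion carries the same clinical signal as
endorsing that assertion on the questionnaire. The method tests this
assumption rather than presuming it: anchors whose similarity
distributions do not separate from their antitheses are reported as
non-significant, not hidden.

## Anchor pairs

An anchor is a short declarative sentence derived from a validated
instrument (McGill Pain Questionnaire descriptors, PROMIS pain
interference, WHOQOL quality-of-life items, a pain-variability item); its
antithesis asserts the opposite state. Seven pairs ship built in
(`builtin_anchor_pairs()`); further pairs are user-supplied through a TSV
or YAML registry, since the full anchor family used in any given study is
a scientific choice, not a package constant.

Two design details deserve note:

* **Negation lint.** Sentence encoders are known to misread negation, so
  antitheses are best phrased positively ("My pain is steady" rather than
  "My pain is not throbbing"). `lint_negation()` flags the surface tokens
  `no, not, never, n't, none, nothing`; it deliberately uses a
  surface-token definition, so morphological negation ("unable",
  "dissatisfied") is not flagged. The lint warns and never blocks: one
  built-in pair legitimately contains "I have no pain", and removing it
  would change the science, not the hygiene.
* **`m_total`.** FDR correction divides by the rank among *all* tests
  performed. A registry that is a printed subset of a larger tested
  family would understate the correction if `m_total` defaulted to its
  own size, so `m_total` is explicit: it defaults to the registry size
  and can be set higher (e.g. `m_total = 33` when the seven built-in
  pairs stand in for a 33-pair family). The package does not invent the
  unpublished pairs.

## Embedding backends

Downstream code only assumes a fixed dimension and deterministic output,
so backends are interchangeable:

* `hashed_embedder()` — character n-grams (n = 3..5, over the lowercased,
  space-padded sentence) hashed with a signed two-hash scheme into 1024
  buckets, then L2-normalized. The two polynomial hashes are computed
  modulo a prime below 2^26 so all arithmetic is exact in doubles on any
  platform. This backend is purely lexical: it sees shared word
  fragments, not meaning. It exists so that the package is fully testable
  and deterministic with no model download, and 1024 dimensions mirror
  the large pretrained sentence encoders typically used in production.
* `embedder(backend = "transformer", embed_fun = ...)` — any pretrained
  sentence encoder the user wraps in a function. Requesting this backend
  without supplying `embed_fun` is a capability error that points back to
  the hashed backend.

Embeddings are cached in memory per embedder object, keyed by sentence
text, so repeated sentences and repeated analyses embed each distinct
sentence once.

## The synthetic cohort generator

Interview corpora in this domain are confidential, so the generator
provides cohorts with a known ground truth. It emulates the study
conditions the analysis is designed for: 20 patients; interviews of 60 to
400 patient sentences (roughly ten minutes to over half an hour at
speech rate); timestamps synthesized at ~116 words per minute with short
interviewer prompts interleaved so the patient speaks most of the time;
and a latent severity variable drawn uniformly on [0, 10] that drives
everything observable.

Severity acts through two channels:

* **Reported scores**: `NRS = clamp(round(severity + ε), 0, 10)` with
  ε ~ N(0, 0.8), and `VAS = clamp(10·severity + ε, 0, 100)` with
  ε ~ N(0, 7). Severity is uniform rather than matched to any particular
  cohort's mean because uniform coverage keeps correlation-recovery tests
  well posed across the whole scale.
* **Content**: each sentence is drawn from four template banks with
  severity-tilted weights. With `g = plogis(mix_slope · (severity −
  mix_midpoint))`, the weights are `0.35 g` (pain descriptors), `0.25 g`
  (dissatisfaction), `0.35 (1 − g)` (positive/satisfaction) and
  `0.65 − 0.25 g` (neutral). They form a simplex at every severity;
  pain-related content rises monotonically with severity and
  positive content falls. `mix_slope` (default 0.8) is the single
  effect-size knob — 0 gives a null cohort whose language carries no
  severity signal — and `mix_midpoint` defaults to 4, the conventional
  moderate-pain cut point on the NRS. Templates are realised with random
  disfluency fillers ("You know, …", "…, these days.") so that, as with
  real speech, almost every uttered sentence is lexically distinct and
  similarity values spread over many levels rather than collapsing onto
  a few tied atoms.

The template banks are deliberately aligned with the built-in anchors
(throbbing/cramping/stabbing descriptors, work- and daily-activity
satisfaction), so even the lexical hashed backend recovers the designed
monotone structure. `expected_effects()` states the guaranteed signs.

What the generator does **not** emulate: discourse structure, topic
drift, ASR transcription errors, and realistic lexical richness (a
template bank has a vocabulary of a few hundred words, so type–token
ratios are far below those of natural speech). Passing recovery tests
therefore demonstrates that the pipeline's plumbing and statistics are
correct and directionally faithful — not that any particular embedding
backend captures clinical meaning in real interviews.

## Numerical and procedural choices

* **Percentile convention.** Linear interpolation between closest order
  statistics (`h = (n−1)p/100`, quantile type 7, the common scientific
  default). The convention is isolated in `robust_max()` so it can be
  swapped; nearest-rank alternatives differ only at small n.
* **Exact KS p-values.** At n = m = 20 the asymptotic KS distribution is
  off by orders of magnitude in the far tail, so the package computes the
  exact null by counting monotone lattice paths: an interleaving of the
  two samples is a path from (0,0) to (n,m), its maximal deviation
  `|i/n − j/m|` is its D statistic, and all `C(n+m, n)` paths are equally
  likely under the null. The count of paths staying strictly below the
  observed deviation is accumulated by dynamic programming on the integer
  lattice (`|i·m − j·n|` versus `ceiling(n·m·d)`), which involves only
  exact integer arithmetic in doubles for the sizes where the exact
  method is used (`n·m ≤ 10^4`; beyond that the Kolmogorov limiting
  distribution takes over). Ties violate the continuity assumption of
  the exact null, so tied samples fall back to the asymptotic form with
  a warning.
* **BH tie handling.** Standard step-up: `q(i) = min_{j≥i} p(j)·m/j`,
  ties sharing the adjusted value of their largest tied rank, clipped at
  1. Some published tables instead assign tied p-values the adjusted
  value of their *smallest* tied rank, which is anti-conservative; the
  package implements the standard procedure, so reproductions of such
  tables agree at untied ranks and differ (conservatively) at tied ones.
* **Spearman p-values.** `stats::cor.test` supplies the small-sample
  exact null for n ≤ 10 without ties and the t approximation otherwise;
  constant columns yield an `NA` sentinel with a warning rather than an
  error, since one degenerate probe should not abort a cohort analysis.
* **Group rule.** Low pain iff VAS ≤ 30 **or** NRS ≤ 3 (both thresholds
  and the combination rule configurable). Boundary values are classified
  low, matching the inclusive inequalities.
* **Degenerate inputs.** Zero-duration interviews report speech rate as
  `NA`, never infinity; empty sentence sets are an error at scoring but
  an empty *segmentation* result is allowed (with a message) because an
  interviewer-only selection is legitimate; a single-interview cohort
  produces scores but skips the statistical layer with a warning.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
percentiles against explicit sort-and-interpolate (1000 random samples),
exact KS p-values against complete enumeration of all interleavings for
n + m ≤ 12 and against R's reference distribution at n = m = 20, BH
against brute-force step-up evaluation, and the full pipeline against
the generator's ground truth.

Two simulation suites are sized for a single CPU. The type-I-error
calibration runs 200 seeded replicates; because an anchor and its
antithesis are different sentences, their similarity distributions differ
by construction even in a null cohort, so the calibration applies the
same two-sample testing procedure where its null genuinely holds: the
same probe scored on two independently generated null cohorts
(`mix_slope = 0`, 20 patients per side). The observed rejection rate at
the 5% level is compared with binomial bounds around the largest
attainable exact test size (the exact KS null is discrete, so the test is
slightly conservative at these sample sizes). The group-separation suite
runs 100 seeded replicates at a steep severity-content link
(`mix_slope = 6`). Both suites use 40–80 sentences per interview — the
robust maximum is length-invariant by design, so per-patient scores are
statistically equivalent to those from full-length interviews while the
suites stay fast.

## Limitations

* The hashed backend measures lexical overlap, not meaning; it validates
  the pipeline but is not a substitute for a pretrained sentence encoder
  in real analyses.
* The exact KS path counting assumes continuous scores; heavily tied
  score columns degrade to the asymptotic approximation.
* Anchor construction remains a content-validity judgement; the package
  checks surface negation but cannot certify that an antithesis is the
  semantic opposite of its anchor.
* With ~20 patients per cohort, only large distributional separations
  reach significance after FDR correction; the statistics are faithful
  to that reality rather than compensating for it.
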