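---
title: "Methods: media-report surveillance of product-related child injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: media-report surveillance of product-related child injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`injurywatch` implements an infoveillance pipeline for product-related
child injury: stories published by news websites and social-media accounts
are searched, filtered, classified, and converted into structured injury
records that support coverage statistics, trend series and early-warning
signal detection. This vignette documents the model and procedure, the
tunable parameters and their defaults, what the synthetic test-bed does and
does not emulate, and the design decisions taken where the design was
genuinely open.

## The unit of analysis and the record schema

The unit of analysis is the media story; one story is assumed to describe
one injury event. From each eligible story the extractor fills a
`structured_record()` over 29 variables, two of which split into
sub-variables (injury outcome into four counts; etiology into a
human-related, a product-related and a free-text detail component), giving
34 leaf fields. Every field is optional: "not stated in the story" is
represented as an absent field, never as zero. Record-level invariants are
checked by `validate_record()` and returned as violations rather than
raised, so that imperfect extractions remain inspectable: counts are
non-negative integers, child deaths/injuries never exceed the
corresponding totals, event dates are 2010 or later for eligible records.

Two field representations deserve a note:

* **Dates carry precision in the ISO string length** (`"2015"`,
  `"2015-09"`, `"2015-09-14"`). Stories often omit the day or month;
  encoding precision in the value keeps serialisation trivial and makes
  the evaluation's precision-aware comparison (`"2015-09-14"` matches a
  gold `"2015-09"`, but not the reverse direction at finer gold precision)
  a string-prefix test.
* **Child age range** defaults to 0–17 inclusive years (the legal minor
  definition in the jurisdiction modelled) and is configurable everywhere
  it is used, because comparable surveillance systems elsewhere use 0–19.

## Dictionary, gazetteer and candidate search

Search and categorical extraction are driven by a six-chapter keyword
dictionary (child, product, injury, environment, activity, other). The
original platform's dictionary is not redistributable, so the shipped
`keyword_dictionary_en.json` is a small, configurable English-pack
stand-in; all dictionary-dependent behaviour is tested against its own
dictionary, not against any particular inventory.

The candidate rule — at least one term from *each* of the child, product
and injury chapters — is the most restrictive reading consistent with the
surveillance topic; the environment/activity/other chapters never gate
candidacy. On the synthetic corpus this rule has perfect recall by
construction (every eligible template realises all three facets), which is
what the recall test demonstrates; real-world recall depends on dictionary
curation and is not claimed.

The two-level gazetteer ships as `gazetteer_cn_synthetic.json`: the 31
real mainland-province names and administrative codes, with 333
prefecture-level units whose *names are synthetic* (pinyin-style strings),
distributed plausibly across provinces (municipalities carry no
prefecture-level units). Totals — the quantities that matter for coverage
statistics — match the real administrative geography. Gazetteer matching is
exact-name (word-bounded), deterministic and testable; fuzzy matching is
deliberately out of scope.

## Eligibility filter

`apply_eligibility_filter()` evaluates independent, individually
switchable rules and reports every failed rule: fiction markers
(movie/film/game vocabulary), jurisdiction (an extracted province must be
a gazetteer province when one is claimed), script share for the active
language pack, child involvement (an extracted child age outside the
configured range fails; otherwise a child-chapter term is required),
product involvement, publication on or after 2010-01-01 (older stories
are not consistently retrievable online, which is why the platform's
collection window starts there), and a topical rule excluding purely
legal/educational commentary (lawsuit/court/verdict markers) that carries
no epidemiological detail. Rule independence makes the filter monotone:
removing a failure trigger can never turn an eligible story ineligible — a
property the test suite checks over trigger subsets.

Near-duplicate suppression treats exact-URL equality as hard identity and
clusters stories with equal normalised titles whose token-shingle (k = 3)
Jaccard body similarity is at least 0.9 (configurable), keeping the
earliest publication as representative. The threshold is conservative:
syndicated reprints are nearly verbatim, while two genuinely distinct
events described with the same template vocabulary fall well below 0.9.

## Classification and the metric suite

The classifier contract is `train_classifier(split, stories, model_spec)`
returning an object whose `predict()` yields a label and a score per
story. The default model is a bag-of-n-grams document-term matrix with
ridge-penalised logistic regression (glmnet, fixed λ = 10⁻³, no internal
cross-validation), chosen because it is deterministic, desk-scale and
linear-separable corpora train to perfection; a fine-tuned transformer is
an intended drop-in behind the same contract, with its weights outside the
package.

`split_dataset()` is stratified and seeded, with overall split sizes
following the ratios exactly by largest-remainder rounding (so 10 000
labelled stories at 8:1:1 give 8000/1000/1000).

The metric suite fixes an averaging convention: **support-weighted**
precision/recall/F1 across both classes plus the positive-class precision,
with "eligible" as the positive class. In the binary case support-weighted
recall is structurally identical to accuracy — the identity that makes a
two-row precision presentation ("average" and "positive") internally
consistent — and specificity is defined as 1 − FPR so that the pair remains
an identity even when a class is empty (zero-denominator ratios report 0 by
convention). F1 is the support-weighted mean of the per-class F1 values,
*not* the harmonic mean of the aggregated precision and recall. These
identities are property-tested over randomly generated prediction/truth
configurations.

## Extraction: three rule families, routing, conflicts

Per field, extraction runs the strategies enabled in the routing table
(default mirroring the published per-variable strategy assignment: e.g.
event date by all three families; child sex only by keyword + relation;
supervisor age only by regex):

* **regex** rules capture numeric and free-text slots behind syntactic
  anchors; number words of the language pack are normalised to digits.
* **entity** rules recognise dates at day/month/year precision and resolve
  places against the gazetteer at the most specific level found (a
  prefecture hit implies its province).
* **keyword_dependency** rules fire only when a vocabulary keyword occurs
  inside its configured relation pattern (trigger phrase and window);
  bare keyword presence never fires, which is what separates "the boy
  swallowed magnetic beads" (product implicated in an injury) from
  "magnetic beads on sale" (no relation). Full dependency parsing is
  intentionally replaced by these configurable relation patterns — the
  published grammar is not available, and the pattern form keeps the rules
  editable and auditable; a parser-backed relation provider can be plugged
  in as an alternative rule source.

When strategies disagree, the earlier strategy in the routing order wins
(regex > entity > keyword_dependency, following the conventional ordering
of the strategy families) and the conflict is logged with all competing
values, so resolution is auditable. Every extracted field carries
provenance: winning strategy, matched text span and a confidence tier
derived from the strategy's routing position.

## Evaluation conventions

Published per-variable validation tables leave the exact denominators of
"extraction rate" and "accuracy" ambiguous, so both conventions are
implemented and the choice is a flag, never hard-coded:

* extraction rate — numerator: stories with a non-missing extraction;
  denominator `all` (all evaluated stories, default) or `including`
  (stories whose gold record states the field);
* accuracy — basis `including` (default; a missing extraction counts as a
  miss) or `extracted` (only stories with a non-missing extraction).

`summarize_evaluation_table()` reduces a per-variable table to the
reporting bands used for headline results (> 95 %, 50–95 % with observed
range, < 50 %, not calculable; accuracy > 70 % with the exception list).
Applied to the shipped reference table
(`reference_extraction_performance.csv`, transcribing a published manual
validation of 1000 stories) it reproduces the published band counts
16 / 7 / 6 / 5 and 25-with-4-exceptions, which the acceptance script
recomputes.

## Surveillance analytics

Coverage reports count distinct gazetteer units touched by located items —
by event location or media-source location, at province or prefecture
level — with unknown names counted as uncovered and listed for audit.
Percentages are rounded half-up to two decimals, matching the convention
of published coverage figures (93.39, 97.30, 86.57).

`detect_first_signal()` defines the first-detection date of a product term
as the earliest date among matching records, using the event date when
present and the publication date otherwise (published early-warning
figures do not state which basis they use; the event date is the
epidemiologically meaningful one and the basis is configurable). A signal
is *confirmed* when at least `k` further matching cases fall within `w`
days after first detection; the defaults `k = 10`, `w = 61` generalise the
published magnetic-beads observation (ten cases in the two months after
first detection) into a rule — they are knobs, not a claim about the
original operators' procedure. `lead_time()` reports signed day counts
(reference − first detection; positive = media led) against named
reference dates. Trend series are zero-filled per group over contiguous
month or year bins so that conservation (counts sum to matching records)
holds bin-wise.

## The synthetic test-bed: what it shows and what it does not

`generate_corpus()` emulates the crawler feed: a mixed corpus with an
*exactly allocated* eligible share (`round(n × fraction)`, then shuffled —
deterministic counts make better fixtures than Bernoulli draws), eligible
stories realised from slot-filling templates that embed a known gold
record, and four distractor families mirroring the exclusion criteria
(fictional scenes, adult injuries, product advertisements, legal
commentary). Defaults follow the study conditions where published numbers
exist: per-field presence rates default to the reference validation's
inclusion counts divided by 1000 (zero for the five variables no evaluated
story mentioned); the date range spans 2010-01-01 to 2023-12-31; the
eligible fraction among candidates is not published anywhere, so the
default 0.5 is an explicit, stated choice. Geographic weights default to
1 + the province's prefecture count as a crude population proxy.

The `noise` parameter replaces a field's realisation with phrasing the
rules cannot match, per story and field. Corruption draws come from a
dedicated RNG stream that depends on the seed but not on the noise level,
so corpora along a noise grid are *nested* and extraction accuracy is
weakly monotone decreasing in noise by construction — the property the
acceptance suite asserts on the grid {0, 0.1, 0.2, 0.4}.

Passing tests on this test-bed demonstrate the pipeline's internal
correctness: perfect candidate recall, filter/label agreement, 100 %
noise-free field recovery, exact first-signal recovery, byte-identical
reruns. They do **not** demonstrate performance on real journalistic
prose — template text has none of the paraphrase variety, reporting bias,
or novel vocabulary of real media, and no claim is transferred from the
synthetic corpus to published real-data accuracy figures (whose underlying
10 000 labelled Chinese stories are not publicly deposited).

Emergence events withhold their product from the base corpus, inject one
story dated exactly at `first_date` plus `burst_size` stories uniformly
dated within the following `burst_window_days`, and therefore make
first-detection recovery exactly checkable.

## Storage, pipeline, determinism

The store is a directory of JSON-lines collections mirroring the five
platform data kinds (raw stories, labelled spans, immutable dictionary
versions, structured records with provenance, run logs); an embedded
file-backed design keeps the artifact dependency-free and diffable while
preserving the relational discipline (records must reference stored
stories; this is enforced). Ingestion is idempotent (story id/URL
duplicates skipped, malformed lines logged by number). `run_pipeline()`
executes ingest → dedup → candidate search → filter → (classify) →
extract → store → analytics → export with per-stage counts and timings;
exports are sorted by story id, so identical config + seed yields
byte-identical export files. Scheduling (the daily batch cadence of a
production deployment) is left to the host scheduler; the CLI exposes one
idempotent batch command instead of a daemon.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use corpora of 25–1000
stories; noise-free recovery is checked at 500 stories (≈ 250 eligible),
the noise grid at 120–500, signal recovery over 20 randomised scenarios,
and the full pipeline at 1000 stories — sizes chosen so the whole suite
characterises every property in a few minutes on a laptop while keeping
binomial fluctuations well inside the asserted tolerances. Percentages are
rounded half away from zero (`round_half_up()`), ties in keyword rankings
break lexicographically, and every stochastic step takes an explicit
integer seed.

## Known limitations

* Extraction quality on real prose is untested here by design; the rule
  inventory is a faithful *mechanism*, not a tuned production grammar.
* One story = one event: multi-event roundup stories are out of scope.
* No coreference across stories; duplicate events reported by different
  outlets survive dedup unless the text is near-identical.
* Media-derived records support signal detection and description, not
  statistical inference: the stream is a selective, non-probability
  sample, so no population rates are estimated anywhere in the package.
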