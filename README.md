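# injurywatch

Media-report surveillance of product-related child injury, as a desk-scale,
fully testable R pipeline.

Consumer products — defective, mis-assembled or improperly used — are a
major etiological factor in child injury, and conventional injury
surveillance systems are slow to notice *new* product hazards (think
magnetic-bead ingestion or electric balance scooters): predefined variable
lists cannot capture them and official data lag by months or years. Online
news and social-media stories, by contrast, describe such events within
days. `injurywatch` implements the full infoveillance workflow that turns a
raw story stream into structured, analysable injury records:

1. **Candidate search** over a six-chapter keyword dictionary (child,
   product, injury, environment, activity, other): a story is a candidate
   when it contains at least one term from each of the three defining
   chapters.
2. **Eligibility filtering** with auditable per-rule reasons (real
   non-fictional event, jurisdiction, language, child involved, consumer
   product implicated, published ≥ 2010, not purely legal/topical
   commentary), plus URL and shingle-Jaccard near-duplicate suppression.
3. **Classification** of eligible vs ineligible stories behind a pluggable
   contract (the default is a deterministic bag-of-n-grams ridge logistic
   model; a fine-tuned transformer can be dropped in), scored with the
   platform metric suite: accuracy, support-weighted average precision,
   positive-class precision, support-weighted recall (≡ accuracy in the
   binary case), specificity, false-positive rate and support-weighted F1.
4. **Structured extraction** of 29 variables (34 leaf fields: event,
   product, child/supervisor, environment and etiology facets) using three
   rule families — regular expressions for numeric slots, gazetteer/date
   entity recognition, and keyword + relation ("dependency") patterns —
   with per-field strategy routing, priority-based conflict resolution and
   span-level provenance.
5. **Evaluation** of extraction output against gold records: per-field
   extraction rate and accuracy under both denominator conventions, and
   band summaries (rate > 95 %, 50–95 %, < 50 %, not calculable;
   accuracy > 70 % with exceptions).
6. **Surveillance analytics**: geographic coverage over a two-level
   gazetteer (31 provinces / 333 prefecture-level divisions), dictionary
   keyword frequencies (word-cloud tables), monthly/annual trend series,
   and early-signal detection — the first dated record of a product term,
   burst confirmation (`k` cases within `w` days) and signed lead times
   against reference dates such as a first literature report or an
   official recall.

Because real crawled corpora cannot ship with a package, `injurywatch`
includes a first-class **synthetic corpus generator**: slot-filling
templates embed a known gold record into every eligible story (mixed with
fictional, advertising, adult-injury and legal-commentary distractors), at
configurable per-field presence rates, geographic mixture, date range,
noise level and product-emergence scenarios. Every pipeline property —
search recall, filter correctness, 100 % noise-free extraction recovery,
monotone degradation with noise, exact first-signal recovery, byte-level
reproducibility — is tested against that ground truth.

## Worked example

```r
library(injurywatch)

# a 300-story corpus in which magnetic beads emerge on 14 Sep 2015
# with 10 confirming cases over the following two months
cfg <- scenario_config(
  n_stories = 300, eligible_fraction = 0.5, seed = 9,
  emergence_events = list(list(product = "magnetic beads",
                               first_date = "2015-09-14",
                               burst_size = 10, burst_window_days = 61)))
bundle <- generate_corpus(cfg)

sig <- detect_first_signal(bundle$labels, "magnetic beads", k = 10, w = 61)
sig <- lead_time(sig, list(literature = "2016-11-25",
                           recall = "2020-12-18"))
print(sig)
#> <signal 'magnetic beads': first 2015-09-14, 10 confirming in 61d, confirmed=TRUE>
#>   lead vs literature: 438 days
#>   lead vs recall: 1922 days
```

The media stream flags the hazard 438 days before the first research
publication and 1922 days (more than five years) before the official
recall — the early-warning lead that motivates media-based surveillance.

Extraction and its evaluation:

```r
elig    <- vapply(bundle$labels, function(l) l$eligible, logical(1))
results <- extract_corpus(bundle$stories[elig])
tab     <- evaluation_table(results, bundle$labels[elig],
                            denominator = "including")
s <- summarize_evaluation_table(tab)
c(rate_over_95 = s$n_rate_over_95,
  not_calculable = s$n_rate_not_calculable,
  accuracy_over_70 = s$n_accuracy_over_70)
#>     rate_over_95   not_calculable accuracy_over_70
#>               28                6               28
```

On this noise-free corpus every field that the generator realises is
recovered exactly (extraction rate and accuracy 100 % for all 28 fields
stated by at least one gold record; the remaining 6 are not calculable
because no story states them at the default presence rates). Raising the
generator's `noise` parameter degrades accuracy monotonically, which is
how the extraction rules' sensitivity is characterised.

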