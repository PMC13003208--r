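---
title: "Methods: topic and sentiment discourse analysis for Q&A corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic and sentiment discourse analysis for Q&A corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qadiscourse)
```

## What the package computes

`qadiscourse` analyses community question-and-answer corpora — collections
of records each holding a question, a set of upvoted answers, a platform
tag, and an upload date — and produces four result surfaces:

1. a **topic table**: how many questions fall into each of a small set of
   interpretable topics;
2. **per-topic answer sentiment proportions** (binary positive/negative);
3. a **question–answer sentiment pair cross-tabulation** per topic (PP,
   PN, NP, NN), which shows whether a question's polarity travels into its
   most-upvoted answer;
4. **monthly sentiment series** per topic, summarised by *majority
   crossovers* (month-to-month flips of which polarity holds more than
   half the answers) and *dominance streaks* (the longest run of strict
   majority for one polarity).

The motivating use case is health infodemiology: comparing what users of
different national Q&A platforms asked about a public-health topic (e.g.
COVID-19 vaccination) and how answer sentiment moved over a year.

## Preprocessing funnel

Ingestion starts from JSONL or CSV files (`read_corpus()`); there is no
scraping. The funnel (`preprocess_corpus()`) applies, in order, a
case-insensitive substring keyword filter ("vaccine" also matches
"vaccines" — substring semantics are deliberate and stemming-free), an
answered-only filter, and an optional uniform subsample to a target size so
two platforms can be compared at equal *N*. Every run records the four
funnel counts and the sampling seed; the counts are asserted weakly
decreasing. By default the keyword is searched in questions *and* answers
(configurable), since the source procedure does not say which; the
resolved choice is serialized with every run.

Only the most upvoted answer of each record is analysed
(`select_top_answer()`). Upvote ties break by earliest answer timestamp,
then input position — the upstream procedure states no rule, and a
deterministic one is required for reproducibility.

## Topic categorization

Questions are tokenized (lowercase, split on any non-alphanumeric run, no
stemming, no default stop list) and modelled with standard LDA via
collapsed Gibbs sampling (`fit_lda()`, Rcpp). Defaults: symmetric priors
`alpha = 50/K`, `beta = 0.01`, 1000 sweeps, estimates from the final
sampler state with Dirichlet smoothing, so every row of the topic–word
matrix `phi` and document–topic matrix `theta` sums to one.

Two numerical choices matter:

* **Restarts.** A single Gibbs chain on corpora with well-separated topics
  traps, on a nontrivial fraction of seeds, in a mode where two true
  topics merge and a third splits; neither longer runs nor different
  priors dislodge it. `fit_lda()` therefore runs 3 independent chains by
  default and keeps the final state with the highest collapsed joint log
  probability. Chain seeds are derived deterministically from the user
  seed, so results remain exactly reproducible.
* **Own sampler RNG.** The sampler uses its own Mersenne Twister stream
  seeded by an explicit integer, so fits are identical regardless of R's
  RNG state.

The number of topics can be chosen by UMass coherence (`select_k()`):
for ranked keywords $w_1 \dots w_M$ the score is
$\sum_{i<j} \log\frac{D(w_i, w_j) + 1}{D(w_j)}$ with $D$ the co-document
counts over the modelled corpus, averaged over topics, argmax over
candidate K, ties to the smallest K. No claim is made that coherence
recovers a planted K; the per-K table is always reported. A keyword absent
from all documents contributes the floor `log(1/n_docs)` with a warning.

Raw topics are then merged into a handful of display labels by a
user-supplied `merge_map()` — the merge is a human judgment expressed as
configuration, never automated. A document's merged label is the label
with maximal *summed* `theta` mass (ties by label order).

### Embedding space and topic vectors

To characterize merged topics semantically, words and documents are placed
in one embedding space (`build_embedding()`): a symmetric 5-token-window
word co-occurrence matrix is transformed to positive pointwise mutual
information and factored by truncated SVD; word vectors are left singular
vectors scaled by singular values (each singular vector sign-fixed so its
largest-magnitude component is positive, for bit-stable output), and a
document vector is the length-normalized mean of its tokens' word vectors.
This deterministic construction replaces a learned joint doc/word
embedding; anything satisfying the same contract (a matrix of word vectors
and one of document vectors in a common space) can be plugged in instead.

Each merged topic's **topic vector** is the centroid (arithmetic mean) of
its documents' vectors (`topic_vector()`), which is also the minimizer of
the summed squared distances to the members. Topic keywords are the
members of the merged LDA keyword pool — the LDA acts as a coarse topical
filter — ranked by cosine similarity to the centroid
(`characterize_topic()`). An optional refinement pass
(`assign_documents()`, off by default) re-labels every document by its
nearest topic centroid; the default keeps the merged LDA labels, because
the source procedure does not state which assignment produced its tables,
and both routes are exported. A topic that loses every document (a
collapsed raw topic under an identity merge) has no centroid and is
skipped with a warning; a centroid that cancels to the zero vector is
flagged degenerate and refuses cosine operations.

## Sentiment classification

Answers (and questions, by the identical procedure) are classified
positive/negative by chunked scoring (`classify_corpus()`): tokens are cut
into consecutive 128-token chunks — mirroring the fixed input window of
transformer sentiment models, whose truncation bias motivates the scheme —
each chunk is scored by every configured scorer, chunk probabilities are
averaged *unweighted* per document (a length-weighted option exists behind
a flag), and the per-scorer document probabilities are averaged across
scorers (bagging). The label is the larger averaged probability; an exact
tie is labelled positive (documented, deterministic).

The reference scorer is a deterministic lexicon backend
(`lexicon_scorer()`): with $n^+$ positive-lexicon and $n^-$
negative-lexicon tokens in a chunk, $s = (n^+ - n^-)/(n^+ + n^- + c)$ and
$p_{pos} = (1+s)/2$. Two ensemble members use smoothing constants $c = 1$
and $c = 2$, giving genuinely distinct scorers without any model download;
transformer scorers can be supplied as objects with the same
`score(tokens)` contract. Probability mass is conserved at every level
(chunk, document, ensemble) and the scorer is monotone: adding a positive
token never lowers a chunk's $p_{pos}$.

## Temporal analysis

Answer sentiment is aggregated monthly (`monthly_series()`). A leading
partial month covering at most `merge_threshold_days` (default 7) days of
the analysis window is merged into the following month — this generalizes
the source's rule of folding a 4-day leading stub into the next month, and
reproduces it for any threshold ≥ 4. Months with no records carry a null
share; they are skipped, never imputed. Crossovers are counted on the
majority sign `sign(pos_share − 0.5)`, with an exact 0.5 carrying the
previous month's sign (a leading 0.5 counts positive): the source never
defines a crossover formally, so the package's definition is stated and
tested rather than claimed identical. Dominance streaks require a strict
majority; null months break runs; ties go to the earliest run.

## Synthetic corpora and what they show

`generate_corpus()` plants the exact structure the pipeline claims to
recover, with every default chosen to mirror the motivating study's
conditions: 3952 records spanning June 27, 2020 – June 27, 2021, five
topics (seven for the second-platform analogue), one designated gold
answer per record with a strictly maximal upvote count, and document
lengths 20–400 tokens so that chunking is genuinely exercised past the
128-token boundary. Topics have private vocabularies (60 tokens each) plus
a shared vocabulary (40 tokens at 20% mass); question sentiment is
Bernoulli per topic (`pi_t`, default 0.5); answer sentiment either agrees
with the question with probability `rho` (default 0.8) or, when a
month-to-rate map is planted, follows the month's rate, which is how
crossovers are planted. Sentiment is expressed purely lexically: tokens
are replaced by polarity-lexicon tokens at rate 0.1 (at least one per
document), so the deterministic reference scorer can recover the truth
without trained weights.

What passing on synthetic data does *not* show: natural-language effects
(negation, sarcasm, morphology — tokens here are abstract symbols),
scraped-data noise (duplicates, deleted posts), or the behaviour of
transformer scorers; the 0.95+ recovery rates bound the pipeline's
bookkeeping, not real-world classifier accuracy, which in the motivating
study was measured at 66%–72% against small hand-labelled sets.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use: the enumeration oracle on a
2-document, 4-token corpus against 8,000 kept Gibbs sweeps; topic recovery
on 500 records with disjoint cores; sentiment recovery on 1,000 records at
`rho = 1`; crossover recovery on 3,000 records over 12 months (≥ 200
answers/month corpus-wide, rates 0.85/0.15); and full-pipeline determinism
on 400 records with K = 4 and 120 sweeps run twice. These sizes keep each
check well-resolved (binomial error far from the asserted thresholds)
while the whole battery completes in about a minute.

## Known limitations

* The merge from raw to display topics is configuration; the package
  cannot validate its semantics, only its totality.
* Percent display uses half-up rounding at the displayed precision;
  published tables that mix truncation and rounding can disagree in the
  last digit.
* The dense PPMI matrix limits the embedding to vocabularies of a few
  thousand types; the pipeline's tokenizer and synthetic vocabularies stay
  well under that.
* With `K = 1` or a single merged label the temporal machinery still runs,
  but crossover counting requires at least two non-null months.
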