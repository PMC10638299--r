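---
title: "Speech-graph analysis of dream reports: methods and conventions"
author: "dreamgraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-graph analysis of dream reports: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamgraphs)
```

# Overview

`dreamgraphs` turns free-text dream reports into directed lemma
multigraphs ("speech graphs"), computes fourteen structural attributes
per report, aggregates them per dreamer, and compares conditions with
weighted linear models. A deterministic synthetic-corpus generator
supports calibration and power studies. This vignette records every
modeling convention precisely enough to reimplement the package.

# From text to graph

1. **Tokenization.** Sentences are split on runs of `.`, `!`, `?`.
   Word tokens are maximal runs of Unicode letters (`\p{L}+`), so
   digits and punctuation never enter a token and diacritics survive.
2. **Annotation.** Each token is looked up (lower-cased) in a
   surface-form lexicon mapping to a part of speech and a lemma.
   Unknown tokens get the default POS (`NOUN`) and their lower-cased
   surface as lemma. The packaged toy lexicon
   (`inst/extdata/lexicon_es.tsv`) covers frequent Spanish dream-journal
   vocabulary plus the function words the generator interleaves.
3. **Content filtering.** Only `NOUN`, `VERB` and `ADJ` tokens are
   kept, in narrative order, as the report's lemma sequence.
4. **Graph construction.** Each consecutive lemma pair contributes one
   directed edge, with multiplicity: a sequence of `k` content lemmas
   yields exactly `k - 1` edges. Repeated bigrams become parallel
   edges; immediate lemma repetition becomes a self-loop. A one-lemma
   report is a single isolated node.

# The fourteen attributes

Let `A` be the multiplicity adjacency matrix (`A[i, j]` = number of
directed edges `i -> j`, diagonal = self-loops).

* **N** — number of distinct lemmas (nodes).
* **E** — total edge count including multiplicity, `sum(A)`.
* **PE** — parallel-edge surplus `sum(pmax(A - 1, 0))`, diagonal
  included.
* **L1** — self-loops, `trace(A)`.
* **L2** — `trace(A^2) / 2`.
* **L3** — `trace(A^3) / 3`.
* **LSC** — node count of the largest strongly connected component of
  the *directed simple projection* (multiplicity collapsed, self-loops
  dropped; reachability is unaffected by either).
* **ATD** — average total degree `2 E / N`.
* **density** — `E / (N (N - 1))`; defined as 0 for `N < 2`. Because
  `E` counts multiplicity, density can exceed 1.
* **diameter** — maximum finite directed shortest-path length over
  ordered pairs `u != v`; 0 when no finite pair exists.
* **ASP** — mean of the same finite ordered-pair distances; 0 when
  none exist.
* **CC** — mean local clustering coefficient on the *undirected simple
  projection*, isolates and degree-1 nodes contributing 0.
* **mean_betweenness** — mean over nodes of directed betweenness on
  the directed simple projection, each node's value normalized by
  `(N - 1)(N - 2)`; 0 for `N < 3`.
* **avg_neighbor_degree** — on the undirected simple projection, each
  node's mean neighbor degree, averaged over nodes with at least one
  neighbor.

igraph implements SCC, shortest paths, betweenness, clustering and
neighbor degrees; the test suite checks all fourteen attributes against
an independent hand-written matrix oracle on hundreds of random
multigraphs.

## Trace cycle counts and self-loops

On self-loop-free graphs `L2` and `L3` equal the number of distinct
directed 2- and 3-cycles counted with multiplicity. Self-loops
contaminate the traces in a documented, exactly characterized way:

```
trace(A^2)/2 = (distinct 2-cycles) + sum_i A[i,i]^2 / 2
trace(A^3)/3 = (distinct 3-cycles) + sum_i A[i,i]^3 / 3
             + sum_i A[i,i] * sum_{j != i} A[i,j] A[j,i]
```

so `L2`/`L3` can be fractional (a single self-loop alone gives
`L2 = 1/2`, `L3 = 1/3`). The trace convention is kept because it is the
standard definition for these attributes; the identities above are
verified in the acceptance tests.

```{r example}
ann <- defaultLexiconAnnotator()
toks <- annotateText("Recuerdo que salí de mi cuerpo. Vi mi cuerpo.", ann)
sq <- filterContentLemmas(toks, "demo")
computeAttributes(buildGraph(sq))
```

# Study design and statistics

Reports carry a `dreamer_group` (`non_lucid_dreamer`, `lucid_dreamer`,
`obe_dreamer`) and a `dream_type` (`non_lucid`, `lucid`, `obe`); only
five combinations are legal and they map to the condition codes `NN`,
`NL`, `LL`, `NO`, `OO`.

* **Aggregation.** Attributes are averaged per dreamer within each
  condition; each dreamer-condition row gets the weight
  `ln(n_dreams + 1)`.
* **Outlier screen.** Per condition, on mean `N` and mean `E`: a row is
  excluded when `|x - median| > 3 * 1.4826 * median(|x - median|)`
  (the 1.4826 constant makes the MAD consistent for a normal
  distribution). With fewer than 3 rows or a zero MAD the screen makes
  no exclusions and says so. The screen runs once (single pass).
* **Comparisons.** `compareAttribute()` fits the weighted one-way
  model `attribute ~ condition` (treatment coding, `NN` reference),
  tests the condition term with a type II F test (`car::Anova`), and
  reports all pairwise contrasts (`emmeans`), unadjusted by default.
* **Associations.** `associateAttributes()` fits
  `response ~ covariate * condition`, tests the interaction (type II),
  and reports per-condition slopes (`emmeans::emtrends`). Either
  attribute of a pair may be the response; contrasts are evaluated at
  the weighted mean of the covariate.

# Co-occurrence networks

`cooccurrenceEdges()` restricts the vocabulary to the `topK` most
frequent words (descending count, lexicographic ties), then reads each
sentence's retained-word sequence: every adjacent pair adds one to an
undirected edge count, never across sentence boundaries, and self-pairs
are ignored. Dropping a rare word therefore joins its retained
neighbors. Centrality is weighted degree divided by total edge weight.
By default the same NOUN/VERB/ADJ filter applies; `allPos = TRUE` keeps
auxiliaries and function words.

# The synthetic generator

`generateCorpus()` produces a labeled corpus plus a ground-truth table,
byte-identical under a fixed seed (`withr::with_seed`; the caller's RNG
stream is untouched). Each group has a recurrence intensity `rho`: the
first content token of a report is a Zipf-weighted draw from a content
lexicon; each later one is, with probability `rho`, resampled uniformly
from the tokens already used in that report (so frequently re-used
lemmas attract further re-use, a Pólya-urn flavor), otherwise a fresh
Zipf draw. Function words are interleaved and sentences closed every
8–16 tokens.

Defaults, chosen a priori as plausible dream-journal magnitudes and
*not* tuned to any test outcome: report length truncated-normal with
mean 217 and sd 53 word tokens (minimum 10), content fraction 0.55,
content lexicon of 300 lemmas, Zipf exponent 1, 5–10 dreams per
dreamer.

**What the generator does emulate.** Higher `rho` compacts the graph:
density and parallel edges rise; distinct nodes, diameter and ASP fall
at fixed length. These orderings are strong and recovered essentially
always at the package's standard study size (20 dreamers per group).

**Known limitation.** The generator holds `rho` constant within a
group and draws report lengths i.i.d., so between-dreamer variation in
mean edge count is almost pure noise. Consequently per-condition
*slopes* of one attribute on another (e.g. ASP on E across dreamers)
are weakly identified, and the generator does not reproduce a
length-dependent vocabulary-saturation contrast between groups: the
low-`rho` group draws more fresh lemmas per token, saturates its finite
lexicon faster, and so its ASP-vs-edges slope is, if anything, the more
negative one. Reproducing a "high-recurrence group has the negative
slope" pattern would require length-dependent or dreamer-correlated
recurrence, which this generator intentionally does not model. The
acceptance suite states the slope-sign expectation faithfully and the
corresponding assertions fail, documenting the gap honestly rather than
papering over it.

# Reproducibility

`scripts/acceptance.R --seed <int> --out <path>` regenerates the
standard two-group simulation, runs the full pipeline against the
installed package, and writes the headline quantities as JSON. The test
suite (`testthat`, edition 3) contains per-module tests, independent
oracles for every derived graph quantity, and one acceptance block per
acceptance criterion.
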