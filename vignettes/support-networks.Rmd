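---
title: "Quantifying social support with word co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social support with word co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supportnet)
```

## The model

`supportnet` treats a disease community's posts as a bag of sentences and
represents their semantics as an undirected weighted graph: one node per
word type, an edge between two words that appear together in at least one
sentence, and edge weight equal to the number of co-occurring sentences.
The sentence is the co-occurrence window because it is the smallest unit
that reliably carries one topic; no sliding sub-window is used. Two
conventions deserve attention:

* **Within-sentence multiplicity.** "the count of joint word occurrence"
  is ambiguous when a word repeats inside a sentence. The default counts
  each sentence once per unordered pair of distinct word *types*
  (binary incidence), so weights read as "number of sentences in which
  the pair co-occurs". `build_cooccurrence(count_multiplicity = TRUE)`
  counts token-pair occurrences instead; neither choice affects the
  unweighted diagnostics.
* **Isolated words** (one-token sentences, or words never co-occurring)
  remain in V with degree 0: they count in n and in the clustering
  average, and `component_coverage` makes the effect visible.

### Network diagnostics

`network_statistics()` reports ASPL (mean hop distance over unordered
pairs), CC (mean local clustering, with nodes of degree < 2 contributing
0 because m_i / (k_i(k_i−1)/2) is undefined there), the Erdős–Rényi
closed forms ASPL_r = ln(n)/(ln(2m)−ln(n)) and CC_r = 2m/(n(n−1)), and a
power-law exponent. Choices worth recording:

* ASPL is computed on the **largest connected component** — hop distance
  is undefined across components — and on the *binarised* graph, since
  the defining formulas use hop counts and edge counts, not weights.
* The small-world label operationalises "ASPL comparable, CC much
  larger": `aspl <= r_aspl * aspl_r` and `cc >= r_cc * cc_r` with
  explicit defaults r_aspl = 2, r_cc = 10. The ratios are configuration,
  not science; published word networks exceed the CC ratio by one to two
  orders of magnitude, so the conclusion is insensitive to r_cc anywhere
  in 5–50.
* A note on CC_r: reported baseline tables in this literature sometimes
  print m/(n(n−1)), i.e. half of 2m/(n(n−1)). The package follows the
  stated formula; the factor-2 ambiguity is another reason the
  small-world call uses a coarse ratio rather than an equality.
* γ is estimated by discrete maximum likelihood with the lower cutoff
  selected by Kolmogorov–Smirnov minimisation (the standard Clauset-type
  recipe, via igraph's `plfit`). A log–log regression mode exists for
  diagnostics only; it is biased and never used in reports.

### Module detection

Modules maximise the resolution-parameterised modularity

Q(c) = (1/2M) Σ_ij [ w_ij − λ ℓ_i ℓ_j / 2M ] δ_ij(c),

summed over ordered pairs with w_ii = 0 and the diagonal null term
included. (Descriptions of this objective occasionally say "minimising";
with this sign convention good partitions have large positive Q — typical
word networks score 0.4–0.8 — so the package maximises.) The optimiser is
a hand-rolled Louvain: randomised local moves to the neighbouring
community with the largest gain until no move helps, then aggregation of
communities into super-nodes (self-loops carrying internal weight),
repeated until a full pass yields no improvement. Because greedy local
moves are visit-order dependent, the visit order is seeded and the best
of `restarts` (default 10) independent runs is kept; identical
`(network, λ, seed, restarts)` always return the identical partition.
Edge weights are used by default (matching common tooling); an
unweighted switch is provided. λ defaults to 1.0, the standard
granularity; larger λ penalises module size and in the limit yields
singletons.

Modules with fewer than `min_module_size = 5` words are then dropped —
tiny modules are mostly tokenisation debris and destabilise the
downstream edge shares — and their words are excluded from the silhouette
and edge-proportion denominators (filtering happens *before* those
statistics). Remaining modules are re-indexed by descending size.

The silhouette uses s(i) = (b(i) − a(i)) / max(a(i), b(i)) with
unweighted shortest-path hop distance on the subgraph of assigned words:
the dissimilarity is deliberately the most parsimonious graph-native
choice, isolated behind a `distance` argument (an inverse-weight option
exists but is not the default). Unreachable pairs get the largest finite
distance plus one; singleton modules score 0. Keywords are the module
members with the highest within-module strength, ties broken
alphabetically — a transparent, reproducible stand-in for the editorial
keyword selection a human analyst would do.

### Support quantification

PC_k is the fraction of all *within-module* edges that fall inside
module k (between-module edges appear in neither numerator nor
denominator, so Σ_k PC_k = 1 exactly). Category shares sum PC_k over the
modules assigned to each support category and are renormalised over the
three classified categories; unclassified modules are excluded so
profiles always total 100%.

Module-to-category assignment is the one genuinely qualitative step in
the workflow. The package substitutes a transparent rule — the
strength-weighted fraction of member words in each category's seed
vocabulary, highest score wins, ties and all-zero scores left
`unclassified` — plus an `overrides` argument so an analyst's reading of
the keywords takes absolute precedence (and is logged). The packaged
seed lexicons follow the standard three-way taxonomy (treatments /
clinicians / insurance words; feeling / encouragement words; daily-life
words) and are expected to be edited for new domains.

Group profiles are compared with a Pearson chi-squared test of
homogeneity, no continuity correction, on the group × category table of
within-module **edge counts** — the unit underlying PC_k. Posts or
modules would be defensible alternative units; edge counts are the
documented convention here, and with edge counts in the thousands the
test is extremely powerful, so its p-value should be read as "the
profiles differ", not as an effect size.

## The synthetic corpus generator

`generate_corpus()` emulates the shape of a patient-forum crawl with
planted structure: several groups, each post 3–6 sentences, each sentence
assigned a support category by the group's mixture, each token drawn from
the category's vocabulary with probability `purity` = 0.95 (else from a
shared background vocabulary), with Zipf-distributed (s = 1) word
frequencies inside every vocabulary. Defaults: 8 groups × 400 posts,
4–10 content tokens per sentence, 400-word category vocabularies, 150
background words.

Sizing rationale: category assignment lives at *sentence* level because
the co-occurrence window is the sentence — post-level structure would not
be recoverable. Zipf frequencies produce the heavy-tailed degrees real
text shows (uniform sampling would not). The vocabularies are large
relative to the sentence budget on purpose: with small vocabularies the
set of distinct pairs saturates, which compresses the edge-proportion
statistic toward uniform; pilot simulation during design showed 400-word
vocabularies keep recovered category shares within a few points of the
planted mixture at 500 posts, while 150-word vocabularies sit at the edge
of usability. Under these defaults an end-to-end run takes well under a
minute per group.

What the generator does **not** emulate: natural-language syntax, word
polysemy and topic overlap (planted vocabularies are disjoint by
construction), user/thread structure, temporal dynamics, and group
vocabularies that differ beyond their mixtures. Passing recovery tests
therefore demonstrate that the pipeline's machinery is correct, not that
lexicon-based category assignment is accurate on real language — on real
data that step should be reviewed via the keyword reports and
`overrides`.

## Numerical and degenerate-input choices

* Modularity on an edgeless network, ASPL with all nodes isolated,
  silhouettes with a single module, PC_k with no within-module edges, and
  profiles where everything is unclassified are all *errors* (classed
  conditions), not NAs: each one signals a misconfigured analysis.
* Louvain tie-breaks: a node stays in its current community on gain
  ties, otherwise moves to the lowest community id; this plus seeded
  visit orders gives bit-reproducible partitions.
* The reported Q is re-evaluated from the final flat assignment with
  `modularity_score()` (and tested to 1e−9 against both a brute-force
  double sum and exhaustive search on small graphs), so the optimiser
  cannot misreport its own objective.
* Sentence splitting is rule-based (terminal `.!?` runs, an abbreviation
  exception list, unterminated text = one sentence); tokenisation strips
  punctuation, folds case, joins multi-word units *before* stopword
  removal (longest match first), and drops numerals and single
  characters, which otherwise become hub nodes with no semantics.
* Report tables round to 2–3 decimals at the formatting boundary only;
  all statistics are computed and returned unrounded.

## Problem sizes used in validation

The test suite validates against brute force where brute force is exact:
Floyd–Warshall ASPL and triangle-counting CC on 100 random graphs of up
to 30 nodes, exhaustive maximum-modularity search on all fixture graphs
of up to 8 nodes (4140 partitions), hand-computed silhouettes on a
12-node two-clique graph, planted-partition recovery (4 × 25-node blocks,
p_in = 0.3, p_out = 0.01, 20 seeds, ARI ≥ 0.9), full-pipeline mixture
recovery at 500 posts and purity 0.95 (max error ≤ 0.08), power-law
recovery at 10⁵ samples for γ ∈ {2.5, 3.9} (±0.05), and chi-squared
power on strongly different planted mixtures (20 runs). These sizes were
chosen so each property is checked at the scale where its oracle is
exact and the whole suite runs comfortably on a laptop.

## Known limitations

* Lexicon scoring is a stand-in for expert judgement; disjoint seed
  vocabularies cannot represent words that serve several support
  functions ("pain" can be informational in a dosage question and
  emotional in a lament).
* Hop-distance silhouettes compress on small-world graphs (most
  distances are 2–3), so absolute silhouette values are best compared
  within one analysis, not across corpora.
* The chi-squared unit (edges) treats edges as independent, which they
  are not; with the edge counts typical here the test is effectively a
  difference detector.
* No lemmatisation or spelling correction is applied; morphological
  variants are distinct nodes unless added to the multi-word/stopword
  resources.
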