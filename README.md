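# supportnet

Patients and caregivers in online health communities (OHCs) exchange
several kinds of social support — **informational support** (facts,
suggestions, guidance about treatments, symptoms, clinicians),
**emotional support** (empathy, encouragement, expressions of feeling) and
**companionship** (everyday chat that is not necessarily health-related).
`supportnet` quantifies how much of each kind a disease community
exchanges, directly from the raw post text, without hand-coding individual
messages. It is aimed at health-informatics researchers comparing support
needs across disease groups (e.g. cancer types) from forum crawls.

## Method

For each group the pipeline:

1. **Builds a word co-occurrence network.** Posts are split into
   sentences; sentences are tokenized (lowercasing, multi-word units such
   as *side effects* joined into single tokens, stopwords / numerals /
   punctuation removed). The network G = (V, E) has a node per word type
   and an undirected edge {i, j} whenever words i and j appear together in
   at least one sentence; the weight w_ij counts the co-occurring
   sentences.
2. **Characterises the network.** Average shortest-path length
   ASPL = 2 Σ_{i>j} d_ij / (n(n−1)) and mean clustering coefficient
   CC = (1/n) Σ_i m_i / (k_i(k_i−1)/2) are compared with the Erdős–Rényi
   closed forms ASPL_r ≈ ln(n)/(ln(2m)−ln(n)) and CC_r ≈ 2m/(n(n−1)) to
   flag small-world structure, and the degree distribution p(k) ∝ k^(−γ)
   is fitted by discrete maximum likelihood with a KS-selected lower
   cutoff to check scale-freeness.
3. **Detects word modules** by maximising the resolution-parameterised
   modularity
   Q(c) = (1/2M) Σ_ij [ w_ij − λ ℓ_i ℓ_j / 2M ] δ_ij(c)
   with a seeded, restarted Louvain optimiser (λ = 1 by default); modules
   with fewer than five words are dropped, and partitions are scored by a
   graph-distance silhouette.
4. **Quantifies support.** Each module k carries the share
   PC_k = (edges within module k) / (all within-module edges); modules are
   assigned to one of the three support categories (lexicon scoring with
   manual override), category shares are obtained by summing PC_k within a
   category, and group profiles are compared by a Pearson chi-squared test
   of homogeneity on the underlying within-module edge counts.

Because real OHC crawls usually cannot be redistributed, the package
includes a planted-structure synthetic corpus generator
(`synthetic_config()` / `generate_corpus()`) whose ground truth (word
categories, per-group mixtures, sentence labels) lets every stage be
validated end to end.

## Worked example

```r
library(supportnet)

cfg <- synthetic_config(
  groups  = c("alpha", "beta"),
  mixture = rbind(c(0.6, 0.25, 0.15),   # alpha: information-heavy
                  c(0.2, 0.3, 0.5)),    # beta: companionship-heavy
  posts_per_group = 120L, seed = 42L)
corp <- generate_corpus(cfg)

res <- run_support_analysis(
  corp$posts, "reports",
  stopwords = character(0), mwu_lexicon = character(0),
  lexicon = split(names(corp$truth$word_category),
                  unname(corp$truth$word_category)),
  seed = 1L)

res$network_summary
#>   group sentences words cooccurrence_pairs  aspl aspl_r    cc  cc_r gamma small_world
#> 1 alpha       545   775               6787  2.86   2.32 0.743 0.023  2.45 TRUE
#> 2 beta        536   826               7217  2.92   2.35 0.747 0.021  2.52 TRUE

res$profile_table
#>   group  informational emotional companionship
#> 1 alpha           59.4      25.6          15.0
#> 2 beta            21.8      30.8          47.4
#> 3 (mean)          40.6      28.2          31.2

res$comparison
#>   statistic    df p_value
#> 1     2317.     2       0
```

Both synthetic networks are flagged small-world (ASPL close to the random
baseline, CC some 30× above it) with power-law degree exponents in the
2.4–2.6 range typical of word networks. The recovered profiles track the
planted mixtures — alpha is information-heavy (59.4% vs planted 60%),
beta is companionship-heavy (47.4% vs planted 50%) — and the chi-squared
test rejects homogeneity decisively (χ² ≈ 2317, df = 2, p < 10⁻¹⁵).
`run_support_analysis()` also writes four CSV reports (network summary,
module summary, module-detection summary, support profiles) plus a run
log with versions, seed and config hash; reruns are byte-identical.

On real data, start from `read_posts("corpus.jsonl", "jsonl")` (fields
`post_id`, `group`, `text`), keep the default stopword/MWU lists, inspect
`module_summary.csv` keywords, and use the `overrides` argument of
`assign_categories()` where expert reading disagrees with the lexicon
score. Networks export to Gephi via `export_network(net, "net.gexf")`.

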