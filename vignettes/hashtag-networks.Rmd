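---
title: "Hashtag co-occurrence networks for cultural ecosystem services discourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hashtag co-occurrence networks for cultural ecosystem services discourse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Visitors to natural areas leave a public trace of how they value those areas
in the hashtags they attach to social-media posts. Aggregated over thousands
of posts about one area, the hashtags form a weighted co-occurrence network:
vertices are hashtags, an edge connects two hashtags posted together, and the
edge weight counts the posts containing both. The structure of that network —
which tags are central, which tags bridge otherwise separate conversations,
which groups of tags cluster together — is a readable summary of the
cultural ecosystem services (CES) people associate with the area: wildlife
watching, beach recreation, diving, hiking, aesthetics and wellbeing,
cultural heritage.

`tagnet` implements this analysis end to end: a synthetic corpus generator
(the original platform data cannot be re-downloaded, and public APIs for such
queries have been closed for years), corpus cleaning, network construction,
centrality, community detection with lexicon-assisted CES labelling, and a
cross-area merged network.

## The model and its statistics

For a cleaned corpus of posts $p$ with hashtag sets $H_p$, restricted to a
selected tag set $S$:

* **Node frequency** $f(t)$ — number of posts with $t \in H_p$.
* **Edge weight** $w(u,v)$ — number of posts with $\{u,v\} \subseteq H_p$
  (binary per post: posts carry hashtag *sets*). The source material never
  defines its edge weight; this is the standard co-occurrence convention.
* **Strength** $s(v) = \sum_{e \ni v} w(e)$ (weighted degree), max-scaled
  for display so the largest value is exactly 1.
* **Eigenvector centrality** — Perron vector $x$ of the weighted adjacency
  $A$, $Ax = \lambda_1 x$, max-scaled to 1. Computed by power iteration with
  a strictly positive start vector.
* **Betweenness** $b(v) = \sum_{s<t} \sigma_{st}(v)/\sigma_{st}$ and **edge
  betweenness** analogously (endpoints included for edges), via Brandes'
  algorithm, with dependencies split equally among multiple shortest paths.
  Normalization: $(n-1)(n-2)/2$ for nodes, $n(n-1)/2$ for edges, per
  connected component.
* **Modularity** $Q = \sum_c \left[ W_c/W - (S_c/2W)^2 \right]$ over
  communities $c$, with $W$ the total edge weight, $W_c$ the intra-community
  weight and $S_c$ the summed strength. Communities come from fast-greedy
  (Clauset–Newman–Moore) agglomeration: merge, at each step, the connected
  pair of communities with the largest $\Delta Q = w_{ij}/W - S_iS_j/2W^2$,
  and cut the resulting dendrogram at the maximum of the $Q$ trace.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `top_hashtags` | 150 | the per-area analysis vocabulary; at this size selected tags co-occur with one another in >90% of the posts that contain any of them, the cohesion rationale behind the selection rule |
| `top_pairs` | 1400 | pairs retained in the merged cross-area network |
| `jaccard_threshold` | 0.65 | near-duplicate similarity cut-off. Bot templates here are ~10 tags; a copy with one or two jittered tags has Jaccard $(T-k)/(T+k) \approx 0.83$–$0.69$ against the template, so 0.65 catches up to two perturbed tags while leaving ordinary posts (which would need ~7 of 9 shared tags) unlinked |
| `min_cluster` | 3 | near-duplicate components below this size are kept; pairs of coincidentally identical short posts are common enough organically |
| betweenness distance | $1/w$ | heavier co-occurrence = closer in discourse; the unweighted mode exists for sensitivity checks |
| eigenvector `tolerance` | 1e-10 | max-norm change of the scaled iterate between iterations |
| discard warning | 0.25 | observed ceiling on the discarded fraction in real corpora of this kind; a warning threshold, not a hard filter |

## What the generator emulates — and what it does not

The synthetic corpus generator is the test bed standing in for corpora that
can no longer be retrieved. Its stated world, fixed once:

* **2,000 posts per area** by default (real corpora ranged from about 1,000
  to the 10,000-post download cap; 2,000 keeps a 14-area run on one CPU in
  minutes). A warning marks corpora under 1,000 posts, the floor real
  corpora respected.
* **5 planted topics per area**, disjoint 120-tag vocabularies, standing in
  for the 3–5 CES themes that community analysis typically finds; a post
  draws each tag from its topic with probability `p_topic = 0.7`, otherwise
  from a 100-tag shared travel/nature/photo vocabulary common to all areas.
* **Zipf rank-frequency** within every vocabulary, exponent 1.0 — the
  canonical heavy tail of tag usage.
* **Post length** `3 + Poisson(5)` tags, i.e. typically 3–15, plus the
  always-present query tag (every downloaded post contained the search
  term; the query tag is excluded from analysis graphs, where it would be a
  trivially dominant hub).
* **Bots**: 10% of posts from 5 accounts, each replicating a fixed ~10-tag
  template with 5% per-tag jitter, all posted inside a one-hour burst
  window. This matches the three detector families the cleaning module
  implements: duplicate content (graph-based), account volume (anomaly),
  burstiness (time series).
* **Ads**: 5% of posts carrying at least one blocklisted tag.
* **Misspellings**: 2% of drawn canonical tags replaced by registered
  variants (`travell`, `naturee`, …), exercising the synonym-merge stage.

A green test on this generator establishes that the pipeline recovers
structure *of the kind the analysis assumes* — planted topics, template
bots, Zipfian tails. It does not establish performance on real platform
data, which has correlated topics, multilingual tags, richer bot behaviour
and humans in the loop for blocklists. The CES labelling layer in particular
is a suggestion mechanism scored against an editable cue lexicon; the CES
class names attached to real areas were a human interpretive act that this
package deliberately does not claim to reproduce.

## Numerical choices

* **Power iteration on `A + 0.1·s_max·I`.** On bipartite components the
  extreme eigenvalues of `A` come in a ± pair and plain power iteration
  oscillates; the diagonal shift leaves the Perron vector unchanged and
  guarantees convergence (the star fixture in the tests is exactly this
  case). Non-convergence within `max_iter` is an error reporting the
  residual, never a silent result.
* **Shortest-path ties** in inverse-weight mode are detected with a 1e-12
  relative tolerance (sums of reciprocals of integer weights tie
  structurally, e.g. $1/2 + 1/2 = 1/4 + 1/4 + 1/2$); the brute-force test
  oracle applies the identical rule, and path-count arithmetic in the oracle
  is exact rational.
* **Deterministic tie-breaks everywhere**: frequency ties in top-150
  selection break lexicographically; fast-greedy merge ties break on the
  lexicographically least member hashtags; all sorts use byte order
  (locale-independent), which is what makes pipeline runs byte-identical
  across machines.
* **Disconnected graphs**: eigenvector is computed on the largest component
  (ties by summed weight) with other nodes scored 0 and a warning;
  betweenness normalizes per component; fast-greedy never merges across
  components, so partitions of disconnected graphs fall out naturally.
* **Degenerate inputs**: edgeless graphs give zero normalized strengths
  with a warning; coverage over a selection no post contains is an explicit
  error, not NaN.

## Design decisions that were genuinely open

* **Detection order**: bots are detected *before* synonym merging, since
  merging alters Jaccard similarities between posts; the converse order is
  defensible but less conservative.
* **"Most frequent hashtag pairs"** for the merged network is read as
  highest summed per-area co-occurrence counts (a per-area quota is the
  documented alternative).
* **Coverage** is read per post: among posts containing at least one
  selected tag, the fraction containing at least two. The alternative
  per-pair reading is noted but not implemented.
* **Weighted everything**: modularity, fast-greedy and default betweenness
  use co-occurrence weights; the unweighted variants are flags, because the
  graphs are intrinsically weighted even though the source material is
  silent on the point.

## Known limitations

* Tags are matched exactly after NFKC/lower-case normalization; no fuzzy
  matching, stemming or machine translation (multilingual corpora are
  handled only through user-supplied synonym maps, or deliberately left
  untranslated).
* The dense community-merge bookkeeping is comfortable to a few thousand
  nodes — plenty for top-150 graphs and 1400-pair merged networks, not for
  full million-tag vocabularies.
* Bot precision degrades if genuinely organic campaigns (many users posting
  identical tag sets) exist; the `min_cluster` and threshold parameters are
  the knobs, and the anomaly/time-series detectors the cross-checks.
* No figure layout is produced; GraphML export is the hand-off point to any
  network viewer.
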