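---
title: "Methods: corpus-based retrieval of peer-support responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corpus-based retrieval of peer-support responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerecho)
```

## The problem and the model

A short-form peer-support platform stores every interaction as a single
post–response pair: a help-seeking post (at most 950 characters) and
independent supportive replies (at most 600 characters), each rated by
the recipient as *good*, *ok* or *bad*. Because exchanges are
single-shot, anonymous and short, a reply written for one post can be
repurposed for a new post that expresses a sufficiently similar
concern. `peerecho` formalizes "sufficiently similar" as a two-stage
retrieval model with a coverage-calibrated decision rule.

**Stage 1 — lexical candidate generation.** Archived posts are held in
an inverted index. An incoming post is tokenized (Unicode letter runs,
lowercased, a small stopword list removed) and its terms weighted by
`tf × idf` with the smoothed dialect

$$\mathrm{idf}(t) = \ln\!\frac{N+1}{\mathrm{df}_t+1} + 1,$$

which is strictly positive and strictly decreasing in document
frequency. The top `max_query_terms` terms form a disjunctive query: any
archived post sharing at least one term is a candidate, scored by
$\sum_t w_q(t)\,\mathrm{tf}_p(t)\,\mathrm{idf}(t) / \lVert p \rVert$,
where $\lVert p \rVert$ is the Euclidean norm of the post's tf-idf
vector. The document-side normalization prevents long posts from
dominating on raw term counts. This stage is recall-oriented: it only
has to put the true nearest neighbours somewhere in the pool.

**Stage 2 — semantic reranking by Word Mover's Distance.** Each
document becomes a normalized bag of words (nBOW): out-of-vocabulary
tokens are dropped and the remaining counts normalized to a unit mass.
With word embeddings $x_i$ and ground cost
$c(i,j) = \lVert x_i - x_j \rVert_2$, the distance between documents
$d$ and $d'$ is the optimum of the balanced transportation problem

$$\mathrm{WMD}(d,d') = \min_{T \ge 0} \sum_{ij} T_{ij}\, c(i,j)
\quad\text{s.t.}\quad \sum_j T_{ij} = d_i,\; \sum_i T_{ij} = d'_j.$$

This is a true metric on nBOW documents (symmetry, identity, triangle
inequality — property-tested), and it recognizes similarity between
posts that share few literal words, because related words sit near each
other in embedding space.

**Decision rule.** The best candidate's WMD is compared to a threshold
τ. τ is not a similarity judgment but a *coverage* instrument: it is set
to the lower empirical q-quantile (the `⌈qn⌉`-th smallest value) of
best-match distances over a calibration stream, so that approximately a
fraction q of incoming posts — 10% by default, the deployment
operating point — receive a match. Matches return the matched post's
most favorably rated retained response (*good* > *ok* > unrated, ties
to the smallest response id).

## Assumptions

- **Reusability** rests on the corpus structure: single-shot,
  anonymous, short exchanges. Threaded or personalized conversations
  would violate it.
- **Embedding fidelity**: WMD is only as semantic as its embedding
  table. The loader accepts the word2vec text format; nothing in the
  package trains embeddings.
- **Stationarity**: quantile calibration transfers to fresh traffic
  only if the calibration stream is drawn from the same distribution as
  deployment traffic. The generalization property is tested on seeded
  streams from the same generator.

## Exact solving, bounds and pruning

The transportation problem is solved exactly by a primal
transportation simplex (northwest-corner start, u/v potentials, cycle
pivots) written for the small instances this corpus produces: documents
rarely exceed a few dozen distinct tokens, so instances are tiny and a
dense network-free implementation is fast and, at the optimum, exact.
Numerical details that matter:

- Optimality is declared when no reduced cost is below
  `-1e-10 · (1 + max |c|)`; the returned objective is optimal well
  within the package-wide `1e-8` contract (cross-checked against an
  independent LP oracle in the test suite).
- Degenerate pivots (zero flow) are accepted; in the rare event the
  pivot loop hits its iteration cap, the instance is re-solved by a
  two-phase simplex (`boot::simplex`) — a correctness backstop, not a
  performance path.
- If the two weight mappings are identical token-for-token the distance
  is 0 by the identity axiom and no solve happens.
- A document emptied by out-of-vocabulary removal is a structured
  signal (`empty document`), never a zero distance: an unrepresentable
  post must not match everything.

Ranking all pool candidates exactly would be wasteful, so two lower
bounds screen candidates, visited in order of the cheap bound:

- **WCD** (word centroid distance): distance between mass-weighted
  embedding centroids; `O(dim)` per pair after precomputation.
- **RWMD** (relaxed WMD): drop one side's marginal constraints; each
  word then ships its whole mass to its nearest counterpart; take the
  maximum of the two one-sided optima.

A candidate is solved exactly only if both bounds fail to exceed the
current m-th best exact distance (with a `1e-12` slack so boundary ties
are always resolved by an exact solve, never by a bound). The pruned
ranking is therefore *identical* — set and order — to exhaustive exact
ranking, which the tests assert directly.

One point of numerical honesty: WCD and RWMD are each provable lower
bounds on WMD, but they are **not mutually ordered**. RWMD is the
tighter screen on most pairs, yet counterexamples with WCD > RWMD occur
at an appreciable rate on random nBOW pairs (the suite exhibits them).
The pruning logic never relies on an ordering between the bounds — each
is compared to the incumbent independently — so this affects neither
correctness nor the ranking.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `post_limit` / `response_limit` | 950 / 600 | characters (code points, trimmed) | the platform's hard limits; what makes reuse viable |
| `max_query_terms` | 25 | terms | common more-like-this default; enough discriminative terms for short posts |
| `pool_size` | 50 | candidates | recall/latency balance for stage 1; rerank cost grows linearly in it |
| `coverage_target` q | 0.10 | fraction | the deployment operating point: enough matches to collect ratings, few enough to keep precision tolerable |
| `tau` | calibrated | WMD units (embedding distance) | never hand-set; the q-quantile of calibration best-scores |
| solicitation patterns | "kik", "instagram" | words | case-insensitive whole-word matches; configurable |

The threshold comparison is inclusive (`wmd ≤ tau`): a verbatim
duplicate (distance 0) must always match, and calibration scores sit
exactly at the quantile cut. With q = 0 the threshold is placed below
the smallest possible score — necessarily below 0, since verbatim
duplicates score 0 and the gate is inclusive — so "no matches" is
achievable; this is the one situation where τ is negative.

Unrated responses are retained (only *bad*-rated ones are excluded):
ratings accumulated gradually on the platform and an unrated archived
reply is not evidence of a poor one. Retrieval prefers rated *good*
over *ok* over unrated, so unrated responses surface only when nothing
rated is available for the matched post.

## The synthetic data layer

The generator emulates the *structure* of the archived corpus, not its
language:

- **Vocabulary and embeddings**: `n_topics = 10` clusters of 40
  alphabetic word stems each, drawn around random centroids at
  separation 10 with unit within-topic spread in 32 dimensions, plus 30
  shared filler words near the origin and a small gendered vocabulary
  in two narrow clusters slightly offset from the origin (so a wrongly
  gendered reply is semantically close but not identical — the
  geometry behind the pronoun-mismatch failure mode).
- **Corpus**: 2,000 posts by default; responses per post are
  `1 + Poisson(3.7)` (mean ≈ 4.7, the archived corpus's
  response-to-post ratio). On-topic responses skew favorable
  (good 0.60 / ok 0.25 / unrated 0.15 before contamination); an
  off-topic fraction (`rating_noise = 0.10`) is rated *bad*.
  Contamination: solicitation 2%, quarantine 2%, additional bad ratings
  5% — low single-digit rates, as expected of a moderated platform.
  30% of posts gender their subject; 5% of their responses gender it
  wrongly, giving the diagnostic a known ground truth.
- **Streams**: calibration and evaluation streams come from independent
  substreams of one master seed (label-keyed), with the same topic
  mixture as the corpus.

All texts respect the character limits by construction, and identical
configurations produce byte-identical files. Problem sizes used by the
test suite and the acceptance script — 2,000 archived posts, 1,000-post
calibration and evaluation streams — are the package's reference
conditions for coverage calibration; smaller fixtures (tens to hundreds
of posts) exercise every other property.

What passing tests on this data do **not** show: robustness to real
linguistic variation (spelling errors, paraphrase, code-switching),
rating behavior of real users, or the semantic quality of any
particular embedding table. The generator's topics are far better
separated than real emotional-support topics, so end-to-end
topic-recovery results are an upper bound on lexical-semantic retrieval
behavior, demonstrating machinery, not clinical performance.

## Evaluation machinery

Rating analytics are deliberately plain: counts, proportions, the
acceptable rate (percentage rated *ok* or *good*, **half-up** rounded —
R's default banker's rounding cannot reproduce conventionally reported
percentages), and the chi-square test of homogeneity
(`E = row·col/total`, `Σ(O−E)²/E`, `(r−1)(c−1)` degrees of freedom, no
continuity correction) for comparing rating distributions across
conditions. Framing-experiment assignment is per-user seeded Bernoulli
with a 1/3 experimental allocation.

The pronoun-mismatch diagnostic flags a response that uses any
opposite-gender term when the incoming post mentions exactly one
gender. It deliberately over-flags responders who gender *themselves*
("I'm a guy and…") — in reuse, a response carrying any wrong-gender
framing is worth auditing — and it never filters retrieval output: the
failure mode is observed, not silently fixed.

## Known limitations

- The solicitation filter is a whole-word keyword stub; it is not a
  moderation system and misses any phrasing beyond its pattern list.
- The inverted index is in-memory and rebuilt per session; persistence
  is a JSON artifact for inspection, not an incremental store.
- WMD cost grows with the product of the documents' distinct token
  counts; the design assumes short texts and would need batching or
  approximation (e.g. entropic regularization, deliberately not the
  default here) for long documents.
- Calibration targets coverage, not precision: τ says nothing about
  whether matched responses are *good*, only how often matching
  happens. Rating analytics exist precisely to evaluate the former.
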