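---
title: "Speech graph analysis of narrative discourse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech graph analysis of narrative discourse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narragraph)
```

## The model

Spoken narratives can be described non-semantically as networks: each
distinct word is a node and each transition between successive words is a
directed edge occurrence. The resulting object is a directed **multigraph**
— repeated transitions raise edge multiplicity and immediate repetitions
("sapo sapo") create self-loops. This representation deliberately ignores
meaning: it captures the *trajectory* of speech through its vocabulary, so
its attributes measure structural properties such as repetitiveness and
connectedness rather than content.

Two families of recurrence are distinguished. **Short-range recurrence** —
immediate repetition of words or word pairs — appears as self-loops (L1) and
repeated edges (RE). **Long-range recurrence** — returning to earlier words
after longer spans, as when a speaker circles back to re-state part of the
story — closes directed cycles and enlarges the largest strongly connected
component (LSC). The average shortest path (ASP) serves as a general measure
of graph size/compactness.

### Attribute definitions and conventions

For a window of `WC` tokens with `N` distinct words and `E = WC − 1` edge
occurrences:

| attribute | definition | convention |
|---|---|---|
| RE | Σ over distinct ordered pairs of (multiplicity − 1) | "excess" mode (default); `re_mode = "all"` counts every occurrence of a repeated pair |
| PE | unordered pairs {a,b}, a ≠ b, linked in both directions | self-loops excluded |
| L1 | self-loop edge occurrences | counted with multiplicity |
| L2 | reciprocal (two-node) cycles | = PE by construction |
| L3 | directed three-node cycles | one count per cyclic class, multiplicities ignored (trace(A³)/3 on the binary zero-diagonal adjacency) |
| LCC / LSC | largest weak / strong component node counts | on distinct edges |
| ATD | 2E/N | self-loops add 2 to their node's degree |
| D | distinct directed non-self edges / N(N−1) | 0 for N = 1 |
| DI / ASP | max / mean unweighted shortest path | see below |
| CC | mean local clustering over all nodes | degree < 2 ⇒ 0; self-loops excluded |

**Distances.** Directed word graphs are usually not strongly connected, so
directed all-pairs distances are undefined for most windows. DI, ASP and CC
are therefore computed on the **undirected simple projection** (distinct
edges, direction and self-loops dropped), restricted to the largest weak
component, over unordered node pairs. This is a documented convention, not a
claim about the historical tooling's internals; `distances = "directed_lsc"`
computes DI/ASP with direction respected inside the LSC instead, without any
fidelity claim. A single-node graph yields DI = ASP = 0.

**Determinism.** Node order is lexicographic (radix/C locale) everywhere, so
outputs are bit-stable across runs and platforms.

**Two routes.** `compute_attributes()` is a self-contained dense-matrix
implementation (tabulated multiplicity matrix; boolean transitive closure by
repeated squaring for components; breadth-first wavefronts for distances),
chosen because per-window graph-object construction dominated pipeline
runtime at ~30-node scale. The per-operation functions
(`largest_strongly_connected()`, `global_measures()`, ...) are an
independent igraph-backed route (Tarjan components, BFS distances). The test
suite checks the two routes against each other on random sequences and both
against brute-force Warshall / Floyd–Warshall oracles.

## Tokenization and stop-words

The tokenizer lowercases, treats every character that is not a letter,
digit, hyphen or apostrophe as a separator, and strips hyphens/apostrophes
from token boundaries (keeping them word-internally: "guarda-chuva").
No lemmatization or canonical-form conversion is applied — word identity is
surface form, which is the intended behavior for picture-book narratives
with limited lexical variation.

Stop-words — liaison terms with no specific meaning in oral speech — are
removed by list membership before graph construction. Bundled Portuguese
(default) and English function-word lists live in
`inst/extdata/stopwords/`; any one-token-per-line file loads with
`read_stopwords()`. Purely numeric tokens (`^[0-9]+$`) are removed by a
regex flag alongside stop-words, keeping the list files purely lexical;
mixed alphanumerics are retained. Filled pauses ("uh", "éh") are ordinary
tokens unless listed as stop-words. The pre-removal token count is retained
on every `token_sequence` so the verbosity measure can be switched.

## The moving-window verbosity control

Longer narratives mechanically inflate N, E and everything downstream of
them, so attributes are computed on fixed-length overlapping windows and
averaged per narrative. Defaults: **window_length = 30 tokens, overlap =
0.5** (step 15). Windows start at offsets 0, step, 2·step, …; only
full-length windows are emitted, so every windowed graph is built from
exactly 30 tokens — trailing tokens are dropped rather than forming a
shorter (hence structurally different) graph. A narrative shorter than one
window contributes a single all-token window. The window length is exposed
because the historical description is internally inconsistent (30 words in
the methods text, 18 in a figure caption); 30 is the default here.

**TNW** defaults to the cleaned (post-stop-word) token count, switchable to
the raw count (`tnw = "raw"`): only "the total number of words" is specified
upstream, and both readings are defensible.

## ASRS scoring

Eighteen items rated 0–3; an item rated 2 ("often") or 3 ("very often") is
one positive symptom. Counts aggregate into inattention (9 items) and
hyperactivity–impulsivity (9 items); total = their sum, range 0–18. The
item-to-domain map defaults to items 1–9 / 10–18 (DSM symptom order) and is
overridable, since the published Portuguese form's assignment is not
printed. Symptom *counts* (not raw 0–3 sums) are the predictors, per the
positivity rule.

## Statistics

Spearman r is the Pearson correlation of midranks; two-sided p from the t
approximation with n − 2 df. The partial Spearman rank-transforms x, y and
every covariate, residualizes the x- and y-ranks on the covariate ranks plus
intercept by least squares, and correlates the residuals; df = n − 2 − k.
With k = 0 this is *identical* (not merely close) to the plain Spearman.
This "Pearson on rank residuals" construction matches mainstream statistical
software's rank-based partial correlation, the closest reconstruction of the
original SPSS procedure. Degenerate inputs fail loudly: constant ranks,
collinear covariate ranks and constant residuals are errors naming the
offending quantity, and the correlation table prepends the offending
attribute/scale pair.

The analyzed family is {RE, L1, LSC, ASP} against three symptom scales;
the Bonferroni threshold is α/m with α = 0.05, m = 4, i.e. 0.0125. TNW is
reported alongside but flagged at the nominal 0.05, mirroring the original
tables' footnote distinction. The adjusted analysis controls age, IQ,
education years, BDI, STAI state *and* trait, and UPPS total — the superset
of the two covariate lists the source reports, with the set recorded in the
output. p-values are clamped to the smallest positive double so p ∈ (0, 1]
holds even under perfect rank agreement.

## The synthetic cohort generator

The generator exists so every pipeline stage has ground truth without any
recordings. A narrative is a three-branch token process: with probability
`p_repeat` re-emit the previous token; with probability `p_backref` draw
uniformly from the last `lag` distinct tokens excluding the previous one;
otherwise emit a previously **unused** vocabulary word. The branches are
engineered for separation: only the repeat branch creates self-loops (so
windowed L1 has binomial expectation `p_repeat · 29`), and only the
back-reference branch creates cycles, driving RE and LSC. Once a narrative
exhausts its vocabulary the fresh branch falls back to a uniform non-previous
draw; tokens are synthetic strings ("w001", …) that never collide with
stop-word lists.

Cohort defaults state a plausible young-adult community sample: n = 58;
symptom counts beta-binomial over 0–18 with shape (0.97, 1.30), giving mean
≈ 7.7 and SD ≈ 5.2; age 26 (SD 4), IQ 119 (8), 17 (3) education years,
BDI 11 (7), STAI state 46 (12) / trait 44 (13), UPPS 101 (24), all clipped
to instrument ranges and drawn independently of the symptom count by
default. The symptom linkage is linear: `p_repeat(S) = 0.05 + 0.010·S`
(range 0.05–0.23), `p_backref(S) = 0.25 − 0.010·S` (0.25–0.07), narrative
length `180 + 4·S` tokens plus inter-subject noise (`length_sd = 25`,
floored at one window). The length noise is part of the stated world for a
reason beyond realism: with zero linkage slopes a noiseless length rule
would make TNW constant across the cohort, and the statistics layer
correctly refuses constant columns — the null-calibration experiment would
be undefined rather than non-significant. ASRS item vectors are constructed
to score back exactly to the drawn S (positives rated 2 or 3 at random
positions, the rest 0 or 1).

`confound_via_bdi = TRUE` injects a deliberate confound: BDI becomes a
linear-plus-noise function of S and the narrative process is driven by the
BDI-derived signal instead of S itself. The unadjusted analysis then shows
an S–L1 association that adjusting for BDI collapses — exercising exactly
the difference between the plain and partial correlation tables.

What a green synthetic test does **not** establish: real narratives have
grammar, topic structure, Zipfian word frequencies and non-stationary
recurrence; the generator has none of these. Green tests establish that the
pipeline measures what it claims on streams with known recurrence structure
and recovers planted monotone linkages — not that any particular clinical
association is true.

## Numerical and degenerate-input choices

- Empty transcripts, empty windows and empty post-stop-word narratives are
  errors, not silent zeros.
- Non-integer window steps are rounded; the step is floored at 1.
- Exact identities (single-window mean = whole-graph attributes; zero-
  covariate partial = plain Spearman) are tested as equalities at machine
  precision; the partial-correlation cross-check against the matrix-
  inversion oracle uses 1e−10.
- `generate_narrative()` and `generate_cohort()` take explicit seeds and
  restore the caller's RNG state.

## Known limitations

- The undirected-projection convention for DI/ASP/CC is a choice among
  several defensible ones; numbers are comparable across this package's
  runs, not necessarily with other implementations' output.
- The optional XLSX metadata reader is not provided (no offline XLSX parser
  in the target environment); subject metadata is CSV.
- Bundled stop-word lists are reconstructions of standard function-word
  inventories, not the (no longer hosted) historical repository file, so
  token-for-token parity with the original preprocessing is not guaranteed.
- L3 ignores multiplicities by design; a multiplicity-weighted triangle
  count would be a different (also defensible) statistic.
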