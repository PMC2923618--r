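---
title: "Information-theoretic quantifiers of transcriptome profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic quantifiers of transcriptome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txentropy)
```

## The model

A bulk or single-cell expression matrix records values $x_{ij}$ for probes
$i = 1, \dots, N$ and samples $j = 1, \dots, M$. txentropy treats each
sample column as a discrete probability distribution over its probes,

$$p^{(j)}_i = \frac{t(x_{ij})}{\sum_k t(x_{kj})},$$

where $t$ is a positivity transform (below), and summarizes each profile
with four quantifiers, all in natural logarithms:

* **Shannon entropy** $S[P] = -\sum_i p_i \ln p_i$, with $0 \ln 0 = 0$.
* **Normalized Shannon entropy** $H[P] = S[P] / \ln N \in [0, 1]$: the
  evenness of the transcriptome. A sample that spreads its expression over
  all probes has $H$ near 1; a sample dominated by a few up-regulated
  transcripts — the "peaked" profile characteristic of advanced tumours —
  has lower $H$. $H$ is base-invariant.
* **Jensen-Shannon divergence**
  $JS(P_1, P_2) = S[\tfrac{P_1 + P_2}{2}] - \tfrac{S[P_1]}{2} - \tfrac{S[P_2]}{2}$,
  symmetric and bounded by $\ln 2$. Entropy alone cannot distinguish two
  profiles that are permutations of each other; JS to a chosen reference
  state can.
* **Statistical complexities**
  $C_{MPR}[P] = Q_0 \, JS(P, P_e) \, H[P]$ against the uniform profile
  $P_e$, and $C_M[P] = Q_0(P_{ref}) \, JS(P, P_{ref}) \, H[P]$ against an
  arbitrary reference $P_{ref}$ (a group-average profile such as
  "M-Normal"). Both vanish for full order (a delta profile, $H = 0$) and,
  for $C_{MPR}$, full disorder (uniform, $JS = 0$), peaking in between.
  $(H, C_{MPR})$ and pairs of $C_M$ values form the complexity-entropy
  planes on which cohorts at different progression stages separate.

### The normalization factor $Q_0$

$Q_0$ must guarantee $Q_0 \, JS(P, P_{ref}) \le 1$ for every $P$. We define
it as the reciprocal of the largest divergence attainable to the reference,
which is reached at a point-mass profile:

$$Q_0(P_{ref}) = \Big[\max_k JS(\delta_k, P_{ref})\Big]^{-1}.$$

For the uniform reference this reduces to the standard closed form
$1/[\ln(2N) - \frac{N+1}{2N}\ln(N+1) - \frac12 \ln N]$, which the test
suite verifies against brute-force maximization over all $N$ deltas. The
implementation evaluates $JS(\delta_k, P_{ref})$ for all $k$ in closed form
in $O(N)$:
$JS(\delta_k, P) = \frac{\ln 2}{2} + \frac{p_k}{2}\ln\frac{p_k}{2} -
\frac{p_k + 1}{2}\ln\frac{p_k + 1}{2}$.

## Tunable parameters

**Positivity transforms** (`build_profile`, `quantify_samples`). The ratio
$x_i / \sum x_i$ is undefined for matrices holding zeros or negative
log2-ratios, so three transforms are exposed:

| transform | action | default for |
|---|---|---|
| `identity_clip` | values below `eps` (default 1e-12) raised to `eps` | intensity data |
| `shift` | add $(\mathrm{eps} - \min x)$ so the minimum becomes `eps` | ad hoc |
| `exp2` | $x \mapsto 2^x$, undoing a log2 ratio | log-ratio data |

The default follows the declared `value_scale` of the matrix and is
recorded in the quantifier table and pipeline metadata, because H and JS
values are only comparable under a common transform.

**Reference averaging** (`average_profile`, `reference_profile`). Two
conventions are in circulation for turning a sample group into one
reference profile: the componentwise mean of the member *probability
profiles* (`mean_of_pdfs`) and the profile of the mean *expression vector*
(`pdf_of_mean`). They coincide exactly when all members have equal
transformed column totals and differ otherwise. Both are implemented;
`mean_of_pdfs` is the default because it stays inside probability space
regardless of scale differences between arrays, and the mode used is
stamped on every `reference_profile`.

**Spike filter** (`spike_filter`). A spike probe shows an anomalously high
value in only a few samples. No canonical published rule exists for this
artifact class, so the filter is an explicit operationalization: a probe is
removed when between 1 and `support_k` samples exceed `dominance_r` times
the probe's median absolute value. The defaults (`support_k = 1`,
`dominance_r = 10`) are deliberately conservative and exposed as pipeline
and CLI flags; on simulated data the rule recovers exactly the planted
spike probes. Because the rule is evaluated per probe, filtering a
filtered matrix removes nothing.

**Imputation** (`impute_missing`). Sporadically missing cells can be
filled by the probe mean (default), the sample mean, or a constant; the
alternative is `drop_missing_probes`, which removes any probe with a
missing cell. Which route fits depends on the missingness mechanism of the
platform; both are recorded (counts and dropped IDs) in the pipeline
metadata. Sample exclusion is annotation-driven only — an outlier call is
an analyst judgment, so the package never drops a sample on its own.

**Correlation rankings** (`probe_correlations`, `rank_by_difference`,
`flag_sign_reversals`). Probe-vs-quantifier correlations use
pairwise-complete samples, require at least 3 complete pairs, and use
average ranks for Spearman ties. Zero-variance probes are reported as
`NA` — *undefined*, deliberately distinct from "uncorrelated" — and are
excluded from rankings; conflating the two corrupts top-k lists.
Difference rankings sort by $\Delta = r_A - r_B$ (signed) or $|\Delta|$
(absolute) with ties broken by probe ID, so output order is reproducible.
Sign-reversal flagging requires strictly opposite signs with both
magnitudes at or above a threshold (default 0.5).

## The synthetic generator

`synthetic_spec()` / `simulate_expression()` emulate the structure the
quantifiers exploit, with full ground truth for recovery tests:

* **Peakedness via Dirichlet concentration.** Each sample's base profile
  is a symmetric Dirichlet($\alpha_g$) draw scaled to a fixed library size
  (default $10^4$). Concentration is the single peakedness knob: expected
  profile entropy increases monotonically with $\alpha$, so a strictly
  decreasing $\alpha$ along the group order encodes "later groups are more
  peaked, hence lower $H$" and yields an analytic recovery target
  (`expected_entropy_order`).
* **Planted progression markers.** Up-markers gain
  `marker_effect` $\times g/(G-1)$ intensity at group index $g$;
  down-markers gain the mirrored `marker_effect` $\times (G-1-g)/(G-1)$.
  The mirrored boost (rather than a subtraction) keeps down-markers
  monotone on the non-negative intensity scale — a subtraction floored at
  zero would destroy the monotone signal the recovery test looks for.
* **The default effect size (50 intensity units)** is chosen against two
  competing constraints: the per-probe shift must dominate within-group
  probe noise (standard deviation up to roughly 28 units in the most
  peaked group at the default geometry) so markers are recoverable, while
  the total marker mass (at most 1000 of a $10^4$ library) must stay small
  enough that the group entropy ordering remains driven by the Dirichlet
  concentrations, not by the markers. A substantially larger effect
  concentrates enough mass on the first group's down-markers to depress
  its entropy below the second group's, contradicting the ordering the
  generator's own truth declares.
* **Artifacts.** Spike probes are overwritten with a large value (default
  1000) in 1–2 random samples; cells are blanked at `missing_rate`.
  An optional log-ratio emission mode exercises the `exp2` transform path.

Everything is a deterministic function of the spec and one integer seed.

What the generator does *not* emulate: platform-specific noise (print-tip
or dye bias), probe-probe correlation structure beyond the compositional
constraint, batch effects, or realistic missingness mechanisms (cells are
blanked uniformly at random). Passing recovery tests therefore shows the
method recovers the planted structure under its own assumptions — it does
not certify performance on any particular array platform.

## Numerical choices

* Natural logarithms everywhere; $0 \ln 0 = 0$ is explicit and unit-tested.
* Profile validity: components non-negative, sum within $10^{-9}$ of 1,
  support at least 2.
* Test tolerances: $10^{-12}$ absolute against independent summation
  oracles (entropy term-by-term, JS via its Kullback-Leibler
  decomposition); printed-precision comparison (2 decimals for $H$, 6 for
  JS) where a published value fixes the precision.
* Degenerate inputs are hard errors, not silent repairs: empty matrices
  after filtering, all-missing probes under imputation, references built
  on a different probe set, unknown sample or probe IDs.
* In output tables floats are serialized at 15 significant digits, so a
  write/read round trip preserves values to well below $10^{-9}$.

## Problem sizes in the test suite

The stochastic suite uses 3 groups × 20 samples × 500 probes with
$\alpha = (50, 5, 0.5)$ and 20 up + 20 down markers, evaluated over 100
seeded replicates for the headline recovery checks (group entropy ordering
recovered in at least 95/100 runs; planted markers at ≥ 0.9 mean precision
in the top 40 of the $|$Spearman$|$ ranking against JS-to-normal), and
smaller geometries for per-module properties. These sizes give stable
proportions while keeping the default `testthat` run around ten seconds.

## Known limitations

* $H$ and the complexities depend on the transform and on upstream
  normalization of the arrays; the package deliberately performs no
  normalization and assumes matrices are already comparable across
  samples.
* The spike-filter rule is an operationalization; different `support_k` /
  `dominance_r` choices change which probes are called artifacts.
* Correlation rankings report magnitudes and ranks only; no inferential
  p-values are attached.
* With $N$ in the tens of thousands, per-sample profiles make $H$
  differences between groups numerically small (all profiles are far from
  delta); the quantifiers remain ordered but plane plots may need zooming.
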