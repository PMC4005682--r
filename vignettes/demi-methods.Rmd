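---
title: "Probe-level differential expression by hypergeometric enrichment: methods and design notes"
author: "demi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-level differential expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demi)
```

## The model

High-density microarrays interrogate every target — a gene, transcript,
exon, gene set or genomic region — with many short probes. Conventional
workflows summarize probe signals into one expression value per target
*before* testing; `demi` inverts this order. Each probe is tested on its
own, and the target-level question becomes purely combinatorial: are
differentially expressed probes over-represented among the target's
probes relative to the array-wide background?

The workflow has three steps.

**1. Relative-rank normalization.** Each array's $q$ intensities are
replaced by relative ranks $100\,r/q \in (0, 100]$, with fractional
(average) ranks for ties. The weakest signal maps near 0, the strongest
to 100, a first-quartile signal to 25, and the column median sits at
$50 \pm 100/q$ regardless of the array's intensity scale. The exact
scaling constant is immaterial: every downstream test is rank-based, so
any order-preserving per-column transform of the raw data yields
identical calls (this invariance is asserted by a test).

**2. Probe classification.** Under a two-group design with $m$ TEST and
$n$ REFERENCE arrays, each probe is assigned to the up set $H$ when the
one-sided Wilcoxon–Mann–Whitney tail probability
$P(\text{TEST rank sum} \ge \text{observed}) \le \alpha$, and to the
down set $L$ symmetrically; both tails include equality. The exact null
distribution is used whenever $mn \le 400$ and the row has no ties,
otherwise the normal approximation with tie and continuity correction.
When $\min(m, n) \le 3$ the discrete null makes small p-values
unattainable, so a heuristic replaces the test: a probe is labeled only
on complete separation of the groups — exactly the configurations where
the one-sided exact p attains its minimum $1/\binom{m+n}{m}$ (verified
against exhaustive enumeration for all $m, n \le 3$).

For time courses the per-probe statistic is Kendall's $T$ (concordant
minus discordant pairs) between signal and covariate. For up to 9 untied
covariate values and an untied signal the exact permutation null is
evaluated from the Mahonian (permutations-by-inversions) counts; with
ties, $\tau_b$ with the tie-corrected normal variance is used. Below 4
distinct covariate values the smallest attainable one-sided p is
$1/3! = 1/6$, so such designs are rejected outright.

**3. Target enrichment.** With $X$ of $n$ background probes in a
direction and $X_i$ of the target's $n_i$ probes among them, the
target's p-value is the hypergeometric upper tail $P(K \ge X_i)$,
$K \sim \mathrm{Hypergeom}(n, X, n_i)$ — the one-sided Fisher's exact
test on the corresponding 2×2 table. Both directions are always
computed. Two filters precede the test:

* **Multiplicity limit `t`** (default 1): probes mapping to more than
  `t` distinct targets of the analyzed category are removed *entirely* —
  from on-target counts and from $X$ and $n$. A differentially expressed
  multi-target probe would otherwise inflate several $X_i$ at once;
  removing it only from numerators would bias the background rate, so
  the background loses it too.
* **Censoring limit `u`** (default 30, near the median gene-specific
  probe count on high-density arrays): when $n_i > u$ the pair
  $(X_i, n_i)$ is scaled to $(\lfloor X_i u / n_i \rfloor, u)$. Very
  large targets would otherwise reach significance at biologically
  trivial excesses over the background rate; the floor is the
  conservative rounding — censoring can only reduce significance.

FDR adjustment is applied within each direction across all targets:
Benjamini–Hochberg for genes, and the Benjamini–Yekutieli variant
(valid under arbitrary dependency) by default for categories whose
probe sets overlap — transcripts, exons, gene sets and genomic windows.
Adjusted p below 0.05 is flagged significant.

Exon mode replaces the array-wide background with the parent gene's
probe set, so a significant exon responds out of proportion with the
rest of its gene (differential exon usage). Censoring is applied
uniformly in this mode as well; nothing in its rationale is specific to
the array-wide background. Gene-set mode promotes genes to the role of
probes, with the tested gene universe as background.

## Sliding genomic windows

Regional expression changes (e.g. long-range epigenetic silencing) are
detected by tiling chromosomes with 0.5-Mbp windows overlapping by 50%
and testing each window as a `genomic_region` target. Windows are laid
at starts $0, s, 2s, \dots$ with step $s = \text{width}(1 -
\text{overlap})$; a trailing start is emitted only when at least one
step of chromosome remains, so a chromosome shorter than the width
yields exactly one truncated window and no redundant sub-windows.
Probes join a window when their alignment *midpoint* falls in the
window's half-open interval — midpoints avoid double-counting a 25-mer
that straddles a boundary. A probe aligned to more than `t` distinct
loci is dropped, but membership in two overlapping windows is by
construction and exempt; this designed dependency between windows is
why BY adjustment is the window-mode default. Candidate regions count
as detected when a significant window overlaps them by at least
0.25 Mbp.

## The simulation benchmark

`simulateExperiment()` generates the study conditions the benchmark is
defined on: two groups of $N = 4$ arrays, 45,000 genes, ~1.3 million
probes, 1,000 DE genes with a $\pm 2$ log2 fold-change applied to 80%
of their probes, and the same-magnitude shift applied to a random 10%
of the remaining probes as probe-level noise. Where the generative
details are not fixed by those figures, the following choices were made
once and documented here:

* **Baseline intensity model**: hierarchical normal on the log2 scale —
  gene mean $\sim U[4, 12]$, probe offset sd 0.5, per-array replicate
  noise sd 0.25. With these defaults a $\pm 2$ shift on 4v4 replicates
  is reliably detected per probe, which is the benchmark's premise.
* **Per-gene probe counts**: discretized gamma with shape 4 and mean
  $1{,}300{,}000 / 45{,}000 \approx 29$, clipped to $[1, 200]$ — a
  right-skewed distribution whose median sits near the censoring
  default $u = 30$.
* **Noise placement**: each noise probe's shift lands in the TEST or
  the REFERENCE columns with equal probability. This keeps the two
  groups' intensity distributions identical in law. Piling all noise
  shifts into one group skews that group's signal distribution, and
  rank normalization then converts the skew into a systematic rank
  drift of *unshifted* probes near the edges of the intensity range.
  The drift is shared by probes of the same gene (they cluster in
  intensity), so it manufactures gene-level false positives that no
  multiplicity or censoring filter can remove — an artifact of the
  generator, not a property of the method, and measurably absent under
  symmetric placement. The one-sided variant remains available as
  `noise_placement = "test_only"` for studying exactly that artifact.
* **Multimapping**: a fraction (default 0.1) of probes additionally
  maps to a second gene, drawn as a random *partner gene per gene*
  rather than independently per probe. Cross-hybridization on real
  arrays is concentrated in paralogous pairs that share many probe
  sequences; per-probe scattering would almost never place two
  differentially expressed probes on the same off-target gene, making
  the multiplicity filter pointless by construction.

Evaluation labels a called target TP only when the direction agrees
with the truth; a call on a null target or in the wrong direction is
FP; an uncalled DE target is FN — the four cells partition the
evaluable targets, and MCC is reported as 0 with a flag when a marginal
vanishes. Cutoff-dependent metrics are averaged over the FDR cutoffs
0.05 and 0.01.

With the filters at their defaults the full-scale benchmark yields a
mean FP count per repetition of order 2–4 with MCC and TPR near 0.99,
and removing both filters raises FP by roughly an order of magnitude —
with the t-filter responsible for most of the reduction and censoring
for a smaller additional part. `scripts/acceptance.R` recomputes these
from scratch.

### What the generator does and does not emulate

The generator reproduces the benchmark's *dimensions* (probe counts,
effect sizes, noise rates, replication) but not several features of
real arrays: no spatial artifacts, no background/cross-hybridization
intensity floor, no GC- or sequence-dependent probe affinity, no
correlated sample quality effects, and an idealized two-level
multimapping structure. Passing benchmarks therefore demonstrate the
statistical machinery under the stated conditions, not robustness to
every laboratory artifact.

## Numerical choices and degenerate inputs

* Probe p-values come from `pwilcox` (exact, $mn \le 400$, no ties) or
  the tie/continuity-corrected normal; the exact upper tail is computed
  as $P(U \le mn - u_\text{obs})$ via the null's symmetry rather than
  $1 - \mathrm{CDF}$, avoiding cancellation.
* The exact Kendall tail sums Mahonian counts ($n \le 9$ means at most
  37 inversion classes; $n! \le 362{,}880$ is exactly representable).
* Constant probe rows have undefined $\tau$ and are labeled `none`.
* Tied rows under the two-group exact regime fall back to the corrected
  normal approximation; the exact rank-sum null assumes distinct ranks.
* A probe significant in both directions is impossible at
  $\alpha < 0.5$; the classifier asserts this rather than assuming it.
* Targets with no probes left after filtering are omitted from results;
  unclassified targets ($X_i = 0$) get $p = 1$ in both directions.
* Result tables are written sorted by FDR with target-id tie-breaks and
  full-precision serialization, so identical analyses produce
  byte-identical files.

## Problem sizes used in the shipped checks

The unit suite runs on fixtures of tens to thousands of probes computed
in milliseconds. The end-to-end benchmark checks in the test suite use
a 1/10-scale configuration (4,500 genes, ~130,000 probes, 100 DE genes)
with false-positive bands scaled proportionally — chosen so the whole
suite re-runs in a few minutes as part of routine development — while
`scripts/acceptance.R` exercises the full printed scale (45,000 genes,
~1.3 million probes, 25 repetitions). The two scales give statistically
consistent results; the reduced configuration is a convenience, not a
different model.

## Known limitations

* The probe-level $\alpha$ (default 0.05 per one-sided direction) is a
  tuning constant: with discrete 4v4 nulls it admits calls at
  $p = 2/70$ as well as $1/70$. Two-sided splitting ($\alpha/2$ per
  tail) is available by passing a halved `alpha`.
* The hypergeometric model treats probe calls as exchangeable draws;
  residual within-target correlation (shared sequence biases) makes the
  test anti-conservative in ways only the BY option and censoring
  mitigate.
* No target-level expression *estimate* is produced — only direction
  and significance of differential expression.
* Window mode is strand-agnostic and assigns probes by midpoint;
  fractional overlaps at window edges are deliberately not weighted.
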