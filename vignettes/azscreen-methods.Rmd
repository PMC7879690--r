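---
title: "Methods: the azscreen multi-scale abscission screen"
author: "azscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the azscreen multi-scale abscission screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azscreen)
```

## The problem and the model

Organ abscission is driven by genes whose expression is restricted both
*spatially* (to the abscission zone, AZ) and *temporally* (to the window in
which cell separation occurs). A single differential-expression contrast
cannot establish either restriction. `azscreen` formalizes a four-step
screen over unreplicated tag-count libraries from a factorial design:
ethylene-treated time courses (0, 3, 6, 9, 12 h) of the ripe-fruit AZ, the
immature-fruit AZ and the ripe-fruit pedicel (the latter two to 9 h), plus
field libraries of the AZ at three ripening stages (30, 120, 160 days after
pollination, the last being the abscising state).

### The exact two-library test

Because the libraries are unreplicated, per-gene dispersion cannot be
estimated; the appropriate test is the exact conditional (Audic–Claverie)
comparison. With totals $N_1, N_2$ and counts $x, y$,

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}
= \mathrm{NB}\!\left(y;\ \text{size}=x+1,\ \text{prob}=\tfrac{N_1}{N_1+N_2}\right).$$

`acPmf()` evaluates this in log space (log binomial coefficient plus log
probabilities, one final exponentiation); `acPvalue()` forms the two-sided
p-value $\min(1,\, 2\min(P(Y \le y), P(Y \ge y)))$ with both tails computed
directly from the regularized incomplete beta function, avoiding both
overflow and subtractive cancellation. The test suite keeps an independent
term-by-term summation oracle next to this closed form.

Two conventions are ours, since the underlying publication record leaves
them open:

* **Two-sidedness.** "Differential" expression means either direction; we
  double the smaller tail and cap at 1, recording the direction (sign of
  $y/N_2 - x/N_1$) separately.
* **Zero–zero ties.** A gene with $x = y = 0$ yields $p = 1$ regardless of
  the totals. The raw conditional arithmetic would call $y = 0$ surprising
  when $N_2 \gg N_1$, but absence from both libraries is no evidence of
  differential expression.

Multiplicity is controlled by Bonferroni within each pairwise library
comparison, family size = number of contigs tested in that comparison (the
comparisons are made and reported separately; a global family across
comparisons is available by passing `m` explicitly). Bonferroni controls
the family-wise error rate — stricter than an FDR criterion, and the
procedure named for this screen.

### The funnel

* **Stage 1** (`stage1EthyleneDegs()`): each treated time point of the ripe
  AZ versus its 0 h control; retention at adjusted $p \le \alpha$
  (default 0.01) for at least `minTimepoints` (default 1) time points. The
  12 h library belongs to stage 1 only, because the comparator series stop
  at 9 h.
* **Stage 2** (`stage2TissueFilter()`): retention requires a *single shared
  time point* (0/3/6/9 h) at which the ripe AZ differs significantly from
  **both** comparators and — by default — in the same direction versus
  both. A gene higher than one comparator but lower than the other is not
  tissue-specific; `requireSameDirection = FALSE` relaxes this for
  sensitivity analysis. The Bonferroni family here is the set of stage-1
  DEGs, since only those are tested.
* **Stage 3** (`ethyleneDirections()`, `classifyShape()`, `hcaCluster()`):
  profiles (counts per million — the tag-count arm has no length-based
  normalization) are classified by explicit rules: `A` non-decreasing with
  a net rise (sustained induction), `D` non-increasing with a net fall,
  `B`/`C` strict maximum at 3/6 h (transient). Monotone classes take
  precedence; tied 3 h/6 h maxima and constant profiles fall into `other`
  rather than being broken arbitrarily. Hierarchical clustering uses
  $1 - $ Pearson correlation with average linkage — the conventional
  defaults of the classic expression-clustering tools — making the
  partition invariant to per-gene affine rescaling, which we assert as a
  property instead of guessing at an unstated log or median-centering
  transform. Zero-variance profiles, for which correlation is undefined,
  are set aside in a reject class and reported.
* **Stage 4** (`stage4Concordance()`): natural-arm abundances are RPKM
  ($c \cdot 10^9 / (L \cdot N)$; `rpkm()`), since the field libraries come
  with transcript lengths. The direction call compares the abscising stage
  against the maximum of the two earlier stages with a fold threshold $f$
  (default 2) after adding a pseudo-floor $\varepsilon = 0.1$ RPKM to both
  sides: `up` iff $r_{160} + \varepsilon \ge f(\max(r_{30}, r_{120}) +
  \varepsilon)$, symmetrically for `down`. The published account requires
  only "comparable profiles" between induced and natural abscission; the
  parameterized fold rule is our concrete stand-in, and $f$ and
  $\varepsilon$ are exposed in `ScreenConfig`. Ethylene-`up` candidates
  need a natural `up` call (and symmetrically); transient candidates enter
  a final set only when the natural call is non-flat and matches the sign
  of their net 0 h → last-time-point change. Candidates absent from the
  natural table are recorded as unresolvable and excluded, never silently
  zero-filled.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.01 | adjusted p | conventional strict threshold for an exact test on unreplicated libraries |
| `minTimepoints` | 1 | count | one decisive time point suffices in a 4-point course |
| `ethyleneTimes` | 0,3,6,9,12 | h | ripe-AZ sampling grid; separation begins by 9 h |
| `sharedTimes` | 0,3,6,9 | h | comparator series end at 9 h |
| `naturalFoldThreshold` | 2 | fold | smallest fold conventionally called a change in RPKM data |
| `pseudoFloor` | 0.1 | RPKM | tames ratios at zero counts without masking real signal |
| `requireSameDirection` | TRUE | — | defines tissue-specificity coherently |

## The synthetic generator

`simulateAbscissionExperiment()` emulates the study conditions: 13
ethylene-arm libraries and 3 natural-arm libraries, counts drawn
independently per library as $\mathrm{Poisson}(N \pi_g f_{gl})$ — the exact
test's own sampling model; with no replicates, overdispersion is not
estimable, though a negative-binomial mode (`dispersion > 0`) exists for
robustness experiments. Base proportions are log-normal
($\mu = \log 10^{-5}$, $\sigma = 1.5$), spanning rare to abundant tags.
Library totals default to $10^6$; the modelled contigs are a subset of each
library, so column sums are far below the total, as in real data where most
reads map to unmodelled transcripts.

Planted labels partition the genes: `az_specific_up`/`down` follow a
saturating ramp $\mathrm{fold}^{\min(t,6)/6}$ (reciprocal for down) in the
ripe AZ only, with a concordant effect at 160 DAP in the natural arm — full
induction from 6 h, ahead of the 9 h onset of separation; `az_transient`
genes peak at 3 or 6 h and are flat in the field; `shared_responsive` genes
carry the ramp identically in all three tissues (stage-2 bait);
`natural_discordant` genes respond in the ripe AZ but stay flat in the
field (stage-4 bait); `null` genes are flat everywhere. Defaults (50 genes
per label, fold 8) were fixed from a pre-implementation power analysis and
not revisited.

What the generator does *not* emulate: assembly artifacts, mapping
ambiguity, compositional coupling between genes (each gene's proportion is
independent), and biological correlation between the ethylene and natural
arms beyond the planted means. Passing recovery tests therefore demonstrate
that the *screen logic and statistics* behave as designed under the assumed
sampling model — not that real libraries satisfy that model.

## What recovery runs show

The acceptance script (`scripts/acceptance.R`) recomputes, per run: pooled
sensitivity for AZ-specific genes, stage-2 exclusion of shared responders,
stage-4 exclusion of natural-discordant genes, the null type-I rate, and
the numerical agreement checks. Two structural effects dominate the
sensitivity it reports:

* **Abundance floor.** With log-normal proportions ($\sigma = 1.5$) a
  material fraction of genes has baseline expectation below a handful of
  reads at $10^6$ total; no exact count test can reach a
  Bonferroni-adjusted $p \le 0.01$ from such counts at 8-fold change, so
  those planted genes are undetectable in principle.
* **Induction/repression asymmetry.** Detecting 8-fold *repression*
  requires a much larger baseline than 8-fold induction — the evidence
  sits in the smaller count — so recovery of down-regulated genes is
  substantially lower than of up-regulated ones at equal abundance. This
  mirrors the real behaviour of count-based screens and is a caveat for
  interpreting any down-regulated candidate list.

Exclusion of confounders is near-total in the same runs: shared responders
die at stage 2 and discordant genes at stage 4 at rates the script reports
(typically above 0.95), and an all-null design yields a conservative
(< 0.05) raw type-I rate and no full-screen survivors.

## qPCR validation arm

Primer efficiency is estimated from a 5-fold serial-dilution standard
curve: slope of mean Cq against $\log_{10}$ relative template,
$E = 10^{-1/\text{slope}}$, reported as amplification factor per cycle
(2.0 = perfect doubling) to match the 1.8–2.0 inclusive retention gate.
A non-negative slope flags an invalid series rather than returning a
nonsense efficiency. `oppositeProfileCheck()` encodes the non-shedding
genotype prediction — peak-normalized profiles, ripe-stage attenuation
below `threshold` (default 0.5) for up genes, symmetric for down. The 0.5
default is our choice; the published criterion is qualitative.
Reference-gene normalization and ΔΔCq statistics are out of scope:
profiles arrive as relative-expression vectors.

## Numerical choices and degenerate inputs

* Tails via `pbeta` (regularized incomplete beta), never `1 − cumsum`;
  pmf in log space; both verified against summation oracles at
  $10^{-10}$ absolute / $10^{-12}$ relative in the test suite.
* Count tables are validated cell-by-cell on input with errors naming the
  offending contig and library; duplicate ids, totals below column sums,
  and non-positive lengths are rejected at construction (class validity).
* A missing library for a design cell is an error, not an imputed zero.
* All-zero profiles: `normalizeToPeak()` errors (undefined);
  `naturalDirection()` returns `flat` via the pseudo-floor.
* Determinism: the generator requires a seed and restores the caller's RNG
  state; identical inputs give byte-identical screen reports.

## Problem sizes

Default test and acceptance runs use 300-gene designs (20 replicate
screens), a 10,000-gene null design, a 33,489-case oracle grid for the
exact test, and 1000 qPCR noise replicates — sizes at which every
stochastic check is stable across seeds while a full run stays within a
few minutes on one core.

## Known limitations

* Sensitivity for low-abundance and down-regulated genes is bounded as
  described above; reported recovery rates quantify it.
* The natural-concordance fold rule and the qPCR match threshold are
  parameterized stand-ins for qualitative published criteria.
* Only the four main profile classes are modelled; finer sub-cluster
  structure is not reproduced.
* The screen assumes Poisson sampling; systematic (non-sampling) variation
  between libraries inflates significance and is not corrected for,
  because unreplicated designs offer no way to estimate it.
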