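# azscreen

Multi-scale transcriptome screening for **abscission-zone (AZ) specific,
abscission-timed genes** from unreplicated tag-count sequencing libraries.

Fleshy fruit drop from the plant through cell separation in a specialized
abscission zone at the fruit base. Finding the genes that drive this requires
more than a single differential-expression contrast: a gene must respond to
the abscission signal (ethylene) *in the ripe-fruit AZ*, must **not** respond
the same way in neighbouring tissue (pedicel) or in the AZ of immature fruit
that cannot abscise, and its expression must move the same way during natural
abscission in the field. `azscreen` implements that four-step screen for
count data from unreplicated libraries (454/SAGE-style tag counts, or any
per-library read-count matrix), together with the profile-clustering,
RPKM and qPCR-validation tooling around it, and a seeded synthetic-data
generator so the whole pipeline can be exercised and power-checked without
raw sequencing data.

Intended users: plant transcriptomics groups working on organ abscission or
any comparative time-course screen over unreplicated count libraries.

## The statistic at the core

Two libraries with total mapped reads \(N_1, N_2\) yield counts \(x, y\) for
one transcript. Conditional on \(x\), under the null of equal underlying
proportion, \(y\) follows

\[
p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+N_2/N_1\right)^{x+y+1}}
\;=\; \mathrm{NB}\!\left(y;\; x+1,\; \tfrac{N_1}{N_1+N_2}\right),
\]

the Audic–Claverie law, algebraically a negative binomial. `acPvalue()`
computes the exact two-sided p-value `min(1, 2 min(P(Y≤y), P(Y≥y)))` with
tails evaluated through the regularized incomplete beta function, stable for
arbitrarily large counts. p-values are Bonferroni-adjusted within each
pairwise library comparison (`bonferroni()`).

The screen (`runScreen()`) then chains:

1. **Stage 1** — each treated ethylene time point vs the 0 h control in the
   ripe-fruit AZ; a contig is a DEG if adjusted p ≤ α at ≥ 1 time point.
2. **Stage 2** — a DEG is AZ-specific if at some shared time point it
   differs significantly from **both** the immature-fruit AZ and the ripe
   pedicel, in the same direction.
3. **Stage 3** — the response profile is classified (sustained up `A`,
   3 h peak `B`, 6 h peak `C`, down `D`) via `classifyShape()` /
   `hcaCluster()` (1 − Pearson, average linkage).
4. **Stage 4** — the candidate's natural-ripening RPKM profile
   (30 → 120 → 160 days after pollination) must move concordantly
   (`naturalDirection()`, 2-fold rule with a 0.1-RPKM floor).

## Worked example

```r
library(azscreen)

## a single exact test: 5 vs 50 reads in two libraries of 1e5
acPvalue(5, 50, 1e5, 1e5)
#> [1] 2.135843e-10

## simulate the full study design (300 genes, 50 per planted-effect label)
set <- simulateAbscissionExperiment(seed = 42)
res <- runScreen(set$ethylene, set$natural)
res
#> ScreenResult (four-step screen)
#>   stage 1 ethylene DEGs:      169
#>   stage 2 AZ-specific:        124
#>   final (natural-concordant): 40 up, 24 down
```

169 of 300 genes respond to ethylene in the ripe AZ; 124 of those are
AZ-specific; 64 survive natural-abscission concordance. The audit trail
records every test performed:

```r
head(screenAudit(res), 3)
#>   contig_id     comparison time_h comparator  x   y    N1    N2        p_raw       p_adj direction
#> 1  gene0001 AZ150_3h_vs_0h      3   AZ150_0h 94 205 1e+06 1e+06 1.233797e-10 3.70139e-08        up
#> 2  gene0002 AZ150_3h_vs_0h      3   AZ150_0h  5  13 1e+06 1e+06 9.625244e-02 1.00000e+00        up
#> 3  gene0003 AZ150_3h_vs_0h      3   AZ150_0h 19  41 1e+06 1e+06 6.217603e-03 1.00000e+00        up
```

qPCR-side helper: efficiency from a 5-fold serial dilution standard curve
(Cq stepping by log2(5) per dilution is perfect doubling):

```r
d <- c(5, 25, 125, 625, 3125)
primerEfficiency(d, 20 + log2(d))
#> $slope
#> [1] -3.321928
#> $efficiency
#> [1] 2
```

A thin command-line front end is in `inst/scripts/az-screen.R`
(`az-screen.R simulate --seed 5 --out simdir`, then `az-screen.R run ...`
to produce the TSV report directory).

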