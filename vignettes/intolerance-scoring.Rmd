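---
title: "Gene intolerance scoring: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene intolerance scoring: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvis)
```

## The problem and the model

Some genes carry many common protein-altering variants in healthy
populations; others carry almost none.  When a patient presents with a
candidate mutation, the gene's tolerance to functional variation is as
informative as the variant's own predicted impact: a damaging-looking
variant in a gene riddled with common stop-gains (an olfactory receptor,
say) is a weak candidate, while the same variant in a gene that the
population keeps scrupulously free of functional variation is a strong
one.

The score this package computes quantifies that contrast.  For every
gene with a consolidated coding footprint we count

* **X** — the total number of qualifying protein-coding site-alleles
  (functional and synonymous alike, at any frequency), a proxy for the
  gene's mutational opportunity: its size, mutability and local coverage;
* **Y** — the number of *common functional* site-alleles: missense,
  nonsense and splice acceptor/donor variants with minor allele
  frequency above a threshold rho (default 0.1%).

Across all assessable genes we fit the ordinary least squares regression

$$ Y_i = \beta_0 + \beta_1 X_i + \varepsilon_i $$

and take the **studentized residual**

$$ S_i = \frac{r_i}{\hat\sigma\sqrt{1 - h_{ii}}} $$

as the intolerance score, where \(r_i\) is the raw residual,
\(\hat\sigma^2 = SSE/(n-2)\) and \(h_{ii}\) is the hat-matrix leverage.
Dividing by the leverage-adjusted residual standard deviation accounts
for the fact that raw residuals are more variable for genes with typical
burden than for genes at the extremes of X.  \(S < 0\) means the gene
carries less common functional variation than the genome-wide trend
predicts — the signature of purifying selection; \(S > 0\) means more —
tolerance, or some form of balancing/positive selection.  Scores are also
reported as percentiles (average ranks, lowest score = lowest
percentile), which is the scale used downstream.

### Assumptions worth stating

* The regression is unweighted: every assessable gene contributes
  equally, and the genome-wide line *is* the definition of "expected".
* X is a sufficient stand-in for mutational opportunity.  Raw residuals
  are orthogonal to X by construction; the test suite additionally checks
  that the *studentized* scores stay essentially uncorrelated with X.
* Classification of effects into functional/non-functional is taken from
  the input annotations as given; it is knowingly imperfect.
* Only SNVs participate; indel calls are excluded as less reliable.

## Inputs, filters and their parameters

| parameter | default | meaning |
|---|---|---|
| `splice_pad` | 2 bp | exon widening on each side so splice acceptor/donor variants fall inside the footprint |
| `min_depth` | 10× | minimum mean coverage for a site to be assessable |
| `min_fraction` | 0.70 | minimum covered fraction of the footprint for a gene to be scored |
| `rho` | 0.1 (%) | common/rare MAF threshold defining Y |
| `population` | ALL | which cohort MAF drives the threshold (ALL/EA/AA) |
| `mode` | standard | `pp2` relabels PolyPhen-2-benign missense as non-functional |
| `studentization` | internal | `external` re-estimates sigma excluding each gene |

Genes are keyed by symbol; all transcripts of a symbol are merged into
one footprint (union of padded exons) so a variant annotated against
several transcripts is counted once.  A symbol appearing on two
chromosomes is rejected rather than silently merged.  Splice pads are
ordinary region sites and therefore subject to the coverage requirement
like any other site.  Internally all coordinates are 0-based half-open;
BED inputs are native, VCF positions are converted on read.

The common/rare threshold is *strict* (MAF > rho).  Multi-allelic sites
contribute one record per alternate allele.  Genes with zero qualifying
variants stay in the regression with X = Y = 0 — dropping them would bias
the fit low.

Internal studentization is the default because the score's claim to
account for burden-dependent variability is exactly the leverage
adjustment; external studentization is offered for users who prefer the
deletion estimate, and the two agree in sign and rank order (a property
the suite checks).  The published genome-wide scores do not document
which variant was used; this package pins its own tests to the internal
form.

## Degenerate inputs and numerical choices

* Fewer than 3 assessable genes, or constant X: the regression refuses
  to fit (explicit errors rather than NaN scores).
* A perfectly collinear fit (residual standard deviation numerically
  zero, relative tolerance 1e-10 on the fitted scale) raises a
  degenerate-fit error when studentizing.
* Leverage of 1 would make a score undefined and errors out by name.
* Percentile ties take average ranks, so the mean percentile of n genes
  is exactly 100(n+1)/2n.
* Representative-mutation ties (same gene percentile) break toward the
  higher damaging score, then the lexicographically first gene, making
  the selection deterministic under any input order.
* Exact tests are delegated to `binom.test`/`fisher.test` (two-tailed,
  minimum-likelihood summation); the rank-sum test is exact below 25
  observations and a continuity-corrected normal approximation above.

## Evaluation battery

`logistic_association` regresses list membership on the score (Wald CI
and p; perfect separation is flagged, not crashed).  `roc_auc_delong`
computes the empirical AUC with midpoint tie handling and a DeLong 95%
CI (via pROC), oriented so that low scores predicting membership gives
AUC > 0.5.  `mann_whitney` reports the rank-sum U whose identity
U/(n1·n2) with the AUC is enforced in tests.  `group_summary` maps a gene
list to its mean score, the percentile at which that mean falls in the
empirical score distribution (a score value mapped onto the genome-wide
ranking — not the mean of member percentiles), and quartile-bin
proportions.

## De novo prioritization

For trio studies the package recodes each de novo mutation onto a [0,1]
damaging scale (missense keeps its PolyPhen-2 score; likely
gene-disrupting events — nonsense, splice, frameshift-class — are 1;
silent are 0), selects per proband the single mutation in the most
intolerant gene, and flags the **hot zone**: damaging ≥ 0.95 and gene
percentile ≤ 25, both boundaries inclusive.  Cohorts are compared by
two-tailed Fisher exact test on the in-zone by case/control table.
Quartile enrichment of mutation *events* uses an exact binomial test
whose null probability is not 0.25 but the fraction of covered coding
real estate held by the bottom-quartile genes (0.38 for the published
gene set) — intolerant genes are disproportionately large, and a de novo
mutation lands in a gene roughly in proportion to its size.

## What the simulator emulates — and what it does not

`simulate_exome` generates the minimal structure the score consumes:
log-normal gene lengths (meanlog log(1500), sdlog 0.6 — a realistic
coding-footprint spread with a ~1.5 kb median), 1–3 exons per gene, full
uniform coverage, Poisson variant counts at 0.02 site-alleles per base
(about 30 per average gene, the order observed in cohort-scale exome
aggregates), a 70/30 functional/synonymous split, and a two-component
MAF mixture in which 15% of variants are common.  In genes designated
intolerant (10% by default) a functional variant that drew "common"
keeps that status only with probability `suppression` (default 0.2), so
Y is thinned while X is untouched — the exact signature the score is
built to detect.  Trio simulation plants, at a configurable rate, one
damaging mutation in a truth-intolerant gene per case proband on top of
a length-weighted background shared with controls.

Deliberately absent: a realistic site-frequency spectrum (the score only
consumes the threshold indicator), linkage, demography and
population-specific MAF differences (the EA/AA columns duplicate the
combined MAF), coverage heterogeneity along genes unless supplied, and
annotation error.  Passing tests on this generator therefore demonstrate
the *statistical machinery* — recovery of suppressed genes, calibration
of p-values, determinism — not robustness to the annotation and coverage
artifacts of real cohort data.

Validation sizes were chosen to keep the full suite comfortably
reproducible on a laptop: 2000-gene exomes for recovery/null checks
(recovery AUC threshold 0.85 at suppression 0.2; null AUC 0.5 ± 0.05
averaged over seeds at suppression 1.0), 1000-replicate uniformity
checks for the association p-values, 200-seed trio sweeps, and exhaustive
exact-test enumeration for tables up to total 14 with random coverage up
to 30.

## Known limitations

* Scores are relative to the cohort that produced the variant table;
  tables from different cohorts should be compared by correlation or
  rank, not by raw S.
* Genes with very low X have noisy scores; the leverage adjustment
  helps, but the score cannot manufacture information the cohort does
  not contain (the published analyses treat sub-threshold-coverage genes
  as unassessable for the same reason).
* The functional/non-functional dichotomy ignores variant severity
  within the missense class except in `pp2` mode, which relies on the
  PolyPhen-2 labels supplied with the input.
* The hot-zone thresholds (0.95/0.25) are illustrative defaults, not
  optimized decision boundaries; both are configurable.
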