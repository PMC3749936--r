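# rvis

Gene-level intolerance to functional variation, from cohort-scale exome
variant data.

Clinical sequencing keeps finding plausible-looking mutations in genes
that, on inspection, carry plenty of equally "damaging" variation in
healthy people. This package ranks every gene by how much common
functional variation it tolerates, so that a candidate mutation can be
weighed by the company its gene keeps. For each gene with an adequately
covered coding footprint it counts

* **X** — all qualifying protein-coding site-alleles (any class, any
  frequency), and
* **Y** — common functional site-alleles (missense, nonsense, splice
  acceptor/donor with MAF > ρ, default ρ = 0.1%),

fits the genome-wide regression **Y = β₀ + β₁X + ε**, and scores each
gene by its studentized residual

**S = r / (σ̂ √(1 − h))**,

where *h* is the hat-matrix leverage. S < 0: the gene has less common
functional variation than its mutational burden predicts (intolerant,
typically under purifying selection); S > 0: more (tolerant). Scores are
ranked into percentiles, lowest = most intolerant.

Around that core the package provides:

* consolidated, splice-padded (±2 bp), coverage-masked gene footprints
  from BED transcript definitions (≥10× depth, ≥70% covered for
  assessability);
* variant filtering (PASS SNVs in covered sites) and classification,
  including a PolyPhen-2-informed mode that treats benign missense as
  non-functional;
* gene-list evaluation: logistic association, DeLong-CI ROC AUC,
  Mann-Whitney U, score-table correlations, and group summaries
  (mean score, its percentile in the empirical distribution,
  quartile-bin proportions);
* de novo mutation prioritization: per-proband representative mutation,
  the 2D "hot zone" (damaging ≥ 0.95, gene percentile ≤ 25), Fisher
  exact cohort comparison, and size-adjusted exact binomial quartile
  enrichment;
* a synthetic exome/trio simulator with known ground truth.

## Worked example

```r
library(rvis)

cfg <- sim_config(n_genes = 300, seed = 7)          # 10% intolerant genes
sim <- simulate_exome(cfg)
res <- compute_rvis(sim$variants, sim$transcripts, sim$coverage,
                    rvis_config(), verbose = TRUE)
#> genes: 300 assessable, 0 dropped; variants: 11129 in, 11129 qualifying;
#> fit: Y = -0.0332 + 0.0986 X
print(res)
#> <rvis_scores> 300 genes (rho=0.1%, ALL, standard mode)
#>   fit: Y = -0.0332 + 0.0986 X, sigma = 1.9701
#>   most intolerant:
#>     GENE0246     S= -4.9947  pct=  0.33
#>     GENE0279     S= -2.9942  pct=  0.67
#>     GENE0271     S= -2.8932  pct=  1.00
```

The fitted line says a gene with X total variants is expected to carry
about 0.1·X common functional ones; GENE0246 sits five
standard-deviations short of that expectation — the strongest
intolerance signal in this simulated cohort. Checking recovery against
the simulator's truth labels and running the trio hot-zone analysis:

```r
roc_auc_delong(res, sim$truth$gene_symbol[sim$truth$intolerant])$auc
#> [1] 0.9050246

tr <- simulate_trios(sim$truth, sim_config(n_genes = 300, seed = 7,
                                           causal_hit_rate = 1))
hz <- hot_zone_enrichment(annotate_denovo(tr$case, res),
                          annotate_denovo(tr$control, res))
c(case = hz$case$proportion, control = hz$control$proportion, p = hz$p)
#>      case   control         p
#> 6.50e-01  5.50e-02  3.56e-39
```

65% of case probands versus 5.5% of controls have their representative
de novo mutation in the hot zone — the planted causal mutations are
found where the 2D scheme looks for them.

A command-line front end (`inst/cli/rvis.R`) exposes the same pipeline
as `simulate`, `score`, `evaluate` and `hotzone` subcommands for
file-based workflows.

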