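# bgfmap

Fine mapping of a biallelic quantitative trait locus (QTL) inside a ~1 cM
region from dense, phased SNP haplotypes of unrelated individuals, using a
Bayesian gene-frequency (BGF) model, with a least-squares haplotype
regression scan (LSR) as comparator and a forward-in-time Wright–Fisher
simulator for generating the linkage disequilibrium (LD) the methods
exploit.

## The model in brief

Phenotypes follow `y_i = x_i'β + Q_i μ + e_i`, where `Q_i ∈ {0,1,2}` is the
unobserved QTL genotype and `μ` the substitution effect. The BGF model
replaces `Q_i` by its conditional mean given the marker haplotypes,
`E(Q_i|M) = π_m(i) + π_p(i)`, where `π_j` is the conditional probability
that a gamete with marker haplotype `H_j` carries QTL allele `Q₂` — the
disequilibrium parameters. The unexplained gametic uncertainty
`π_h(1−π_h)μ²` of each gamete is folded into a heterogeneous residual
variance

```
σ*²_i = σ²_e + [π_m(1−π_m) + π_p(1−π_p)] μ² .
```

Priors: flat on `β`, scaled inverse chi-square on `σ²_e`, normal on `μ`,
logit-normal on `π`, discrete uniform on the QTL location `l` (window
markers for the 1-SNP model, bracket midpoints for the 2-SNP model). A
Metropolis–Hastings within blocked Gibbs sampler targets the joint
posterior; the location estimate is the posterior mode of `l`, and the
detection statistic is the posterior mean of the marker-explained QTL
variance `μ² Var_i(E(Q_i|M))`. The LSR comparator regresses phenotypes on
haplotype copy numbers at every SNP (or SNP pair) and takes the position
with the smallest F-test p-value. Power for both methods is calibrated
against an empirical null: the upper 10% quantile of the statistic over
replicates simulated without a QTL.

## Worked example

```r
library(bgfmap)

sim   <- simulateStudy(spacingCM = 0.01, n = 500,
                       qtlVarianceFraction = 0.05, seed = 42)
lsr   <- lsrScan(sim$study, k = 1)
chain <- runBgfChain(sim$study, k = 1,
                     chain = chainConfig(20000, 5000, 5, seed = 1))
bgf   <- summarizeChain(chain)

lsr
#> ScanResult [LSR1]: estimated QTL position 0.4 cM (candidate 5 of 11);
#>   detection statistic 17.08124
bgf
#> ScanResult [BGF1]: estimated QTL position 0.4 cM (candidate 5 of 11);
#>   detection statistic 0.03038596
```

The simulated truth puts the QTL at 0.3 cM on the window grid; on this
replicate both methods land on the adjacent marker at 0.4 cM (a 0.1 cM
error, typical of the mean absolute errors the evaluation reports). The
LSR statistic is the F value at the chosen SNP; `detectionStatistic(bgf)`
is the posterior mean marker-explained QTL variance (the trait has unit
variance, so 0.030 means ~3% explained). `scanTable()` returns the
per-position table for either method.

A full power/precision cell (fresh LD history per replicate, shared
datasets across methods, null-calibrated critical values):

```r
runExperiment(methods = c("BGF1", "LSR1"), qtlVarianceFraction = 0.05,
              markerSpacingCM = 0.1, n = 200, nNullReps = 150,
              nPowerReps = 150, seed = 7)
```

A command-line driver with `simulate`, `map-bgf`, `map-lsr` and `power`
subcommands is installed under `exec/bgfmap`; it reads a declarative YAML
configuration and writes TSV outputs plus a manifest recording config,
seeds and version.

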