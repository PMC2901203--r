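---
title: "Fine mapping QTL with the Bayesian gene-frequency model"
author: "bgfmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine mapping QTL with the Bayesian gene-frequency model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A quantitative trait locus (QTL) has been localized to a ~1 cM chromosomal
segment, and the goal is to fine map it inside that segment using dense,
phased SNP haplotypes of *unrelated* individuals. With unrelated
individuals there is no cosegregation signal; all positional information
comes from linkage disequilibrium (LD) - the population-level association
between marker alleles and the unobserved QTL alleles.

## The gene-frequency model

Phenotypes follow the linear model

$$y_i = \mathbf{x}_i'\boldsymbol\beta + Q_i\,\mu + e_i,$$

where $Q_i \in \{0,1,2\}$ counts copies of QTL allele $Q_2$ and $\mu$ is
the allele substitution effect. $Q_i$ is unobserved, so it is replaced by
its conditional expectation given the marker data. The key parameters are
the *conditional gene frequencies* $\pi_j$: the probability that a gamete
carrying marker haplotype $H_j$ (at the SNP or SNP pair flanking the
putative QTL position) carries $Q_2$. Each gamete's contribution is
Bernoulli, so

$$E(Q_i \mid M) = \pi_{m(i)} + \pi_{p(i)},$$

with $m(i), p(i)$ the maternal and paternal haplotype codes. The leftover
uncertainty of each gamete, $\pi_h(1-\pi_h)\mu^2$, cannot be dropped: it is
folded into the residual, giving *heterogeneous* residual variances

$$\sigma^{*2}_i = \sigma^2_e + \left[\pi_{m(i)}(1-\pi_{m(i)}) +
\pi_{p(i)}(1-\pi_{p(i)})\right]\mu^2 .$$

This heterogeneity is the essential difference from the least-squares
regression comparator: when every $\pi_j$ is 0 or 1 (complete LD) the
residuals are homogeneous and the two methods coincide. When all $\pi_j$
are equal (linkage equilibrium), $E(Q|M)$ is constant and the markers carry
no positional information at all.

Unrelated individuals are independent, so the likelihood is a product of
univariate normal densities with the means and variances above, evaluated
at the SNP (1-SNP model, $k=1$) or SNP bracket (2-SNP model, $k=2$)
indexed by the location parameter $l$.

## Priors and the sampler

* $\boldsymbol\beta$: flat.
* $\sigma^2_e$: scaled inverse chi-square $(\nu_e, S^2_e)$.
* $\mu$: normal with null mean, variance $\sigma^2_\mu$.
* $\boldsymbol\pi$: logit-normal - $x_j = \mathrm{logit}(\pi_j)$ is normal
  with null mean and diagonal covariance $\sigma^2_x I$. The logit
  parameterization keeps every $\pi_j$ strictly inside $(0,1)$, so the
  gametic variances never degenerate during sampling.
* $l$: discrete uniform over the candidate grid (all window markers for
  $k=1$; all adjacent-bracket midpoints for $k=2$).

Sampling uses a blocked Gibbs scheme: (1) $\boldsymbol\beta$ is drawn
exactly from its multivariate-normal full conditional (weighted normal
equations with weights $1/\sigma^{*2}_i$); (2) $(\boldsymbol\pi, \mu, l)$
are updated jointly by Metropolis-Hastings with symmetric random walks on
the logit and effect scales and a uniform draw of $l$; the acceptance
ratio is formed on the logit scale (likelihood times the normal densities
of $x$ and $\mu$) - the random walk is symmetric in $x$, not in $\pi$, so
the logit Jacobian of the $\pi$-scale prior cancels exactly against the
Jacobian hidden in the $\pi$-scale proposal density, and evaluating the
ratio with the $\pi$-scale prior would count it twice;
(3) $\sigma^2_e$ is updated by Metropolis-Hastings with a normal random
walk (the heterogeneous residuals make its full conditional non-standard);
non-positive candidates have zero prior support and are rejected outright.

Two further posterior-invariant moves per sweep address a real pathology
of the random-walk block: the joint posterior is typically *multimodal
across candidate locations* - once $\boldsymbol\pi$ has adapted to one
SNP, joint moves to another candidate are almost never accepted, so
independent chains lock into different location basins and the posterior
mode of $l$ becomes a lottery (in diagnostics, two chains on the same data
agreed on the mode only ~50% of the time, each reporting near-unit
posterior mass for its own basin). The package therefore adds (2b) a few
*mode-jumping independence proposals*: a uniformly drawn candidate
location together with $(\mathbf{x}, \mu)$ drawn around that location's
moment anchors - per-location least-squares fits of the haplotype effects,
using $a_j \approx c + \mu\pi_j$ - accepted with the full
Metropolis-Hastings ratio including the reverse/forward proposal
densities; and (2c) a Gibbs draw of $l$ from its exact full conditional
(uniform prior times likelihood over all candidates, $O(nL)$). Chains also
start at the dominant anchor rather than from a diffuse state. The grid
detailed-balance test verifies that the composed kernel still targets the
joint posterior.

The paper-level description leaves all hyperparameters, proposal variances
and chain lengths open; the package defaults are chosen to be weakly
informative for phenotypes standardized to unit variance:
$\sigma^2_\mu = 1$, $\nu_e = 4$, $S^2_e = 0.5$, $\sigma^2_x = 4$. The
logit-scale prior variance matters more than it looks: with
$\sigma^2_x = 1$ the prior confines each $\pi_j$ to roughly (0.12, 0.88),
so the model cannot express the near-complete-LD regime that dense
markers produce (and in which the method provably reduces to least
squares); a standard-deviation of 2 on the logit scale reaches
$\pi \approx 0.02$-$0.98$ while remaining proper. Proposal
variances start at $(0.25, 0.01, 0.01)$ and are tuned during burn-in
toward acceptance rates of 0.2-0.5, then frozen so the sampling phase uses
fixed symmetric proposals (the fixed-proposal acceptance ratios stay
exact). Default chain geometry is 20 000 sweeps, 5 000 burn-in, thinning 5;
the evaluation harness uses short 6 000-sweep chains. When a location move
is proposed, the $\pi$ vector (of fixed length $2^k$) is re-interpreted
with respect to the haplotypes at the proposed location; the source model
is silent on this coupling and this is the simplest choice that keeps the
parameter dimension constant.

## Detection statistic

Power is calibrated like a frequentist test: simulate many datasets with
no QTL, take the empirical upper 10% quantile of a detection statistic as
the critical value, and report the fraction of QTL datasets whose
statistic exceeds it. For the regression scan the statistic is the F value
at the best position. For the BGF scan the chain records two per-sample
functionals:

* `vq` $= 2\bar p(1-\bar p)\mu^2$ with $\bar p = \sum_j f_j \pi_j$ (sample
  haplotype frequencies $f_j$ at the current location): the marginal
  additive variance of the QTL;
* `vexp` $= \mu^2 \,\mathrm{Var}_i\!\left(E(Q_i|M)\right)$: the variance
  of the marker-predicted QTL term across individuals.

The detection statistic is the posterior mean of `vexp`. The marginal
functional `vq` is unusable for detection: under the null the posterior of
$\boldsymbol\pi$ stays diffuse, $E(Q|M)$ is nearly constant, $\mu$ is then
confounded with the intercept and simply follows its prior, so $\mu^2$ -
and with it `vq` - is large no matter what the data say; its null
distribution drowns the signal and calibrated power collapses, most
severely for the 2-SNP model where $\pi$ has four diffuse elements.
`vexp` vanishes in exactly that situation, because a flat $\pi$ vector
predicts nothing. Both functionals are retained in the chain output.

## The LD simulator

The simulator emulates a livestock-like history: 2000 biallelic loci
spaced 0.01, 0.005 or 0.002 cM apart; every tenth locus is a QTL; founder
alleles are independent Bernoulli(0.5) draws (Hardy-Weinberg and linkage
equilibrium); then 1000 generations of random mating at census size 500
followed by 50 generations at size 100, with a per-locus, per-gamete
mutation (allele flip) rate of 2.5e-5. This approaches mutation-drift
equilibrium and builds the LD the methods exploit. Meioses place
crossovers as a Poisson process along the genetic map (no interference) -
at these distances indistinguishable from any map function - and parents
are drawn uniformly with replacement (selfing allowed, discrete
generations).

In the final generation each 10-locus bin contributes the segregating
marker with allele frequency closest to 0.5 (ties to the lowest index),
and the QTL locus with frequency closest to 0.5 is the mapped target. The
analysis window is 11/21/51 consecutive selected markers (marker spacing
0.1/0.05/0.02 cM) placed so the QTL sits 0.3 cM right of the first window
marker; the number of adjacent brackets is then 10/20/50. Window markers
are reported on the idealized evenly spaced grid (marker $j$ at
$j \times$ spacing; QTL at exactly 0.3 cM), matching how the marker panel
is described even though each selected marker sits somewhere inside its
bin; all location errors are measured on that grid.

Study individuals are drawn by one additional meiosis per gamete from the
final population - equivalent to one more random-mating generation of the
requested size - because the requested sample sizes (200, 500) exceed the
final census of 100. Phenotypes are $y_i = g_i\mu + e_i$ with
$\mu = \sqrt{f/(2p(1-p))}$ ($p$ the pool QTL frequency) and
$e_i \sim N(0, 1-f)$, so the QTL explains fraction $f$ of a unit
phenotypic variance. Monomorphic chosen QTL, monomorphic window bins, or a
window that would overrun the segment trigger resimulation of the whole
history with a new derived seed.

What the generator does *not* emulate: selection, population structure and
admixture, variable recombination/mutation rates, genotyping error, and
unphased data (true phase is used throughout, as in the evaluation it
reproduces). Passing tests therefore demonstrate correctness of the
machinery under this idealized history, not performance on real livestock
data.

## Worked example

```{r example}
library(bgfmap)

sim <- simulateStudy(spacingCM = 0.01, n = 500,
                     qtlVarianceFraction = 0.05, seed = 42)
lsr <- lsrScan(sim$study, k = 1)
chain <- runBgfChain(sim$study, k = 1,
                     chain = chainConfig(20000, 5000, 5, seed = 1))
bgf <- summarizeChain(chain)
estimatedPositionCM(lsr)
estimatedPositionCM(bgf)   # truth is 0.3 cM
```

A full power/precision cell is one call:

```{r experiment}
runExperiment(methods = c("BGF1", "LSR1"), qtlVarianceFraction = 0.05,
              markerSpacingCM = 0.1, n = 200, nNullReps = 150,
              nPowerReps = 150, seed = 7)
```

## Numerical and design notes

* Critical values use the inverse-empirical-CDF convention: the
  $\lceil 0.9R\rceil$-th order statistic of $R$ null statistics.
* The regression scan calls p-values below 1e-15 "numerically zero"; among
  zero-p positions the middle one is chosen (the lower of the two middles
  for an even count). Monomorphic positions are skipped; haplotypes
  unobserved in the sample are dropped from the design with the numerator
  degrees of freedom adjusted.
* The BGF location estimate is the posterior mode of $l$ (ties to the
  lower index). The sign of $\mu$ is not identifiable jointly with
  $\pi \to 1-\pi$, so summaries report $|\mu|$ alongside $\mu$.
* All randomness flows from user-supplied seeds; per-replicate seeds are
  spawned from the master seed and recorded in experiment results, and the
  compiled simulation and chain loops draw from R's RNG, so runs are
  exactly reproducible.
* The statistical test suite runs the full protocol at reduced replicate
  counts (e.g. 200 null + 200 QTL replicates for one published table cell,
  with 6 000-sweep chains; 20 recovery replicates at $n = 1000$), chosen
  as the smallest sizes at which the published values still pin the
  results to useful precision.

## Limitations

* Only unrelated individuals: the cosegregation (pedigree) component of
  the gene-frequency framework - gametic covariance recursions and
  relationship matrices - is out of scope here.
* Biallelic QTL only, and $k \le 2$ markers per haplotype.
* True phase is assumed known for the 2-SNP models; unphased input is
  rejected rather than phased.
* The marginal QTL-variance functional is computed with *sample* haplotype
  frequencies at the current location; population frequencies are not
  identified by the model.
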