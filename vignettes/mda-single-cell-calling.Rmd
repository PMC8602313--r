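---
title: "Calling SNVs in MDA-amplified single cells with a bulk background sample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling SNVs in MDA-amplified single cells with a bulk background sample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdavar)
```

## The problem

Single-cell DNA sequencing libraries require whole-genome amplification, and
multiple displacement amplification (MDA) is the least error-prone protocol
in routine use. MDA still distorts the data in two ways that break
bulk-trained variant callers:

* **amplification bias** — the two alleles of a diploid cell are amplified
  unevenly, so the observed alternative-read fraction at a site can sit
  anywhere between 0 and 1 even at a true heterozygous site, up to the
  complete **allele dropout** of one allele;
* **amplification errors** — the polymerase introduces copy errors early
  enough that they can be amplified to large read fractions,
  indistinguishable, per site, from real variants.

`mdavar` models both effects jointly with an **unamplified bulk sample** of
the same cell population. The bulk is an unbiased sample of which alleles
exist in the population and at what frequency: an allele absent from a deep
bulk is most likely an amplification error in the cell, and a bulk
frequency near 1/2 rescues a cell site whose reads lost one allele.

## The model

### Amplification bias

Let $\theta_s \in \{0, \tfrac12, 1\}$ be the true alternative allele
frequency in the diploid cell and $\rho_s = k/l$ the observed
alternative-read fraction at a site covered by $l$ reads. The distortion
$P(\rho_s \mid \theta_s)$ is modelled with beta-binomial read-count
distributions whose shapes scale linearly with coverage:

$$
\begin{aligned}
P(\rho_s = k/l \mid \theta_s = 0) &= BB(k, l;\, \alpha(l), \beta(l)) \\
P(\rho_s = k/l \mid \theta_s = \tfrac12) &= w(l)\, BB(k, l;\, \alpha_1(l), \alpha_1(l)) + (1 - w(l))\, BB(k, l;\, \alpha_2(l), \alpha_2(l)) \\
P(\rho_s = k/l \mid \theta_s = 1) &= BB(k, l;\, \beta(l), \alpha(l))
\end{aligned}
$$

The homozygous cases are mirror images (shape swap); the heterozygous case
is a symmetric two-component mixture that peaks at $k = 0$ and $k = l$ —
allele dropout is the *likely* outcome of MDA at moderate coverage, not a
rare corruption. The slope/intercept coefficients are empirical, derived
from read-count distributions observed at known homozygous and heterozygous
sites in MDA-amplified single cells; they are fixed constants of the
package (see `bias_params()`), not refit per dataset. Because the linear
extrapolation leaves the legal range at extreme coverage ($\alpha(l)$ turns
negative beyond $l \approx 2285$, $w(l)$ exceeds 1 beyond $l \approx 836$),
shapes are floored at $10^{-6}$ and $w$ is clipped to $[0, 1]$.

```{r}
plot_bias_model(20)
```

### Read and sample likelihoods

Each read overlapping a site is classified as REF, ALT, or OTHER (any other
base, deletion, or reference skip); the model is strictly biallelic, so
OTHER reads are excluded from all counts. A read's miscall probability
$e = 10^{-Q/10}$ comes from its PHRED base quality, floored at $Q \ge 3$
and capped at $e \le 0.75$. The per-read likelihood is

$$P(Z_i = \text{ALT} \mid \rho) = \rho (1 - e_i) + (1 - \rho)\, e_i / 3,$$

and symmetrically for REF — a deliberately simple biallelic base-quality
model that ignores mapping quality, read-pair evidence and alignment
artifacts. The single-cell sample likelihood marginalizes the read product
over the distorted-frequency grid,

$$P(Z^s \mid \theta_s) = \sum_{k=0}^{l} P(Z^s \mid \rho_s = k/l)\,
  P(\rho_s = k/l \mid \theta_s),$$

which costs $O(l)$ per frequency with per-class read counting. The bulk has
no amplification step, so its observed frequency is the true one and
$P(Z^b \mid \theta_b = m/n)$ is a plain read product over the grid
$m \in \{0, \ldots, n\}$. For bulks deeper than 1000 reads the grid is
downsampled to 1001 equally spaced frequencies to keep the sums linear.

### The seven single-cell events

The joint space $\{0, \tfrac12, 1\}_{\theta_s} \times [0, 1]_{\theta_b}$ is
partitioned into seven mutually exclusive events (`event_regions()`),
assuming the bulk population mixes at most two genotype subpopulations one
mutated allele apart. Where the bulk contradicts the cell — e.g.
$\theta_s = 0$ but $\theta_b \ge \tfrac12$ — the bulk is trusted and the
event is read as allele dropout (or an amplified copy error) in the cell.
Under a flat prior over the $(\theta_s, m/n)$ cells of each region, an
event's likelihood is

$$P(Z^s, Z^b \mid E) = \Big[\sum_{\theta_s \in E} P(Z^s \mid \theta_s)\Big]
  \times \sum_{m/n \in E} P(Z^b \mid \theta_b = m/n),$$

and posteriors are the normalized event likelihoods. Interval endpoints are
applied *strictly* to the grid points ($(\tfrac12$ means $m/n > \tfrac12$,
$[\tfrac12$ means $m/n \ge \tfrac12$), which is what keeps the seven
regions an exact partition of every grid — the test suite verifies this for
every $n \le 50$. Genotype calls take the maximum-posterior genotype
compound (hom_ref $\leftarrow$ {hom_ref, err_alt}; het $\leftarrow$ {het,
ado_to_ref, ado_to_alt}; hom_alt $\leftarrow$ {hom_alt, err_ref}), with
exact ties resolved in that fixed order. The alt-presence compound sums the
five events implying the alternative allele exists in the cell.

### Imputation and degenerate inputs

With zero single-cell coverage the empty read product makes every
$P(Z^s \mid \theta_s) = 1$, so under `impute = TRUE` the posterior is
driven by the bulk alone and the genotype call converges to the bulk
majority genotype. Note the *posterior mass* of that genotype saturates
near 0.76 rather than 1 even for a perfectly clean deep bulk: under the
flat prior per grid point, the grid points adjacent to the majority
frequency keep roughly a quarter of the mass on the neighbouring
(het-implying) events. The argmax is what imputation uses, and it is
correct in over 99% of unambiguous simulated sites.

Sites with zero bulk coverage are uncallable and reported as `NA` by
default. The `missing_bulk = "flat"` mode instead sets every bulk factor to
1; each $\theta_s$ then contributes once to each genotype compound, so all
three genotype posteriors collapse to exactly 1/3 — the model carries no
genotype information without a bulk, and this degenerate mode makes that
explicit (it serves as the zero-bulk baseline in the bulk-benefit
analysis).

A related grid-granularity effect: deepening the bulk adds grid points to
every interval, which under the flat per-grid-point prior slightly
increases the likelihood leak into adjacent events (the leak converges as
$n$ grows; between 10× and 30× bulk it moves the mean true-genotype
posterior by about 0.005 on simulated data). The statistical benefit of
depth dominates at low coverage — going from no bulk to 4× already lifts
the mean true-genotype posterior from 1/3 to about 0.9 in the packaged
simulations.

### FDR control

Posterior probabilities of any compound event support Bayesian expected-FDR
control (`control_fdr()`): sort sites by descending posterior and select
the longest prefix whose mean $(1 - p_i)$ does not exceed the nominal
level. Prefix means are non-decreasing in that order, so the rule yields
the maximal selection; ties at the threshold posterior are admitted
all-or-none so that one posterior value maps to one decision. Selections
are computed on linear-scale probabilities reconstructed from the
PHRED-scaled VCF fields, whose round trip is accurate to well below
$10^{-4}$ (PHRED values are capped at 10000), so writing and re-reading
calls cannot change a selection.

### Allele-dropout estimators

Three per-cell ADO rates over ground-truth heterozygous sites with
single-cell coverage $\ge 1$ (`ado_report()`): the **expected** rate (mean
posterior of the two dropout events), the **mismatch** rate (fraction
called homozygous), and the **naive** rate (coverage $\ge 7$ with one
allele entirely unobserved). On model-matched simulations the expected rate
tracks the realized dropout fraction within Monte-Carlo error. The mismatch
rate, however, is structurally about half the expected rate there: at a
dropout site the bulk splits its mass roughly symmetrically around
$\theta_b = \tfrac12$, and only the draws favouring $[0, \tfrac12)$ produce
a (false) homozygous call — the remainder are rescued into the het-implying
dropout events, which is precisely the benefit of the joint model. The
naive rate undercounts at low coverage by construction.

## The simulator

`simulate_dataset()` generates model-matched data for calibration: per
site, a germline genotype from the configured proportions (defaults 90%
hom_ref, 5% het, 5% hom_alt — a candidate-site mix with 10% true
alternative alleles); single-cell ALT counts drawn directly from the
compounded amplification-bias distributions above (so the simulation
matches the likelihood model exactly, making calibration tests sharp; a
separate Pólya-urn draw, `rpolya_urn()`, exists for mechanism checks);
bulk ALT templates Binomial($n, \theta_b$) with per-read miscalls uniform
over the three other bases. Defaults are 20× cell coverage, 30× bulk, Q30
— a realistic MDA-exome working point. Optional subclonal somatic sites
place a het subclone at frequency `subclone_fraction` in the bulk.

What the simulator does **not** emulate — and what passing calibration
tests therefore cannot certify on real data: site-to-site variation in
amplification-bias beyond the coverage dependence (the empirical
coefficients are fixed, and real datasets deviate from them in both
directions); mapping errors, strand or position artifacts; doublets;
indels; base-quality heterogeneity along reads (simulated reads share one
quality); and somatic-mutation priors for the bulk. Coverage can be fixed
or Poisson, but real MDA coverage is far more overdispersed.

## Numerical choices

All likelihoods are computed in log space (`lchoose`/`lbeta`, log-sum-exp
normalization) and stay finite at coverages of $10^4$. Grid endpoints 0,
1/2 and 1 are exactly representable in floating point and grid membership
uses exact comparisons. Per-coverage distortion grids and per-$n$ interval
memberships are cached; sites whose per-sample base qualities are
homogeneous share posteriors through a count-signature memo, which is what
makes calling tens of thousands of simulated sites take seconds. Test and
calibration problem sizes (10,000 sites for calibration and FDR studies,
2,000 for the bulk-coverage sweep, 3,000 for imputation) were chosen to
keep Monte-Carlo standard errors a few times smaller than the effects being
checked.

## Known limitations

* The bias coefficients are fixed, not refit per cell or dataset; datasets
  whose amplification variability differs will shift all posterior-derived
  rates (refitting at germline het sites would be the natural extension).
* The per-read model ignores mapping quality and alignment artifacts;
  candidate sites in repetitive regions should be pre-filtered.
* The bulk model has no somatic prior: a subclonal variant absent from the
  bulk reads cannot be called (deeper bulk sequencing is the remedy).
* Each cell is called independently against the bulk; no information is
  shared across cells.
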