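# mdavar

Calling and genotyping single nucleotide variants (SNVs) in **diploid
single cells whose DNA was amplified by multiple displacement amplification
(MDA)**, jointly with an **unamplified bulk sample** of the same cell
population.

MDA makes single-cell genotyping hard in two specific ways: the two alleles
of a site are amplified unevenly (up to the complete **allele dropout** of
one of them), and polymerase copy errors can be amplified to read fractions
that look like real variants. `mdavar` addresses both with a probabilistic
model instead of heuristic filters, and reports calibrated posterior
probabilities that support genotyping, imputation, allele-dropout
estimation and exact Bayesian false-discovery-rate control.

## The model in brief

* The observed alternative-read fraction $\rho_s = k/l$ in the cell is a
  distorted measurement of the true allele frequency
  $\theta_s \in \{0, \tfrac12, 1\}$. The distortion
  $P(\rho_s \mid \theta_s)$ is modelled with coverage-dependent
  beta-binomials: $BB(k, l; \alpha(l), \beta(l))$ at homozygous sites
  (shape-swapped for $\theta_s = 1$) and a symmetric mixture
  $w(l)\,BB(k,l;\alpha_1,\alpha_1) + (1-w(l))\,BB(k,l;\alpha_2,\alpha_2)$
  at heterozygous sites, which peaks at $k = 0$ and $k = l$ — dropout is
  the likely outcome, not a rare one.
* The bulk needs no amplification, so its read data directly measures the
  population allele frequency $\theta_b$ on the grid $m/n$.
* The joint space $\{0,\tfrac12,1\}_{\theta_s} \times [0,1]_{\theta_b}$ is
  partitioned into **seven mutually exclusive single-cell events** (hom
  ref, err alt, ADO to alt, het, ADO to ref, err ref, hom alt); posteriors
  are computed per site under a flat prior, in log space. Compound events
  (e.g. *alt presence*, or a genotype) are sums of member posteriors.
* A nominal expected FDR $\alpha$ is controlled by selecting the longest
  posterior-sorted prefix $S$ with $\frac{1}{|S|}\sum_{i \in S}(1-p_i)
  \le \alpha$.

See the vignette (`vignettes/mda-single-cell-calling.Rmd`) for the full
account, including imputation of zero-coverage sites from the bulk and the
three allele-dropout-rate estimators.

## Worked example

Simulate a model-matched dataset (20× cell coverage, 30× bulk, Q30), call
it, and control the FDR of alt-presence calls:

```r
library(mdavar)

sim   <- simulate_dataset(n_sites = 2000, sc_coverage = 20,
                          bulk_coverage = 30, seed = 42)
calls <- call_sites(sim$pileups)
calls |>
  dplyr::select(chrom, pos, l, k, n, m_obs, p_het, p_ado_to_ref,
                genotype, p_alt_presence)
#> # A tibble: 2,000 × 10
#>   chrom   pos     l     k     n m_obs  p_het p_ado_to_ref genotype p_alt_presence
#>   <chr> <int> <int> <int> <int> <int>  <dbl>        <dbl> <chr>             <dbl>
#> 1 sim1      1    20    10    30    30 0.316      1.95e- 2 hom_alt           1.00
#> 2 sim1      2    20    20    30    30 0.0338     5.35e- 5 hom_alt           1.00
#> 3 sim1      3    20     0    30     0 0.0338     6.27e-10 hom_ref           0.0338
#> 4 sim1      4    20     0    30     0 0.0338     6.27e-10 hom_ref           0.0338
#> # i 1,996 more rows

mean(calls$genotype == sim$truth$genotype, na.rm = TRUE)
#> [1] 0.9945
```

Row 1 is a homozygous-alternative site whose cell reads came back 50/50 —
the deep all-ALT bulk resolves it; rows 3–4 are ordinary homozygous
reference sites. `p_ado_to_ref` is the posterior that the cell is truly
heterozygous but amplification lost the alternative allele.

```r
sel <- control_fdr(calls, fdr = 0.05)   # alt-presence compound by default
sel
#> Bayesian FDR selection
#>   nominal expected FDR: 0.05
#>   compound event: ado_to_ref + err_ref + het + ado_to_alt + hom_alt
#>   selected: 225 of 2000 sites
#>   posterior threshold: 0.3504773
#>   achieved expected FDR: 0.03730378

het <- sim$truth[sim$truth$genotype == "het", ]
ado_report(calls, truth_het = het)
#> # A tibble: 1 × 4
#>   expected_rate mismatch_rate naive_rate n_sites_covered
#>           <dbl>         <dbl>      <dbl>           <int>
#> 1         0.142        0.0421      0.105              95
```

The expected ADO rate (mean posterior of the two dropout events at
truth-het sites) tracks the simulation's realized dropout fraction; the
mismatch reading is lower because the joint model rescues most dropout
sites into a heterozygous call via the bulk — see the vignette.

Calls round-trip through VCF with PHRED-scaled event probabilities
(`write_calls()` / `read_calls()`), pileups can be extracted from indexed
BAMs at candidate sites (`extract_pileup()`) or read from plain TSVs, and
`exec/mdavar` exposes the same pipeline as a command line tool:

```sh
mdavar call cell.bam bulk.bam --candidates sites.vcf --output calls.vcf
mdavar call --pileup-tsv pileup.tsv --output calls.vcf --imputation
mdavar control-fdr calls.vcf --fdr 0.05 --output confident.vcf
mdavar estimate-ado calls.vcf --truth-het het_sites.tsv --output ado.tsv
mdavar simulate --n-sites 1000 --seed 1 --out sim
```

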