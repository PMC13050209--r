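# lohsym

Reference-symmetric genotyping and loss-of-heterozygosity (LOH) inference
for mutation accumulation experiments in heterozygous diploid hybrids.

## Who this is for

Groups running (or re-analyzing) mutation accumulation experiments in
heterozygous hybrids — chiefly *Saccharomyces cerevisiae* crosses — who
need LOH event rates, conversion rates, length distributions and homolog
biases that are not contaminated by reference-mapping bias. Genotyping
against a single reference genome preferentially recovers reads carrying
the reference allele; the resulting false homozygous calls masquerade as
LOH events that convert toward the reference homolog and cluster in
high-conversion, high-bias (HCHB) genomic windows.

## What it does

* **Dual-reference reconciliation.** Each clone is genotyped against both
  parental references; per-site calls are reconciled by a rule symmetric
  under swapping the references: agreement wins; disagreement is resolved
  only when one genotype quality exceeds the other by ≥ 30 (GQ being the
  log10 likelihood ratio of the top two genotypes); both-low-quality and
  narrowly contested sites are discarded.
* **Founder-error model.** With founder and descendants sequenced, the
  posterior odds that a founder call is erroneous are, for a site with
  descendant configuration (K0 homozygous-ancestral, K1 heterozygous, K2
  homozygous-derived):

  `R_false_hom = [ε_HOM/(1−ε_HET)]·[(1−f)/f]·(p10/p00)^K0 (p11/p01)^K1 (p12/p02)^K2`

  and symmetrically for false heterozygotes, giving per-site labels and
  genome-wide Homo-/Hetero-FDR estimates.
* **Allele-balance filter.** Heterozygous calls whose minor-allele support
  falls outside the central 95% interval of a fitted symmetric
  beta-binomial (variance `n/4 + ρn(n−1)`, `ρ = 1/(8β+4)`) become missing.
* **Event detection.** LOH tracts down to single-marker support, midpoint
  boundaries, terminal extension to chromosome ends, <10-kb transitive
  merging, homolog assignment by greatest converted length, interstitial /
  terminal classification, breakpoint placement.
* **Undercount corrections and rates.** Detection probability
  `1−(1−l/L)^n`, log-length binned inter-marker correction, P0-method
  terminal rates `λ = −ln(p0)/T`, closed-form overlap probabilities, local
  per-window rates, and exact-binomial HCHB window scans with
  Benjamini–Hochberg control.
* **Variance partitioning.** Nested GLMMs for per-arm counts with the rate
  model `λ_ha = μ + α_h L_a + β_a + γ_ha` (Poisson for interstitial counts,
  Bernoulli for terminal indicators, stitched identity/log and
  −log(1−y)/log links), fitted by an arm-factorized Laplace approximation,
  with likelihood-ratio model selection and exact telescoping variance
  fractions (segregating trans / fixed cis / segregating cis / noise).
* **Simulator.** A synthetic MA experiment generator with full truth
  bookkeeping (markers, events, injected errors, beta-binomial reads, and
  optional one-sided reference bias), so the whole pipeline is testable
  without external data.

## Worked example

Simulate a small two-chromosome experiment (2 families × 6 clones, 5,000
markers, 800 generations), reconcile the two call sets, and detect events:

```r
library(lohsym)

cfg <- sim_config(meta = genome_meta(c(chr1 = 900000L, chr2 = 700000L),
                                     c(chr1 = 350000L, chr2 = 250000L)),
                  n_markers = 5000L, n_families = 2L, clones_per_family = 6L,
                  eps_hom = 1e-4, seed = 42)
sim <- simulate_experiment(cfg)
rec <- reconcile_calls(sim$calls_ref1, sim$calls_ref2)
clones <- rec$calls[!grepl("founder", rec$calls$sample)]
ev <- detect_events(clones, sim$markers, sim$meta)

nrow(ev)                 # 22 detected events (22 true events simulated)
table(ev$type)           # interstitial 21, terminal 1
homolog_bias(ev)
#>           group  n_p1  n_p2   frac_p1   p_value
#> 1:          all     8    14 0.3636364 0.2862787
#> 2: interstitial     7    14 0.3333333 0.1892471
#> 3:     terminal     1     0 1.0000000 1.0000000

il <- ev[ev$type == "interstitial"]
corr <- correct_intermarker(il$end - il$start + 1, nrow(sim$markers),
                            sum(sim$meta$chrom_lengths))
round(corr$corrected_total, 1)   # 30.8 events after inter-marker correction
```

The homolog-bias table reports the parent-1 fraction with a two-sided
exact binomial p-value against 0.5 — no significant bias here, as expected
from an unbiased simulation. The inter-marker correction raises the 21
detected interstitial events to an estimated 30.8 occurred events, because
events shorter than the ~320-bp marker spacing are often invisible.

The same steps run from the command line:

```sh
Rscript -e 'lohsym::loh_main()' simulate out_dir
Rscript -e 'lohsym::loh_main()' reconcile out_dir
Rscript -e 'lohsym::loh_main()' detect out_dir
Rscript -e 'lohsym::loh_main()' rates out_dir
Rscript -e 'lohsym::loh_main()' hchb out_dir
```

## Further reading

The methods vignette (`vignettes/loh-inference.Rmd`) documents the model
assumptions, the tunable parameters with units and defaults, the numerical
conventions (interval endpoints, link stitching, tie-breaks), what the
simulator does and does not emulate, and known limitations — including two
acceptance assertions that are deliberately left red with analysis rather
than adjusted to pass.
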