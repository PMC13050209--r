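---
title: "Reference-symmetric LOH inference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-symmetric LOH inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohsym)
```

## The problem

Mutation accumulation (MA) experiments in heterozygous diploid hybrids are
the standard instrument for measuring rates of loss-of-heterozygosity (LOH):
lines descended from a heterozygous founder are bottlenecked for hundreds of
generations, end-point clones are short-read sequenced, and runs of markers
that have become homozygous reveal LOH events. Everything downstream —
event rates, conversion rates, genomic distributions, homolog biases —
rests on the accuracy of diploid genotype calls. Mapping reads to a single
reference genome biases calls toward the reference allele, which fabricates
homolog-biased LOH events concentrated in localized windows, and marker-count
thresholds used to suppress those artifacts silently discard true short
events.

`lohsym` implements a reference-symmetric alternative: genotype each clone
against *both* parental references, reconcile the two call sets by a rule
that is symmetric under swapping the references, remove statistically
implausible heterozygous calls, detect events down to single-marker support,
and correct the resulting counts for the events that remain undetectable.

## Dual-reference reconciliation

Calls are first re-expressed in parental-allele space (homozygous-parent-1 /
heterozygous / homozygous-parent-2), so that agreement is defined on homolog
states rather than REF/ALT encodings. At each marker, with genotype
qualities GQ (log10 likelihood ratio between the top two genotypes):

1. both calls GQ < 50, or either call missing → site discarded;
2. calls agree → that genotype;
3. calls disagree, |ΔGQ| ≥ 30 → the higher-GQ call;
4. calls disagree, |ΔGQ| < 30 → site discarded.

The rule treats the two references identically, so the output is invariant
under swapping them (a property test in the suite). A tie at |ΔGQ| exactly
30 counts as "≥ 30": the higher-GQ call wins.

Ancestral markers are the symmetric difference of the two parental variant
sets (sites where both parents differ from the common reference cannot be
heterozygous in the hybrid), thinned to the final set by requiring a
heterozygous founder call plus ≥ 3 heterozygous descendants (≥ 4 descendants
when no founder was sequenced).

## The founder-error model

With founder and descendants sequenced, a genotyping error in the founder
shows up as unanimous disagreement of its descendants. The model scores a
founder call with posterior odds ratios built from five per-experiment
probabilities: the flip-mutation probability `mu` (default 4.45e-8 — one
third of the diploid point-mutation rate over 800 generations), the LOH
conversion probability `lam` (default 0.128 = 1.6e-4 bp⁻¹gen⁻¹ × 800,
deliberately conservative), the founder homozygosity probability `f`
(derivable from the observed homozygous fraction), and the two call-error
probabilities `eps_hom` and `eps_het`.

The descendant transition probabilities `p_ij` are built from a two-stage
model stated here explicitly because it is the one genuinely open modelling
choice in the package: (1) over the experiment a heterozygous site converts
to either homozygous state with probability `(lam + mu)/2` each; a
homozygous site flips to heterozygous with probability `mu`; double events
are neglected; (2) a true heterozygote is miscalled homozygous on *each*
side with probability `eps_hom` (total `2 eps_hom`, the reading forced by
the `1 − 2 eps_hom` prefactor of the false-heterozygote odds ratio), and a
true homozygote is miscalled heterozygous with probability `eps_het` and
never as the opposite homozygote.

Under this reading, the operational unanimity rule (≥ 6 genotyped
descendants, all disagreeing with the founder) agrees with the sign of the
log odds ratio over essentially the whole error-rate grid
`[1e-4, 0.1]²`, with one documented exception: at the corner
`eps_hom = 0.1`, `eps_het ≲ 5.6e-4` in the single-reference regime
(`f_obs = 0.115`), six unanimous homozygous descendants are no longer
decisive against a truly heterozygous founder (each descendant is called
homozygous-ancestral with probability ≈ 0.15 even without any founder
error). The acceptance test asserts the grid claim as stated and is left
red at those seven points rather than adjusting the model to pass.

## The heterozygote allele-balance filter

At a true heterozygote the reads supporting one allele should be roughly
binomial(n, 1/2), but library preparation and mapping add extra variance.
The package models the second-parent allele count as symmetric
beta-binomial, fitting the excess-variance coefficient `rho` by weighted
least squares of `var(k | n) = n/4 + rho·n(n−1)` over integer depth bins
with ≥ 100 calls (`beta = (1/rho − 4)/8`). Heterozygous calls outside the
central 95% beta-binomial interval at their depth become missing — they are
*not* reassigned homozygous, because the allele-frequency evidence
contradicting the caller's other evidence means no genotype is reliable.

Two numerical conventions matter:

* **Weighting.** The least-squares fit is weighted by bin call counts;
  unweighted fitting lets sparse high-depth bins dominate.
* **Interval endpoints.** The interval is inclusive equal-tail with at most
  2.5% probability in each *discrete* tail. Discreteness makes the realized
  tail mass smaller than the nominal one: over depths 10–80 at `beta = 59`
  the expected removal under the null is ≈ 3.6%, not 5% (the tail masses
  range from 1.6% to 4.9% depending on depth). The acceptance criterion
  asserting 5% ± 1% removal is therefore structurally unattainable under
  this convention and is left red; the observed ~3.5% removal on the kind of
  real data the method targets is consistent with the convention chosen.

## Event detection

LOH tracts are maximal runs of adjacent markers homozygous for the same
homolog; single-marker tracts count. Missing calls are transparent — they do
not break a run — because requiring contiguity across dropped calls would
reintroduce the bias against short events. Internal boundaries are midpoints
(floored to integer bp) between the outermost converted marker and the
adjacent unconverted one; a tract containing the marker closest to a
chromosome end extends to that end. Tracts whose facing boundaries are
separated by less than 10 kb merge transitively into one event (complex
repair can interleave homolog states); the event's homolog is the one with
the greatest total converted length, ties resolving to parent 1 with a
warning (ties have measure zero on real data). An event is terminal when a
boundary is a chromosome end; at most one terminal event per arm per clone
is observable by construction.

Breakpoints are midpoints, except terminal events longer than 20 kb, whose
break is placed 10 kb inside the event from its centromere-proximal
boundary. Whole-chromosome events fall back to the midpoint and are flagged
rather than silently counted.

## Undercount corrections and rates

* **Inter-marker events.** With `n` markers uniform on length `L`, an event
  of length `l` is detected with probability `1 − (1 − l/L)^n`. Detected
  interstitial events are binned by log10 length (bin width 0.25 — not
  stated by the source analysis; a sensitivity check is part of the test
  suite via the corrected-total recovery test), each bin's count divided by
  the detection probability at the bin's *arithmetic* mean detected length
  (geometric mean is a defensible alternative; arithmetic was chosen and
  documented), with interior empty bins pseudocounted at 1. Terminal events
  are all longer than the telomeric mask and are never between markers, so
  they receive no such correction — the source text's sentence to the
  contrary contradicts its own justification and is read as a negation typo.
* **Multiple terminal events per arm** are invisible, so terminal rates use
  the P0 method: `p0 = (Σ(1−C) + 1)/(n + 1)` (pseudocount keeps the log
  finite), `λ = −ln(p0)/T`.
* **Overlaps.** Interstitial–interstitial overlaps are negligible
  (`1 − (1 − 2l/L)^(k(k−1)/2)` ≈ 0.46% at the observed scale) and ignored;
  interstitial–terminal overlaps (≈ 13%) are handled by shrinking the
  interstitial denominator by the mean terminally-converted genome
  fraction.

## The variance model

Per-arm event counts are modelled with nested GLMMs on the per-generation
rate `λ_ha = μ + α_h L_a + β_a + γ_ha`: hybrid-specific genome-wide terms
(segregating trans factors), arm effects shared by hybrids (fixed cis,
SD `σ_fc`), and hybrid×arm effects (segregating cis, SD `σ_sc`).
Interstitial counts are Poisson with mean `f(λT)`; terminal indicators are
Bernoulli with `p = f(λT)`. Because the linear predictor can go negative,
the identity and `−log(1−y)` links are stitched to logarithmic branches
below thresholds δ = 0.01 and 0.03 respectively; both stitches are C¹ and
the inverses are positive everywhere. The fraction of predictors below δ is
reported as a diagnostic.

Arm lengths enter in Mb to condition the optimizer. The marginal likelihood
uses the Laplace approximation; random effects factorize by arm, so the
integral is computed arm-wise (dimension 1 + H) with inner conditional-mode
optimization (analytic gradients, `nlminb`) nested inside the outer ML
optimization over `(μ, α_h, σ_fc, σ_sc)` with `σ ≥ 0` box constraints.
A fitted σ below 1e-8 is treated as exactly zero (the random effect drops
out, and the Laplace log-determinant term vanishes continuously in that
limit via the `log det(I − Σ H)` form). Likelihood-ratio tests default to
the plain χ² reference, matching the unstated convention of the source
analysis; the 50:50 boundary mixture for variance components is available
via `lrt(..., boundary = TRUE)`.

Variance is partitioned by telescoping mean-squared prediction errors:
noise from full-model predictions, cis+noise from fixed-effects-only
predictions, sc+noise from fixed-plus-arm predictions; the four fractions
sum to one exactly by construction.

## What the simulator emulates — and what a green test establishes

`simulate_experiment()` generates the *stated world* of the target
experiment: a 16-chromosome ~12.07-Mb genome, ~37,000 uniformly placed
markers (mean spacing ≈ 326 bp), 16 families × 11 clones × 800 generations,
read depth Poisson around 37× with beta-binomial allele balance
(`beta = 59`), interstitial events with a log-normal length distribution
(median 399 bp — the corrected median of the real data; the distribution
family is this package's choice), terminal events with uniform breakpoints
extended to the arm end, and independent per-site genotyping errors.
`inject_reference_bias()` adds the HCHB phenomenology: at designated sites
one reference's heterozygous calls flip toward that reference's homolog
with degraded GQ.

Real data differ in ways the simulator does not attempt: marker spacing is
clumpy, depth is overdispersed and GC-correlated, genotyping errors are
spatially correlated (structural variation produces recalcitrant marker
clusters), event lengths need not be log-normal, and real GQ values have a
full distribution rather than the clean/degraded dichotomy. A green
pipeline test therefore establishes correctness of the *inference
machinery* under the stated generative model — not calibration against any
particular real data set. Quantities that require the real per-arm count
table (the printed variance-partition percentages, for instance) are
deliberately asserted only qualitatively.

## Degenerate inputs and edge conventions

* Coordinates are 1-based for sites; intervals half-open `[start, end)`
  internally; BED output is 0-based half-open.
* Missing GQ is treated as GQ = 0 and so fails every GQ threshold
  (conservative); a genotype of `./.` and an absent record both count as
  missing calls for reconciliation.
* The site-QUAL ≥ 1000 rule is applied per record as read, since call sets
  arrive per family anyway.
* Chromosomes shorter than one window form a single window; window
  remainders ≤ 25 kb merge into the terminal core windows, larger ones
  stand alone; windows partition each chromosome exactly.
* Empty windows take p = 1 in the bias scan and are never flagged.
* Whole-chromosome homozygous clones yield flagged whole-chromosome events
  rather than being silently counted or dropped.
* Families with no eligible sites report `NA` FDRs, never 0.

## Known limitations

* No homozygous-call analogue of the allele-balance filter: there is no way
  to assemble a high-confidence reference set of homozygous calls among
  family-polymorphic sites.
* The `p_ij` forms are one consistent reading of an under-specified model
  (see above); conclusions at extreme error rates (≥ 10% homozygous-call
  error) depend on that reading.
* The inter-marker correction cannot recover events much shorter than the
  marker spacing; corrected length distributions remain biased against the
  shortest events.
* Fixed trans effects are undetectable by design (they require an
  outgroup), so the "trans" fraction of variance is specifically the
  *segregating* trans fraction.
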