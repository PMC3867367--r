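---
title: "Rare-allele discovery in deeply pooled amplicons: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-allele discovery in deeply pooled amplicons: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillpool)
library(dplyr)
```

## The problem

TILLING-by-sequencing screens a chemically mutagenised plant population
for point mutations in candidate genes by sequencing PCR amplicons from
pooled DNA very deeply, instead of genotyping individuals. In a pool of
hundreds of individuals a single mutant allele appears at a frequency
far below 1%, so everything hinges on two questions:

1. *What frequency should a real mutant allele have?* That is fixed by
   the pooling arithmetic, not by statistics.
2. *What frequency can sequencing noise reach?* That sets the calling
   threshold.

`tillpool` implements both, plus the downstream classification of calls
into wild-type (natural) variation versus putatively EMS-induced
mutations, codon-level effect annotation, and a synthetic-data
generator that reproduces the population and sequencing structure so
the whole chain is testable end to end without any external data.

## The pool frequency model

In an equimolar pool of $n$ individuals contributing $m$ allele copies
each, a variant carried by $c$ copies is expected at frequency

$$f = \frac{c}{n\,m}.$$

The package keeps $c$ and $nm$ as integers and renders percentages by
exact integer round-half-up (`render_percent()`), because the published
values of interest are roundings of exact copy ratios and should never
depend on binary floating point.

The species under study is tetraploid and predominantly selfing, so an
individual is modelled as $m = 4$ copies across two diploid homeologous
subgenomes. An EMS-induced mutation arising in one M1 plant is assumed
homozygous within a single subgenome: each carrier contributes 2
copies. For the 109-individual discovery pool:

```{r}
m109 <- pool_design("M109", 109, is_mutant = TRUE)
expected_allele_frequency(m109, c(2, 6))
```

One carrier gives 2/436 = 0.46%; because up to three M2 siblings of one
family may be pooled, the same mutation can reach 6/436 = 1.38%. That
pair of numbers is the **EMS window** used by the classifier
(`ems_frequency_window()`); for the 754-individual screening pool it is
0.07%–0.20%, which sits *below* the noise threshold — that pool can
confirm common variants but cannot reveal single EMS carriers, and the
package treats that as a property of the design rather than a defect.

## Thresholds

* **Coverage ≥ 400×**, inclusive. Roughly ten times the effective pool
  size of the 109 pools; below this the binomial sampling error on a
  0.5% allele is too large to interpret.
* **Frequency > 0.5%**, strict. At per-base error $e \approx 10^{-3}$
  spread over three alternate bases, the count of any specific wrong
  base at depth $n$ is $\mathrm{Bin}(n, e/3)$; at $n = 10^4$ the
  probability of exceeding $0.005\,n$ is below $10^{-20}$, so the
  threshold sits far above the noise floor while still admitting the
  0.46%-expected single carrier most of the time (its observed
  frequency is over-dispersed upwards by error flow from the other
  9,996 reads). `error_threshold_report()` quantifies this on any
  data set, real or simulated.

Site-level variability is summarised by the Shenkin information
content $S = k\,2^H$ with $H$ the Shannon entropy of the base
frequencies. $S$ runs from $k$ (conserved) to $4k$ (uniform). The
scale constant $k$ defaults to 6, the convention the score was
originally published with; no decision in the pipeline depends on $k$,
it only scales the variability plots. Ambiguous `N` calls are excluded
from both coverage and the entropy — they carry no allele information.

## Classification logic

A distinct SNP is the full key (amplicon, position, ref, alt):
different alternate alleles at one site are different mutations. After
per-pool calling, `compare_pools()` records each SNP's pool membership
(the three-pool Venn diagram), and `classify_ems()` marks a SNP
putatively EMS-induced only if **all** of:

* it is called in no control pool (with an optional strict switch
  requiring presence in exactly one named pool);
* it is the EMS alkylation signature read on the reference strand as
  written: G→A or C→T (the two strand-complementary renderings of the
  same O6-ethylguanine event; transversions never qualify);
* in every mutant pool where it is called, its frequency lies inside
  that pool's predicted window, inclusively at both ends — the ends
  are themselves the idealised 1- and max-sibling carrier frequencies,
  so excluding them would be arbitrary.

Everything else is wild-type variation. The partition is exhaustive
and disjoint by construction, and `build_summary()` refuses to emit a
report whose Venn regions, partition or effect categories fail to sum.

## Effect annotation

Annotation uses the supplied exon intervals, strand and phase, maps an
exonic SNP to its codon through the concatenated coding sequence, and
translates ref and alt codons with the standard genetic code:
synonymous, nonsynonymous, or stop-gained (reported inside the
nonsynonymous total *and* separately, the way such screens publish
their counts). It rests on the premise that both homeologues are
potentially functional and carry the polymorphism, and that no other
frame-disrupting variant lies upstream; that premise is a property of
the whole report, not of individual SNPs. Amplicons are partial gene
sequences, so leading/trailing partial codons are flagged
`not_applicable` rather than guessed; splice-site disruption is not
annotated. Reading-frame bookkeeping is the part most worth
distrusting, so the test suite checks every annotated effect against a
brute-force oracle that rebuilds the whole CDS, substitutes, translates
both proteins and diffs them.

## The synthetic study

`simulate_study()` generates: random amplicons with exon structures;
a base population with segregating wild-type variants (per-site
density `wt_snp_per_bp`, population frequencies uniform on a
configurable range, genotypes drawn nearly homozygous to reflect an
inbred selfing line with residual heterozygosity 5%); EMS mutations
planted per M1 family at G/C sites and shared by the family's pooled
siblings; and per-pool count tables with lognormal per-site depth
non-uniformity and a uniform base-error channel. A `SimTruth` ledger
records every planted variant with its exact expected pool frequency,
which always equals the pool model's copy ratio.

Defaults are the study conditions the generator emulates: four
amplicons of 7800/4800/3400/400 bp (16.4 kb total, sized so the
per-gene SNP loads fall out roughly proportional), pools C109/M109/M754
with 4 copies per individual and up to 3 siblings per family, mean
depths 27118×/32289×/10171×, error rate 0.001, `wt_snp_per_bp = 0.0143`
(calibrated to the base population's segregating diversity) and
`ems_rate = 1.7e-5` per G/C site per family, which yields a handful of
detectable induced mutations in the discovery pool — the regime the
design targets.

What the generator does **not** emulate: PCR amplification bias and
duplicates, equimolar-quantification error, platform-specific error
spectra and strand bias, indels, and mapping artefacts (counts are
placed at known amplicon offsets, so alignment is replaced by
known-truth placement; the upstream read-trimming and base-quality
filters of a real run are represented by the single error-rate
parameter). Passing tests therefore demonstrate the correctness of the
arithmetic and the classification logic under the stated statistical
model, not robustness to those real-data artefacts.

Counts are generated directly rather than as reads: for amplicon
sequencing with known placement, read-level simulation adds nothing
this pipeline consumes.

## Density conventions

Published per-Mb densities from pooled screens are ambiguous about the
denominator: amplicon length alone, or amplicon length × individuals
(× subgenomes) screened. `snp_density()` therefore *requires* a
convention label and the summary reports both conventions side by
side; no bare "per Mb" number is ever emitted.

## Numerical and test-design choices

* Internal coordinates are 0-based half-open everywhere; 1-based
  appears only at the VCF boundary.
* The multinomial count sampler uses successive conditional binomials,
  vectorised over sites, so full-study depth (∼3×10⁴ over 16.4 kb × 3
  pools) simulates in under a second.
* Determinism: each simulation stage seeds its own stream from the
  config seed plus a fixed offset, so staged and composed runs are
  identical and every output is a pure function of the config.
* The round-trip recovery test runs error-free at 10⁴× depth with
  wild-type population frequencies ≥ 0.15. At error zero a non-planted
  site has zero alternate reads, so the called set must equal — not
  approximately, exactly — the planted variants whose realised
  count-level frequency clears the threshold; the high wild-type
  frequencies make absence from a 109-individual control pool
  essentially impossible (P ≈ 0.85^109 ≈ 2×10⁻⁸), isolating the
  mechanics of the classifier from the genuine biological confound
  that rare wild-type variants can be unique to mutant pools by
  sampling. That confound is real in the full-scale regime and is the
  reason the strict `unique_to` switch exists; the default
  classification asks only "no control pool".
* Test problem sizes are chosen to exercise the full pool structure at
  small amplicon totals (1.5–4 kb for most property tests, 10 kb for
  the noise-floor check, 1000 variants for the annotation oracle); the
  full 16.4 kb defaults run in the acceptance script.

## Limitations

Single-nucleotide substitutions only; no genotype likelihoods or joint
calling (the frequency threshold *is* the model); no deconvolution of
which pooled individual carries a variant — in practice that is the
follow-up genotyping step, outside this package's scope.
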