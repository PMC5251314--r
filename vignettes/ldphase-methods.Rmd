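---
title: "Models and methods behind ldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ldphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldphase)
```

`ldphase` characterises diploid SNP panels the way a livestock genomics
study does: quality control, diversity, inbreeding, runs of
homozygosity, genomic relationships, linkage disequilibrium and its
decay, persistence of gametic phase between populations, and LD-based
effective population size. This vignette explains each model, the
choices made where the methods literature leaves room, and what the
package's simulation-based tests do and do not establish.

## The data model

Everything operates on a `genotype_panel`: an animals-by-markers matrix
of counted-allele dosages (0, 1, 2, `NA`), a marker map (chromosome,
1-based bp position, markers sorted within chromosome), and an animal
table with population and herd labels. All distances are physical,
`|bp_i - bp_j| / 1e6` Mbp. The *counted allele* is an explicit part of
the data model because two of the core statistics depend on it: the
dosage `c` enters the inbreeding formulas directly, and the sign of the
composite disequilibrium D flips when one marker of a pair is recoded.
When reading PLINK text files the default policy counts the sample-wide
minor allele, with exact ties broken lexicographically so the coding is
reproducible; `first_listed` is available for callers that need
file-order coding. Cross-population comparisons (phase persistence)
require the same coding in both panels, which holds automatically for
panels subset from one jointly coded read or exported from one
simulation.

## Quality control

Four criteria run in a fixed sequential order: animals with call rate
below 0.90 are removed first, then markers are attributed to the first
criterion they fail among MAF < 0.05, SNP call rate < 0.90, and a
Hardy–Weinberg chi-square p-value below 1e-6. Sequential attribution is
a deliberate choice: the alternatives (simultaneous filters, or other
orders) remove the same markers but make per-criterion counts
ambiguous; a fixed order makes the QC report reproducible. The HWE test
is the 1-df goodness-of-fit chi-square against `n(p², 2pq, q²)` with p
estimated from the same counts, no continuity correction; monomorphic
markers return chi² = 0, p = 1 by convention (they cannot be tested,
and the MAF filter removes them anyway). All frequencies use
non-missing calls only. QC is idempotent and insensitive to animal or
marker order, both of which are asserted by tests.

The misplaced-SNP screen formalises a diagnostic that is often done by
eye on LD-decay plots: a marker assigned the wrong position keeps
strong LD with its true (now distant) neighbourhood and shows none with
its mapped one. Per marker we compute the fraction of same-chromosome
pairs farther than 10 Mbp with r² ≥ 0.3, and the mean r² with up to 10
nearest markers within 1 Mbp; a marker is flagged when the far fraction
is ≥ 0.05 while the near mean is ≤ 0.1. The five knobs are exposed
because the right values depend on marker density and the population's
true LD; the defaults were chosen once against simulated relocations
(a relocated marker is flagged, an intact map is not) and are not
tuned further. The screen is defined on post-QC panels — low-MAF
markers produce noisy r² estimates that inflate the far fraction.

## Composite LD, signed phase, and clamping

D is estimated directly from unphased genotype counts with the
small-sample factor N/(N-1); the weighted double-heterozygote count in
its numerator equals `sum(x*y)` over dosage vectors, which is how both
the scalar and the matrix implementation compute it, with missing data
handled by per-pair complete observations (N is the complete-pair
count). r² divides D² by the product of the four allele frequencies,
and the signed phase correlation is `sign(D)·sqrt(r²)` with
`sign(0) = +1` so it is defined when D = 0.

The N/(N-1) factor can push the raw r² ratio above 1 on tiny or
degenerate samples (a marker paired with itself at N = 4 gives 16/9 of
the uncorrected value). r² is clamped at 1 and the event recorded in
the output; without the clamp the signed-phase transform would be
undefined. Pairs that are monomorphic among the complete observations,
or have fewer than two of them, are skipped with a reason code rather
than returning a number that means nothing.

The matrix path (`ld_scan`) is verified pair-by-pair against the scalar
estimator, and both against an independent 3×3 contingency-table
implementation on a thousand random dosage pairs to 1e-12.

## Binning conventions

All distance bins in the package are half-open `[lo, hi)` anchored at
0; a pair at exactly 5.00 Mbp falls outside the 4–5 Mbp class. The
decay curve uses 0.01-Mbp bins to 5 Mbp; the class table uses the
conventional 0–0.01 / 0.01–0.05 / 0.05–0.10 / 0.10–0.50 / 0.50–1 /
1–2 / 2–3 / 3–4 / 4–5 Mbp classes. The Ne grid uses windows of
half-width 0.05 Mbp at centres every 0.10 Mbp from 0.05 to 10 Mbp and
every 0.5 Mbp from 10 to 20 Mbp. Window edges are compared with a 1e-9
Mbp tolerance — a thousandth of a base pair — purely to keep the binary
representation of the grid from excluding a pair that sits exactly on
an edge.

## Persistence of gametic phase

The phrase "correlation of phase at a distance" admits two readings:
correlate the pair-level signed r values of the shared marker pairs
within each distance bin, or correlate the two populations' bin-mean
curves as whole vectors. The package implements the first as the
default — it is the construction that yields one correlation per
distance, matching how persistence is plotted and interpreted, and it
degrades gracefully as bins thin out (bins with fewer than 3 shared
pairs are omitted). The second reading is available via
`method = "bin_means"`. Identical panels give r = 1 in every bin;
recoding one marker of each pair gives exactly −1, which is why shared
allele coding is a precondition and not a footnote.

## Effective population size

Sved's drift-recombination expectation `E(r²) = 1/(1+4Nec)` is inverted
per distance bin, with c obtained from physical distance at 1 cM = 1
Mbp (configurable), and each bin dated at T = 1/(2c) generations ago —
near pairs reflect ancient Ne, distant pairs recent Ne. No sample-size
correction is applied to r² before inversion by default; an optional
`r2_adjust_n` subtracts 1/N for callers who want it. With ~100 sampled
animals the uncorrected bias is ~0.01 in r², visible mainly in the most
recent bins; the parameter-recovery test bounds its practical effect.
Bins with fewer than 10 pairs or mean r² outside (0, 1) are omitted.
The inversion is exact by construction (feeding bins that follow the
expectation returns Ne to machine precision), so the substantive test
is recovery from simulation: a constant-size population of true Ne 100
(10 × 100 cM chromosomes, 3,000 SNPs, 200 burn-in generations) yields a
mean estimate within ±30% of truth over T ∈ [10, 100].

## Runs of homozygosity

A run is a maximal within-chromosome interval with ≥ 40 SNPs, ≤ 1
heterozygote, ≤ 2 missing calls, and homozygous non-missing endpoints.
The detector is a direct two-pointer scan over these constraints, not a
sliding-window heuristic: the window mechanics of common tools are a
computational device whose extra parameters (window length, allowed
window failures) are not part of the rule set here, and results can
differ slightly near run boundaries; the method name is recorded in the
output attributes for that reason. "Maximal" means not contained in any
larger satisfying interval — maximal runs may overlap (two long
stretches sharing a single heterozygote budget). The scan is proven
equal to exhaustive maximal-interval enumeration on hundreds of random
genotype strings. No minimum physical length or density filter is
applied beyond the SNP count, and segment length is measured
endpoint-to-endpoint in bp. F_ROH divides an animal's summed segment
lengths by the SNP-covered genome (sum over chromosomes of last minus
first marker position). The summary's `density` is mean kb per SNP
within runs, the ratio its name suggests in chip-panel reports.

## Inbreeding coefficients

Four estimators target the same latent quantity from different data:

* **F_EH** (excess homozygosity): mean over usable markers of
  `1 − c(2−c)/(2p(1−p))`; −1 for a fully heterozygous animal at
  p = 0.5, +1 for a fully homozygous one.
* **F_VR** (VanRaden): `Σ(c−2p)² / (2Σp(1−p)) − 1`, the GRM
  self-relationship minus one; the identity with `diag(G) − 1` is
  asserted to 1e-10 on complete panels. With missing calls the
  per-animal sums run over observed markers, which is the honest
  per-animal estimator even though it then deviates from the
  imputation-based GRM diagonal.
* **F_ROH**: genomic fraction in runs of homozygosity.
* **F_PED**: Wright's coefficient by the recursive tabular method on
  the numerator relationship matrix. Indirect methods used for very
  large pedigrees compute the identical quantity; at this package's
  scale the tabular method is the clearer reference, and it is verified
  against independent Wright path-counting exhaustively on every
  pedigree topology of up to 5 animals plus random deeper ones.

Allele frequencies default to the current sample per population; a
frequency table can be supplied to emulate base-population frequencies,
which matters for crosses (an F1's genomic coefficients computed with
its own sample frequencies are systematically negative, since the
cross's heterozygosity exceeds what its own frequencies predict — the
behaviour visible in the crossbred column of any such study).
Cross-estimator Pearson correlations are computed per population on
complete cases; a coefficient with zero variance (every F1 has
F_PED = 0 exactly) gets correlation 0 with an explicit degenerate flag
rather than NA, so downstream tables keep their shape.

## GRM and principal components

`G = ZZ'/(2Σp(1−p))` with Z the dosage matrix centred by 2p over
polymorphic markers; missing dosages are imputed at 2p, i.e. contribute
zero. PCA is defined as the eigendecomposition of the double-centred G
— the standard population-structure projection; scores are eigenvectors
scaled by the square root of their eigenvalues and variance fractions
are taken over positive eigenvalues. Running a column-wise PCA directly
on G instead shifts scores by a constant per component but the same
cluster geometry; the double-centred definition is documented here
because generic PCA calls differ in exactly this detail.

## The simulator and what the tests show

`simulate_population` is a forward Wright–Fisher model: diploid
monoecious random mating without selfing (so effective size equals
census size), discrete generations, no mutation or selection, gametes
formed with Poisson(L/100) crossovers at uniform genetic positions
(Haldane, no interference), equally spaced markers, physical positions
from 1 cM = 1 Mbp by default. Founders start at linkage equilibrium
with frequencies uniform in (0.1, 0.5) and LD accumulates during
burn-in — a transparent alternative to coalescent initialisation; the
cost is that bins dated beyond the burn-in horizon reflect the
equilibration transient, which is why parameter-recovery experiments
use 100–200 burn-in generations. Splits copy the final haplotype state
and evolve independently; F1 crosses draw one gamete from each line.
The pedigree of the last generations is exported and is
Mendelian-consistent with the panel by construction.

Test problem sizes (hundreds of markers, Ne of tens to a hundred,
tens-of-seconds runs) were chosen as the smallest scales at which each
property has clear signal; they establish that the estimators recover
the truth of *this* model. Real chip data differ in ways the simulator
deliberately omits — site-frequency spectra shaped by ascertainment,
variable marker spacing, genotyping error, selection and migration — so
passing tests validate the statistics' implementation and their
behaviour under drift-recombination dynamics, not any claim about a
particular real population.

## Pipeline

`run_pipeline` orchestrates the full analysis per population — QC,
misplacement screen, diversity, inbreeding with correlations, ROH, LD
decay and useful-LD fractions, Ne — plus cross-population phase
persistence and a joint GRM/PCA, writing every table as TSV with an
MD5-checksummed JSON manifest. QC runs within each population
independently (per-breed exclusion counts are the reproducible
currency of chip QC reports), and cross-population stages use the
intersection of surviving markers, whose shared coding is guaranteed by
the jointly coded input. Identical inputs, configuration and seed give
byte-identical tables. YAML configurations are supported through
`read_run_config`; `demo_config` provides a built-in two-line-plus-F1
synthetic study sized to run in well under five minutes.

## Known limitations

Pair scans materialise per-chromosome LD matrices, fine for panels up
to a few thousand markers per chromosome but not for sequence data.
The composite-D estimator is the genotype-based one throughout; no
EM/haplotype-based D is provided. The misplacement screen searches
within chromosomes only and does not propose corrected positions. The
simulator has no mutation, so very long runs accumulate homozygosity
indefinitely; simulations here stay in the drift-recombination regime
where Sved's equation applies.
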