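---
title: "Mapping a recessive resistance locus from phenotype-selected bulks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive resistance locus from phenotype-selected bulks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The problem

A laboratory-selected insect strain resists a Bacillus thuringiensis
(Bt) toxin at several-thousand-fold the susceptible strain's EC50, and
the resistance behaves as a single autosomal, largely recessive factor.
`bsamapr` implements the computational chain that takes such a strain
from bioassay to candidate allele:

1. **Inheritance analytics** — probit dose-response fits, Abbott's
   control correction, resistance ratios, the dominance parameter *h*,
   and exact tests of observed mortality against one-locus Mendelian
   expectations.
2. **Bulked segregant analysis (BSA)** — a delta-SNP index computed
   from pooled sequencing of phenotype-selected F2 bulks, windowed,
   smoothed, thresholded at the top percentile, and condensed into
   candidate regions; plus fine-mapping genotype tallies.
3. **Insertion-allele detection** — screening short reads against
   junction constructs for a transposable-element insertion that
   disrupts the candidate gene (here the motif of interest is an LTR
   retrotransposon with a 5-bp target site duplication), with a
   read-count positivity rule and cohort allele-frequency summaries.
4. **Transcript quantification** — 2^-ΔCt / 2^-ΔΔCt fold values from
   qPCR cycle thresholds, wild-type versus total transcript
   composition, and summary-statistic t tests.

Every stage can be exercised end to end on synthetic data: the
simulation layer generates crosses, selected bulks, pooled counts,
junction reads and Ct tables with known truth, so the statistical
behaviour of the pipeline is testable without any external data.

## The cross simulator

`simulate_cross()` models a resistant x susceptible pedigree. The
resistant founder is homozygous for the R-origin allele at every
informative marker and at the causal locus; the susceptible founder is
homozygous S-origin. Physical coordinates map to genetic distance at a
constant rate (default 3 cM/Mb, a typical lepidopteran genome-wide
average) and meioses place crossovers as a Poisson process along the
genetic map — exactly Haldane's map function, i.e. no crossover
interference. The causal locus travels through the same meioses as the
markers, so causal genotypes and flanking-marker diplotypes are always
consistent. Supported designs: F1, F2, backcross to the resistant
parent, and an advanced intercross maintained by random pan-mixis with
50 breeding pairs per generation (mirroring an F7 fine-mapping screen).

Phenotypes are Bernoulli draws from genotype-specific probit curves:
P(respond) = Φ(α_g + β_g log10 c), with genotype EC50s constrained
RR ≥ RS ≥ SS. "Respond" is the composite bioassay endpoint (death or
failure to reach third instar); larval size and growth rate are not
modelled, so a screen that picks the "largest survivors" is represented
simply as survival at the high dose. `phenotype_and_bulk()` splits
progeny into two dose arms (default half and half; the study design
places 480 F2 neonates on each arm), keeps non-responders at the high
dose as the resistant bulk and responders at the low dose as the
susceptible bulk, truncating requested bulk sizes to availability.

Pooled sequencing of a bulk is emulated as Poisson depth per marker and
binomial sampling of origin-labelled alleles at the bulk's true allele
frequency (`sample_pool_counts()`). No base-call errors are simulated:
for a counts-based statistic an error process would only dilute allele
frequencies slightly, and mismatch tolerance is exercised where it
matters, in the junction-read matcher. These are the main senses in
which the generator is simpler than real data: real pools have
GC-dependent depth, mapping bias toward the reference allele, and
correlated errors; passing tests show the statistics behave correctly
under the sampling model, not that the wet-lab pipeline upstream is
unbiased.

## The delta-SNP index

For each informative SNP (parents homozygous for different alleles —
`filter_snps()` drops sites with read support below 4 in either bulk,
sites without a parental genotype difference, and sites whose bulk
alleles cannot be attributed to either parent), the statistic is the
frequency of R-origin reads minus the frequency of S-origin reads in
the resistant bulk:

delta = f_R − f_S = 2 f_R − 1.

At a marker linked to a recessive causal locus the resistant bulk is
fixed for R, so delta = 1; at unlinked markers E[f_R] = 1/2 and
E[delta] = 0. Sampling noise makes raw values dip below zero; they are
clipped to 0 and flagged (keeping the 0–1 range and preserving window
SNP counts) rather than dropped. A two-bulk mode
(f_R in resistant bulk − f_R in susceptible bulk) is provided for
designs where both bulks are sequenced.

The per-SNP values are averaged over 1-kb half-open windows
[k·w, (k+1)·w) (a SNP at exactly position w belongs to the second
window; windows without SNPs are omitted), smoothed per chromosome by
tricube-weighted degree-1 local regression over the `ceiling(span * n)`
nearest windows (span 0.1 by default, chosen to resolve Mb-scale
linkage peaks on a ~15-Mb chromosome; no robustness iterations;
chromosomes with fewer than 10 windows fall back to the raw index with
a warning), and thresholded at the genome-wide top percentile (99th by
default, linear interpolation between order statistics). Candidate
regions are maximal runs of above-threshold windows, with a
configurable tolerance for below-threshold gaps (default 0), ranked by
peak value and then width.

One design point was genuinely open: whether the top-percentile line
and the region flags should use the raw or the smoothed index. The
package computes the threshold over the same quantity it flags, and
defaults to the **raw** index. Two reasons. First, the percentile line
in a Manhattan-style presentation is conventionally drawn over the
plotted index values, with the local-regression curve overlaid for
trend. Second, and more consequentially for inference: in a
recessive-selection design the markers nearest the causal locus are
*exactly* fixed in the resistant bulk out to the nearest recombination
breakpoint, so the raw index sits at exactly 1 on a plateau containing
the causal locus, while the argmax of a smoothed surface can drift to
either edge of that plateau and detach the top region from the locus.

## Probit analytics

`fit_probit()` is a maximum-likelihood binomial probit regression of
response on log10 concentration (IRLS, at most 100 iterations,
log-likelihood tolerance 1e-10). If the table carries a concentration-0
control row, treated responses are first Abbott-corrected,
(p − c)/(1 − c), clipped below at 0. EC50 = 10^(−α/β); its 95% CI comes
from the delta method on log10 EC50, which is stable at bioassay sample
sizes. Complete separation (no partial response anywhere) yields a
flagged non-converged fit whose point estimate and interval are the
geometric mean of, and the interval between, the highest all-survive
and lowest all-respond concentrations. Resistance ratios are reported
to 3 significant figures, matching bioassay-table convention.

Dose placement is a design choice the package makes explicit:
`ec50_dose_series()` builds a geometric series centred on the
anticipated EC50 with a default factor of 1.35. When the EC50 is
approximately known, information about it concentrates in doses with
intermediate kill; a wide 2-fold series spends two of six doses in the
saturated tails and demonstrably cannot reach the ~4–5% median
recovery error that the tighter series achieves at 24 larvae per dose.

Dominance is h = (Z − X)/(Y − X) on survival proportions of
susceptible, resistant and F1 larvae at one concentration; values
outside [0, 1] are returned unclipped with a flag, and
`dominance_curve()` reports (not enforces) monotonicity across
concentrations. Monogenic expectations assume only RR survives a
discriminating dose: expected mortality 50% (backcross to resistant),
75% (F2), 100% (F1).

`fisher_exact()` sums hypergeometric probabilities of all tables no
more probable than the observed one (relative tie tolerance 1e-7),
in log space, so p-values in the 10^-88 range — as arise when 214
resistant and 109 susceptible individuals segregate perfectly with a
marker — remain accurate. `observed_vs_expected_test()` builds the 2x2
of observed versus expected counts with half-to-even rounding of n·p
and *always* reports the exact binomial test alongside: constructing a
contingency table from an expectation involves a rounding convention
the source material leaves unstated, and on large counts the two
constructions can disagree materially, so both are surfaced.

## Insertion detection

`build_junction_refs()` assembles three constructs of 2 x flank bp
(default 600 bp) around an insertion point: the wild-type junction, the
upstream junction (flank ending in the TSD + element 5' end) and the
downstream junction (element 3' end + TSD + downstream flank) — the
duplicated TSD flanks the element, per the geometry a target-site-
duplicating element leaves behind. A read supports a junction when it
aligns ungapped (≤ 2 mismatches, either strand) straddling the junction
with at least 20 bp on each side; 20 bp exceeds the 5-bp TSD, which
guarantees no read can support both the wild-type and an insertion
junction. A sample is positive when either insertion junction is
covered by more than 3 reads (≥ 4; the per-junction OR is the weaker
reading of the rule and is configurable). Genotype classes refine this:
positive with zero wild-type support is called homozygous; positive and
wild-type-covered, heterozygous; these finer classes are an extension
beyond the positive/negative screen. Cohort summaries feed
`allele_frequency()` ((2·hom + het)/2n) and `founder_probability()`
(1 − (1 − q)^(2·founders)).

## Transcript quantification

`rel_abundance()` computes per-sample ΔCt against the reference gene
and normalizes 2^-ΔCt per assay to the calibrator group's geometric
mean — the natural aggregator for log-scale Ct data, making the
calibrator's geometric mean fold exactly 1 (an arithmetic-mean option
is provided). `mutant_fraction()` is (total − wildtype)/total, with
wildtype > total flagged and clamped. `summary_t()` reproduces
published summary-statistic t tests: unpooled standard error
√(SEM1² + SEM2²) with additive degrees of freedom n1 + n2 − 2 — the
combination that matches both printed t/df pairs this package's tests
check — with the Welch–Satterthwaite df reported as an alternative.

## Validation scale and reproducibility

The test suite validates the pipeline at these problem sizes, chosen to
mirror the study design while keeping a full run in minutes:

- BSA recovery: 50 replicates of a 15-Mb causal + 10-Mb null genome,
  markers every 2 kb, F2 with 480 larvae per dose arm, bulks of 89/75,
  100x pooled depth; the causal locus must fall inside the top
  candidate region in ≥ 95% of replicates, and the null-chromosome raw
  delta-SNP mean must sit within 3 SE of 0.
- Probit recovery: 200 simulated bioassays (6 doses x 24 larvae) from
  slope 4.7 and EC50 0.077; median |EC50 error| < 5% and ≥ 90% CI
  coverage.
- Oracle equivalence: Fisher p-values against full enumeration for all
  2x2 tables with total ≤ 40; windowing against brute-force grouping;
  the probit optimum against a 200x200 grid; the percentile threshold
  against sort-and-interpolate.

All randomness flows through explicit integer seeds
(`withr::with_seed`), so every simulation, test and pipeline run is
bit-reproducible; `run_pipeline()` writes a JSON manifest with md5
checksums of every stage output to make that property checkable.

## Limitations

- The simulator draws a constant recombination rate per chromosome and
  no interference; real linkage maps are locally uneven.
- Pooled counts carry no sequencing error, reference bias or
  over-dispersion beyond Poisson x binomial; real delta-SNP noise is
  typically somewhat wider, which argues for the smoothing and
  windowing the pipeline applies but is not itself modelled.
- The insertion matcher is ungapped; indel-containing reads near a
  junction are not counted (a conservative loss of support).
- Growth-rate phenotypes (e.g. "slowest-growing survivors") are
  collapsed onto the binary response endpoint.
- Printed Fisher p-values for observed-vs-expected mortality in
  published tables can depend on an unstated table construction; this
  package reports both exact constructions rather than matching any
  particular one.
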