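---
title: "Mutation profiling by multiplexed single-base extension: models and methods"
author: "hotplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation profiling by multiplexed single-base extension: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotplex)
```

## The assay model

hotplex models hotspot somatic mutation profiling by single-base extension
(SBE) genotyping read out on a linear MALDI-TOF instrument. For each
interrogated position, an extension primer anneals immediately adjacent to
the mutation site and is extended by exactly one chain-terminating
nucleotide. Because each terminator base has a distinct mass, the mass of
the extension product reports the allele, and because the extension is a
linear amplification of whatever template is present, the *area* under each
product's peak is proportional to the amount of that allele in the DNA. One
assay therefore contributes up to five expected analytes to a spectrum: the
unextended primer (UEP) and one extension product per allele (wild type
plus up to three mutants).

Three quantities summarise an assay's read-out:

* **allele fraction** — the area of one extension product divided by the
  summed areas of all extension products of that assay; the estimator of
  the mutant allele proportion;
* **UEP fraction** — UEP area over UEP plus extension areas; a per-assay
  extension-efficiency quality metric. It behaves as a step function of the
  DNA input into the PCR: about 0.09 below 3 ng of input and about 0.07 at
  3 ng and above. We model exactly this step and deliberately no smoother
  curve;
* **mutation ratio** — the ratio of two co-occurring mutations' allele
  fractions within one sample, comparing their clonal representation.

Oligonucleotide masses are *average* masses (linear MALDI-TOF of oligos
does not resolve isotopes): the mass of a primer is the sum of internal
residue masses plus a constant terminal adjustment, and an extension
product adds the terminator mass. All constants live in a swappable
`mass_table()` because published panels do not print their chemistry. The
default terminator masses obey two design constraints: every pairwise
terminator gap is at least 15 Da, and no gap lies within 5 Da of a sodium
(+21.98 Da) or potassium (+37.95 Da) adduct shift. The second constraint is
what makes salt satellites distinguishable from allele peaks by mass alone;
without it, a Na satellite of a large wild-type peak can sit on a mutant
analyte's expected position and create false mutant calls.

Assays come in two kinds. A *simple* assay resolves every amino-acid change
at its codon alone. A *complex* group interrogates different nucleotide
positions of one codon with separate sub-assays (e.g. the two positions of
KRAS codon 12); `resolve_complex()` substitutes the called mutant base into
the reference codon, translates with the standard genetic code, and emits
the codon-level label (`G12D` etc.). If two sub-assays of one codon are
simultaneously mutant the group is flagged `multi-hit-codon` for review
rather than silently combined — such calls are rare, never reported in the
reference cohort, and automatic resolution would hide errors.

## The synthetic-data generator

No raw clinical spectra are publicly available for this assay family, so
the package ships a generator whose defaults are the study conditions of
the reference colon-cancer cohort (239 stage II–III tumors, 39 paired
metastatic lymph nodes):

* **cohort truths** (`simulate_cohort_truth()`) draw each mutation
  independently per sample at the frequencies of `ref_mutation_counts()`
  (KRAS 43.5%, PIK3CA 20.1%, BRAF 12.1%, NRAS 3.8%, MET 3.3%, plus single
  ABL1/AKT1 events). Allele fractions default to the heterozygous 0.5; the
  MET mutations may instead draw from 0.58–0.70 with probability 0.5,
  reflecting the mutant-allele amplification observed for half of the
  MET-mutant samples. An `enriched` mode multiplies the probability of
  second hits for positive co-occurrence; the default is independence,
  which is also what the co-occurrence analysis tests against.
* **purity** is Beta(5, 2) (mean 0.71) — a realistic range for
  macrodissected FFPE tumor sections; purity multiplies the allele-level
  truth fraction at render time. Truth fractions are allele-level, not
  cell-level, because the platform reports peak-area fractions directly.
* **spectra** (`render_spectrum()`) place Gaussian peaks (constant sd in
  Da — the simplest shape with a closed-form area) at analyte masses, with
  expected areas `u·T` (UEP), `(1−u)·T·(1−f)` (wild type) and `(1−u)·T·f`
  (each mutant), where `u` is the input-dependent UEP share and `T` a
  per-assay total-primer scale. Noise comprises per-peak area jitter
  (CV 4%, consistent with the platform's demonstrated re-profiling
  repeatability), mass calibration error (sd 0.2 Da), a noisy flat
  baseline, Na/K adduct satellites (probability 0.1 each, area 15% of the
  parent), and spurious background peaks at 0.5 expected peaks per kDa of
  span. The background rate is a *density* rather than a per-spectrum
  count so that a single-assay validation spectrum and a 9-plex production
  spectrum see the same local contamination.
* **mixing series** (`simulate_mixing_series()`) emulate titrating a
  heterozygous mutant cell line into a wild-type line: 10% mutant cells
  carry 5% mutant alleles.
* **node pairs** (`simulate_node_pairs()`) give each lymph node its
  primary's mutations minus independent per-mutation dropouts, with a
  truncated-normal drift on retained fractions; nodes never gain mutations
  absent from the primary, matching the observed regime.

A single global seed expands into per-sample substreams through a
documented counter scheme (`seed·48271 + index·16807 mod 2³¹−1`), so
cohorts are reproducible piecewise and adding samples does not reshuffle
existing ones.

What the generator does *not* model — PCR amplification bias, phosphatase
kinetics, detector saturation, resolution-dependent peak widths, isotope
envelopes — bounds what passing tests show about real data: they validate
the analysis chain under the stated statistical structure (areas
proportional to allele content plus the listed artifacts), not instrument
physics.

## Signal processing and calling

`estimate_baseline()` is a running median with a 150 Da default window —
several times the width of a cluster of extension products, so peaks
occupy a minority of any window and cannot lift the estimate.
`detect_peaks()` keeps local maxima whose apex exceeds the baseline by at
least 3 robust noise units (MAD of baseline residuals). Noise jitter can
split one physical peak's flat top into several local maxima, so adjacent
maxima are merged unless a genuine valley (below half the smaller apex)
separates them; this prominence rule keeps truly adjacent species — e.g. a
mutant peak and a salt satellite 7 Da away — separate while never
fragmenting a single peak. Areas are trapezoidal integrals of the residual
over apex ± 4 peak-widths, truncated at the residual minimum towards any
adjacent detected peak so neighbours never share area.

`assign_peaks()` matches peaks to expected analytes greedily by mass
within ± 1 Da (generous against ≥ 15 Da terminator gaps), then flags
remaining peaks as `adduct-of(...)` when they sit on an analyte-plus-shift
position, else `background`. Adduct and background areas are *excluded*
from quantification — satellites are artifacts to reject, not signal to
reclaim.

`call_assay()` applies three rules: fail when the UEP fraction exceeds
0.90 (extension failure) or nothing was detected; otherwise call mutant
when a mutant allele fraction reaches the decision point with peak SNR at
least 3; otherwise wild type. The decision point deserves a note. The
validated limit of detection (`min_fraction`) is 0.05 — the platform
demonstrably detects mutations at 5% of extension areas. A detector that
thresholds *at* its limit of detection calls a sample truly at that limit
only half the time, because estimator noise is symmetric. Following the
standard blank/detection-limit convention, the decision point is therefore
`min_fraction × decision_fraction` with `decision_fraction = 0.5`: blanks
stay far below 0.025 (wild-type false-call rate ≤ 1% under default noise,
driven only by rare background peaks landing on a mutant position), while
samples at the 5% limit are called with ≥ 95% probability. All thresholds
are configurable; they are declared surrogates for the manual three-reviewer
curation used in the original workflow, which published no numeric rules.

Calls are ratio-based throughout, so rescaling a spectrum's intensities
leaves every result unchanged.

## Cohort analyses

`frequency_table()` tallies distinct-sample counts per amino-acid change
and per gene, reporting both the event sum and the distinct-sample count
(they coincide when no sample carries two mutations of one gene). The
"multiple mutations" share counts, among a gene's mutant samples, those
carrying any further mutation — in another gene or a second one in the
same gene; the source material leaves this choice open and we document it
rather than guess narrower. The overall mutation burden is reported as
distinct samples with ≥ 1 mutation across the profiled genes — the
reference publication prints both 64% and 60.2%/60.3% for closely related
definitions; this package computes the one well-defined quantity above.

`cooccurrence()` compares each gene pair's actual double-mutant frequency
with the independence expectation — the product of the two gene-level
frequencies. The reference table's MET×KRAS (1.44%) and NRAS×KRAS (1.66%)
expectations reproduce under the product rule; its NRAS×PIK3CA cell
(0.40% printed) does not (0.038 × 0.201 = 0.76%) — the implementation uses
the product rule uniformly and notes the discrepancy here. No
multiple-testing correction is applied anywhere, matching the source
analysis. `chisq_association()` is Pearson's chi-square without continuity
correction (Yates available behind a flag).

`concordance()` declares a primary/node pair concordant when the two
mutation *sets* (gene + amino-acid change) are identical, and lists
primary-only and node-only mutations otherwise. `mutation_ratio()` returns
a flagged undefined value when the denominator mutation is absent — as in
the reported node that lost its PIK3CA mutation — rather than an infinite
ratio.

## Panel reduction and replexing

`select_assays()` keeps assays (or whole genes) whose observed mutation
frequency reaches a threshold, default 1% — the rule that reduces the
wide screening panel to the colon-specific one. `replex()` then re-pools
the selection: a conflict graph joins assays whose analytes (optionally
including adduct satellites) come within `min_gap` Da (default 16, chosen
to exceed the adduct shifts only when `include_adducts` is on; the shipped
panel was pooled *with* adduct checking so no satellite can alias another
assay's analyte). Pooling is greedy first-fit-decreasing by conflict
degree with deterministic tie-breaks, minimising pool count only — fewest
pools is the stated economic goal, and pool-size balance is left to the
fill order. `replex_optimal()` provides an exhaustive branch-and-bound
minimum for instances up to 12 assays and serves as the greedy's oracle in
the tests; greedy equals the optimum on edgeless and complete instances
and never beats it. Primer–primer interaction constraints are out of
scope (the shipped primer sequences are synthetic stand-ins for
proprietary ones); the conflict predicate is pluggable so such checks can
be added.

The shipped `colon_hotspot_panel()` carries 25 sub-assays. The source
material is internally inconsistent about this count — its results section
says 24 assays while its conclusions say 25, and its assay table expands to
25 once the two-position codon groups are counted as separate sub-assays —
so the fixture mirrors the table and records the discrepancy here. It also
carries an HRAS Q61 assay although no HRAS mutation appears in the
frequency table; the assay is included with an explanatory `note` flag.
MET records use short-isoform protein numbering (R970C, T992I) with the
long-isoform labels (R988C, T1010I) carried as aliases, since the two
numbering systems coexist in public databases.

## Numerical choices and degenerate inputs

* Integration grid 0.3 Da, peak sd 1.5 Da; trapezoid error on a sampled
  Gaussian is far below the 2% test tolerance.
* Assignment ties break toward the smaller mass difference, then the
  lower-mass analyte; two expected analytes within the matching tolerance
  of each other raise an `ambiguous-panel` error instead of guessing.
* Zero extension signal with nonzero UEP is an extension failure; an
  all-zero assignment is a no-signal error; both become `fail` statuses,
  not exceptions, at the calling layer.
* Fractions are renormalised over detected extension products, so they
  always sum to 1 when any product is present.
* Problem sizes in the test-suite and the acceptance script — 100 spectra
  per recovery grid point, 200 sensitivity and ~500 specificity spectra,
  50-seed mixing series, a 5000-sample independence cohort, 200 random
  replexing instances — were chosen as the smallest sizes at which the
  binomial/Monte-Carlo error of each check is comfortably below its
  acceptance margin.

## Known limitations

Peak shape is idealised (Gaussian, constant width); no recalibration
against internal standards; no germline/SNP annotation of calls (the MET
juxtamembrane variants are known to coincide with dbSNP entries — a
documentation caveat, not a computation); no copy-number inference beyond
reporting allele fractions above 0.5; COSMIC-style external frequency
comparison is limited to accepting a user-supplied reference column.
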