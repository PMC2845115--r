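# hotplex

Hotspot somatic mutation profiling by multiplexed single-base extension
(SBE) genotyping with MALDI-TOF read-out — an end-to-end, testable model of
the assay chemistry, the spectra, the mutation caller, the cohort
statistics, and the multiplex-pool design.

## The problem

Targeted hotspot panels interrogate recurrent cancer mutations (KRAS G12,
BRAF V600, PIK3CA H1047, ...) with single-base-extension assays: a primer
anneals immediately adjacent to the interrogated base and is extended by
exactly one mass-modified terminator nucleotide. On a linear MALDI-TOF
spectrum each assay shows an unextended-primer (UEP) peak and one
extension-product peak per allele, and because the extension is a linear
amplification, **peak areas are proportional to allele content**. The
mutant allele fraction of allele *b* is estimated as

    f_b = area(b) / Σ area(extension products)

and the UEP share, `area(UEP) / (area(UEP) + Σ area(ext))`, is a per-assay
extension-efficiency QC metric. This works on the degraded, low-input DNA
of formalin-fixed (FFPE) clinical samples and detects mutant alleles down
to ~5% of the extension signal — which matters because tumor samples are
diluted by normal tissue.

hotplex provides, as R functions over plain S3 objects:

* **panel model** — assays, analyte masses from a configurable average-mass
  table, JSON panel files, mass-resolvability validation
  (`sbe_assay()`, `oligo_mass()`, `analytes_for()`, `load_panel()`,
  `pool_conflicts()`);
* **simulator** — cohort mutation truths at published colon-cancer
  frequencies, rendered spectra with UEP/adduct/baseline/background
  artifacts, purity dilution, cell-line mixing series, paired
  primary/lymph-node profiles (`simulate_cohort_truth()`,
  `render_spectrum()`, `simulate_mixing_series()`, `simulate_node_pairs()`);
* **signal processing** — rolling-median baseline, prominence-aware peak
  detection with trapezoidal area integration, greedy mass assignment with
  salt-adduct and background flagging (`estimate_baseline()`,
  `detect_peaks()`, `assign_peaks()`);
* **caller** — allele fractions from areas, QC-aware mutation calls,
  codon-level resolution of multi-position (complex) assays through the
  genetic code, per-sample mutation reports (`allele_fractions()`,
  `call_assay()`, `resolve_complex()`, `sample_report()`);
* **cohort statistics** — frequency tables, double-mutation co-occurrence
  against the independence product rule, mutant-allele-ratio summaries,
  primary/node concordance, chi-square association
  (`frequency_table()`, `cooccurrence()`, `mutation_ratio()`,
  `concordance()`, `chisq_association()`);
* **replexing** — frequency-threshold assay selection and re-pooling into
  the fewest mass-resolvable pools, with an exhaustive optimum as oracle
  (`select_assays()`, `replex()`, `replex_optimal()`), plus a thin CLI at
  `inst/scripts/replex.R`.

A 25-assay colon hotspot panel (synthetic primer sequences, published
assay names and mutation targets) ships as a built-in fixture together
with the reference cohort's printed frequency and paired-profile tables
(`colon_hotspot_panel()`, `ref_mutation_counts()`, ...).

## Worked example

Simulate a double-mutant sample — KRAS-G12D at allele fraction 0.45 and
PIK3CA-H1047R at 0.24 — render all pools, and call it:

```r
library(hotplex)

panel <- colon_hotspot_panel()
panel
#> <sbe_panel> colon_hotspot: 25 assays in 4 pools (max plex 9)
#>   plex1 [9]: HRAS_6, KRAS_2, KRAS_7, BRAF_15, KRAS_8, KRAS_4, NRAS_8, PIK3CA_9, PIK3CA_1
#>   plex2 [9]: KRAS_1, NRAS_3, BRAF_16, BRAF_9, NRAS_1, MET_2, NRAS_2, NRAS_4, PIK3CA_3
#>   plex3 [5]: MET_1, NRAS_7, PIK3CA_7, PIK3CA_6, KRAS_5
#>   plex4 [2]: PIK3CA_5, PIK3CA_8

fr <- data.frame(assay_id = c("KRAS_2", "PIK3CA_9"),
                 mut_base = c("A", "G"), fraction = c(0.45, 0.24))
calls <- unlist(lapply(names(panel$pools), function(p) {
  sp <- render_spectrum(fr, panel, p, purity = 1,
                        noise = noise_model(), seed = 42,
                        sample_id = "C07-demo")
  call_pool(sp, panel, p)
}), recursive = FALSE)
sample_report(calls, panel)
#>   sample_id   gene aa_change  fraction
#> 1  C07-demo   KRAS      G12D 0.4579256
#> 2  C07-demo PIK3CA    H1047R 0.2513769
```

The KRAS mutation was planted on the position-2 sub-assay of the complex
codon-12 group; the caller resolved it through the genetic code
(GGT → GAT = Asp) to the codon-level label `G12D`. Both fractions are
recovered within ~0.01 of the planted truth from a noisy 9-plex spectrum.
The clonal-representation ratio of the two mutations,

```r
round(mutation_ratio(0.4579256, 0.2513769), 2)
#> [1] 1.82
```

says the KRAS mutant allele is ~1.8× as abundant as the PIK3CA one — the
typical pattern in double-mutant colon tumors, where KRAS dominates in
about 71% of cases.

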