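make_assignment <- function(areas, snr = 100) {
  # areas: named c(UEP=, wt=, mut...) for a single assay with wt G, mut A/T
  labels <- names(areas)
  roles <- c("unextended", "wt_extension",
             rep("mut_extension", length(areas) - 2))
  an <- data.frame(assay_id = "A_1", label = labels,
                   mass = seq(5000, by = 300, length.out = length(areas)),
                   role = roles, matched = areas > 0,
                   peak_mass = ifelse(areas > 0, seq(5000, by = 300,
                                                     length.out = length(areas)),
                                      NA_real_),
                   area = unname(areas),
                   snr = ifelse(areas > 0, snr, NA_real_))
  structure(list(analytes = an,
                 unassigned = data.frame(apex_mass = numeric(),
                                         height = numeric(),
                                         area = numeric(), snr = numeric(),
                                         flag = character())),
            class = "peak_assignment")
}

test_that("allele fractions are area ratios over extension products", {
  af <- allele_fractions(make_assignment(c(UEP = 10, G = 76, A = 24)))
  expect_equal(unname(af$fractions[["A"]]), 0.24)
  expect_equal(unname(af$fractions[["G"]]), 0.76)
  expect_equal(af$uep_fraction, 10 / 110)
  expect_equal(sum(af$fractions), 1)

  # areas proportional to a reported double-mutant sample: mutant 45 vs 55
  af2 <- allele_fractions(make_assignment(c(UEP = 8, G = 55, A = 45)))
  expect_equal(unname(af2$fractions[["A"]]), 0.45)

  af3 <- allele_fractions(make_assignment(c(UEP = 5, G = 30, A = 30)))
  expect_equal(unname(af3$fractions[["A"]]), 0.5)
  expect_equal(unname(af3$fractions[["G"]]), 0.5)
})

test_that("degenerate assignments raise classed signal errors", {
  expect_error(allele_fractions(make_assignment(c(UEP = 10, G = 0, A = 0))),
               class = "hotplex_extension_failure")
  expect_error(allele_fractions(make_assignment(c(UEP = 0, G = 0, A = 0))),
               class = "hotplex_no_signal")
})

test_that("call_assay applies detection-limit, SNR and UEP rules", {
  assay <- make_assay("A_1", mut_alleles = c(A = "G12D"))
  th <- call_thresholds()

  af <- allele_fractions(make_assignment(c(UEP = 7, G = 95, A = 5)))
  cl <- call_assay(af, assay, th)
  expect_equal(cl$status, "mutant")
  expect_equal(cl$aa_change, "G12D")

  af0 <- allele_fractions(make_assignment(c(UEP = 7, G = 100, A = 0)))
  expect_equal(call_assay(af0, assay, th)$status, "wildtype")

  # extension failure: almost everything unextended
  af_uep <- allele_fractions(make_assignment(c(UEP = 98, G = 2, A = 0)))
  cl_uep <- call_assay(af_uep, assay, th)
  expect_equal(cl_uep$status, "fail")
  expect_true("insufficient-extension" %in% cl_uep$qc_flags)

  # a candidate below the SNR floor is not called, only flagged
  low <- make_assignment(c(UEP = 7, G = 90, A = 10), snr = 2)
  cl_low <- call_assay(allele_fractions(low), assay, th)
  expect_equal(cl_low$status, "wildtype")
  expect_true("low-snr-candidate" %in% cl_low$qc_flags)

  expect_equal(call_assay(NULL, assay, th,
                          fail_reason = "no-signal")$status, "fail")
})

test_that("complex groups resolve through the genetic code", {
  k1 <- make_assay("KRAS_1", primer_seq = det_primer(17),
                   mut_alleles = c(T = "G12C", A = "G12S", C = "G12R"),
                   complex_group = "KRAS_G12", codon_pos = 1,
                   codon_ref = "GGT", kind = "complex")
  k2 <- make_assay("KRAS_2", primer_seq = det_primer(21),
                   mut_alleles = c(T = "G12V", C = "G12A", A = "G12D"),
                   complex_group = "KRAS_G12", codon_pos = 2,
                   codon_ref = "GGT", kind = "complex")
  assays <- list(KRAS_1 = k1, KRAS_2 = k2)
  mk_call <- function(assay, status, base = NA, fraction = NA) {
    fr <- if (!is.na(base)) stats::setNames(c(fraction, 1 - fraction),
                                            c(base, assay$wt_base)) else
                                              numeric()
    structure(list(sample_id = "s", assay_id = assay$assay_id,
                   gene = assay$gene, status = status, mut_base = base,
                   aa_change = NA, allele_fractions = fr,
                   uep_fraction = 0.07, snr = NULL, qc_flags = character()),
              class = "assay_call")
  }
  # GGT with position-2 G->A gives GAT = Asp: G12D (frozen codon fact)
  res <- resolve_complex(list(mk_call(k1, "wildtype"),
                              mk_call(k2, "mutant", "A", 0.3)), assays)
  expect_equal(res$status, "mutant")
  expect_equal(res$aa_change, "G12D")
  expect_equal(res$fraction, 0.3)
  # GGT with position-1 G->T gives TGT = Cys: G12C (frozen codon fact)
  res2 <- resolve_complex(list(mk_call(k1, "mutant", "T", 0.2),
                               mk_call(k2, "wildtype")), assays)
  expect_equal(res2$aa_change, "G12C")

  expect_equal(resolve_complex(list(mk_call(k1, "wildtype"),
                                    mk_call(k2, "wildtype")),
                               assays)$status, "wildtype")
  expect_equal(resolve_complex(list(mk_call(k1, "mutant", "T", 0.2),
                                    mk_call(k2, "mutant", "A", 0.1)),
                               assays)$status, "multi-hit-codon")
})

test_that("sample reports collapse complex groups and order records", {
  panel <- load_panel(system.file("extdata", "colon_hotspot_panel.json",
                                  package = "hotplex"))
  fr <- data.frame(assay_id = c("PIK3CA_9", "KRAS_2"),
                   mut_base = c("G", "A"), fraction = c(0.24, 0.45))
  calls <- list()
  for (p in names(panel$pools)) {
    sp <- render_spectrum(fr, panel, p, noise = noiseless(), seed = 5,
                          sample_id = "s1")
    calls <- c(calls, call_pool(sp, panel, p))
  }
  rep1 <- sample_report(calls, panel)
  expect_equal(nrow(rep1), 2L)
  expect_equal(rep1$gene, c("KRAS", "PIK3CA"))
  expect_equal(rep1$aa_change, c("G12D", "H1047R"))
  expect_equal(rep1$fraction, c(0.45, 0.24), tolerance = 0.01)

  # no mutant calls: empty report
  sp_wt <- render_spectrum(fr[0, ], panel, "plex1", noise = noiseless(),
                           seed = 5, sample_id = "s2")
  rep0 <- sample_report(call_pool(sp_wt, panel, "plex1"), panel)
  expect_equal(nrow(rep0), 0L)
})

test_that("calls are invariant to intensity rescaling of the spectrum", {
  p <- make_two_pool_panel()
  fr <- data.frame(assay_id = "A_1", mut_base = "A", fraction = 0.2)
  sp <- render_spectrum(fr, p, "pool1", noise = noise_model(), seed = 31)
  sp10 <- sp
  sp10$intensity <- sp$intensity * 10
  c1 <- calls_df(call_pool(sp, p))
  c10 <- calls_df(call_pool(sp10, p))
  expect_equal(c10$status, c1$status)
  expect_equal(c10$mutant_fraction, c1$mutant_fraction, tolerance = 1e-6)
  expect_equal(c10$uep_fraction, c1$uep_fraction, tolerance = 1e-6)
})

test_that("cohort profiling recovers known truths at callable fractions", {
  panel <- load_panel(system.file("extdata", "colon_hotspot_panel.json",
                                  package = "hotplex"))
  freqs <- ref_mutation_counts()
  freqs <- freqs[freqs$gene %in% c("KRAS", "PIK3CA", "BRAF"), ]
  truth <- simulate_cohort_truth(freqs, 12, purity_shape1 = 1e6,
                                 purity_shape2 = 1, seed = 55)
  records <- profile_cohort(truth, panel, seed = 56)
  truth_key <- paste(truth$mutations$sample_id, truth$mutations$gene,
                     truth$mutations$aa_change)
  rec_key <- paste(records$sample_id, records$gene, records$aa_change)
  expect_gte(mean(truth_key %in% rec_key), 0.95)
  expect_gte(mean(rec_key %in% truth_key), 0.95)
})
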