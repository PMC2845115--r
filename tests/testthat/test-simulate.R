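test_that("cohort truth generation is deterministic and respects bounds", {
  freqs <- data.frame(gene = c("KRAS", "BRAF"),
                      aa_change = c("G12D", "V600E"),
                      frequency = c(0, 0))
  t0 <- simulate_cohort_truth(freqs, 20, seed = 3)
  expect_equal(nrow(t0$mutations), 0L)
  expect_true(all(t0$samples$purity > 0 & t0$samples$purity <= 1))

  freqs$frequency <- c(0.4, 0.1)
  t1 <- simulate_cohort_truth(freqs, 50, seed = 11)
  t2 <- simulate_cohort_truth(freqs, 50, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_cohort_truth(freqs, 50, seed = 12)
  expect_false(identical(t1$mutations, t3$mutations))
  expect_true(all(t1$mutations$fraction >= 0 & t1$mutations$fraction <= 1))
  expect_error(simulate_cohort_truth(
    data.frame(gene = "X", aa_change = "Y", frequency = 1.2), 5),
    "frequencies")
})

test_that("empirical cohort frequencies match the generating table", {
  freqs <- ref_mutation_counts()
  n <- 239
  truth <- simulate_cohort_truth(freqs, n, seed = 101)
  # per-gene empirical frequency within 3 binomial standard errors of the
  # frequency implied by the generating per-mutation table
  for (g in unique(freqs$gene)) {
    p_gene <- 1 - prod(1 - freqs$frequency[freqs$gene == g])
    obs <- length(unique(
      truth$mutations$sample_id[truth$mutations$gene == g])) / n
    se <- sqrt(p_gene * (1 - p_gene) / n)
    expect_lt(abs(obs - p_gene), 3 * se + 1e-12)
  }
})

test_that("amplified mutations draw fractions from the amplified range", {
  freqs <- data.frame(gene = "MET", aa_change = "R970C", frequency = 1,
                      amplified = TRUE)
  truth <- simulate_cohort_truth(freqs, 400, seed = 5, amplified_prob = 0.5)
  f <- truth$mutations$fraction
  expect_true(all(f == 0.5 | (f >= 0.58 & f <= 0.70)))
  expect_gt(mean(f > 0.5), 0.35)
  expect_lt(mean(f > 0.5), 0.65)
})

test_that("noiseless rendering reproduces allele-proportional areas", {
  p <- make_two_pool_panel()
  nm <- noiseless()
  # f = 0.5, purity 1: mutant share of extension areas is exactly 1/2
  fr <- data.frame(assay_id = "A_1", mut_base = "A", fraction = 0.5)
  sp <- render_spectrum(fr, p, "pool1", noise = nm, seed = 1)
  ap <- assign_peaks(detect_peaks(sp, estimate_baseline(sp)),
                     panel_analytes(p, "pool1"))
  af <- allele_fractions(ap, "A_1")
  expect_equal(unname(af$fractions[["A"]]), 0.5, tolerance = 0.005)

  # triploid-like truth: one mutant of three alleles
  fr$fraction <- 1 / 3
  sp <- render_spectrum(fr, p, "pool1", noise = nm, seed = 1)
  ap <- assign_peaks(detect_peaks(sp, estimate_baseline(sp)),
                     panel_analytes(p, "pool1"))
  af <- allele_fractions(ap, "A_1")
  expect_equal(unname(af$fractions[["A"]]), 1 / 3, tolerance = 0.005)

  # low DNA input selects the higher unextended-primer share
  sp2 <- render_spectrum(fr, p, "pool1", input_ng = 2, noise = nm, seed = 1)
  ap2 <- assign_peaks(detect_peaks(sp2, estimate_baseline(sp2)),
                      panel_analytes(p, "pool1"))
  expect_equal(allele_fractions(ap2, "A_1")$uep_fraction, 0.09,
               tolerance = 0.005)
  expect_equal(af$uep_fraction, 0.07, tolerance = 0.005)
})

test_that("purity scales the rendered mutant fraction across a grid", {
  p <- make_two_pool_panel()
  nm <- noiseless()
  purity <- 0.6
  for (f in c(0.05, 0.25, 0.5, 0.75, 1)) {
    fr <- data.frame(assay_id = "A_3", mut_base = "G", fraction = f)
    sp <- render_spectrum(fr, p, "pool2", purity = purity, noise = nm,
                          seed = 2)
    ap <- assign_peaks(detect_peaks(sp, estimate_baseline(sp)),
                       panel_analytes(p, "pool2"))
    af <- allele_fractions(ap, "A_3")
    expect_equal(unname(af$fractions[["G"]]), purity * f,
                 tolerance = 0.006)
  }
})

test_that("expected per-assay total area is conserved before noise", {
  p <- make_two_pool_panel()
  nm <- noiseless()
  fr <- data.frame(assay_id = "A_1", mut_base = "A", fraction = 0.3)
  sp <- render_spectrum(fr, p, "pool1", noise = nm, seed = 1)
  ap <- assign_peaks(detect_peaks(sp, estimate_baseline(sp)),
                     panel_analytes(p, "pool1"))
  an <- ap$analytes
  for (aid in c("A_1", "A_2"))
    expect_equal(sum(an$area[an$assay_id == aid]), nm$total_area,
                 tolerance = 0.02 * nm$total_area)
})

test_that("mixing series applies heterozygous allele scaling", {
  assay <- make_assay("MIX_1", "PIK3CA", "E545",
                      primer_seq = det_primer(20), wt_base = "G",
                      mut_alleles = c(A = "E545K"))
  mix <- simulate_mixing_series(c(0, 0.10, 0.5, 1.0), assay,
                                heterozygous = TRUE, noise = noiseless(),
                                seed = 4)
  expect_equal(mix$allele_fraction, c(0, 0.05, 0.25, 0.5))
  # fraction 0: no mutant peak above baseline
  calls0 <- call_pool(mix$spectra[[1]], mix$panel, "mix")
  expect_equal(calls0[[1]]$status, "wildtype")
  # fraction 1, heterozygous: recovered mutant fraction 0.5
  ap <- assign_peaks(detect_peaks(mix$spectra[[4]],
                                  estimate_baseline(mix$spectra[[4]])),
                     panel_analytes(mix$panel, "mix"))
  expect_equal(unname(allele_fractions(ap, "MIX_1")$fractions[["A"]]), 0.5,
               tolerance = 0.005)
  hom <- simulate_mixing_series(c(0.10), assay, heterozygous = FALSE,
                                noise = noiseless(), seed = 4)
  expect_equal(hom$allele_fraction, 0.10)
})

test_that("node pairs inherit, drop and never gain mutations", {
  freqs <- ref_mutation_counts()
  primary <- simulate_cohort_truth(freqs, 30, seed = 21)
  same <- simulate_node_pairs(primary, dropout_prob = 0,
                              fraction_drift_sd = 0, seed = 1)
  expect_equal(same$node$mutations$gene, primary$mutations$gene)
  expect_equal(same$node$mutations$fraction, primary$mutations$fraction)
  expect_true(all(endsWith(same$node$mutations$sample_id, "_LN")))

  gone <- simulate_node_pairs(primary, dropout_prob = 1, seed = 1)
  expect_equal(nrow(gone$node$mutations), 0L)

  some <- simulate_node_pairs(primary, dropout_prob = 0.3, seed = 9)
  key <- function(m) paste(sub("_LN$", "", m$sample_id), m$gene,
                           m$aa_change)
  expect_true(all(key(some$node$mutations) %in% key(primary$mutations)))
})

test_that("simulated node concordance matches its analytic expectation", {
  freqs <- ref_mutation_counts()
  primary <- simulate_cohort_truth(freqs, 39, seed = 77)
  d <- 4 / 26
  n_mut <- table(factor(primary$mutations$sample_id,
                        levels = primary$samples$sample_id))
  analytic <- mean((1 - d)^as.numeric(n_mut))
  n_rep <- 120
  conc <- vapply(seq_len(n_rep), function(r) {
    pr <- simulate_node_pairs(primary, dropout_prob = d, seed = r)
    kp <- split(paste(pr$primary$mutations$gene,
                      pr$primary$mutations$aa_change),
                sub("_LN$", "", pr$primary$mutations$sample_id))
    kn <- split(paste(pr$node$mutations$gene, pr$node$mutations$aa_change),
                sub("_LN$", "", pr$node$mutations$sample_id))
    mean(vapply(primary$samples$sample_id, function(s)
      identical(sort(kp[[s]] %||% character()),
                sort(kn[[s]] %||% character())), logical(1)))
  }, numeric(1))
  mc_se <- stats::sd(conc) / sqrt(n_rep)
  expect_lt(abs(mean(conc) - analytic), 4 * mc_se + 0.005)
  # and the regime sits near the observed 35/39 pair concordance
  expect_lt(abs(analytic - 35 / 39), 0.06)
})
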