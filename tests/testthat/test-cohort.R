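test_that("frequency tables reproduce the reference cohort gene totals", {
  records <- records_from_counts(ref_mutation_counts())
  ft <- frequency_table(records, 239)
  g <- ft$by_gene
  expect_equal(g$n_events[g$gene == "KRAS"], 104L)
  expect_equal(g$n_samples[g$gene == "KRAS"], 104L)
  expect_equal(round(100 * g$frequency[g$gene == "KRAS"], 1), 43.5)
  expect_equal(round(100 * g$frequency[g$gene == "PIK3CA"], 1), 20.1)
  expect_equal(round(100 * g$frequency[g$gene == "BRAF"], 1), 12.1)
  expect_equal(round(100 * g$frequency[g$gene == "NRAS"], 1), 3.8)
  bm <- ft$by_mutation
  expect_equal(round(100 * bm$frequency[bm$gene == "KRAS" &
                                          bm$aa_change == "G12D"], 1), 16.7)
  expect_equal(nrow(g), 7L)
})

test_that("frequency tables handle empty input and match a tally oracle", {
  empty <- frequency_table(
    data.frame(sample_id = character(), gene = character(),
               aa_change = character()), 10)
  expect_equal(nrow(empty$by_mutation), 0L)
  expect_equal(empty$overall_mutated, 0L)

  freqs <- ref_mutation_counts()
  truth <- simulate_cohort_truth(freqs, 150, seed = 42)
  ft <- frequency_table(truth$mutations, 150)
  # brute-force tally oracle
  for (r in seq_len(nrow(ft$by_mutation))) {
    n_oracle <- 0L
    for (s in unique(truth$mutations$sample_id)) {
      hit <- truth$mutations[truth$mutations$sample_id == s, ]
      if (any(hit$gene == ft$by_mutation$gene[r] &
                hit$aa_change == ft$by_mutation$aa_change[r]))
        n_oracle <- n_oracle + 1L
    }
    expect_equal(ft$by_mutation$n[r], n_oracle)
  }
  # gene frequency dominates every per-mutation frequency in that gene
  for (g in ft$by_gene$gene)
    expect_gte(ft$by_gene$frequency[ft$by_gene$gene == g],
               max(ft$by_mutation$frequency[ft$by_mutation$gene == g]))
})

test_that("multiple-mutation share counts cross-gene and same-gene seconds", {
  records <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3", "S3", "S4"),
    gene = c("KRAS", "PIK3CA", "KRAS", "PIK3CA", "PIK3CA", "BRAF"),
    aa_change = c("G12D", "E545K", "G12V", "E542K", "H1047R", "V600E"))
  ft <- frequency_table(records, 10)
  g <- ft$by_gene
  expect_equal(g$multiple_share[g$gene == "KRAS"], 0.5)    # S1 of S1,S2
  expect_equal(g$multiple_share[g$gene == "PIK3CA"], 1)    # S1 and S3
  expect_equal(g$multiple_share[g$gene == "BRAF"], 0)
  expect_equal(g$n_events[g$gene == "PIK3CA"], 3L)
  expect_equal(g$n_samples[g$gene == "PIK3CA"], 2L)
})

test_that("expected co-occurrence is the product of gene frequencies", {
  expect_equal(round(100 * expected_cooccurrence(0.033, 0.437), 2), 1.44)
  expect_equal(expected_cooccurrence(0, 0.3), 0)
  co <- cooccurrence(
    data.frame(sample_id = c("S1", "S1", "S2"),
               gene = c("KRAS", "PIK3CA", "KRAS"),
               aa_change = c("G12D", "E545K", "G12V")), 10)
  expect_equal(co$actual[co$gene_a == "KRAS" & co$gene_b == "PIK3CA"], 0.1)
  expect_equal(co$expected[co$gene_a == "KRAS" & co$gene_b == "PIK3CA"],
               0.2 * 0.1)
})

test_that("independence-mode cohorts co-occur at the product rate", {
  freqs <- ref_mutation_counts()
  truth <- simulate_cohort_truth(freqs, 5000, seed = 31)
  co <- cooccurrence(truth$mutations, 5000)
  for (r in seq_len(nrow(co))) {
    se <- sqrt(co$expected[r] * (1 - co$expected[r]) / 5000)
    expect_lt(abs(co$actual[r] - co$expected[r]), 3 * se + 1e-9)
  }
})

test_that("mutation ratios follow the reported area arithmetic", {
  expect_equal(round(mutation_ratio(0.45, 0.24), 2), 1.88)
  expect_equal(round(mutation_ratio(0.22, 0.05), 2), 4.40)
  expect_equal(mutation_ratio(0.3, 0.3), 1)
  und <- mutation_ratio(0.15, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("ratio summaries band and count dominance correctly", {
  rs <- ratio_summary(ref_ratio_values())
  expect_equal(rs$n, 31L)
  expect_equal(rs$n_above, 22L)
  expect_equal(round(rs$percent_above), 71)
  expect_equal(unname(rs$bands), c(2L, 7L, 22L))

  same <- ratio_summary(rep(1.6, 8))
  expect_equal(same$median, 1.6)
  expect_equal(same$mean, 1.6)

  set.seed(9)
  x <- stats::rlnorm(50, 0.2, 0.4)
  rs2 <- ratio_summary(x)
  # sorting-based oracle: even-length median is the mid-pair average
  xs <- sort(x)
  expect_equal(rs2$median, (xs[25] + xs[26]) / 2)
  expect_equal(rs2$n_above, sum(xs >= 1.25))
  expect_equal(rs2$mean, sum(x) / 50)
})

test_that("concordance reproduces the reference paired-profile facts", {
  ref <- ref_node_pair_reports()
  cr <- concordance(ref$primary, ref$node, ref$pairs)
  expect_equal(cr$n_pairs, 39L)
  expect_equal(cr$n_identical, 35L)
  expect_equal(round(cr$percent_concordant, 1), 89.7)
  expect_equal(nrow(cr$node_only), 0L)
  dropped <- table(sub("-.*", "", cr$primary_only$mutation))
  expect_equal(dropped[["BRAF"]], 2L)
  expect_equal(dropped[["KRAS"]], 1L)
  expect_equal(dropped[["PIK3CA"]], 1L)
  # permutation invariance and the all-identical case
  perm <- sample(nrow(ref$primary))
  cr2 <- concordance(ref$primary[perm, ], ref$node, ref$pairs)
  expect_equal(cr2$percent_concordant, cr$percent_concordant)
  all_same <- concordance(ref$primary, {
    n <- ref$primary
    n$sample_id <- paste0(n$sample_id, "_LN")
    n
  }, ref$pairs)
  expect_equal(all_same$percent_concordant, 100)
})

test_that("chi-square association equals the closed form", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  res <- chisq_association(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(chisq_association(matrix(10, 2, 2))$statistic, 0)

  closed_form <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(4, 20) + 1, 2)
    expect_equal(chisq_association(tab)$statistic, closed_form(tab),
                 tolerance = 1e-12)
  }
  expect_error(chisq_association(matrix(c(0, 0, 5, 5), 2)),
               "marginals")
})

test_that("assay selection keeps genes/assays at or above the threshold", {
  panel <- load_panel(system.file("extdata", "colon_hotspot_panel.json",
                                  package = "hotplex"))
  records <- records_from_counts(ref_mutation_counts())
  ft <- frequency_table(records, 239)
  sel_gene <- select_assays(ft, panel, level = "gene", threshold = 0.01)
  genes_kept <- unique(vapply(panel$assays[sel_gene], `[[`, "", "gene"))
  expect_setequal(genes_kept, c("KRAS", "PIK3CA", "BRAF", "MET", "NRAS"))
  expect_equal(length(select_assays(ft, panel, "gene", threshold = 1)), 0L)
  low <- select_assays(ft, panel, "assay", threshold = 1e-9)
  # every assay interrogating an observed mutation survives a ~0 threshold
  observed <- vapply(panel$assays, function(a)
    any(paste(a$gene, a$mut_alleles) %in%
          paste(records$gene, records$aa_change)), logical(1))
  expect_setequal(low, names(panel$assays)[observed])
})
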