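#' Reference hotspot mutation frequencies from a colon-cancer cohort
#'
#' Per-mutation counts observed when 239 stage II–III colon carcinomas were
#' profiled with a 19-gene hotspot SBE panel. Mutations were found in 7
#' genes; these counts drive the synthetic cohort generator and the
#' frequency-threshold panel reduction. The `amplified` column marks the MET
#' mutations, for which about half of the mutant samples showed
#' mutant-allele amplification (allele fractions 0.58–0.70).
#'
#' @return data.frame with columns `gene`, `aa_change`, `n`, `frequency`
#'   (over `n = 239`), `amplified`; attribute `n_samples = 239`.
#' @export
ref_mutation_counts <- function() {
  df <- data.frame(
    gene = c("ABL1", "AKT1", "BRAF", "BRAF",
             rep("KRAS", 10), rep("MET", 2), rep("NRAS", 6),
             rep("PIK3CA", 8)),
    aa_change = c("F359V", "E17K", "D594V", "V600E",
                  "G12A", "G12C", "G12D", "G12R", "G12S", "G12V", "G13D",
                  "A59T", "Q61L", "Q61R",
                  "R970C", "T992I",
                  "G12C", "G12D", "G13R", "G13V", "Q61H", "Q61K",
                  "R88Q", "C420R", "E542K", "E545K", "Q546K", "H701P",
                  "H1047L", "H1047R"),
    n = c(1L, 1L, 1L, 28L,
          2L, 10L, 40L, 3L, 3L, 20L, 23L, 1L, 1L, 1L,
          2L, 6L,
          1L, 4L, 1L, 1L, 1L, 1L,
          5L, 2L, 9L, 12L, 4L, 1L, 1L, 14L),
    stringsAsFactors = FALSE)
  df$frequency <- df$n / 239
  df$amplified <- df$gene == "MET"
  attr(df, "n_samples") <- 239L
  df
}

#' Reference single-gene frequencies used for co-occurrence expectations
#'
#' Gene-level mutation frequencies of the reference cohort as used in its
#' double-mutation analysis (the KRAS entry, 43.7%, reflects the
#' double-mutation subset bookkeeping and differs slightly from the 43.5%
#' of the per-mutation tally).
#'
#' @return Named numeric of proportions.
#' @export
ref_single_gene_frequencies <- function() {
  c(KRAS = 0.437, PIK3CA = 0.201, BRAF = 0.118, MET = 0.033, NRAS = 0.038)
}

#' Reference paired primary/lymph-node allele fractions
#'
#' Mutant allele fractions, measured from peak areas, for five primary
#' tumors carrying two mutations and their matched metastatic lymph nodes.
#'
#' @return data.frame with one row per (sample, mutation): columns `sample`,
#'   `which` (`"M1"`/`"M2"`), `mutation`, `primary`, `node`.
#' @export
ref_paired_fractions <- function() {
  data.frame(
    sample = rep(c("C07-0388", "C07-0717", "C07-0940", "C07-2244",
                   "C07-1837"), each = 2),
    which = rep(c("M1", "M2"), 5),
    mutation = c("KRAS-G12D", "PIK3CA-H1047R",
                 "KRAS-G13D", "PIK3CA-H1047R",
                 "KRAS-G12D", "PIK3CA-E542K",
                 "KRAS-G12C", "PIK3CA-H1047R",
                 "BRAF-V600E", "PIK3CA-H1047R"),
    primary = c(0.45, 0.24, 0.08, 0.07, 0.42, 0.22, 0.37, 0.21, 0.20, 0.12),
    node = c(0.44, 0.27, 0.09, 0.10, 0.34, 0.31, 0.15, 0.00, 0.22, 0.05),
    stringsAsFactors = FALSE)
}

#' Reference KRAS/PIK3CA ratio bands
#'
#' Banded counts of the KRAS-to-PIK3CA mutant-allele-fraction ratio among
#' 31 double-mutant primary tumors: 22 samples in 1.25–3.22, 7 in
#' 0.93–1.13, 2 in 0.42–0.81.
#'
#' @return data.frame with columns `n`, `lo`, `hi`.
#' @export
ref_ratio_bands <- function() {
  data.frame(n = c(22L, 7L, 2L),
             lo = c(1.25, 0.93, 0.42),
             hi = c(3.22, 1.13, 0.81))
}

#' Representative ratio set consistent with the reference bands
#'
#' Expands [ref_ratio_bands()] into one ratio per sample, spacing the values
#' evenly across each band; used where a summary needs an explicit ratio
#' vector rather than band counts.
#'
#' @return Numeric vector of length 31.
#' @export
ref_ratio_values <- function() {
  b <- ref_ratio_bands()
  unlist(lapply(seq_len(nrow(b)), function(i)
    seq(b$lo[i], b$hi[i], length.out = b$n[i])))
}

#' Reference primary / lymph-node mutation reports
#'
#' Deterministic mutation reports for the 39 profiled primary-tumor /
#' metastatic-lymph-node pairs, reconstructed from the cohort's reported
#' facts: 35 pairs with identical profiles, 4 pairs in which one mutation of
#' the primary (two BRAF, one PIK3CA, one KRAS) was absent from the node, 26
#' mutations detected in nodes overall, and no node-only mutations.
#'
#' @return List with `primary` and `node` mutation-record data.frames and
#'   `pairs` (primary_id, node_id).
#' @export
ref_node_pair_reports <- function() {
  mk <- function(id, gene, aa) data.frame(sample_id = id, gene = gene,
                                          aa_change = aa,
                                          stringsAsFactors = FALSE)
  primary <- list(); node <- list()
  add <- function(i, p_muts, n_muts) {
    pid <- sprintf("P%02d", i); nid <- sprintf("P%02d_LN", i)
    if (nrow(p_muts)) { p_muts$sample_id <- pid
      primary[[length(primary) + 1L]] <<- p_muts }
    if (nrow(n_muts)) { n_muts$sample_id <- nid
      node[[length(node) + 1L]] <<- n_muts }
  }
  none <- mk(character(0), character(0), character(0))
  # 4 discordant pairs: the node lacks one mutation of its primary
  add(1, mk("x", "BRAF", "V600E"), none)
  add(2, rbind(mk("x", "BRAF", "V600E"), mk("x", "PIK3CA", "H1047R")),
      mk("x", "PIK3CA", "H1047R"))
  add(3, rbind(mk("x", "PIK3CA", "H1047R"), mk("x", "KRAS", "G12D")),
      mk("x", "KRAS", "G12D"))
  add(4, mk("x", "KRAS", "G12D"), none)
  # 18 concordant single-mutant pairs
  singles <- c(rep("KRAS|G12D", 10), rep("PIK3CA|E545K", 4),
               rep("BRAF|V600E", 2), rep("NRAS|G12D", 2))
  for (k in seq_along(singles)) {
    ga <- strsplit(singles[k], "|", fixed = TRUE)[[1]]
    m <- mk("x", ga[1], ga[2])
    add(4 + k, m, m)
  }
  # 3 concordant double-mutant pairs
  doubles <- list(
    rbind(mk("x", "KRAS", "G12D"), mk("x", "PIK3CA", "H1047R")),
    rbind(mk("x", "KRAS", "G13D"), mk("x", "PIK3CA", "E542K")),
    rbind(mk("x", "KRAS", "G12V"), mk("x", "PIK3CA", "H1047R")))
  for (k in seq_along(doubles)) add(22 + k, doubles[[k]], doubles[[k]])
  # 14 concordant wild-type pairs (25 + 1 .. 39): no records
  primary <- do.call(rbind, primary)
  node <- do.call(rbind, node)
  list(primary = primary, node = node,
       pairs = data.frame(primary_id = sprintf("P%02d", 1:39),
                          node_id = sprintf("P%02d_LN", 1:39),
                          stringsAsFactors = FALSE))
}
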