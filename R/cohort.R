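#' Cohort mutation frequency table
#'
#' Tallies mutation records into per-amino-acid-change and per-gene counts
#' and frequencies over the cohort. Counts are distinct-sample counts. The
#' per-gene table reports both the sum of the amino-acid-change counts
#' (`n_events`) and the number of distinct mutated samples (`n_samples`);
#' the two coincide when no sample carries two mutations of the same gene.
#' `multiple_share` is, among a gene's mutant samples, the share that carry
#' at least one further mutation (in another gene or a second one in the
#' same gene).
#'
#' @param records data.frame of mutation records (`sample_id`, `gene`,
#'   `aa_change`, optionally `fraction`).
#' @param n_samples Cohort size (>= 1, and >= every per-gene sample count).
#' @return An object of class `frequency_table`: list with `by_mutation`,
#'   `by_gene` (data.frames), `overall_mutated` (distinct samples with >= 1
#'   mutation), `overall_frequency`, and `n_samples`.
#' @export
frequency_table <- function(records, n_samples) {
  stopifnot(is.data.frame(records), n_samples >= 1)
  needed <- c("sample_id", "gene", "aa_change")
  if (!all(needed %in% names(records)))
    stop("records need columns sample_id, gene, aa_change", call. = FALSE)
  if (nrow(records)) {
    per_sample <- table(records$sample_id)
    if (length(unique(records$sample_id)) > n_samples)
      stop("more distinct samples in records than n_samples", call. = FALSE)
  }
  key <- paste(records$gene, records$aa_change, sep = "|")
  by_mut <- if (nrow(records)) {
    agg <- stats::aggregate(records$sample_id,
                            by = list(gene = records$gene,
                                      aa_change = records$aa_change),
                            FUN = function(s) length(unique(s)))
    names(agg)[3] <- "n"
    agg$frequency <- agg$n / n_samples
    agg[order(agg$gene, agg$aa_change), , drop = FALSE]
  } else data.frame(gene = character(), aa_change = character(),
                    n = integer(), frequency = numeric(),
                    stringsAsFactors = FALSE)
  rownames(by_mut) <- NULL
  genes <- unique(by_mut$gene)
  by_gene <- do.call(rbind, lapply(genes, function(g) {
    rg <- records[records$gene == g, , drop = FALSE]
    samples_g <- unique(rg$sample_id)
    multi <- vapply(samples_g, function(s) {
      n_here <- nrow(records[records$sample_id == s, , drop = FALSE])
      n_here > nrow(rg[rg$sample_id == s, , drop = FALSE]) ||
        nrow(rg[rg$sample_id == s, , drop = FALSE]) > 1L
    }, logical(1))
    data.frame(gene = g,
               n_events = sum(by_mut$n[by_mut$gene == g]),
               n_samples = length(samples_g),
               frequency = length(samples_g) / n_samples,
               multiple_share = if (length(samples_g)) mean(multi) else 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_gene))
    by_gene <- data.frame(gene = character(), n_events = integer(),
                          n_samples = integer(), frequency = numeric(),
                          multiple_share = numeric(),
                          stringsAsFactors = FALSE)
  rownames(by_gene) <- NULL
  overall <- length(unique(records$sample_id))
  structure(list(by_mutation = by_mut, by_gene = by_gene,
                 overall_mutated = overall,
                 overall_frequency = overall / n_samples,
                 n_samples = n_samples),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, digits = 1, ...) {
  cat(sprintf("<frequency_table> n = %d samples, %d mutated (%.1f%%)\n",
              x$n_samples, x$overall_mutated, 100 * x$overall_frequency))
  if (nrow(x$by_gene)) {
    df <- x$by_gene
    df$frequency <- sprintf("%.*f%%", digits, 100 * df$frequency)
    df$multiple_share <- sprintf("%.0f%%", 100 * df$multiple_share)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Write a frequency table to TSV
#'
#' @param x A `frequency_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "frequency_table"))
  utils::write.table(x$by_mutation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene-pair co-occurrence against independence
#'
#' For every gene pair, the actual double-mutant frequency (distinct samples
#' mutated in both genes over the cohort size) next to the frequency
#' expected under independence — the product of the two gene-level
#' frequencies.
#'
#' @param records Mutation records data.frame.
#' @param n_samples Cohort size.
#' @param gene_freqs Optional named numeric of gene-level frequencies to use
#'   for the expected values (defaults to frequencies computed from
#'   `records`).
#' @return data.frame with columns `gene_a`, `gene_b`, `actual`, `expected`
#'   (proportions), one row per unordered pair, class `cooccurrence_table`.
#' @export
cooccurrence <- function(records, n_samples, gene_freqs = NULL) {
  ft <- frequency_table(records, n_samples)
  genes <- ft$by_gene$gene
  if (is.null(gene_freqs))
    gene_freqs <- stats::setNames(ft$by_gene$frequency, genes)
  if (length(genes) < 2L)
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                actual = numeric(), expected = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("cooccurrence_table", "data.frame")))
  samples_of <- lapply(genes, function(g)
    unique(records$sample_id[records$gene == g]))
  names(samples_of) <- genes
  pairs <- utils::combn(genes, 2)
  out <- data.frame(
    gene_a = pairs[1, ], gene_b = pairs[2, ],
    actual = apply(pairs, 2, function(p)
      length(intersect(samples_of[[p[1]]], samples_of[[p[2]]])) / n_samples),
    expected = apply(pairs, 2, function(p)
      unname(gene_freqs[p[1]] * gene_freqs[p[2]])),
    stringsAsFactors = FALSE)
  structure(out, class = c("cooccurrence_table", "data.frame"))
}

#' Expected double-mutation frequency under independence
#'
#' @param f_a,f_b Gene-level mutation frequencies (proportions).
#' @return `f_a * f_b`.
#' @export
expected_cooccurrence <- function(f_a, f_b) {
  stopifnot(all(f_a >= 0 & f_a <= 1), all(f_b >= 0 & f_b <= 1))
  f_a * f_b
}

#' Ratio of two mutant allele fractions in one sample
#'
#' Compares the clonal representation of two co-occurring mutations. When
#' the second mutation's fraction is zero (e.g. lost in a metastasis) the
#' ratio is undefined and returned as `NA` with attribute
#' `undefined = TRUE`.
#'
#' @param fraction_m1,fraction_m2 Mutant allele fractions of mutation 1
#'   and 2.
#' @return The ratio `fraction_m1 / fraction_m2`, or flagged `NA`.
#' @export
mutation_ratio <- function(fraction_m1, fraction_m2) {
  stopifnot(fraction_m1 >= 0, fraction_m2 >= 0)
  if (fraction_m2 == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  fraction_m1 / fraction_m2
}

#' Summarise a set of mutation ratios
#'
#' Counts ratios at or above a clonal-dominance threshold and bands them into
#' below-parity (< `band_breaks[1]`), near-parity, and dominant
#' (> `band_breaks[2]`) groups, alongside mean and median.
#'
#' @param ratios Finite numeric ratios.
#' @param threshold Dominance threshold (default 1.25).
#' @param band_breaks Two interior band edges (default `c(0.93, 1.25)`).
#' @return List with `n`, `n_above`, `percent_above`, `bands` (named counts),
#'   `mean`, `median`.
#' @export
ratio_summary <- function(ratios, threshold = 1.25,
                          band_breaks = c(0.93, 1.25)) {
  ratios <- ratios[!is.na(ratios)]
  stopifnot(all(is.finite(ratios)), length(band_breaks) == 2L,
            band_breaks[1] < band_breaks[2])
  bands <- table(cut(ratios, breaks = c(-Inf, band_breaks, Inf),
                     labels = c("below", "near_parity", "dominant"),
                     right = FALSE))
  list(n = length(ratios),
       n_above = sum(ratios >= threshold),
       percent_above = 100 * sum(ratios >= threshold) / length(ratios),
       bands = as.vector(bands) |> stats::setNames(names(bands)),
       mean = mean(ratios), median = stats::median(ratios))
}

#' Primary tumor / lymph-node concordance
#'
#' Pairs a primary tumor's mutation report with its node's; a pair is
#' concordant when the two mutation sets (gene plus amino-acid change) are
#' identical. Also lists mutations seen only in the primary or only in the
#' node of discordant pairs.
#'
#' @param primary_records,node_records Mutation record data.frames.
#' @param pairs data.frame with columns `primary_id`, `node_id` defining the
#'   pairing.
#' @return An object of class `concordance_report`: list with `n_pairs`,
#'   `n_identical`, `percent_concordant`, `primary_only` and `node_only`
#'   (data.frames of mutations), `discordant_pairs`.
#' @export
concordance <- function(primary_records, node_records, pairs) {
  stopifnot(all(c("primary_id", "node_id") %in% names(pairs)))
  miss_p <- setdiff(pairs$primary_id, primary_records$sample_id)
  miss_n <- setdiff(pairs$node_id, node_records$sample_id)
  # ids absent from the records simply have empty mutation sets; but ids in
  # the records that are never paired indicate a bookkeeping error
  unpaired <- union(setdiff(unique(primary_records$sample_id),
                            pairs$primary_id),
                    setdiff(unique(node_records$sample_id), pairs$node_id))
  if (length(unpaired))
    stop(sprintf("unpaired sample ids in records: %s",
                 paste(unpaired, collapse = ", ")), call. = FALSE)
  mut_set <- function(records, id) {
    r <- records[records$sample_id == id, , drop = FALSE]
    sort(paste(r$gene, r$aa_change, sep = "-"))
  }
  identical_pair <- logical(nrow(pairs))
  p_only <- list(); n_only <- list()
  for (i in seq_len(nrow(pairs))) {
    sp <- mut_set(primary_records, pairs$primary_id[i])
    sn <- mut_set(node_records, pairs$node_id[i])
    identical_pair[i] <- identical(sp, sn)
    if (!identical_pair[i]) {
      po <- setdiff(sp, sn); no <- setdiff(sn, sp)
      if (length(po))
        p_only[[length(p_only) + 1L]] <- data.frame(
          primary_id = pairs$primary_id[i], mutation = po,
          stringsAsFactors = FALSE)
      if (length(no))
        n_only[[length(n_only) + 1L]] <- data.frame(
          node_id = pairs$node_id[i], mutation = no,
          stringsAsFactors = FALSE)
    }
  }
  structure(
    list(n_pairs = nrow(pairs),
         n_identical = sum(identical_pair),
         percent_concordant = 100 * sum(identical_pair) / nrow(pairs),
         primary_only = do.call(rbind, p_only) %||%
           data.frame(primary_id = character(), mutation = character(),
                      stringsAsFactors = FALSE),
         node_only = do.call(rbind, n_only) %||%
           data.frame(node_id = character(), mutation = character(),
                      stringsAsFactors = FALSE),
         discordant_pairs = pairs[!identical_pair, , drop = FALSE]),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d/%d pairs identical (%.1f%% concordant)\n",
    x$n_identical, x$n_pairs, x$percent_concordant))
  if (nrow(x$primary_only))
    cat(sprintf("  primary-only mutations: %s\n",
                paste(x$primary_only$mutation, collapse = ", ")))
  if (nrow(x$node_only))
    cat(sprintf("  node-only mutations: %s\n",
                paste(x$node_only$mutation, collapse = ", ")))
  invisible(x)
}

#' Pearson chi-square association test for a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom, by default without the
#' Yates continuity correction; the corrected variant is available behind
#' `correct = TRUE`. No multiple-testing correction is applied.
#'
#' @param table 2x2 matrix of nonnegative counts with positive marginals.
#' @param correct Apply the Yates continuity correction? (default FALSE)
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chisq_association <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Select assays by observed mutation frequency
#'
#' Keeps, at `level = "assay"`, the assays whose interrogated mutations sum
#' to at least `threshold` frequency in the table; at `level = "gene"`, all
#' assays of genes whose total frequency reaches the threshold. This is the
#' frequency-driven panel-reduction step that precedes [replex()].
#'
#' @param freq_table A [frequency_table()].
#' @param panel An [sbe_panel()].
#' @param level `"assay"` or `"gene"`.
#' @param threshold Frequency threshold in (0, 1\] (default 0.01). A mutation
#'   frequency `>= threshold` keeps the assay/gene.
#' @return Character vector of selected assay ids, in panel order.
#' @export
select_assays <- function(freq_table, panel, level = c("gene", "assay"),
                          threshold = 0.01) {
  level <- match.arg(level)
  stopifnot(inherits(freq_table, "frequency_table"),
            inherits(panel, "sbe_panel"), threshold > 0, threshold <= 1)
  keep <- vapply(panel$assays, function(a) {
    if (level == "gene") {
      g <- freq_table$by_gene
      any(g$gene == a$gene & g$frequency >= threshold)
    } else {
      bm <- freq_table$by_mutation
      f <- sum(bm$frequency[bm$gene == a$gene &
                              bm$aa_change %in% a$mut_alleles])
      f >= threshold
    }
  }, logical(1))
  names(panel$assays)[keep]
}
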