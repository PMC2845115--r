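# Independent oracles and small fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-character summation oracle for oligo masses, written independently of
# oligo_mass(): explicit loop, no vectorised lookup.
oracle_oligo_mass <- function(sequence, mt) {
  total <- mt$terminal_adjustment
  if (nchar(sequence) == 0) return(total)
  for (ch in strsplit(sequence, "")[[1]]) {
    total <- total + switch(ch,
                            A = mt$residue_mass[["A"]],
                            C = mt$residue_mass[["C"]],
                            G = mt$residue_mass[["G"]],
                            T = mt$residue_mass[["T"]])
  }
  total
}

# All-pairs brute-force conflict oracle: enumerates every cross-assay mass
# pair (optionally adduct-shifted vs plain) and counts |gap| < min_gap.
oracle_pool_conflicts <- function(assays, mt, min_gap,
                                  include_adducts = FALSE) {
  plain <- list()
  for (a in assays) {
    uep <- oracle_oligo_mass(a$primer_seq, mt)
    m <- uep
    for (b in c(a$wt_base, names(a$mut_alleles)))
      m <- c(m, uep + mt$terminator_mass[[b]])
    plain[[a$assay_id]] <- m
  }
  shifted <- lapply(plain, function(m) {
    out <- numeric()
    for (s in mt$adduct_shifts) out <- c(out, m + s)
    out
  })
  hits <- 0L
  ids <- names(plain)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    for (x in plain[[ids[i]]]) for (y in plain[[ids[j]]])
      if (abs(x - y) < min_gap) hits <- hits + 1L
    if (include_adducts) {
      for (x in shifted[[ids[i]]]) for (y in plain[[ids[j]]])
        if (abs(x - y) < min_gap) hits <- hits + 1L
      for (x in plain[[ids[i]]]) for (y in shifted[[ids[j]]])
        if (abs(x - y) < min_gap) hits <- hits + 1L
    }
  }
  hits
}

# Mutation records realising a per-mutation count table: each gene's events
# get distinct samples within the gene (so gene totals equal count sums).
records_from_counts <- function(counts) {
  rows <- list()
  for (g in unique(counts$gene)) {
    cg <- counts[counts$gene == g, , drop = FALSE]
    next_id <- 1L
    for (r in seq_len(nrow(cg))) {
      ids <- sprintf("S%03d", seq(next_id, length.out = cg$n[r]))
      next_id <- next_id + cg$n[r]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids, gene = g, aa_change = cg$aa_change[r],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Small assay factory with sensible defaults.
make_assay <- function(assay_id = "TEST_1", gene = "KRAS",
                       aa_label = "G12",
                       primer_seq = "ACGTACGTACGTACGTA",
                       wt_base = "G", mut_alleles = c(A = "G12D"), ...) {
  sbe_assay(assay_id, gene, aa_label, primer_seq, wt_base, mut_alleles, ...)
}

# A deterministic primer of given length (no RNG involved).
det_primer <- function(len, phase = 0) {
  paste(c("A", "C", "G", "T")[((seq_len(len) * 3 + phase) %% 4) + 1],
        collapse = "")
}

make_two_pool_panel <- function() {
  a1 <- make_assay("A_1", "KRAS", "G12", det_primer(17))
  a2 <- make_assay("A_2", "BRAF", "V600", det_primer(21, 1), wt_base = "T",
                   mut_alleles = c(A = "V600E"))
  a3 <- make_assay("A_3", "PIK3CA", "H1047", det_primer(25, 2),
                   wt_base = "A", mut_alleles = c(G = "H1047R"))
  sbe_panel("toy", list(a1, a2, a3),
            pools = list(pool1 = c("A_1", "A_2"), pool2 = "A_3"))
}

# Synthetic trace made of Gaussian peaks on a flat baseline; independent of
# render_spectrum().
gauss_spectrum <- function(centers, areas, sd = 1.5, baseline = 0,
                           from = min(centers) - 50, to = max(centers) + 50,
                           step = 0.3, sample_id = "synthetic",
                           pool_id = "synthetic") {
  grid <- seq(from, to, by = step)
  y <- rep(baseline, length(grid))
  for (k in seq_along(centers))
    y <- y + areas[k] * stats::dnorm(grid, centers[k], sd)
  structure(list(sample_id = sample_id, pool_id = pool_id,
                 mass = grid, intensity = y), class = "maldi_spectrum")
}

# Trapezoidal integral oracle over the whole grid.
oracle_trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Random assay sets for replexing tests: random primers give irregularly
# spaced masses; a large min_gap then yields non-trivial conflict graphs.
random_assays <- function(n, seed, min_len = 15, max_len = 24) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    make_assay(sprintf("R_%02d", i), "GENE", "X1",
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
  })
}
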