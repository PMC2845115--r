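#' Built-in colon hotspot assay set
#'
#' The 25 SBE assays covering the hotspot mutations detected at >= 1%
#' frequency in the reference colon-cancer cohort (see
#' [ref_mutation_counts()]): KRAS codons 12 (complex pair), 13, 59, 61;
#' BRAF 594 and the codon-600 complex pair; the NRAS codon 12/13/61 assays;
#' the two MET juxtamembrane mutations (short-isoform numbering, long-form
#' labels carried as aliases); the PIK3CA hotspots; and HRAS Q61 (carried
#' with a note — no HRAS mutation was observed in the reference cohort).
#' Primer sequences are synthetic stand-ins (the commercial assay sequences
#' are proprietary and unpublished), chosen to spread the analyte masses
#' over the working 4.9–9.7 kDa range.
#'
#' @return List of [sbe_assay()] objects.
#' @export
colon_hotspot_assays <- function() {
  A <- sbe_assay
  list(
    A("BRAF_9", "BRAF", "D594", "TTGCCAGGTGCTTCTG", "A",
      c(T = "D594V", G = "D594G")),
    A("BRAF_15", "BRAF", "V600", "TGATATGTAAACTAGCTCAAATGGT", "G",
      c(T = "V600L", C = "V600L"), complex_group = "BRAF_V600",
      codon_pos = 1, codon_ref = "GTG", kind = "complex"),
    A("BRAF_16", "BRAF", "V600", "GGTGTGATATGAAGTCAAGC", "T",
      c(A = "V600E"), complex_group = "BRAF_V600",
      codon_pos = 2, codon_ref = "GTG", kind = "complex"),
    A("HRAS_6", "HRAS", "Q61", "TTGAGTCTTAGAGCAAG", "A",
      c(T = "Q61L"), note = "no HRAS mutation observed in reference cohort"),
    A("KRAS_1", "KRAS", "G12", "GAAGTGTCTTAACAGTGC", "G",
      c(T = "G12C", A = "G12S", C = "G12R"), complex_group = "KRAS_G12",
      codon_pos = 1, codon_ref = "GGT", kind = "complex"),
    A("KRAS_2", "KRAS", "G12", "TCTGAGACGCGTGTGTGATTACA", "G",
      c(T = "G12V", C = "G12A", A = "G12D"), complex_group = "KRAS_G12",
      codon_pos = 2, codon_ref = "GGT", kind = "complex"),
    A("KRAS_4", "KRAS", "G13", "TCATACTAGCGCGGGTTGTAAATGTTGAC", "G",
      c(A = "G13D")),
    A("KRAS_5", "KRAS", "A59", "CGGCCCTCAGAGGAGTAGGGCTCCCAGGAC", "G",
      c(A = "A59T")),
    A("KRAS_7", "KRAS", "Q61", "AGCTCAGCGGCAATGGGGA", "A",
      c(T = "Q61L", G = "Q61R")),
    A("KRAS_8", "KRAS", "Q61", "CGCTCCTGGAACTCACAGCTCG", "A",
      c(C = "Q61H", T = "Q61H")),
    A("MET_1", "MET", "R970", "TCGAATAACAGTAGCAA", "C",
      c(T = "R970C"), aliases = c(long_isoform = "R988C")),
    A("MET_2", "MET", "T992", "TACTTTCATCGAGTTGTGCAG", "C",
      c(T = "T992I"), aliases = c(long_isoform = "T1010I")),
    A("NRAS_1", "NRAS", "G12", "TGAGAGGGATGTTAGGAA", "G",
      c(T = "G12V", C = "G12A", A = "G12D")),
    A("NRAS_2", "NRAS", "G12", "TGGGTTGTGATTATCTCGATTTCGGCCG", "G",
      c(T = "G12C", C = "G12R", A = "G12S")),
    A("NRAS_3", "NRAS", "G13", "CCGAGTGCCAGGGCCAATACTAAA", "G",
      c(T = "G13V", C = "G13A", A = "G13D")),
    A("NRAS_4", "NRAS", "G13", "ACCGGATTAGGAAAGTTAGGTC", "G",
      c(T = "G13C", C = "G13R", A = "G13S")),
    A("NRAS_7", "NRAS", "Q61", "AATGCCATTGTTTCCTTGGTTGT", "A",
      c(T = "Q61H", C = "Q61H")),
    A("NRAS_8", "NRAS", "Q61", "GCGACCACCTTGGATACACC", "C",
      c(G = "Q61E", A = "Q61K")),
    A("PIK3CA_1", "PIK3CA", "R88", "CTCAGACCCGTCTCTTGTCGCCAAA", "G",
      c(A = "R88Q")),
    A("PIK3CA_3", "PIK3CA", "C420", "TTCGACCTATACGAGCGTCTGGGCTG", "T",
      c(C = "C420R")),
    A("PIK3CA_5", "PIK3CA", "E542", "TAGCGCCTTAGACGAAGATAACAA", "G",
      c(A = "E542K")),
    A("PIK3CA_6", "PIK3CA", "E545", "GAGAGACAGTACAGTCGGGCA", "G",
      c(A = "E545K")),
    A("PIK3CA_7", "PIK3CA", "Q546", "GGTATAAAAAGTGAGCCGC", "C",
      c(A = "Q546K")),
    A("PIK3CA_8", "PIK3CA", "H701", "TCCTAAGGGGCCTAGG", "A",
      c(C = "H701P")),
    A("PIK3CA_9", "PIK3CA", "H1047", "CTAATATTCTGTTTAGGGTACAATTGT", "A",
      c(G = "H1047R", T = "H1047L")))
}

#' Built-in colon hotspot panel
#'
#' The [colon_hotspot_assays()] pooled by the package's own [replex()] with
#' adduct-aware conflict checking (`include_adducts = TRUE`), so that no
#' salt satellite of one assay can alias an allele peak of another within a
#' pool.
#'
#' @param max_plex Maximum pool size (default 9).
#' @param min_gap Minimum cross-assay analyte gap in Da (default 16).
#' @return An [sbe_panel()].
#' @export
colon_hotspot_panel <- function(max_plex = 9, min_gap = 16) {
  replex(colon_hotspot_assays(), default_mass_table(),
         max_plex = max_plex, min_gap = min_gap, include_adducts = TRUE,
         name = "colon_hotspot")
}
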