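{
  "name": "colon_hotspot",
  "max_plex": 9,
  "mass_table": {
    "residue_mass": {
      "A": 313.21,
      "C": 289.18,
      "G": 329.21,
      "T": 304.2
    },
    "terminator_mass": {
      "A": 329.4,
      "C": 271.2,
      "G": 344.4,
      "T": 301.2
    },
    "terminal_adjustment": 18.02,
    "adduct_shifts": {
      "Na": 21.98,
      "K": 37.95
    }
  },
  "pools": {
    "plex1": [
      {
        "assay_id": "HRAS_6",
        "gene": "HRAS",
        "aa_label": "Q61",
        "primer_seq": "TTGAGTCTTAGAGCAAG",
        "wt_base": "A",
        "mut_alleles": {
          "T": "Q61L"
        },
        "kind": "simple",
        "note": "no HRAS mutation observed in reference cohort"
      },
      {
        "assay_id": "KRAS_2",
        "gene": "KRAS",
        "aa_label": "G12",
        "primer_seq": "TCTGAGACGCGTGTGTGATTACA",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G12V",
          "C": "G12A",
          "A": "G12D"
        },
        "kind": "complex",
        "complex_group": "KRAS_G12",
        "codon_pos": 2,
        "codon_ref": "GGT"
      },
      {
        "assay_id": "KRAS_7",
        "gene": "KRAS",
        "aa_label": "Q61",
        "primer_seq": "AGCTCAGCGGCAATGGGGA",
        "wt_base": "A",
        "mut_alleles": {
          "T": "Q61L",
          "G": "Q61R"
        },
        "kind": "simple"
      },
      {
        "assay_id": "BRAF_15",
        "gene": "BRAF",
        "aa_label": "V600",
        "primer_seq": "TGATATGTAAACTAGCTCAAATGGT",
        "wt_base": "G",
        "mut_alleles": {
          "T": "V600L",
          "C": "V600L"
        },
        "kind": "complex",
        "complex_group": "BRAF_V600",
        "codon_pos": 1,
        "codon_ref": "GTG"
      },
      {
        "assay_id": "KRAS_8",
        "gene": "KRAS",
        "aa_label": "Q61",
        "primer_seq": "CGCTCCTGGAACTCACAGCTCG",
        "wt_base": "A",
        "mut_alleles": {
          "C": "Q61H",
          "T": "Q61H"
        },
        "kind": "simple"
      },
      {
        "assay_id": "KRAS_4",
        "gene": "KRAS",
        "aa_label": "G13",
        "primer_seq": "TCATACTAGCGCGGGTTGTAAATGTTGAC",
        "wt_base": "G",
        "mut_alleles": {
          "A": "G13D"
        },
        "kind": "simple"
      },
      {
        "assay_id": "NRAS_8",
        "gene": "NRAS",
        "aa_label": "Q61",
        "primer_seq": "GCGACCACCTTGGATACACC",
        "wt_base": "C",
        "mut_alleles": {
          "G": "Q61E",
          "A": "Q61K"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_9",
        "gene": "PIK3CA",
        "aa_label": "H1047",
        "primer_seq": "CTAATATTCTGTTTAGGGTACAATTGT",
        "wt_base": "A",
        "mut_alleles": {
          "G": "H1047R",
          "T": "H1047L"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_1",
        "gene": "PIK3CA",
        "aa_label": "R88",
        "primer_seq": "CTCAGACCCGTCTCTTGTCGCCAAA",
        "wt_base": "G",
        "mut_alleles": {
          "A": "R88Q"
        },
        "kind": "simple"
      }
    ],
    "plex2": [
      {
        "assay_id": "KRAS_1",
        "gene": "KRAS",
        "aa_label": "G12",
        "primer_seq": "GAAGTGTCTTAACAGTGC",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G12C",
          "A": "G12S",
          "C": "G12R"
        },
        "kind": "complex",
        "complex_group": "KRAS_G12",
        "codon_pos": 1,
        "codon_ref": "GGT"
      },
      {
        "assay_id": "NRAS_3",
        "gene": "NRAS",
        "aa_label": "G13",
        "primer_seq": "CCGAGTGCCAGGGCCAATACTAAA",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G13V",
          "C": "G13A",
          "A": "G13D"
        },
        "kind": "simple"
      },
      {
        "assay_id": "BRAF_16",
        "gene": "BRAF",
        "aa_label": "V600",
        "primer_seq": "GGTGTGATATGAAGTCAAGC",
        "wt_base": "T",
        "mut_alleles": {
          "A": "V600E"
        },
        "kind": "complex",
        "complex_group": "BRAF_V600",
        "codon_pos": 2,
        "codon_ref": "GTG"
      },
      {
        "assay_id": "BRAF_9",
        "gene": "BRAF",
        "aa_label": "D594",
        "primer_seq": "TTGCCAGGTGCTTCTG",
        "wt_base": "A",
        "mut_alleles": {
          "T": "D594V",
          "G": "D594G"
        },
        "kind": "simple"
      },
      {
        "assay_id": "NRAS_1",
        "gene": "NRAS",
        "aa_label": "G12",
        "primer_seq": "TGAGAGGGATGTTAGGAA",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G12V",
          "C": "G12A",
          "A": "G12D"
        },
        "kind": "simple"
      },
      {
        "assay_id": "MET_2",
        "gene": "MET",
        "aa_label": "T992",
        "primer_seq": "TACTTTCATCGAGTTGTGCAG",
        "wt_base": "C",
        "mut_alleles": {
          "T": "T992I"
        },
        "kind": "simple",
        "aliases": {
          "long_isoform": "T1010I"
        }
      },
      {
        "assay_id": "NRAS_2",
        "gene": "NRAS",
        "aa_label": "G12",
        "primer_seq": "TGGGTTGTGATTATCTCGATTTCGGCCG",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G12C",
          "C": "G12R",
          "A": "G12S"
        },
        "kind": "simple"
      },
      {
        "assay_id": "NRAS_4",
        "gene": "NRAS",
        "aa_label": "G13",
        "primer_seq": "ACCGGATTAGGAAAGTTAGGTC",
        "wt_base": "G",
        "mut_alleles": {
          "T": "G13C",
          "C": "G13R",
          "A": "G13S"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_3",
        "gene": "PIK3CA",
        "aa_label": "C420",
        "primer_seq": "TTCGACCTATACGAGCGTCTGGGCTG",
        "wt_base": "T",
        "mut_alleles": {
          "C": "C420R"
        },
        "kind": "simple"
      }
    ],
    "plex3": [
      {
        "assay_id": "MET_1",
        "gene": "MET",
        "aa_label": "R970",
        "primer_seq": "TCGAATAACAGTAGCAA",
        "wt_base": "C",
        "mut_alleles": {
          "T": "R970C"
        },
        "kind": "simple",
        "aliases": {
          "long_isoform": "R988C"
        }
      },
      {
        "assay_id": "NRAS_7",
        "gene": "NRAS",
        "aa_label": "Q61",
        "primer_seq": "AATGCCATTGTTTCCTTGGTTGT",
        "wt_base": "A",
        "mut_alleles": {
          "T": "Q61H",
          "C": "Q61H"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_7",
        "gene": "PIK3CA",
        "aa_label": "Q546",
        "primer_seq": "GGTATAAAAAGTGAGCCGC",
        "wt_base": "C",
        "mut_alleles": {
          "A": "Q546K"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_6",
        "gene": "PIK3CA",
        "aa_label": "E545",
        "primer_seq": "GAGAGACAGTACAGTCGGGCA",
        "wt_base": "G",
        "mut_alleles": {
          "A": "E545K"
        },
        "kind": "simple"
      },
      {
        "assay_id": "KRAS_5",
        "gene": "KRAS",
        "aa_label": "A59",
        "primer_seq": "CGGCCCTCAGAGGAGTAGGGCTCCCAGGAC",
        "wt_base": "G",
        "mut_alleles": {
          "A": "A59T"
        },
        "kind": "simple"
      }
    ],
    "plex4": [
      {
        "assay_id": "PIK3CA_5",
        "gene": "PIK3CA",
        "aa_label": "E542",
        "primer_seq": "TAGCGCCTTAGACGAAGATAACAA",
        "wt_base": "G",
        "mut_alleles": {
          "A": "E542K"
        },
        "kind": "simple"
      },
      {
        "assay_id": "PIK3CA_8",
        "gene": "PIK3CA",
        "aa_label": "H701",
        "primer_seq": "TCCTAAGGGGCCTAGG",
        "wt_base": "A",
        "mut_alleles": {
          "C": "H701P"
        },
        "kind": "simple"
      }
    ]
  }
}
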