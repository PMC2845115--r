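#' Define a single-base-extension assay
#'
#' An SBE assay extends a primer annealed immediately 5' of the interrogated
#' base by exactly one chain-terminating nucleotide; the incorporated base —
#' and therefore the mass of the extension product — reports the allele.
#' A *simple* assay resolves all amino-acid changes at its codon by itself; a
#' *complex* assay is a member of a group of sub-assays that interrogate
#' different nucleotide positions of one codon and must be combined (see
#' [resolve_complex()]) to name the amino-acid change.
#'
#' @param assay_id Unique assay identifier within a panel.
#' @param gene Gene symbol.
#' @param aa_label Amino-acid position label, e.g. `"G12"` (wild-type residue
#'   plus 1-based protein coordinate in the isoform named by the panel).
#' @param primer_seq Extension primer, 5'→3', over `A`,`C`,`G`,`T`, length
#'   >= 15.
#' @param wt_base Wild-type base at the interrogated position on the assayed
#'   strand.
#' @param mut_alleles Named character: mutant base → amino-acid-change label
#'   (e.g. `c(T = "G12V")`). 1–3 entries; must not contain `wt_base`.
#' @param complex_group Optional group id linking the sub-assays of one codon.
#' @param codon_pos Position (1–3) of the interrogated base within the codon;
#'   required for complex assays.
#' @param codon_ref Wild-type codon (3 bases, assayed strand); required for
#'   complex assays, used by [resolve_complex()].
#' @param kind `"simple"` or `"complex"`.
#' @param aliases Optional named character of alternative labels (e.g.
#'   long-isoform protein coordinates) carried as metadata.
#' @param note Optional free-text flag.
#' @return An object of class `sbe_assay`.
#' @export
sbe_assay <- function(assay_id, gene, aa_label, primer_seq, wt_base,
                      mut_alleles, complex_group = NULL, codon_pos = NULL,
                      codon_ref = NULL, kind = c("simple", "complex"),
                      aliases = NULL, note = NULL) {
  kind <- match.arg(kind)
  bases <- c("A", "C", "G", "T")
  primer_seq <- toupper(primer_seq)
  stopifnot(is.character(assay_id), nzchar(assay_id),
            is.character(gene), is.character(aa_label))
  chars <- strsplit(primer_seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% bases)
  if (length(bad))
    stop(invalid_sequence_error(chars[bad[1]], bad[1]))
  if (nchar(primer_seq) < 15)
    stop("primer length must be >= 15", call. = FALSE)
  if (!wt_base %in% bases)
    stop(sprintf("wt_base '%s' is not one of A, C, G, T", wt_base),
         call. = FALSE)
  mut_alleles <- unlist(mut_alleles)
  if (length(mut_alleles) < 1L || length(mut_alleles) > 3L)
    stop("mut_alleles must have 1-3 entries", call. = FALSE)
  if (!all(names(mut_alleles) %in% bases))
    stop("mut_alleles must be named by bases A, C, G, T", call. = FALSE)
  if (wt_base %in% names(mut_alleles))
    stop("wt_base must not appear among mut_alleles", call. = FALSE)
  if (kind == "complex") {
    if (is.null(complex_group))
      stop("complex assays require a complex_group", call. = FALSE)
    if (is.null(codon_pos) || !codon_pos %in% 1:3)
      stop("complex assays require codon_pos in 1:3", call. = FALSE)
    if (is.null(codon_ref) || nchar(codon_ref) != 3L)
      stop("complex assays require a 3-base codon_ref", call. = FALSE)
    codon_ref <- toupper(codon_ref)
    if (substr(codon_ref, codon_pos, codon_pos) != wt_base)
      stop("codon_ref must carry wt_base at codon_pos", call. = FALSE)
  }
  structure(
    list(assay_id = assay_id, gene = gene, aa_label = aa_label,
         primer_seq = primer_seq, wt_base = wt_base,
         mut_alleles = mut_alleles, complex_group = complex_group,
         codon_pos = if (is.null(codon_pos)) NA_integer_ else
           as.integer(codon_pos),
         codon_ref = codon_ref,
         kind = kind, aliases = aliases, note = note),
    class = "sbe_assay")
}

#' @export
print.sbe_assay <- function(x, ...) {
  cat(sprintf("<sbe_assay> %s  %s %s  (%s)\n", x$assay_id, x$gene,
              x$aa_label, x$kind))
  cat(sprintf("  primer: %s (%d nt)\n", x$primer_seq, nchar(x$primer_seq)))
  cat(sprintf("  wt %s; mutants: %s\n", x$wt_base,
              paste(sprintf("%s=%s", names(x$mut_alleles), x$mut_alleles),
                    collapse = ", ")))
  if (!is.null(x$complex_group))
    cat(sprintf("  complex group %s, codon position %d\n",
                x$complex_group, x$codon_pos))
  invisible(x)
}

#' Expected analytes of an assay
#'
#' Every assay contributes one unextended-primer (UEP) analyte plus one
#' extension product per interrogated allele (the wild type and each mutant),
#' whose mass is the UEP mass plus the corresponding terminator mass.
#'
#' @param assay An [sbe_assay()].
#' @param mass_table A [mass_table()].
#' @return A data.frame with columns `assay_id`, `label` (`"UEP"` or a base),
#'   `mass` (Da) and `role` (`unextended`, `wt_extension`, `mut_extension`),
#'   ordered UEP, wild type, then mutants by base.
#' @export
analytes_for <- function(assay, mass_table = default_mass_table()) {
  stopifnot(inherits(assay, "sbe_assay"), inherits(mass_table, "mass_table"))
  uep <- oligo_mass(assay$primer_seq, mass_table)
  mut_bases <- sort(names(assay$mut_alleles))
  data.frame(
    assay_id = assay$assay_id,
    label = c("UEP", assay$wt_base, mut_bases),
    mass = c(uep,
             uep + mass_table$terminator_mass[[assay$wt_base]],
             uep + unname(mass_table$terminator_mass[mut_bases])),
    role = c("unextended", "wt_extension",
             rep("mut_extension", length(mut_bases))),
    stringsAsFactors = FALSE)
}

#' Assemble a validated panel
#'
#' @param name Panel name.
#' @param assays List of [sbe_assay()] objects.
#' @param pools Named list: pool id → character vector of assay ids. Every
#'   assay must appear in exactly one pool.
#' @param mass_table A [mass_table()].
#' @param max_plex Maximum pool size (default 9).
#' @return An object of class `sbe_panel`.
#' @export
sbe_panel <- function(name, assays, pools, mass_table = default_mass_table(),
                      max_plex = 9) {
  stopifnot(is.list(assays), length(assays) >= 1L,
            inherits(mass_table, "mass_table"))
  ok <- vapply(assays, inherits, logical(1), "sbe_assay")
  if (!all(ok)) stop("assays must all be sbe_assay objects", call. = FALSE)
  ids <- vapply(assays, `[[`, character(1), "assay_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(panel_error("duplicate_assay_id",
                     sprintf("duplicate assay_id: %s",
                             paste(unique(dup), collapse = ", "))))
  names(assays) <- ids
  if (is.null(names(pools)) || any(!nzchar(names(pools))))
    stop(panel_error("invalid_pool", "pools must be a named list"))
  pooled <- unlist(pools, use.names = FALSE)
  if (anyDuplicated(pooled))
    stop(panel_error("assay_in_multiple_pools",
                     sprintf("assay in more than one pool: %s",
                             paste(unique(pooled[duplicated(pooled)]),
                                   collapse = ", "))))
  unknown <- setdiff(pooled, ids)
  if (length(unknown))
    stop(panel_error("unknown_assay",
                     sprintf("pool references unknown assay: %s",
                             paste(unknown, collapse = ", "))))
  missing_pool <- setdiff(ids, pooled)
  if (length(missing_pool))
    stop(panel_error("unpooled_assay",
                     sprintf("assay not assigned to any pool: %s",
                             paste(missing_pool, collapse = ", "))))
  sizes <- lengths(pools)
  if (any(sizes < 1L) || any(sizes > max_plex))
    stop(panel_error("pool_size",
                     sprintf("pool sizes must lie in [1, %d]; got %s",
                             max_plex, paste(sizes, collapse = ", "))))
  groups <- unlist(lapply(assays, function(a)
    if (is.null(a$complex_group)) NULL else a$complex_group))
  for (g in unique(groups)) {
    members <- ids[vapply(assays, function(a)
      identical(a$complex_group, g), logical(1))]
    if (length(members) < 2L)
      stop(panel_error("complex_group",
                       sprintf("complex_group '%s' has a single member (%s)",
                               g, members)))
  }
  structure(
    list(name = name, assays = assays, pools = pools,
         mass_table = mass_table, max_plex = max_plex),
    class = "sbe_panel")
}

panel_error <- function(subclass, message) {
  structure(
    class = c(paste0("hotplex_", subclass), "hotplex_panel_error",
              "error", "condition"),
    list(message = message, call = NULL))
}

#' @export
print.sbe_panel <- function(x, ...) {
  cat(sprintf("<sbe_panel> %s: %d assays in %d pools (max plex %d)\n",
              x$name, length(x$assays), length(x$pools), x$max_plex))
  for (p in names(x$pools))
    cat(sprintf("  %s [%d]: %s\n", p, length(x$pools[[p]]),
                paste(x$pools[[p]], collapse = ", ")))
  invisible(x)
}

#' All analytes of a panel (optionally one pool)
#'
#' @param panel An [sbe_panel()].
#' @param pool_id Optional pool id; default all assays.
#' @return data.frame as in [analytes_for()], row-bound over assays.
#' @export
panel_analytes <- function(panel, pool_id = NULL) {
  stopifnot(inherits(panel, "sbe_panel"))
  ids <- if (is.null(pool_id)) names(panel$assays) else {
    if (!pool_id %in% names(panel$pools))
      stop(sprintf("unknown pool '%s'", pool_id), call. = FALSE)
    panel$pools[[pool_id]]
  }
  do.call(rbind, lapply(panel$assays[ids], analytes_for,
                        mass_table = panel$mass_table))
}

#' Load a panel from its JSON description
#'
#' The file lays out `name`, an optional `max_plex`, an optional embedded
#' `mass_table`, and `pools` as a map from pool id to a list of assay
#' records with the fields of [sbe_assay()]. All [sbe_panel()] invariants are
#' checked; violations raise named validation errors
#' (`hotplex_duplicate_assay_id`, `hotplex_pool_size`, ...).
#'
#' @param path Path to a panel JSON file.
#' @param mass_table A [mass_table()] used when the file embeds none.
#' @return An [sbe_panel()].
#' @export
load_panel <- function(path, mass_table = default_mass_table()) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$name) || is.null(x$pools))
    stop(panel_error("invalid_panel_file",
                     "panel file must contain 'name' and 'pools'"))
  mt <- if (!is.null(x$mass_table)) {
    m <- x$mass_table
    mass_table(residue_mass = unlist(m$residue_mass),
               terminator_mass = unlist(m$terminator_mass),
               terminal_adjustment = m$terminal_adjustment,
               adduct_shifts = unlist(m$adduct_shifts))
  } else mass_table
  assays <- list()
  pools <- list()
  for (pool_id in names(x$pools)) {
    recs <- x$pools[[pool_id]]
    pools[[pool_id]] <- vapply(recs, function(r) r$assay_id, character(1))
    for (r in recs) {
      assays[[length(assays) + 1L]] <- sbe_assay(
        assay_id = r$assay_id, gene = r$gene, aa_label = r$aa_label,
        primer_seq = r$primer_seq, wt_base = r$wt_base,
        mut_alleles = unlist(r$mut_alleles),
        complex_group = r$complex_group,
        codon_pos = r$codon_pos,
        codon_ref = r$codon_ref,
        kind = if (is.null(r$kind)) "simple" else r$kind,
        aliases = if (is.null(r$aliases)) NULL else unlist(r$aliases),
        note = r$note)
    }
  }
  groups <- unique(unlist(lapply(assays, `[[`, "complex_group")))
  sbe_panel(name = x$name, assays = assays, pools = pools, mass_table = mt,
            max_plex = if (is.null(x$max_plex)) 9 else x$max_plex)
}

#' Write a panel to JSON / TSV
#'
#' `write_panel()` emits the JSON consumed by [load_panel()] (round-trip
#' identity on the structured content). `panel_tsv()` writes one row per
#' assay for human review.
#'
#' @param panel An [sbe_panel()].
#' @param path Output file path.
#' @return `path`, invisibly (`panel_tsv` returns the data.frame invisibly).
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "sbe_panel"))
  pools <- lapply(panel$pools, function(ids)
    lapply(panel$assays[ids], function(a) {
      r <- list(assay_id = a$assay_id, gene = a$gene, aa_label = a$aa_label,
                primer_seq = a$primer_seq, wt_base = a$wt_base,
                mut_alleles = as.list(a$mut_alleles), kind = a$kind)
      if (!is.null(a$complex_group)) {
        r$complex_group <- a$complex_group
        r$codon_pos <- a$codon_pos
        r$codon_ref <- a$codon_ref
      }
      if (!is.null(a$aliases)) r$aliases <- as.list(a$aliases)
      if (!is.null(a$note)) r$note <- a$note
      r
    }))
  pools <- lapply(pools, unname)
  mt <- panel$mass_table
  jsonlite::write_json(
    list(name = panel$name, max_plex = panel$max_plex,
         mass_table = list(residue_mass = as.list(mt$residue_mass),
                           terminator_mass = as.list(mt$terminator_mass),
                           terminal_adjustment = mt$terminal_adjustment,
                           adduct_shifts = as.list(mt$adduct_shifts)),
         pools = pools),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "sbe_panel"))
  pool_of <- rep(names(panel$pools), lengths(panel$pools))
  names(pool_of) <- unlist(panel$pools, use.names = FALSE)
  rows <- lapply(panel$assays, function(a) {
    an <- analytes_for(a, panel$mass_table)
    data.frame(assay_id = a$assay_id, gene = a$gene, aa_label = a$aa_label,
               pool = unname(pool_of[a$assay_id]), kind = a$kind,
               primer_seq = a$primer_seq,
               uep_mass = an$mass[an$role == "unextended"],
               wt_base = a$wt_base,
               mut_bases = paste(names(a$mut_alleles), collapse = ","),
               mut_labels = paste(a$mut_alleles, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Mass conflicts among the assays of a pool
#'
#' Lists every unordered cross-assay analyte pair closer than `min_gap` Da.
#' Pairs within one assay are not reported: the gaps there are fixed by the
#' terminator chemistry. With `include_adducts`, each analyte's
#' adduct-shifted satellites are additionally compared against the other
#' assays' analytes, so that a salt peak of one assay cannot alias an allele
#' peak of another.
#'
#' @param assays List of [sbe_assay()] objects forming one pool.
#' @param mass_table A [mass_table()].
#' @param min_gap Minimum tolerated mass gap in Da (> 0).
#' @param include_adducts Also test adduct-shifted masses (default FALSE).
#' @return data.frame with columns `assay_a`, `analyte_a`, `assay_b`,
#'   `analyte_b`, `delta` (absolute mass gap, Da); zero rows when the pool is
#'   fully resolvable.
#' @export
pool_conflicts <- function(assays, mass_table = default_mass_table(),
                           min_gap = 16, include_adducts = FALSE) {
  stopifnot(min_gap > 0)
  if (inherits(assays, "sbe_assay")) assays <- list(assays)
  empty <- data.frame(assay_a = character(), analyte_a = character(),
                      assay_b = character(), analyte_b = character(),
                      delta = numeric(), stringsAsFactors = FALSE)
  if (!length(assays)) return(empty)
  an <- do.call(rbind, lapply(assays, analytes_for, mass_table = mass_table))
  an$adduct <- FALSE
  if (include_adducts && length(mass_table$adduct_shifts)) {
    sat <- do.call(rbind, lapply(names(mass_table$adduct_shifts), function(ad)
      transform(an, label = paste0(label, "+", ad),
                mass = mass + mass_table$adduct_shifts[[ad]],
                adduct = TRUE)))
    an <- rbind(an, sat)
  }
  n <- nrow(an)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (an$assay_id[i] == an$assay_id[j]) next
      # adduct-shifted masses are compared against the other assay's plain
      # analytes only: two satellites colliding is not a calling hazard
      if (an$adduct[i] && an$adduct[j]) next
      d <- abs(an$mass[i] - an$mass[j])
      if (d < min_gap)
        out[[length(out) + 1L]] <- data.frame(
          assay_a = an$assay_id[i], analyte_a = an$label[i],
          assay_b = an$assay_id[j], analyte_b = an$label[j],
          delta = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Validate that every pool of a panel is mass-resolvable
#'
#' @inheritParams pool_conflicts
#' @param panel An [sbe_panel()].
#' @return data.frame of conflicts across all pools with a `pool` column
#'   (zero rows when clean).
#' @export
panel_conflicts <- function(panel, min_gap = 16, include_adducts = FALSE) {
  stopifnot(inherits(panel, "sbe_panel"))
  out <- lapply(names(panel$pools), function(p) {
    cf <- pool_conflicts(panel$assays[panel$pools[[p]]], panel$mass_table,
                         min_gap = min_gap, include_adducts = include_adducts)
    if (nrow(cf)) cbind(pool = p, cf) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(pool = character(), assay_a = character(),
                      analyte_a = character(), assay_b = character(),
                      analyte_b = character(), delta = numeric(),
                      stringsAsFactors = FALSE)
  out
}
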