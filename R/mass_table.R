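#' Mass tables for oligonucleotide analytes
#'
#' A mass table collects the constants needed to compute the mass of every
#' analyte of a single-base-extension (SBE) assay: the internal residue mass
#' of each deoxynucleotide within an oligo, the mass added by each
#' chain-terminating nucleotide, a per-oligo terminal adjustment for the end
#' groups, and the cation adduct shifts (sodium, potassium) that give rise to
#' salt satellite peaks.
#'
#' Linear MALDI-TOF of oligonucleotides resolves average (not monoisotopic)
#' mass, so the shipped defaults are average masses. Terminator masses are
#' mass-modified so the four bases are separated by at least `min_term_gap`
#' daltons, which is what makes the four possible extension products of one
#' assay distinguishable on the spectrum.
#'
#' @param residue_mass Named numeric (names `A`,`C`,`G`,`T`): internal residue
#'   mass in Da of each deoxynucleotide monophosphate within an oligo.
#' @param terminator_mass Named numeric (names `A`,`C`,`G`,`T`): mass in Da
#'   added by the chain-terminating nucleotide of each base.
#' @param terminal_adjustment Constant (Da) added once per oligo for the
#'   terminal H/OH end groups.
#' @param adduct_shifts Named numeric of positive cation adduct shifts in Da.
#' @param min_term_gap Minimum allowed pairwise gap (Da) between terminator
#'   masses; validation fails below it.
#' @return An object of class `mass_table`.
#' @examples
#' mt <- default_mass_table()
#' oligo_mass("ACGT", mt)
#' @export
mass_table <- function(residue_mass,
                       terminator_mass,
                       terminal_adjustment,
                       adduct_shifts = c(Na = 21.98, K = 37.95),
                       min_term_gap = 8) {
  bases <- c("A", "C", "G", "T")
  residue_mass <- unlist(residue_mass)
  terminator_mass <- unlist(terminator_mass)
  adduct_shifts <- unlist(adduct_shifts)
  if (!setequal(names(residue_mass), bases))
    stop("residue_mass must be named A, C, G, T", call. = FALSE)
  if (!setequal(names(terminator_mass), bases))
    stop("terminator_mass must be named A, C, G, T", call. = FALSE)
  residue_mass <- residue_mass[bases]
  terminator_mass <- terminator_mass[bases]
  if (any(residue_mass <= 0) || any(terminator_mass <= 0))
    stop("all residue and terminator masses must be strictly positive",
         call. = FALSE)
  if (length(adduct_shifts) && any(adduct_shifts <= 0))
    stop("adduct shifts must be strictly positive", call. = FALSE)
  gaps <- abs(outer(terminator_mass, terminator_mass, "-"))
  min_gap <- min(gaps[upper.tri(gaps)])
  if (min_gap < min_term_gap)
    stop(sprintf(
      "terminator masses must differ pairwise by >= %.3g Da (observed %.3g)",
      min_term_gap, min_gap), call. = FALSE)
  structure(
    list(residue_mass = residue_mass,
         terminator_mass = terminator_mass,
         terminal_adjustment = terminal_adjustment,
         adduct_shifts = adduct_shifts,
         min_term_gap = min_term_gap),
    class = "mass_table")
}

#' Default average-mass table
#'
#' Average internal residue masses of the four deoxynucleotides, a +18.02 Da
#' terminal adjustment (H and OH end groups of a 5'-phosphorylated oligo),
#' mass-modified terminator masses, and sodium/potassium adduct shifts.
#'
#' The terminator masses are chosen with two constraints that make a
#' multiplexed spectrum interpretable: every pairwise terminator gap is at
#' least 15 Da (so the four possible extension products of one assay are
#' baseline-resolved), and no pairwise gap lies within 5 Da of a cation
#' adduct shift (so a salt satellite of one allele peak can never sit on
#' top of another allele's expected position).
#'
#' @return A `mass_table`.
#' @export
default_mass_table <- function() {
  mass_table(
    residue_mass = c(A = 313.21, C = 289.18, G = 329.21, T = 304.20),
    terminator_mass = c(A = 329.40, C = 271.20, G = 344.40, T = 301.20),
    terminal_adjustment = 18.02,
    adduct_shifts = c(Na = 21.98, K = 37.95))
}

#' @export
print.mass_table <- function(x, ...) {
  cat("<mass_table>\n")
  cat("  residues (Da):   ",
      paste(sprintf("%s=%.2f", names(x$residue_mass), x$residue_mass),
            collapse = "  "), "\n")
  cat("  terminators (Da):",
      paste(sprintf("%s=%.2f", names(x$terminator_mass), x$terminator_mass),
            collapse = "  "), "\n")
  cat(sprintf("  terminal adjustment: %+.2f Da\n", x$terminal_adjustment))
  if (length(x$adduct_shifts))
    cat("  adducts (Da):    ",
        paste(sprintf("%s=%+.2f", names(x$adduct_shifts), x$adduct_shifts),
              collapse = "  "), "\n")
  invisible(x)
}

#' Compute the mass of an oligonucleotide
#'
#' Sums the internal residue masses over the sequence and adds the per-oligo
#' terminal adjustment. The empty sequence returns the terminal adjustment
#' alone.
#'
#' @param sequence Character scalar over the DNA alphabet `A`,`C`,`G`,`T`
#'   (5'→3'). Case-insensitive.
#' @param mass_table A [mass_table()].
#' @return Mass in Da.
#' @export
oligo_mass <- function(sequence, mass_table = default_mass_table()) {
  stopifnot(inherits(mass_table, "mass_table"),
            is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) == 0L)
    return(mass_table$terminal_adjustment)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(invalid_sequence_error(chars[bad[1]], bad[1]))
  sum(mass_table$residue_mass[chars]) + mass_table$terminal_adjustment
}

invalid_sequence_error <- function(symbol, position) {
  structure(
    class = c("hotplex_invalid_sequence", "error", "condition"),
    list(message = sprintf(
      "invalid symbol '%s' at position %d: sequence must contain only A, C, G, T",
      symbol, position),
      call = NULL))
}

#' Read / write a mass table as JSON
#'
#' @param path File path.
#' @rdname mass_table_io
#' @return `read_mass_table()` returns a validated `mass_table`;
#'   `write_mass_table()` returns `path` invisibly.
#' @export
read_mass_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mass_table(residue_mass = x$residue_mass,
             terminator_mass = x$terminator_mass,
             terminal_adjustment = x$terminal_adjustment,
             adduct_shifts = if (is.null(x$adduct_shifts)) numeric() else
               x$adduct_shifts,
             min_term_gap = if (is.null(x$min_term_gap)) 8 else x$min_term_gap)
}

#' @param x A `mass_table`.
#' @rdname mass_table_io
#' @export
write_mass_table <- function(x, path) {
  stopifnot(inherits(x, "mass_table"))
  jsonlite::write_json(
    list(residue_mass = as.list(x$residue_mass),
         terminator_mass = as.list(x$terminator_mass),
         terminal_adjustment = x$terminal_adjustment,
         adduct_shifts = as.list(x$adduct_shifts),
         min_term_gap = x$min_term_gap),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
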