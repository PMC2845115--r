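#' Write / read cohort truth as TSV
#'
#' One row per simulated mutant assay: `sample_id`, `assay_id`,
#' `true_fraction`, `purity`, `input_ng`. Wild-type assays are implicit.
#'
#' @param truth A `cohort_truth`.
#' @param panel The [sbe_panel()] used to map amino-acid changes to assays.
#' @param path Output path.
#' @return The written data.frame, invisibly.
#' @export
write_truth_tsv <- function(truth, panel, path) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(panel, "sbe_panel"))
  rows <- lapply(seq_len(nrow(truth$samples)), function(i) {
    sid <- truth$samples$sample_id[i]
    m <- truth$mutations[truth$mutations$sample_id == sid, , drop = FALSE]
    fr <- truth_assay_fractions(m, panel)
    if (!nrow(fr)) return(NULL)
    data.frame(sample_id = sid, assay_id = fr$assay_id,
               true_fraction = fr$fraction,
               purity = truth$samples$purity[i],
               input_ng = truth$samples$input_ng[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), assay_id = character(),
                      true_fraction = numeric(), purity = numeric(),
                      input_ng = numeric(), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Write / read a spectrum as a peak-list TSV
#'
#' Columns `mass_da`, `intensity`, one row per grid point, masses ascending.
#'
#' @param spectrum A `maldi_spectrum`.
#' @param path File path.
#' @rdname spectrum_tsv
#' @return `write_spectrum_tsv()` returns `path` invisibly;
#'   `read_spectrum_tsv()` returns a `maldi_spectrum`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(mass_da = spectrum$mass, intensity = spectrum$intensity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param sample_id,pool_id Labels attached to the read spectrum.
#' @rdname spectrum_tsv
#' @export
read_spectrum_tsv <- function(path, sample_id = "sample",
                              pool_id = "pool") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("mass_da", "intensity") %in% names(df)))
  o <- order(df$mass_da)
  df <- df[o, , drop = FALSE]
  if (any(diff(df$mass_da) <= 0))
    stop("masses must be strictly ascending", call. = FALSE)
  if (any(df$intensity < 0))
    stop("intensities must be nonnegative", call. = FALSE)
  structure(list(sample_id = sample_id, pool_id = pool_id,
                 mass = df$mass_da, intensity = df$intensity),
            class = "maldi_spectrum")
}

#' Write a set of spectra as peak-list TSVs plus a manifest
#'
#' One `<sample>_<pool>.tsv` peak list per spectrum and a `manifest.tsv`
#' mapping each file to its sample and pool.
#'
#' @param spectra List of `maldi_spectrum` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (columns `file`, `sample_id`,
#'   `pool_id`), invisibly.
#' @export
write_spectra_tsv <- function(spectra, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(spectra, function(sp) {
    fname <- sprintf("%s_%s.tsv", sp$sample_id, sp$pool_id)
    write_spectrum_tsv(sp, file.path(dir, fname))
    data.frame(file = fname, sample_id = sp$sample_id,
               pool_id = sp$pool_id, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write assay calls to TSV
#'
#' @param calls List of `assay_call` objects (or a data.frame from
#'   [calls_df()]).
#' @param path Output path.
#' @return The written data.frame, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  df <- if (is.data.frame(calls)) calls else calls_df(calls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a peak assignment audit TSV
#'
#' One row per expected analyte (matched or not) followed by one row per
#' unassigned peak with its adduct/background flag.
#'
#' @param assignment A `peak_assignment`.
#' @param path Output path.
#' @param sample_id Sample label column value.
#' @return The written data.frame, invisibly.
#' @export
write_assignment_tsv <- function(assignment, path, sample_id = "sample") {
  an <- assignment$analytes
  a <- data.frame(sample_id = sample_id, assay_id = an$assay_id,
                  analyte = an$label, expected_mass = an$mass,
                  matched_mass = an$peak_mass, area = an$area,
                  snr = an$snr, flag = ifelse(an$matched, "", "absent"),
                  stringsAsFactors = FALSE)
  un <- assignment$unassigned
  if (nrow(un))
    a <- rbind(a, data.frame(sample_id = sample_id, assay_id = "",
                             analyte = "", expected_mass = NA_real_,
                             matched_mass = un$apex_mass, area = un$area,
                             snr = un$snr, flag = un$flag,
                             stringsAsFactors = FALSE))
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(a)
}
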