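#' Allele fractions from a peak assignment
#'
#' The area under each extension-product peak is proportional to the amount
#' of the corresponding allele, so the fraction of allele `b` is
#' `area(b) / sum(extension-product areas)`. Unmatched analytes contribute
#' zero area; peaks flagged as adducts or background are excluded. The UEP
#' fraction — `UEP area / (UEP + sum of extension areas)` — is the per-assay
#' extension-efficiency quality metric.
#'
#' @param assignment A `peak_assignment` (see [assign_peaks()]).
#' @param assay_id Optional: restrict to one assay of a multi-assay
#'   assignment.
#' @return List with `fractions` (named by base, summing to 1 when any
#'   extension product was detected), `uep_fraction`, `snr` (named by base,
#'   `NA` for unmatched), and `n_matched`.
#'   Signals a classed error when no analyte carries signal
#'   (`hotplex_no_signal`) or when the UEP is present but no extension
#'   product is (`hotplex_extension_failure`).
#' @export
allele_fractions <- function(assignment, assay_id = NULL) {
  stopifnot(inherits(assignment, "peak_assignment"))
  an <- assignment$analytes
  if (!is.null(assay_id)) an <- an[an$assay_id == assay_id, , drop = FALSE]
  if (!nrow(an)) stop("no analytes for this assay", call. = FALSE)
  ext <- an[an$role != "unextended", , drop = FALSE]
  uep_area <- sum(an$area[an$role == "unextended"])
  ext_total <- sum(ext$area)
  if (uep_area + ext_total <= 0)
    stop(structure(class = c("hotplex_no_signal", "error", "condition"),
                   list(message = "no signal at any expected analyte mass",
                        call = NULL)))
  if (ext_total <= 0)
    stop(structure(
      class = c("hotplex_extension_failure", "error", "condition"),
      list(message = "unextended primer present but no extension product",
           call = NULL)))
  fractions <- stats::setNames(ext$area / ext_total, ext$label)
  snr <- stats::setNames(ext$snr, ext$label)
  list(fractions = fractions,
       uep_fraction = uep_area / (uep_area + ext_total),
       snr = snr, n_matched = sum(an$matched))
}

#' Calling thresholds
#'
#' `min_fraction` is the assay's validated limit of detection for a mutant
#' allele; the mutant decision itself fires at
#' `min_fraction * decision_fraction`, following the blank/detection-limit
#' convention under which a sample truly at the detection limit is called
#' positive with high probability while blanks stay below the decision
#' point. `max_uep` bounds the tolerated unextended-primer share (extension
#' failure above it); `min_snr` is the minimum peak signal-to-noise for a
#' mutant call.
#'
#' @param min_fraction Mutant-allele detection limit (default 0.05).
#' @param decision_fraction Decision point as a fraction of `min_fraction`
#'   (default 0.5).
#' @param min_snr Minimum mutant peak SNR (default 3).
#' @param max_uep Maximum tolerated UEP fraction (default 0.90).
#' @return A named list of thresholds.
#' @export
call_thresholds <- function(min_fraction = 0.05, decision_fraction = 0.5,
                            min_snr = 3, max_uep = 0.90) {
  stopifnot(min_fraction > 0, decision_fraction > 0, min_snr > 0,
            max_uep > 0)
  list(min_fraction = min_fraction, decision_fraction = decision_fraction,
       min_snr = min_snr, max_uep = max_uep)
}

#' Call one assay from its allele fractions
#'
#' @param af Result of [allele_fractions()], or `NULL` together with
#'   `fail_reason` to record a failed assay.
#' @param assay The [sbe_assay()] being called.
#' @param thresholds A [call_thresholds()] list.
#' @param sample_id Sample label.
#' @param fail_reason Optional failure reason when `af` is `NULL`
#'   (e.g. `"no-signal"`).
#' @return An object of class `assay_call`: `status` is `"wildtype"`,
#'   `"mutant"` or `"fail"`; mutant calls carry `mut_base` and `aa_change`;
#'   `qc_flags` collects quality annotations.
#' @export
call_assay <- function(af, assay, thresholds = call_thresholds(),
                       sample_id = "sample", fail_reason = NULL) {
  stopifnot(inherits(assay, "sbe_assay"))
  mk <- function(status, mut_base = NA_character_,
                 aa_change = NA_character_, fractions = numeric(),
                 uep = NA_real_, snr = numeric(), qc = character()) {
    structure(list(sample_id = sample_id, assay_id = assay$assay_id,
                   gene = assay$gene, status = status, mut_base = mut_base,
                   aa_change = aa_change, allele_fractions = fractions,
                   uep_fraction = uep, snr = snr, qc_flags = qc),
              class = "assay_call")
  }
  if (is.null(af))
    return(mk("fail", qc = fail_reason %||% "no-signal"))
  qc <- character()
  if (af$uep_fraction > thresholds$max_uep)
    return(mk("fail", fractions = af$fractions, uep = af$uep_fraction,
              snr = af$snr, qc = "insufficient-extension"))
  decision <- thresholds$min_fraction * thresholds$decision_fraction
  mut_bases <- names(assay$mut_alleles)
  fr <- af$fractions[mut_bases]
  fr[is.na(fr)] <- 0
  names(fr) <- mut_bases
  snr <- af$snr[mut_bases]
  ok <- fr >= decision & !is.na(snr) & snr >= thresholds$min_snr
  low <- fr >= decision & (is.na(snr) | snr < thresholds$min_snr)
  if (any(low)) qc <- c(qc, "low-snr-candidate")
  if (any(ok)) {
    b <- mut_bases[which.max(ifelse(ok, fr, -Inf))]
    if (fr[b] < thresholds$min_fraction)
      qc <- c(qc, "below-validated-lod")
    return(mk("mutant", mut_base = b,
              aa_change = unname(assay$mut_alleles[[b]]),
              fractions = af$fractions, uep = af$uep_fraction,
              snr = af$snr, qc = qc))
  }
  mk("wildtype", fractions = af$fractions, uep = af$uep_fraction,
     snr = af$snr, qc = qc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assay_call <- function(x, ...) {
  cat(sprintf("<assay_call> %s %s: %s", x$sample_id, x$assay_id, x$status))
  if (x$status == "mutant")
    cat(sprintf(" %s (%s, fraction %.3f)", x$aa_change, x$mut_base,
                x$allele_fractions[[x$mut_base]]))
  if (length(x$qc_flags) && any(nzchar(x$qc_flags)))
    cat(sprintf(" [%s]", paste(x$qc_flags, collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Resolve a complex assay group to a codon-level call
#'
#' Complex sub-assays interrogate different nucleotide positions of one
#' codon. Substituting each mutant base into its position of the wild-type
#' codon and translating with the standard genetic code yields the
#' amino-acid-change label (`"G12D"` style). Two simultaneously mutant
#' sub-assays are flagged `multi-hit-codon` for manual review rather than
#' silently combined.
#'
#' @param calls List of `assay_call`s sharing one `complex_group`.
#' @param assays Named list of the corresponding [sbe_assay()] objects.
#' @param codon_ref Optional override of the wild-type codon; defaults to
#'   the `codon_ref` stored on the assays.
#' @return List with `status` (`"wildtype"`, `"mutant"`, `"multi-hit-codon"`
#'   or `"fail"`), `aa_change` (label or `NA`), and `fraction` (mutant allele
#'   fraction or `NA`).
#' @export
resolve_complex <- function(calls, assays, codon_ref = NULL) {
  stopifnot(length(calls) >= 1L)
  ids <- vapply(calls, `[[`, character(1), "assay_id")
  group <- unique(unlist(lapply(assays[ids], `[[`, "complex_group")))
  if (length(group) != 1L)
    stop("calls do not share a single complex_group", call. = FALSE)
  refs <- unique(unlist(lapply(assays[ids], `[[`, "codon_ref")))
  if (is.null(codon_ref)) {
    if (length(refs) != 1L)
      stop("inconsistent codon_ref across the group", call. = FALSE)
    codon_ref <- refs
  }
  if (nchar(codon_ref) != 3L)
    stop("codon_ref must have length 3", call. = FALSE)
  statuses <- vapply(calls, `[[`, character(1), "status")
  if (all(statuses == "fail"))
    return(list(status = "fail", aa_change = NA_character_,
                fraction = NA_real_))
  mutant <- which(statuses == "mutant")
  if (!length(mutant))
    return(list(status = "wildtype", aa_change = NA_character_,
                fraction = NA_real_))
  if (length(mutant) > 1L)
    return(list(status = "multi-hit-codon", aa_change = NA_character_,
                fraction = NA_real_))
  call <- calls[[mutant]]
  assay <- assays[[call$assay_id]]
  pos <- assay$codon_pos
  if (is.na(pos)) stop("assay lacks codon_pos metadata", call. = FALSE)
  codon <- codon_ref
  substr(codon, pos, pos) <- call$mut_base
  wt_aa <- translate_codon(codon_ref)
  mut_aa <- translate_codon(codon)
  aa_pos <- as.integer(gsub("\\D", "", assay$aa_label))
  label <- if (identical(wt_aa, mut_aa))
    sprintf("%s%d%s(syn)", wt_aa, aa_pos, mut_aa) else
      sprintf("%s%d%s", wt_aa, aa_pos, mut_aa)
  list(status = "mutant", aa_change = label,
       fraction = unname(call$allele_fractions[[call$mut_base]]))
}

translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop(sprintf("invalid codon '%s'", codon), call. = FALSE)
  aa
}

#' Per-sample mutation report
#'
#' Collapses one sample's assay calls into mutation records: one record per
#' mutant simple assay, and one codon-level record per complex group with a
#' single mutant sub-assay (multi-hit groups are flagged, not reported).
#' Records are ordered by gene, then amino-acid-change label.
#'
#' @param calls List of `assay_call`s for one sample.
#' @param panel The [sbe_panel()] the calls came from.
#' @return data.frame with columns `sample_id`, `gene`, `aa_change`,
#'   `fraction`; attribute `qc` lists flagged complex groups.
#' @export
sample_report <- function(calls, panel) {
  stopifnot(inherits(panel, "sbe_panel"))
  sids <- unique(vapply(calls, `[[`, character(1), "sample_id"))
  if (length(sids) > 1L)
    stop("sample_report expects the calls of a single sample", call. = FALSE)
  ids <- vapply(calls, `[[`, character(1), "assay_id")
  groups <- vapply(panel$assays[ids], function(a)
    a$complex_group %||% NA_character_, character(1))
  rows <- list()
  qc <- character()
  # simple assays
  for (k in which(is.na(groups))) {
    cl <- calls[[k]]
    if (cl$status == "mutant")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cl$sample_id, gene = cl$gene, aa_change = cl$aa_change,
        fraction = unname(cl$allele_fractions[[cl$mut_base]]),
        stringsAsFactors = FALSE)
  }
  # complex groups
  for (g in unique(groups[!is.na(groups)])) {
    k <- which(!is.na(groups) & groups == g)
    res <- resolve_complex(calls[k], panel$assays)
    if (res$status == "mutant") {
      cl <- calls[[k[1]]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cl$sample_id, gene = cl$gene, aa_change = res$aa_change,
        fraction = res$fraction, stringsAsFactors = FALSE)
    } else if (res$status == "multi-hit-codon") {
      qc <- c(qc, sprintf("multi-hit-codon:%s", g))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), gene = character(),
               aa_change = character(), fraction = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$aa_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  out
}

#' Call every assay of a pool from a rendered or measured spectrum
#'
#' Runs the full signal chain — baseline estimation, peak detection, peak
#' assignment — then quantifies and calls each assay of the pool.
#'
#' @param spectrum A `maldi_spectrum`.
#' @param panel An [sbe_panel()].
#' @param pool_id Pool the spectrum belongs to (default: the spectrum's own).
#' @param thresholds A [call_thresholds()].
#' @param tol Peak-to-analyte matching tolerance in Da.
#' @param window Baseline window (Da).
#' @param snr_min Peak detection SNR threshold.
#' @param peak_width_sd Assumed peak sd (Da) for integration support.
#' @return List of `assay_call` objects, one per assay of the pool.
#' @export
call_pool <- function(spectrum, panel, pool_id = spectrum$pool_id,
                      thresholds = call_thresholds(), tol = 1,
                      window = 150, snr_min = 3, peak_width_sd = 1.5) {
  stopifnot(inherits(panel, "sbe_panel"))
  analytes <- panel_analytes(panel, pool_id)
  baseline <- estimate_baseline(spectrum, window = window)
  peaks <- detect_peaks(spectrum, baseline, snr_min = snr_min,
                        peak_width_sd = peak_width_sd)
  assignment <- assign_peaks(peaks, analytes, tol = tol,
                             adduct_shifts = panel$mass_table$adduct_shifts)
  lapply(panel$pools[[pool_id]], function(aid) {
    assay <- panel$assays[[aid]]
    af <- tryCatch(allele_fractions(assignment, assay_id = aid),
                   hotplex_no_signal = function(e) NULL,
                   hotplex_extension_failure = function(e)
                     structure(list(reason = "extension-failure"),
                               class = "hotplex_fail_marker"))
    if (inherits(af, "hotplex_fail_marker"))
      call_assay(NULL, assay, thresholds, sample_id = spectrum$sample_id,
                 fail_reason = "extension-failure")
    else if (is.null(af))
      call_assay(NULL, assay, thresholds, sample_id = spectrum$sample_id,
                 fail_reason = "no-signal")
    else
      call_assay(af, assay, thresholds, sample_id = spectrum$sample_id)
  })
}

#' Flatten assay calls to a data.frame
#'
#' @param calls List of `assay_call` objects.
#' @return data.frame with one row per call (sample_id, assay_id, gene,
#'   status, mut_base, aa_change, mutant_fraction, uep_fraction, qc_flags).
#' @export
calls_df <- function(calls) {
  rows <- lapply(calls, function(cl) {
    data.frame(
      sample_id = cl$sample_id, assay_id = cl$assay_id, gene = cl$gene,
      status = cl$status, mut_base = cl$mut_base, aa_change = cl$aa_change,
      mutant_fraction = if (cl$status == "mutant")
        unname(cl$allele_fractions[[cl$mut_base]]) else NA_real_,
      uep_fraction = cl$uep_fraction,
      qc_flags = paste(cl$qc_flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate, process and call a whole cohort
#'
#' Convenience wrapper: renders every pool of every sample of a cohort truth
#' through [render_spectrum()], runs [call_pool()] and collects the
#' per-sample mutation reports.
#'
#' @param truth A `cohort_truth` (see [simulate_cohort_truth()]).
#' @param panel An [sbe_panel()].
#' @param noise A [noise_model()].
#' @param thresholds A [call_thresholds()].
#' @param seed Integer seed for the rendering.
#' @param pools Pools to render (default: all pools of the panel).
#' @return data.frame of mutation records (sample_id, gene, aa_change,
#'   fraction) across the cohort.
#' @export
profile_cohort <- function(truth, panel, noise = noise_model(),
                           thresholds = call_thresholds(), seed = 1,
                           pools = names(panel$pools)) {
  stopifnot(inherits(truth, "cohort_truth"))
  reports <- list()
  for (i in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[i]
    m <- truth$mutations[truth$mutations$sample_id == sid, , drop = FALSE]
    fr <- truth_assay_fractions(m, panel)
    calls <- list()
    for (p in pools) {
      sp <- render_spectrum(fr, panel, p,
                            purity = truth$samples$purity[i],
                            input_ng = truth$samples$input_ng[i],
                            noise = noise,
                            seed = substream_seed(seed, i * 101 +
                                                    match(p, pools)),
                            sample_id = sid)
      calls <- c(calls, call_pool(sp, panel, p, thresholds))
    }
    reports[[i]] <- sample_report(calls, panel)
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}
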