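#' Rolling-median baseline of a spectrum
#'
#' Estimates the slowly varying chemical baseline with a running median whose
#' window (in Da) is much wider than a peak, so that peaks — which occupy a
#' minority of any window — do not pull the estimate up. The result never
#' exceeds the local window maximum.
#'
#' @param spectrum A `maldi_spectrum` (see [render_spectrum()]) or any list
#'   with ascending `mass` and `intensity`.
#' @param window Window width in Da (> 0, default 150): several times the
#'   width of a cluster of extension products, so peaks occupy a minority
#'   of any window.
#' @return Numeric baseline, same length as the spectrum.
#' @export
estimate_baseline <- function(spectrum, window = 150) {
  stopifnot(window > 0)
  n <- length(spectrum$mass)
  if (n == 0L) stop("empty spectrum", call. = FALSE)
  if (n == 1L) return(spectrum$intensity)
  step <- stats::median(diff(spectrum$mass))
  k <- max(3L, as.integer(round(window / step)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  as.numeric(stats::runmed(spectrum$intensity, k, endrule = "median"))
}

#' Detect peaks above a baseline
#'
#' Local maxima of the baseline-subtracted trace are kept when their
#' signal-to-noise ratio — apex residual divided by a robust noise scale, the
#' median absolute deviation of the baseline residuals — reaches `snr_min`.
#' Each peak's area is the trapezoidal integral of the residual over the
#' peak's support: apex ± 4 peak-width sd, truncated at the neighbouring
#' local minima so that adjacent peaks do not share area.
#'
#' @param spectrum A `maldi_spectrum`.
#' @param baseline Numeric baseline (default: [estimate_baseline()]).
#' @param snr_min Minimum signal-to-noise ratio (> 0, default 3).
#' @param peak_width_sd Assumed Gaussian peak sd in Da (default 1.5), fixes
#'   the integration support.
#' @return data.frame with columns `apex_mass`, `height`, `area`, `snr`,
#'   sorted by mass.
#' @export
detect_peaks <- function(spectrum, baseline = estimate_baseline(spectrum),
                         snr_min = 3, peak_width_sd = 1.5) {
  stopifnot(snr_min > 0, peak_width_sd > 0)
  n <- length(spectrum$mass)
  if (n == 0L) stop("empty spectrum", call. = FALSE)
  resid <- spectrum$intensity - baseline
  noise_scale <- max(stats::mad(resid), 1e-9)
  empty <- data.frame(apex_mass = numeric(), height = numeric(),
                      area = numeric(), snr = numeric())
  if (n < 3L) return(empty)
  core <- resid[2:(n - 1L)]
  is_max <- core > resid[1:(n - 2L)] & core >= resid[3:n] & core > 0
  apex <- which(is_max) + 1L
  snr <- resid[apex] / noise_scale
  keep <- snr >= snr_min
  apex <- apex[keep]; snr <- snr[keep]
  if (!length(apex)) return(empty)
  step <- stats::median(diff(spectrum$mass))
  # noise jitter can split one physical peak into several local maxima near
  # its flat top; merge adjacent maxima not separated by a real valley
  # (valley deeper than half the smaller apex), keeping the tallest
  repeat {
    if (length(apex) < 2L) break
    merged <- FALSE
    for (j in seq_len(length(apex) - 1L)) {
      valley <- min(resid[apex[j]:apex[j + 1L]])
      if (valley > 0.5 * min(resid[apex[j]], resid[apex[j + 1L]])) {
        drop <- if (resid[apex[j]] >= resid[apex[j + 1L]]) j + 1L else j
        apex <- apex[-drop]; snr <- snr[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  half <- max(1L, as.integer(round(4 * peak_width_sd / step)))
  rows <- lapply(seq_along(apex), function(j) {
    i <- apex[j]
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    # truncate the support at the residual minimum between this apex and an
    # adjacent detected apex, so neighbouring peaks never share area
    if (j > 1L && apex[j - 1L] >= lo) {
      between <- apex[j - 1L]:i
      lo <- between[which.min(resid[between])]
    }
    if (j < length(apex) && apex[j + 1L] <= hi) {
      between <- i:apex[j + 1L]
      hi <- between[which.min(resid[between])]
    }
    idx <- lo:hi
    y <- pmax(0, resid[idx])
    x <- spectrum$mass[idx]
    area <- if (length(idx) > 1L)
      sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) else 0
    data.frame(apex_mass = spectrum$mass[i], height = resid[i],
               area = area, snr = snr[j])
  })
  out <- do.call(rbind, rows)
  out[order(out$apex_mass), , drop = FALSE]
}

#' Assign detected peaks to expected analytes
#'
#' Greedy nearest-mass matching: peak/analyte pairs within `tol` Da are
#' matched in order of increasing mass difference (ties broken toward the
#' lower-mass analyte); each peak matches at most one analyte and vice
#' versa. Remaining peaks lying within `tol` of an analyte mass plus a
#' cation adduct shift are flagged `adduct-of(<analyte>)`; everything else is
#' flagged `background`. Adduct and background areas are excluded from
#' allele quantification downstream.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param analytes data.frame from [analytes_for()] / [panel_analytes()].
#' @param tol Matching tolerance in Da (> 0, default 1).
#' @param adduct_shifts Named numeric of adduct shifts in Da.
#' @return An object of class `peak_assignment`: list with `analytes` (the
#'   analyte table plus `matched`, `peak_mass`, `area`, `snr`) and
#'   `unassigned` (peaks with a `flag` column).
#' @export
assign_peaks <- function(peaks, analytes, tol = 1,
                         adduct_shifts = c(Na = 21.98, K = 37.95)) {
  stopifnot(tol > 0, is.data.frame(analytes), nrow(analytes) >= 1L)
  if (nrow(analytes) > 1L) {
    gaps <- abs(outer(analytes$mass, analytes$mass, "-"))
    if (min(gaps[upper.tri(gaps)]) < tol)
      stop(structure(
        class = c("hotplex_ambiguous_panel", "error", "condition"),
        list(message = sprintf(
          "two expected analyte masses lie within tol = %g Da of each other",
          tol), call = NULL)))
  }
  analytes <- analytes[order(analytes$mass), , drop = FALSE]
  analytes$matched <- FALSE
  analytes$peak_mass <- NA_real_
  analytes$area <- 0
  analytes$snr <- NA_real_
  peaks <- peaks[order(peaks$apex_mass), , drop = FALSE]
  used <- rep(FALSE, nrow(peaks))
  if (nrow(peaks)) {
    cand <- expand.grid(p = seq_len(nrow(peaks)),
                        a = seq_len(nrow(analytes)))
    cand$d <- abs(peaks$apex_mass[cand$p] - analytes$mass[cand$a])
    cand <- cand[cand$d <= tol, , drop = FALSE]
    cand <- cand[order(cand$d, analytes$mass[cand$a]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      p <- cand$p[r]; a <- cand$a[r]
      if (used[p] || analytes$matched[a]) next
      used[p] <- TRUE
      analytes$matched[a] <- TRUE
      analytes$peak_mass[a] <- peaks$apex_mass[p]
      analytes$area[a] <- peaks$area[p]
      analytes$snr[a] <- peaks$snr[p]
    }
  }
  un <- peaks[!used, , drop = FALSE]
  flag <- character(nrow(un))
  if (nrow(un)) {
    for (r in seq_len(nrow(un))) {
      flag[r] <- "background"
      best <- Inf
      for (a in seq_len(nrow(analytes))) for (ad in names(adduct_shifts)) {
        d <- abs(un$apex_mass[r] - (analytes$mass[a] + adduct_shifts[[ad]]))
        if (d <= tol && d < best) {
          best <- d
          flag[r] <- sprintf("adduct-of(%s:%s)", analytes$assay_id[a],
                             analytes$label[a])
        }
      }
    }
  }
  un$flag <- flag
  rownames(analytes) <- rownames(un) <- NULL
  structure(list(analytes = analytes, unassigned = un),
            class = "peak_assignment")
}

#' @export
print.peak_assignment <- function(x, ...) {
  cat(sprintf("<peak_assignment> %d/%d analytes matched, %d unassigned (%s)\n",
              sum(x$analytes$matched), nrow(x$analytes), nrow(x$unassigned),
              if (nrow(x$unassigned))
                paste(x$unassigned$flag, collapse = ", ") else "none"))
  invisible(x)
}
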