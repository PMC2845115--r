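#' Noise and artifact model for simulated SBE spectra
#'
#' Collects the parameters that turn ideal allele-proportional peak areas
#' into a realistic MALDI-TOF trace. The unextended-primer (UEP) share is a
#' step function of the DNA input into the PCR: below 3 ng a fraction
#' `uep_fraction_low` of each assay's primer remains unextended, at or above
#' 3 ng the smaller `uep_fraction_high` applies.
#'
#' @param uep_fraction_low UEP area share for input DNA < 3 ng (default 0.09).
#' @param uep_fraction_high UEP area share for input DNA >= 3 ng
#'   (default 0.07).
#' @param peak_width_sd Gaussian peak width (sd, Da; default 1.5).
#' @param area_cv Relative sd of each rendered peak's area (default 0.04,
#'   consistent with the repeatability of SBE peak areas on re-profiled
#'   samples).
#' @param baseline_level,baseline_sd Mean and sd of the flat chemical
#'   baseline, intensity units (defaults 0.5 and 0.05).
#' @param adduct_prob Probability that an analyte peak spawns each adduct
#'   satellite (default 0.1).
#' @param adduct_area_frac Satellite area as a fraction of the parent peak
#'   area (default 0.15).
#' @param mass_error_sd Calibration error of peak centers (sd, Da;
#'   default 0.2).
#' @param background_rate_per_kda Expected number of spurious (salt /
#'   matrix) peaks per 1000 Da of rendered span (default 0.5).
#' @param background_area_mean Mean area of a spurious peak (exponential;
#'   default 3).
#' @param total_area Per-assay total primer area scale `T` (default 100).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(uep_fraction_low = 0.09,
                        uep_fraction_high = 0.07,
                        peak_width_sd = 1.5,
                        area_cv = 0.04,
                        baseline_level = 0.5,
                        baseline_sd = 0.05,
                        adduct_prob = 0.1,
                        adduct_area_frac = 0.15,
                        mass_error_sd = 0.2,
                        background_rate_per_kda = 0.5,
                        background_area_mean = 3,
                        total_area = 100) {
  vals <- c(uep_fraction_low, uep_fraction_high, peak_width_sd, area_cv,
            baseline_level, baseline_sd, adduct_prob, adduct_area_frac,
            mass_error_sd, background_rate_per_kda, background_area_mean,
            total_area)
  if (any(vals < 0)) stop("noise model parameters must be nonnegative",
                          call. = FALSE)
  if (uep_fraction_low >= 1 || uep_fraction_high >= 1)
    stop("uep fractions must lie in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "noise_model")
}

#' A noiseless variant of a noise model
#'
#' Keeps the deterministic structure (UEP step, peak shape, total area) and
#' zeroes every stochastic term; useful for exactness tests.
#'
#' @param base A [noise_model()] supplying the deterministic parameters.
#' @return A [noise_model()].
#' @export
noiseless <- function(base = noise_model()) {
  noise_model(uep_fraction_low = base$uep_fraction_low,
              uep_fraction_high = base$uep_fraction_high,
              peak_width_sd = base$peak_width_sd,
              area_cv = 0, baseline_level = 0, baseline_sd = 0,
              adduct_prob = 0, adduct_area_frac = base$adduct_area_frac,
              mass_error_sd = 0, background_rate_per_kda = 0,
              background_area_mean = 0, total_area = base$total_area)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>\n")
  cat(sprintf("  UEP share: %.3f (<3 ng) / %.3f (>=3 ng)\n",
              x$uep_fraction_low, x$uep_fraction_high))
  cat(sprintf("  peak sd %.2f Da, area CV %.3f, mass error sd %.2f Da\n",
              x$peak_width_sd, x$area_cv, x$mass_error_sd))
  cat(sprintf("  baseline %.2f +/- %.2f, adduct p=%.2f (area x%.2f)\n",
              x$baseline_level, x$baseline_sd, x$adduct_prob,
              x$adduct_area_frac))
  cat(sprintf("  background %.2f peaks/kDa (mean area %.1f), T = %.0f\n",
              x$background_rate_per_kda, x$background_area_mean,
              x$total_area))
  invisible(x)
}

## Deterministic substream scheme: every sample/spectrum draws from
## set.seed(substream_seed(seed, i)) so cohorts are reproducible piecewise.
substream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
}

with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, index))
  force(expr)
}

#' Simulate cohort mutation ground truth
#'
#' Draws per-sample mutation profiles from a table of per-mutation
#' frequencies. Under `cooccurrence_mode = "independent"` every mutation is
#' an independent Bernoulli draw at its stated frequency; `"enriched"`
#' multiplies the frequency of each further mutation by `enrichment` once a
#' sample already carries one (capped at 1), modelling positively associated
#' second hits. Mutant allele fractions default to the heterozygous 0.5 (the
#' value is allele-level; tumor purity multiplies it at render time).
#' Optionally a subset of mutations can be marked amplified, drawing their
#' fraction uniformly from `amplified_fraction_range` instead (mutant-allele
#' amplification, as seen for MET).
#'
#' @param freqs data.frame with columns `gene`, `aa_change`, `frequency`
#'   (proportion in \[0,1\]). Optional logical column `amplified`.
#' @param n_samples Number of samples (>= 1).
#' @param cooccurrence_mode `"independent"` or `"enriched"`.
#' @param enrichment Multiplier applied in `"enriched"` mode (default 2).
#' @param purity_shape1,purity_shape2 Beta parameters of the tumor purity
#'   distribution on (0, 1] (defaults 5 and 2, mean 0.71 — typical of
#'   macrodissected FFPE tumor sections).
#' @param input_dna_ng DNA input per sample in ng; recycled (default 10).
#' @param het_fraction Default mutant allele fraction (default 0.5).
#' @param amplified_fraction_range Range for amplified mutations
#'   (default c(0.58, 0.70)).
#' @param amplified_prob Probability that a mutation flagged `amplified`
#'   actually shows the amplified fraction in a given sample (default 0.5).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return An object of class `cohort_truth`: a list with `samples`
#'   (data.frame sample_id, purity, input_ng) and `mutations` (data.frame
#'   sample_id, gene, aa_change, fraction).
#' @export
simulate_cohort_truth <- function(freqs, n_samples,
                                  cooccurrence_mode = c("independent",
                                                        "enriched"),
                                  enrichment = 2,
                                  purity_shape1 = 5, purity_shape2 = 2,
                                  input_dna_ng = 10,
                                  het_fraction = 0.5,
                                  amplified_fraction_range = c(0.58, 0.70),
                                  amplified_prob = 0.5,
                                  seed = 1) {
  cooccurrence_mode <- match.arg(cooccurrence_mode)
  stopifnot(is.data.frame(freqs),
            all(c("gene", "aa_change", "frequency") %in% names(freqs)),
            n_samples >= 1)
  if (any(freqs$frequency < 0 | freqs$frequency > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  amplified <- if ("amplified" %in% names(freqs)) freqs$amplified else
    rep(FALSE, nrow(freqs))
  input_dna_ng <- rep_len(input_dna_ng, n_samples)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  muts <- vector("list", n_samples)
  purity <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    muts[[i]] <- with_substream(seed, i, {
      purity[i] <- stats::rbeta(1, purity_shape1, purity_shape2)
      hit <- logical(nrow(freqs))
      any_prior <- FALSE
      for (k in seq_len(nrow(freqs))) {
        p <- freqs$frequency[k]
        if (cooccurrence_mode == "enriched" && any_prior)
          p <- min(1, p * enrichment)
        hit[k] <- stats::runif(1) < p
        if (hit[k]) any_prior <- TRUE
      }
      if (!any(hit)) NULL else {
        f <- rep(het_fraction, sum(hit))
        amp <- amplified[hit] & (stats::runif(sum(hit)) < amplified_prob)
        if (any(amp))
          f[amp] <- stats::runif(sum(amp), amplified_fraction_range[1],
                                 amplified_fraction_range[2])
        data.frame(sample_id = sample_ids[i],
                   gene = freqs$gene[hit],
                   aa_change = freqs$aa_change[hit],
                   fraction = f, stringsAsFactors = FALSE)
      }
    })
  }
  purity[purity <= 0] <- .Machine$double.eps
  mutations <- do.call(rbind, muts)
  if (is.null(mutations))
    mutations <- data.frame(sample_id = character(), gene = character(),
                            aa_change = character(), fraction = numeric(),
                            stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  structure(
    list(samples = data.frame(sample_id = sample_ids, purity = purity,
                              input_ng = input_dna_ng,
                              stringsAsFactors = FALSE),
         mutations = mutations),
    class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d samples, %d mutation events (%d genes)\n",
              nrow(x$samples), nrow(x$mutations),
              length(unique(x$mutations$gene))))
  invisible(x)
}

## Map one sample's aa-change truths to per-assay mutant base + fraction for
## the assays of a panel. Mutations whose label matches no panel assay are
## ignored (the panel does not interrogate them).
truth_assay_fractions <- function(truth_mutations, panel) {
  rows <- list()
  for (a in panel$assays) {
    for (b in names(a$mut_alleles)) {
      m <- truth_mutations[truth_mutations$gene == a$gene &
                             truth_mutations$aa_change == a$mut_alleles[[b]], ,
                           drop = FALSE]
      if (nrow(m))
        rows[[length(rows) + 1L]] <- data.frame(
          assay_id = a$assay_id, mut_base = b, fraction = m$fraction[1],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(assay_id = character(), mut_base = character(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Render one simulated spectrum for a pool
#'
#' Implements the generative model of the SBE read-out: after PCR, phosphatase
#' treatment and single-base extension, each assay yields an unextended-primer
#' peak and one extension-product peak per allele, with areas proportional to
#' the allele content. For UEP share `u` (chosen by the sample's DNA input),
#' per-assay total `T` and effective mutant fraction `f_eff = purity * f`:
#' UEP area `u*T`, wild-type area `(1-u)*T*(1-sum f_eff)`, each mutant
#' `(1-u)*T*f_eff`. Peaks are Gaussians of sd `peak_width_sd` centered at the
#' analyte mass plus a calibration error; adduct satellites and spurious
#' background peaks are added stochastically on top of a noisy baseline.
#'
#' @param assay_fractions data.frame (`assay_id`, `mut_base`, `fraction`) of
#'   mutant allele fractions; assays absent from it are wild type.
#' @param panel An [sbe_panel()].
#' @param pool_id Pool to render.
#' @param purity Tumor purity in (0, 1]; multiplies every mutant fraction.
#' @param input_ng DNA input (ng), selects the UEP share.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the spectrum is deterministic given it.
#' @param sample_id Sample label carried on the spectrum.
#' @param grid_step Mass grid spacing in Da (default 0.3).
#' @param pad Da of margin beyond the extreme analyte masses (default 60).
#' @return An object of class `maldi_spectrum`: list with `sample_id`,
#'   `pool_id`, `mass` (strictly ascending), `intensity` (>= 0).
#' @export
render_spectrum <- function(assay_fractions, panel, pool_id,
                            purity = 1, input_ng = 10,
                            noise = noise_model(), seed = 1,
                            sample_id = "sample", grid_step = 0.3,
                            pad = 60) {
  stopifnot(inherits(panel, "sbe_panel"), inherits(noise, "noise_model"),
            purity > 0, purity <= 1)
  if (!pool_id %in% names(panel$pools))
    stop(sprintf("unknown pool '%s'", pool_id), call. = FALSE)
  an <- panel_analytes(panel, pool_id)
  u <- if (input_ng < 3) noise$uep_fraction_low else noise$uep_fraction_high
  with_substream(seed, 0, {
    grid <- seq(min(an$mass) - pad, max(an$mass) + pad, by = grid_step)
    intensity <- pmax(0, noise$baseline_level +
                        stats::rnorm(length(grid), 0, noise$baseline_sd))
    add_peak <- function(center, area) {
      if (area <= 0) return()
      center <- center + stats::rnorm(1, 0, noise$mass_error_sd)
      if (noise$area_cv > 0)
        area <- max(0, area * (1 + stats::rnorm(1, 0, noise$area_cv)))
      intensity <<- intensity +
        area * stats::dnorm(grid, center, noise$peak_width_sd)
      c(center = center, area = area)
    }
    for (aid in panel$pools[[pool_id]]) {
      assay <- panel$assays[[aid]]
      rows <- assay_fractions[assay_fractions$assay_id == aid, , drop = FALSE]
      f_eff <- stats::setNames(rep(0, length(assay$mut_alleles)),
                               names(assay$mut_alleles))
      if (nrow(rows)) {
        keep <- rows$mut_base %in% names(f_eff)
        f_eff[rows$mut_base[keep]] <- pmin(1, rows$fraction[keep]) * purity
      }
      f_tot <- min(1, sum(f_eff))
      a_an <- an[an$assay_id == aid, , drop = FALSE]
      areas <- numeric(nrow(a_an))
      for (r in seq_len(nrow(a_an))) {
        areas[r] <- switch(
          a_an$role[r],
          unextended = u * noise$total_area,
          wt_extension = (1 - u) * noise$total_area * (1 - f_tot),
          mut_extension = (1 - u) * noise$total_area *
            unname(f_eff[a_an$label[r]]))
        placed <- add_peak(a_an$mass[r], areas[r])
        if (!is.null(placed)) {
          for (ad in names(panel$mass_table$adduct_shifts)) {
            if (stats::runif(1) < noise$adduct_prob)
              add_peak(a_an$mass[r] + panel$mass_table$adduct_shifts[[ad]],
                       placed[["area"]] * noise$adduct_area_frac)
          }
        }
      }
    }
    span_kda <- (max(grid) - min(grid)) / 1000
    n_bg <- stats::rpois(1, noise$background_rate_per_kda * span_kda)
    if (n_bg > 0) {
      for (b in seq_len(n_bg))
        add_peak(stats::runif(1, min(grid), max(grid)),
                 stats::rexp(1, 1 / noise$background_area_mean))
    }
    structure(list(sample_id = sample_id, pool_id = pool_id,
                   mass = grid, intensity = intensity),
              class = "maldi_spectrum")
  })
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<maldi_spectrum> %s / %s: %d points, %.0f-%.0f Da, max intensity %.2f\n",
    x$sample_id, x$pool_id, length(x$mass), min(x$mass), max(x$mass),
    max(x$intensity)))
  invisible(x)
}

#' @export
plot.maldi_spectrum <- function(x, ...) {
  plot(x$mass, x$intensity, type = "l", xlab = "m/z (Da)",
       ylab = "intensity (a.u.)",
       main = sprintf("%s / %s", x$sample_id, x$pool_id), ...)
  invisible(x)
}

#' Simulate a cell-line mixing series
#'
#' Emulates titrating a mutant cell line into a wild-type line: at cell-DNA
#' fraction `p` the mutant allele fraction is `p * 0.5` for a heterozygous
#' mutation (10% cells → 5% mutant alleles) or `p` for a homozygous one.
#' Renders one single-assay spectrum per mixing fraction.
#'
#' @param mix_fractions Numeric vector of mutant-line DNA fractions in
#'   \[0, 1\].
#' @param assay An [sbe_assay()]; its first mutant allele is the spiked one.
#' @param heterozygous Is the cell-line mutation heterozygous? (default TRUE)
#' @param noise A [noise_model()].
#' @param mass_table A [mass_table()].
#' @param seed Integer seed.
#' @return List with `allele_fraction` (numeric, the true allele fractions)
#'   and `spectra` (list of `maldi_spectrum`, one per mixing fraction), plus
#'   `panel` (the single-assay panel used, pool `"mix"`).
#' @export
simulate_mixing_series <- function(mix_fractions, assay,
                                   heterozygous = TRUE,
                                   noise = noise_model(),
                                   mass_table = default_mass_table(),
                                   seed = 1) {
  stopifnot(all(mix_fractions >= 0 & mix_fractions <= 1))
  af <- mix_fractions * (if (heterozygous) 0.5 else 1)
  panel <- sbe_panel("mixing", list(assay),
                     pools = stats::setNames(list(assay$assay_id), "mix"),
                     mass_table = mass_table)
  mut_base <- names(assay$mut_alleles)[1]
  spectra <- lapply(seq_along(af), function(i) {
    fr <- data.frame(assay_id = assay$assay_id, mut_base = mut_base,
                     fraction = af[i], stringsAsFactors = FALSE)
    render_spectrum(fr, panel, "mix", purity = 1,
                    noise = noise, seed = substream_seed(seed, i),
                    sample_id = sprintf("mix_%0.3f", mix_fractions[i]))
  })
  list(allele_fraction = af, spectra = spectra, panel = panel)
}

#' Simulate paired primary-tumor / lymph-node truths
#'
#' Each node inherits each mutation of its primary independently with
#' probability `1 - dropout_prob`; retained mutant fractions are perturbed by
#' a normal drift truncated to (0, 1]. Nodes never gain mutations absent
#' from the primary.
#'
#' @param primary A `cohort_truth` (see [simulate_cohort_truth()]).
#' @param dropout_prob Per-mutation probability that the node lacks it.
#' @param fraction_drift_sd sd of the truncated-normal fraction drift
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A list with `primary` (as given) and `node` (a `cohort_truth`
#'   with sample ids suffixed `"_LN"`).
#' @export
simulate_node_pairs <- function(primary, dropout_prob,
                                fraction_drift_sd = 0.05, seed = 1) {
  stopifnot(inherits(primary, "cohort_truth"),
            dropout_prob >= 0, dropout_prob <= 1)
  node_muts <- list()
  for (i in seq_len(nrow(primary$samples))) {
    sid <- primary$samples$sample_id[i]
    m <- primary$mutations[primary$mutations$sample_id == sid, ,
                           drop = FALSE]
    node_muts[[i]] <- with_substream(seed, i, {
      if (nrow(m)) {
        keep <- stats::runif(nrow(m)) >= dropout_prob
        m <- m[keep, , drop = FALSE]
      }
      if (nrow(m)) {
        if (fraction_drift_sd > 0) {
          f <- m$fraction + stats::rnorm(nrow(m), 0, fraction_drift_sd)
          m$fraction <- pmin(1, pmax(.Machine$double.eps, f))
        }
        m$sample_id <- paste0(sid, "_LN")
        m
      } else NULL
    })
  }
  node_mutations <- do.call(rbind, node_muts)
  if (is.null(node_mutations))
    node_mutations <- primary$mutations[0, , drop = FALSE]
  rownames(node_mutations) <- NULL
  node_samples <- primary$samples
  node_samples$sample_id <- paste0(node_samples$sample_id, "_LN")
  node <- structure(list(samples = node_samples,
                         mutations = node_mutations),
                    class = "cohort_truth")
  list(primary = primary, node = node)
}
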