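#' Rectification-index cut point for heteromer classification
#'
#' Responses with RI above this value are classified as dominated by
#' linear (calcium-impermeable, edited-subunit-containing) receptors; an
#' analysis convention, not a biophysical constant.
#' @export
RI_HETEROMER_CUTOFF <- 0.7

#' Build a current-voltage curve from peak currents
#'
#' Sorts peak currents by voltage and computes the rectification index
#' when both +60 and -60 mV are present. The curve is still built when
#' either is missing; the RI is then reported absent (`NA`) with a flag.
#'
#' @param peaks_by_voltage named numeric vector or two-column data frame
#'   (`voltage_mV`, `peak_pA`) of peak current (pA, signed) per holding
#'   potential (mV); at least 3 voltages.
#' @param normalize_to optional reference voltage; currents are divided by
#'   `|I(reference)|` for display.
#' @return an `iv_curve`: `voltages`, `peak_currents`, `ri`, `flags`.
#' @export
build_iv <- function(peaks_by_voltage, normalize_to = NULL) {
  if (is.data.frame(peaks_by_voltage)) {
    v <- peaks_by_voltage[[1]]
    i <- peaks_by_voltage[[2]]
  } else {
    v <- as.numeric(names(peaks_by_voltage))
    i <- as.numeric(peaks_by_voltage)
  }
  if (length(v) < 3) stop("need at least 3 voltages")
  if (anyNA(v)) stop("voltages must be numeric (named vector or data frame)")
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  if (anyDuplicated(v)) stop("duplicate voltages")
  flags <- character()
  norm <- 1
  if (!is.null(normalize_to)) {
    k <- match(normalize_to, v)
    if (is.na(k)) stop("normalization voltage absent from curve")
    norm <- abs(i[k])
  }
  ri <- NA_real_
  if (all(c(-60, 60) %in% v)) {
    i_neg <- i[match(-60, v)]
    if (i_neg == 0) stop("current at -60 mV is zero; RI undefined")
    ri <- abs(i[match(60, v)]) / abs(i_neg)
  } else {
    flags <- c(flags, "missing +60 or -60 mV; RI not computed")
  }
  structure(
    list(voltages = v, peak_currents = i / norm, ri = ri,
         normalization = normalize_to, flags = flags),
    class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d voltages (%g to %g mV), RI = %s\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              if (is.na(x$ri)) "absent" else sprintf("%.3f", x$ri)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Rectification index of an I-V curve
#'
#' `RI = |I(+60 mV)| / |I(-60 mV)|`. Values well below 1 indicate
#' voltage-dependent block of outward current (intracellular polyamine
#' block of calcium-permeable receptors); ~1 indicates a linear response.
#'
#' @param curve an `iv_curve` from [build_iv()].
#' @return the rectification index (fraction).
#' @export
rectification_index <- function(curve) {
  stopifnot(inherits(curve, "iv_curve"))
  if (is.na(curve$ri)) stop("RI unavailable: +/-60 mV missing from curve")
  curve$ri
}

#' Classify a patch by its rectification index
#'
#' @param ri rectification index.
#' @param cutoff classification threshold (default [RI_HETEROMER_CUTOFF]).
#' @return `"heteromer-dominated"` (RI > cutoff) or
#'   `"rectifying (homomer contamination)"`.
#' @export
classify_rectification <- function(ri, cutoff = RI_HETEROMER_CUTOFF) {
  ifelse(ri > cutoff, "heteromer-dominated",
         "rectifying (homomer contamination)")
}

#' Peak currents of a simulated I-V family
#'
#' Signed peak (largest-magnitude) mean current per voltage.
#'
#' @param iv_sets a named list of [sweep_set()]s from [simulate_iv()].
#' @return data frame `voltage_mV`, `peak_pA`.
#' @export
iv_peaks <- function(iv_sets) {
  v <- vapply(iv_sets, function(s) s$v_hold, numeric(1))
  pk <- vapply(iv_sets, function(s) {
    m <- mean_trace(s)
    idx <- window_index(s$time_ms, s$analysis_window)
    m[idx][which.max(abs(m[idx]))]
  }, numeric(1))
  data.frame(voltage_mV = unname(v), peak_pA = unname(pk))
}

#' Relative conductance as a percentage of a reference condition
#'
#' `100 * g / g_ref`, the one-line arithmetic used to express conductance
#' changes between conditions (e.g. 15.85 pS vs a 5.13 pS reference gives
#' 309%).
#'
#' @param g conductance(s) in pS.
#' @param g_ref reference conductance in pS.
#' @return percentage(s).
#' @export
conductance_percent_of <- function(g, g_ref) {
  if (g_ref <= 0) stop("reference conductance must be positive")
  100 * g / g_ref
}
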