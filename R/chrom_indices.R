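# Transforms between gradient retention times, chromatographic hydrophobicity
# indices and the plasma-protein-binding scales.

#' Fit a gradient calibration line
#'
#' Fast-gradient biomimetic chromatography reports indices (CHI, log k) on
#' scales defined by reference standards: a set of standards is run, and a
#' least-squares line maps gradient retention time (minutes) to the
#' standards' literature index values. New compounds are then converted via
#' [index_from_retention()].
#'
#' @param times gradient retention times of the standards, minutes
#' @param refs reference index values of the standards, same length
#' @param names optional standard names
#' @return A `calibration_curve` with `slope`, `intercept` and `r2_fit`.
#' @examples
#' cal <- fit_calibration(c(1, 2, 3), c(10, 20, 30))
#' index_from_retention(2.5, cal)
#' @export
fit_calibration <- function(times, refs, names = NULL) {
  if (length(times) != length(refs)) {
    stop("times and refs must have equal length")
  }
  if (length(times) < 2L) stop("need at least 2 calibration standards")
  if (diff(range(times)) == 0) {
    stop("degenerate calibration: all retention times identical")
  }
  fit <- stats::lm.fit(cbind(1, times), refs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((refs - mean(refs))^2)
  curve <- list(
    standard_names = names %||% paste0("std", seq_along(times)),
    retention_times = as.numeric(times),
    reference_values = as.numeric(refs),
    intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L]),
    r2_fit = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  )
  class(curve) <- "calibration_curve"
  curve
}

#' Convert a retention time to an index value
#'
#' @param t_r gradient retention time(s), minutes
#' @param curve a fitted `calibration_curve`
#' @return Index value(s) `slope * t_r + intercept`.
#' @export
index_from_retention <- function(t_r, curve) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a fitted calibration_curve")
  }
  curve$slope * t_r + curve$intercept
}

#' Plasma-protein binding transforms
#'
#' Conversion between percent binding to human serum albumin (%HSA) and the
#' retention-derived log affinity LogK_HSA. The transform is the logistic
#' form `logk = log10(pct / (101 - pct))` with inverse
#' `pct = 101 * 10^logk / (1 + 10^logk)`. The 101 denominator is the
#' convention of the HSA-column binding scale (a 100-denominator logit
#' cannot reproduce published index tables); see the package vignette for
#' how this form was established.
#'
#' @param pct percent bound, in (0, 101)
#' @return `logk_from_percent_hsa()`: the log affinity;
#'   `percent_hsa_from_logk()`: percent bound in (0, 101).
#' @examples
#' logk_from_percent_hsa(92.07)  # ~1.01
#' percent_hsa_from_logk(0)      # 50.5
#' @export
logk_from_percent_hsa <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= 0 | pct >= 101)) {
    stop("pct must lie strictly between 0 and 101")
  }
  log10(pct / (101 - pct))
}

#' @rdname logk_from_percent_hsa
#' @param logk log HSA affinity, finite
#' @export
percent_hsa_from_logk <- function(logk) {
  if (any(!is.finite(logk))) stop("logk must be finite")
  101 * 10^logk / (1 + 10^logk)
}
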