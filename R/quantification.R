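# Gel-fluorescence peptide quantification: replicate standard-curve
# fitting, internal-standard correction, and the zero rule for bands
# whose loading control shows no visible signal.

#' Fit a fluorescence standard curve
#'
#' Ordinary least squares of mean band intensity on amount: replicate
#' intensities are averaged per amount first, then a line is fitted to
#' the means (intensity = slope * amount + intercept).
#'
#' @param points Data frame with columns `amount` (nmol) and `intensity`
#'   (arbitrary units); replicates are rows sharing an `amount`.
#' @return List of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the per-amount `means` table.
#' @examples
#' fit_standard_curve(data.frame(amount = 0:5, intensity = 2 * (0:5) + 1))
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("amount", "intensity") %in% names(points)))
  if (any(points$intensity < 0)) stop("intensities must be non-negative")
  means <- stats::aggregate(intensity ~ amount, data = points, FUN = mean)
  if (nrow(means) < 2L) {
    stop("need at least 2 distinct amounts to fit a line")
  }
  fit <- stats::lm(intensity ~ amount, data = means)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((means$intensity - mean(means$intensity))^2)
  structure(list(slope = unname(stats::coef(fit)["amount"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 means = means),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> intensity = ", format(x$slope), " * amount + ",
      format(x$intercept), "  (r^2 = ", format(x$r_squared), ")\n", sep = "")
  invisible(x)
}

# Invert the curve: intensity -> amount.
.invert_curve <- function(curve, intensity) {
  (intensity - curve$intercept) / curve$slope
}

#' Quantify a band with internal-standard correction
#'
#' The raw estimate is the curve-inverted band intensity; it is then
#' multiplied by a correction factor defined as (known amount of the
#' internal standard) / (curve-inverted observed intensity of the
#' internal standard), so a standard that reads exactly as predicted
#' gives factor 1. A band whose loading control shows no visible signal
#' is reported as exactly 0 regardless of intensity (the zero rule).
#'
#' @param intensity Observed band intensity.
#' @param curve A [fit_standard_curve()] result.
#' @param internal_standard Named vector or list with `known` (nmol) and
#'   `observed` (intensity) for the internal standard; `NULL` skips the
#'   correction (factor 1).
#' @param control_visible Logical; the zero rule applies when `FALSE`.
#' @return Estimated amount (nmol).
#' @export
quantify_band <- function(intensity, curve, internal_standard = NULL,
                          control_visible = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!control_visible) return(0)
  correction <- 1
  if (!is.null(internal_standard)) {
    known <- internal_standard[["known"]]
    observed <- internal_standard[["observed"]]
    if (is.null(known) || is.null(observed)) {
      stop("internal_standard needs 'known' and 'observed'")
    }
    if (observed <= 0) stop("non-positive internal-standard intensity")
    inverted <- .invert_curve(curve, observed)
    if (inverted <= 0) stop("internal standard inverts to a non-positive ",
                            "amount; curve and standard are inconsistent")
    correction <- known / inverted
  }
  .invert_curve(curve, intensity) * correction
}
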