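# Psychometric score harmonization across depression scales.
# BDI (self-report) ranges 0-63; HDRS (clinician-rated) ranges 0-52 here.
# Scores enter the model as Z-transformed values; an HDRS cohort is scored
# against BDI-derived parameters rescaled by the ratio of scale ranges
# (rule of three), so z(0) is identical on both scales.

.scale_ranges <- c(BDI = 63, HDRS = 52)

#' Supported depression scales and their ranges
#' @return Named numeric vector of maximum scores (`BDI` = 63, `HDRS` = 52).
#' @export
scale_ranges <- function() .scale_ranges

#' Score-scale standardization parameters
#'
#' Bundles the distribution mean and standard deviation of raw scores on a
#' named scale, together with the scale's maximum, for Z-transformation.
#'
#' @param scale Scale name, `"BDI"` or `"HDRS"` (or any name when
#'   `range_max` is given explicitly).
#' @param mean Distribution mean of the raw scores (scale units).
#' @param sd Distribution standard deviation (> 0, scale units).
#' @param range_max Maximum of the scale; defaults to the known range for
#'   BDI/HDRS.
#' @return Object of class `scale_params`.
#' @export
#' @examples
#' scale_params("BDI", mean = 9.5207, sd = 10.5064)
scale_params <- function(scale, mean, sd, range_max = NULL) {
  stopifnot(is.character(scale), length(scale) == 1L)
  if (is.null(range_max)) {
    if (!scale %in% names(.scale_ranges)) {
      stop("unknown scale '", scale, "'; give range_max explicitly")
    }
    range_max <- .scale_ranges[[scale]]
  }
  if (!is.finite(mean)) stop("mean must be finite")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.finite(range_max) || range_max <= 0) stop("range_max must be > 0")
  structure(list(scale = scale, mean = as.numeric(mean), sd = as.numeric(sd),
                 range_max = as.numeric(range_max)),
            class = "scale_params")
}

#' Estimate scale parameters from a cohort of raw scores
#'
#' @param raw Numeric vector of raw scores.
#' @param scale Scale name.
#' @return `scale_params` with the sample mean and (n-1) standard deviation.
#' @export
fit_scale_params <- function(raw, scale = "BDI") {
  stopifnot(length(raw) >= 2L, all(is.finite(raw)))
  s <- stats::sd(raw)
  if (s <= 0) stop("raw scores are constant; cannot standardize")
  scale_params(scale, mean(raw), s)
}

#' Z-transform raw scores
#'
#' @param raw Raw score(s) in scale units.
#' @param params A [scale_params()] object.
#' @return `(raw - mean) / sd`, in z units.
#' @export
#' @examples
#' standardize_scores(0, scale_params("BDI", 9.5207, 10.5064))  # -0.9062
standardize_scores <- function(raw, params) {
  stopifnot(inherits(params, "scale_params"))
  (raw - params$mean) / params$sd
}

#' Invert the Z-transformation
#' @param z Standardized score(s).
#' @param params A [scale_params()] object.
#' @return Raw score(s) in scale units.
#' @export
unstandardize_scores <- function(z, params) {
  stopifnot(inherits(params, "scale_params"))
  z * params$sd + params$mean
}

#' Equivalent parameters on another scale's range (rule of three)
#'
#' Rescales the mean and standard deviation by `target_range / range_max`
#' so that a second scale spanning a different range can be Z-transformed
#' against parameters learned on the source scale. Because mean and sd are
#' rescaled by the same factor, z-scores of proportionally equivalent raw
#' scores are preserved (in particular z(0) is invariant).
#'
#' @param src Source [scale_params()].
#' @param target_range Maximum of the target scale (> 0), e.g. 52 for HDRS.
#' @param scale Name for the resulting scale (default `"HDRS"` when the
#'   target range is 52, otherwise `"<src>_equiv"`).
#' @return `scale_params` on the target range.
#' @export
#' @examples
#' bdi <- scale_params("BDI", 9.5207, 10.5064)
#' equivalent_scale_params(bdi, 52)  # mean 7.8583, sd 8.6720
equivalent_scale_params <- function(src, target_range, scale = NULL) {
  stopifnot(inherits(src, "scale_params"))
  if (!is.finite(target_range) || target_range <= 0) {
    stop("target_range must be > 0")
  }
  if (is.null(scale)) {
    scale <- if (target_range == .scale_ranges[["HDRS"]]) "HDRS"
             else paste0(src$scale, "_equiv")
  }
  f <- target_range / src$range_max
  scale_params(scale, src$mean * f, src$sd * f, range_max = target_range)
}

#' @export
print.scale_params <- function(x, ...) {
  cat(sprintf("<scale_params> %s: mean %.4f, sd %.4f, range 0-%g\n",
              x$scale, x$mean, x$sd, x$range_max))
  invisible(x)
}
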