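#' Absolute deviation of computed shieldings from reference values
#'
#' @param sigma computed isotropic shielding(s), ppm
#' @param lambda_ref reference shielding(s), ppm
#' @return |sigma - lambda_ref|, ppm (vectorized)
#' @export
absolute_deviation <- function(sigma, lambda_ref) {
  stopifnot(all(is.finite(sigma)), all(is.finite(lambda_ref)))
  abs(sigma - lambda_ref)
}

#' Mean absolute deviation per element
#'
#' Averages per-nucleus absolute deviations over all nuclei of the same
#' element within one molecule (the aggregation used when comparing
#' shielding methods element by element).
#'
#' @param devs numeric vector of per-nucleus absolute deviations (ppm)
#' @param elements element symbol per nucleus
#' @return named numeric vector: MAD (ppm) per element
#' @export
mad_by_element <- function(devs, elements) {
  stopifnot(length(devs) > 0, length(devs) == length(elements))
  vapply(split(devs, elements), mean, 0)
}

#' Variance-ratio F test on two sets of deviations
#'
#' Classical two-sample F test comparing the variances of two MAD (or AD)
#' sets, with the larger variance in the numerator so F >= 1, two-sided
#' p-value from the F distribution, and a significance flag at the stated
#' level.  Thin wrapper over [stats::var.test()].
#'
#' @param mads_a,mads_b numeric vectors (each n >= 2)
#' @param level significance level (default 0.01, i.e. the 99 percent
#'   confidence statement)
#' @return list with `F`, `df`, `p_value`, `significant`, `level`
#' @export
f_test <- function(mads_a, mads_b, level = 0.01) {
  stopifnot(length(mads_a) >= 2, length(mads_b) >= 2)
  va <- stats::var(mads_a); vb <- stats::var(mads_b)
  if (va == 0 && vb == 0) {
    stop("both sets have zero variance; F statistic undefined")
  }
  if (va >= vb) { x <- mads_a; y <- mads_b } else { x <- mads_b; y <- mads_a }
  vt <- stats::var.test(x, y)
  list(F = unname(vt$statistic), df = unname(vt$parameter),
       p_value = vt$p.value, significant = vt$p.value < level,
       level = level)
}

#' Deviation statistics for a set of computed vs reference shieldings
#'
#' @param sigma computed shieldings (ppm)
#' @param lambda_ref reference shieldings (ppm)
#' @param elements element symbol per nucleus
#' @return list with per-nucleus `ad`, per-element `mad`, and `median_ad`
#' @export
deviation_stats <- function(sigma, lambda_ref, elements) {
  ad <- absolute_deviation(sigma, lambda_ref)
  list(ad = ad, mad = mad_by_element(ad, elements),
       median_ad = stats::median(ad))
}
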