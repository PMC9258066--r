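#' Delta notation from isotope ratios
#'
#' Expresses a 13C/12C ratio in per mil (permil) relative to a reference:
#' `delta = (r_sample / r_reference - 1) * 1000`.
#'
#' @param r_sample Sample 13C/12C ratio(s), > 0.
#' @param r_reference Reference ratio, > 0.
#' @return delta value(s) in permil.
#' @examples
#' delta_from_ratio(0.0112372, 0.0112372)  # 0 permil
#' @export
delta_from_ratio <- function(r_sample, r_reference) {
  if (any(r_sample <= 0) || any(r_reference <= 0))
    stop("isotope ratios must be positive", call. = FALSE)
  (r_sample / r_reference - 1) * 1000
}

#' Inverse of [delta_from_ratio()]
#'
#' @param delta delta value(s) in permil.
#' @param r_reference Reference ratio, > 0.
#' @return Sample ratio(s).
#' @export
ratio_from_delta <- function(delta, r_reference) {
  if (any(r_reference <= 0))
    stop("isotope ratios must be positive", call. = FALSE)
  (delta / 1000 + 1) * r_reference
}

#' Two-point normalization of delta-13C values to the VPDB scale
#'
#' IRMS raw deltas are placed on the international Vienna Pee Dee Belemnite
#' scale by a linear map fitted from certified reference standards (e.g.
#' USGS40 and USGS41) measured within the sequence: with exactly two
#' distinct standards the map passes through them exactly; with more it is
#' the least-squares line. Replicate measurements of the same standard are
#' averaged before fitting, the common IRMS practice.
#'
#' @param measurements Data frame with columns `sample_id`, `delta_raw`
#'   (permil, instrument scale), `material` ("sample" or "standard") and
#'   `certified_delta` (permil, standards only).
#' @param window Plausibility window on raw deltas, default wide enough for
#'   strongly 13C-enriched tissue.
#' @return The input with a `delta_vpdb` column added (standards are mapped
#'   too, so residual calibration error is visible).
#' @export
normalize_two_point <- function(measurements, window = c(-100, 1000)) {
  need <- c("sample_id", "delta_raw", "material")
  if (length(setdiff(need, names(measurements))))
    stop("validation error: measurements need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad_mat <- setdiff(unique(measurements$material), c("sample", "standard"))
  if (length(bad_mat))
    stop("validation error: unknown material value(s): ",
         paste(bad_mat, collapse = ", "), call. = FALSE)
  out_w <- measurements$delta_raw < window[1] | measurements$delta_raw > window[2]
  if (any(out_w))
    stop("range error: delta_raw outside plausibility window for sample(s): ",
         paste(measurements$sample_id[out_w], collapse = ", "), call. = FALSE)
  std <- measurements[measurements$material == "standard", , drop = FALSE]
  if (!nrow(std) || !("certified_delta" %in% names(std)) ||
      anyNA(std$certified_delta))
    stop("validation error: standards must carry certified_delta",
         call. = FALSE)
  # average replicate measurements per standard before fitting
  agg <- stats::aggregate(delta_raw ~ certified_delta, data = std, FUN = mean)
  if (nrow(agg) < 2L)
    stop("degenerate-calibration error: need >= 2 standards with distinct ",
         "certified values", call. = FALSE)
  fit <- stats::lm(certified_delta ~ delta_raw, data = agg)
  measurements$delta_vpdb <- unname(
    stats::coef(fit)[1] + stats::coef(fit)[2] * measurements$delta_raw)
  measurements
}
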