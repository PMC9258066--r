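#' Convert refractive index to buoyant density
#'
#' Isopycnic gradient fractions are assayed by refractometry at 20 degrees C;
#' buoyant density (g/mL) is recovered through a linear calibration
#' `density = slope * nD + intercept` established for the gradient medium.
#' The package default (slope 11.43, intercept -13.907) is a documented
#' convention for CsTFA gradients, anchored so that unlabelled rRNA bands
#' near 1.775 g/mL (nD ~ 1.3720) and fully 13C-labelled rRNA near
#' 1.815 g/mL (nD ~ 1.3755). It is a stand-in for a laboratory's own
#' calibration and should be overridden via `ri_calibration` in
#' [sip_config()] whenever one is available.
#'
#' @param ri Numeric vector of refractive indices (nD at 20 C).
#' @param cal List with `slope` (> 0) and `intercept`.
#' @param ri_window Length-2 plausibility window; refractive indices outside
#'   it raise a range error (a common symptom of swapped nD/density columns).
#' @return Buoyant densities in g/mL.
#' @examples
#' ri_to_density(1.38, cal = list(slope = 1, intercept = 0))
#' @export
ri_to_density <- function(ri, cal = sip_config()$ri_calibration,
                          ri_window = c(1.35, 1.42)) {
  if (cal$slope <= 0)
    stop("config error: calibration slope must be > 0", call. = FALSE)
  out_of_range <- !is.na(ri) & (ri < ri_window[1] | ri > ri_window[2])
  if (any(out_of_range))
    stop("range error: refractive index outside plausible window [",
         ri_window[1], ", ", ri_window[2], "]: ",
         paste(unique(ri[out_of_range]), collapse = ", "), call. = FALSE)
  cal$slope * ri + cal$intercept
}

#' Classify gradient fractions into heavy/middle/light density classes
#'
#' Fractions whose buoyant density lies in the configured heavy window are
#' "heavy", in the light window "light", between the two windows "middle",
#' and anywhere else "unassigned". Densities missing from the metadata are
#' first computed from the refractive index via [ri_to_density()].
#' Classification depends only on density and windows, so it is invariant to
#' input order.
#'
#' @param meta Fraction-metadata `data.frame` (see [read_fraction_meta()]).
#' @param cfg A [sip_config()].
#' @return `meta` with `buoyant_density` filled and `density_class` set.
#' @export
classify_fractions <- function(meta, cfg = sip_config()) {
  validate_sip_config(cfg)
  need_bd <- is.na(meta$buoyant_density)
  if (any(need_bd)) {
    meta$buoyant_density[need_bd] <- ri_to_density(
      meta$refractive_index[need_bd], cfg$ri_calibration, cfg$ri_window)
  }
  meta$density_class <- classify_density(meta$buoyant_density, cfg)
  meta
}

classify_density <- function(bd, cfg) {
  hw <- cfg$heavy_density_window
  lw <- cfg$light_density_window
  between <- c(min(hw[2], lw[2]), max(hw[1], lw[1]))  # gap between windows
  ifelse(bd >= hw[1] & bd <= hw[2], "heavy",
         ifelse(bd >= lw[1] & bd <= lw[2], "light",
                ifelse(bd > between[1] & bd < between[2], "middle",
                       "unassigned")))
}
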