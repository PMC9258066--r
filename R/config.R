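#' Pipeline configuration
#'
#' Bundles the tunable parameters of the SIP label-calling pipeline: the
#' heavy/light enrichment factor `K`, the minimum heavy-fraction relative
#' abundance, the density windows defining the heavy and light gradient
#' classes, the refractometry calibration, and the pseudo-abundance used when
#' a taxon is absent from the light fraction.
#'
#' @param K Enrichment factor for the heavy-vs-light criterion. The
#'   heavy-fraction relative abundance of a labelled taxon must exceed `K`
#'   times its light-fraction abundance. Default 2.
#' @param min_heavy_abundance Minimum relative abundance (proportion) a taxon
#'   must reach in the 13C heavy fraction to be callable. Default 0.0005
#'   (i.e. 0.05%).
#' @param heavy_density_window Numeric length-2, g/mL. Buoyant densities in
#'   this closed interval are classified "heavy".
#' @param light_density_window Numeric length-2, g/mL. Densities in this
#'   interval are classified "light".
#' @param ri_calibration List with `slope` ((g/mL) per refractive-index unit,
#'   must be > 0) and `intercept` (g/mL) of the linear refractometry
#'   calibration. The default is a package convention for CsTFA gradients
#'   (see [ri_to_density()]); laboratories should supply their own.
#' @param ri_window Plausibility window for refractive indices; values
#'   outside it are rejected (guards against swapped nD/density columns).
#' @param pseudo_abundance Proportion substituted for a zero light-fraction
#'   abundance in the enrichment criterion. `NULL` (default) means
#'   1 / (2 * light-fraction pooled read depth), computed per gradient pair.
#' @param shannon_base Base of the logarithm for Shannon diversity, default
#'   `exp(1)` (natural log).
#' @param rng_seed Integer seed recorded for pipeline runs.
#'
#' @return An object of class `sip_config` (a named list).
#' @examples
#' cfg <- sip_config()
#' cfg$K
#' @export
sip_config <- function(K = 2,
                       min_heavy_abundance = 0.0005,
                       heavy_density_window = c(1.795, 1.825),
                       light_density_window = c(1.760, 1.780),
                       ri_calibration = list(slope = 11.43, intercept = -13.907),
                       ri_window = c(1.35, 1.42),
                       pseudo_abundance = NULL,
                       shannon_base = exp(1),
                       rng_seed = 1L) {
  cfg <- list(
    K = K,
    min_heavy_abundance = min_heavy_abundance,
    heavy_density_window = as.numeric(heavy_density_window),
    light_density_window = as.numeric(light_density_window),
    ri_calibration = ri_calibration,
    ri_window = as.numeric(ri_window),
    pseudo_abundance = pseudo_abundance,
    shannon_base = shannon_base,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sip_config"
  validate_sip_config(cfg)
  cfg
}

validate_sip_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$K) || length(cfg$K) != 1L || cfg$K <= 0)
    stop("config error: K must be a single positive number", call. = FALSE)
  if (!is.numeric(cfg$min_heavy_abundance) ||
      cfg$min_heavy_abundance < 0 || cfg$min_heavy_abundance >= 1)
    stop("config error: min_heavy_abundance must lie in [0, 1)", call. = FALSE)
  for (w in c("heavy_density_window", "light_density_window")) {
    win <- cfg[[w]]
    if (length(win) != 2L || !is.numeric(win) || win[1] >= win[2])
      stop("config error: ", w, " must be numeric c(low, high) with low < high",
           call. = FALSE)
  }
  hw <- cfg$heavy_density_window
  lw <- cfg$light_density_window
  if (max(lw[1], hw[1]) <= min(lw[2], hw[2]))
    stop("config error: heavy and light density windows overlap", call. = FALSE)
  cal <- cfg$ri_calibration
  if (!is.list(cal) || is.null(cal$slope) || is.null(cal$intercept) ||
      cal$slope <= 0)
    stop("config error: ri_calibration needs slope > 0 and an intercept",
         call. = FALSE)
  if (!is.null(cfg$pseudo_abundance) &&
      (cfg$pseudo_abundance <= 0 || cfg$pseudo_abundance >= 1))
    stop("config error: pseudo_abundance must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [sip_config()] defaults.
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [sip_config()].
#' @return A `sip_config` object.
#' @export
read_sip_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sip_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("config error: unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(sip_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `sip_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sip_config <- function(cfg, path) {
  validate_sip_config(cfg)
  out <- unclass(cfg)
  out$shannon_base <- as.numeric(out$shannon_base)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sip_config <- function(x, ...) {
  cat("SIP pipeline configuration\n")
  cat(sprintf("  enrichment factor K:        %g\n", x$K))
  cat(sprintf("  min heavy abundance:        %g (%.3g%%)\n",
              x$min_heavy_abundance, 100 * x$min_heavy_abundance))
  cat(sprintf("  heavy density window:       [%.3f, %.3f] g/mL\n",
              x$heavy_density_window[1], x$heavy_density_window[2]))
  cat(sprintf("  light density window:       [%.3f, %.3f] g/mL\n",
              x$light_density_window[1], x$light_density_window[2]))
  cat(sprintf("  RI calibration:             density = %g * nD + %g\n",
              x$ri_calibration$slope, x$ri_calibration$intercept))
  cat(sprintf("  pseudo-abundance:           %s\n",
              if (is.null(x$pseudo_abundance)) "1 / (2 * light depth)"
              else format(x$pseudo_abundance)))
  invisible(x)
}
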