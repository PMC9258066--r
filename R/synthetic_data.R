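#' Parameters for a simulated SIP gradient experiment
#'
#' The generator emulates RNA stable isotope probing of a methanol-fed
#' community: each taxon's rRNA settles in an isopycnic gradient as a
#' Gaussian mass profile over buoyant density, centred at a taxon-specific
#' unlabelled density (GC-content variation). In 13C gradients, taxa that
#' assimilated the labelled substrate carry a second, heavier component:
#' a fraction `label_fraction` of their rRNA shifted up by `density_shift`.
#' Unlabelled taxa — and every taxon in the paired 12C control — keep the
#' unshifted profile. On top of the Gaussian peak, a fraction
#' `background_smear` of every taxon's RNA is spread uniformly across the
#' gradient: real gradients carry such a smear in every fraction, and it is
#' what makes the heavy fraction of a 12C control resemble the overall
#' community (the premise of the control-comparison criterion) instead of
#' being composed purely of extreme Gaussian tails. Sequencing of each
#' gradient fraction draws a multinomial of `reads_per_fraction` reads from
#' the taxon mass in that fraction's density bin.
#'
#' Defaults describe a short-incubation, partial-labelling regime: a shift
#' of 0.03 g/mL (order of magnitude of full 13C labelling of RNA), 80% of
#' a labelled taxon's RNA heavy, within-gradient spread 0.008 g/mL, a 5%
#' uniform smear, and per-taxon unlabelled densities drawn from
#' N(1.772, 0.002) g/mL so that unlabelled RNA bands in the light window
#' and shifted RNA in the heavy window of [sip_config()].
#'
#' @param n_taxa Number of taxa (default 20).
#' @param n_labelled Number of truly labelled taxa (default 5); ignored
#'   when `labelled_taxa` is given.
#' @param labelled_taxa Character vector of labelled taxon IDs, or `NULL`
#'   to take the first `n_labelled` of the generated IDs.
#' @param base_abundances Community proportions (length `n_taxa`, summing
#'   to 1), or `NULL` to draw once from a log-normal (sdlog 1) and
#'   normalize.
#' @param density_mean,density_sd Mean and SD (g/mL) of the per-taxon
#'   unlabelled buoyant-density means.
#' @param density_shift Density increment of the labelled component, g/mL.
#' @param profile_sd Within-gradient Gaussian spread per taxon, g/mL.
#' @param background_smear Fraction of every taxon's RNA spread uniformly
#'   over the fraction grid (non-ideal gradient behaviour), default 0.05.
#' @param label_fraction Weight of the shifted component for labelled taxa
#'   in 13C gradients.
#' @param fraction_edges Strictly increasing density bin edges (g/mL)
#'   defining the gradient fractions; the default five bins cover the full
#'   profile span, with interior bins matching the light / middle / heavy
#'   windows of [sip_config()].
#' @param reads_per_fraction Sequencing depth per fraction (default 50000).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   seed.
#' @return A `sip_sim_params` list.
#' @export
sip_sim_params <- function(n_taxa = 20L, n_labelled = 5L,
                           labelled_taxa = NULL, base_abundances = NULL,
                           density_mean = 1.772, density_sd = 0.002,
                           density_shift = 0.03, profile_sd = 0.008,
                           background_smear = 0.05, label_fraction = 0.8,
                           fraction_edges = c(1.730, 1.760, 1.780, 1.795,
                                              1.825, 1.855),
                           reads_per_fraction = 50000L, seed = 1L) {
  if (any(diff(fraction_edges) <= 0))
    stop("fraction_edges must be strictly increasing", call. = FALSE)
  if (density_shift < 0) stop("density_shift must be >= 0", call. = FALSE)
  if (label_fraction < 0 || label_fraction > 1)
    stop("label_fraction must lie in [0, 1]", call. = FALSE)
  if (background_smear < 0 || background_smear >= 1)
    stop("background_smear must lie in [0, 1)", call. = FALSE)
  p <- list(n_taxa = as.integer(n_taxa), n_labelled = as.integer(n_labelled),
            labelled_taxa = labelled_taxa, base_abundances = base_abundances,
            density_mean = density_mean, density_sd = density_sd,
            density_shift = density_shift, profile_sd = profile_sd,
            background_smear = background_smear,
            label_fraction = label_fraction,
            fraction_edges = as.numeric(fraction_edges),
            reads_per_fraction = as.integer(reads_per_fraction),
            seed = as.integer(seed))
  class(p) <- "sip_sim_params"
  p
}

# Gaussian mass of one taxon in each density bin (mixture for labelled taxa
# in 13C gradients), blended with a uniform background smear over the grid.
.bin_masses <- function(mu, sd, edges, shift = 0, weight_shifted = 0,
                        smear = 0) {
  base <- diff(stats::pnorm(edges, mean = mu, sd = sd))
  if (weight_shifted > 0) {
    heavy <- diff(stats::pnorm(edges, mean = mu + shift, sd = sd))
    base <- (1 - weight_shifted) * base + weight_shifted * heavy
  }
  if (smear > 0) {
    uni <- diff(edges) / (edges[length(edges)] - edges[1])
    base <- (1 - smear) * base + smear * uni
  }
  base
}

#' Simulate a paired 13C/12C SIP gradient experiment
#'
#' Generates, for one experimental context, a 12C-control gradient and a
#' 13C-treatment gradient over the fraction grid of `params`, with known
#' ground truth. See [sip_sim_params()] for the generative model.
#'
#' @param params A [sip_sim_params()].
#' @param context List with `species`, `compartment`, `timepoint_h` stamped
#'   into the metadata.
#' @param gradient_prefix Prefix for gradient and sample IDs.
#' @return List with `table` (an [otu_table()]), `meta` (fraction metadata,
#'   one row per fraction per gradient, `density_class` unassigned), and
#'   `truth` (a `synthetic_truth` list: `labelled_taxa`, `taxonomy`,
#'   `params`).
#' @export
simulate_gradient_experiment <- function(params = sip_sim_params(),
                                         context = list(
                                           species = "T_officinale",
                                           compartment = "phyllosphere",
                                           timepoint_h = 24),
                                         gradient_prefix = "G") {
  withr_seed <- params$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  sim <- .simulate_pair_counts(params)
  edges <- params$fraction_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n_frac <- length(mids)
  meta <- do.call(rbind, lapply(c("C12", "C13"), function(iso) {
    gid <- paste0(gradient_prefix, "_", iso)
    data.frame(sample_id = paste0(gid, "_F", seq_len(n_frac)),
               isotope = iso, gradient_id = gid,
               fraction_index = seq_len(n_frac),
               refractive_index = NA_real_, buoyant_density = mids,
               compartment = context$compartment,
               timepoint_h = context$timepoint_h,
               species = context$species, density_class = "unassigned",
               stringsAsFactors = FALSE)
  }))
  counts <- cbind(sim$c12, sim$c13)
  colnames(counts) <- meta$sample_id
  truth <- list(labelled_taxa = sim$labelled_taxa, taxonomy = sim$taxonomy,
                base_abundances = sim$base_abundances, params = params)
  class(truth) <- "synthetic_truth"
  list(table = otu_table(counts), meta = validate_fraction_meta(meta),
       truth = truth)
}

# Core generator: counts for one 12C and one 13C gradient (taxa x fractions
# each). Assumes the RNG state is already seeded by the caller.
.simulate_pair_counts <- function(params) {
  n <- params$n_taxa
  taxa <- sprintf("OTU%03d", seq_len(n))
  ab <- params$base_abundances
  if (is.null(ab)) {
    ab <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    ab <- ab / sum(ab)
  }
  lab <- params$labelled_taxa %||% taxa[seq_len(min(params$n_labelled, n))]
  mus <- stats::rnorm(n, params$density_mean, params$density_sd)
  edges <- params$fraction_edges
  n_frac <- length(edges) - 1L
  # mass leakage check: grid should span +-3 profile_sd around all means
  span_lo <- min(mus) - 3 * params$profile_sd
  span_hi <- max(mus + ifelse(taxa %in% lab, params$density_shift, 0)) +
    3 * params$profile_sd
  if (span_lo < edges[1] || span_hi > edges[length(edges)])
    warning(sprintf(
      "fraction grid [%.3f, %.3f] does not cover +-3 SD of all profiles [%.3f, %.3f]; mass outside the grid is discarded",
      edges[1], edges[length(edges)], span_lo, span_hi), call. = FALSE)
  draw_gradient <- function(is_c13) {
    mass <- vapply(seq_len(n), function(i) {
      w <- if (is_c13 && taxa[i] %in% lab) params$label_fraction else 0
      ab[i] * .bin_masses(mus[i], params$profile_sd, edges,
                          params$density_shift, w,
                          params$background_smear %||% 0)
    }, numeric(n_frac))
    mass <- matrix(mass, nrow = n_frac)  # fractions x taxa
    counts <- apply(mass, 1, function(frac_mass) {
      if (sum(frac_mass) <= 0) return(integer(length(frac_mass)))
      as.integer(stats::rmultinom(1, params$reads_per_fraction,
                                  prob = frac_mass))
    })
    matrix(counts, nrow = n)  # taxa x fractions
  }
  c12 <- draw_gradient(FALSE)
  c13 <- draw_gradient(TRUE)
  rownames(c12) <- rownames(c13) <- taxa
  classes <- c("Alphaproteobacteria", "Gammaproteobacteria", "Actinobacteria")
  taxonomy <- stats::setNames(
    ifelse(taxa %in% lab,
           classes[(match(taxa, lab) - 1L) %% length(classes) + 1L],
           paste0("OtherClass", (seq_len(n) - 1L) %% 4 + 1L)),
    taxa)
  list(c12 = c12, c13 = c13, labelled_taxa = lab, taxonomy = taxonomy,
       base_abundances = stats::setNames(ab, taxa))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Parameters for a simulated radiotracer incubation
#'
#' Emulates a 14C-methanol incubation: biological oxidation releases 14CO2
#' at a constant true rate, so cumulative trapped activity grows linearly
#' at `trap_efficiency * true_rate * specific_activity * dry_mass` Bq/h
#' with additive Gaussian measurement noise (clipped non-negative and made
#' non-decreasing, as a cumulative trap reading must be). The methanol
#' water trap receives `methanol_volatile_fraction * administered_activity`
#' at the end of the run. Defaults mirror the reference incubation design:
#' 631 kBq administered for 3.5 h with traps exchanged every 30 min.
#'
#' @param true_rate True consumption rate, nmol g^-1 h^-1 (default 100).
#' @param dry_mass Dry biomass, g (default 0.05, a typical leaf sample).
#' @param specific_activity Bq/nmol (default 100).
#' @param administered_activity Bq (default 631000).
#' @param duration_h Incubation length, h (default 3.5).
#' @param interval_h Trap exchange interval, h (default 0.5).
#' @param noise_sd Gaussian measurement noise SD, Bq (default 2).
#' @param trap_efficiency Fraction of released 14CO2 caught by the NaOH
#'   traps (default 0.97).
#' @param methanol_volatile_fraction Fraction of the administered activity
#'   recovered in the methanol trap (default 0.965).
#' @param seed Integer seed.
#' @return A `trap_sim_params` list.
#' @export
trap_sim_params <- function(true_rate = 100, dry_mass = 0.05,
                            specific_activity = 100,
                            administered_activity = 631000,
                            duration_h = 3.5, interval_h = 0.5,
                            noise_sd = 2, trap_efficiency = 0.97,
                            methanol_volatile_fraction = 0.965,
                            seed = 1L) {
  stopifnot(true_rate >= 0, dry_mass > 0, specific_activity > 0,
            administered_activity > 0, duration_h > 0, interval_h > 0,
            noise_sd >= 0)
  if (trap_efficiency <= 0 || trap_efficiency > 1)
    stop("trap_efficiency must lie in (0, 1]", call. = FALSE)
  if (methanol_volatile_fraction < 0 || methanol_volatile_fraction > 1)
    stop("methanol_volatile_fraction must lie in [0, 1]", call. = FALSE)
  p <- list(true_rate = true_rate, dry_mass = dry_mass,
            specific_activity = specific_activity,
            administered_activity = administered_activity,
            duration_h = duration_h, interval_h = interval_h,
            noise_sd = noise_sd, trap_efficiency = trap_efficiency,
            methanol_volatile_fraction = methanol_volatile_fraction,
            seed = as.integer(seed))
  class(p) <- "trap_sim_params"
  p
}

#' Simulate a radiotracer trap series with known true rate
#'
#' @param params A [trap_sim_params()].
#' @param label Optional label list passed to [trap_series()].
#' @return List with `series` (a [trap_series()]) and `true_rate`.
#' @export
simulate_trap_series <- function(params = trap_sim_params(), label = list()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  slope <- params$true_rate * params$specific_activity * params$dry_mass
  times <- seq(params$interval_h, params$duration_h, by = params$interval_h)
  co2_frac_end <- params$trap_efficiency * slope * params$duration_h /
    params$administered_activity
  if (co2_frac_end + params$methanol_volatile_fraction > 1)
    stop("parameter error: implied total recovery exceeds the administered ",
         "activity", call. = FALSE)
  y <- params$trap_efficiency * slope * times +
    stats::rnorm(length(times), 0, params$noise_sd)
  y <- cummax(pmax(y, 0))
  series <- trap_series(
    times = times, co2_activity = y,
    methanol_trap_activity =
      params$methanol_volatile_fraction * params$administered_activity,
    administered_activity = params$administered_activity,
    dry_mass = params$dry_mass,
    specific_activity = params$specific_activity,
    label = label)
  list(series = series, true_rate = params$true_rate)
}

#' Generate the full paired study design
#'
#' Emits an OTU table, fraction metadata and ground truth mirroring the
#' reference design: 2 plant species x 3 compartments x {12C, 13C} x 2
#' timepoints (8 h and 24 h) = 24 gradients. Each 13C gradient contributes
#' its heavy, middle and light fractions and each 12C control its heavy and
#' light fractions, for 12 x 3 + 12 x 2 = 60 sequenced samples — one
#' reading of a design whose per-gradient fraction count is a free choice.
#' The same taxa, truly-labelled set and taxonomy are shared across
#' contexts; counts are drawn independently per gradient.
#'
#' @param seed Integer seed.
#' @param params A [sip_sim_params()] used for every context (its `seed`
#'   field is ignored; per-gradient seeds derive from `seed`).
#' @param cfg A [sip_config()] supplying the density windows that decide
#'   which simulated fractions were "sequenced".
#' @return List with `table`, `meta`, `truth` (shared `labelled_taxa` and
#'   `taxonomy`, plus the per-context parameters).
#' @export
make_study_design <- function(seed = 1L, params = sip_sim_params(),
                              cfg = sip_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  species <- c("F_arundinacea", "T_officinale")
  compartments <- c("phyllosphere", "roots", "rhizosphere_soil")
  timepoints <- c(8, 24)
  tables <- list()
  metas <- list()
  truth <- NULL
  g <- 0L
  for (sp in species) for (cp in compartments) for (tp in timepoints) {
    g <- g + 1L
    p <- params
    p$seed <- as.integer((seed * 1000L + g) %% .Machine$integer.max)
    sim <- simulate_gradient_experiment(
      p, context = list(species = sp, compartment = cp, timepoint_h = tp),
      gradient_prefix = sprintf("G%02d_%s_%s_%gh", g, substr(sp, 1, 1), cp, tp))
    # 13C gradients keep heavy+middle+light; 12C controls heavy+light only
    cls <- classify_density(sim$meta$buoyant_density, cfg)
    keep <- ifelse(sim$meta$isotope == "C13",
                   cls %in% c("heavy", "middle", "light"),
                   cls %in% c("heavy", "light"))
    metas[[g]] <- sim$meta[keep, , drop = FALSE]
    tables[[g]] <- unclass(sim$table)[, sim$meta$sample_id[keep], drop = FALSE]
    if (is.null(truth)) truth <- sim$truth
  }
  counts <- do.call(cbind, tables)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  truth$params$seed <- as.integer(seed)
  list(table = otu_table(counts), meta = validate_fraction_meta(meta),
       truth = truth)
}

#' Write synthetic ground truth to plain-text files
#'
#' @param truth A `synthetic_truth` object.
#' @param truth_path Output TSV path (taxon, class, labelled flag, base
#'   abundance).
#' @param params_path Output YAML path for the generating parameters.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, truth_path, params_path) {
  taxa <- names(truth$taxonomy)
  df <- data.frame(taxon_id = taxa, lineage = unname(truth$taxonomy),
                   labelled = taxa %in% truth$labelled_taxa,
                   base_abundance = unname(truth$base_abundances[taxa]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- truth$params
  p$labelled_taxa <- as.list(truth$labelled_taxa)
  p$base_abundances <- NULL
  yaml::write_yaml(lapply(unclass(p), function(v)
    if (is.null(v)) NULL else v), params_path)
  invisible(c(truth_path, params_path))
}
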