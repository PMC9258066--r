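#' Relative abundance of a count vector
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @return Proportions summing to 1.
#' @examples
#' relative_abundance(c(5, 5, 10))
#' @export
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0)
    stop("empty fraction: all counts are zero", call. = FALSE)
  counts / total
}

#' Build paired 13C/12C gradient abundance profiles
#'
#' For each experimental context (species where recorded, compartment,
#' timepoint) present in both isotope treatments, pools the counts of all
#' fractions classified "heavy" (resp. "light") within each gradient,
#' normalizes to relative abundances, and assembles the three vectors the
#' labelling criteria compare: the 13C heavy fraction, the 13C light
#' fraction and the 12C heavy fraction. Pooling before normalization is a
#' package convention: when several fractions of one gradient fall in a
#' density class their counts are summed, so "the heavy fraction" is always
#' a single profile per gradient.
#'
#' @param table An [otu_table()].
#' @param meta Fraction metadata with `density_class` assigned (see
#'   [classify_fractions()]).
#' @param cfg A [sip_config()].
#' @return A list of `gradient_pair` objects. Each carries `taxon_ids`,
#'   proportions `c13_heavy`, `c13_light`, `c12_heavy`, pooled read depths
#'   `depth_c13_heavy`, `depth_c13_light`, `depth_c12_heavy`, and a
#'   `context` list (species, compartment, timepoint_h).
#' @export
build_gradient_pairs <- function(table, meta, cfg = sip_config()) {
  validate_otu_table(table)
  join_validate(table, meta)
  if (all(meta$density_class == "unassigned"))
    stop("fractions are unclassified; run classify_fractions() first",
         call. = FALSE)
  key <- paste(meta$species, meta$compartment, meta$timepoint_h, sep = "\r")
  contexts <- unique(key)
  pairs <- list()
  for (ctx in contexts) {
    sub <- meta[key == ctx, , drop = FALSE]
    has13 <- any(sub$isotope == "C13")
    has12 <- any(sub$isotope == "C12")
    ctx_label <- paste(sub$species[1], sub$compartment[1], sub$timepoint_h[1],
                       sep = "/")
    if (has13 && !has12)
      stop("pairing error: 13C gradient without 12C control in context ",
           ctx_label, call. = FALSE)
    if (!has13) next  # control-only context carries no call
    pooled <- function(iso, cls) {
      ids <- sub$sample_id[sub$isotope == iso & sub$density_class == cls]
      if (!length(ids))
        stop("pairing error: no ", cls, " fraction for ", iso,
             " gradient in context ", ctx_label, call. = FALSE)
      rowSums(unclass(table)[, ids, drop = FALSE])
    }
    h13 <- pooled("C13", "heavy")
    l13 <- pooled("C13", "light")
    h12 <- pooled("C12", "heavy")
    pair <- list(
      taxon_ids = rownames(table),
      c13_heavy = relative_abundance(h13),
      c13_light = relative_abundance(l13),
      c12_heavy = relative_abundance(h12),
      depth_c13_heavy = sum(h13),
      depth_c13_light = sum(l13),
      depth_c12_heavy = sum(h12),
      context = list(species = sub$species[1],
                     compartment = sub$compartment[1],
                     timepoint_h = sub$timepoint_h[1])
    )
    class(pair) <- "gradient_pair"
    pairs[[length(pairs) + 1L]] <- pair
  }
  if (!length(pairs))
    stop("pairing error: no 13C/12C gradient pair found", call. = FALSE)
  pairs
}

#' Call 13C-labelled taxa in one gradient pair
#'
#' Applies the three enrichment criteria that define a 13C-labelled taxon:
#'
#' 1. its relative abundance in the 13C treatment's heavy fraction is
#'    strictly higher than in the same (heavy) fraction of the 12C control;
#' 2. its heavy-fraction abundance is strictly higher than `K` times its
#'    abundance in the light fraction of the 13C gradient (default K = 2,
#'    chosen low because short incubations label RNA only partially);
#' 3. its heavy-fraction abundance is at least `min_heavy_abundance`
#'    (default 0.05%).
#'
#' A taxon is labelled iff all three hold. When a taxon is absent from the
#' light fraction, criterion 2 compares against `K *` a pseudo-abundance
#' (default 1 / (2 * pooled light read depth)) so the rule stays monotone in
#' `K` and aware of sequencing depth.
#'
#' @param pair A `gradient_pair` from [build_gradient_pairs()].
#' @param cfg A [sip_config()].
#' @return A `sip_calls` data frame with one row per taxon: the three
#'   abundances, `c1_pass`, `c2_pass`, `c3_pass` and `labelled`.
#' @export
call_labelled <- function(pair, cfg = sip_config()) {
  validate_sip_config(cfg)
  h13 <- pair$c13_heavy
  l13 <- pair$c13_light
  h12 <- pair$c12_heavy
  stopifnot(length(h13) == length(l13), length(h13) == length(h12))
  pseudo <- cfg$pseudo_abundance %||% (1 / (2 * pair$depth_c13_light))
  l13_eff <- ifelse(l13 > 0, l13, pseudo)
  c1 <- h13 > h12
  c2 <- h13 > cfg$K * l13_eff
  c3 <- h13 >= cfg$min_heavy_abundance
  calls <- data.frame(
    taxon_id = pair$taxon_ids,
    abund_heavy_c13 = h13,
    abund_heavy_c12 = h12,
    abund_light_c13 = l13,
    c1_pass = c1,
    c2_pass = c2,
    c3_pass = c3,
    labelled = c1 & c2 & c3,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(calls, "context") <- pair$context
  attr(calls, "config") <- cfg[c("K", "min_heavy_abundance")]
  class(calls) <- c("sip_calls", "data.frame")
  calls
}

#' @export
print.sip_calls <- function(x, ...) {
  ctx <- attr(x, "context")
  cfg <- attr(x, "config")
  cat("13C label calls")
  if (!is.null(ctx))
    cat(sprintf(" [%s%s, %g h]",
                if (nzchar(ctx$species)) paste0(ctx$species, ", ") else "",
                ctx$compartment, ctx$timepoint_h))
  cat("\n")
  cat(sprintf("  %d taxa evaluated (K = %g, floor = %.3g%%); %d labelled\n",
              nrow(x), cfg$K, 100 * cfg$min_heavy_abundance,
              sum(x$labelled)))
  lab <- x[x$labelled, c("taxon_id", "abund_heavy_c13", "abund_heavy_c12",
                         "abund_light_c13")]
  if (nrow(lab)) {
    lab[-1] <- lapply(lab[-1], function(v) sprintf("%.4f", v))
    print.data.frame(utils::head(lab, 20), row.names = FALSE)
    if (nrow(lab) > 20) cat("  ...", nrow(lab) - 20, "more\n")
  }
  invisible(x)
}

#' @export
summary.sip_calls <- function(object, ...) {
  c(n_taxa = nrow(object),
    n_labelled = sum(object$labelled),
    n_c1 = sum(object$c1_pass),
    n_c2 = sum(object$c2_pass),
    n_c3 = sum(object$c3_pass))
}

#' Aggregate labelled taxa into a lineage-level community profile
#'
#' Restricts the calls to labelled taxa, maps each to a lineage group (e.g.
#' bacterial class), and reports the group's share of the labelled
#' community: heavy-fraction 13C abundances renormalized over labelled taxa
#' (a documented convention, so profiles of pairs with different overall
#' labelling strength remain comparable).
#'
#' @param calls A `sip_calls` object.
#' @param taxonomy Optional named character vector mapping `taxon_id` to a
#'   lineage group; taxa missing from the map (or when `NULL`) group as
#'   themselves.
#' @return A data frame `group`, `labelled_abundance` (shares summing to 1),
#'   `n_taxa`; zero rows when nothing is labelled.
#' @export
summarize_calls <- function(calls, taxonomy = NULL) {
  lab <- calls[calls$labelled, , drop = FALSE]
  if (!nrow(lab))
    return(data.frame(group = character(), labelled_abundance = numeric(),
                      n_taxa = integer(), stringsAsFactors = FALSE))
  group <- if (is.null(taxonomy)) lab$taxon_id else {
    g <- unname(taxonomy[lab$taxon_id])
    ifelse(is.na(g), lab$taxon_id, g)
  }
  share <- lab$abund_heavy_c13 / sum(lab$abund_heavy_c13)
  agg <- stats::aggregate(list(labelled_abundance = share),
                          by = list(group = group), FUN = sum)
  agg$n_taxa <- as.integer(table(group)[agg$group])
  agg[order(-agg$labelled_abundance), , drop = FALSE]
}
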