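#' Construct and validate an OTU count table
#'
#' The canonical abundance container: a non-negative integer matrix of taxa
#' (rows) by samples (columns) with unique identifiers on both margins.
#' Relative abundances are always derived downstream, never stored here.
#'
#' @param counts Integer matrix (taxa x samples), non-negative.
#' @param taxon_ids Character vector of unique row identifiers.
#' @param sample_ids Character vector of unique column identifiers.
#' @return An `otu_table` object: the counts matrix with dimnames set.
#' @examples
#' tab <- otu_table(matrix(c(5L, 1L, 0L, 3L), 2), c("otu1", "otu2"), c("s1", "s2"))
#' sum(tab)
#' @export
otu_table <- function(counts, taxon_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids))
    stop("validation error: taxon and sample IDs are required", call. = FALSE)
  rownames(counts) <- as.character(taxon_ids)
  colnames(counts) <- as.character(sample_ids)
  class(counts) <- c("otu_table", class(counts))
  validate_otu_table(counts)
  counts
}

validate_otu_table <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("validation error: OTU table needs at least 1 taxon and 1 sample",
         call. = FALSE)
  dup_t <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_t))
    stop("validation error: duplicate taxon ID(s): ",
         paste(dup_t, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("validation error: duplicate sample ID(s): ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad))
    stop("validation error: negative or non-integer count at [",
         rownames(x)[bad[1, 1]], ", ", colnames(x)[bad[1, 2]], "]",
         call. = FALSE)
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Expects a UTF-8 TSV whose header row holds sample IDs and whose first
#' column holds taxon IDs. Row and column order are preserved.
#'
#' @param path File path.
#' @return An `otu_table`.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("validation error: OTU table needs a taxon column and >= 1 sample",
         call. = FALSE)
  sample_ids <- colnames(df)[-1]
  taxon_ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  num <- matrix(num, nrow = nrow(df))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("validation error: non-numeric count at [", taxon_ids[bad[1]], ", ",
         sample_ids[bad[2]], "]", call. = FALSE)
  }
  storage.mode(num) <- "double"
  otu_table(num, taxon_ids, sample_ids)
}

#' Write an OTU count table to TSV
#'
#' @param table An `otu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  df <- data.frame(taxon_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.isotope_levels <- c("C12", "C13")
.compartment_levels <- c("phyllosphere", "roots", "rhizosphere_soil")
.density_class_levels <- c("heavy", "middle", "light", "unassigned")

normalize_isotope <- function(x) {
  up <- toupper(gsub("[^0-9A-Za-z]", "", x))
  out <- ifelse(up %in% c("C12", "12C"), "C12",
                ifelse(up %in% c("C13", "13C"), "C13", NA_character_))
  if (anyNA(out))
    stop("validation error: unknown isotope value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected 12C/13C)", call. = FALSE)
  out
}

#' Read per-sample gradient fraction metadata from TSV
#'
#' One row per sequenced gradient fraction. Required columns: `sample_id`,
#' `isotope` ("12C"/"13C" or "C12"/"C13"), `gradient_id`, `fraction_index`,
#' `compartment`, `timepoint_h`, and at least one of `refractive_index` /
#' `buoyant_density` per row. Optional columns: `species` (used in the
#' gradient pairing key when present) and `density_class`.
#'
#' @param path File path.
#' @return A `data.frame` of validated fraction metadata with a
#'   `density_class` column (filled with "unassigned" when absent).
#' @export
read_fraction_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_fraction_meta(df)
}

validate_fraction_meta <- function(df) {
  required <- c("sample_id", "isotope", "gradient_id", "fraction_index",
                "compartment", "timepoint_h")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("validation error: metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!("refractive_index" %in% names(df))) df$refractive_index <- NA_real_
  if (!("buoyant_density" %in% names(df))) df$buoyant_density <- NA_real_
  if (!("species" %in% names(df))) df$species <- ""
  if (!("density_class" %in% names(df))) df$density_class <- "unassigned"
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("validation error: sample_id appears in more than one record: ",
         paste(dup, collapse = ", "), call. = FALSE)
  df$isotope <- normalize_isotope(df$isotope)
  bad_comp <- setdiff(unique(df$compartment), .compartment_levels)
  if (length(bad_comp))
    stop("validation error: unknown compartment value(s): ",
         paste(bad_comp, collapse = ", "), call. = FALSE)
  bad_class <- setdiff(unique(df$density_class), .density_class_levels)
  if (length(bad_class))
    stop("validation error: unknown density_class value(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  df$fraction_index <- as.integer(df$fraction_index)
  if (any(is.na(df$fraction_index)) || any(df$fraction_index < 1L))
    stop("validation error: fraction_index must be an integer >= 1",
         call. = FALSE)
  df$timepoint_h <- as.numeric(df$timepoint_h)
  if (any(is.na(df$timepoint_h)) || any(df$timepoint_h < 0))
    stop("validation error: timepoint_h must be a number >= 0", call. = FALSE)
  df$refractive_index <- as.numeric(df$refractive_index)
  df$buoyant_density <- as.numeric(df$buoyant_density)
  neither <- is.na(df$refractive_index) & is.na(df$buoyant_density)
  if (any(neither))
    stop("validation error: sample(s) lacking both refractive_index and ",
         "buoyant_density: ", paste(df$sample_id[neither], collapse = ", "),
         call. = FALSE)
  if (any(!is.na(df$buoyant_density) & df$buoyant_density < 1.0))
    stop("validation error: buoyant_density below 1.0 g/mL", call. = FALSE)
  df
}

#' Write fraction metadata to TSV
#'
#' @param meta A fraction-metadata `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fraction_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Cross-validate an OTU table against fraction metadata
#'
#' Accepts iff the OTU table's sample IDs and the metadata's sample IDs are
#' exactly the same set.
#'
#' @param table An `otu_table`.
#' @param meta A fraction-metadata `data.frame`.
#' @return `TRUE`, invisibly, on success.
#' @export
join_validate <- function(table, meta) {
  in_table <- colnames(table)
  in_meta <- meta$sample_id
  only_t <- setdiff(in_table, in_meta)
  only_m <- setdiff(in_meta, in_table)
  if (length(only_t) || length(only_m))
    stop("cross-reference error: sample ID mismatch",
         if (length(only_t)) paste0("; in table only: ",
                                    paste(only_t, collapse = ", ")),
         if (length(only_m)) paste0("; in metadata only: ",
                                    paste(only_m, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read radiotracer trap series from TSV
#'
#' Long format: a time-series file with columns
#' `incubation_id, time_h, co2_bq` (cumulative trapped 14CO2 activity), plus
#' a per-incubation header file with columns `incubation_id, administered_bq,
#' methanol_trap_bq, dry_mass_g, specific_activity_bq_per_nmol, species,
#' compartment`.
#'
#' @param series_path Path to the long time-series TSV.
#' @param header_path Path to the per-incubation header TSV.
#' @return A list of [trap_series()] objects, named by incubation ID.
#' @export
read_trap_series <- function(series_path, header_path) {
  long <- utils::read.delim(series_path, sep = "\t", stringsAsFactors = FALSE)
  hdr <- utils::read.delim(header_path, sep = "\t", stringsAsFactors = FALSE)
  need_long <- c("incubation_id", "time_h", "co2_bq")
  need_hdr <- c("incubation_id", "administered_bq", "methanol_trap_bq",
                "dry_mass_g", "specific_activity_bq_per_nmol")
  if (length(setdiff(need_long, names(long))))
    stop("validation error: trap series file lacks column(s): ",
         paste(setdiff(need_long, names(long)), collapse = ", "), call. = FALSE)
  if (length(setdiff(need_hdr, names(hdr))))
    stop("validation error: trap header file lacks column(s): ",
         paste(setdiff(need_hdr, names(hdr)), collapse = ", "), call. = FALSE)
  orphans <- setdiff(unique(long$incubation_id), hdr$incubation_id)
  if (length(orphans))
    stop("cross-reference error: incubation(s) in series without header: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(hdr)), function(i) {
    h <- hdr[i, ]
    rows <- long[long$incubation_id == h$incubation_id, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    trap_series(
      times = rows$time_h,
      co2_activity = rows$co2_bq,
      methanol_trap_activity = h$methanol_trap_bq,
      administered_activity = h$administered_bq,
      dry_mass = h$dry_mass_g,
      specific_activity = h$specific_activity_bq_per_nmol,
      label = list(species = if ("species" %in% names(h)) h$species else "",
                   compartment = if ("compartment" %in% names(h)) h$compartment else "",
                   replicate = h$incubation_id)
    )
  })
  names(out) <- hdr$incubation_id
  out
}

#' Write a list of trap series to the TSV pair read by [read_trap_series()]
#'
#' @param series_list Named list of `trap_series` objects.
#' @param series_path Output path for the long time-series TSV.
#' @param header_path Output path for the per-incubation header TSV.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_trap_series <- function(series_list, series_path, header_path) {
  ids <- names(series_list)
  if (is.null(ids)) ids <- paste0("inc", seq_along(series_list))
  long <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(incubation_id = ids[i], time_h = s$times, co2_bq = s$co2_activity,
               stringsAsFactors = FALSE)
  }))
  hdr <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(incubation_id = ids[i],
               administered_bq = s$administered_activity,
               methanol_trap_bq = s$methanol_trap_activity,
               dry_mass_g = s$dry_mass,
               specific_activity_bq_per_nmol = s$specific_activity,
               species = s$label$species %||% "",
               compartment = s$label$compartment %||% "",
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, series_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hdr, header_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(series_path, header_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
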