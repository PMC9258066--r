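#' Remove dataset-wide singleton taxa
#'
#' Drops every taxon whose total count across ALL samples equals 1 (the
#' whole-dataset definition, not per-sample). Idempotent.
#'
#' @param table An [otu_table()].
#' @return The filtered `otu_table` (may have fewer taxa; errors only if no
#'   taxon survives, since an empty table violates the container invariant).
#' @export
remove_singletons <- function(table) {
  validate_otu_table(table)
  keep <- rowSums(unclass(table)) != 1
  otu_table(unclass(table)[keep, , drop = FALSE])
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i`, natural logarithm by default (configurable, e.g.
#' base 2); zero proportions contribute nothing.
#'
#' @param p Proportion vector summing to 1 (counts are accepted and
#'   normalized).
#' @param base Logarithm base, default `exp(1)`.
#' @return H (dimensionless).
#' @examples
#' shannon(rep(0.25, 4))  # log(4)
#' @export
shannon <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("empty abundance vector", call. = FALSE)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1 and F2 are the numbers of
#' taxa observed exactly once and twice in the sample. The bias-corrected
#' (+1) denominator keeps the estimator defined when no doubletons occur.
#'
#' @param counts Non-negative integer vector of per-taxon counts in one
#'   sample.
#' @return Estimated richness, always >= observed richness.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), rep(5, 4)))  # 10 + 4*3/(2*3) = 12
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Expected rarefied richness
#'
#' Analytic hypergeometric expectation of the number of taxa observed in a
#' random subsample of `depth` reads drawn without replacement:
#' `sum_i [1 - C(N - N_i, depth) / C(N, depth)]`. Computed on log scale for
#' numerical stability.
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param depth Subsample size, `1 <= depth <= sum(counts)`.
#' @return Expected richness at `depth`.
#' @export
rarefy_expected <- function(counts, depth) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (depth > n)
    stop("depth (", depth, ") exceeds total count (", n, ")", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  counts <- counts[counts > 0]
  miss <- ifelse(n - counts < depth, 0,
                 exp(lchoose(n - counts, depth) - lchoose(n, depth)))
  sum(1 - miss)
}

#' Rarefaction curve for one sample
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param depths Integer subsample sizes (values above the total count are
#'   dropped).
#' @return Data frame `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  depths <- sort(unique(as.integer(depths)))
  depths <- depths[depths >= 1 & depths <= sum(counts)]
  data.frame(depth = depths,
             expected_richness = vapply(depths, function(d)
               rarefy_expected(counts, d), numeric(1)))
}

#' Asymptotic richness by Michaelis-Menten fit
#'
#' Fits `r(d) = n_max * d / (k + d)` to a rarefaction curve by
#' Levenberg-Marquardt least squares, giving the asymptotic ("maximal")
#' OTU number n_max and the half-saturation depth k. Initialized at
#' n_max = max observed richness and k solved from the first point of the
#' curve (falling back to the median depth when that is degenerate), with
#' both parameters bounded positive; the first-point start keeps already
#' saturated curves, whose k is far below any sampled depth, inside the
#' solver's basin.
#'
#' @param depths Strictly increasing subsample sizes, >= 3 points.
#' @param richness Observed or expected richness at each depth.
#' @return List with `n_max`, `half_saturation`, `converged`.
#' @export
fit_nmax <- function(depths, richness) {
  if (length(depths) < 3L)
    stop("need at least 3 points to fit the saturation curve", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  df <- data.frame(d = as.numeric(depths), r = as.numeric(richness))
  nmax0 <- max(df$r)
  # invert the first curve point for k; degenerate when r1 ~ nmax0 * 1
  k0 <- if (df$r[1] > 0 && df$r[1] < nmax0)
    df$d[1] * (nmax0 / df$r[1] - 1) else stats::median(df$d)
  start <- list(n_max = nmax0, k = max(k0, 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ n_max * d / (k + d), data = df, start = start,
                      lower = c(n_max = 1e-8, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(n_max = NA_real_, half_saturation = NA_real_,
                converged = FALSE))
  co <- stats::coef(fit)
  list(n_max = unname(co["n_max"]), half_saturation = unname(co["k"]),
       converged = TRUE)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 sum min(x_i, y_i) / (sum x + sum y)`, in `[0, 1]`; 0 for
#' identical vectors, 1 for disjoint supports.
#'
#' @param x,y Non-negative vectors of equal length (counts or proportions).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero", call. = FALSE)
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Per-sample diversity summary of an OTU table
#'
#' Observed richness, Shannon (natural log by default), bias-corrected
#' Chao1, and the Michaelis-Menten asymptotic richness n_max fitted to the
#' sample's analytic rarefaction curve.
#'
#' @param table An [otu_table()].
#' @param n_curve Number of rarefaction depths used for the n_max fit,
#'   default 20 (evenly spaced up to the sample depth).
#' @param shannon_base Logarithm base for Shannon, default natural log.
#' @return Data frame with one row per sample.
#' @export
diversity_table <- function(table, n_curve = 20L, shannon_base = exp(1)) {
  validate_otu_table(table)
  m <- unclass(table)
  rows <- lapply(colnames(m), function(sid) {
    v <- m[, sid]
    total <- sum(v)
    nmax <- c(n_max = NA_real_)
    if (total >= 3) {
      depths <- unique(pmax(1, round(seq(1, total, length.out = n_curve))))
      curve <- rarefaction_curve(v, depths)
      if (nrow(curve) >= 3) {
        fit <- fit_nmax(curve$depth, curve$expected_richness)
        nmax <- c(n_max = fit$n_max)
      }
    }
    data.frame(sample_id = sid, total_reads = total,
               observed_richness = sum(v > 0),
               shannon = shannon(v, base = shannon_base),
               chao1 = chao1(v), n_max = unname(nmax),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
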