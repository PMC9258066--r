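test_that("relative abundance normalizes and rejects empty fractions", {
  expect_equal(relative_abundance(c(5, 5, 10)), c(0.25, 0.25, 0.5))
  expect_equal(relative_abundance(7), 1)
  expect_error(relative_abundance(c(0, 0)), "empty fraction")
  set.seed(42)
  for (i in 1:50) {
    v <- rpois(sample(1:30, 1), 5) + 1
    expect_equal(sum(relative_abundance(v)), 1)
  }
})

test_that("the three criteria reproduce their worked examples", {
  mk_pair <- function(h13, h12, l13) {
    # embed the focal taxon in a 2-taxon pair; the filler absorbs the rest
    pair <- list(taxon_ids = c("focal", "rest"),
                 c13_heavy = c(h13, 1 - h13),
                 c13_light = c(l13, 1 - l13),
                 c12_heavy = c(h12, 1 - h12),
                 depth_c13_heavy = 10000, depth_c13_light = 10000,
                 depth_c12_heavy = 10000,
                 context = list(species = "", compartment = "roots",
                                timepoint_h = 8))
    class(pair) <- "gradient_pair"
    pair
  }
  cfg <- sip_config()  # K = 2, floor 0.05%

  # all three criteria pass
  cl <- call_labelled(mk_pair(0.0020, 0.0005, 0.0008), cfg)
  expect_true(cl$c1_pass[1] && cl$c2_pass[1] && cl$c3_pass[1])
  expect_true(cl$labelled[1])

  # below the abundance floor: not labelled regardless of c1/c2
  cl <- call_labelled(mk_pair(0.0004, 0.0001, 0.0001), cfg)
  expect_false(cl$c3_pass[1])
  expect_false(cl$labelled[1])

  # heavy/light enrichment below K = 2 (0.0010 <= 2 * 0.0006)
  cl <- call_labelled(mk_pair(0.0010, 0.0001, 0.0006), cfg)
  expect_false(cl$c2_pass[1])
  expect_false(cl$labelled[1])

  # labelled is exactly the conjunction, for every taxon
  cl <- call_labelled(mk_pair(0.0020, 0.0005, 0.0008), cfg)
  expect_equal(cl$labelled, cl$c1_pass & cl$c2_pass & cl$c3_pass)
})

test_that("strict and non-strict inequalities sit exactly at the boundaries", {
  pair <- list(taxon_ids = c("eq_ctrl", "eq_K", "eq_floor"),
               c13_heavy = c(0.001, 0.0012, 0.0005),
               c12_heavy = c(0.001, 0.00001, 0.00001),
               c13_light = c(0.0001, 0.0006, 0.0001),
               depth_c13_heavy = 1e6, depth_c13_light = 1e6,
               depth_c12_heavy = 1e6,
               context = list(species = "", compartment = "roots",
                              timepoint_h = 8))
  # pad vectors to sum 1 with a fourth taxon
  pair$taxon_ids <- c(pair$taxon_ids, "pad")
  pair$c13_heavy <- c(pair$c13_heavy, 1 - sum(pair$c13_heavy))
  pair$c12_heavy <- c(pair$c12_heavy, 1 - sum(pair$c12_heavy))
  pair$c13_light <- c(pair$c13_light, 1 - sum(pair$c13_light))
  class(pair) <- "gradient_pair"
  cl <- call_labelled(pair, sip_config())
  expect_false(cl$c1_pass[1])  # equal to control: strict > fails
  expect_false(cl$c2_pass[2])  # exactly K * light: strict > fails
  expect_true(cl$c3_pass[3])   # exactly at the floor: >= passes
})

test_that("caller agrees with the brute-force oracle on random pairs", {
  set.seed(101)
  cfg <- sip_config()
  for (i in 1:200) {
    pair <- random_pair(n_taxa = sample(2:50, 1))
    cl <- call_labelled(pair, cfg)
    expect_identical(cl$labelled, oracle_labelled(pair))
  }
})

test_that("labelled sets shrink monotonically in K and in the floor", {
  set.seed(202)
  pairs <- replicate(20, random_pair(30), simplify = FALSE)
  for (pair in pairs) {
    prev <- NULL
    for (K in c(1, 2, 4, 8)) {
      lab <- call_labelled(pair, sip_config(K = K))$labelled
      if (!is.null(prev)) expect_true(all(lab <= prev))
      prev <- lab
    }
    prev <- NULL
    for (fl in c(0, 0.0005, 0.005)) {
      lab <- call_labelled(pair, sip_config(min_heavy_abundance = fl))$labelled
      if (!is.null(prev)) expect_true(all(lab <= prev))
      prev <- lab
    }
  }
})

test_that("gradient pairing keys on context and surfaces orphans", {
  d <- make_study_design(seed = 3)
  meta <- classify_fractions(d$meta)
  pairs <- build_gradient_pairs(d$table, meta)
  # one pair per (species, compartment, timepoint) context
  expect_length(pairs, 2 * 3 * 2)
  ctxs <- vapply(pairs, function(p)
    paste(p$context$species, p$context$compartment, p$context$timepoint_h),
    character(1))
  expect_false(any(duplicated(ctxs)))
  # pooled profiles are simplex vectors with shared taxon order
  for (p in pairs[1:3]) {
    expect_equal(sum(p$c13_heavy), 1, tolerance = 1e-9)
    expect_equal(sum(p$c13_light), 1, tolerance = 1e-9)
    expect_equal(sum(p$c12_heavy), 1, tolerance = 1e-9)
    expect_identical(p$taxon_ids, rownames(d$table))
  }
  # removing a 12C control orphans its 13C gradient
  drop <- meta$isotope == "C12" & meta$species == "T_officinale" &
    meta$compartment == "roots" & meta$timepoint_h == 8
  meta2 <- meta[!drop, , drop = FALSE]
  tab2 <- otu_table(unclass(d$table)[, meta2$sample_id, drop = FALSE])
  expect_error(build_gradient_pairs(tab2, meta2),
               "pairing error.*T_officinale/roots/8")
})

test_that("pooling sums fraction counts within a density class before normalizing", {
  counts <- matrix(c(10, 30, 20, 40, 5, 5, 1, 9), nrow = 2,
                   dimnames = list(c("a", "b"),
                                   c("h1_13", "h2_13", "l_13", "h_12")))
  meta <- data.frame(
    sample_id = colnames(counts), isotope = c("C13", "C13", "C13", "C12"),
    gradient_id = c("g13", "g13", "g13", "g12"),
    fraction_index = c(1, 2, 3, 1),
    buoyant_density = c(1.80, 1.81, 1.77, 1.80),
    refractive_index = NA_real_,
    compartment = "phyllosphere", timepoint_h = 8, species = "sp",
    density_class = "unassigned")
  meta <- classify_fractions(validate_fraction_meta(meta), sip_config())
  # only 13C heavy/light and 12C heavy are required, so this pairs cleanly
  pair <- build_gradient_pairs(otu_table(counts), meta)[[1]]
  expect_equal(pair$c13_heavy, c(a = 30 / 100, b = 70 / 100))
  expect_equal(pair$depth_c13_heavy, 100)
})

test_that("summaries aggregate labelled taxa by lineage with renormalized shares", {
  calls <- data.frame(
    taxon_id = c("t1", "t2", "t3"),
    abund_heavy_c13 = c(0.02, 0.03, 0.5),
    abund_heavy_c12 = 0, abund_light_c13 = 0,
    c1_pass = TRUE, c2_pass = TRUE,
    c3_pass = c(TRUE, TRUE, FALSE),
    labelled = c(TRUE, TRUE, FALSE))
  class(calls) <- c("sip_calls", "data.frame")
  out <- summarize_calls(calls, c(t1 = "ClassA", t2 = "ClassA", t3 = "ClassB"))
  expect_equal(nrow(out), 1)
  expect_equal(out$labelled_abundance, 1)
  expect_equal(out$n_taxa, 2L)
  # no labelled taxa -> empty table, not an error
  calls$labelled <- FALSE
  expect_equal(nrow(summarize_calls(calls)), 0)
})

test_that("simulated truth classes are exactly the summarized classes", {
  d <- make_study_design(seed = 9)
  meta <- classify_fractions(d$meta)
  pairs <- build_gradient_pairs(d$table, meta)
  cl <- call_labelled(pairs[[1]])
  s <- summarize_calls(cl, d$truth$taxonomy)
  truth_classes <- sort(unique(unname(
    d$truth$taxonomy[d$truth$labelled_taxa])))
  expect_equal(sort(s$group), truth_classes)
  expect_equal(sum(s$labelled_abundance), 1)
})
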