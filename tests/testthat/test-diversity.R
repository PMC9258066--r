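test_that("singleton removal drops dataset-wide singletons only, idempotently", {
  m <- matrix(c(1, 0, 0,   # total 1 -> dropped
                1, 1, 0,   # total 2 -> kept
                0, 0, 1,   # total 1 -> dropped
                5, 2, 3),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  out <- remove_singletons(otu_table(m))
  expect_equal(rownames(out), c("t2", "t4"))
  expect_identical(unclass(remove_singletons(out)), unclass(out))
  # conservation: output total = input total - number of singletons
  set.seed(5)
  for (i in 1:10) {
    r <- matrix(rpois(60, 0.7), nrow = 12,
                dimnames = list(paste0("t", 1:12), paste0("s", 1:5)))
    r[1, ] <- c(9, rep(0, 4))  # guarantee a survivor
    n_single <- sum(rowSums(r) == 1)
    expect_equal(sum(remove_singletons(otu_table(r))),
                 sum(r) - n_single)
  }
})

test_that("Shannon index hits the closed forms and entropy bounds", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(1)), 0)
  expect_equal(shannon(c(0.5, 0.5, 0)), log(2))
  expect_equal(shannon(rep(0.25, 4), base = 2), 2)
  set.seed(3)
  for (i in 1:100) {
    k <- sample(2:40, 1)
    p <- rexp(k); p <- p / sum(p)
    h <- shannon(p)
    expect_gte(h, 0)
    expect_lte(h, log(sum(p > 0)) + 1e-12)
  }
})

test_that("Chao1 uses the bias-corrected form and never undershoots richness", {
  # no singletons: estimate equals observed
  expect_equal(chao1(c(2, 3, 5)), 3)
  # S_obs 10, F1 4, F2 2 -> 10 + 4*3/(2*3) = 12
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(7, 4))), 12)
  # F2 = 0 stays defined: 3 + 2*1/(2*1)
  expect_equal(chao1(c(1, 1, 5)), 4)
  set.seed(23)
  for (i in 1:100) {
    v <- rpois(50, 1)
    if (all(v == 0)) v[1] <- 1
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("analytic rarefaction matches the hypergeometric limits", {
  v <- c(10, 5, 1, 0, 30)
  expect_equal(rarefy_expected(v, sum(v)), 4)  # full depth: observed richness
  expect_equal(rarefy_expected(v, 1), 1)       # one read, one taxon
  expect_error(rarefy_expected(v, sum(v) + 1), "exceeds")
  # concave non-decreasing in depth, bounded by observed richness
  curve <- rarefaction_curve(v, 1:46)
  expect_true(all(diff(curve$expected_richness) >= -1e-12))
  expect_true(all(diff(diff(curve$expected_richness)) <= 1e-9))
  expect_true(all(curve$expected_richness <= 4 + 1e-12))
})

test_that("analytic rarefaction matches Monte-Carlo subsampling and vegan", {
  set.seed(77)
  v <- c(40, 25, 12, 6, 3, 2, 1, 1)
  depth <- 30
  reads <- rep(seq_along(v), v)
  mc <- replicate(4000, length(unique(sample(reads, depth))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(rarefy_expected(v, depth) - mean(mc)), 3 * se)
  # independent implementation cross-check
  expect_equal(rarefy_expected(v, depth),
               as.numeric(vegan::rarefy(v, depth)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Michaelis-Menten fit inverts noiseless curves and saturates", {
  d <- c(10, 25, 50, 100, 250, 500, 1000)
  r <- 100 * d / (50 + d)
  fit <- fit_nmax(d, r)
  expect_true(fit$converged)
  expect_equal(fit$n_max, 100, tolerance = 1e-6)
  expect_equal(fit$half_saturation, 50, tolerance = 1e-6)
  # flat richness at large depth: asymptote approaches the plateau
  d2 <- c(500, 1000, 2000, 4000, 8000)
  fit2 <- fit_nmax(d2, 42 * d2 / (1 + d2))
  expect_equal(fit2$n_max, 42, tolerance = 0.01)
  # asymptote bounds the observed maximum on monotone data
  expect_gte(fit$n_max, max(r) - 1e-6)
  expect_error(fit_nmax(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Bray-Curtis hits its closed forms and metric properties", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 4, 0)), 1)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 - 2 * 4 / 12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(19)
  for (i in 1:50) {
    x <- rpois(10, 3); y <- rpois(10, 3); z <- rpois(10, 3)
    x[1] <- x[1] + 1; y[1] <- y[1] + 1; z[1] <- z[1] + 1
    dxy <- bray_curtis(x, y); dyx <- bray_curtis(y, x)
    expect_identical(dxy, dyx)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    # cross-check against vegan
    expect_equal(dxy, as.numeric(vegan::vegdist(rbind(x, y))),
                 tolerance = 1e-12)
  }
})

test_that("per-sample diversity table is permutation-invariant in taxon order", {
  set.seed(55)
  m <- matrix(rpois(80, 8) + 1, nrow = 16,
              dimnames = list(paste0("t", 1:16), paste0("s", 1:5)))
  tab <- otu_table(m)
  d1 <- diversity_table(tab, n_curve = 8)
  perm <- sample(16)
  d2 <- diversity_table(otu_table(m[perm, , drop = FALSE]), n_curve = 8)
  expect_equal(d1$shannon, d2$shannon)
  expect_equal(d1$chao1, d2$chao1)
  expect_equal(d1$n_max, d2$n_max, tolerance = 1e-6)
  expect_true(all(d1$n_max >= d1$observed_richness - 1e-6 |
                    is.na(d1$n_max)))
})
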