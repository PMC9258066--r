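# Shared fixture builders and independent oracles.

# Tiny 2-taxon, 2-sample table.
tiny_table <- function() {
  otu_table(matrix(c(5, 1, 0, 3), nrow = 2),
            taxon_ids = c("otuA", "otuB"), sample_ids = c("s1", "s2"))
}

# A random gradient pair built directly from count draws: heavy/light 13C
# and heavy 12C count vectors are independent multinomial-ish draws with a
# point mass at zero so the pseudo-abundance path is exercised.
random_pair <- function(n_taxa, depth = 2000, zero_prob = 0.3) {
  draw <- function() {
    w <- rexp(n_taxa)
    w[runif(n_taxa) < zero_prob] <- 0
    if (all(w == 0)) w[1] <- 1
    as.numeric(rmultinom(1, depth, prob = w))
  }
  h13 <- draw(); l13 <- draw(); h12 <- draw()
  pair <- list(
    taxon_ids = sprintf("t%02d", seq_len(n_taxa)),
    c13_heavy = h13 / sum(h13),
    c13_light = l13 / sum(l13),
    c12_heavy = h12 / sum(h12),
    depth_c13_heavy = sum(h13),
    depth_c13_light = sum(l13),
    depth_c12_heavy = sum(h12),
    context = list(species = "", compartment = "phyllosphere",
                   timepoint_h = 8))
  class(pair) <- "gradient_pair"
  pair
}

# Independent brute-force evaluation of the three labelling criteria,
# written taxon by taxon straight from their verbal statement:
# (1) heavy 13C abundance strictly above the 12C control's heavy fraction;
# (2) heavy strictly above K times the 13C light fraction (a taxon absent
#     from the light fraction is compared against the pseudo-abundance);
# (3) heavy at least the minimum abundance floor.
oracle_labelled <- function(pair, K = 2, floor_ab = 0.0005,
                            pseudo = NULL) {
  if (is.null(pseudo)) pseudo <- 1 / (2 * pair$depth_c13_light)
  n <- length(pair$taxon_ids)
  out <- logical(n)
  for (i in seq_len(n)) {
    h <- pair$c13_heavy[i]
    l <- pair$c13_light[i]
    ctrl <- pair$c12_heavy[i]
    crit1 <- h > ctrl
    crit2 <- if (l > 0) h > K * l else h > K * pseudo
    crit3 <- h >= floor_ab
    out[i] <- crit1 && crit2 && crit3
  }
  out
}
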