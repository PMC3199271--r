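# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

quartet_labels <- c("a1", "a2", "b1", "b2")

make_quartet_aln <- function(seqs) {
  dna_seqs(seqs, ids = quartet_labels, alignment = TRUE)
}

# Independent brute-force quartet likelihood: explicit sum over the 16
# internal-node state pairs per site, for topology ((t1,t2),(t3,t4)).
brute_quartet_lnl <- function(states, b, kappa, bf) {
  P <- lapply(b, paraconv::hky_prob, kappa = kappa, bf = bf)
  tot <- 0
  for (s in seq_len(ncol(states))) {
    lik <- 0
    for (x in 1:4) for (y in 1:4) {
      lik <- lik + bf[x] *
        P[[1]][x, states[1, s]] * P[[2]][x, states[2, s]] *
        P[[5]][x, y] *
        P[[3]][y, states[3, s]] * P[[4]][y, states[4, s]]
    }
    tot <- tot + log(lik)
  }
  tot
}

# Independent Tajima's D, written out from the published constants.
oracle_tajima <- function(n, S, pi_total) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Published null-allele counts (alt/ref chromosomes) for macaque CYP1A2,
# two species, five sites.
null_allele_fixture <- function() {
  variant_table(
    position = c(138, 286, 1066, 1090, 1103, 138, 286, 1066, 1090, 1103),
    ref = c("G", "A", "C", "C", "T", "G", "A", "C", "C", "T"),
    alt = c("A", "del1", "T", "T", "A", "A", "del1", "T", "T", "A"),
    functional_class = c("nonsense", "frameshift", "nonsense", "nonsense",
                         "nonsense", "nonsense", "frameshift", "nonsense",
                         "nonsense", "nonsense"),
    alt_count = c(0, 4, 8, 2, 11, 5, 0, 22, 0, 0),
    ref_count = c(126, 122, 118, 124, 115, 51, 56, 34, 56, 56),
    species = rep(c("M. fascicularis", "M. mulatta"), each = 5))
}
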