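test_that("zero-divergence limit: identical sequences give lnL = L*log(1/4)", {
  aln <- make_quartet_aln(rep("ACGT", 4))
  fN <- quartet_loglik(aln, quartet_labels, "type_N")
  fC <- quartet_loglik(aln, quartet_labels, "type_C")
  expect_equal(fN$logLik, 4 * log(0.25), tolerance = 1e-4)
  expect_equal(fC$logLik, fN$logLik, tolerance = 1e-5)
  expect_true(all(fN$branch_lengths < 1e-4))
})

test_that("pruning likelihood equals brute-force state summation on short alignments", {
  set.seed(21)
  for (rep in 1:25) {
    L <- sample(1:4, 1)
    states <- matrix(sample(4, 4 * L, replace = TRUE), nrow = 4)
    b <- runif(5, 0, 1.5)
    kappa <- runif(1, 0.3, 8)
    bf <- c(0.1, 0.2, 0.3, 0.4)
    pat <- paraconv:::site_patterns(states)
    expect_equal(paraconv:::quartet_lnl(pat, b, kappa, bf),
                 brute_quartet_lnl(states, b, kappa, bf),
                 tolerance = 1e-12)
  }
})

test_that("likelihood at fixed parameters matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  seqs <- replicate(4, rand_dna(60))
  aln <- make_quartet_aln(seqs)
  b <- c(0.12, 0.31, 0.08, 0.22, 0.15)
  kappa <- 2.7
  states <- matrix(match(unlist(strsplit(seqs, "")), c("A", "C", "G", "T")),
                   nrow = 4, byrow = TRUE)
  bf <- tabulate(states, 4) / length(states)
  pat <- paraconv:::site_patterns(states)
  mine <- paraconv:::quartet_lnl(pat, b, kappa, bf)
  tre <- ape::read.tree(text = sprintf(
    "((t1:%f,t2:%f):%f,t3:%f,t4:%f);", b[1], b[2], b[5], b[3], b[4]))
  dat <- phangorn::phyDat(setNames(strsplit(seqs, ""),
                                   paste0("t", 1:4)), type = "DNA")
  # phangorn Q order: ac, ag, at, cg, ct, gt
  fit <- phangorn::pml(tre, dat, bf = bf, Q = c(1, kappa, 1, 1, kappa, 1))
  expect_equal(mine, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("maximized likelihood agrees with phangorn's independent optimizer", {
  skip_if_not_installed("phangorn")
  sim <- simulate_quartet(120, t_dup = 0.25, t_spec = 0.08, kappa = 3,
                          seed = 77)
  fit <- quartet_loglik(sim$aln, quartet_labels, "type_N")
  seqs <- as.character(sim$aln)
  dat <- phangorn::phyDat(setNames(strsplit(seqs, ""), quartet_labels),
                          type = "DNA")
  tre <- ape::read.tree(text = "((a1:0.1,b1:0.1):0.1,a2:0.1,b2:0.1);")
  bf <- fit$bf
  pf <- phangorn::pml(tre, dat, bf = bf, Q = c(1, 2, 1, 1, 2, 1))
  opt <- phangorn::optim.pml(pf, optEdge = TRUE, optQ = TRUE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(fit$logLik, as.numeric(stats::logLik(opt)), tolerance = 0.05)
})

test_that("lnL is invariant to relabelings that preserve the topology class", {
  sim <- simulate_quartet(90, t_dup = 0.3, t_spec = 0.1, seed = 13)
  base_fit <- quartet_loglik(sim$aln, c("a1", "a2", "b1", "b2"), "type_N")
  # swap species: (b1, b2, a1, a2) pairs the same ortholog cherries
  swapped <- quartet_loglik(sim$aln, c("b1", "b2", "a1", "a2"), "type_N")
  expect_equal(base_fit$logLik, swapped$logLik, tolerance = 1e-4)
  # swap copies: (a2, a1, b2, b1) also preserves type-N cherries
  copyswap <- quartet_loglik(sim$aln, c("a2", "a1", "b2", "b1"), "type_N")
  expect_equal(base_fit$logLik, copyswap$logLik, tolerance = 1e-4)
})

test_that("delta is antisymmetric under swapping the topology definitions", {
  sim <- simulate_quartet(90, t_dup = 0.3, t_spec = 0.1, seed = 29)
  fN <- quartet_loglik(sim$aln, quartet_labels, "type_N")
  fC <- quartet_loglik(sim$aln, quartet_labels, "type_C")
  # relabeling (a1, b1, a2, b2) turns the type-N pairing into type-C and
  # vice versa
  gN <- quartet_loglik(sim$aln, c("a1", "b1", "a2", "b2"), "type_N")
  gC <- quartet_loglik(sim$aln, c("a1", "b1", "a2", "b2"), "type_C")
  expect_equal(fC$logLik - fN$logLik, -(gC$logLik - gN$logLik),
               tolerance = 1e-3)
  expect_lte(fN$logLik, 0)
  expect_lte(fC$logLik, 0)
})

test_that("gapped columns are excluded and degenerate windows error", {
  aln <- make_quartet_aln(c("AC-T", "ACGT", "ACGT", "ACGT"))
  f <- quartet_loglik(aln, quartet_labels, "type_N")
  expect_identical(f$n_columns, 3L)
  allgap <- make_quartet_aln(c("-A", "A-", "-A", "A-"))
  expect_error(quartet_loglik(allgap, quartet_labels, "type_N"), "degenerate")
  expect_error(quartet_loglik(aln, c("a1", "a2", "b1", "zz"), "type_N"),
               "zz")
  expect_error(quartet_loglik(aln, c("a1", "a1", "b1", "b2"), "type_N"))
})

test_that("quartet_fit exposes standard accessors", {
  sim <- simulate_quartet(60, 0.2, 0.05, seed = 3)
  f <- quartet_loglik(sim$aln, quartet_labels, "type_C")
  expect_s3_class(f, "quartet_fit")
  expect_named(coef(f), c("a1", "a2", "b1", "b2", "internal", "kappa"))
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_output(print(f), "kappa")
})
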