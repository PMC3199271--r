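test_that("fixed seeds give bit-identical simulator output", {
  cds <- make_cpg_rich_cds(90, target = 0.1, seed = 2)
  a <- simulate_population_sample(6, 0.02, cds, seed = 123)
  b <- simulate_population_sample(6, 0.02, cds, seed = 123)
  expect_identical(as.character(a$haplotypes$aln),
                   as.character(b$haplotypes$aln))
  expect_identical(a$truth$mutations, b$truth$mutations)
  q1 <- simulate_quartet(60, 0.2, 0.1, seed = 9)
  q2 <- simulate_quartet(60, 0.2, 0.1, seed = 9)
  expect_identical(as.character(q1$aln), as.character(q2$aln))
  expect_identical(make_cpg_rich_cds(90, 0.1, seed = 5),
                   make_cpg_rich_cds(90, 0.1, seed = 5))
})

test_that("zero-rate limits are exact", {
  cds <- make_cpg_rich_cds(90, target = 0.08, seed = 3)
  s <- simulate_population_sample(8, theta = 0, cds = cds, seed = 1)
  expect_identical(segregating_sites(s$haplotypes), 0L)
  expect_identical(nucleotide_diversity(s$haplotypes)$pi, 0)
  q <- simulate_quartet(60, t_dup = 0, t_spec = 0, seed = 1)
  expect_identical(length(unique(as.character(q$aln))), 1L)
})

test_that("full constraint suppresses function-altering variants", {
  cds <- make_cpg_rich_cds(300, target = 0.1, seed = 4)
  s <- simulate_population_sample(10, theta = 0.05, cds = cds,
                                  constraint = 1, seed = 17)
  v <- detect_null_alleles(s$haplotypes, cds)
  seg <- v[v$alt_count > 0, ]
  expect_true(all(seg$functional_class == "synonymous"))
  mut <- s$truth$mutations
  rejected <- mut[mut$class %in% c("nonsynonymous", "nonsense"), ]
  expect_true(all(!rejected$accepted))
})

test_that("accepted mutations appear in haplotypes; rejected ones do not", {
  cds <- make_cpg_rich_cds(150, target = 0.1, seed = 5)
  s <- simulate_population_sample(6, theta = 0.03, cds = cds,
                                  constraint = 0.5, seed = 19)
  v <- detect_null_alleles(s$haplotypes, cds)
  # every segregating substitution traces back to an accepted mutation
  mut <- s$truth$mutations
  acc <- mut[mut$accepted, ]
  for (pos in v$position[v$alt_count > 0 & nchar(v$alt) == 1]) {
    expect_true(pos %in% acc$site)
  }
})

test_that("Watterson consistency: mean S tracks theta * L * a(n)", {
  cds <- make_cpg_rich_cds(300, target = 0.08, seed = 6)
  n <- 10; theta <- 0.01
  set.seed(200)
  S <- replicate(400, segregating_sites(
    simulate_population_sample(n, theta, cds, cpg_multiplier = 1,
                               constraint = 0)$haplotypes))
  expected <- theta * 300 * sum(1 / (1:(n - 1)))
  expect_equal(mean(S), expected, tolerance = 0.1)
})

test_that("CpG hypermutability inflates diversity on the same ancestral CDS", {
  cds <- make_cpg_rich_cds(300, target = 0.1, seed = 7)
  set.seed(300)
  pi_fast <- replicate(60, nucleotide_diversity(
    simulate_population_sample(8, 0.005, cds, cpg_multiplier = 10,
                               constraint = 0)$haplotypes)$pi)
  pi_slow <- replicate(60, nucleotide_diversity(
    simulate_population_sample(8, 0.005, cds, cpg_multiplier = 1,
                               constraint = 0)$haplotypes)$pi)
  expect_gt(mean(pi_fast), mean(pi_slow))
})

test_that("ortholog distances undercut paralog distances when t_spec << t_dup", {
  set.seed(23)
  pdist <- function(x, y) mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  d_orth <- d_para <- numeric(40)
  for (r in 1:40) {
    q <- simulate_quartet(120, t_dup = 0.3, t_spec = 0.03)$aln
    d_orth[r] <- (pdist(q[["a1"]], q[["b1"]]) + pdist(q[["a2"]], q[["b2"]])) / 2
    d_para[r] <- (pdist(q[["a1"]], q[["a2"]]) + pdist(q[["b1"]], q[["b2"]])) / 2
  }
  expect_gt(mean(d_para), mean(d_orth))
})

test_that("conversion tracts homogenize the within-species paralogs", {
  q <- simulate_quartet(300, t_dup = 0.4, t_spec = 0.1,
                        tract = c(90, 240), conversion_time = 0.5,
                        seed = 31)
  a1 <- strsplit(q$aln[["a1"]], "")[[1]]
  a2 <- strsplit(q$aln[["a2"]], "")[[1]]
  inside <- mean(a1[91:240] != a2[91:240])
  outside <- mean(a1[-(91:240)] != a2[-(91:240)])
  expect_lt(inside, outside)
  expect_identical(q$truth$tract, list(c(90, 240)))
})

test_that("CpG-rich CDS generation hits its target without internal stops", {
  cds <- make_cpg_rich_cds(1548, target = 0.08, seed = 8)
  expect_identical(nchar(cds), 1548L)
  f <- cpg_fraction(cds)
  expect_gte(f, 0.07); expect_lte(f, 0.09)
  pep <- translate_cds(cds)
  expect_false(grepl("*", substr(pep, 1, nchar(pep) - 1), fixed = TRUE))
  none <- make_cpg_rich_cds(300, target = 0, tol = 0.001, seed = 9)
  expect_identical(count_cpg(none), 0L)
})

test_that("diploid pairing requires even n and yields dosage genotypes", {
  cds <- make_cpg_rich_cds(120, 0.08, seed = 10)
  expect_error(simulate_population_sample(7, 0.01, cds, diploids = TRUE),
               "even")
  s <- simulate_population_sample(8, 0.05, cds, diploids = TRUE, seed = 33)
  if (!is.null(s$genotypes) && ncol(s$genotypes)) {
    expect_true(all(s$genotypes %in% 0:2))
    expect_identical(nrow(s$genotypes), 4L)
  }
})

test_that("outgroup sequences are emitted and usable for polarization", {
  cds <- make_cpg_rich_cds(150, 0.08, seed = 11)
  s <- simulate_population_sample(6, 0.02, cds, outgroup_split = 5, seed = 35)
  expect_identical(nchar(s$outgroup), 150L)
  d <- mean(strsplit(s$outgroup, "")[[1]] !=
              strsplit(s$haplotypes$aln[[1]], "")[[1]])
  within <- nucleotide_diversity(s$haplotypes)$pi
  expect_gt(d, within)  # divergence exceeds within-sample diversity
})
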