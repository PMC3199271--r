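test_that("nucleotide diversity matches brute-force pairwise counting", {
  two <- dna_seqs(c(h1 = "ACGTACGTAC", h2 = "ACGTACGTAC"), alignment = TRUE)
  nd <- nucleotide_diversity(two)
  expect_identical(nd$pi_total, 0)
  expect_identical(nd$pi, 0)
  set.seed(2)
  s1 <- strsplit(rand_dna(100), "")[[1]]
  s2 <- s1; s2[37] <- setdiff(c("A", "C", "G", "T"), s1[37])[1]
  nd2 <- nucleotide_diversity(dna_seqs(c(h1 = paste(s1, collapse = ""),
                                         h2 = paste(s2, collapse = "")),
                                       alignment = TRUE))
  expect_equal(nd2$pi, 0.01)
  four <- dna_seqs(c(h1 = "AATT", h2 = "AATA", h3 = "AGTT", h4 = "AGTA"),
                   alignment = TRUE)
  nd4 <- nucleotide_diversity(four)
  expect_equal(nd4$pi_total, 8 / 6)
  expect_equal(nd4$pi, (8 / 6) / 4, tolerance = 1e-12)
  expect_identical(segregating_sites(four), 2L)
})

test_that("segregating sites ignore gap-only and N-only variation", {
  x <- dna_seqs(c(h1 = "AC-T", h2 = "ACGT", h3 = "ACNT"), alignment = TRUE)
  expect_identical(segregating_sites(x), 0L)
  y <- dna_seqs(c(h1 = "ACGT", h2 = "ACAT"), alignment = TRUE)
  expect_identical(segregating_sites(y), 1L)
})

test_that("Tajima's D equals the textbook formula on random triples", {
  expect_equal(tajimas_d(4, 2, 4 / 3), 1.8931, tolerance = 1e-4)
  expect_true(is.na(tajimas_d(10, 0, 0)))
  # numerator-zero configuration: pi_total = S / a1
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(10, 5, 5 / a1), 0, tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:1000) {
    n <- sample(4:60, 1)
    S <- sample(1:80, 1)
    pt <- runif(1, 0, 20)
    expect_equal(tajimas_d(n, S, pt), oracle_tajima(n, S, pt),
                 tolerance = 1e-9)
  }
})

test_that("Nei-Gojobori site counts match enumeration of single-base changes", {
  expect_equal(ng_site_counts("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_equal(ng_site_counts("ATG"), c(syn = 0, nonsyn = 3))
  # conservation: syn + nonsyn = CDS length
  set.seed(8)
  for (rep in 1:10) {
    cds <- make_cpg_rich_cds(60, target = 0.1, seed = rep)
    expect_equal(sum(ng_site_counts(cds)), 60)
  }
})

test_that("synonymous/nonsynonymous diversity partitions pairwise differences", {
  same <- dna_seqs(c(h1 = "ATGAAACCC", h2 = "ATGAAACCC"), alignment = TRUE)
  sn <- pi_syn_nonsyn(same)
  expect_identical(c(sn$pi_S, sn$pi_A), c(0, 0))
  expect_true(is.na(sn$ratio))
  syn_only <- dna_seqs(c(h1 = "ATGAAA", h2 = "ATGAAG"), alignment = TRUE)
  sn2 <- pi_syn_nonsyn(syn_only)
  expect_identical(sn2$pi_A, 0)
  expect_gt(sn2$pi_S, 0)
  expect_identical(sn2$ratio, 0)
})

test_that("NG86 dN/dS with Jukes-Cantor correction on hand-enumerated pairs", {
  same <- dnds_ng86("ATGAAA", "ATGAAA")
  expect_identical(c(same$dN, same$dS), c(0, 0))
  expect_true(is.na(same$omega))
  # one nonsynonymous difference over ATG+AAA/ACA: mean nonsyn sites
  # (3 + 8/3 + 3 + 2)/2 = 16/3, pN = 3/16
  toy <- dnds_ng86("ATGAAA", "ATGACA")
  expect_equal(toy$pN, 3 / 16, tolerance = 1e-12)
  expect_equal(toy$dN, -3 / 4 * log(1 - 4 * (3 / 16) / 3), tolerance = 1e-12)
  expect_identical(toy$dS, 0)
  expect_true(is.na(toy$omega))
  # saturated synonymous proportion: correction undefined
  expect_error(dnds_ng86("TTA", "CTG"), "undefined")
})

test_that("multi-hit codons average over substitution pathways excluding stops", {
  # TTT -> GAT: paths TTT>GAT via GTT(V)/TAT(Y); both changes nonsynonymous
  d <- paraconv:::ng_codon_diffs("TTT", "GAT")
  expect_equal(sum(d), 2)
  # TGT -> TAA: direct path enumeration; pathways through stop codons are
  # excluded unless all are blocked
  d2 <- paraconv:::ng_codon_diffs("AGA", "TGA")  # single change to a stop
  expect_equal(unname(d2), c(0, 1))
})

test_that("HKA test: symmetric loci fit exactly, imbalance raises X2", {
  h <- hka_test(S = c(10, 10), n = c(12, 12), D = c(40, 40), L = c(500, 500))
  expect_equal(h$X2, 0, tolerance = 1e-9)
  expect_equal(h$p_value, 1, tolerance = 1e-6)
  h2 <- hka_test(S = c(20, 10), n = c(12, 12), D = c(40, 40), L = c(500, 500))
  h3 <- hka_test(S = c(30, 10), n = c(12, 12), D = c(40, 40), L = c(500, 500))
  expect_gt(h2$X2, 0)
  expect_gt(h3$X2, h2$X2)
  expect_error(hka_test(S = 5, n = 10, D = 10, L = 100), "2 loci")
})

test_that("Hardy-Weinberg chi-square matches direct expected-count arithmetic", {
  exact <- hwe_chisq(c(25, 50, 25))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p_value, 1)
  obs <- c(55, 8, 0)
  p <- (2 * 55 + 8) / 126
  e <- 63 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((obs - e)^2 / e)
  got <- hwe_chisq(obs)
  expect_equal(got$chi2, chi2, tolerance = 1e-12)
  expect_equal(got$chi2, 0.29, tolerance = 0.01)
  expect_equal(got$p_value, 0.59, tolerance = 0.01)
  extreme <- hwe_chisq(c(50, 0, 50))
  expect_lt(extreme$p_value, 1e-10)
  mono <- hwe_chisq(c(63, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("null-allele detection classifies stops, frameshifts and silent changes", {
  ref <- "ATGCAGAAACCCGGGTGA"   # M Q K P G *
  haps <- c(ref,
            sub("CAG", "TAG", ref),                  # premature stop (C>T at 4)
            paste0(substr(ref, 1, 6), substr(ref, 8, 18), "-"),
            sub("AAA", "AAG", ref))                  # synonymous K
  haps[3] <- paste0(substr(ref, 1, 6), "-", substr(ref, 8, 18))  # 1-bp deletion
  h <- haplotype_set(dna_seqs(haps, ids = paste0("h", 1:4), alignment = TRUE),
                     species = "toy")
  v <- detect_null_alleles(h, ref)
  stop_row <- v[v$position == 4 & v$alt == "T", ]
  expect_identical(stop_row$functional_class, "nonsense")
  expect_true(stop_row$is_null)
  del_row <- v[v$alt == "del1", ]
  expect_identical(del_row$functional_class, "frameshift")
  expect_true(del_row$is_null)
  expect_identical(del_row$position, 7L)
  syn_row <- v[v$position == 9, ]
  expect_identical(syn_row$functional_class, "synonymous")
  expect_false(syn_row$is_null)
  expect_identical(sum(v$alt_count), 3L)
  expect_error(detect_null_alleles(h, paste0(ref, "AAA")), "frame")
})

test_that("allele summary reproduces frequencies, sharing and the null maximum", {
  v <- null_allele_fixture()
  s <- allele_summary(v)
  expect_identical(s$max_null$position, 1066L)
  expect_identical(s$max_null$species, "M. mulatta")
  expect_identical(s$max_null$freq_pct, 39)
  expect_equal(s$max_null$freq, 22 / 56, tolerance = 1e-12)
  # 138 segregates only in M. mulatta; 1066 in both; the rest only in
  # M. fascicularis
  expect_identical(unname(s$sharing), c(4L, 1L))
  zero <- s$table[s$table$position == 138 &
                    s$table$species == "M. fascicularis", ]
  expect_identical(zero$freq, 0)
  empty <- allele_summary(variant_table(integer(0), character(0),
                                        character(0), character(0),
                                        integer(0), integer(0), character(0)))
  expect_null(empty$max_null)
})

test_that("amino-acid p-distance counts differing comparable sites", {
  expect_identical(aa_p_distance("MKVLW", "MKVLW"), 0)
  expect_equal(aa_p_distance("MKVLW", "MKALW"), 0.2)
  expect_equal(aa_p_distance("MKV-W", "MKALW"), 0.25)
  expect_equal(aa_p_distance("MKVXW", "MKALW"), 1 / 4 * 1)
  expect_error(aa_p_distance("XXX", "XXX"), "comparable")
  expect_error(aa_p_distance("MK", "MKA"))
})

test_that("diversity_stats ties the battery together on duplicated sequences", {
  dup <- haplotype_set(dna_seqs(rep("ATGAAACCCGGG", 4),
                                ids = paste0("h", 1:4), alignment = TRUE))
  ds <- diversity_stats(dup)
  expect_identical(ds$S, 0L)
  expect_identical(ds$pi, 0)
  expect_identical(ds$pi_S, 0)
  expect_identical(ds$pi_A, 0)
  expect_true(is.na(ds$tajima_D))
})
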