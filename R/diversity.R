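## Within-species diversity statistics for coding haplotypes: nucleotide
## diversity, segregating sites, Tajima's D, and Nei-Gojobori (1986)
## synonymous/nonsynonymous partitioning.

#' Haplotype sets
#'
#' A set of sampled coding haplotypes from one locus in one species: an
#' aligned set of CDS sequences, one per chromosome.
#'
#' @param aln a `"dna_alignment"` (or named character vector) of equal-length
#'   CDS haplotypes; length must be divisible by 3.
#' @param species,locus labels.
#' @return Object of class `"haplotype_set"`.
#' @export
haplotype_set <- function(aln, species = "sp", locus = "locus") {
  if (!inherits(aln, "dna_alignment"))
    aln <- dna_seqs(as.character(aln), names(aln), alignment = TRUE)
  if (nchar(aln[[1]]) %% 3L != 0L)
    stop("haplotype length must be divisible by 3")
  structure(list(aln = aln, species = species, locus = locus,
                 n = length(aln)), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", x$locus, "in", x$species, "-", x$n,
      "chromosomes x", nchar(x$aln[[1]]), "bp\n")
  invisible(x)
}

as_hapmat <- function(h) {
  if (inherits(h, "haplotype_set")) seq_matrix(h$aln)
  else seq_matrix(dna_seqs(as.character(h), names(h), alignment = TRUE))
}

#' Nucleotide diversity
#'
#' Mean pairwise difference count over all `n(n-1)/2` haplotype pairs
#' (`pi_total`) and its per-site value `pi`.  Columns with a gap or `N` in
#' either member of a pair are excluded pairwise; each pair's difference
#' proportion is taken over its own compared length and `pi` is the average
#' of those proportions.
#'
#' @param h a [haplotype_set()] or alignment.
#' @return list with `pi_total`, `pi`, `n_pairs`.
#' @export
nucleotide_diversity <- function(h) {
  m <- as_hapmat(h)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 haplotypes")
  ok <- m != "-" & m != "N"
  tot <- 0; prop <- 0; np <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    L <- sum(use)
    if (L == 0L) stop("zero compared length for pair ", i, ",", j)
    d <- sum(m[i, use] != m[j, use])
    tot <- tot + d; prop <- prop + d / L; np <- np + 1L
  }
  list(pi_total = tot / np, pi = prop / np, n_pairs = np)
}

#' Number of segregating sites
#'
#' Count of alignment columns with at least two distinct non-gap, non-N
#' states.
#'
#' @param h a [haplotype_set()] or alignment.
#' @return integer S.
#' @export
segregating_sites <- function(h) {
  m <- as_hapmat(h)
  sum(apply(m, 2L, function(col) {
    col <- col[col != "-" & col != "N"]
    length(unique(col)) >= 2L
  }))
}

#' Tajima's D
#'
#' The standardized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate
#' (Tajima 1989): `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the
#' usual constants from the sample size.
#'
#' @param n number of sampled chromosomes (`>= 4` for a stable denominator).
#' @param S number of segregating sites.
#' @param pi_total mean pairwise difference count (not per site).
#' @return D, or `NA` when `S = 0` (the statistic is undefined, not zero).
#' @export
tajimas_d <- function(n, S, pi_total) {
  if (S == 0L) return(NA_real_)
  if (n < 4L) stop("need n >= 4")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Nei-Gojobori fractional site counts for one codon: the fraction of the 9
# single-base changes that are synonymous, per position, summed.  Changes to
# stop codons count as nonsynonymous.
ng_codon_sites <- function(codon, gc = genetic_code()) {
  aa <- gc[[codon]]
  syn <- 0
  v <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (p in 1:3) {
    for (b in setdiff(BASES, v[p])) {
      w <- v; w[p] <- b
      if (identical(gc[[paste(w, collapse = "")]], aa)) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' Fractional site counting: each codon position contributes the fraction of
#' its three possible changes that are synonymous to the synonymous-site
#' total and the complement to the nonsynonymous total, so the two totals sum
#' to the sequence length.  Codons containing an ambiguous base or gap are
#' skipped (the effective length shrinks accordingly).
#'
#' @param cds a CDS string, length divisible by 3.
#' @return c(syn = , nonsyn = ).
#' @export
ng_site_counts <- function(cds) {
  s <- toupper(as.character(cds)[1])
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  gc <- genetic_code()
  out <- c(syn = 0, nonsyn = 0)
  for (codon in codon_split(s)) {
    if (grepl("[^ACGT]", codon)) next
    if (codon %in% STOP_CODONS) next
    out <- out + ng_codon_sites(codon, gc)
  }
  out
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons (NG86): all orderings of the differing positions are enumerated,
# pathways passing through a stop codon are excluded (unless all are blocked,
# in which case all orderings are used), and counts are averaged uniformly.
ng_codon_diffs <- function(c1, c2, gc = genetic_code()) {
  v1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(v1 != v2)
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- switch(k, list(1L),
                  list(1:2, 2:1),
                  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  paths <- list()
  for (ord in perms) {
    cur <- v1; sy <- 0; ns <- 0; blocked <- FALSE
    for (p in pos[ord]) {
      nxt <- cur; nxt[p] <- v2[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% STOP_CODONS && !identical(to, c2)) blocked <- TRUE
      if (from %in% STOP_CODONS || to %in% STOP_CODONS) {
        # step through a stop: still classify (nonsense is nonsynonymous)
        ns <- ns + 1
      } else if (identical(gc[[from]], gc[[to]])) sy <- sy + 1
      else ns <- ns + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(syn = sy, nonsyn = ns, blocked = blocked)
  }
  mat <- do.call(rbind, paths)
  use <- mat[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(mat))
  c(syn = mean(mat[use, "syn"]), nonsyn = mean(mat[use, "nonsyn"]))
}

# memoized lookups: 61 sense codons for site counts, codon pairs for
# pathway-averaged difference counts
.ng_cache <- new.env(parent = emptyenv())

ng_sites_lookup <- function() {
  if (is.null(.ng_cache$sites)) {
    gc <- genetic_code()
    sense <- setdiff(names(gc), STOP_CODONS)
    syn <- vapply(sense, function(cd) ng_codon_sites(cd, gc)[["syn"]],
                  numeric(1))
    .ng_cache$sites <- cbind(syn = syn, nonsyn = 3 - syn)
  }
  .ng_cache$sites
}

ng_diffs_lookup <- function(c1, c2, gc) {
  key <- paste0(c1, c2)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng_codon_diffs(c1, c2, gc)
  assign(key, val, envir = .ng_cache)
  val
}

# per-pair NG86 counts over a pair of aligned CDS strings; codons containing
# a gap or N in either sequence are skipped in both counts and sites
ng_pair <- function(s1, s2, gc = genetic_code()) {
  cod1 <- codon_split(s1); cod2 <- codon_split(s2)
  keep <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2) &
    !(cod1 %in% STOP_CODONS) & !(cod2 %in% STOP_CODONS)
  tab <- ng_sites_lookup()
  S1 <- colSums(tab[cod1[keep], , drop = FALSE])
  S2 <- colSums(tab[cod2[keep], , drop = FALSE])
  D <- c(syn = 0, nonsyn = 0)
  for (i in which(keep)) {
    if (cod1[i] != cod2[i]) D <- D + ng_diffs_lookup(cod1[i], cod2[i], gc)
  }
  list(sites = (S1 + S2) / 2, diffs = D)
}

#' Synonymous and nonsynonymous nucleotide diversity
#'
#' Pairwise Nei-Gojobori partitioning of within-sample diversity: for each
#' haplotype pair, synonymous/nonsynonymous differences (pathway-averaged)
#' are divided by the pair's mean synonymous/nonsynonymous site counts; the
#' per-pair proportions are averaged.  Reported without multiple-hit
#' correction (within-species proportions are far below saturation).
#'
#' @param h a [haplotype_set()] or alignment of CDS haplotypes.
#' @return list with `pi_S`, `pi_A`, `ratio` (`pi_A/pi_S`; `NA` when
#'   `pi_S = 0`).
#' @export
pi_syn_nonsyn <- function(h) {
  m <- as_hapmat(h)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 haplotypes")
  gc <- genetic_code()
  seqs <- apply(m, 1L, paste, collapse = "")
  pa <- 0; ps <- 0; np <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pr <- ng_pair(seqs[i], seqs[j], gc)
    if (pr$sites[["syn"]] == 0 || pr$sites[["nonsyn"]] == 0)
      stop("zero synonymous or nonsynonymous sites in pair ", i, ",", j)
    ps <- ps + pr$diffs[["syn"]] / pr$sites[["syn"]]
    pa <- pa + pr$diffs[["nonsyn"]] / pr$sites[["nonsyn"]]
    np <- np + 1L
  }
  pi_S <- ps / np; pi_A <- pa / np
  list(pi_S = pi_S, pi_A = pi_A,
       ratio = if (pi_S > 0) pi_A / pi_S else NA_real_)
}

#' Nei-Gojobori dN/dS between two coding sequences
#'
#' NG86 proportions of synonymous and nonsynonymous differences with the
#' Jukes-Cantor multiple-hit correction `d = -(3/4) log(1 - 4p/3)`, and their
#' ratio `omega = dN/dS`.
#'
#' @param cds1,cds2 equal-length aligned CDS strings.
#' @return list with `dN`, `dS`, `omega` (`NA` when `dS = 0`), and the raw
#'   proportions `pN`, `pS`.
#' @export
dnds_ng86 <- function(cds1, cds2) {
  s1 <- toupper(as.character(cds1)[1]); s2 <- toupper(as.character(cds2)[1])
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned (equal length)")
  if (nchar(s1) %% 3L != 0L) stop("CDS length not divisible by 3")
  pr <- ng_pair(s1, s2)
  pS <- pr$diffs[["syn"]] / pr$sites[["syn"]]
  pN <- pr$diffs[["nonsyn"]] / pr$sites[["nonsyn"]]
  jc <- function(p) {
    if (p >= 3 / 4) stop("proportion ", format(p), " >= 3/4: Jukes-Cantor ",
                         "correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  list(dN = dN, dS = dS, omega = if (dS > 0) dN / dS else NA_real_,
       pN = pN, pS = pS)
}

#' Summary diversity statistics for one locus
#'
#' One-call computation of the standard per-locus table row: sample size,
#' segregating sites, per-site nucleotide diversity, its synonymous and
#' nonsynonymous components, and Tajima's D.
#'
#' @param h a [haplotype_set()].
#' @return Object of class `"diversity_stats"`.
#' @export
diversity_stats <- function(h) {
  if (!inherits(h, "haplotype_set")) h <- haplotype_set(h)
  nd <- nucleotide_diversity(h)
  S <- segregating_sites(h)
  sn <- pi_syn_nonsyn(h)
  D <- if (S > 0) tajimas_d(h$n, S, nd$pi_total) else NA_real_
  structure(list(species = h$species, locus = h$locus, n = h$n, S = S,
                 pi = nd$pi, pi_total = nd$pi_total, pi_S = sn$pi_S,
                 pi_A = sn$pi_A, ratio = sn$ratio, tajima_D = D),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("Diversity of", x$locus, "in", x$species, "\n")
  cat(sprintf("  N = %d  S = %d  pi = %.5f  pi_S = %.5f  pi_A = %.5f  D = %s\n",
              x$n, x$S, x$pi, x$pi_S, x$pi_A,
              if (is.na(x$tajima_D)) "NA" else sprintf("%.3f", x$tajima_D)))
  if (!is.na(x$ratio)) cat(sprintf("  pi_A/pi_S = %.2f\n", x$ratio))
  invisible(x)
}

#' Amino-acid p-distance
#'
#' Proportion of differing residues between two aligned peptides; sites with
#' a gap, `X`, or `*` in either sequence are excluded.
#'
#' @param pep1,pep2 equal-length peptide strings.
#' @return numeric p-distance.
#' @export
aa_p_distance <- function(pep1, pep2) {
  a <- strsplit(toupper(as.character(pep1)[1]), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(as.character(pep2)[1]), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("peptides must be aligned (equal length)")
  bad <- c("-", "X", "*")
  use <- !(a %in% bad) & !(b %in% bad)
  if (!any(use)) stop("no comparable sites")
  sum(a[use] != b[use]) / sum(use)
}
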