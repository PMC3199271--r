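## CpG dinucleotide accounting and CpG-degeneration analysis.  Methylated
## CpG dinucleotides hypermutate (roughly an order of magnitude above the
## background rate), predominantly by deamination to TpG (on the C strand)
## or CpA (on the G strand).  Once purifying selection on a CpG-rich gene is
## lost, CpG degeneration inflates its polymorphism level.

#' Count CpG dinucleotides
#'
#' Overlap-permitting scan: the number of positions `i` with `C` at `i` and
#' `G` at `i+1` (`"CGCG"` contains 2).  Set `overlapping = FALSE` for
#' non-overlapping counting.
#'
#' @param seq gap-free DNA string.
#' @param overlapping logical.
#' @return integer count.
#' @export
count_cpg <- function(seq, overlapping = TRUE) {
  s <- toupper(as.character(seq)[1])
  if (grepl("-", s, fixed = TRUE)) stop("sequence contains gaps")
  pat <- if (overlapping) "(?=CG)" else "CG"
  m <- gregexpr(pat, s, perl = overlapping, fixed = !overlapping)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Fraction of CpG sites in a sequence
#'
#' Each CpG dinucleotide contributes two sites: `2 * count_cpg / length`.
#'
#' @inheritParams count_cpg
#' @return numeric fraction.
#' @export
cpg_fraction <- function(seq, overlapping = TRUE) {
  s <- toupper(as.character(seq)[1])
  if (nchar(s) < 2L) stop("need at least 2 bases")
  2 * count_cpg(s, overlapping) / nchar(s)
}

#' Classify a SNP with respect to ancestral CpG context
#'
#' Polarizes a variant against an outgroup ("ancestral") sequence aligned to
#' the same coordinates and classifies CpG-degenerating changes: a derived
#' `T` at the `C` of an ancestral `CG` is `CG_to_TG`; a derived `A` at the
#' `G` of an ancestral `CG` is `CG_to_CA`; any other change inside an
#' ancestral `CG` is `other_CpG`; changes outside ancestral CpG context are
#' `non_CpG`.  If the ancestral base matches neither allele the site cannot
#' be polarized and is flagged.
#'
#' @param position 1-based coordinate of the SNP.
#' @param ref,alt the two observed alleles.
#' @param ancestral the outgroup sequence (string) on the same coordinates.
#' @return list with `category` (`CG_to_TG`, `CG_to_CA`, `other_CpG`,
#'   `non_CpG`, or `NA` if unpolarizable), `derived`, `polarized`.
#' @export
classify_cpg_snp <- function(position, ref, alt, ancestral) {
  anc <- strsplit(toupper(as.character(ancestral)[1]), "", fixed = TRUE)[[1]]
  if (position < 1L || position > length(anc)) stop("position out of range")
  a <- anc[position]
  ref <- toupper(ref); alt <- toupper(alt)
  if (!(a %in% c(ref, alt)))
    return(list(category = NA_character_, derived = NA_character_,
                polarized = FALSE))
  derived <- if (a == ref) alt else ref
  c_of_cg <- a == "C" && position < length(anc) && anc[position + 1L] == "G"
  g_of_cg <- a == "G" && position > 1L && anc[position - 1L] == "C"
  category <- if (c_of_cg && derived == "T") "CG_to_TG"
  else if (g_of_cg && derived == "A") "CG_to_CA"
  else if (c_of_cg || g_of_cg) "other_CpG"
  else "non_CpG"
  list(category = category, derived = derived, polarized = TRUE)
}

#' Classify every variant in a table against an ancestral sequence
#'
#' @param variants a [variant_table()] (substitution rows only are
#'   classified; indels get `NA`).
#' @param ancestral outgroup sequence on CDS coordinates.
#' @return the table with added `cpg_category` and `derived` columns.
#' @export
classify_cpg_snps <- function(variants, ancestral) {
  v <- as.data.frame(variants)
  v$cpg_category <- NA_character_; v$derived <- NA_character_
  sub <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$alt %in% BASES
  for (i in which(sub)) {
    cl <- classify_cpg_snp(v$position[i], v$ref[i], v$alt[i], ancestral)
    v$cpg_category[i] <- cl$category
    v$derived[i] <- cl$derived
  }
  v
}

#' Region CpG/diversity profiles
#'
#' @param region_id identifiers.
#' @param kind `"genic"` or `"intergenic"`.
#' @param length region length (bp).
#' @param cpg_count CpG dinucleotide count (or supply `seq`).
#' @param pi per-site nucleotide diversity of the region.
#' @param seq optional sequences from which `length` and `cpg_count` are
#'   computed.
#' @return data.frame of class `"region_profile"` with `cpg_fraction =
#'   2 * cpg_count / length`.
#' @export
region_profile <- function(region_id, kind, length = NULL, cpg_count = NULL,
                           pi, seq = NULL) {
  if (!is.null(seq)) {
    length <- nchar(seq)
    cpg_count <- vapply(seq, count_cpg, integer(1))
  }
  kind <- match.arg(kind, c("genic", "intergenic"), several.ok = TRUE)
  if (base::length(kind) == 1L) kind <- rep(kind, base::length(region_id))
  d <- data.frame(region_id = as.character(region_id), kind = kind,
                  length = as.integer(length),
                  cpg_count = as.integer(cpg_count),
                  cpg_fraction = 2 * cpg_count / length,
                  pi = as.numeric(pi), stringsAsFactors = FALSE)
  if (any(d$cpg_fraction < 0 | d$cpg_fraction > 1))
    stop("cpg_fraction out of [0, 1]")
  structure(d, class = c("region_profile", "data.frame"))
}

#' Spearman correlation between CpG fraction and diversity, per region kind
#'
#' Rank correlation (mid-ranks for ties) of `cpg_fraction` against `pi`
#' within each region kind; two-sided p-value by the t approximation.
#'
#' @param profiles a [region_profile()] table.
#' @return data.frame with one row per kind: `kind`, `n`, `rho`, `p_value`
#'   (`NA` when a vector is constant).
#' @export
cpg_diversity_correlation <- function(profiles) {
  out <- lapply(split(as.data.frame(profiles), profiles$kind), function(d) {
    if (nrow(d) < 5L) stop("need at least 5 regions per kind")
    if (length(unique(d$cpg_fraction)) == 1L || length(unique(d$pi)) == 1L)
      return(data.frame(kind = d$kind[1], n = nrow(d), rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(cor.test(d$cpg_fraction, d$pi,
                                    method = "spearman", exact = FALSE))
    data.frame(kind = d$kind[1], n = nrow(d),
               rho = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Compare CpG density between genic and intergenic regions
#'
#' Two-sided Wilcoxon rank-sum test on `cpg_fraction`: exact null
#' distribution when the combined sample size is at most 20 (and there are
#' no ties), normal approximation with tie correction otherwise.
#'
#' @param genic,intergenic [region_profile()] tables (or numeric vectors of
#'   CpG fractions).
#' @return list with `W`, `p_value`, `exact`.
#' @export
compare_cpg_density <- function(genic, intergenic) {
  gx <- if (is.data.frame(genic)) genic$cpg_fraction else as.numeric(genic)
  ix <- if (is.data.frame(intergenic)) intergenic$cpg_fraction else as.numeric(intergenic)
  if (!length(gx) || !length(ix)) stop("both groups must be non-empty")
  exact <- (length(gx) + length(ix)) <= 20L && !anyDuplicated(c(gx, ix))
  wt <- suppressWarnings(wilcox.test(gx, ix, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
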