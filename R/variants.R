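## Segregating-site annotation against a coding reference: functional class
## (synonymous / nonsynonymous / nonsense / frameshift) and null-allele
## calling, plus per-species allele-frequency summaries.

#' Construct a variant table
#'
#' One row per segregating site per species, with derived/reference
#' chromosome counts.  `functional_class` must be one of `synonymous`,
#' `nonsynonymous`, `nonsense`, `frameshift`, `inframe_deletion`; null
#' alleles are those abolishing gene function (`nonsense` or `frameshift`).
#'
#' @param position 1-based CDS coordinate of the variant (for deletions, the
#'   first deleted base).
#' @param ref,alt reference and alternative alleles (a base, or a token such
#'   as `del1` for a 1-bp deletion).
#' @param functional_class character vector, see above.
#' @param alt_count,ref_count chromosome counts per species.
#' @param species species label per row.
#' @return data.frame of class `"variant_table"` with an `is_null` column.
#' @export
variant_table <- function(position, ref, alt, functional_class,
                          alt_count, ref_count, species = "sp") {
  classes <- c("synonymous", "nonsynonymous", "nonsense", "frameshift",
               "inframe_deletion")
  if (length(functional_class))
    functional_class <- match.arg(functional_class, classes,
                                  several.ok = TRUE)
  else functional_class <- character(0)
  if (any(alt_count < 0) || any(ref_count < 0)) stop("negative allele count")
  d <- data.frame(position = as.integer(position), ref = as.character(ref),
                  alt = as.character(alt),
                  functional_class = functional_class,
                  is_null = functional_class %in% c("nonsense", "frameshift"),
                  alt_count = as.integer(alt_count),
                  ref_count = as.integer(ref_count),
                  species = as.character(species), stringsAsFactors = FALSE)
  structure(d, class = c("variant_table", "data.frame"))
}

#' Read a variant table from TSV
#'
#' Expects columns `position, ref, alt, functional_class, alt_count,
#' ref_count, species` (comment lines starting with `#` ignored).
#'
#' @param path TSV path.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  variant_table(d$position, d$ref, d$alt, d$functional_class,
                d$alt_count, d$ref_count, d$species)
}

# classify a single-base substitution in reference coding context
classify_substitution <- function(refseq_vec, pos, alt, gc = genetic_code()) {
  ci <- (pos - 1L) %/% 3L           # 0-based codon index
  cstart <- ci * 3L + 1L
  cod <- refseq_vec[cstart:(cstart + 2L)]
  ref_cod <- paste(cod, collapse = "")
  cod[pos - cstart + 1L] <- alt
  alt_cod <- paste(cod, collapse = "")
  n_codons <- length(refseq_vec) %/% 3L
  if (alt_cod %in% STOP_CODONS) {
    if (ci + 1L < n_codons) return("nonsense")      # premature stop
    return(if (ref_cod %in% STOP_CODONS) "synonymous" else "nonsense")
  }
  if (ref_cod %in% STOP_CODONS) return("nonsynonymous")  # reference stop lost
  aa_ref <- gc[[ref_cod]]; aa_alt <- gc[[alt_cod]]
  if (is.null(aa_ref) || is.null(aa_alt)) return(NA_character_)
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Detect and classify segregating variants, including null alleles
#'
#' Scans an aligned set of haplotypes against the reference coding sequence
#' that defines the reading frame.  Every segregating substitution is
#' classified synonymous / nonsynonymous / nonsense (a premature stop before
#' the reference stop codon); deletion runs whose length is not divisible by
#' 3 are frameshifts.  Nonsense and frameshift alleles are flagged as null
#' alleles.
#'
#' @param h a [haplotype_set()] (haplotypes aligned to the reference frame:
#'   alignment columns = reference coordinates, deletions as `-`).
#' @param reference gap-free reference CDS string, same length as the
#'   alignment.
#' @return a [variant_table()] sorted by position.
#' @export
detect_null_alleles <- function(h, reference) {
  if (!inherits(h, "haplotype_set")) h <- haplotype_set(h)
  refseq <- toupper(as.character(reference)[1])
  m <- seq_matrix(h$aln)
  if (nchar(refseq) != ncol(m))
    stop("reference length ", nchar(refseq), " != alignment columns ", ncol(m),
         ": frame cannot be established")
  rv <- strsplit(refseq, "", fixed = TRUE)[[1]]
  gc <- genetic_code()
  n <- nrow(m)
  rows <- list()
  # substitutions
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- setdiff(unique(col), c("-", "N"))
    alts <- setdiff(obs, rv[j])
    for (alt in alts) {
      cls <- classify_substitution(rv, j, alt, gc)
      ac <- sum(col == alt)
      rc <- sum(col == rv[j])
      rows[[length(rows) + 1L]] <- data.frame(
        position = j, ref = rv[j], alt = alt, functional_class = cls,
        alt_count = ac, ref_count = rc, stringsAsFactors = FALSE)
    }
  }
  # deletion runs per haplotype, pooled into events keyed by (start, length)
  ev <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    gaps <- m[i, ] == "-"
    if (!any(gaps)) next
    r <- rle(gaps)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      key <- paste(starts[k], r$lengths[k], sep = "_")
      ev[[key]] <- c(if (!is.null(ev[[key]])) ev[[key]], i)
    }
  }
  for (key in ls(ev)) {
    sl <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    len <- sl[2]
    rows[[length(rows) + 1L]] <- data.frame(
      position = sl[1],
      ref = substr(refseq, sl[1], min(sl[1] + len - 1L, nchar(refseq))),
      alt = paste0("del", len),
      functional_class = if (len %% 3L != 0L) "frameshift" else "inframe_deletion",
      alt_count = length(ev[[key]]), ref_count = n - length(ev[[key]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(variant_table(integer(0), character(0), character(0),
                         character(0), integer(0), integer(0),
                         character(0)))
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$position), , drop = FALSE]
  variant_table(d$position, d$ref, d$alt, d$functional_class,
                d$alt_count, d$ref_count, species = h$species)
}

#' Summarize allele frequencies and null-allele sharing
#'
#' Per site and species, the derived-allele frequency
#' `alt / (alt + ref)`; the summary reports the maximum null-allele
#' frequency, which variants are species-specific versus shared (segregating
#' in more than one species), and null-allele counts.
#'
#' @param variants a [variant_table()] (possibly spanning several species).
#' @return Object of class `"allele_summary"`: list with the per-row
#'   frequency table (`freq`, `freq_pct` rounded to whole percent),
#'   `max_null` (row of the highest-frequency null allele), `n_null_sites`,
#'   and SNP sharing counts by species.
#' @export
allele_summary <- function(variants) {
  v <- as.data.frame(variants)
  if (nrow(v) == 0L) {
    return(structure(list(table = v, max_null = NULL, n_null_sites = 0L,
                          sharing = integer(0)), class = "allele_summary"))
  }
  v$freq <- v$alt_count / (v$alt_count + v$ref_count)
  v$freq_pct <- round(100 * v$freq)
  seg <- v[v$alt_count > 0, , drop = FALSE]
  # sharing: a site segregates in a species if alt_count > 0 there
  sp_by_site <- tapply(seg$species, seg$position,
                       function(s) length(unique(s)))
  sharing <- c(specific = sum(sp_by_site == 1),
               shared = sum(sp_by_site > 1))
  nulls <- v[v$is_null & v$alt_count > 0, , drop = FALSE]
  max_null <- if (nrow(nulls)) nulls[which.max(nulls$freq), , drop = FALSE]
  structure(list(table = v, max_null = max_null,
                 n_null_sites = length(unique(v$position[v$is_null])),
                 sharing = sharing),
            class = "allele_summary")
}

#' @export
print.allele_summary <- function(x, ...) {
  cat("Allele summary:", nrow(x$table), "variant records,",
      x$n_null_sites, "null-allele sites\n")
  if (!is.null(x$max_null)) {
    mn <- x$max_null
    cat(sprintf("  highest null-allele frequency: %d%% at site %d in %s (%d/%d)\n",
                mn$freq_pct, mn$position, mn$species, mn$alt_count,
                mn$alt_count + mn$ref_count))
  }
  if (length(x$sharing))
    cat("  segregating sites: ", x$sharing[["specific"]],
        " species-specific, ", x$sharing[["shared"]], " shared\n", sep = "")
  invisible(x)
}
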