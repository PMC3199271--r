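#' @importFrom stats pchisq optim cor.test wilcox.test runif rexp uniroot setNames
#' @importFrom utils packageVersion read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a set of named DNA sequences
#'
#' The basic sequence container used throughout the package: a named character
#' vector of uppercase DNA strings over the alphabet `A C G T N -`.  When
#' `alignment = TRUE` all sequences must have equal length and the object also
#' gains class `"dna_alignment"`.
#'
#' @param seq character vector of DNA strings.
#' @param ids sequence identifiers; defaults to `names(seq)`.
#' @param alignment logical; enforce equal lengths.
#' @return An object of class `"dna_seqs"` (and `"dna_alignment"` if aligned):
#'   a named character vector.
#' @export
dna_seqs <- function(seq, ids = names(seq), alignment = FALSE) {
  seq <- toupper(as.character(seq))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seq))
  ids <- as.character(ids)
  if (length(ids) != length(seq)) stop("ids and seq lengths differ")
  if (any(!nzchar(ids))) stop("empty sequence id")
  if (any(!nzchar(seq))) stop("empty sequence for id ", ids[which(!nzchar(seq))[1]])
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seq)
  if (any(bad)) {
    stop("sequence '", ids[which(bad)[1]], "' contains characters outside {A,C,G,T,N,-}")
  }
  names(seq) <- ids
  cls <- "dna_seqs"
  if (alignment) {
    if (length(seq) < 2L) stop("an alignment needs at least 2 sequences")
    L <- nchar(seq)
    if (length(unique(L)) != 1L) {
      off <- which(L != L[1])[1]
      stop("ragged alignment: record '", ids[off], "' has length ", L[off],
           " but record '", ids[1], "' has length ", L[1])
    }
    cls <- c("dna_alignment", cls)
  }
  structure(seq, class = cls)
}

#' @export
print.dna_seqs <- function(x, ...) {
  cat(if (inherits(x, "dna_alignment")) "DNA alignment:" else "DNA sequences:",
      length(x), "records",
      if (inherits(x, "dna_alignment")) paste0("x ", nchar(x[[1]]), " bp"), "\n")
  for (i in seq_len(min(6L, length(x)))) {
    s <- x[[i]]
    cat(sprintf("  %-12s %s%s (%d bp)\n", names(x)[i],
                substr(s, 1, 40), if (nchar(s) > 40) "..." else "", nchar(s)))
  }
  if (length(x) > 6L) cat("  ...", length(x) - 6L, "more\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses FASTA via [Biostrings::readBStringSet()] and validates the records
#' against the package alphabet.  With `alignment = TRUE` ragged records are a
#' format error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param alignment logical; require equal-length records.
#' @return A [dna_seqs()] object (a `"dna_alignment"` when `alignment = TRUE`).
#' @export
read_fasta <- function(path, alignment = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))  # first token of the header
  dna_seqs(as.character(ss), ids = ids, alignment = alignment)
}

#' Write sequences to FASTA
#'
#' @param x a [dna_seqs()] object or named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  ss <- Biostrings::BStringSet(setNames(as.character(x), names(x)))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Exon maps on a concatenated CDS
#'
#' An exon map is an ordered table of non-overlapping `(name, start, end)`
#' intervals in 0-based half-open coordinates on the concatenated coding
#' sequence.  User-facing reports are 1-based inclusive; internals stay
#' 0-based half-open.
#'
#' @param name exon names.
#' @param start,end 0-based half-open bounds.
#' @return data.frame of class `"exon_map"` with columns name, start, end.
#' @export
exon_map <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("exon end must exceed start")
  o <- order(start)
  name <- as.character(name)[o]; start <- start[o]; end <- end[o]
  if (any(duplicated(name))) stop("duplicated exon names")
  if (length(start) > 1L && any(start[-1] < end[-length(end)]))
    stop("overlapping exons")
  structure(data.frame(name = name, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("exon_map", "data.frame"))
}

#' Read an exon map from TSV
#'
#' Expects a header line `name  start  end`; coordinates 0-based half-open
#' (comment lines starting with `#` are ignored).
#'
#' @param path TSV file path.
#' @return An [exon_map()].
#' @export
read_exon_map <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(d))) stop("exon map needs columns: name, start, end")
  exon_map(d$name, d$start, d$end)
}

#' Extract a coding sequence by exon map
#'
#' Concatenates the exon slices of `seq` in map order.
#'
#' @param seq a single DNA string (or length-1 [dna_seqs()]).
#' @param map an [exon_map()].
#' @return Single character string: the concatenated CDS.
#' @export
extract_cds <- function(seq, map) {
  s <- as.character(seq)[1]
  if (max(map$end) > nchar(s)) stop("exon beyond sequence end (length ", nchar(s), ")")
  paste(substring(s, map$start + 1L, map$end), collapse = "")
}

.GENETIC_CODE <- NULL

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons are reported as `*` and translation is
#' not truncated at the first stop (downstream analyses need premature-stop
#' positions).  Gap characters are stripped before translation; codons
#' containing `N` (or any non-ACGT base) translate to `X`.
#'
#' @param cds DNA string, length divisible by 3 after gap removal.
#' @return Single character string: the peptide.
#' @export
translate_cds <- function(cds) {
  s <- gsub("-", "", toupper(as.character(cds)[1]), fixed = TRUE)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# character matrix view of an alignment: rows = sequences, cols = columns
seq_matrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

matrix_to_seqs <- function(m, alignment = TRUE) {
  dna_seqs(apply(m, 1L, paste, collapse = ""), ids = rownames(m),
           alignment = alignment)
}
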