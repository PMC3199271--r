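## One-call orchestration of the three analysis stages (conversion scan,
## population genetics, CpG analysis) from a config list or YAML file, with
## TSV/JSON outputs and a machine-readable report.

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — quartet conversion scan,
#' population-genetic statistics, CpG analysis — from a configuration list
#' or YAML file, writes per-stage TSV/JSON outputs under `outdir`, and
#' returns a run report.  Identical config and seed give an identical
#' report.
#'
#' Config structure (all stages optional):
#' \preformatted{
#' seed: 1
#' outdir: path
#' conversion:
#'   alignment: quartet FASTA    exons: exon-map TSV
#'   labels: [a1, a2, b1, b2]    window: 150    step: 9
#' popgen:
#'   haplotypes: FASTA           reference: FASTA (1 record)
#'   species: label              outgroup: FASTA (optional, for HKA-style D)
#' cpg:
#'   cds: FASTA (1+ records)     regions: region-profile TSV (optional)
#' }
#'
#' @param config a list, or path to a YAML file.
#' @return Object of class `"run_report"`: per-stage results, package
#'   version, config echo, warnings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  outdir <- config$outdir %||% tempfile("paraconv_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(packageVersion("paraconv")),
                 seed = seed, config = config, stages = list(),
                 warnings = character(0))

  need <- function(paths, stage) {
    missing <- paths[!file.exists(unlist(paths))]
    if (length(missing))
      stop("stage '", stage, "': missing input(s): ",
           paste(unlist(missing), collapse = ", "))
  }

  if (!is.null(config$conversion)) {
    cc <- config$conversion
    need(c(cc$alignment, cc$exons), "conversion")
    aln <- read_fasta(cc$alignment, alignment = TRUE)
    exons <- read_exon_map(cc$exons)
    scan <- conversion_scan(aln, unlist(cc$labels), exons,
                            window = cc$window %||% 150L,
                            step = cc$step %||% 9L)
    write.table(as.data.frame(scan), file.path(outdir, "conversion_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$conversion <- list(
      n_windows = nrow(scan),
      summary = unclass(summary(scan))[c("n_positive", "n_failed")],
      max_delta = suppressWarnings(max(scan$delta, na.rm = TRUE)),
      table = as.data.frame(scan))
  }

  if (!is.null(config$popgen)) {
    pc <- config$popgen
    need(c(pc$haplotypes, pc$reference), "popgen")
    haps <- read_fasta(pc$haplotypes, alignment = TRUE)
    ref <- read_fasta(pc$reference)[[1]]
    h <- haplotype_set(haps, species = pc$species %||% "sample",
                       locus = pc$locus %||% "locus")
    ds <- diversity_stats(h)
    variants <- detect_null_alleles(h, ref)
    summ <- allele_summary(variants)
    write.table(as.data.frame(variants), file.path(outdir, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    divergence <- NULL
    if (!is.null(pc$outgroup)) {
      need(pc$outgroup, "popgen")
      og <- read_fasta(pc$outgroup)[[1]]
      m <- seq_matrix(h$aln)
      ov <- strsplit(toupper(og), "", fixed = TRUE)[[1]]
      if (length(ov) == ncol(m)) {
        d <- mean(apply(m, 1L, function(row) {
          use <- row != "-" & row != "N" & ov != "-" & ov != "N"
          sum(row[use] != ov[use])
        }))
        divergence <- d
      } else {
        report$warnings <- c(report$warnings,
                             "popgen: outgroup length mismatch; divergence skipped")
      }
    }
    report$stages$popgen <- list(diversity = unclass(ds),
                                 n_variants = nrow(variants),
                                 max_null = summ$max_null,
                                 divergence = divergence)
  }

  if (!is.null(config$cpg)) {
    gc_ <- config$cpg
    need(gc_$cds, "cpg")
    cds <- read_fasta(gc_$cds)
    cpg <- data.frame(id = names(cds),
                      length = nchar(cds),
                      cpg_count = vapply(cds, count_cpg, integer(1)),
                      cpg_fraction = vapply(cds, cpg_fraction, numeric(1)),
                      row.names = NULL)
    stage <- list(cds = cpg)
    if (!is.null(gc_$regions)) {
      need(gc_$regions, "cpg")
      rp <- read.delim(gc_$regions, comment.char = "#",
                       stringsAsFactors = FALSE)
      prof <- region_profile(rp$region_id, rp$kind, rp$length, rp$cpg_count,
                             rp$pi)
      stage$correlation <- cpg_diversity_correlation(prof)
      if (all(c("genic", "intergenic") %in% prof$kind)) {
        stage$density_test <- compare_cpg_density(
          prof[prof$kind == "genic", ], prof[prof$kind == "intergenic", ])
      }
    }
    report$stages$cpg <- stage
  }

  class(report) <- "run_report"
  jsonlite::write_json(report_to_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  report$outdir <- outdir
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip non-serializable bits, keep the numbers
report_to_json <- function(report) {
  r <- unclass(report)
  r$stages <- lapply(r$stages, function(s) {
    if (!is.null(s$table)) s$table <- NULL
    s
  })
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("paraconv run report (version", x$version, ")\n")
  cat("  stages run:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$stages$conversion))
    cat(sprintf("  conversion: %d windows, max delta %.2f\n",
                x$stages$conversion$n_windows, x$stages$conversion$max_delta))
  if (!is.null(x$stages$popgen)) {
    d <- x$stages$popgen$diversity
    cat(sprintf("  popgen: n=%d S=%d pi=%.5f D=%s\n", d$n, d$S, d$pi,
                if (is.na(d$tajima_D)) "NA" else sprintf("%.3f", d$tajima_D)))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
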