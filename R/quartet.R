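## Quartet maximum-likelihood test for inter-paralog gene conversion.
##
## A duplicated gene pair sampled in two species (alpha1, alpha2, beta1,
## beta2) admits two informative unrooted topologies: the "type-N" tree
## ((a1,b1),(a2,b2)) pairing orthologs, expected when the paralogs diverged
## at duplication and never exchanged sequence, and the "type-C" tree
## ((a1,a2),(b1,b2)) pairing within-species paralogs, the signature of gene
## conversion after speciation.  Windows along the CDS are scored by the
## difference of the two maximized HKY85 log-likelihoods.

BASES <- c("A", "C", "G", "T")

#' HKY85 transition probability matrix
#'
#' Closed-form transition probabilities for the HKY85 model, with the rate
#' matrix normalized so that `t` is measured in expected substitutions per
#' site.
#'
#' @param t branch length (expected substitutions/site), `>= 0`.
#' @param kappa transition/transversion rate ratio.
#' @param bf base frequencies in A,C,G,T order, summing to 1.
#' @return 4x4 matrix `P` with `P[i, j] = P(j at end | i at start)`.
#' @export
hky_prob <- function(t, kappa, bf) {
  piA <- bf[1]; piC <- bf[2]; piG <- bf[3]; piT <- bf[4]
  R <- piA + piG; Y <- piC + piT
  beta <- 1 / (2 * (R * Y + kappa * (piA * piG + piC * piT)))
  e2 <- exp(-beta * t)
  # group-specific decay for transitions within purines / pyrimidines
  eR <- exp(-beta * t * (R * kappa + Y))
  eY <- exp(-beta * t * (Y * kappa + R))
  pj <- rep(bf, each = 4)               # target-base frequency, by column
  Pi <- rep(c(R, Y, R, Y), each = 4)    # target's group total
  e3 <- rep(c(eR, eY, eR, eY), each = 4)
  P <- pj * (1 - e2)                    # transversions (default)
  d <- .HKY_DIAG
  P[d] <- pj[d] + pj[d] * (1 / Pi[d] - 1) * e2 + ((Pi[d] - pj[d]) / Pi[d]) * e3[d]
  s <- .HKY_TS
  P[s] <- pj[s] + pj[s] * (1 / Pi[s] - 1) * e2 - (pj[s] / Pi[s]) * e3[s]
  dim(P) <- c(4L, 4L)
  dimnames(P) <- list(BASES, BASES)
  P
}

# linear indices into the 4x4 (A,C,G,T) matrix: diagonal and transitions
.HKY_DIAG <- c(1L, 6L, 11L, 16L)
.HKY_TS <- c(3L, 8L, 9L, 14L)        # G>A, T>C, A>G, C>T

# derivative of the HKY transition matrix with respect to branch length
hky_dprob <- function(t, kappa, bf) {
  piA <- bf[1]; piC <- bf[2]; piG <- bf[3]; piT <- bf[4]
  R <- piA + piG; Y <- piC + piT
  beta <- 1 / (2 * (R * Y + kappa * (piA * piG + piC * piT)))
  e2 <- exp(-beta * t)
  rR <- R * kappa + Y; rY <- Y * kappa + R    # group decay rates / beta
  eR <- exp(-beta * t * rR)
  eY <- exp(-beta * t * rY)
  pj <- rep(bf, each = 4)
  Pi <- rep(c(R, Y, R, Y), each = 4)
  e3 <- rep(c(eR, eY, eR, eY), each = 4)
  r3 <- rep(c(rR, rY, rR, rY), each = 4)
  D <- pj * beta * e2                          # transversions
  d <- .HKY_DIAG
  D[d] <- -pj[d] * (1 / Pi[d] - 1) * beta * e2 -
    ((Pi[d] - pj[d]) / Pi[d]) * beta * r3[d] * e3[d]
  s <- .HKY_TS
  D[s] <- -pj[s] * (1 / Pi[s] - 1) * beta * e2 +
    (pj[s] / Pi[s]) * beta * r3[s] * e3[s]
  dim(D) <- c(4L, 4L)
  D
}

# log-likelihood and gradient (5 branch lengths analytic, kappa by central
# difference), sharing the per-site quantities
quartet_lnl_grad <- function(pat, par, bf) {
  b <- par[1:5]; kappa <- exp(par[6])
  P <- lapply(b, hky_prob, kappa = kappa, bf = bf)
  s <- pat$states; w <- pat$w
  T1 <- P[[1]][, s[1, ], drop = FALSE]; T2 <- P[[2]][, s[2, ], drop = FALSE]
  T3 <- P[[3]][, s[3, ], drop = FALSE]; T4 <- P[[4]][, s[4, ], drop = FALSE]
  L1 <- T1 * T2; L2 <- T3 * T4
  M <- P[[5]] %*% L2
  sl <- pmax(colSums((bf * L1) * M), 1e-300)
  lnl <- sum(w * log(sl))
  dP <- lapply(b, hky_dprob, kappa = kappa, bf = bf)
  g <- numeric(6)
  g[1] <- sum(w * colSums((bf * (dP[[1]][, s[1, ], drop = FALSE] * T2)) * M) / sl)
  g[2] <- sum(w * colSums((bf * (T1 * dP[[2]][, s[2, ], drop = FALSE])) * M) / sl)
  bl1 <- bf * L1
  g[3] <- sum(w * colSums(bl1 * (P[[5]] %*% (dP[[3]][, s[3, ], drop = FALSE] * T4))) / sl)
  g[4] <- sum(w * colSums(bl1 * (P[[5]] %*% (T3 * dP[[4]][, s[4, ], drop = FALSE]))) / sl)
  g[5] <- sum(w * colSums(bl1 * (dP[[5]] %*% L2)) / sl)
  eps <- 1e-5
  g[6] <- (quartet_lnl(pat, b, exp(par[6] + eps), bf) -
             quartet_lnl(pat, b, exp(par[6] - eps), bf)) / (2 * eps)
  list(lnl = lnl, grad = g)
}

# Collapse a 4 x L state matrix (integer codes 1..4) to site patterns.
# Returns list(states = 4 x npat integer matrix, w = pattern counts).
site_patterns <- function(states) {
  key <- paste(states[1, ], states[2, ], states[3, ], states[4, ], sep = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = states[, first, drop = FALSE], w = as.numeric(tab))
}

# Pruning-algorithm log-likelihood of an unrooted quartet ((t1,t2),(t3,t4))
# with terminal branches b1..b4 and internal branch b5.  pat as returned by
# site_patterns() with tip rows ordered t1..t4.  Plist: optional list of 5
# precomputed transition matrices (avoids rebuilding unchanged ones during
# coordinate-wise optimization).
quartet_lnl <- function(pat, b, kappa, bf, Plist = NULL) {
  if (is.null(Plist)) Plist <- lapply(b, hky_prob, kappa = kappa, bf = bf)
  s <- pat$states
  L1 <- Plist[[1]][, s[1, ], drop = FALSE] * Plist[[2]][, s[2, ], drop = FALSE]
  L2 <- Plist[[3]][, s[3, ], drop = FALSE] * Plist[[4]][, s[4, ], drop = FALSE]
  sl <- colSums((bf * L1) * (Plist[[5]] %*% L2))
  sum(pat$w * log(pmax(sl, 1e-300)))   # guard against underflow at extremes
}

# tip order (within the labels vector a1,a2,b1,b2) for each topology's
# cherries ((t1,t2),(t3,t4))
topology_order <- function(topology) {
  switch(topology,
         type_N = c(1L, 3L, 2L, 4L),  # (a1,b1) vs (a2,b2)
         type_C = c(1L, 2L, 3L, 4L),  # (a1,a2) vs (b1,b2)
         stop("unknown topology: ", topology))
}

#' Maximized quartet log-likelihood under a fixed topology
#'
#' Fits the HKY85 model (five branch lengths plus a shared kappa; base
#' frequencies fixed at their empirical window values) on one of the two
#' informative unrooted quartet topologies by Felsenstein's pruning
#' algorithm.  Optimization is bounded quasi-Newton (L-BFGS-B) over the five
#' branch lengths (bounded `[0, 5]`) and log-kappa (kappa in `[0.01, 100]`),
#' run from two starting points (branch lengths 0.05 and 0.5) to guard
#' against local optima.  Columns containing a gap or `N` in any of the four
#' sequences are excluded.
#'
#' @param aln a `"dna_alignment"` containing the four labelled sequences
#'   (extra records are ignored).
#' @param labels character(4): ids of species-A copy 1/copy 2 and species-B
#'   copy 1/copy 2, in that order (`a1, a2, b1, b2`).
#' @param topology `"type_N"` (orthologs paired: `((a1,b1),(a2,b2))`) or
#'   `"type_C"` (within-species paralogs paired: `((a1,a2),(b1,b2))`).
#' @param max_iter iteration cap passed to the optimizer.
#' @return Object of class `"quartet_fit"`: list with elements `logLik`,
#'   `kappa`, `branch_lengths` (named, 4 terminal + internal), `bf`,
#'   `topology`, `n_columns`, `labels`.
#' @export
quartet_loglik <- function(aln, labels, topology = c("type_N", "type_C"),
                           max_iter = 500L) {
  topology <- match.arg(topology)
  if (length(labels) != 4L || anyDuplicated(labels))
    stop("labels must be four distinct sequence ids")
  miss <- setdiff(labels, names(aln))
  if (length(miss)) stop("labels not in alignment: ", paste(miss, collapse = ", "))
  m <- seq_matrix(aln[labels])
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) stop("degenerate window: all columns contain a gap or N")
  m <- m[, keep, drop = FALSE]
  states <- matrix(match(m, BASES), nrow = 4L)
  bf <- tabulate(states, 4L) / length(states)
  bf <- pmax(bf, 1e-6); bf <- bf / sum(bf)
  ord <- topology_order(topology)
  pat <- site_patterns(states[ord, , drop = FALSE])

  lower <- c(rep(0, 5L), log(0.01)); upper <- c(rep(5, 5L), log(100))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!identical(cache$par, par)) {
      cache$par <- par
      cache$val <- quartet_lnl_grad(pat, par, bf)
    }
    cache$val
  }
  negloglik <- function(par) {
    v <- evaluate(par)$lnl
    if (!is.finite(v)) 1e10 else -v
  }
  neggrad <- function(par) -evaluate(par)$grad
  fit_from <- function(b0) {
    o <- stats::optim(c(rep(b0, 5L), log(2)), negloglik, neggrad,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = 1e6, maxit = max_iter))
    list(par = o$par, lnl = -o$value)
  }
  best <- fit_from(0.05)
  alt <- fit_from(0.5)
  if (alt$lnl > best$lnl) best <- alt
  if (!is.finite(best$lnl))
    stop("optimizer failure: non-finite likelihood (n_columns=", sum(keep), ")")
  # snap near-zero branch lengths for readability
  b <- best$par[1:5]; b[b < 1e-7] <- 0
  tipnames <- labels[ord]
  structure(list(logLik = best$lnl, kappa = exp(best$par[6]),
                 branch_lengths = setNames(b, c(tipnames, "internal")),
                 bf = setNames(bf, BASES), topology = topology,
                 n_columns = sum(keep), labels = labels),
            class = "quartet_fit")
}

#' @export
print.quartet_fit <- function(x, ...) {
  cat("Quartet HKY85 fit (", x$topology, "), ", x$n_columns,
      " gap-free columns\n", sep = "")
  cat("  lnL =", format(x$logLik, digits = 8), " kappa =",
      format(x$kappa, digits = 4), "\n")
  cat("  branch lengths:",
      paste(names(x$branch_lengths),
            formatC(x$branch_lengths, digits = 4, format = "g"),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.quartet_fit <- function(object, ...) {
  structure(object$logLik, df = 6L, class = "logLik")
}

#' @export
coef.quartet_fit <- function(object, ...) {
  c(object$branch_lengths, kappa = object$kappa)
}

#' Bin exons into sliding windows
#'
#' Exons at least as long as `window` are cut into `window`-bp windows
#' advanced by `step` bp; shorter exons are kept as single whole-exon
#' windows.
#'
#' @param exon_lengths named integer vector of exon lengths (bp), in CDS
#'   order, or an [exon_map()].
#' @param window window width in bp.
#' @param step step in bp; must be a multiple of 3.
#' @return data.frame with columns `exon`, `start`, `end` (0-based half-open
#'   on the concatenated CDS), `start_1based`, `is_whole_exon`.
#' @export
bin_windows <- function(exon_lengths, window = 150L, step = 9L) {
  if (inherits(exon_lengths, "exon_map")) {
    exon_lengths <- setNames(exon_lengths$end - exon_lengths$start,
                             exon_lengths$name)
  }
  window <- as.integer(window); step <- as.integer(step)
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  if (step %% 3L != 0L) stop("step must be a multiple of 3")
  nm <- names(exon_lengths)
  if (is.null(nm)) nm <- paste0("exon", seq_along(exon_lengths))
  offs <- c(0L, cumsum(as.integer(exon_lengths)))
  out <- list()
  for (i in seq_along(exon_lengths)) {
    L <- as.integer(exon_lengths[i])
    if (L < 1L) stop("exon length must be >= 1")
    if (L >= window) {
      starts <- seq.int(0L, L - window, by = step)
      out[[i]] <- data.frame(exon = nm[i], start = offs[i] + starts,
                             end = offs[i] + starts + window,
                             is_whole_exon = FALSE, stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(exon = nm[i], start = offs[i], end = offs[i] + L,
                             is_whole_exon = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$start_1based <- res$start + 1L
  res[, c("exon", "start", "end", "start_1based", "is_whole_exon")]
}

#' Sliding-window quartet scan for gene conversion
#'
#' For each window of the concatenated-CDS alignment, maximizes the HKY85
#' log-likelihood under the no-conversion (type-N) and conversion (type-C)
#' quartet topologies and reports their difference
#' `delta = lnL_C - lnL_N`.  Windows where `delta > 0` favour the
#' within-species pairing expected after inter-paralog gene conversion.  The
#' scan is not sensitive to conversion tracts much shorter than the window.
#'
#' @param aln `"dna_alignment"` of the four sequences over the concatenated
#'   CDS (columns consistent with `exons`).
#' @param labels character(4): ids `a1, a2, b1, b2` (two paralogs in each of
#'   two species).
#' @param exons an [exon_map()] (or named vector of exon lengths).
#' @param window,step window width and slide step in bp (see
#'   [bin_windows()]).
#' @param min_columns windows retaining fewer gap-free columns are flagged
#'   `low_information`.
#' @return Object of class `"conversion_scan"`: a data.frame with one row
#'   per window (`exon`, `start_1based`, `lnL_N`, `lnL_C`, `delta`,
#'   `p_value`, `n_columns`, `flags`) plus attributes.  `p_value` is the
#'   upper tail of chi-square(1) at `2*|delta|`, a descriptive index only:
#'   the two topologies are not nested hypotheses.
#' @export
conversion_scan <- function(aln, labels, exons, window = 150L, step = 9L,
                            min_columns = 30L) {
  wins <- bin_windows(exons, window = window, step = step)
  total <- max(wins$end)
  if (nchar(aln[[1]]) < total)
    stop("alignment has ", nchar(aln[[1]]), " columns but exon map spans ", total)
  n <- nrow(wins)
  lnl_n <- lnl_c <- rep(NA_real_, n)
  ncols <- integer(n); flags <- character(n)
  for (i in seq_len(n)) {
    sub <- dna_seqs(substring(as.character(aln), wins$start[i] + 1L, wins$end[i]),
                    ids = names(aln), alignment = TRUE)
    fN <- tryCatch(quartet_loglik(sub, labels, "type_N"), error = function(e) e)
    fC <- tryCatch(quartet_loglik(sub, labels, "type_C"), error = function(e) e)
    if (inherits(fN, "error") || inherits(fC, "error")) {
      flags[i] <- "failed"
      next
    }
    lnl_n[i] <- fN$logLik; lnl_c[i] <- fC$logLik
    ncols[i] <- fN$n_columns
    if (fN$n_columns < min_columns) flags[i] <- "low_information"
  }
  delta <- lnl_c - lnl_n
  res <- data.frame(exon = wins$exon, start = wins$start, end = wins$end,
                    start_1based = wins$start_1based,
                    is_whole_exon = wins$is_whole_exon,
                    lnL_N = lnl_n, lnL_C = lnl_c, delta = delta,
                    p_value = pchisq(2 * abs(delta), df = 1, lower.tail = FALSE),
                    n_columns = ncols, flags = flags,
                    stringsAsFactors = FALSE)
  structure(res, class = c("conversion_scan", "data.frame"),
            labels = labels, window = window, step = step)
}

# contiguous runs of delta > 0: candidate conversion tracts
positive_runs <- function(x) {
  pos <- !is.na(x$delta) & x$delta > 0
  if (!any(pos)) return(x[0, c("exon", "start", "end")])
  r <- rle(pos)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(exon = x$exon[starts[idx]],
             start = x$start[starts[idx]], end = x$end[ends[idx]],
             n_windows = r$lengths[idx], max_delta = vapply(idx, function(k)
               max(x$delta[starts[k]:ends[k]]), numeric(1)))
}

#' @export
summary.conversion_scan <- function(object, ...) {
  ok <- !is.na(object$delta)
  top <- if (any(ok)) which.max(ifelse(ok, object$delta, -Inf)) else NA_integer_
  out <- list(n_windows = nrow(object), n_failed = sum(!ok),
              argmax = if (!is.na(top)) object[top, , drop = FALSE],
              tracts = positive_runs(object),
              n_positive = sum(object$delta > 0, na.rm = TRUE))
  class(out) <- "summary.conversion_scan"
  out
}

#' @export
print.summary.conversion_scan <- function(x, ...) {
  cat("Gene-conversion quartet scan:", x$n_windows, "windows,",
      x$n_positive, "with delta > 0 (type-C favoured)\n")
  if (!is.null(x$argmax) && nrow(x$argmax)) {
    a <- x$argmax
    cat(sprintf("  max delta = %.2f in %s at CDS position %d (lnL_C %.2f vs lnL_N %.2f)\n",
                a$delta, a$exon, a$start_1based, a$lnL_C, a$lnL_N))
  }
  if (nrow(x$tracts)) {
    cat("  candidate conversion tracts (runs of delta > 0):\n")
    for (i in seq_len(nrow(x$tracts)))
      cat(sprintf("    %s: columns %d-%d (%d windows, max delta %.2f)\n",
                  x$tracts$exon[i], x$tracts$start[i] + 1L, x$tracts$end[i],
                  x$tracts$n_windows[i], x$tracts$max_delta[i]))
  } else cat("  no windows favour the type-C (conversion) topology\n")
  invisible(x)
}

#' @export
print.conversion_scan <- function(x, ...) {
  need <- c("exon", "start_1based", "lnL_N", "lnL_C", "delta", "n_columns")
  if (!all(need %in% names(x))) return(NextMethod())  # column subset
  cat("conversion_scan:", nrow(x), "windows; labels:",
      paste(attr(x, "labels"), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x)[,
    c("exon", "start_1based", "lnL_N", "lnL_C", "delta", "n_columns")], 10),
    digits = 6)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more windows\n")
  invisible(x)
}

#' Plot a conversion scan
#'
#' Window plot of the two maximized log-likelihoods against CDS position:
#' type-N in red, type-C in black, with dashed vertical exon boundaries.
#'
#' @param x a `"conversion_scan"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.conversion_scan <- function(x, ...) {
  pos <- (x$start + x$end) / 2
  graphics::plot(range(pos), range(c(x$lnL_N, x$lnL_C), na.rm = TRUE),
                 type = "n", xlab = "CDS position (bp)",
                 ylab = "log-likelihood", ...)
  for (e in unique(x$exon)) {
    i <- x$exon == e
    graphics::lines(pos[i], x$lnL_N[i], col = "red")
    graphics::lines(pos[i], x$lnL_C[i], col = "black")
  }
  bounds <- tapply(x$end, x$exon, max)
  graphics::abline(v = bounds[-length(bounds)], lty = 2, col = "grey50")
  graphics::legend("bottomleft", legend = c("type-N (no conversion)",
                                            "type-C (conversion)"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}
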