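## Hudson-Kreitman-Aguade test, one-species-polymorphism form: under
## neutrality, within-species polymorphism and divergence to an outgroup are
## proportional across loci, both being driven by the same per-locus mutation
## rate.

#' HKA polymorphism-divergence test
#'
#' Method-of-moments fit of the neutral model across `L >= 2` loci.  With
#' `M_i = theta_i * L_i` (the per-locus population mutation rate) and `T` the
#' divergence-time parameter (in 2N generations), the model moments are
#' `E[S_i] = M_i * a(n_i)`, `Var[S_i] = E[S_i] + M_i^2 * a2(n_i)`,
#' `E[D_i] = M_i * (T + 1)`, `Var[D_i] = E[D_i] + M_i^2`.  The estimates
#' solve `S_i + D_i = M_i (a_i + T + 1)` per locus together with
#' `sum(D_i) = (T + 1) sum(M_i)`; the goodness-of-fit statistic sums the
#' squared standardized deviations of every `S_i` and `D_i` and is referred
#' to chi-square with `L - 1` degrees of freedom.
#'
#' @param S integer vector: segregating sites per locus.
#' @param n integer vector: chromosomes sampled per locus.
#' @param D numeric vector: divergence difference counts to the outgroup per
#'   locus (mean pairwise differences between each sampled haplotype and the
#'   outgroup sequence).
#' @param L numeric vector: compared sites per locus.
#' @param loci optional locus names.
#' @return Object of class `"hka_test"` with `theta_hat` (per site), `T_hat`,
#'   `X2`, `df`, `p_value`, and the expected values.
#' @export
hka_test <- function(S, n, D, L, loci = NULL) {
  k <- length(S)
  if (k < 2L) stop("need at least 2 loci")
  if (length(n) != k || length(D) != k || length(L) != k)
    stop("S, n, D, L must have one entry per locus")
  if (any(S < 0) || any(D < 0) || any(L <= 0)) stop("counts must be non-negative")
  if (any(n < 2)) stop("need n >= 2 at every locus")
  if (is.null(loci)) loci <- paste0("locus", seq_len(k))
  a1 <- vapply(n, function(m) sum(1 / seq_len(m - 1)), numeric(1))
  a2 <- vapply(n, function(m) sum(1 / seq_len(m - 1)^2), numeric(1))
  f <- function(Tv) sum(D) - (Tv + 1) * sum((S + D) / (a1 + Tv + 1))
  lo <- -1 + 1e-9; hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
  if (f(lo) < 0 || f(hi) > 0)
    stop("no root for the divergence-time parameter; inputs: S=",
         paste(S, collapse = ","), " D=", paste(D, collapse = ","))
  T_hat <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  M <- (S + D) / (a1 + T_hat + 1)
  ES <- M * a1; VS <- ES + M^2 * a2
  ED <- M * (T_hat + 1); VD <- ED + M^2
  X2 <- sum((S - ES)^2 / VS + (D - ED)^2 / VD)
  df <- k - 1L
  structure(list(loci = loci, theta_hat = M / L, M_hat = M, T_hat = T_hat,
                 E_S = ES, E_D = ED, X2 = X2, df = df,
                 p_value = pchisq(X2, df, lower.tail = FALSE)),
            class = "hka_test")
}

#' @export
print.hka_test <- function(x, ...) {
  cat("HKA test over", length(x$loci), "loci\n")
  cat(sprintf("  X2 = %.4f  df = %d  P = %.4f   T_hat = %.3f\n",
              x$X2, x$df, x$p_value, x$T_hat))
  tab <- data.frame(locus = x$loci, theta = signif(x$theta_hat, 4),
                    E_S = round(x$E_S, 2), E_D = round(x$E_D, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square comparing observed genotype counts with expectations
#' `p^2, 2pq, q^2` from the sample allele frequencies; 1 degree of freedom,
#' no continuity correction.  A monomorphic sample returns `p = 1` with a
#' flag.
#'
#' @param counts integer(3): `(hom_ref, het, hom_alt)` individual counts.
#' @return list with `chi2`, `df`, `p_value`, `expected`, `monomorphic`.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3L || any(counts < 0)) stop("counts must be (hom_ref, het, hom_alt)")
  N <- sum(counts)
  if (N < 1L) stop("need at least one individual")
  p <- (2 * counts[1] + counts[2]) / (2 * N)
  q <- 1 - p
  if (p == 0 || q == 0) {
    return(list(chi2 = 0, df = 1L, p_value = 1, monomorphic = TRUE,
                expected = as.numeric(counts)))
  }
  expd <- N * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = chi2, df = 1L, p_value = pchisq(chi2, 1, lower.tail = FALSE),
       expected = expd, monomorphic = FALSE)
}
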