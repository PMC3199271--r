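## Simulators producing data with the statistical structure the analyses
## assume: quartet alignments descending from a duplication-then-speciation
## history with optional gene-conversion tracts, and coalescent population
## samples with CpG-context hypermutability, deamination bias, and tunable
## functional constraint.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# evolve a sequence (integer codes 1..4) along a branch of t expected
# substitutions/site under HKY (site-independent)
evolve_hky <- function(states, t, kappa, bf) {
  if (t <= 0) return(states)
  P <- hky_prob(t, kappa, bf)
  out <- states
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                            prob = P[s, ])
  }
  out
}

states_to_seq <- function(states) paste(BASES[states], collapse = "")
seq_to_states <- function(s) match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)

#' Simulate a paralog quartet with an optional gene-conversion tract
#'
#' Evolves sequences along the duplication-then-speciation history of a
#' tandem gene pair sampled in two species: a duplication ancestor spawns the
#' copy-1 and copy-2 lineages (each evolving `t_dup` expected
#' substitutions/site until speciation), after which each copy splits into
#' the two species' terminal branches (`t_spec` each), yielding `a1, a2, b1,
#' b2`.  If `tract` is given, at fraction `conversion_time` of the terminal
#' branch the tract of `a2` is overwritten with `a1`'s current state
#' (non-reciprocal gene conversion in species A) and both continue evolving.
#'
#' @param length sequence length in bp (codon multiple not required here).
#' @param t_dup,t_spec branch lengths in expected substitutions/site.
#' @param kappa,bf HKY parameters.
#' @param tract optional `c(start, end)` 0-based half-open conversion tract,
#'   or a list of such tracts (one conversion event copying all of them at
#'   the same time).
#' @param conversion_time fraction of the terminal branch elapsed before the
#'   conversion event, in `[0, 1]`.
#' @param both_species logical; if `TRUE` the conversion event also
#'   overwrites the tract of `b2` with `b1`'s state at the same relative
#'   time (independent homogenization in both lineages, as observed when
#'   both species' paralog pairs are near-identical in converted regions).
#'   The unrooted topology within the tract is type-C either way.
#' @param root optional root DNA string (e.g. from [make_cpg_rich_cds()]);
#'   drawn from `bf` if `NULL`.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return list with `aln` (a `"dna_alignment"` named a1, a2, b1, b2) and
#'   `truth` (tract, times, parameters).
#' @export
simulate_quartet <- function(length = 501L, t_dup = 0.3, t_spec = 0.1,
                             kappa = 2, bf = rep(0.25, 4), tract = NULL,
                             conversion_time = 0.5, both_species = FALSE,
                             root = NULL, seed = NULL) {
  stopifnot(t_dup >= 0, t_spec >= 0,
            conversion_time >= 0, conversion_time <= 1)
  if (!is.null(tract)) {
    if (!is.list(tract)) tract <- list(tract)
    for (tr in tract)
      stopifnot(base::length(tr) == 2L, tr[1] >= 0, tr[2] <= length,
                tr[2] > tr[1])
  }
  with_seed(seed, {
    r <- if (is.null(root)) sample.int(4L, length, replace = TRUE, prob = bf)
         else seq_to_states(root)
    c1 <- evolve_hky(r, t_dup, kappa, bf)   # copy-1 lineage at speciation
    c2 <- evolve_hky(r, t_dup, kappa, bf)
    convert_pair <- function() {
      t1 <- conversion_time * t_spec
      m1 <- evolve_hky(c1, t1, kappa, bf)
      m2 <- evolve_hky(c2, t1, kappa, bf)
      for (tr in tract) {
        idx <- (tr[1] + 1L):tr[2]
        m2[idx] <- m1[idx]                 # conversion: copy-1 donor
      }
      list(evolve_hky(m1, t_spec - t1, kappa, bf),
           evolve_hky(m2, t_spec - t1, kappa, bf))
    }
    if (is.null(tract)) {
      a1 <- evolve_hky(c1, t_spec, kappa, bf)
      a2 <- evolve_hky(c2, t_spec, kappa, bf)
      b1 <- evolve_hky(c1, t_spec, kappa, bf)
      b2 <- evolve_hky(c2, t_spec, kappa, bf)
    } else {
      ab <- convert_pair()
      a1 <- ab[[1]]; a2 <- ab[[2]]
      if (both_species) {
        bb <- convert_pair()
        b1 <- bb[[1]]; b2 <- bb[[2]]
      } else {
        b1 <- evolve_hky(c1, t_spec, kappa, bf)
        b2 <- evolve_hky(c2, t_spec, kappa, bf)
      }
    }
    aln <- dna_seqs(vapply(list(a1, a2, b1, b2), states_to_seq, character(1)),
                    ids = c("a1", "a2", "b1", "b2"), alignment = TRUE)
    list(aln = aln,
         truth = list(tract = tract, conversion_time = conversion_time,
                      both_species = both_species,
                      t_dup = t_dup, t_spec = t_spec, kappa = kappa))
  })
}

# Kingman coalescent genealogy for n lineages; optionally an outgroup
# lineage joining the pool at time `outgroup_split` (coalescent units of 2N
# generations).  Returns an edge list (parent, child, child_time,
# parent_time) with tips 1..n (+ outgroup tip n+1), internal nodes above.
coalescent_tree <- function(n, outgroup_split = NULL) {
  active <- seq_len(n)
  times <- rep(0, n)                 # birth (tipward) time of each node
  if (!is.null(outgroup_split)) {
    og <- n + 1L
    times <- c(times, outgroup_split)
  }
  next_node <- n + if (is.null(outgroup_split)) 1L else 2L
  t <- 0
  edges <- list()
  og_added <- is.null(outgroup_split)
  repeat {
    k <- length(active)
    if (k == 1L && og_added) break
    rate <- k * (k - 1) / 2
    dt <- if (rate > 0) rexp(1, rate) else Inf
    if (!og_added && t + dt > outgroup_split) {
      t <- outgroup_split
      active <- c(active, n + 1L)
      og_added <- TRUE
      next
    }
    t <- t + dt
    pair <- sample(active, 2L)
    node <- next_node; next_node <- next_node + 1L
    times <- c(times, t)
    edges[[length(edges) + 1L]] <- data.frame(
      parent = node, child = pair, child_time = times[pair], parent_time = t)
    active <- c(setdiff(active, pair), node)
  }
  list(edges = do.call(rbind, edges), times = times,
       root = active, n = n,
       outgroup = if (is.null(outgroup_split)) NA_integer_ else n + 1L)
}

# per-site mutation weights: 1, or cpg_multiplier for bases inside a CpG
cpg_weights <- function(states, cpg_multiplier) {
  L <- length(states)
  w <- rep(1, L)
  if (cpg_multiplier != 1 && L >= 2L) {
    is_c <- states == 2L; is_g <- states == 3L
    cg_c <- which(is_c[-L] & is_g[-1L])         # C of a CG
    w[cg_c] <- cpg_multiplier
    w[cg_c + 1L] <- cpg_multiplier              # G of the same CG
  }
  w
}

# classify a substitution at site i (reading frame from codon position)
mutation_class <- function(states, i, new_state, gc) {
  ci <- (i - 1L) %/% 3L
  idx <- (ci * 3L + 1L):(ci * 3L + 3L)
  if (max(idx) > length(states)) return("noncoding")
  ref_cod <- paste(BASES[states[idx]], collapse = "")
  v <- states[idx]; v[i - ci * 3L] <- new_state
  alt_cod <- paste(BASES[v], collapse = "")
  if (alt_cod %in% STOP_CODONS) return("nonsense")
  if (ref_cod %in% STOP_CODONS) return("nonsynonymous")
  if (identical(gc[[ref_cod]], gc[[alt_cod]])) "synonymous" else "nonsynonymous"
}

# draw the target state for a mutation at site i given CpG-deamination bias
draw_target <- function(states, i, cpg_bias) {
  L <- length(states)
  s <- states[i]
  c_of_cg <- s == 2L && i < L && states[i + 1L] == 3L
  g_of_cg <- s == 3L && i > 1L && states[i - 1L] == 2L
  if (c_of_cg && runif(1) < cpg_bias) return(4L)       # C -> T
  if (g_of_cg && runif(1) < cpg_bias) return(1L)       # G -> A
  sample(setdiff(1:4, s), 1L)
}

# place mutations on one branch, sequentially with context re-evaluation
mutate_branch <- function(states, t_len, theta, cpg_multiplier, cpg_bias,
                          constraint, gc, truth, branch_id) {
  t_rem <- t_len
  w <- cpg_weights(states, cpg_multiplier)
  repeat {
    R <- theta / 2 * sum(w)
    if (R <= 0) break
    dt <- rexp(1, R)
    if (dt > t_rem) break
    t_rem <- t_rem - dt
    i <- sample.int(length(states), 1L, prob = w)
    new_state <- draw_target(states, i, cpg_bias)
    cls <- mutation_class(states, i, new_state, gc)
    accepted <- TRUE
    if (cls %in% c("nonsynonymous", "nonsense") && runif(1) < constraint)
      accepted <- FALSE
    truth$mutations[[length(truth$mutations) + 1L]] <- data.frame(
      site = i, branch = branch_id, from = BASES[states[i]],
      to = BASES[new_state], class = cls, accepted = accepted,
      stringsAsFactors = FALSE)
    if (accepted) {
      states[i] <- new_state
      lo <- max(1L, i - 1L); hi <- min(length(states), i + 1L)
      w[lo:hi] <- cpg_weights(states, cpg_multiplier)[lo:hi]
    }
  }
  list(states = states, truth = truth)
}

#' Simulate a coalescent population sample with CpG hypermutability
#'
#' Draws a Kingman coalescent genealogy for `n` chromosomes (constant
#' population size, no recombination), then places mutations along branches
#' as a Poisson process with per-site rate `theta/2`, multiplied by
#' `cpg_multiplier` at sites currently inside a CpG dinucleotide of the
#' carrying lineage (context re-evaluated after every mutation, so CpGs
#' created along a lineage become hypermutable).  CpG mutations are
#' deamination-biased (`C>T` at the C, `G>A` at the G, with probability
#' `cpg_bias`).  Each nonsynonymous or nonsense mutation is rejected with
#' probability `constraint` (0 = unconstrained pseudogene, 1 = full
#' constraint).  Diploid genotypes are formed by random pairing of the
#' haplotypes (Hardy-Weinberg by construction).
#'
#' @param n sampled chromosomes.
#' @param theta per-site population mutation rate (4Nu).
#' @param cds ancestral coding sequence (see [make_cpg_rich_cds()]).
#' @param cpg_multiplier rate factor at CpG sites.
#' @param cpg_bias probability a CpG mutation is the deamination change.
#' @param constraint rejection probability for function-altering mutations.
#' @param diploids logical; emit a genotype table (requires even `n`).
#' @param outgroup_split optional time (2N units) at which an outgroup
#'   lineage joins the genealogy; the outgroup sequence is returned
#'   separately.
#' @param seed optional integer seed.
#' @param species,locus labels for the returned [haplotype_set()].
#' @return list with `haplotypes` (a [haplotype_set()]), `outgroup` (string
#'   or `NULL`), `genotypes` (individuals x segregating-site dosage matrix,
#'   or `NULL`), and `truth` (placed mutations with acceptance flags).
#' @export
simulate_population_sample <- function(n, theta, cds, cpg_multiplier = 10,
                                       cpg_bias = 30 / 32, constraint = 0,
                                       diploids = FALSE,
                                       outgroup_split = NULL, seed = NULL,
                                       species = "sim", locus = "simlocus") {
  stopifnot(n >= 2, theta >= 0, constraint >= 0, constraint <= 1,
            cpg_bias >= 0, cpg_bias <= 1, cpg_multiplier >= 1)
  if (diploids && n %% 2L != 0L) stop("diploid output needs even n")
  root <- seq_to_states(as.character(cds)[1])
  gc <- genetic_code()
  with_seed(seed, {
    tree <- coalescent_tree(n, outgroup_split)
    truth <- list(mutations = list())
    # traverse rootward-to-tipward: order edges by decreasing parent_time
    e <- tree$edges[order(-tree$edges$parent_time), ]
    node_states <- list()
    node_states[[as.character(tree$root)]] <- root
    for (r in seq_len(nrow(e))) {
      par <- as.character(e$parent[r]); ch <- as.character(e$child[r])
      res <- mutate_branch(node_states[[par]],
                           e$parent_time[r] - e$child_time[r],
                           theta, cpg_multiplier, cpg_bias, constraint, gc,
                           truth, branch_id = paste0(par, "->", ch))
      node_states[[ch]] <- res$states
      truth <- res$truth
    }
    haps <- vapply(seq_len(n), function(i)
      states_to_seq(node_states[[as.character(i)]]), character(1))
    h <- haplotype_set(dna_seqs(haps, ids = sprintf("hap%02d", seq_len(n)),
                                alignment = TRUE),
                       species = species, locus = locus)
    outg <- if (!is.na(tree$outgroup))
      states_to_seq(node_states[[as.character(tree$outgroup)]])
    genotypes <- NULL
    if (diploids) {
      ord <- sample.int(n)
      m <- seq_matrix(h$aln)
      seg <- which(apply(m, 2L, function(cl) length(unique(cl)) > 1L))
      anc <- BASES[root]
      ind <- matrix(0L, nrow = n %/% 2L, ncol = length(seg),
                    dimnames = list(NULL, paste0("pos", seg)))
      for (j in seq_along(seg)) {
        derived <- m[, seg[j]] != anc[seg[j]]
        ind[, j] <- derived[ord[seq(1, n, 2)]] + derived[ord[seq(2, n, 2)]]
      }
      genotypes <- ind
    }
    truth$mutations <- if (length(truth$mutations))
      do.call(rbind, truth$mutations) else NULL
    list(haplotypes = h, outgroup = outg, genotypes = genotypes,
         truth = truth)
  })
}

#' Generate a CpG-rich coding sequence
#'
#' Random CDS without internal stop codons whose CpG fraction
#' (`2 * count / length`) is within `tol` of `target`; built by stochastic
#' codon replacement toward the target.
#'
#' @param length CDS length in bp (codon multiple).
#' @param target target CpG fraction in `[0, 0.5]`.
#' @param tol acceptance tolerance on the fraction.
#' @param seed optional integer seed.
#' @param max_iter bound on replacement proposals.
#' @return DNA string.
#' @export
make_cpg_rich_cds <- function(length, target = 0.08, tol = 0.01,
                              seed = NULL, max_iter = 50000L) {
  stopifnot(length %% 3L == 0L, target >= 0, target <= 0.5)
  tol <- max(tol, 1 / length)   # the fraction is quantized in steps of 2/length
  gc <- genetic_code()
  sense <- setdiff(names(gc), STOP_CODONS)
  with_seed(seed, {
    cod <- sample(sense, length %/% 3L, replace = TRUE)
    s <- paste(cod, collapse = "")
    f <- cpg_fraction(s)
    it <- 0L
    while (abs(f - target) > tol && it < max_iter) {
      it <- it + 1L
      i <- sample.int(base::length(cod), 1L)
      old <- cod[i]
      cod[i] <- sample(sense, 1L)
      s2 <- paste(cod, collapse = "")
      f2 <- cpg_fraction(s2)
      if (abs(f2 - target) < abs(f - target)) { s <- s2; f <- f2 }
      else cod[i] <- old
    }
    if (abs(f - target) > tol)
      stop("could not reach target CpG fraction ", target, " (at ",
           signif(f, 3), " after ", max_iter, " proposals)")
    s
  })
}
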