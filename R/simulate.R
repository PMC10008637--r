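#' Simulation specification
#'
#' Parameters of the synthetic genotype/phenotype generator. The defaults
#' emulate the structure of the pepper core-collection dataset the package
#' targets: 179 diploid accessions (two diverged source populations plus a
#' small admixed fraction), 27 codominant loci with 2-20 alleles each, 22
#' categorical and 13 numeric traits, a few percent missing calls and
#' clear between-population divergence.
#'
#' @param n_pops number of source populations.
#' @param n_per_pop pure individuals per population (recycled to
#'   `n_pops`).
#' @param n_admixed individuals whose ancestry mixes all populations.
#' @param n_loci number of loci.
#' @param alleles_per_locus length-2 range of allele counts per locus.
#' @param fst Balding-Nichols divergence parameter F in (0, 1); the
#'   expected locus-wise FST is approximately F.
#' @param missing_rate probability a call (or phenotype value) is masked.
#' @param admixture_alpha symmetric Dirichlet parameter for admixed Q rows.
#' @param n_qual_traits,n_quant_traits trait counts used when explicit
#'   specs are not given.
#' @param qual_traits optional named list; per trait a `n_pops x k` matrix
#'   of per-population category frequencies (rows summing to 1).
#' @param quant_traits optional named list; per trait a list with numeric
#'   vectors `mean` and `sd` of length `n_pops`.
#' @param seed integer seed; every draw is reproducible from it.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_pops = 2, n_per_pop = c(85, 80),
                            n_admixed = 14, n_loci = 27,
                            alleles_per_locus = c(2, 20), fst = 0.25,
                            missing_rate = 0.02, admixture_alpha = 1,
                            n_qual_traits = 22, n_quant_traits = 13,
                            qual_traits = NULL, quant_traits = NULL,
                            seed = 20230311) {
  n_per_pop <- rep_len(n_per_pop, n_pops)
  if (any(c(n_per_pop, n_admixed, n_loci) < 0)) stop("counts must be >= 0")
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (admixture_alpha <= 0) stop("admixture_alpha must be positive")
  if (alleles_per_locus[1] < 2)
    stop("polymorphic loci need at least 2 alleles per locus")
  if (!is.null(qual_traits)) {
    for (nm in names(qual_traits)) {
      f <- qual_traits[[nm]]
      if (!is.matrix(f) || nrow(f) != n_pops || any(abs(rowSums(f) - 1) > 1e-8))
        stop("qual trait '", nm, "': frequency rows must sum to 1 (one row per population)")
    }
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 n_admixed = n_admixed, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus, fst = fst,
                 missing_rate = missing_rate,
                 admixture_alpha = admixture_alpha,
                 n_qual_traits = n_qual_traits,
                 n_quant_traits = n_quant_traits,
                 qual_traits = qual_traits, quant_traits = quant_traits,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

## the true ancestry matrix shared by genotype and phenotype generators:
## pure blocks first, then admixed rows ~ Dirichlet(admixture_alpha).
## Drawn on its own seed stream so both generators see identical ancestry.
true_ancestry <- function(spec) {
  n <- sum(spec$n_per_pop) + spec$n_admixed
  Q <- matrix(0, n, spec$n_pops)
  row <- 0
  for (k in seq_len(spec$n_pops)) {
    Q[row + seq_len(spec$n_per_pop[k]), k] <- 1
    row <- row + spec$n_per_pop[k]
  }
  if (spec$n_admixed > 0) {
    set.seed(spec$seed + 7L)
    Q[row + seq_len(spec$n_admixed), ] <-
      rdirichlet(spec$n_admixed, rep(spec$admixture_alpha, spec$n_pops))
  }
  ids <- sprintf("acc%03d", seq_len(n))
  labels <- max.col(Q, ties.method = "first")
  pop_names <- if (spec$n_pops == 2) c("LLR", "CBL") else
    paste0("Pop", seq_len(spec$n_pops))
  list(Q = Q, ids = ids, labels = labels, pop = pop_names[labels],
       admixed = c(rep(FALSE, n - spec$n_admixed), rep(TRUE, spec$n_admixed)))
}

#' Simulate diploid genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies per locus come from a flat Dirichlet;
#' population frequencies from `Dirichlet(p_anc * (1 - F) / F)`, so the
#' expected divergence (locus-wise FST) is approximately `F`. Each
#' individual draws two allele copies per locus from its population
#' (admixed individuals first draw the copy's source population from their
#' Q row), allele codes are emitted as plausible fragment sizes
#' (`150 + 2 * index` bp) and calls are masked at `missing_rate`.
#'
#' @param spec a [simulation_spec()].
#' @return list: `gm` (a [genotype_matrix()] with population labels set to
#'   each individual's majority-ancestry population), `labels` (true source
#'   cluster, argmax of Q), `Q` (true ancestry matrix), `admixed` (logical),
#'   `pop_freqs` (per locus a `n_pops x k` matrix of the drawn population
#'   frequencies, columns named by allele code).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  anc <- true_ancestry(spec)
  n <- length(anc$ids)
  set.seed(spec$seed)
  a1 <- matrix(NA_integer_, n, spec$n_loci)
  a2 <- a1
  pop_freqs <- vector("list", spec$n_loci)
  F <- spec$fst
  for (l in seq_len(spec$n_loci)) {
    k <- sample(seq(spec$alleles_per_locus[1], spec$alleles_per_locus[2]), 1)
    p_anc <- as.numeric(rdirichlet(1, rep(1, k)))
    pf <- rdirichlet(spec$n_pops, p_anc * (1 - F) / F)
    codes <- 150L + 2L * (seq_len(k) - 1L)
    colnames(pf) <- codes
    pop_freqs[[l]] <- pf
    ## source population of each copy, then the allele from that population
    z1 <- vapply(seq_len(n), function(i)
      sample.int(spec$n_pops, 1, prob = anc$Q[i, ]), integer(1))
    z2 <- vapply(seq_len(n), function(i)
      sample.int(spec$n_pops, 1, prob = anc$Q[i, ]), integer(1))
    a1[, l] <- codes[vapply(z1, function(z) sample.int(k, 1, prob = pf[z, ]), integer(1))]
    a2[, l] <- codes[vapply(z2, function(z) sample.int(k, 1, prob = pf[z, ]), integer(1))]
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * spec$n_loci) < spec$missing_rate,
                   n, spec$n_loci)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  rownames(a1) <- rownames(a2) <- anc$ids
  colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(spec$n_loci))
  names(pop_freqs) <- colnames(a1)
  gm <- genotype_matrix(a1, a2, pop = anc$pop)
  list(gm = gm, labels = anc$labels, Q = anc$Q, admixed = anc$admixed,
       pop_freqs = pop_freqs)
}

## default per-population trait distributions, drawn once from the spec seed
default_qual_specs <- function(spec) {
  set.seed(spec$seed + 11L)
  out <- list()
  for (j in seq_len(spec$n_qual_traits)) {
    k <- sample(2:6, 1)
    base <- as.numeric(rdirichlet(1, rep(1, k)))
    ## moderate between-population divergence of category frequencies
    out[[sprintf("qual%02d", j)]] <- rdirichlet(spec$n_pops, base * 9)
  }
  out
}

default_quant_specs <- function(spec) {
  set.seed(spec$seed + 13L)
  out <- list()
  for (j in seq_len(spec$n_quant_traits)) {
    m0 <- 10^stats::runif(1, 0.5, 2)              # trait scale 3-100 units
    cv <- stats::runif(1, 0.15, 0.5)              # CVs as seen in field panels
    shift <- stats::rnorm(spec$n_pops, 0, 0.15)
    out[[sprintf("quant%02d", j)]] <-
      list(mean = m0 * (1 + shift),
           sd = m0 * cv * stats::runif(spec$n_pops, 0.8, 1.2))
  }
  out
}

#' Simulate phenotype data
#'
#' Categorical traits are drawn from per-population category frequencies,
#' quantitative traits from per-population normals; each individual uses
#' the distributions of its majority-ancestry population, which matches
#' [simulate_genotypes()] run from the same spec (identical ids, labels
#' and population assignment). Values are masked at `missing_rate`.
#'
#' @param spec a [simulation_spec()].
#' @return a [trait_table()].
#' @export
simulate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  anc <- true_ancestry(spec)
  n <- length(anc$ids)
  qual_specs <- if (is.null(spec$qual_traits)) default_qual_specs(spec) else spec$qual_traits
  quant_specs <- if (is.null(spec$quant_traits)) default_quant_specs(spec) else spec$quant_traits
  set.seed(spec$seed + 1L)
  qual <- as.data.frame(lapply(qual_specs, function(f) {
    vapply(anc$labels, function(z)
      sample.int(ncol(f), 1, prob = f[z, ]), integer(1))
  }))
  quant <- as.data.frame(lapply(quant_specs, function(tq) {
    stats::rnorm(n, mean = tq$mean[anc$labels], sd = tq$sd[anc$labels])
  }))
  if (spec$missing_rate > 0) {
    for (nm in names(qual))
      qual[[nm]][stats::runif(n) < spec$missing_rate] <- NA_integer_
    for (nm in names(quant))
      quant[[nm]][stats::runif(n) < spec$missing_rate] <- NA_real_
  }
  dict <- lapply(qual_specs, function(f) as.character(seq_len(ncol(f))))
  trait_table(anc$ids, anc$pop,
              qualitative = if (length(qual)) qual,
              quantitative = if (length(quant)) quant,
              dictionaries = dict)
}

#' Paper-structured synthetic dataset
#'
#' Convenience preset: genotypes and phenotypes from one
#' [simulation_spec()] with the default (pepper-panel-like) dimensions.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_spec()].
#' @return list: `gm`, `tt`, `labels`, `Q`, `admixed`, `spec`.
#' @export
simulate_paperlike <- function(seed = 20230311, ...) {
  spec <- simulation_spec(seed = seed, ...)
  g <- simulate_genotypes(spec)
  tt <- simulate_phenotypes(spec)
  c(g, list(tt = tt, spec = spec))
}

#' Multi-locus FST estimate from labelled genotypes
#'
#' Nei-style estimator `1 - HS / HT` aggregated over loci: `HS` is the
#' average within-population expected heterozygosity and `HT` the expected
#' heterozygosity of the pooled allele frequencies (population-weighted).
#' Used to check the divergence the generator actually produces.
#'
#' @param gm a [genotype_matrix()].
#' @param labels population assignment per accession (defaults to
#'   `gm$pop`).
#' @return scalar FST estimate.
#' @export
fst_estimate <- function(gm, labels = gm$pop) {
  if (is.null(labels)) stop("population labels required")
  labels <- as.factor(labels)
  hs_sum <- ht_sum <- 0
  for (l in seq_len(ncol(gm$a1))) {
    a1 <- gm$a1[, l]; a2 <- gm$a2[, l]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    pk <- sapply(levels(labels), function(g) {
      sel <- ok & labels == g
      if (!any(sel)) return(rep(NA_real_, length(alleles)))
      copies <- c(a1[sel], a2[sel])
      vapply(alleles, function(a) mean(copies == a), numeric(1))
    })
    pk <- t(pk)                       # pop x allele
    w <- vapply(levels(labels), function(g) sum(ok & labels == g), numeric(1))
    pk <- pk[w > 0, , drop = FALSE]
    w <- w[w > 0] / sum(w)
    hs <- sum(w * (1 - rowSums(pk^2)))
    pbar <- colSums(w * pk)
    ht <- 1 - sum(pbar^2)
    hs_sum <- hs_sum + hs
    ht_sum <- ht_sum + ht
  }
  if (ht_sum == 0) return(0)
  1 - hs_sum / ht_sum
}
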