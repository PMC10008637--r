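#' Admixture-model configuration
#'
#' MCMC settings for [run_admixture()]. The defaults are desk-scale (5,000
#' sweeps, 1,000 burn-in, 4 chains); the study-scale settings used with
#' real panels (100,000 iterations, 30,000 burn-in, 8 chains per K) are
#' available by raising `iterations`/`burnin`/`runs`.
#'
#' @param K number of ancestral clusters (>= 1).
#' @param iterations total Gibbs sweeps per chain.
#' @param burnin discarded sweeps (`< iterations`).
#' @param runs independent chains.
#' @param seed base seed; chain `r` at this `K` uses
#'   `seed + 1000 * K + r`, so chains and K values are independent and the
#'   whole scan reproducible.
#' @param lambda Dirichlet prior parameter for cluster allele frequencies
#'   (independent-frequencies model).
#' @param alpha0 initial admixture concentration; alpha is then updated by
#'   reflected random-walk Metropolis (step 0.05) under a uniform prior on
#'   (0, 10].
#' @param thin record the log-likelihood/alpha traces every `thin`
#'   post-burn-in sweeps.
#' @return an `admixture_config` list.
#' @export
admixture_config <- function(K, iterations = 5000, burnin = 1000, runs = 4,
                             seed = 1, lambda = 1, alpha0 = 1, thin = 10) {
  if (K < 1) stop("K must be >= 1")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (runs < 1) stop("need at least 1 run")
  if (lambda <= 0 || alpha0 <= 0) stop("lambda and alpha0 must be positive")
  structure(list(K = as.integer(K), iterations = as.integer(iterations),
                 burnin = as.integer(burnin), runs = as.integer(runs),
                 seed = as.integer(seed), lambda = lambda, alpha0 = alpha0,
                 thin = as.integer(thin)),
            class = "admixture_config")
}

## recode allele sizes as per-locus indices 1..A_l (0 = missing) and drop
## all-missing loci
encode_alleles <- function(gm) {
  L <- ncol(gm$a1)
  keep <- logical(L)
  a1 <- gm$a1; a2 <- gm$a2
  e1 <- matrix(0L, nrow(a1), L); e2 <- e1
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    ok <- !is.na(a1[, l])
    if (!any(ok)) next
    keep[l] <- TRUE
    alleles <- sort(unique(c(a1[ok, l], a2[ok, l])))
    n_alleles[l] <- length(alleles)
    e1[ok, l] <- match(a1[ok, l], alleles)
    e2[ok, l] <- match(a2[ok, l], alleles)
  }
  if (!all(keep))
    warning("excluding all-missing loci: ",
            paste(locus_names(gm)[!keep], collapse = ", "))
  list(a1 = e1[, keep, drop = FALSE], a2 = e2[, keep, drop = FALSE],
       n_alleles = n_alleles[keep], loci = locus_names(gm)[keep])
}

#' Fit the Bayesian admixture model
#'
#' STRUCTURE-like Gibbs sampler under Hardy-Weinberg equilibrium within
#' clusters, independent loci and independent Dirichlet(`lambda`) cluster
#' allele frequencies. Each sweep resamples allele-copy origins, cluster
#' allele frequencies, per-individual admixture proportions Q and the
#' concentration alpha; missing allele copies are skipped everywhere. The
#' per-sweep log-likelihood is the sum over non-missing copies of
#' `ln sum_k q_ik p_kla`, and `ln Pr(X|K)` is estimated per chain as
#' `mean(lnL) - var(lnL) / 2` over the thinned post-burn-in trace.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg an [admixture_config()].
#' @param pin optional integer vector (one per accession): 0 leaves the
#'   individual free, `k` fixes its Q row at cluster `k` (used to anchor
#'   cluster labels in calibration experiments).
#' @return a `structure_result`: list with `K`, `config` and `runs`, where
#'   each run holds `Q` (posterior-mean admixture matrix, rows = accessions),
#'   `lnl` and `alpha` traces, posterior-mean `P` per locus, and `lnpk`.
#' @export
run_admixture <- function(gm, cfg, pin = NULL) {
  stopifnot(inherits(cfg, "admixture_config"))
  n <- nrow(gm$a1)
  if (n < 2) stop("need at least 2 accessions")
  enc <- encode_alleles(gm)
  if (is.null(pin)) pin <- integer(n)
  if (length(pin) != n) stop("`pin` must have one entry per accession")
  runs <- vector("list", cfg$runs)
  for (r in seq_len(cfg$runs)) {
    set.seed(cfg$seed + 1000L * cfg$K + r)
    fit <- gibbs_admixture(enc$a1, enc$a2, enc$n_alleles, cfg$K,
                           cfg$iterations, cfg$burnin, cfg$lambda,
                           cfg$alpha0, cfg$thin, as.integer(pin))
    rownames(fit$Q) <- accession_ids(gm)
    names(fit$P) <- enc$loci
    fit$lnpk <- ln_pr_k(fit$lnl)
    runs[[r]] <- fit
  }
  structure(list(K = cfg$K, config = cfg, runs = runs,
                 lnpk = vapply(runs, `[[`, numeric(1), "lnpk")),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat("structure_result: K =", x$K, "with", length(x$runs), "runs;",
      "ln Pr(X|K) =", paste(sprintf("%.1f", x$lnpk), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate ln Pr(X|K) from a log-likelihood trace
#'
#' The harmonic-style estimator used by the reference tool:
#' `mean(lnL) - var(lnL) / 2` over post-burn-in sweeps.
#'
#' @param lnl numeric log-likelihood trace.
#' @return scalar estimate.
#' @export
ln_pr_k <- function(lnl) {
  if (length(lnl) < 2) stop("need at least 2 trace points")
  mean(lnl) - stats::var(lnl) / 2
}

#' Scan K values with repeated chains
#'
#' Runs [run_admixture()] for each `K` in `k_range` with `runs` chains each
#' and collects the `ln Pr(X|K)` estimates for [evanno_delta_k()].
#'
#' @param gm a [genotype_matrix()].
#' @param k_range integer vector of K values (e.g. `1:10`).
#' @param ... further arguments to [admixture_config()] (`iterations`,
#'   `burnin`, `runs`, `seed`, ...).
#' @return list: `fits` (per-K `structure_result`s, named by K) and `lnpk`
#'   (matrix, rows = K values, columns = runs).
#' @export
structure_scan <- function(gm, k_range, ...) {
  fits <- lapply(k_range, function(k) run_admixture(gm, admixture_config(K = k, ...)))
  names(fits) <- k_range
  lnpk <- do.call(rbind, lapply(fits, `[[`, "lnpk"))
  rownames(lnpk) <- k_range
  list(fits = fits, lnpk = lnpk)
}

#' Evanno delta-K table
#'
#' From per-K, per-run `ln Pr(X|K)` estimates: `L(K)` = mean over runs,
#' `L'(K) = L(K) - L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `delta_K = |L''(K)| / sd(L(K))`. Delta-K is defined only for interior K
#' with a positive run-to-run sd; where sd is 0 the value is reported as
#' `NA` (never fabricated).
#'
#' @param lnpk matrix of `ln Pr(X|K)` values, rows = consecutive K values
#'   (rownames = K), columns = runs; e.g. `structure_scan()$lnpk`.
#' @return data.frame `K`, `mean_l`, `sd_l`, `l_prime`, `l_second_abs`,
#'   `delta_k`, with attribute `"optimal_k"` = K at the delta-K maximum.
#' @export
evanno_delta_k <- function(lnpk) {
  lnpk <- as.matrix(lnpk)
  if (nrow(lnpk) < 3) stop("need at least 3 consecutive K values")
  if (ncol(lnpk) < 2) stop("need at least 2 runs per K")
  ks <- as.integer(rownames(lnpk))
  if (is.null(rownames(lnpk)) || anyNA(ks)) ks <- seq_len(nrow(lnpk))
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  mean_l <- rowMeans(lnpk)
  sd_l <- apply(lnpk, 1, stats::sd)
  l_prime <- c(NA, diff(mean_l))
  l_second <- c(NA, abs(diff(l_prime[-1])), NA)
  delta <- l_second / sd_l
  delta[c(1, length(delta))] <- NA
  undef <- !is.na(l_second) & sd_l == 0
  if (any(undef)) {
    warning("delta-K undefined at K = ", paste(ks[undef], collapse = ", "),
            " (zero run-to-run sd)")
    delta[undef] <- NA
  }
  out <- data.frame(K = ks, mean_l = mean_l, sd_l = sd_l, l_prime = l_prime,
                    l_second_abs = l_second, delta_k = delta,
                    row.names = NULL)
  if (all(is.na(delta))) {
    attr(out, "optimal_k") <- NA_integer_
  } else {
    attr(out, "optimal_k") <- ks[which.max(delta)]
  }
  out
}

#' Assign accessions to clusters by Q threshold
#'
#' Each accession goes to its argmax cluster and is flagged admixed when
#' its largest Q does not exceed `threshold` (the reference analysis used
#' Q > 0.6 as clear membership).
#'
#' @param Q admixture matrix (rows sum to 1; rownames = accession ids).
#' @param threshold clear-membership threshold in (0.5, 1).
#' @return list: `assignments` (data.frame `id`, `cluster`, `max_q`,
#'   `admixed`) and `counts` (per cluster: members, above- and
#'   below-threshold counts).
#' @export
assign_groups <- function(Q, threshold = 0.6) {
  Q <- as.matrix(Q)
  if (threshold <= 0.5 || threshold >= 1) stop("threshold must be in (0.5, 1)")
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("Q rows must sum to 1")
  cl <- max.col(Q, ties.method = "first")
  mq <- Q[cbind(seq_len(nrow(Q)), cl)]
  ids <- rownames(Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
  assignments <- data.frame(id = ids, cluster = cl, max_q = mq,
                            admixed = mq <= threshold,
                            stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(seq_len(ncol(Q)), function(k) {
    in_k <- cl == k
    data.frame(cluster = k, members = sum(in_k),
               above_threshold = sum(in_k & mq > threshold),
               admixed = sum(in_k & mq <= threshold))
  }))
  list(assignments = assignments, counts = counts)
}

#' Align cluster labels across chains
#'
#' Label switching makes cluster indices arbitrary per chain. Each run is
#' aligned to the first by the greedy column matching that maximises the
#' summed column correlation, then the aligned runs are averaged.
#'
#' @param q_runs list of Q matrices with identical dimensions.
#' @return list: `aligned` (permuted Q matrices), `permutations` (per run,
#'   `aligned[[r]][, k] == q_runs[[r]][, perm[k]]`), `mean_q`.
#' @export
align_runs <- function(q_runs) {
  if (!length(q_runs)) stop("no runs given")
  dims <- vapply(q_runs, dim, integer(2))
  if (any(dims[2, ] != dims[2, 1])) stop("runs have differing K")
  ref <- q_runs[[1]]
  K <- ncol(ref)
  perms <- vector("list", length(q_runs))
  aligned <- vector("list", length(q_runs))
  for (r in seq_along(q_runs)) {
    if (r == 1 || K == 1) {
      perms[[r]] <- seq_len(K)
      aligned[[r]] <- q_runs[[r]]
      next
    }
    score <- suppressWarnings(stats::cor(ref, q_runs[[r]]))
    score[!is.finite(score)] <- 0     # constant columns (e.g. near-empty clusters)
    perm <- integer(K)
    for (step in seq_len(K)) {
      best <- which(score == max(score), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      score[best[1], ] <- -Inf
      score[, best[2]] <- -Inf
    }
    perms[[r]] <- perm
    aligned[[r]] <- q_runs[[r]][, perm, drop = FALSE]
    dimnames(aligned[[r]]) <- dimnames(q_runs[[r]])
  }
  mean_q <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, permutations = perms, mean_q = mean_q)
}
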