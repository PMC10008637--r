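#' Category frequencies of a qualitative trait
#'
#' Frequencies over non-missing values; missing values are dropped and the
#' frequencies renormalised. The returned vector spans codes
#' `1..n_categories` (zero for unobserved categories) so two populations can
#' be compared on a common dictionary.
#'
#' @param values integer category codes (`NA` = missing).
#' @param n_categories length of the category dictionary; defaults to the
#'   largest observed code.
#' @return named numeric vector of proportions summing to 1.
#' @export
category_frequencies <- function(values, n_categories = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty trait: all values missing")
  if (is.null(n_categories)) n_categories <- max(values)
  if (any(values < 1 | values > n_categories))
    stop("category code outside dictionary of size ", n_categories)
  counts <- tabulate(values, nbins = n_categories)
  stats::setNames(counts / sum(counts), seq_len(n_categories))
}

#' Shannon diversity index H' (natural log)
#'
#' `H' = -sum(Pi * ln(Pi))` over category (or score) frequencies, with
#' `0 * ln(0) := 0`. Computed at full precision; round only when reporting
#' (the reference tables print 2 dp).
#'
#' @param freqs non-negative frequencies summing to ~1.
#' @return H' in nats.
#' @export
shannon_index <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency")
  s <- sum(freqs)
  if (abs(s - 1) > 1e-6) stop("frequencies must sum to 1 (got ", s, ")")
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' 1-10 scoring scheme for a quantitative trait
#'
#' Scores are anchored on the aggregate mean `M` and sample standard
#' deviation `S` of the trait pooled over all accessions (both populations
#' together, so they share one scale): score 1 below `M - 2S`, score 10 at
#' or above `M + 2S`, and scores 2-9 on consecutive half-`S` intervals in
#' between (left-closed, right-open).
#'
#' @param values numeric trait values used to fit `M` and `S`
#'   (missing dropped), or `NULL` when `M`/`S` are given directly.
#' @param M,S mean and sample SD; computed from `values` when omitted.
#' @return an object of class `scoring_scheme` with fields `M`, `S` and the
#'   11 bin `edges`.
#' @export
scoring_scheme <- function(values = NULL, M = NULL, S = NULL) {
  if (is.null(M) || is.null(S)) {
    v <- values[!is.na(values)]
    if (length(v) < 2) stop("need at least 2 values to fit a scoring scheme")
    M <- mean(v)
    S <- stats::sd(v)
  }
  if (is.na(S) || S < 0) stop("S must be a non-negative number")
  if (S == 0) stop("degenerate trait: S = 0, identical values cannot be scored")
  edges <- M - 2 * S + 0.5 * S * (0:8)   # interior edges for scores 1|2 .. 9|10
  structure(list(M = M, S = S, edges = c(-Inf, edges, Inf)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: M = %.4g, S = %.4g; score 1 below %.4g, 10 at/above %.4g\n",
              x$M, x$S, x$M - 2 * x$S, x$M + 2 * x$S))
  invisible(x)
}

#' Score quantitative values on the 1-10 scale
#'
#' Every value maps to exactly one score: `x < M - 2S` gives 1,
#' `x >= M + 2S` gives 10, and each half-`S` interval in between is
#' left-closed/right-open, so `x = M` falls in the score-6 bin.
#'
#' @param values numeric vector (`NA` passed through).
#' @param scheme a [scoring_scheme()].
#' @return integer scores 1-10.
#' @export
score_quantitative <- function(values, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  ## right-open bins: score k for x in [edge[k], edge[k+1])
  out[ok] <- findInterval(values[ok], scheme$edges[-c(1, 11)],
                          left.open = FALSE) + 1L
  out
}

#' Summary of one quantitative trait
#'
#' H' comes from the frequencies of the 1-10 scores (not raw values); Max,
#' Min, Range, Mean, sample SD and CV = SD/Mean x 100 come from the raw
#' values.
#'
#' @param values numeric trait values (missing dropped).
#' @param scheme a [scoring_scheme()], normally fitted on the data pooled
#'   over both populations; defaults to a scheme fitted on `values`.
#' @return a one-row data.frame: `h`, `cv`, `max`, `min`, `range`, `mean`,
#'   `sd`, `n`.
#' @export
quantitative_trait_summary <- function(values, scheme = NULL) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  if (is.null(scheme)) scheme <- scoring_scheme(values)
  scores <- score_quantitative(v, scheme)
  h <- shannon_index(category_frequencies(scores, n_categories = 10))
  m <- mean(v)
  if (m == 0) stop("mean is 0: CV undefined")
  s <- stats::sd(v)
  data.frame(h = h, cv = s / m * 100, max = max(v), min = min(v),
             range = max(v) - min(v), mean = m, sd = s, n = length(v))
}

#' Per-population phenotypic diversity tables
#'
#' Builds the two report tables for a trait table: qualitative traits
#' (per-category frequencies and H' per population) and quantitative traits
#' (H' from pooled-scale scores, CV, Max/Min/Range/Mean/SD per population).
#' Scoring schemes for quantitative traits are fitted on the aggregate data
#' pooled over all populations, so populations are scored on one scale.
#'
#' @param tt a [trait_table()].
#' @return list with data.frames `qualitative` (columns `trait`, `pop`,
#'   `h`, `freq.1` ... in percent) and `quantitative` (columns `trait`,
#'   `pop`, `h`, `cv`, `max`, `min`, `range`, `mean`, `sd`).
#' @export
pheno_diversity <- function(tt) {
  pops <- unique(tt$pop)
  qual_rows <- list()
  for (trait in names(tt$qualitative)) {
    k <- length(tt$dictionaries[[trait]])
    for (p in pops) {
      v <- tt$qualitative[[trait]][tt$pop == p]
      f <- category_frequencies(v, n_categories = k)
      row <- data.frame(trait = trait, pop = p, h = shannon_index(f),
                        stringsAsFactors = FALSE)
      for (j in seq_len(k)) row[[paste0("freq.", j)]] <- 100 * f[j]
      qual_rows[[length(qual_rows) + 1L]] <- row
    }
  }
  qualitative <- if (length(qual_rows)) {
    all_cols <- unique(unlist(lapply(qual_rows, names)))
    do.call(rbind, lapply(qual_rows, function(r) {
      for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA_real_
      r[all_cols]
    }))
  } else data.frame()
  quant_rows <- list()
  for (trait in names(tt$quantitative)) {
    scheme <- scoring_scheme(tt$quantitative[[trait]])  # pooled M, S
    for (p in pops) {
      v <- tt$quantitative[[trait]][tt$pop == p]
      s <- quantitative_trait_summary(v, scheme)
      quant_rows[[length(quant_rows) + 1L]] <-
        cbind(data.frame(trait = trait, pop = p, stringsAsFactors = FALSE), s)
    }
  }
  quantitative <- if (length(quant_rows)) do.call(rbind, quant_rows) else data.frame()
  rownames(qualitative) <- rownames(quantitative) <- NULL
  list(qualitative = qualitative, quantitative = quantitative)
}

#' Population difference table
#'
#' Per trait, the difference `A - B` in H' (and, for qualitative traits,
#' per-category frequency differences in percentage points) between two
#' populations' summaries as produced by [pheno_diversity()].
#'
#' @param summary_a,summary_b data.frames for populations A and B: matching
#'   rows of the `qualitative` or `quantitative` element of
#'   [pheno_diversity()] output (same traits, same category dictionaries).
#' @return data.frame with `trait`, `dh` (H' difference) and any
#'   `dfreq.<k>` columns.
#' @export
compare_populations <- function(summary_a, summary_b) {
  if (!identical(summary_a$trait, summary_b$trait))
    stop("summaries cover different traits: ",
         paste(union(setdiff(summary_a$trait, summary_b$trait),
                     setdiff(summary_b$trait, summary_a$trait)), collapse = ", "))
  fcols_a <- grep("^freq\\.", names(summary_a), value = TRUE)
  fcols_b <- grep("^freq\\.", names(summary_b), value = TRUE)
  if (!identical(fcols_a, fcols_b))
    stop("category dictionaries differ between populations: ",
         paste(union(setdiff(fcols_a, fcols_b), setdiff(fcols_b, fcols_a)),
               collapse = ", "))
  ## a category present in one population's dictionary but absent in the
  ## other surfaces as NA vs number
  mism <- vapply(fcols_a, function(cl)
    any(xor(is.na(summary_a[[cl]]), is.na(summary_b[[cl]]))), logical(1))
  if (any(mism))
    stop("category dictionaries differ between populations: ",
         paste(fcols_a[mism], collapse = ", "))
  out <- data.frame(trait = summary_a$trait, dh = summary_a$h - summary_b$h,
                    stringsAsFactors = FALSE)
  for (cl in fcols_a)
    out[[sub("^freq", "dfreq", cl)]] <- summary_a[[cl]] - summary_b[[cl]]
  out
}
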