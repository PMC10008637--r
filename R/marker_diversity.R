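#' Allele frequencies at one locus
#'
#' Frequencies are proportions over the `2 * n_obs` allele copies of the
#' accessions with a non-missing call at the locus.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name or column index.
#' @return list: `freq` (named numeric, names = allele codes, ascending,
#'   all > 0, summing to 1) and `n_obs` (accessions with a non-missing
#'   call).
#' @export
allele_frequencies <- function(gm, locus) {
  a1 <- gm$a1[, locus]; a2 <- gm$a2[, locus]
  ok <- !is.na(a1)
  if (!any(ok)) stop("empty locus '", locus, "': every call missing")
  copies <- c(a1[ok], a2[ok])
  counts <- table(copies)
  freq <- as.numeric(counts) / length(copies)
  names(freq) <- names(counts)          # ascending numeric order from table()
  list(freq = freq, n_obs = sum(ok))
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p allele frequency vector (non-negative, sums to ~1).
#' @return PIC in `[0, 1)`.
#' @export
pic_index <- function(p) {
  if (any(p < 0)) stop("negative allele frequency")
  s2 <- sum(p^2)
  ## sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Gene diversity (expected heterozygosity)
#'
#' Uncorrected `1 - sum(p^2)`; set `correct = TRUE` for the
#' `2n/(2n-1)`-style small-sample correction (off by default, matching
#' PowerMarker's report).
#'
#' @param p allele frequency vector.
#' @param n_obs number of genotyped accessions (only used when
#'   `correct = TRUE`).
#' @param correct apply the small-sample correction?
#' @return gene diversity in `[0, 1)`.
#' @export
gene_diversity <- function(p, n_obs = NULL, correct = FALSE) {
  if (any(p < 0)) stop("negative allele frequency")
  d <- 1 - sum(p^2)
  if (correct) {
    if (is.null(n_obs)) stop("n_obs required for the small-sample correction")
    nc <- 2 * n_obs
    d <- d * nc / (nc - 1)
  }
  d
}

#' Per-locus diversity summary (one reference-table row)
#'
#' The eight statistics reported per marker: major allele frequency,
#' number of distinct observed genotypes (unordered pairs, missing
#' excluded), sample size, number of genotyped accessions, allele count,
#' gene diversity `1 - sum(p^2)`, observed heterozygosity (fraction of
#' heterozygous calls among non-missing) and PIC. Major-allele ties are
#' broken by the smallest allele code.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name or column index.
#' @return one-row data.frame with columns `locus`, `major_allele_freq`,
#'   `genotype_no`, `sample_size`, `n_obs`, `allele_no`, `gene_diversity`,
#'   `heterozygosity`, `pic`.
#' @export
locus_summary <- function(gm, locus) {
  af <- allele_frequencies(gm, locus)
  p <- af$freq
  a1 <- gm$a1[, locus]; a2 <- gm$a2[, locus]
  ok <- !is.na(a1)
  genos <- unique(paste(a1[ok], a2[ok]))   # calls stored order-normalised
  het <- mean(a1[ok] != a2[ok])
  lname <- if (is.character(locus)) locus else locus_names(gm)[locus]
  data.frame(locus = lname,
             major_allele_freq = max(p),   # ties: max() keeps value; code order in names is ascending
             genotype_no = length(genos),
             sample_size = nrow(gm$a1),
             n_obs = af$n_obs,
             allele_no = length(p),
             gene_diversity = gene_diversity(p),
             heterozygosity = het,
             pic = pic_index(p),
             stringsAsFactors = FALSE)
}

#' Major allele (smallest code on frequency ties)
#' @param gm a [genotype_matrix()].
#' @param locus locus name or index.
#' @return integer allele code.
#' @export
major_allele <- function(gm, locus) {
  p <- allele_frequencies(gm, locus)$freq
  as.integer(names(p)[which.max(p)])     # names ascend, which.max takes first
}

#' Marker panel summary (reference-table layout)
#'
#' Per-locus rows plus a mean row and the total allele count, optionally
#' restricted to one population (the reference tables are computed
#' separately for LLR and CBL; allele frequencies are then computed within
#' that population only).
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label to restrict to, or `NULL` for all
#'   accessions.
#' @return list: `per_locus` (data.frame of [locus_summary()] rows),
#'   `means` (numeric vector of column means), `total_alleles`.
#' @export
summarize_panel <- function(gm, pop = NULL) {
  if (!is.null(pop)) gm <- subset_population(gm, pop)
  if (!ncol(gm$a1)) stop("genotype matrix has no loci")
  rows <- do.call(rbind, lapply(locus_names(gm), function(l) locus_summary(gm, l)))
  num <- rows[, -1]
  list(per_locus = rows,
       means = colMeans(num),
       total_alleles = sum(rows$allele_no))
}
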