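#' Cavalli-Sforza and Edwards chord distance between two individuals
#'
#' Each individual's single-locus profile is a within-individual allele
#' frequency vector with entries in {0, 0.5, 1}. Per shared locus the chord
#' distance is `(2/pi) * sqrt(2 * (1 - sum(sqrt(x * y))))`, and the overall
#' distance is the arithmetic mean over loci where both individuals are
#' genotyped. The theoretical maximum of the per-locus (and hence mean)
#' distance is `2 * sqrt(2) / pi ~ 0.9003`, matching the upper end of
#' distances reported for the pepper panels. `variant` isolates the
#' scaling: `"chord"` is the form above; `"angular"` drops the `2/pi`
#' prefactor.
#'
#' @param g1,g2 per-individual genotype profiles: 2-column matrices
#'   (or vectors of length `2 * n_loci`) of allele codes, `NA` = missing —
#'   normally rows of a [genotype_matrix()] via [distance_matrix()].
#' @param variant `"chord"` (default) or `"angular"`.
#' @return distance in `[0, 2 * sqrt(2) / pi]` (or `[0, sqrt(2)]` for
#'   `"angular"`).
#' @export
chord_distance <- function(g1, g2, variant = c("chord", "angular")) {
  variant <- match.arg(variant)
  g1 <- matrix(g1, ncol = 2); g2 <- matrix(g2, ncol = 2)
  if (nrow(g1) != nrow(g2)) stop("profiles cover different numbers of loci")
  shared <- !is.na(g1[, 1]) & !is.na(g2[, 1])
  if (!any(shared)) stop("incomparable pair: no shared non-missing locus")
  d <- vapply(which(shared), function(l) {
    chord_locus(g1[l, ], g2[l, ])
  }, numeric(1))
  mean(d) * chord_prefactor(variant)
}

## per-locus unscaled chord term sqrt(2 * (1 - sum(sqrt(x_a * y_a))))
chord_locus <- function(al1, al2) {
  alleles <- unique(c(al1, al2))
  x <- vapply(alleles, function(a) mean(al1 == a), numeric(1))
  y <- vapply(alleles, function(a) mean(al2 == a), numeric(1))
  s <- min(sum(sqrt(x * y)), 1)
  sqrt(2 * (1 - s))
}

chord_prefactor <- function(variant) if (variant == "chord") 2 / pi else 1

#' Pairwise chord-distance matrix
#'
#' All accession pairs of a genotype matrix, computed per locus from
#' within-individual allele frequencies and averaged over the loci shared
#' by each pair (pairwise deletion of missing calls; no imputation).
#'
#' @param gm a [genotype_matrix()].
#' @param variant scaling variant, see [chord_distance()].
#' @return list of class `chord_dist`: `d` (symmetric matrix, zero
#'   diagonal, labelled by accession id), `shared_loci` (per-pair counts)
#'   and `summary` (min/mean/max over the upper triangle).
#' @export
distance_matrix <- function(gm, variant = c("chord", "angular")) {
  variant <- match.arg(variant)
  n <- nrow(gm$a1)
  if (n < 2) stop("need at least 2 accessions")
  ids <- accession_ids(gm)
  acc <- matrix(0, n, n)      # sum of per-locus chord terms
  cnt <- matrix(0L, n, n)     # shared-locus counts
  for (l in seq_len(ncol(gm$a1))) {
    a1 <- gm$a1[, l]; a2 <- gm$a2[, l]
    ok <- which(!is.na(a1))
    if (length(ok) < 2) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    ## sqx[i, a] = sqrt(within-individual frequency of allele a in i)
    sqx <- matrix(0, length(ok), length(alleles))
    i1 <- match(a1[ok], alleles); i2 <- match(a2[ok], alleles)
    hom <- i1 == i2
    sqx[cbind(which(hom), i1[hom])] <- 1
    sqx[cbind(which(!hom), i1[!hom])] <- sqrt(0.5)
    sqx[cbind(which(!hom), i2[!hom])] <- sqrt(0.5)
    s <- tcrossprod(sqx)                 # sum_a sqrt(x_a y_a)
    dl <- sqrt(2 * pmax(1 - pmin(s, 1), 0))
    acc[ok, ok] <- acc[ok, ok] + dl
    cnt[ok, ok] <- cnt[ok, ok] + 1L
  }
  if (any(cnt[upper.tri(cnt)] == 0)) {
    bad <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)[1, ]
    stop("incomparable pair: '", ids[bad[1]], "' and '", ids[bad[2]],
         "' share no non-missing locus")
  }
  d <- acc / cnt * chord_prefactor(variant)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  ut <- d[upper.tri(d)]
  structure(list(d = d, shared_loci = cnt,
                 summary = c(min = min(ut), mean = mean(ut), max = max(ut)),
                 variant = variant),
            class = "chord_dist")
}

#' @export
print.chord_dist <- function(x, ...) {
  cat("chord_dist:", nrow(x$d), "accessions;",
      sprintf("distances %.3f-%.3f (mean %.3f), variant '%s'\n",
              x$summary["min"], x$summary["max"], x$summary["mean"], x$variant))
  invisible(x)
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "chord_dist")) dm <- dm$d
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(is.na(dm)))
    stop("distance matrix must be square without NAs")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  dm
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei NJ (via \pkg{ape}); negative branch lengths, an artefact of
#' the algorithm on non-additive matrices, are clamped to 0 and the total
#' clamped length recorded in attribute `"clamped"`.
#'
#' @param dm a [distance_matrix()] result, `dist` or symmetric matrix.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  m <- as_dist_matrix(dm)
  if (nrow(m) < 3) stop("need at least 3 taxa for NJ")
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  clamped <- sum(abs(tr$edge.length[neg]))
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the result is rooted and ultrametric
#' (every leaf at the same depth), node heights equal to half the merge
#' distances.
#'
#' @param dm a [distance_matrix()] result, `dist` or symmetric matrix.
#' @return a rooted ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(dm) {
  m <- as_dist_matrix(dm)
  if (nrow(m) < 2) stop("need at least 2 taxa")
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Write / read a tree in Newick format
#'
#' Branch lengths at 6 significant digits; labels with whitespace are
#' handled by \pkg{ape}'s Newick writer. Reading back gives a tree equal to
#' the written one up to rotation.
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return `path` ([write_newick()]) or an `ape::phylo` ([read_newick()]).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}

#' Write / read a square PHYLIP distance matrix
#' @param dm a [distance_matrix()] result or symmetric matrix.
#' @param path file path.
#' @return `path` / a symmetric labelled matrix.
#' @export
write_phylip <- function(dm, path) {
  m <- as_dist_matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[`, character(1), 1)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}
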