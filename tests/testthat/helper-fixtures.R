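# small builders and independent oracles shared across test files

# genotype matrix from per-locus call strings: list(locus = c("155/155", NA, ...))
make_gm <- function(calls, ids = NULL, pop = NULL) {
  loci <- names(calls)
  n <- length(calls[[1]])
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(ids, loci))
  a2 <- a1
  for (j in seq_along(loci)) {
    parts <- strsplit(calls[[j]], "/", fixed = TRUE)
    a1[, j] <- vapply(parts, function(p) if (length(p) == 2) as.integer(p[1]) else NA_integer_, 1L)
    a2[, j] <- vapply(parts, function(p) if (length(p) == 2) as.integer(p[2]) else NA_integer_, 1L)
  }
  genotype_matrix(a1, a2, pop = pop)
}

random_gm <- function(n, L, seed, missing_rate = 0.1, max_allele = 6) {
  set.seed(seed)
  codes <- 150L + 2L * seq_len(max_allele)
  a1 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  miss <- matrix(runif(n * L) < missing_rate, n, L)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  rownames(a1) <- rownames(a2) <- sprintf("s%03d", seq_len(n))
  colnames(a1) <- colnames(a2) <- sprintf("loc%02d", seq_len(L))
  genotype_matrix(a1, a2)
}

# brute-force allele-copy tally at one locus
oracle_allele_freq <- function(gm, locus) {
  copies <- integer(0)
  for (i in seq_len(nrow(gm$a1))) {
    if (!is.na(gm$a1[i, locus]))
      copies <- c(copies, gm$a1[i, locus], gm$a2[i, locus])
  }
  tab <- table(copies)
  setNames(as.numeric(tab) / length(copies), names(tab))
}

# Botstein PIC by explicit double loop
oracle_pic <- function(p) {
  k <- length(p)
  cross <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i)
    cross <- cross + 2 * p[i]^2 * p[j]^2
  1 - sum(p^2) - cross
}

# chord distance recomputed per pair from first principles
oracle_chord <- function(gm, i, j, variant = "chord") {
  terms <- c()
  for (l in seq_len(ncol(gm$a1))) {
    if (is.na(gm$a1[i, l]) || is.na(gm$a1[j, l])) next
    g1 <- c(gm$a1[i, l], gm$a2[i, l])
    g2 <- c(gm$a1[j, l], gm$a2[j, l])
    alleles <- union(g1, g2)
    x <- sapply(alleles, function(a) sum(g1 == a) / 2)
    y <- sapply(alleles, function(a) sum(g2 == a) / 2)
    terms <- c(terms, sqrt(2 * (1 - min(sum(sqrt(x * y)), 1))))
  }
  mean(terms) * (if (variant == "chord") 2 / pi else 1)
}

# Hardy-Weinberg locus: genotypes drawn as two independent copies
hw_gm <- function(p, n, seed) {
  set.seed(seed)
  codes <- 150L + 2L * seq_along(p)
  a1 <- matrix(sample(codes, n, replace = TRUE, prob = p), n, 1)
  a2 <- matrix(sample(codes, n, replace = TRUE, prob = p), n, 1)
  rownames(a1) <- rownames(a2) <- sprintf("s%04d", seq_len(n))
  colnames(a1) <- colnames(a2) <- "hw"
  genotype_matrix(a1, a2)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}
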