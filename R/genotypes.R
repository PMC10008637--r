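#' Diploid codominant genotype matrix
#'
#' Container for diploid SSR/InDel calls: one row per accession, one column
#' per locus, each call an unordered pair of positive integer allele codes
#' (typically fragment sizes in bp) or missing. Calls are stored
#' order-normalised (smaller code first) so genotype equality is insensitive
#' to allele order. Missing is `NA` for both copies; a half-missing call is
#' rejected.
#'
#' @param a1,a2 integer matrices (accession x locus) holding the two allele
#'   codes per call; `NA` in both marks a missing call. Row names are
#'   accession ids, column names are locus names.
#' @param pop character vector of population labels (e.g. `"LLR"`, `"CBL"`),
#'   one per accession, or `NULL`.
#' @param origin character vector of free-text origins, or `NULL`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `a1`, `a2` (normalised allele matrices), `pop`, `origin`.
#' @export
genotype_matrix <- function(a1, a2, pop = NULL, origin = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices `a1` and `a2` must have identical dimensions")
  if (is.null(rownames(a1)) && nrow(a1))
    rownames(a1) <- paste0("acc", seq_len(nrow(a1)))
  if (is.null(colnames(a1)) && ncol(a1))
    colnames(a1) <- paste0("locus", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  if (anyDuplicated(rownames(a1)))
    stop("duplicate accession id: ",
         paste(unique(rownames(a1)[duplicated(rownames(a1))]), collapse = ", "))
  if (anyDuplicated(colnames(a1)))
    stop("duplicate locus name: ",
         paste(unique(colnames(a1)[duplicated(colnames(a1))]), collapse = ", "))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing call at accession '", rownames(a1)[bad[1]],
         "', locus '", colnames(a1)[bad[2]], "': both allele codes or neither")
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers (missing is NA, never 0)")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  if (!is.null(pop)) {
    pop <- as.character(pop)
    if (length(pop) != nrow(a1))
      stop("`pop` must have one label per accession")
    if (any(is.na(pop) | !nzchar(pop)))
      stop("population labels must be non-empty")
  }
  if (!is.null(origin)) {
    origin <- as.character(origin)
    if (length(origin) != nrow(a1))
      stop("`origin` must have one entry per accession")
  }
  structure(list(a1 = a1, a2 = a2, pop = pop, origin = origin),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$a1), "accessions x", ncol(x$a1), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  if (!is.null(x$pop)) {
    tb <- table(x$pop)
    cat("  populations:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Accession ids and locus names of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return character vector.
#' @export
accession_ids <- function(gm) rownames(gm$a1)

#' @rdname accession_ids
#' @export
locus_names <- function(gm) colnames(gm$a1)

#' Subset a genotype matrix by accession and/or locus
#' @param x a [genotype_matrix()].
#' @param i accession index (ids, logical or integer).
#' @param j locus index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  if (is.character(i)) i <- match(i, rownames(x$a1))
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  pop = if (!is.null(x$pop)) x$pop[i],
                  origin = if (!is.null(x$origin)) x$origin[i])
}

#' Keep only the accessions of one population
#' @param gm a [genotype_matrix()].
#' @param pop population label to keep (e.g. `"LLR"`).
#' @return the subset [genotype_matrix()].
#' @export
subset_population <- function(gm, pop) {
  if (is.null(gm$pop)) stop("genotype matrix carries no population labels")
  keep <- gm$pop == pop
  if (!any(keep)) stop("no accessions with population label '", pop, "'")
  gm[keep, ]
}

## ---- readers / writers ----------------------------------------------------

#' Read a diploid genotype table
#'
#' Two dialects are supported. `"delimited"` is a CSV/TSV with a header row:
#' an `id` column, optional `pop` and `origin` columns, then one column per
#' locus whose cells are `"a/b"` allele pairs (empty or `NA` = missing), or
#' alternatively two columns per locus named `<locus>_1` / `<locus>_2`.
#' `"structure"` is the classic STRUCTURE layout: a first line of locus
#' names, then two rows per individual (`id [pop] allele...`) with `-9` as
#' the missing code.
#'
#' @param path file to read.
#' @param dialect `"delimited"` or `"structure"`.
#' @param sep field separator for the delimited dialect; guessed from the
#'   file extension (`.csv` = comma, otherwise tab) when `NULL`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("delimited", "structure"),
                           sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "delimited") {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            na.strings = c("NA", ""), quote = "\"",
                            comment.char = "")
    if (!"id" %in% names(df)) stop("delimited genotype file needs an 'id' column")
    ids <- df$id
    pop <- if ("pop" %in% names(df)) df$pop else NULL
    origin <- if ("origin" %in% names(df)) df$origin else NULL
    locus_cols <- setdiff(names(df), c("id", "pop", "origin"))
    if (!length(locus_cols)) {
      a1 <- matrix(NA_integer_, length(ids), 0, dimnames = list(ids, NULL))
      return(genotype_matrix(a1, a1, pop = pop, origin = origin))
    }
    two_col <- all(grepl("_[12]$", locus_cols))
    if (two_col) {
      loci <- unique(sub("_[12]$", "", locus_cols))
      need <- c(paste0(loci, "_1"), paste0(loci, "_2"))
      if (!all(need %in% locus_cols))
        stop("two-column layout: missing mate column for some locus")
      a1 <- sapply(paste0(loci, "_1"), function(cl) suppressWarnings(as.integer(df[[cl]])))
      a2 <- sapply(paste0(loci, "_2"), function(cl) suppressWarnings(as.integer(df[[cl]])))
      a1 <- matrix(a1, nrow = length(ids), dimnames = list(ids, loci))
      a2 <- matrix(a2, nrow = length(ids), dimnames = list(ids, loci))
    } else {
      parse_cell <- function(cell, locus, id) {
        if (is.na(cell)) return(c(NA_integer_, NA_integer_))
        parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
        if (length(parts) != 2)
          stop("malformed call '", cell, "' at accession '", id,
               "', locus '", locus, "': expected 'a/b'")
        v <- suppressWarnings(as.integer(parts))
        if (anyNA(v))
          stop("unknown allele token '", cell, "' at accession '", id,
               "', locus '", locus, "'")
        v
      }
      a1 <- matrix(NA_integer_, length(ids), length(locus_cols),
                   dimnames = list(ids, locus_cols))
      a2 <- a1
      for (l in locus_cols) {
        for (r in seq_along(ids)) {
          v <- parse_cell(df[[l]][r], l, ids[r])
          a1[r, l] <- v[1]
          a2[r, l] <- v[2]
        }
      }
    }
    return(genotype_matrix(a1, a2, pop = pop, origin = origin))
  }
  ## structure dialect
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("structure-format file too short")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) %% 2 != 0)
    stop("structure-format file: odd number of genotype rows (need 2 per individual)")
  nfield <- lengths(body)
  if (length(unique(nfield)) != 1)
    stop("structure-format file: ragged rows (row ",
         which(nfield != nfield[1])[1] + 1, ")")
  has_pop <- nfield[1] == length(loci) + 2
  if (!has_pop && nfield[1] != length(loci) + 1)
    stop("structure-format file: ", nfield[1], " fields per row but ",
         length(loci), " loci in header")
  n <- length(body) / 2
  ids <- character(n); pop <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (k in seq_len(n)) {
    r1 <- body[[2 * k - 1]]; r2 <- body[[2 * k]]
    if (r1[1] != r2[1])
      stop("structure-format file: row pair ", k, " has mismatched ids '",
           r1[1], "' / '", r2[1], "'")
    ids[k] <- r1[1]
    off <- if (has_pop) 2 else 1
    if (has_pop) pop[k] <- r1[2]
    v1 <- suppressWarnings(as.integer(r1[-seq_len(off)]))
    v2 <- suppressWarnings(as.integer(r2[-seq_len(off)]))
    if (anyNA(v1) || anyNA(v2))
      stop("structure-format file: non-integer allele token for individual '",
           ids[k], "'")
    v1[v1 == -9L] <- NA_integer_
    v2[v2 == -9L] <- NA_integer_
    ## a copy missing on one row only would be half-missing; treat the whole
    ## call as missing following STRUCTURE practice of -9/-9 pairs
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    a1[k, ] <- v1; a2[k, ] <- v2
  }
  rownames(a1) <- rownames(a2) <- ids
  genotype_matrix(a1, a2, pop = if (has_pop) pop else NULL)
}

#' Write a genotype matrix
#'
#' Deterministic output: accessions and loci are written in their stored
#' order, so the same matrix always produces byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"delimited"` (CSV/TSV of `"a/b"` cells) or `"structure"`
#'   (two rows per individual, `-9` missing).
#' @param sep field separator for the delimited dialect (default by
#'   extension, as in [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("delimited", "structure"),
                            sep = NULL) {
  dialect <- match.arg(dialect)
  ids <- accession_ids(gm)
  if (is.null(ids)) ids <- character(0)
  loci <- locus_names(gm)
  if (dialect == "delimited") {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    cells <- matrix("", length(ids), length(loci), dimnames = list(NULL, loci))
    if (length(ids) && length(loci)) {
      ok <- !is.na(gm$a1)
      cells[ok] <- paste0(gm$a1[ok], "/", gm$a2[ok])
      cells[!ok] <- "NA"
    }
    df <- data.frame(id = ids, stringsAsFactors = FALSE)
    if (!is.null(gm$pop)) df$pop <- gm$pop
    if (!is.null(gm$origin)) df$origin <- gm$origin
    df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(loci, collapse = "\t"), con)
    pop_int <- if (!is.null(gm$pop)) as.integer(factor(gm$pop, levels = unique(gm$pop)))
    for (k in seq_along(ids)) {
      v1 <- gm$a1[k, ]; v2 <- gm$a2[k, ]
      v1[is.na(v1)] <- -9L; v2[is.na(v2)] <- -9L
      lead <- if (is.null(pop_int)) ids[k] else paste(ids[k], pop_int[k], sep = "\t")
      writeLines(paste(lead, paste(v1, collapse = "\t"), sep = "\t"), con)
      writeLines(paste(lead, paste(v2, collapse = "\t"), sep = "\t"), con)
    }
  }
  invisible(path)
}

## ---- validation -----------------------------------------------------------

#' Cross-validate a genotype matrix and trait table
#'
#' Report-only consistency check: accession ids present in one table but not
#' the other, monomorphic loci, all-missing loci and all-missing traits.
#' Inputs are never modified.
#'
#' @param gm a [genotype_matrix()] (or `NULL`).
#' @param tt a [trait_table()] (or `NULL`).
#' @return a data.frame with columns `type`, `item`, `message`; zero rows
#'   when the dataset is consistent.
#' @export
validate_dataset <- function(gm = NULL, tt = NULL) {
  issues <- data.frame(type = character(), item = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(type, item, message)
    rbind(issues, data.frame(type = type, item = item, message = message,
                             stringsAsFactors = FALSE))
  if (!is.null(gm)) {
    for (l in locus_names(gm)) {
      calls1 <- gm$a1[, l]; calls2 <- gm$a2[, l]
      if (all(is.na(calls1))) {
        issues <- add("all_missing_locus", l, "every call missing")
      } else if (length(unique(c(calls1[!is.na(calls1)], calls2[!is.na(calls2)]))) == 1L) {
        issues <- add("monomorphic_locus", l, "single allele observed")
      }
    }
  }
  if (!is.null(gm) && !is.null(tt)) {
    g_ids <- accession_ids(gm)
    t_ids <- tt$id
    for (i in setdiff(t_ids, g_ids))
      issues <- add("unmatched_accession", i, "in trait table but not genotype matrix")
    for (i in setdiff(g_ids, t_ids))
      issues <- add("unmatched_accession", i, "in genotype matrix but not trait table")
  }
  if (!is.null(tt)) {
    all_na <- function(x) all(is.na(x))
    for (nm in names(tt$qualitative))
      if (all_na(tt$qualitative[[nm]]))
        issues <- add("all_missing_trait", nm, "qualitative trait entirely missing")
    for (nm in names(tt$quantitative))
      if (all_na(tt$quantitative[[nm]]))
        issues <- add("all_missing_trait", nm, "quantitative trait entirely missing")
  }
  issues
}
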