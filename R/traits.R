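#' Phenotype trait table
#'
#' Holds qualitative traits (small-integer category codes, with a per-trait
#' category dictionary) and quantitative traits (numeric, in trait units)
#' for a set of accessions, together with their population labels.
#'
#' @param id character vector of accession ids (unique).
#' @param pop character vector of population labels, one per accession.
#' @param qualitative data.frame of integer category codes (one column per
#'   trait, `NA` = missing), or `NULL`.
#' @param quantitative data.frame of numeric values (one column per trait,
#'   `NA` = missing), or `NULL`.
#' @param dictionaries named list: for each qualitative trait, a character
#'   vector of category names indexed by code. Built from the observed codes
#'   when omitted.
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(id, pop, qualitative = NULL, quantitative = NULL,
                        dictionaries = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate accession id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  pop <- as.character(pop)
  if (length(pop) != length(id)) stop("`pop` must have one label per accession")
  if (any(is.na(pop) | !nzchar(pop))) stop("population labels must be non-empty")
  qualitative <- if (is.null(qualitative)) {
    data.frame(row.names = id)
  } else {
    as.data.frame(qualitative, row.names = id)
  }
  for (nm in names(qualitative)) {
    v <- qualitative[[nm]]
    if (!all(is.na(v) | (v == as.integer(v) & v >= 1)))
      stop("qualitative trait '", nm, "' must hold positive integer codes")
    qualitative[[nm]] <- as.integer(v)
  }
  quantitative <- if (is.null(quantitative)) {
    data.frame(row.names = id)
  } else {
    as.data.frame(quantitative, row.names = id)
  }
  for (nm in names(quantitative)) {
    v <- as.numeric(quantitative[[nm]])
    if (any(!is.na(v) & !is.finite(v)))
      stop("quantitative trait '", nm, "' has non-finite values")
    quantitative[[nm]] <- v
  }
  if (is.null(dictionaries)) {
    dictionaries <- lapply(qualitative, function(v) {
      k <- max(c(v, 0L), na.rm = TRUE)
      as.character(seq_len(k))
    })
  }
  for (nm in names(qualitative)) {
    v <- qualitative[[nm]]
    dict <- dictionaries[[nm]]
    if (is.null(dict))
      stop("no category dictionary for qualitative trait '", nm, "'")
    if (any(!is.na(v) & v > length(dict)))
      stop("qualitative trait '", nm, "' has codes outside its dictionary")
  }
  structure(list(id = id, pop = pop, qualitative = qualitative,
                 quantitative = quantitative, dictionaries = dictionaries),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$id), "accessions,",
      ncol(x$qualitative), "qualitative +",
      ncol(x$quantitative), "quantitative traits\n")
  tb <- table(x$pop)
  cat("  populations:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a trait table
#'
#' CSV/TSV with header: `id`, `pop`, then one column per trait. Qualitative
#' trait columns are named `q_<trait>` (integer codes); all other columns
#' are treated as quantitative.
#'
#' @param path file path.
#' @param sep separator; guessed from the extension when `NULL`.
#' @return [read_traits()]: a [trait_table()]. [write_traits()]: `path`.
#' @export
read_traits <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!all(c("id", "pop") %in% names(df)))
    stop("trait file needs 'id' and 'pop' columns")
  traits <- setdiff(names(df), c("id", "pop"))
  qual <- traits[startsWith(traits, "q_")]
  quant <- setdiff(traits, qual)
  qualitative <- if (length(qual)) {
    q <- df[qual]
    names(q) <- sub("^q_", "", qual)
    q
  }
  trait_table(df$id, df$pop,
              qualitative = qualitative,
              quantitative = if (length(quant)) df[quant])
}

#' @rdname read_traits
#' @param tt a [trait_table()].
#' @export
write_traits <- function(tt, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = tt$id, pop = tt$pop, stringsAsFactors = FALSE)
  for (nm in names(tt$qualitative)) df[[paste0("q_", nm)]] <- tt$qualitative[[nm]]
  for (nm in names(tt$quantitative)) df[[nm]] <- tt$quantitative[[nm]]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only the accessions of one population
#' @param tt a [trait_table()].
#' @param pop population label to keep.
#' @return the subset [trait_table()].
#' @export
subset_traits <- function(tt, pop) {
  keep <- tt$pop == pop
  if (!any(keep)) stop("no accessions with population label '", pop, "'")
  trait_table(tt$id[keep], tt$pop[keep],
              qualitative = tt$qualitative[keep, , drop = FALSE],
              quantitative = tt$quantitative[keep, , drop = FALSE],
              dictionaries = tt$dictionaries)
}
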