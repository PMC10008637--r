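#' Published reference summary tables for the pepper panels
#'
#' Summary statistics published for the two pepper germplasm panels the
#' package targets — 94 local landraces (LLR) and 85 current breeding
#' lines (CBL) — shipped as plain CSV. They serve as worked-example inputs:
#' the qualitative table carries per-category frequencies (percent) and
#' the printed Shannon index per trait and population; the quantitative
#' table carries H', CV and Max/Min/Range/Mean/SD per trait and
#' population; the marker tables carry the eight per-locus diversity
#' statistics for the 27 SSR/InDel loci of each panel.
#'
#' @param name one of `"qualitative"`, `"quantitative"`, `"marker_llr"`,
#'   `"marker_cbl"`.
#' @return a data.frame.
#' @export
reference_table <- function(name = c("qualitative", "quantitative",
                                     "marker_llr", "marker_cbl")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("table_", name, ".csv"),
                      package = "pepperdiv", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
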