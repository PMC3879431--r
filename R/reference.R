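#' Published functional-category counts of the reference study
#'
#' Loads the bundled category x class count table reported by the
#' reference A. thaliana repeated-dehydration study: gene counts per
#' functional category for the eight responding classes (class sizes
#' 362/310/857/434 memory, 2177/2439 non-memory, 798/573 late
#' response). Useful for sanity-checking percentage formatting and for
#' arithmetic on the published class partition without any raw data.
#'
#' @return A list: `counts` (category x class integer matrix) and
#'   `class_totals` (named vector over the eight responding classes).
#' @export
#' @examples
#' ref <- reference_go_table()
#' format_percent(ref$counts["Chloroplast", "MM"], ref$class_totals["MM"])
reference_go_table <- function() {
  path <- system.file("extdata", "reference_go_counts.tsv",
                      package = "stressmem", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$category
  totals <- reference_class_counts()
  list(counts = m,
       class_totals = totals[setdiff(memory_classes(), "NR")])
}
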