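#' Combine two sign calls into a response class
#'
#' Deterministic total function over the 3x3 sign grid. The first call
#' is the S1-vs-W response, the second the S3-vs-S1 response:
#' `("+","+") -> PP`, `("-","-") -> MM`, `("+","-") -> PM`,
#' `("-","+") -> MP` (memory); `("+","=") -> PE`, `("-","=") -> ME`
#' (non-memory); `("=","+") -> EP`, `("=","-") -> EM` (late response);
#' `("=","=") -> NR`.
#'
#' @param sign_s1w,sign_s3s1 Character vectors with values in
#'   `{"+", "-", "="}`.
#' @return Character vector of class codes (see [memory_classes()]).
#' @export
#' @examples
#' classify_gene("+", "+")  # "PP"
#' classify_gene("-", "+")  # "MP"
classify_gene <- function(sign_s1w, sign_s3s1) {
  stopifnot(length(sign_s1w) == length(sign_s3s1))
  ok <- c("+", "-", "=")
  if (any(!sign_s1w %in% ok) || any(!sign_s3s1 %in% ok))
    stop("sign calls must be one of '+', '-', '='")
  lut <- c("+|+" = "PP", "-|-" = "MM", "+|-" = "PM", "-|+" = "MP",
           "+|=" = "PE", "-|=" = "ME", "=|+" = "EP", "=|-" = "EM",
           "=|=" = "NR")
  unname(lut[paste(sign_s1w, sign_s3s1, sep = "|")])
}

#' Classify every gene of a master table
#'
#' Applies the three-criterion significance gate to both contrasts and
#' assigns the nine-class response typology. Each contrast gets its own
#' expression floor: the `floor_percentile`-th percentile of the FPKM
#' values of its two samples pooled across all genes. Fold changes are
#' taken from the `lfc_*` columns when present, otherwise recomputed
#' from FPKM with the pseudocount. q-values are taken from `q_*` columns
#' when present, otherwise derived from replicate columns via
#' [simple_de_test()] + [bh_adjust()]. Genes with missing contrast data
#' are classified `NR` (never dropped) and counted in a warning.
#'
#' @param master A `master_table` data.frame (see [read_master_table()]).
#' @param thresholds A [gate_thresholds()] object.
#' @return The input with added columns `sign_s1w`, `sign_s3s1`,
#'   `memory_class`; class `classified_table`. Attributes `floor_s1w`
#'   and `floor_s3s1` record the floors used.
#' @export
classify_table <- function(master, thresholds = gate_thresholds()) {
  validate_master_table(master)
  df <- as.data.frame(master)
  p <- thresholds$floor_percentile / 100

  lfc1 <- column_or_lfc(df, "lfc_s1w", "fpkm_w", "fpkm_s1", thresholds$epsilon)
  lfc2 <- column_or_lfc(df, "lfc_s3s1", "fpkm_s1", "fpkm_s3", thresholds$epsilon)
  q1 <- column_or_q(df, "q_s1w", "w", "s1", thresholds$epsilon)
  q2 <- column_or_q(df, "q_s3s1", "s1", "s3", thresholds$epsilon)

  floor1 <- expression_floor(c(df$fpkm_w, df$fpkm_s1), p)
  floor2 <- expression_floor(c(df$fpkm_s1, df$fpkm_s3), p)

  sign1 <- call_significance(lfc1, q1, df$fpkm_w, df$fpkm_s1, floor1, thresholds)
  sign2 <- call_significance(lfc2, q2, df$fpkm_s1, df$fpkm_s3, floor2, thresholds)

  df$sign_s1w <- sign1
  df$sign_s3s1 <- sign2
  df$memory_class <- classify_gene(sign1, sign2)
  attr(df, "floor_s1w") <- floor1
  attr(df, "floor_s3s1") <- floor2
  attr(df, "thresholds") <- thresholds
  class(df) <- c("classified_table", "data.frame")
  df
}

# lfc column if present, else recomputed from the two FPKM columns
column_or_lfc <- function(df, col, a, b, epsilon) {
  if (col %in% names(df) && !all(is.na(df[[col]]))) return(df[[col]])
  compute_log2fc(df[[a]], df[[b]], epsilon)
}

# q column if present, else Welch test on replicate columns + BH; NA if
# neither is available (gene can then never be significant).
column_or_q <- function(df, col, cond_a, cond_b, epsilon) {
  if (col %in% names(df)) return(df[[col]])
  reps_a <- grep(sprintf("^fpkm_%s_rep[0-9]+$", cond_a), names(df), value = TRUE)
  reps_b <- grep(sprintf("^fpkm_%s_rep[0-9]+$", cond_b), names(df), value = TRUE)
  if (length(reps_a) < 2L || length(reps_b) < 2L)
    return(rep(NA_real_, nrow(df)))
  a <- as.matrix(df[, reps_a, drop = FALSE])
  b <- as.matrix(df[, reps_b, drop = FALSE])
  pvals <- vapply(seq_len(nrow(df)), function(i)
    simple_de_test(a[i, ], b[i, ], epsilon), numeric(1))
  bh_adjust(pvals)
}

#' Summarize a classified table into per-class counts and totals
#'
#' Produces the study-style summary: counts for each of the nine classes
#' plus the derived totals — dehydration-responsive genes (S1-vs-W call
#' not `"="`), responsive up/down, memory genes (both calls not `"="`)
#' with their up/down split by S1 direction, non-memory genes, and
#' late-response genes. The partition invariants (classes sum to the
#' gene count; responsive = memory + non-memory; memory up + down =
#' memory) are asserted before returning.
#'
#' @param classified A `classified_table` from [classify_table()], or
#'   any data.frame with a `memory_class` column.
#' @return A list of class `class_summary`: `counts` (named integer
#'   vector over [memory_classes()]), `total_genes`,
#'   `dehydration_responsive`, `responsive_up`, `responsive_down`,
#'   `memory_total`, `memory_up`, `memory_down`, `nonmemory_total`,
#'   `late_total`, `nonresponsive_remainder`.
#' @export
summarize_classes <- function(classified) {
  stopifnot("memory_class" %in% names(classified))
  cls <- factor(classified$memory_class, levels = memory_classes())
  if (anyNA(cls)) stop("unknown memory_class code in input")
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))

  s <- list(
    counts = counts,
    total_genes = sum(counts),
    dehydration_responsive = sum(counts[c("PP", "MM", "PM", "MP", "PE", "ME")]),
    responsive_up = sum(counts[c("PP", "PM", "PE")]),
    responsive_down = sum(counts[c("MM", "MP", "ME")]),
    memory_total = sum(counts[c("PP", "MM", "PM", "MP")]),
    memory_up = sum(counts[c("PP", "PM")]),
    memory_down = sum(counts[c("MM", "MP")]),
    nonmemory_total = sum(counts[c("PE", "ME")]),
    late_total = sum(counts[c("EP", "EM")])
  )
  s$nonresponsive_remainder <- s$dehydration_responsive - s$memory_total

  stopifnot(
    s$memory_total == s$counts[["PP"]] + s$counts[["MM"]] +
      s$counts[["PM"]] + s$counts[["MP"]],
    s$dehydration_responsive == s$memory_total + s$nonmemory_total,
    s$memory_up + s$memory_down == s$memory_total,
    s$responsive_up + s$responsive_down == s$dehydration_responsive,
    sum(s$counts) == nrow(classified)
  )
  structure(s, class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  lab <- class_labels()
  cat(sprintf("Total genes              %8d\n", x$total_genes))
  cat(sprintf("Dehydration response     %8d  (up %d, down %d)\n",
              x$dehydration_responsive, x$responsive_up, x$responsive_down))
  cat(sprintf("Memory genes             %8d  (up %d, down %d)\n",
              x$memory_total, x$memory_up, x$memory_down))
  for (k in c("PP", "MM", "PM", "MP"))
    cat(sprintf("  %s %30d\n", lab[[k]], x$counts[[k]]))
  cat("Non-memory genes\n")
  for (k in c("PE", "ME"))
    cat(sprintf("  %s %30d\n", lab[[k]], x$counts[[k]]))
  cat("Late-response genes\n")
  for (k in c("EP", "EM"))
    cat(sprintf("  %s %30d\n", lab[[k]], x$counts[[k]]))
  cat(sprintf("Non-responsive           %8d\n", x$counts[["NR"]]))
  invisible(x)
}

#' Convert a class summary to a tidy data frame
#'
#' @param x A `class_summary`.
#' @param ... Unused.
#' @return A data.frame with columns `class`, `label`, `count`.
#' @export
as.data.frame.class_summary <- function(x, ...) {
  data.frame(class = names(x$counts),
             label = unname(class_labels()[names(x$counts)]),
             count = unname(x$counts),
             stringsAsFactors = FALSE)
}

#' Scatter coordinates of S1-responding genes
#'
#' For every gene whose S1-vs-W call is significant, emits the
#' coordinates used to visualise the memory-class structure:
#' `x = log2(fpkm_s1 + epsilon)`, `y1 = log2` fold change of S1 over W,
#' and `y3 = log2` fold change of S3 over W (both with the same
#' pseudocount). Plotting `y1` and `y3` against `x` shows revised-
#' response memory genes returning toward pre-stress levels while
#' `[+/+]` and `[-/-]` genes separate further.
#'
#' @param classified A `classified_table`.
#' @param epsilon FPKM pseudocount.
#' @return A data.frame: `gene_id`, `memory_class`, `x`, `y1`, `y3`.
#' @export
figure_coordinates <- function(classified, epsilon = 0.05) {
  stopifnot(all(c("sign_s1w", "memory_class") %in% names(classified)))
  keep <- classified$sign_s1w != "="
  df <- classified[keep, , drop = FALSE]
  data.frame(
    gene_id = df$gene_id,
    memory_class = df$memory_class,
    x = log2(df$fpkm_s1 + epsilon),
    y1 = compute_log2fc(df$fpkm_w, df$fpkm_s1, epsilon),
    y3 = compute_log2fc(df$fpkm_w, df$fpkm_s3, epsilon),
    stringsAsFactors = FALSE
  )
}
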