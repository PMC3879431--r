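#' Integer percentage with round-half-up
#'
#' Formats a count as an integer percentage of its class total using
#' round-half-up (so 24.5 -> 25), the convention that reproduces the
#' reference study's printed category percentages (75/310 -> 24,
#' 53/310 -> 17, 121/857 -> 14).
#'
#' @param count Nonnegative count (vectorised).
#' @param class_total Positive class size (vectorised or scalar).
#' @return Integer percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' format_percent(75, 310)  # 24
format_percent <- function(count, class_total) {
  if (any(class_total == 0)) stop("class_total must be positive")
  if (any(count < 0 | count > class_total))
    stop("count must lie in [0, class_total]")
  as.integer(floor(100 * count / class_total + 0.5))
}

#' Cross-tabulate response classes against functional categories
#'
#' Counts, for every (category, class) pair, the genes of that class
#' carrying that category, and expresses each cell as an integer
#' percentage of the class total. A gene with several categories is
#' counted once per category, so category rows may overlap and columns
#' need not sum to the class total. Annotated genes absent from the
#' classified table are ignored with a message.
#'
#' @param classified A `classified_table` (needs `gene_id`,
#'   `memory_class`).
#' @param ann An `annotation_map` (`gene_id`, `category`).
#' @param categories Category row order; defaults to the categories
#'   present in `ann`, sorted.
#' @return A list of class `category_crosstab`: `counts` and `percent`
#'   (category x class matrices over [memory_classes()]),
#'   `class_totals` (named vector).
#' @export
crosstab <- function(classified, ann, categories = NULL) {
  stopifnot(all(c("gene_id", "memory_class") %in% names(classified)),
            all(c("gene_id", "category") %in% names(ann)))
  if (is.null(categories)) categories <- sort(unique(ann$category))
  if (length(categories) == 0L)
    stop("no categories to tabulate")
  cls_levels <- memory_classes()
  class_totals <- table(factor(classified$memory_class, levels = cls_levels))
  class_totals <- stats::setNames(as.integer(class_totals), cls_levels)

  unknown <- !(ann$gene_id %in% classified$gene_id)
  if (any(unknown)) {
    message(sum(unknown), " annotated gene(s) absent from the classified ",
            "table; ignored")
    ann <- ann[!unknown, , drop = FALSE]
  }
  gene_class <- stats::setNames(classified$memory_class, classified$gene_id)
  tab <- table(factor(ann$category, levels = categories),
               factor(gene_class[ann$gene_id], levels = cls_levels))
  counts <- matrix(as.integer(tab), nrow = length(categories),
                   dimnames = list(categories, cls_levels))
  percent <- counts
  for (cl in cls_levels) {
    percent[, cl] <- if (class_totals[[cl]] > 0)
      format_percent(counts[, cl], class_totals[[cl]])
    else 0L
  }
  structure(list(counts = counts, percent = percent,
                 class_totals = class_totals),
            class = "category_crosstab")
}

#' @export
print.category_crosstab <- function(x, ...) {
  cat("Category x class cross-tabulation (count (pct%)):\n")
  print(format_crosstab(x))
  invisible(x)
}

#' Format a crosstab as "count (pct%)" cells
#'
#' @param x A `category_crosstab`.
#' @return Character matrix in the published table dialect.
#' @export
format_crosstab <- function(x) {
  stopifnot(inherits(x, "category_crosstab"))
  out <- matrix(sprintf("%d (%d%%)", x$counts, x$percent),
                nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  out
}

#' Tidy long form of a crosstab
#'
#' @param x A `category_crosstab`.
#' @param ... Unused.
#' @return A data.frame: `category`, `class`, `count`, `class_total`,
#'   `percent`.
#' @export
as.data.frame.category_crosstab <- function(x, ...) {
  cats <- rownames(x$counts)
  cls <- colnames(x$counts)
  data.frame(
    category = rep(cats, times = length(cls)),
    class = rep(cls, each = length(cats)),
    count = as.integer(x$counts),
    class_total = rep(unname(x$class_totals[cls]), each = length(cats)),
    percent = as.integer(x$percent),
    stringsAsFactors = FALSE
  )
}

#' Venn memberships of 2-3 response classes within a category
#'
#' Restricts each requested class to the genes carrying a functional
#' category (or all its genes for `category = "ALL"`) and computes every
#' Venn region size by inclusion-exclusion. Because the nine classes
#' partition the genes, inter-class intersections are empty whenever the
#' inputs are classes of one classified table — the informative use is
#' comparing category composition across classes.
#'
#' @param classified A `classified_table`.
#' @param ann An `annotation_map`; may be `NULL` when `category =
#'   "ALL"`.
#' @param category A single category label, or `"ALL"`.
#' @param classes Character vector of 2 or 3 distinct class codes.
#' @return A list of class `venn_sets`: `sets` (named list of gene-id
#'   vectors) and `regions` (named integer vector of exclusive region
#'   sizes, e.g. `"A"`, `"A&B"`, `"A&B&C"`).
#' @export
venn_sets <- function(classified, ann = NULL, category = "ALL", classes) {
  if (length(classes) < 2L || length(classes) > 3L)
    stop("venn_sets supports 2 or 3 classes")
  if (anyDuplicated(classes)) stop("classes must be distinct")
  bad <- setdiff(classes, memory_classes())
  if (length(bad) > 0L) stop("unknown class code(s): ",
                             paste(bad, collapse = ", "))
  in_cat <- if (identical(category, "ALL")) {
    classified$gene_id
  } else {
    if (is.null(ann)) stop("annotation map required for category != 'ALL'")
    ann$gene_id[ann$category == category]
  }
  sets <- lapply(classes, function(cl)
    intersect(classified$gene_id[classified$memory_class == cl], in_cat))
  names(sets) <- classes

  regions <- integer(0)
  k <- length(sets)
  for (size in seq_len(k)) {
    for (combo in utils::combn(seq_len(k), size, simplify = FALSE)) {
      inside <- Reduce(intersect, sets[combo])
      outside <- unlist(sets[setdiff(seq_len(k), combo)], use.names = FALSE)
      regions[[paste(classes[combo], collapse = "&")]] <-
        length(setdiff(inside, outside))
    }
  }
  structure(list(sets = sets, regions = regions, category = category),
            class = "venn_sets")
}

#' @export
print.venn_sets <- function(x, ...) {
  cat(sprintf("Venn memberships (category: %s)\n", x$category))
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %d\n", nm, x$regions[[nm]]))
  invisible(x)
}
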