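# Canonical TSV dialects. All readers skip provenance comment lines
# beginning with '#', accept gzip transparently (base connections), and
# use the C locale decimal point.

master_mandatory_cols <- c("gene_id", "fpkm_w", "fpkm_s1", "fpkm_s3")
master_stat_cols <- c("lfc_s1w", "q_s1w", "lfc_s3s1", "q_s3s1")

#' Read a master expression table
#'
#' Reads the tab-separated per-gene master table combining FPKM-scale
#' expression for the watered (W), first-stress (S1) and third-stress
#' (S3) samples with the statistics of the two contrasts. Mandatory
#' columns: `gene_id`, `fpkm_w`, `fpkm_s1`, `fpkm_s3`. Optional:
#' per-replicate columns `fpkm_<cond>_rep<k>`, and per-contrast
#' statistics `lfc_s1w`, `q_s1w`, `lfc_s3s1`, `q_s3s1` (recomputable /
#' derivable from replicates). Missing values are encoded `NA`; a gene
#' with missing q in a contrast can never be called significant there.
#'
#' @param path Path to a TSV file (plain or gzip).
#' @param quiet Suppress the row-count message.
#' @return A `data.frame` of class `master_table`.
#' @export
read_master_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("master table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  validate_master_table(df, context = path)
  if (!quiet) {
    missing_q <- setdiff(c("q_s1w", "q_s3s1"), names(df))
    message(sprintf("read %d genes from %s", nrow(df), path))
    if (length(missing_q) > 0L)
      message("q columns absent (", paste(missing_q, collapse = ", "),
              "): significance requires simple_de_test on replicate columns")
  }
  class(df) <- c("master_table", "data.frame")
  df
}

validate_master_table <- function(df, context = "master table") {
  missing <- setdiff(master_mandatory_cols, names(df))
  if (length(missing) > 0L)
    stop(context, ": missing mandatory column(s) ",
         paste(missing, collapse = ", "),
         "; expected header starts: ",
         paste(master_mandatory_cols, collapse = ", "))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L)
    stop(context, ": duplicate gene_id ", paste(unique(dup), collapse = ", "))
  fpkm_cols <- grep("^fpkm_", names(df), value = TRUE)
  for (col in fpkm_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0L)
      stop(context, ": negative FPKM in column ", col, " at row ", bad[1L])
  }
  for (col in intersect(c("q_s1w", "q_s3s1"), names(df))) {
    bad <- which(df[[col]] < 0 | df[[col]] > 1)
    if (length(bad) > 0L)
      stop(context, ": q-value outside [0, 1] in column ", col,
           " at row ", bad[1L])
  }
  # consistency of per-sample means with replicate columns, when present
  for (cond in c("w", "s1", "s3")) {
    reps <- grep(sprintf("^fpkm_%s_rep[0-9]+$", cond), names(df), value = TRUE)
    if (length(reps) > 0L) {
      m <- rowMeans(as.matrix(df[, reps, drop = FALSE]))
      ref <- df[[paste0("fpkm_", cond)]]
      rel <- abs(m - ref) / pmax(abs(ref), 1e-12)
      if (any(rel > 1e-6 & abs(m - ref) > 1e-9, na.rm = TRUE))
        stop(context, ": per-sample mean fpkm_", cond,
             " disagrees with its replicate mean")
    }
  }
  invisible(df)
}

#' Write a master expression table
#'
#' Writes the canonical TSV dialect; [read_master_table()] on the result
#' round-trips the table (floating values kept to full precision via
#' exact decimal formatting of R doubles).
#'
#' @param table A `master_table` data.frame.
#' @param path Output path.
#' @param provenance Optional character vector written as leading
#'   `#`-comment lines.
#' @return The path, invisibly.
#' @export
write_master_table <- function(table, path, provenance = NULL) {
  validate_master_table(table)
  write_tsv(table, path, provenance)
}

write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance) > 0L)
    writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a gene-to-category annotation map
#'
#' Two-column TSV (`gene_id <TAB> category`, header optional but
#' recommended). Duplicate (gene, category) pairs collapse to one;
#' a gene may carry any number of categories, including zero.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `annotation_map` with columns
#'   `gene_id`, `category` (unique pairs).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_annotation())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("annotation file ", path, ": expected two tab-separated columns")
  df <- data.frame(gene_id = vapply(parts, `[[`, "", 1L),
                   category = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$gene_id[1L]), "gene_id"))
    df <- df[-1L, , drop = FALSE]
  if (any(!nzchar(df$category)))
    stop("annotation file ", path, ": empty category label")
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("annotation_map", "data.frame")
  df
}

empty_annotation <- function() {
  df <- data.frame(gene_id = character(0), category = character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_map", "data.frame")
  df
}

#' Write a gene-to-category annotation map
#'
#' @param ann An `annotation_map` data.frame (`gene_id`, `category`).
#' @param path Output path.
#' @param provenance Optional `#`-comment header lines.
#' @return The path, invisibly.
#' @export
write_annotation <- function(ann, path, provenance = NULL) {
  stopifnot(all(c("gene_id", "category") %in% names(ann)))
  write_tsv(ann[, c("gene_id", "category")], path, provenance)
}

#' Read a binary annotation matrix
#'
#' TSV with a `gene_id` first column and one column per pathway or
#' annotation label; entries must be 0 (absence) or 1 (presence).
#' Used for the transcription-factor pathway-membership matrices that
#' feed bidirectional UPGMA clustering.
#'
#' @param path Path to the TSV.
#' @return An integer matrix with gene row names and pathway column
#'   names, entries in `{0, 1}`.
#' @export
read_binary_matrix <- function(path) {
  if (!file.exists(path)) stop("binary matrix file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L)
    stop("binary matrix ", path, ": expected gene_id plus >= 1 label column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("binary matrix ", path, ": duplicate row id ",
         ids[duplicated(ids)][1L])
  if (anyDuplicated(names(df)[-1L]))
    stop("binary matrix ", path, ": duplicate column label")
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("binary matrix %s: non-binary entry %s at (row %d, col %d)",
                 path, m[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a binary annotation matrix
#'
#' @param m Binary matrix with row and column names.
#' @param path Output path.
#' @param provenance Optional `#`-comment header lines.
#' @return The path, invisibly.
#' @export
write_binary_matrix <- function(m, path, provenance = NULL) {
  stopifnot(is.matrix(m), all(m == 0 | m == 1),
            !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, provenance)
}
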