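#' Run the full classification pipeline and write a report bundle
#'
#' Orchestrates the stages end to end: read (or simulate) a master
#' table, apply the three-criterion gate and nine-class typology, write
#' the classified table and class summary, and — when the inputs are
#' available — the category cross-tabulation, Venn region tables,
#' bidirectional TF clustering outputs and a replicate-QC report. Every
#' output is TSV with a provenance header (`#` lines) recording the
#' thresholds, seed and package version, so identical configurations
#' produce byte-identical bundles.
#'
#' @param master A `master_table`, a path to one, or `NULL` to simulate
#'   from `sim`.
#' @param annotation Optional `annotation_map` or path.
#' @param tf_matrix Optional binary matrix or path.
#' @param out_dir Output directory (created if absent).
#' @param thresholds A [gate_thresholds()] object.
#' @param sim A [sim_config()] used when `master` is `NULL`; its `seed`
#'   is the pipeline seed.
#' @param venn_classes Optional list of 2-3-class code vectors for Venn
#'   tables (default: the up-in-S1 and down-in-S1 triples).
#' @return Invisibly, a list: `classified`, `summary`, `crosstab`,
#'   `venn`, `clustering`, `qc`, `files` (paths written).
#' @export
run_pipeline <- function(master = NULL, annotation = NULL,
                         tf_matrix = NULL, out_dir = "stressmem_out",
                         thresholds = gate_thresholds(),
                         sim = sim_config(),
                         venn_classes = list(c("PP", "PM", "PE"),
                                             c("MM", "MP", "ME"))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth <- NULL

  if (is.null(master)) {
    simdata <- simulate_master_table(sim)
    master <- simdata$master
    truth <- simdata$truth
    files["truth"] <- file.path(out_dir, "truth_table.tsv")
    write_tsv(truth, files["truth"],
              provenance = provenance_lines(thresholds, sim$seed))
  } else if (is.character(master)) {
    master <- read_master_table(master, quiet = TRUE)
  }
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(tf_matrix)) tf_matrix <- read_binary_matrix(tf_matrix)

  seed <- if (!is.null(truth)) sim$seed else NA_integer_
  prov <- provenance_lines(thresholds, seed)

  classified <- classify_table(master, thresholds)
  summ <- summarize_classes(classified)

  files["classified"] <- file.path(out_dir, "classified_table.tsv")
  write_tsv(as.data.frame(classified), files["classified"], prov)
  files["summary"] <- file.path(out_dir, "class_summary.tsv")
  write_tsv(summary_to_tsv(summ), files["summary"], prov)

  xt <- NULL
  vn <- NULL
  if (!is.null(annotation)) {
    xt <- crosstab(classified, annotation)
    files["crosstab_counts"] <- file.path(out_dir, "crosstab_long.tsv")
    write_tsv(as.data.frame(xt), files["crosstab_counts"], prov)
    files["crosstab_formatted"] <- file.path(out_dir, "crosstab_formatted.tsv")
    fm <- format_crosstab(xt)
    write_tsv(data.frame(category = rownames(fm), fm, check.names = FALSE,
                         stringsAsFactors = FALSE),
              files["crosstab_formatted"], prov)
    vn <- lapply(venn_classes, function(cls)
      venn_sets(classified, annotation, "ALL", cls))
    venn_df <- do.call(rbind, lapply(vn, function(v)
      data.frame(classes = paste(names(v$sets), collapse = "+"),
                 region = names(v$regions),
                 size = unname(v$regions), stringsAsFactors = FALSE)))
    files["venn"] <- file.path(out_dir, "venn_regions.tsv")
    write_tsv(venn_df, files["venn"], prov)
  }

  clust <- NULL
  if (!is.null(tf_matrix)) {
    clust <- cluster_bidirectional(tf_matrix)
    files["row_merges"] <- file.path(out_dir, "tf_row_merges.tsv")
    write_tsv(merge_table(clust$row_dendrogram), files["row_merges"], prov)
    files["col_merges"] <- file.path(out_dir, "tf_col_merges.tsv")
    write_tsv(merge_table(clust$col_dendrogram), files["col_merges"], prov)
    files["reordered"] <- file.path(out_dir, "tf_matrix_reordered.tsv")
    write_binary_matrix(clust$reordered, files["reordered"], prov)
  }

  qc <- replicate_qc_report(master)
  if (!is.null(qc)) {
    files["qc"] <- file.path(out_dir, "replicate_qc.tsv")
    write_tsv(qc, files["qc"], prov)
  }

  invisible(list(classified = classified, summary = summ, crosstab = xt,
                 venn = vn, clustering = clust, qc = qc, truth = truth,
                 files = files))
}

provenance_lines <- function(thresholds, seed = NA_integer_) {
  c(sprintf("stressmem %s", as.character(utils::packageVersion("stressmem"))),
    sprintf("thresholds: q_max=%g lfc_min=%g floor_percentile=%g epsilon=%g",
            thresholds$q_max, thresholds$lfc_min,
            thresholds$floor_percentile, thresholds$epsilon),
    sprintf("seed: %s", ifelse(is.na(seed), "none", seed)))
}

summary_to_tsv <- function(s) {
  df <- as.data.frame(s)
  totals <- data.frame(
    class = c("TOTAL_GENES", "DEHYDRATION_RESPONSE", "RESPONSIVE_UP",
              "RESPONSIVE_DOWN", "MEMORY", "MEMORY_UP", "MEMORY_DOWN",
              "NON_MEMORY", "LATE_RESPONSE"),
    label = "-",
    count = c(s$total_genes, s$dehydration_responsive, s$responsive_up,
              s$responsive_down, s$memory_total, s$memory_up,
              s$memory_down, s$nonmemory_total, s$late_total),
    stringsAsFactors = FALSE)
  rbind(df, totals)
}

# per-condition replicate concordance on raw FPKM (rep2 on rep1); NULL
# when no condition carries >= 2 replicate columns
replicate_qc_report <- function(master) {
  rows <- list()
  for (cond in c("w", "s1", "s3")) {
    reps <- grep(sprintf("^fpkm_%s_rep[0-9]+$", cond),
                 names(master), value = TRUE)
    if (length(reps) >= 2L && nrow(master) >= 3L) {
      qc <- replicate_qc(master[[reps[1L]]], master[[reps[2L]]])
      rows[[cond]] <- data.frame(condition = cond,
                                 r_squared = qc$r_squared,
                                 slope = qc$slope,
                                 intercept = qc$intercept,
                                 n = qc$n, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
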