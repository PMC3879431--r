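# Sign patterns of the nine classes: S1-vs-W call, S3-vs-S1 call.
class_sign_patterns <- function() {
  list(PP = c("+", "+"), MM = c("-", "-"), PM = c("+", "-"),
       MP = c("-", "+"), PE = c("+", "="), ME = c("-", "="),
       EP = c("=", "+"), EM = c("=", "-"), NR = c("=", "="))
}

#' Default planted class proportions
#'
#' Proportions matching the class partition of the reference
#' repeated-dehydration study (33,555 genes: 362/310/857/434 memory,
#' 2177/2439 non-memory, 798/573 late-response, remainder
#' non-responsive), so synthetic fixtures have a realistic shape.
#'
#' @return Named numeric vector over [memory_classes()] summing to 1.
#' @export
default_class_proportions <- function() {
  counts <- reference_class_counts()
  counts / sum(counts)
}

#' Simulation configuration
#'
#' Parameters of the synthetic master-table generator. Baseline
#' expression is log-normal (`baseline_log_mean`, `baseline_log_sd` in
#' log2 FPKM units); planted responsive fold changes have magnitudes in
#' `[effect_lfc_min, effect_lfc_max]` (log2 units) while planted `"="`
#' contrasts stay below `null_lfc_max`; replicate noise is multiplicative
#' log-normal with coefficient of variation `replicate_cv`, centred so
#' that replicate means equal the planted condition means exactly;
#' q-values are planted consistent with the truth (below `q_sig_max` for
#' responsive contrasts, above `q_null_min` otherwise).
#'
#' The defaults describe the reference study conditions: 33,555 genes in
#' the reference class proportions, two biological replicates with a
#' replicate CV of 0.10 (which reproduces the study's reported
#' between-replicate concordance of R-squared 0.96-0.99 on raw FPKM),
#' planted effect magnitudes of at least 2 log2 units, and
#' gate-compatible q-value ranges.
#'
#' @param n_genes Number of genes (positive integer).
#' @param class_proportions Named nonnegative vector over
#'   [memory_classes()] summing to 1.
#' @param baseline_log_mean,baseline_log_sd Log2-FPKM mean and sd of the
#'   baseline expression distribution.
#' @param effect_lfc_min,effect_lfc_max Magnitude range of planted
#'   responsive log2 fold changes; `effect_lfc_min` must be >= the
#'   significance threshold (1).
#' @param null_lfc_max Maximum |log2 fold change| of planted `"="`
#'   contrasts; must be < 1.
#' @param n_replicates Replicates per condition (>= 1).
#' @param replicate_cv Coefficient of variation of replicate noise.
#' @param q_sig_max Planted q-values of responsive contrasts are drawn
#'   from `(0, q_sig_max]`; must be <= 0.05.
#' @param q_null_min Planted q-values of `"="` contrasts are drawn from
#'   `(q_null_min, 1]`; must be > 0.05.
#' @param seed Integer random seed.
#' @param epsilon FPKM pseudocount.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 33555,
                       class_proportions = default_class_proportions(),
                       baseline_log_mean = 4,
                       baseline_log_sd = 2,
                       effect_lfc_min = 2,
                       effect_lfc_max = 4,
                       null_lfc_max = 0.5,
                       n_replicates = 2,
                       replicate_cv = 0.10,
                       q_sig_max = 0.05,
                       q_null_min = 0.1,
                       seed = 1,
                       epsilon = 0.05) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_proportions = class_proportions,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              effect_lfc_min = effect_lfc_min,
              effect_lfc_max = effect_lfc_max,
              null_lfc_max = null_lfc_max,
              n_replicates = as.integer(n_replicates),
              replicate_cv = replicate_cv,
              q_sig_max = q_sig_max, q_null_min = q_null_min,
              seed = as.integer(seed), epsilon = epsilon)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (is.null(names(p)) || !setequal(names(p), memory_classes()))
    stop("class_proportions must be named over all nine classes: ",
         paste(memory_classes(), collapse = ", "))
  if (any(p < 0)) stop("class_proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must sum to 1 (got ", format(sum(p)), ")")
  stopifnot(cfg$n_genes >= 1L,
            cfg$effect_lfc_min >= 1,
            cfg$effect_lfc_max >= cfg$effect_lfc_min,
            cfg$null_lfc_max < 1, cfg$null_lfc_max >= 0,
            cfg$q_sig_max <= 0.05, cfg$q_sig_max > 0,
            cfg$q_null_min > 0.05, cfg$q_null_min < 1,
            cfg$n_replicates >= 1L, cfg$replicate_cv >= 0,
            cfg$epsilon >= 0)
  nonzero <- p[p > 0]
  small <- names(nonzero)[cfg$n_genes * nonzero < 1]
  if (length(small) > 0L)
    warning("n_genes x proportion < 1 for class(es) ",
            paste(small, collapse = ", "), "; they may be empty")
  invisible(cfg)
}

# largest-remainder apportionment of n among the 9 classes, so that the
# reference defaults at n = 33,555 reproduce the reference counts exactly
apportion_classes <- function(n, proportions) {
  p <- proportions[memory_classes()]
  quota <- n * p
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Generate a synthetic master table with planted class structure
#'
#' Simulates a per-gene master table whose memory-class structure is
#' known ("planted") and exactly recoverable by [classify_table()]:
#' condition means obey the planted sign patterns with effect magnitudes
#' in the configured range, planted q-values are consistent with the
#' truth, and the baseline expression of every responsive gene is
#' placed (and if needed lifted) above the realised pooled-percentile
#' expression floor of each contrast it responds in. Replicate noise is
#' multiplicative log-normal, centred per gene and condition so that the
#' replicate mean equals the planted condition mean exactly — the
#' per-sample FPKM columns and the emitted fold changes are therefore
#' the planted values, not noisy estimates.
#'
#' The same `sim_config` (including its seed) always produces
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list: `master` (a `master_table` with per-replicate
#'   columns) and `truth` (a data.frame `gene_id`, `planted_class`,
#'   `planted_lfc_s1w`, `planted_lfc_s3s1`).
#' @export
simulate_master_table <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  counts <- apportion_classes(n, config$class_proportions)
  cls <- rep(names(counts), counts)
  # fixed deterministic shuffle so classes are not contiguous in the file
  cls <- cls[sample.int(n)]
  patterns <- class_sign_patterns()
  sign1 <- vapply(patterns[cls], `[[`, "", 1L)
  sign2 <- vapply(patterns[cls], `[[`, "", 2L)

  lfc1 <- planted_lfc(sign1, config)
  lfc2 <- planted_lfc(sign2, config)

  # baseline: log-normal; responsive genes drawn above the baseline
  # distribution's lower quartile so the expression floor is passable
  u <- stats::runif(n)
  responsive <- sign1 != "=" | sign2 != "="
  u[responsive] <- 0.30 + 0.70 * u[responsive]
  log2_w <- stats::qnorm(u, config$baseline_log_mean, config$baseline_log_sd)

  w <- 2^log2_w
  s1 <- w * 2^lfc1
  s3 <- s1 * 2^lfc2

  # lift any responsive gene whose floor-relevant sample pair would fail
  # the strict percentile criterion; floors are recomputed until stable
  p25 <- 0.25
  for (iter in seq_len(50L)) {
    floor1 <- expression_floor(c(w, s1), p25)
    floor2 <- expression_floor(c(s1, s3), p25)
    need1 <- sign1 != "=" & pmax(w, s1) <= floor1 * 2^0.1
    need2 <- sign2 != "=" & pmax(s1, s3) <= floor2 * 2^0.1
    if (!any(need1 | need2)) break
    lift <- rep(1, n)
    lift[need1] <- pmax(lift[need1],
                        floor1 * 2^0.2 / pmax(w, s1)[need1])
    lift[need2] <- pmax(lift[need2],
                        floor2 * 2^0.2 / pmax(s1, s3)[need2])
    w <- w * lift; s1 <- s1 * lift; s3 <- s3 * lift
    if (iter == 50L)
      stop("expression-floor adjustment did not converge; ",
           "widen baseline_log_sd or reduce effect sizes")
  }

  q1 <- planted_q(sign1, config)
  q2 <- planted_q(sign2, config)

  gene_id <- sprintf("SIMG%0*d", nchar(n), seq_len(n))
  master <- data.frame(gene_id = gene_id,
                       fpkm_w = w, fpkm_s1 = s1, fpkm_s3 = s3,
                       stringsAsFactors = FALSE)
  for (cond in c("w", "s1", "s3")) {
    means <- master[[paste0("fpkm_", cond)]]
    reps <- centred_replicates(means, config$n_replicates,
                               config$replicate_cv)
    for (k in seq_len(config$n_replicates))
      master[[sprintf("fpkm_%s_rep%d", cond, k)]] <- reps[, k]
  }
  master$lfc_s1w <- lfc1
  master$q_s1w <- q1
  master$lfc_s3s1 <- lfc2
  master$q_s3s1 <- q2
  class(master) <- c("master_table", "data.frame")

  truth <- data.frame(gene_id = gene_id, planted_class = cls,
                      planted_lfc_s1w = lfc1, planted_lfc_s3s1 = lfc2,
                      stringsAsFactors = FALSE)
  list(master = master, truth = truth)
}

planted_lfc <- function(signs, config) {
  n <- length(signs)
  lfc <- stats::runif(n, -config$null_lfc_max, config$null_lfc_max)
  eff <- stats::runif(n, config$effect_lfc_min, config$effect_lfc_max)
  lfc[signs == "+"] <- eff[signs == "+"]
  lfc[signs == "-"] <- -eff[signs == "-"]
  lfc
}

planted_q <- function(signs, config) {
  n <- length(signs)
  q <- config$q_null_min + stats::runif(n) * (1 - config$q_null_min)
  sig <- signs != "="
  q[sig] <- stats::runif(sum(sig)) * config$q_sig_max
  q
}

# multiplicative log-normal replicate noise with the requested CV,
# renormalised per gene so the replicate mean equals the condition mean
centred_replicates <- function(means, n_rep, cv) {
  n <- length(means)
  if (n_rep == 1L || cv == 0)
    return(matrix(rep(means, n_rep), ncol = n_rep))
  sdlog <- sqrt(log(1 + cv^2))
  mult <- matrix(exp(stats::rnorm(n * n_rep, -sdlog^2 / 2, sdlog)),
                 nrow = n, ncol = n_rep)
  mult <- mult / rowMeans(mult)
  means * mult
}

#' Generate a class-conditional annotation map
#'
#' Assigns each gene each functional category independently with a
#' class-conditional probability, emulating category enrichment across
#' response classes. Deterministic under the seed.
#'
#' @param truth Truth table from [simulate_master_table()] (`gene_id`,
#'   `planted_class`).
#' @param categories Character vector of category labels.
#' @param enrichment Named list: class code -> named numeric vector of
#'   per-category probabilities in `[0, 1]`. Categories absent from a
#'   class's vector default to `base_prob`.
#' @param base_prob Background annotation probability (default 0).
#' @param seed Integer seed.
#' @return An `annotation_map` data.frame (`gene_id`, `category`).
#' @export
#' @examples
#' sim <- simulate_master_table(sim_config(n_genes = 90, seed = 1))
#' ann <- simulate_annotation_map(sim$truth, c("chloroplast"),
#'   enrichment = list(MM = c(chloroplast = 1)), seed = 1)
simulate_annotation_map <- function(truth, categories,
                                    enrichment = list(),
                                    base_prob = 0, seed = 1) {
  stopifnot(all(c("gene_id", "planted_class") %in% names(truth)),
            base_prob >= 0, base_prob <= 1)
  bad <- setdiff(names(enrichment), memory_classes())
  if (length(bad) > 0L)
    stop("unknown class key(s) in enrichment: ", paste(bad, collapse = ", "))
  for (cl in names(enrichment)) {
    pr <- enrichment[[cl]]
    if (any(pr < 0 | pr > 1))
      stop("enrichment probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  out_gene <- character(0)
  out_cat <- character(0)
  for (cat in categories) {
    prob <- rep(base_prob, nrow(truth))
    for (cl in names(enrichment)) {
      pr <- enrichment[[cl]]
      if (cat %in% names(pr))
        prob[truth$planted_class == cl] <- pr[[cat]]
    }
    hit <- stats::runif(nrow(truth)) < prob
    out_gene <- c(out_gene, truth$gene_id[hit])
    out_cat <- c(out_cat, rep(cat, sum(hit)))
  }
  df <- data.frame(gene_id = out_gene, category = out_cat,
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_map", "data.frame")
  df
}

#' Generate a planted-block binary TF annotation matrix
#'
#' Simulates a transcription-factor x pathway presence/absence matrix
#' with block structure: TFs fall into groups sharing a preferred subset
#' of pathways (present with probability `within_prob`), with sparse
#' background annotation elsewhere (`between_prob`). Bidirectional UPGMA
#' clustering of such a matrix should place same-group TFs together.
#'
#' @param n_tfs Number of transcription factors (rows).
#' @param pathways Character vector of pathway labels (columns).
#' @param n_groups Number of planted TF groups.
#' @param within_prob,between_prob Annotation probabilities inside and
#'   outside a group's preferred pathways.
#' @param seed Integer seed.
#' @return An integer 0/1 matrix with TF row names, pathway column
#'   names and a `planted_group` attribute.
#' @export
simulate_tf_matrix <- function(n_tfs = 20,
                               pathways = c("ABA", "JA", "SA", "ethylene",
                                            "cold", "salt", "light", "GA"),
                               n_groups = 3, within_prob = 0.9,
                               between_prob = 0.1, seed = 1) {
  stopifnot(n_tfs >= 2, length(pathways) >= 2, n_groups >= 1,
            within_prob >= 0, within_prob <= 1,
            between_prob >= 0, between_prob <= 1)
  set.seed(seed)
  group <- rep(seq_len(n_groups), length.out = n_tfs)
  blocks <- split(seq_along(pathways),
                  rep(seq_len(n_groups), length.out = length(pathways)))
  prob <- matrix(between_prob, n_tfs, length(pathways))
  for (g in seq_len(n_groups))
    prob[group == g, blocks[[g]]] <- within_prob
  m <- matrix(as.integer(stats::runif(length(prob)) < prob),
              n_tfs, length(pathways),
              dimnames = list(sprintf("TF%02d", seq_len(n_tfs)), pathways))
  attr(m, "planted_group") <- group
  m
}
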