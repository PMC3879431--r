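# Independent oracles and small fixture builders used across the suite.

# Benjamini-Hochberg by direct min-over-tails on the sorted p-values:
# q_(i) = min over j >= i of p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    tails <- vapply(i:n, function(j) ps[j] * n / j, numeric(1))
    q[i] <- min(1, min(tails))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Naive UPGMA that recomputes every cluster-pair average from the
# original distance matrix at every step; same deterministic tie-break
# (lexicographically smallest sorted pair of minimal member indices).
upgma_oracle <- function(dm) {
  clusters <- as.list(seq_len(nrow(dm)))
  steps <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L]))))
          best <- list(i = i, j = j, d = d, key = key)
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    steps[[length(steps) + 1L]] <- list(members = sort(merged),
                                        height = best$d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  steps
}

# merged member sets per step of an upgma()/hclust object, as sorted
# original indices
merge_member_sets <- function(dend) {
  members <- function(node) {
    if (node < 0L) return(-node)
    c(members(dend$merge[node, 1L]), members(dend$merge[node, 2L]))
  }
  lapply(seq_len(nrow(dend$merge)), function(s) sort(members(s)))
}

# classified table with prescribed per-class sizes (counts named over
# class codes); no expression columns, enough for summarize/crosstab
make_classified <- function(counts) {
  cls <- rep(names(counts), counts)
  df <- data.frame(gene_id = sprintf("g%05d", seq_along(cls)),
                   memory_class = cls, stringsAsFactors = FALSE)
  patterns <- list(PP = c("+", "+"), MM = c("-", "-"), PM = c("+", "-"),
                   MP = c("-", "+"), PE = c("+", "="), ME = c("-", "="),
                   EP = c("=", "+"), EM = c("=", "-"), NR = c("=", "="))
  df$sign_s1w <- vapply(patterns[df$memory_class], `[[`, "", 1L)
  df$sign_s3s1 <- vapply(patterns[df$memory_class], `[[`, "", 2L)
  df
}

# sim config with equal class proportions, safe for very small n
small_sim_cfg <- function(n, seed = 1, ...) {
  sim_config(n_genes = n, seed = seed,
             class_proportions = stats::setNames(rep(1 / 9, 9),
                                                 memory_classes()),
             ...)
}

# small well-formed master table for io tests
make_master <- function(n = 3) {
  data.frame(gene_id = sprintf("AT%dG0101%d", seq_len(n), seq_len(n)),
             fpkm_w = seq_len(n) * 1.5,
             fpkm_s1 = seq_len(n) * 3.0,
             fpkm_s3 = seq_len(n) * 0.5,
             lfc_s1w = rep(1, n), q_s1w = rep(0.01, n),
             lfc_s3s1 = rep(-2.584963, n), q_s3s1 = rep(0.2, n),
             stringsAsFactors = FALSE)
}
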