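#' Log2 fold change with pseudocount
#'
#' Computes `log2((fpkm_b + epsilon) / (fpkm_a + epsilon))`, the signed
#' log2 fold change of the stressed sample `b` over the reference sample
#' `a`. The pseudocount guards against zero FPKM; it is antisymmetric
#' under swapping the two samples.
#'
#' @param fpkm_a Numeric vector of reference-sample FPKM (>= 0).
#' @param fpkm_b Numeric vector of stressed-sample FPKM (>= 0).
#' @param epsilon FPKM pseudocount; must be > 0 if any input is 0.
#' @return Numeric vector of signed log2 fold changes.
#' @export
#' @examples
#' compute_log2fc(1, 2)        # doubling: 1
#' compute_log2fc(0, 1, 1)     # log2(2/1) = 1
compute_log2fc <- function(fpkm_a, fpkm_b, epsilon = 0.05) {
  stopifnot(is.numeric(fpkm_a), is.numeric(fpkm_b),
            length(epsilon) == 1L, epsilon >= 0)
  if (any(fpkm_a < 0, na.rm = TRUE) || any(fpkm_b < 0, na.rm = TRUE))
    stop("FPKM values must be nonnegative")
  if (epsilon == 0 && any(fpkm_a == 0 & fpkm_b == 0, na.rm = TRUE))
    stop("log2 fold change undefined: both samples 0 and epsilon = 0")
  log2((fpkm_b + epsilon) / (fpkm_a + epsilon))
}

#' Expression floor: percentile of pooled FPKM
#'
#' The minimum-expression criterion of the significance gate uses the
#' 25th percentile of the FPKM values pooled over both samples of a
#' contrast across all genes. Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param fpkm Numeric vector: pooled FPKM values of both contrast
#'   samples over all genes.
#' @param probs Percentile as a fraction (default 0.25).
#' @return The percentile value (scalar, >= 0).
#' @export
#' @examples
#' expression_floor(0:7)   # 1.75
expression_floor <- function(fpkm, probs = 0.25) {
  fpkm <- fpkm[!is.na(fpkm)]
  if (length(fpkm) == 0L) stop("expression_floor: no FPKM values supplied")
  if (any(fpkm < 0)) stop("expression_floor: FPKM values must be nonnegative")
  unname(stats::quantile(fpkm, probs = probs, type = 7))
}

#' Gate thresholds for the three-criterion significance call
#'
#' Bundles the thresholds of the per-contrast significance gate:
#' FDR cutoff `q_max` (default 0.05, inclusive), minimum absolute log2
#' fold change `lfc_min` (default 1, inclusive), the percentile at which
#' the expression floor is taken (default the 25th, strict), and the FPKM
#' pseudocount used when fold changes must be recomputed.
#'
#' @param q_max Maximum FDR-adjusted p-value, in (0, 1).
#' @param lfc_min Minimum |log2 fold change|, > 0.
#' @param floor_percentile Percentile (0-100) defining the expression floor.
#' @param epsilon FPKM pseudocount for fold-change recomputation.
#' @return A list of class `gate_thresholds`.
#' @export
gate_thresholds <- function(q_max = 0.05, lfc_min = 1,
                            floor_percentile = 25, epsilon = 0.05) {
  stopifnot(q_max > 0, q_max < 1, lfc_min > 0,
            floor_percentile >= 0, floor_percentile <= 100, epsilon >= 0)
  structure(list(q_max = q_max, lfc_min = lfc_min,
                 floor_percentile = floor_percentile, epsilon = epsilon),
            class = "gate_thresholds")
}

#' Three-criterion significance call for one contrast
#'
#' A gene is called significantly up (`"+"`) in a contrast when all three
#' criteria hold: q <= `q_max`, lfc >= `lfc_min`, and the FPKM of at
#' least one of the two samples is strictly larger than the expression
#' floor. It is called down (`"-"`) with lfc <= -`lfc_min` instead, and
#' not significant (`"="`) otherwise. Boundary values q = `q_max` and
#' |lfc| = `lfc_min` are significant; FPKM exactly at the floor is not.
#' Missing q-values yield `"="` (conservative) with a warning.
#'
#' @param lfc Numeric vector of signed log2 fold changes.
#' @param q Numeric vector of FDR-adjusted p-values in `[0, 1]` (NA allowed).
#' @param fpkm_a,fpkm_b FPKM of the reference and stressed sample.
#' @param floor Expression floor (scalar FPKM value).
#' @param thresholds A [gate_thresholds()] object.
#' @return Character vector of sign calls in `{"+", "-", "="}`.
#' @export
#' @examples
#' call_significance(lfc = 1, q = 0.05, fpkm_a = 1, fpkm_b = 10, floor = 2)
call_significance <- function(lfc, q, fpkm_a, fpkm_b, floor,
                              thresholds = gate_thresholds()) {
  n <- length(lfc)
  stopifnot(length(q) == n, length(fpkm_a) == n, length(fpkm_b) == n,
            length(floor) == 1L, floor >= 0)
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]")
  n_missing <- sum(is.na(q))
  if (n_missing > 0L)
    warning(sprintf("%d gene(s) with missing q-value called '=' (not significant)",
                    n_missing))
  expressed <- pmax(fpkm_a, fpkm_b) > floor
  sig <- !is.na(q) & q <= thresholds$q_max &
    abs(lfc) >= thresholds$lfc_min & expressed
  out <- rep("=", n)
  out[sig & lfc > 0] <- "+"
  out[sig & lfc < 0] <- "-"
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values, as used to
#' derive per-contrast q-values. Delegates to `stats::p.adjust(method =
#' "BH")` after validating the input range.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of q-values, elementwise >= `p` and <= 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Welch t-test on log2(FPKM + epsilon) replicates
#'
#' A simple per-gene differential-expression test for master tables that
#' carry raw replicate FPKM values but no upstream q-values. Replicates
#' are log2-transformed with a pseudocount and compared by a two-sample
#' Welch t-test. If both groups are constant the test degenerates: p = 1
#' when the constants are equal, p = 0 otherwise.
#'
#' @param replicates_a,replicates_b Numeric vectors (>= 2 each) of FPKM
#'   replicate values for the two conditions.
#' @param epsilon FPKM pseudocount.
#' @return A single p-value in `[0, 1]`.
#' @export
simple_de_test <- function(replicates_a, replicates_b, epsilon = 0.05) {
  if (length(replicates_a) < 2L || length(replicates_b) < 2L)
    stop("simple_de_test needs >= 2 replicates per group; ",
         "supply upstream q-values instead")
  la <- log2(replicates_a + epsilon)
  lb <- log2(replicates_b + epsilon)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  stats::t.test(la, lb, var.equal = FALSE)$p.value
}

#' Replicate-concordance regression
#'
#' Ordinary least-squares regression of the second biological replicate
#' on the first, across genes, reporting R-squared, slope, intercept and
#' gene count. High R-squared (the reference study reports 0.96-0.99)
#' and a slope near 1 indicate concordant replicates. The scale is
#' selectable because library-size differences can shift the raw-scale
#' slope away from 1.
#'
#' @param rep1,rep2 Equal-length numeric FPKM vectors (n >= 3).
#' @param log_scale If `TRUE`, regress on log2(FPKM + epsilon) instead
#'   of raw FPKM.
#' @param epsilon Pseudocount used when `log_scale = TRUE`.
#' @return A list of class `qc_result`: `r_squared`, `slope`,
#'   `intercept`, `n`.
#' @export
replicate_qc <- function(rep1, rep2, log_scale = FALSE, epsilon = 0.05) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 3L)
  if (log_scale) {
    rep1 <- log2(rep1 + epsilon)
    rep2 <- log2(rep2 + epsilon)
  }
  if (stats::sd(rep1) == 0)
    stop("replicate_qc: zero variance in the first replicate")
  fit <- stats::lm(rep2 ~ rep1)
  structure(list(r_squared = summary(fit)$r.squared,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = length(rep1)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Replicate concordance: R^2 = %.4f, slope = %.4f, intercept = %.4g (n = %d)\n",
              x$r_squared, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative qRT-PCR quantification comparing the target-vs-reference
#' cycle-threshold difference of a sample against that of a calibrator
#' condition: `2^-[(ct_target_sample - ct_ref_sample) -
#' (ct_target_calibrator - ct_ref_calibrator)]`. In the reference study
#' the reference gene is ubiquitin and the calibrator the watered state.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene
#'   in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and
#'   reference gene in the calibrator condition.
#' @return Relative expression (strictly positive).
#' @export
#' @examples
#' ddct_quantify(24, 20, 26, 20)  # ddCt = -2 -> 4-fold
ddct_quantify <- function(ct_target_sample, ct_ref_sample,
                          ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample,
           ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
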