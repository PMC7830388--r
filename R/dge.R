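#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants computed as the median, over genes
#' with all-positive counts, of the ratio between a sample's count and the
#' gene's geometric mean across samples.  Genes with a zero anywhere are
#' excluded from the reference (toy matrices are zero-rich, so this
#' convention matters).
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0
  stop_if_not(any(all_pos),
              "no gene has positive counts in every sample; size factors undefined")
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2,
              function(col) median(exp(log(col) - log_geo)))
  stop_if_not(all(sf > 0), "degenerate size factor")
  sf
}

#' Method-of-moments NB dispersion per gene
#'
#' Pools normalised counts within each condition, computes
#' `alpha = max(0, (s^2 - mean) / mean^2)` per condition, and averages the
#' two conditions.  With only a handful of replicates this raw
#' method-of-moments value is extremely noisy (2 df per condition), which
#' makes a Wald test built on it anti-conservative, so by default the
#' per-gene estimate is squeezed towards the trimmed across-gene mean with
#' a prior weight of `prior_df` pseudo-degrees of freedom — a lightweight
#' stand-in for the information sharing that dedicated DGE packages
#' perform.  Set `moderate = FALSE` for the raw per-gene values.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors, one per sample ([size_factors()]).
#' @param condition factor of length `ncol(counts)` with two levels.
#' @param moderate squeeze per-gene estimates towards the global mean.
#' @param prior_df weight (pseudo-df) of the global mean in the squeeze.
#' @return numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, sf, condition, moderate = TRUE,
                                prior_df = 20) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stop_if_not(all(table(condition) >= 2), "need >= 2 samples per condition")
  norm <- sweep(counts, 2, sf, "/")
  per_cond <- vapply(levels(condition), function(lv) {
    x <- norm[, condition == lv, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  }, numeric(nrow(counts)))
  disp <- rowMeans(matrix(per_cond, nrow = nrow(counts)))
  if (moderate && length(disp) > 1) {
    gene_df <- max(1, ncol(counts) - nlevels(condition))
    target <- mean(disp)
    disp <- (gene_df * disp + prior_df * target) / (gene_df + prior_df)
  }
  disp
}

#' NB Wald test for differential expression
#'
#' Estimates the log2 fold change as the log-ratio of normalised group
#' means (with a pseudo-mean of 0.5 added to both groups only when a
#' group mean is exactly 0, so inductions from zero stay large but
#' finite), derives its standard error from the NB variance
#' `mu + alpha * mu^2` by the delta method, and computes a two-sided
#' normal-tail p-value with Benjamini-Hochberg adjustment.  Genes with no
#' counts in either group get `log2FC = 0`, `p = 1`.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors ([size_factors()]).
#' @param dispersions per-gene dispersions ([estimate_dispersion()]).
#' @param condition two-level factor; the fold change is second level vs
#'   first level.
#' @return data frame of class `dge_result` with columns `gene_id`,
#'   `baseMean`, `log2FC`, `SE`, `pvalue`, `padj`.
#' @export
wald_test <- function(counts, sf, dispersions, condition) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stop_if_not(nlevels(condition) == 2, "condition must have exactly two levels")
  stop_if_not(all(table(condition) >= 1), "both conditions must be populated")
  norm <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- condition == levels(condition)[2]
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  zero_gene <- m1 == 0 & m2 == 0
  pseudo <- (m1 == 0 | m2 == 0) & !zero_gene
  m1a <- m1 + 0.5 * pseudo
  m2a <- m2 + 0.5 * pseudo
  lfc <- ifelse(zero_gene, 0, log2(m2a / m1a))
  group_var <- function(m, idx) {
    s <- sf[idx]
    vapply(seq_along(m), function(g) {
      sum(m[g] / s + dispersions[g] * m[g]^2) / length(s)^2
    }, numeric(1))
  }
  v1 <- group_var(m1a, which(g1))
  v2 <- group_var(m2a, which(g2))
  se <- sqrt(v1 / (m1a^2) + v2 / (m2a^2)) / log(2)
  z <- ifelse(zero_gene | se == 0, 0, lfc / se)
  p <- ifelse(zero_gene, 1, 2 * pnorm(-abs(z)))
  p <- pmin(p, 1)
  res <- data.frame(
    gene_id = rownames(counts), baseMean = rowMeans(norm),
    log2FC = lfc, SE = ifelse(zero_gene, NA_real_, se),
    pvalue = p, padj = bh_adjust(p),
    stringsAsFactors = FALSE)
  class(res) <- c("dge_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")` (step-up
#' with running-minimum monotonicity, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(is.finite(p) & p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression on a count matrix
#'
#' Convenience wrapper chaining [size_factors()],
#' [estimate_dispersion()] and [wald_test()].
#'
#' @param counts integer matrix (genes x samples) or a `count_matrix`.
#' @param condition two-level factor per sample; taken from the
#'   `count_matrix` when omitted.
#' @return a `dge_result` data frame, see [wald_test()].
#' @export
dge <- function(counts, condition = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(condition)) condition <- counts$condition
    counts <- counts$counts
  }
  stop_if_not(!is.null(condition), "condition labels are required")
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, condition)
  wald_test(counts, sf, disp, condition)
}

#' @export
print.dge_result <- function(x, ...) {
  n_sig <- sum(x$padj < 0.05, na.rm = TRUE)
  cat(sprintf("<dge_result> %d genes; %d at padj < 0.05\n", nrow(x), n_sig))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more genes\n", nrow(x) - 10))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR quantification `2^-((Ct_target,treated - Ct_ref,treated)
#' - (Ct_target,control - Ct_ref,control))` against a house-keeping
#' reference gene.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite numerics, vectorised).
#' @return relative expression (fold change), 1 when all four Ct are equal.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  stop_if_not(all(is.finite(c(ct_target_treated, ct_ref_treated,
                              ct_target_control, ct_ref_control))),
              "Ct values must be finite")
  ddct_val <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct_val)
}

#' Write a DGE result table as TSV
#'
#' @param result a `dge_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dge_tsv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
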