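#' Select the regulon by the joint DGE + occupancy rule
#'
#' A gene is called regulon member iff it is (i) more than
#' `fc_threshold`-fold up-regulated (strict inequality on the fold
#' change) at adjusted p below `alpha`, and (ii) has binding occupancy of
#' at least `occ_threshold` (inclusive) in both ChIP conditions.  The
#' asymmetric boundary semantics — FC strictly greater, occupancy
#' inclusive — are deliberate and tested.  Genes with missing occupancy
#' are never selected and carry an explanatory reason.
#'
#' @param dge a `dge_result` ([wald_test()] / [dge()]).
#' @param occupancy data frame `gene_id`, `occupancy_control`,
#'   `occupancy_shock` ([experiment_occupancy()]).
#' @param fc_threshold fold-change threshold (linear scale); default 2.
#' @param alpha adjusted-p threshold; default 0.05.
#' @param occ_threshold occupancy threshold; default 2.
#' @return data frame of class `regulon_call`: per gene `log2FC`, `padj`,
#'   `occupancy_control`, `occupancy_shock`, `selected`, and `reasons`
#'   (comma-joined failed criteria, empty when selected).
#' @export
select_regulon <- function(dge, occupancy, fc_threshold = 2, alpha = 0.05,
                           occ_threshold = 2) {
  stop_if_not(nrow(dge) > 0, "empty gene universe")
  tab <- merge(as.data.frame(dge)[, c("gene_id", "log2FC", "padj")],
               occupancy, by = "gene_id", all.x = TRUE, sort = FALSE)
  tab <- tab[match(dge$gene_id, tab$gene_id), ]
  lfc_thr <- log2(fc_threshold)
  fc_ok <- !is.na(tab$log2FC) & tab$log2FC > lfc_thr
  p_ok <- !is.na(tab$padj) & tab$padj < alpha
  occ_missing <- is.na(tab$occupancy_control) | is.na(tab$occupancy_shock)
  occ_ok <- !occ_missing & tab$occupancy_control >= occ_threshold &
    tab$occupancy_shock >= occ_threshold
  tab$selected <- fc_ok & p_ok & occ_ok
  tab$reasons <- vapply(seq_len(nrow(tab)), function(i) {
    r <- character()
    if (!fc_ok[i]) r <- c(r, "fold-change")
    if (!p_ok[i]) r <- c(r, "padj")
    if (occ_missing[i]) r <- c(r, "occupancy_missing")
    else if (!occ_ok[i]) r <- c(r, "occupancy")
    paste(r, collapse = ",")
  }, character(1))
  class(tab) <- c("regulon_call", "data.frame")
  tab
}

#' @export
print.regulon_call <- function(x, ...) {
  cat(sprintf("<regulon_call> %d genes, %d selected\n", nrow(x),
              sum(x$selected)))
  sel <- as.data.frame(x)[x$selected, , drop = FALSE]
  if (nrow(sel) > 0) print.data.frame(sel, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Precision and recall of a regulon call against planted truth
#'
#' @param calls a `regulon_call` ([select_regulon()]).
#' @param truth_ids character vector of true regulon gene ids.
#' @return named numeric vector `precision`, `recall`, `n_selected`.
#' @export
regulon_recovery <- function(calls, truth_ids) {
  sel <- calls$gene_id[calls$selected]
  tp <- length(intersect(sel, truth_ids))
  c(precision = if (length(sel) > 0) tp / length(sel) else NA_real_,
    recall = tp / length(truth_ids),
    n_selected = length(sel))
}

#' Length-bias-corrected category enrichment
#'
#' Tests whether functional categories are over-represented among
#' selected genes while correcting for gene-length selection bias (long
#' genes are more likely to be detected).  The null distribution of
#' per-category counts is built by repeatedly drawing `|selected|` genes
#' without replacement with probability proportional to a binned
#' length-based selection propensity: genes are split into
#' `n_bins` equal-occupancy length bins, each bin's propensity is its
#' observed selected fraction, floored at `1 / (2N)` so no gene has zero
#' weight.  One-sided p-values use the add-one estimator
#' `(1 + #resamples >= observed) / (1 + n_resample)`, BH-adjusted across
#' categories.
#'
#' @param selected character vector of selected gene ids.
#' @param table data frame `gene_id`, `category`, `length` covering the
#'   gene universe (selected genes may be "unassigned" but must appear).
#' @param n_resample number of weighted resamples (>= 1000).
#' @param n_bins number of length bins; default 20.
#' @param seed integer seed.
#' @return data frame per category: `category`, `observed`, `expected`,
#'   `ratio`, `pvalue`, `padj`.
#' @export
category_enrichment <- function(selected, table, n_resample = 10000L,
                                n_bins = 20L, seed = 1L) {
  stop_if_not(n_resample >= 1000, "n_resample must be >= 1000")
  stop_if_not(all(selected %in% table$gene_id),
              "every selected gene must appear in the category table")
  n <- nrow(table)
  k <- length(selected)
  stop_if_not(k >= 1, "selected set is empty")
  is_sel <- table$gene_id %in% selected
  # equal-occupancy length bins (ties collapse bins; constant length -> 1 bin)
  br <- unique(quantile(table$length, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) rep(1L, n) else
    cut(table$length, breaks = br, include.lowest = TRUE, labels = FALSE)
  prop <- tapply(is_sel, bin, mean)
  w <- pmax(prop[as.character(bin)], 1 / (2 * n))
  cats <- sort(unique(table$category))
  cat_idx <- match(table$category, cats)
  observed <- tabulate(cat_idx[is_sel], nbins = length(cats))
  with_seed(seed, {
    null_counts <- matrix(0L, n_resample, length(cats))
    for (b in seq_len(n_resample)) {
      draw <- sample.int(n, k, replace = FALSE, prob = w)
      null_counts[b, ] <- tabulate(cat_idx[draw], nbins = length(cats))
    }
    expected <- colMeans(null_counts)
    p <- vapply(seq_along(cats), function(j) {
      (1 + sum(null_counts[, j] >= observed[j])) / (1 + n_resample)
    }, numeric(1))
    data.frame(category = cats, observed = observed, expected = expected,
               ratio = ifelse(expected > 0, observed / expected, NA_real_),
               pvalue = p, padj = bh_adjust(p), stringsAsFactors = FALSE)
  })
}

#' Write regulon calls or enrichment tables as TSV
#'
#' @param x a data frame (`regulon_call` or enrichment table).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_regulon_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
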