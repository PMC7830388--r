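#' Extract TSS-anchored sequence windows
#'
#' Cuts a fixed window around every gene's TSS, strand-aware: windows of
#' minus-strand genes are reverse-complemented so that "upstream" is
#' always to the left.  Relative position 0 is the first transcribed
#' base; -1 is the base immediately upstream.  Windows wrap on circular
#' genomes; on linear genomes overhanging windows are an error (or are
#' dropped with `overhang = "drop"`).
#'
#' @param genome a [genome()] object.
#' @param genes gene table (defaults to all genes of `genome`).
#' @param from_pos,to_pos window bounds relative to the TSS (half-open,
#'   `from_pos < to_pos`); default -150 to +50.
#' @param label free-text set label (`"target"`/`"background"`).
#' @param overhang behaviour on linear genomes: `"error"` or `"drop"`.
#' @return object of class `anchored_set`: `sequences` (named by
#'   gene id), `positions` (relative coordinates per window column),
#'   `from`, `to`, `label`.
#' @export
extract_anchored <- function(genome, genes = genome$genes, from_pos = -150L,
                             to_pos = 50L, label = "target",
                             overhang = c("error", "drop")) {
  overhang <- match.arg(overhang)
  stop_if_not(from_pos < to_pos, "from_pos must be < to_pos")
  width <- to_pos - from_pos
  len <- genome$length
  seqs <- character(nrow(genes))
  keep <- rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    start <- if (genes$strand[i] == "+") tss + from_pos else tss - to_pos + 1L
    if (!genome$circular && (start < 0 || start + width > len)) {
      if (overhang == "drop") { keep[i] <- FALSE; next }
      stop("anchored window overhangs a linear genome end", call. = FALSE)
    }
    s <- genome_subseq(genome, start, width)
    seqs[i] <- if (genes$strand[i] == "+") s else revcomp(s)
  }
  structure(list(sequences = setNames(seqs[keep], genes$gene_id[keep]),
                 positions = seq.int(from_pos, to_pos - 1L),
                 from = from_pos, to = to_pos, label = label),
            class = "anchored_set")
}

#' @export
print.anchored_set <- function(x, ...) {
  cat(sprintf("<anchored_set> %s: %d windows, positions %d..%d relative to TSS\n",
              x$label, length(x$sequences), x$from, x$to - 1L))
  invisible(x)
}

# n_seq x width matrix of base characters for an anchored set
anchored_base_matrix <- function(set) {
  do.call(rbind, strsplit(toupper(set$sequences), "", fixed = TRUE))
}

#' Positional nucleotide enrichment of target vs background promoters
#'
#' Per TSS-relative position and base, the log2 ratio of pseudocounted
#' base frequencies in the target window set over the background set.
#' Raw frequency tables are returned alongside so alternative statistics
#' can be layered on.  The statistic is exactly antisymmetric under
#' swapping target and background.
#'
#' @param target,background `anchored_set`s with identical window
#'   geometry.
#' @param pseudocount added to each base count before normalising;
#'   default 1.
#' @return list of class `positional_enrichment`: `enrichment` (4 x
#'   width matrix, rows A/C/G/T), `positions`, `freq_target`,
#'   `freq_background`.
#' @export
positional_enrichment <- function(target, background, pseudocount = 1) {
  stop_if_not(identical(target$positions, background$positions),
              "target and background window geometry differ")
  count_freq <- function(set) {
    m <- anchored_base_matrix(set)
    cnt <- apply(m, 2, function(col) {
      table(factor(col, levels = DNA_BASES))
    })
    freq <- sweep(cnt + pseudocount, 2,
                  colSums(cnt) + 4 * pseudocount, "/")
    list(count = cnt, freq = freq)
  }
  ft <- count_freq(target)
  fb <- count_freq(background)
  enr <- log2(ft$freq / fb$freq)
  dimnames(enr) <- list(DNA_BASES, target$positions)
  structure(list(enrichment = enr, positions = target$positions,
                 freq_target = ft$freq, freq_background = fb$freq),
            class = "positional_enrichment")
}

#' Trinucleotide bendability scale
#'
#' Expands a table of strand-symmetric trinucleotide classes into a full
#' 64-entry lookup: each listed trinucleotide and its reverse complement
#' receive the same value.  All 64 trinucleotides must resolve.
#'
#' @param table data frame with columns `trinucleotide`, `value` (32
#'   class representatives suffice).
#' @return named numeric vector of length 64, class `trinuc_scale`.
#' @export
trinucleotide_scale <- function(table) {
  vals <- setNames(rep(NA_real_, 64),
                   as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                   DNA_BASES, paste0)))
  for (i in seq_len(nrow(table))) {
    tri <- toupper(table$trinucleotide[i])
    rc <- revcomp(tri)
    for (t in c(tri, rc)) {
      if (!is.na(vals[t]) && vals[t] != table$value[i]) {
        stop(sprintf("conflicting values for trinucleotide class %s/%s",
                     tri, rc), call. = FALSE)
      }
      vals[t] <- table$value[i]
    }
  }
  stop_if_not(!anyNA(vals), "scale does not cover all 64 trinucleotides")
  stop_if_not(all(is.finite(vals)), "scale values must be finite")
  structure(vals, class = "trinuc_scale")
}

#' Read a trinucleotide scale from a 2-column TSV
#'
#' @param path TSV with columns `trinucleotide`, `value`.
#' @return a `trinuc_scale` ([trinucleotide_scale()]).
#' @export
read_trinucleotide_scale <- function(path) {
  trinucleotide_scale(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Synthetic bendability scale shipped for tests and examples
#'
#' The published DNase-I-derived trinucleotide bendability values are not
#' redistributed here; this accessor loads a clearly synthetic,
#' deterministic stand-in scale (strand-symmetric, values in roughly
#' -0.3..0.3) shipped as a plain-text table.  Supply a real scale via
#' [read_trinucleotide_scale()] for scientific use.
#'
#' @return a `trinuc_scale`.
#' @export
synthetic_bendability_scale <- function() {
  read_trinucleotide_scale(system.file("extdata",
                                       "synthetic_bendability_scale.tsv",
                                       package = "regulonkit",
                                       mustWork = TRUE))
}

# centered running mean of width `span`, window shrunk at the edges
running_mean <- function(x, span) {
  stop_if_not(span >= 1 && span %% 2 == 1, "span must be a positive odd integer")
  h <- (span - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (cn[hi + 1L] - cn[lo])
}

# per-sequence trinucleotide profile matrix (n_seq x (width - 2)),
# NA where the trinucleotide contains a non-ACGT base
trinuc_profile_matrix <- function(windows, scale) {
  width <- length(windows$positions)
  stop_if_not(width >= 3, "window must be at least 3 bases for trinucleotides")
  t(vapply(windows$sequences, function(s) {
    tri <- substring(s, seq_len(width - 2L), seq_len(width - 2L) + 2L)
    unname(unclass(scale)[tri])
  }, numeric(width - 2L)))
}

#' TSS-anchored DNA bendability profile
#'
#' Scores every trinucleotide of every window with the scale, averages
#' across sequences per TSS-relative position, smooths with a centered
#' running mean, and puts a percentile-bootstrap confidence band around
#' the smoothed mean (resampling whole sequences).  Positions whose
#' trinucleotide contains an ambiguous base are skipped and counted.
#'
#' @param windows an `anchored_set` ([extract_anchored()]).
#' @param scale a `trinuc_scale`.
#' @param span running-mean width in positions (odd); default 11.
#' @param ci confidence level of the bootstrap band; default 0.95.
#' @param n_boot bootstrap resamples; default 1000.
#' @param seed integer seed for the bootstrap.
#' @return object of class `tss_profile`: `positions` (relative position
#'   of each trinucleotide start), `mean` (unsmoothed per-position mean),
#'   `smoothed`, `lower`, `upper`, `span`, `ci`, `n_seqs`, `n_skipped`,
#'   and the per-sequence `matrix` (kept for profile comparison).
#' @export
bendability_profile <- function(windows, scale, span = 11L, ci = 0.95,
                                n_boot = 1000L, seed = 1L) {
  P <- trinuc_profile_matrix(windows, scale)
  positions <- windows$positions[seq_len(ncol(P))]
  raw_mean <- colMeans(P, na.rm = TRUE)
  smoothed <- running_mean(raw_mean, span)
  n <- nrow(P)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      running_mean(colMeans(P[sample.int(n, n, replace = TRUE), , drop = FALSE],
                            na.rm = TRUE), span)
    }, numeric(ncol(P)))
  })
  qs <- apply(boot, 1, quantile, probs = c((1 - ci) / 2, 1 - (1 - ci) / 2),
              na.rm = TRUE)
  structure(list(positions = positions, mean = raw_mean, smoothed = smoothed,
                 lower = qs[1, ], upper = qs[2, ], span = span, ci = ci,
                 n_seqs = n, n_skipped = sum(is.na(P)), matrix = P),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("<tss_profile> %d sequences, positions %d..%d, span %d, %.0f%% CI\n",
              x$n_seqs, min(x$positions), max(x$positions), x$span,
              100 * x$ci))
  invisible(x)
}

#' @export
plot.tss_profile <- function(x, main = "bendability profile", ...) {
  plot(x$positions, x$smoothed, type = "l", xlab = "position relative to TSS",
       ylab = "bendability (scale units)", main = main, ...)
  graphics::polygon(c(x$positions, rev(x$positions)),
                    c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$positions, x$smoothed)
  invisible(x)
}

#' Compare two bendability profiles
#'
#' Difference of the smoothed means (target minus background) with a
#' combined confidence band obtained by bootstrapping both sequence sets
#' independently.
#'
#' @param target,background `tss_profile`s on identical position grids.
#' @param n_boot bootstrap resamples; default 1000.
#' @param seed integer seed.
#' @return object of class `profile_comparison`: `positions`,
#'   `difference`, `lower`, `upper`.
#' @export
compare_profiles <- function(target, background, n_boot = 1000L, seed = 1L) {
  stop_if_not(identical(target$positions, background$positions),
              "profiles are on different position grids")
  diff <- target$smoothed - background$smoothed
  span <- target$span
  boot_diff <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      t_m <- colMeans(target$matrix[sample.int(target$n_seqs, target$n_seqs,
                                               replace = TRUE), , drop = FALSE],
                      na.rm = TRUE)
      b_m <- colMeans(background$matrix[sample.int(background$n_seqs,
                                                   background$n_seqs,
                                                   replace = TRUE), ,
                                        drop = FALSE], na.rm = TRUE)
      running_mean(t_m, span) - running_mean(b_m, background$span)
    }, numeric(length(diff)))
  })
  qs <- apply(boot_diff, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(positions = target$positions, difference = diff,
                 lower = qs[1, ], upper = qs[2, ]),
            class = "profile_comparison")
}

#' Write a profile (or enrichment matrix) as TSV
#'
#' @param x a `tss_profile`, `profile_comparison` or
#'   `positional_enrichment`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profile_tsv <- function(x, path) {
  df <- if (inherits(x, "tss_profile")) {
    data.frame(position = x$positions, mean = x$mean, smoothed = x$smoothed,
               lower = x$lower, upper = x$upper)
  } else if (inherits(x, "profile_comparison")) {
    data.frame(position = x$positions, difference = x$difference,
               lower = x$lower, upper = x$upper)
  } else if (inherits(x, "positional_enrichment")) {
    data.frame(position = x$positions, t(x$enrichment))
  } else stop("unsupported profile object", call. = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
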