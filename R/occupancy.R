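#' Extend mapped reads to fragment length
#'
#' Each read's 1-base 5' anchor is extended towards 3' to the expected
#' fragment size, so that coverage represents the precise protein-DNA
#' contact region rather than the sequenced end.  A plus-strand read at
#' `p` becomes `[p, p + L)`; a minus-strand read at `p` (its 5' end)
#' becomes `[p - L + 1, p + 1)`.  Intervals may run off the coordinate
#' space; [coverage_track()] wraps them on circular genomes.
#'
#' @param reads a [read_set()].
#' @param fragment_length fragment size in bases (>= 1); default 200.
#' @return data frame with 0-based half-open `start`, `end` columns, one
#'   row per read (possibly with `start < 0` or `end > genome_length`,
#'   to be wrapped downstream).
#' @export
extend_reads <- function(reads, fragment_length = 200L) {
  stop_if_not(fragment_length >= 1, "fragment_length must be >= 1")
  p <- reads$position
  plus <- reads$strand == "+"
  start <- ifelse(plus, p, p - fragment_length + 1L)
  end <- ifelse(plus, p + fragment_length, p + 1L)
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Per-position coverage of a set of intervals
#'
#' Counts, at 1-bp resolution, how many intervals cover each genome
#' position.  On circular genomes intervals wrap modulo the genome
#' length; the sum of the track always equals the total interval length.
#'
#' @param intervals data frame with `start`, `end` (0-based half-open).
#' @param genome_length track length in bases.
#' @param circular wrap out-of-range intervals when `TRUE`; otherwise
#'   out-of-range intervals are an error.
#' @return an unscaled `coverage_track` (numeric vector of length
#'   `genome_length` with attribute `scaled = FALSE`).
#' @export
coverage_track <- function(intervals, genome_length, circular = TRUE) {
  len <- as.integer(genome_length)
  start <- intervals$start
  end <- intervals$end
  stop_if_not(all(end > start), "intervals must satisfy start < end")
  width <- end - start
  stop_if_not(all(width <= len), "intervals longer than the genome are not supported")
  if (!circular) {
    stop_if_not(all(start >= 0 & end <= len),
                "interval outside coordinate space on a linear genome")
  }
  s <- wrap_pos(start, len)
  e1 <- pmin(s + width, len)
  over <- s + width - len  # > 0 where the interval wraps
  delta <- numeric(len + 1L)
  inc <- tabulate(s + 1L, nbins = len + 1L)
  dec <- tabulate(e1 + 1L, nbins = len + 1L)
  delta <- inc - dec
  wrapped <- over > 0L
  if (any(wrapped)) {
    delta[1L] <- delta[1L] + sum(wrapped)
    delta <- delta - tabulate(over[wrapped] + 1L, nbins = len + 1L)
  }
  values <- cumsum(delta[seq_len(len)])
  structure(values, scaled = FALSE, class = "coverage_track")
}

#' Scale a coverage track to sequencing depth
#'
#' Divides by the genome-wide mean coverage so tracks from libraries of
#' different depths are comparable; the scaled track has mean exactly 1.
#' (Equivalent to counts-per-million scaling up to a constant that cancels
#' in the IP/input ratio.)
#'
#' @param track a `coverage_track`.
#' @return the scaled track (attribute `scaled = TRUE`).
#' @export
scale_track <- function(track) {
  m <- mean(track)
  stop_if_not(m > 0, "cannot scale an all-zero coverage track")
  structure(as.numeric(track) / m, scaled = TRUE, class = "coverage_track")
}

#' Per-position IP/input ratio track
#'
#' Computes `(ip + eps) / (input + eps)` position by position on
#' depth-scaled tracks.  The pseudocount keeps zero-input positions finite
#' (double-zero positions get ratio 1).
#'
#' @param ip,input depth-scaled `coverage_track`s of equal length.
#' @param pseudocount epsilon added to both numerator and denominator
#'   (> 0); default 0.1.
#' @return numeric `ratio_track` of the same length.
#' @export
ratio_track <- function(ip, input, pseudocount = 0.1) {
  stop_if_not(length(ip) == length(input), "ip/input track length mismatch")
  stop_if_not(pseudocount > 0, "pseudocount must be > 0")
  structure((as.numeric(ip) + pseudocount) / (as.numeric(input) + pseudocount),
            class = "ratio_track")
}

#' Replicate-averaged linear ratio track
#'
#' Arithmetic mean of per-replicate linear IP/input ratios, position by
#' position.  This linear mean is what per-gene occupancy thresholds are
#' applied to.
#'
#' @param ratios list of equal-length `ratio_track`s (>= 1 replicate).
#' @return numeric vector of per-position mean ratios.
#' @export
mean_ratio_track <- function(ratios) {
  stop_if_not(length(ratios) >= 1, "need at least one replicate ratio track")
  lens <- vapply(ratios, length, integer(1))
  stop_if_not(length(unique(lens)) == 1, "replicate track length mismatch")
  Reduce(`+`, lapply(ratios, as.numeric)) / length(ratios)
}

#' Log2 of the replicate-averaged ratio track
#'
#' Averages the linear replicate ratios first, then takes log2 — the
#' display/export transform for genome-browser style comparison.
#'
#' @param ratios list of equal-length `ratio_track`s.
#' @return numeric vector of per-position `log2(mean ratio)` values.
#' @export
mean_log2_track <- function(ratios) {
  log2(mean_ratio_track(ratios))
}

#' Per-gene window occupancy
#'
#' Mean of the replicate-averaged linear IP/input ratio in a fixed window
#' at each gene start.  With the default `centered` anchor the window is
#' `[tss - floor(w/2), tss + ceiling(w/2))`, strand-agnostic; with
#' `upstream` it is the `w` bases 5' of the TSS on the gene's strand.
#' Windows wrap on circular genomes.
#'
#' @param mean_ratio per-position linear mean ratio ([mean_ratio_track()]).
#' @param genes gene table (as in a [genome()] object).
#' @param window window size in bases (>= 1); default 300.
#' @param anchor `"centered"` (default) or `"upstream"`.
#' @param circular wrap windows modulo the track length.
#' @return data frame `gene_id`, `occupancy`.
#' @export
window_occupancy <- function(mean_ratio, genes, window = 300L,
                             anchor = c("centered", "upstream"),
                             circular = TRUE) {
  anchor <- match.arg(anchor)
  stop_if_not(window >= 1, "window must be >= 1")
  len <- length(mean_ratio)
  stop_if_not(all(genes$tss >= 0 & genes$tss < len),
              "gene TSS outside coordinate space")
  vals <- as.numeric(mean_ratio)
  occ <- vapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[i]
    idx <- if (anchor == "centered") {
      seq.int(tss - window %/% 2, tss + (window - window %/% 2) - 1L)
    } else if (genes$strand[i] == "+") {
      seq.int(tss - window, tss - 1L)
    } else {
      seq.int(tss + 1L, tss + window)
    }
    if (circular) {
      idx <- wrap_pos(idx, len)
    } else {
      stop_if_not(all(idx >= 0 & idx < len),
                  "occupancy window outside a linear genome")
    }
    mean(vals[idx + 1L])
  }, numeric(1))
  data.frame(gene_id = genes$gene_id, occupancy = occ,
             stringsAsFactors = FALSE)
}

#' Full peak-free occupancy quantification for one condition
#'
#' Runs the whole track pipeline for one ChIP condition: extend reads to
#' fragment size, compute depth-scaled coverage per sample, form the
#' per-replicate IP/input ratio, average replicates, and summarise
#' per-gene window occupancy.  Replicate `r` of the IP list is paired with
#' replicate `r` of the input list.
#'
#' @param ip,input lists of [read_set()]s (equal length, >= 1).
#' @param genes gene table (as in a [genome()] object).
#' @param fragment_length fragment extension length; default 200.
#' @param window occupancy window size; default 300.
#' @param pseudocount ratio pseudocount; default 0.1.
#' @param anchor occupancy window anchor, see [window_occupancy()].
#' @param circular wrap coordinates modulo the genome length.
#' @return list with `mean_ratio` (per-position linear mean),
#'   `log2_track` (its log2), `occupancy` (data frame `gene_id`,
#'   `occupancy`), and `replicate_ratios`.
#' @export
chip_occupancy <- function(ip, input, genes, fragment_length = 200L,
                           window = 300L, pseudocount = 0.1,
                           anchor = "centered", circular = TRUE) {
  stop_if_not(length(ip) == length(input) && length(ip) >= 1,
              "need equal, non-empty IP and input replicate lists")
  len <- ip[[1]]$genome_length
  scaled <- function(rs) {
    scale_track(coverage_track(extend_reads(rs, fragment_length), len,
                               circular = circular))
  }
  ratios <- lapply(seq_along(ip), function(r) {
    ratio_track(scaled(ip[[r]]), scaled(input[[r]]), pseudocount)
  })
  mr <- mean_ratio_track(ratios)
  list(mean_ratio = mr,
       log2_track = log2(mr),
       occupancy = window_occupancy(mr, genes, window, anchor = anchor,
                                    circular = circular),
       replicate_ratios = ratios)
}

#' Occupancy for both conditions of a simulated experiment
#'
#' Convenience wrapper running [chip_occupancy()] on the `control` and
#' `copper_shock` read sets of [simulate_regulon_experiment()] output and
#' merging the per-gene occupancies into one table.
#'
#' @param experiment output of [simulate_regulon_experiment()].
#' @param ... passed to [chip_occupancy()].
#' @return data frame `gene_id`, `occupancy_control`, `occupancy_shock`.
#' @export
experiment_occupancy <- function(experiment, ...) {
  genes <- experiment$genome$genes
  occ_c <- chip_occupancy(experiment$chip$control$ip,
                          experiment$chip$control$input, genes, ...)$occupancy
  occ_s <- chip_occupancy(experiment$chip$copper_shock$ip,
                          experiment$chip$copper_shock$input, genes, ...)$occupancy
  data.frame(gene_id = occ_c$gene_id,
             occupancy_control = occ_c$occupancy,
             occupancy_shock = occ_s$occupancy,
             stringsAsFactors = FALSE)
}

#' Write a per-position track as bedGraph
#'
#' Runs of equal value are collapsed into intervals (0-based half-open,
#' 4 columns).
#'
#' @param values numeric per-position track.
#' @param path output path.
#' @param chrom chromosome name.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(values, path, chrom = "synthetic_chr") {
  r <- rle(as.numeric(values))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    score = r$values)
  suppressWarnings(rtracklayer::export(gr, path, format = "bedGraph"))
  invisible(path)
}

#' Write an occupancy table as TSV
#'
#' @param occupancy data frame as from [experiment_occupancy()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_occupancy_tsv <- function(occupancy, path) {
  write.table(occupancy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
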