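#' Read set container
#'
#' A `read_set` holds mapped single-end reads as 0-based 5' positions plus
#' strands on one chromosome — the minimal representation the occupancy
#' stage needs (alignment itself is out of scope; synthetic reads arrive
#' pre-mapped).
#'
#' @param position integer vector of 0-based 5' coordinates.
#' @param strand character vector of "+"/"-" per read.
#' @param genome_length chromosome length in bases.
#' @param label free-text sample label.
#' @return an object of class `read_set`.
#' @export
read_set <- function(position, strand, genome_length, label = "") {
  stop_if_not(length(position) == length(strand), "position/strand length mismatch")
  stop_if_not(all(position >= 0 & position < genome_length),
              "read positions must lie in [0, genome_length)")
  stop_if_not(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  structure(list(position = as.integer(position), strand = strand,
                 genome_length = as.integer(genome_length), label = label),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s: %d reads on %d bp\n", x$label,
              length(x$position), x$genome_length))
  invisible(x)
}

#' Simulate ChIP IP and input read sets
#'
#' Input reads start uniformly on the (circular) genome.  IP reads follow a
#' mixture: with probability `k * a / (1 + k * a)`, where
#' `a = enrichment * 2 * site_halfwidth / genome_length` and `k` is the
#' number of sites, a read starts uniformly within `site_halfwidth` bases
#' of a (uniformly chosen) site center; otherwise it starts uniformly.
#' `enrichment = 1` therefore collapses the IP distribution to uniform.
#' Strands are drawn 50/50 and each replicate uses an independent sub-seed,
#' so replicates are reproducibly distinct.
#'
#' @param genome a [genome()] object.
#' @param sites data frame of planted sites (needs a `center` column), as
#'   returned by [plant_motif()]; may have zero rows.
#' @param n_reads reads per sample (exactly this many are emitted).
#' @param enrichment IP read-density multiplier at sites (>= 1).
#' @param site_halfwidth half-width of the enriched window (bases).
#' @param n_replicates biological replicates per sample type.
#' @param seed master seed; replicate r of sample type s is seeded with a
#'   hash of `(seed, s, r)`.
#' @param label_prefix prefix for sample labels.
#' @return list with elements `ip` and `input`, each a list of
#'   `n_replicates` [read_set()] objects.
#' @export
simulate_chip_reads <- function(genome, sites, n_reads, enrichment = 20,
                                site_halfwidth = 150L, n_replicates = 3L,
                                seed = 1L, label_prefix = "chip") {
  stop_if_not(enrichment >= 1, "enrichment must be >= 1")
  stop_if_not(n_reads > 0, "n_reads must be positive")
  len <- genome$length
  k <- if (is.null(sites)) 0L else nrow(sites)
  # only the *excess* over uniform density is routed through the site
  # component, so in-window density is exactly `enrichment` times the
  # background density and enrichment = 1 is exactly uniform
  a_excess <- (enrichment - 1) * (2 * site_halfwidth) / len
  p_site <- if (k > 0) k * a_excess / (1 + k * a_excess) else 0

  draw_sample <- function(stype, r, is_ip) {
    with_seed(sub_seed(seed, stype, r), {
      pos <- sample.int(len, n_reads, replace = TRUE) - 1L
      if (is_ip && p_site > 0) {
        hit <- runif(n_reads) < p_site
        n_hit <- sum(hit)
        if (n_hit > 0) {
          which_site <- sample.int(k, n_hit, replace = TRUE)
          offset <- sample.int(2 * site_halfwidth, n_hit, replace = TRUE) -
            site_halfwidth - 1L
          pos[hit] <- wrap_pos(sites$center[which_site] + offset, len)
        }
      }
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      read_set(pos, strand, len,
               sprintf("%s_%s_rep%d", label_prefix,
                       if (is_ip) "IP" else "input", r))
    })
  }
  list(
    ip = lapply(seq_len(n_replicates), function(r) draw_sample(1L, r, TRUE)),
    input = lapply(seq_len(n_replicates), function(r) draw_sample(2L, r, FALSE))
  )
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Counts follow `NB(mean = sf_j * base_mean_g * 2^(lfc_g * shock_j),
#' variance = mu + alpha * mu^2)`; `alpha = 0` degenerates to Poisson.
#' Samples are laid out as `n_replicates` control columns followed by
#' `n_replicates` treated ("copper_shock") columns.
#'
#' @param gene_ids character vector of gene ids (row names).
#' @param base_mean scalar or per-gene vector of untreated mean counts.
#' @param log2fc scalar or per-gene vector of planted log2 fold changes
#'   (treated vs control); 0 for unaffected genes.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param n_replicates replicates per condition.
#' @param size_factors per-sample depth multipliers (length
#'   `2 * n_replicates`); default all 1.
#' @param seed integer seed.
#' @return list of class `count_matrix` with elements `counts` (integer
#'   matrix, genes x samples), `condition` (factor with levels `control`,
#'   `copper_shock`) and `base_mean`, `log2fc` as used.
#' @export
simulate_counts <- function(gene_ids, base_mean = 500, log2fc = 0,
                            dispersion = 0.05, n_replicates = 3L,
                            size_factors = NULL, seed = 1L) {
  stop_if_not(dispersion >= 0, "dispersion must be >= 0")
  n_genes <- length(gene_ids)
  n_samples <- 2L * n_replicates
  if (is.null(size_factors)) size_factors <- rep(1, n_samples)
  stop_if_not(length(size_factors) == n_samples && all(size_factors > 0),
              "size_factors must be positive, one per sample")
  base_mean <- rep_len(base_mean, n_genes)
  log2fc <- rep_len(log2fc, n_genes)
  shock <- rep(c(0, 1), each = n_replicates)
  condition <- factor(rep(c("control", "copper_shock"), each = n_replicates),
                      levels = c("control", "copper_shock"))
  with_seed(seed, {
    counts <- matrix(0L, n_genes, n_samples)
    for (j in seq_len(n_samples)) {
      mu <- size_factors[j] * base_mean * 2^(log2fc * shock[j])
      counts[, j] <- if (dispersion == 0) {
        stats::rpois(n_genes, mu)
      } else {
        rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      }
    }
    dimnames(counts) <- list(gene_ids,
                             paste0(rep(c("control_", "shock_"), each = n_replicates),
                                    rep(seq_len(n_replicates), 2)))
    structure(list(counts = counts, condition = condition,
                   base_mean = base_mean, log2fc = log2fc),
              class = "count_matrix")
  })
}

#' Simulate a complete regulon experiment
#'
#' Builds the full synthetic study the pipeline is tested on: a circular
#' genome with annotated genes, a planted regulon whose promoters carry one
#' realization of the binding-site consensus each, ChIP IP/input read sets
#' in biological triplicate for two conditions (binding is condition-
#' independent, as for a constitutively bound regulator), and an NB count
#' matrix with induction only at regulon genes.  A truth record for
#' recovery scoring is attached.
#'
#' @param n_genes number of genes.
#' @param n_regulon number of regulon genes (with planted site + induction).
#' @param genome_length genome length in bases.
#' @param consensus IUPAC binding-site consensus planted at regulon promoters.
#' @param offset_upstream site-to-TSS gap in bases.
#' @param enrichment ChIP enrichment at sites.
#' @param n_reads reads per ChIP sample.
#' @param site_halfwidth enriched-window half-width (bases).
#' @param n_replicates replicates per sample type and condition.
#' @param base_mean median untreated expression level (counts); per-gene
#'   means are drawn log-normally around it.
#' @param base_mean_sdlog log-sd of the per-gene base-mean draw.
#' @param dispersion NB dispersion.
#' @param log2fc_ladder planted induction sizes cycled over regulon genes.
#' @param gc genome GC fraction.
#' @param seed master seed.
#' @return list with elements `genome`, `sites`, `truth`
#'   (`regulon_gene_ids`, `planted_sites`, `log2_fold_changes`,
#'   `chip_enrichment`), `chip` (per condition: `ip`, `input` read-set
#'   lists) and `counts` (a `count_matrix`).
#' @export
simulate_regulon_experiment <- function(n_genes = 200L, n_regulon = 10L,
                                        genome_length = 150000L,
                                        consensus = "TTNNCAWWWTGNNAA",
                                        offset_upstream = 30L,
                                        enrichment = 20, n_reads = 50000L,
                                        site_halfwidth = 150L,
                                        n_replicates = 3L,
                                        base_mean = 500, base_mean_sdlog = 0.7,
                                        dispersion = 0.05,
                                        log2fc_ladder = c(2.5, 6.14, 8.2),
                                        gc = 0.45, seed = 1L) {
  gen <- generate_genome(genome_length, n_genes, gc = gc,
                         seed = sub_seed(seed, 1))
  regulon_ids <- with_seed(sub_seed(seed, 2),
                           sort(sample(gen$genes$gene_id, n_regulon)))
  planted <- plant_motif(gen, consensus, regulon_ids,
                         offset_upstream = offset_upstream,
                         seed = sub_seed(seed, 3))
  gen <- planted$genome
  lfc <- setNames(rep(0, n_genes), gen$genes$gene_id)
  lfc[regulon_ids] <- rep_len(log2fc_ladder, n_regulon)
  base_means <- with_seed(sub_seed(seed, 4),
                          stats::rlnorm(n_genes, meanlog = log(base_mean),
                                        sdlog = base_mean_sdlog))
  chip <- list(
    control = simulate_chip_reads(gen, planted$sites, n_reads, enrichment,
                                  site_halfwidth, n_replicates,
                                  seed = sub_seed(seed, 5),
                                  label_prefix = "control"),
    copper_shock = simulate_chip_reads(gen, planted$sites, n_reads, enrichment,
                                       site_halfwidth, n_replicates,
                                       seed = sub_seed(seed, 6),
                                       label_prefix = "shock"))
  counts <- simulate_counts(gen$genes$gene_id, base_mean = base_means,
                            log2fc = unname(lfc), dispersion = dispersion,
                            n_replicates = n_replicates,
                            seed = sub_seed(seed, 7))
  truth <- list(regulon_gene_ids = regulon_ids,
                planted_sites = planted$sites,
                log2_fold_changes = lfc,
                chip_enrichment = enrichment)
  list(genome = gen, sites = planted$sites, truth = truth, chip = chip,
       counts = counts)
}

#' Write reads as 6-column BED
#'
#' One record per read: a 1-base interval anchored at the 5' position,
#' strand in column 6 (0-based half-open convention).
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @param chrom chromosome name for column 1.
#' @return invisibly, `path`.
#' @export
write_reads_bed <- function(reads, path, chrom = "synthetic_chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = reads$position + 1L, width = 1L),
    strand = reads$strand)
  S4Vectors::mcols(gr)$name <- sprintf("read_%d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a 6-column BED of mapped reads
#'
#' @param path BED path.
#' @param genome_length chromosome length (bases).
#' @param label sample label.
#' @return a [read_set()].
#' @export
read_reads_bed <- function(path, genome_length, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "bed")
  read_set(GenomicRanges::start(gr) - 1L,
           as.character(GenomicRanges::strand(gr)),
           genome_length, label)
}

#' Write / read a count matrix as TSV
#'
#' Plain gene-by-sample TSV with a `gene_id` first column.
#'
#' @param counts a `count_matrix` (or plain integer matrix).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Write the synthetic truth record as JSON
#'
#' @param truth the `truth` element of [simulate_regulon_experiment()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(regulon_gene_ids = truth$regulon_gene_ids,
         planted_sites = truth$planted_sites,
         log2_fold_changes = as.list(truth$log2_fold_changes),
         chip_enrichment = truth$chip_enrichment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
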