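#' Synthetic genome container
#'
#' A `genome` object bundles a single (by default circular) chromosome
#' sequence with a minimal gene annotation.  It is the single source of
#' coordinates for the whole pipeline: all positions are 0-based, gene
#' intervals are half-open `[start, end)`, and the TSS of a gene is its
#' first transcribed base (`start` on the plus strand, `end - 1` on the
#' minus strand).
#'
#' @param name chromosome name.
#' @param sequence DNA string over A/C/G/T.
#' @param genes data frame with columns `gene_id`, `start`, `end`,
#'   `strand`, `tss`, `length` (0-based half-open coordinates).
#' @param circular logical; coordinate arithmetic wraps modulo the genome
#'   length when `TRUE`.
#' @return an object of class `genome`.
#' @export
genome <- function(name, sequence, genes = empty_gene_table(), circular = TRUE) {
  stop_if_not(nchar(sequence) > 0, "genome sequence must be non-empty")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) > 0) {
    stop_if_not(all(genes$start < genes$end), "gene intervals must satisfy start < end")
    stop_if_not(all(genes$start >= 0 & genes$end <= nchar(sequence)),
                "gene intervals must lie within [0, genome length)")
    o <- order(genes$start)
    go <- genes[o, ]
    if (nrow(go) > 1) {
      stop_if_not(all(go$start[-1] >= go$end[-nrow(go)]),
                  "gene intervals must be pairwise non-overlapping")
    }
    stop_if_not(all(genes$tss >= genes$start & genes$tss < genes$end),
                "gene TSS must lie within the gene interval")
  }
  structure(list(name = name, sequence = toupper(sequence),
                 length = nchar(sequence), circular = circular,
                 genes = genes),
            class = "genome")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), tss = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp (%s), %d genes\n", x$name, x$length,
              if (x$circular) "circular" else "linear", nrow(x$genes)))
  invisible(x)
}

#' Generate a random annotated genome
#'
#' Draws a random DNA sequence at a given GC content and packs
#' non-overlapping genes onto it, alternating strands by a seeded draw and
#' keeping at least `min_intergenic` bases between consecutive gene bodies
#' so that promoter windows stay intergenic.  Intended as a toy stand-in
#' for a small prokaryotic chromosome.
#'
#' @param length genome length in bases.
#' @param n_genes number of genes to place.
#' @param min_intergenic minimum gap between consecutive gene bodies (bases).
#' @param gc target GC fraction of the random sequence.
#' @param gene_length_range min/max gene body length (bases).
#' @param circular logical, see [genome()].
#' @param seed integer seed; the whole construction is a pure function of
#'   the arguments and the seed.
#' @return a [genome()] object.
#' @export
generate_genome <- function(length, n_genes, min_intergenic = 150, gc = 0.5,
                            gene_length_range = c(300L, 900L),
                            circular = TRUE, seed = 1L) {
  stop_if_not(length > 0, "genome length must be positive")
  stop_if_not(n_genes >= 0, "n_genes must be non-negative")
  min_gene <- gene_length_range[1]
  if (n_genes * (min_gene + min_intergenic) > length) {
    stop("infeasible packing: n_genes * (min gene length + min_intergenic) exceeds genome length",
         call. = FALSE)
  }
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seq <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
                 collapse = "")
    if (n_genes == 0) return(genome("synthetic_chr", seq, circular = circular))
    # draw gene lengths, shrinking if the draw over-packs
    glen <- sample(seq.int(gene_length_range[1], gene_length_range[2]),
                   n_genes, replace = TRUE)
    while (sum(glen) + n_genes * min_intergenic > length) {
      glen <- pmax(min_gene, glen - min_intergenic)
      if (all(glen == min_gene)) break
    }
    stop_if_not(sum(glen) + n_genes * min_intergenic <= length,
                "infeasible packing after length draw")
    # distribute the slack over the n_genes gaps at random
    slack <- length - sum(glen) - n_genes * min_intergenic
    extra <- if (slack > 0) {
      cuts <- sort(sample.int(slack + n_genes - 1, n_genes - 1))
      diff(c(0L, cuts, slack + n_genes - 1L)) - 1L
    } else rep(0L, n_genes)
    gap <- min_intergenic + extra
    start <- cumsum(c(gap[1], head(glen, -1) + gap[-1]))
    end <- start + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- ifelse(strand == "+", start, end - 1L)
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      start = as.integer(start), end = as.integer(end),
      strand = strand, tss = as.integer(tss), length = as.integer(glen),
      stringsAsFactors = FALSE)
    genome("synthetic_chr", seq, genes, circular = circular)
  })
}

#' Realize an IUPAC consensus into a concrete DNA word
#'
#' Degenerate positions are drawn uniformly from their allowed bases.
#'
#' @param consensus IUPAC string.
#' @return a concrete DNA string of the same width.
#' @export
iupac_realize <- function(consensus) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  sets <- IUPAC_SETS[letters]
  stop_if_not(!any(vapply(sets, is.null, logical(1))),
              "consensus contains non-IUPAC characters")
  paste(vapply(sets, function(s) if (length(s) == 1) s else sample(s, 1),
               character(1)), collapse = "")
}

# replace `width` bases starting at 0-based genomic position `pos`
# (wrapping on circular genomes) with `word`
splice_sequence <- function(seq, pos, word, circular) {
  len <- nchar(seq)
  w <- nchar(word)
  if (pos + w <= len) {
    substr(seq, pos + 1, pos + w) <- word
    return(seq)
  }
  stop_if_not(circular, "site overhangs a linear genome end")
  n1 <- len - pos
  substr(seq, pos + 1, len) <- substr(word, 1, n1)
  substr(seq, 1, w - n1) <- substr(word, n1 + 1, w)
  seq
}

#' Plant realizations of a binding-site consensus upstream of target genes
#'
#' For each target gene, one realization of the IUPAC consensus (degenerate
#' positions drawn uniformly) overwrites the genomic sequence so that, read
#' on the gene's strand, the site ends `offset_upstream` bases 5' of the
#' TSS.  All other sequence is untouched.  The default consensus is the
#' palindromic archaeal copper-box `TTNNCAWWWTGNNAA`.
#'
#' @param genome a [genome()] object.
#' @param consensus IUPAC consensus to realize at each target promoter.
#' @param target_gene_ids character vector of gene ids to receive a site.
#' @param offset_upstream gap (bases) between the site's 3' edge and the TSS.
#' @param seed integer seed for the degenerate-base draws.
#' @return list with elements `genome` (modified) and `sites`, a data frame
#'   with one row per planted site: `gene_id`, `position` (0-based genomic
#'   start), `strand`, `center` (genomic center), and `site_seq` (the
#'   realized word in gene-strand orientation).
#' @export
plant_motif <- function(genome, consensus = "TTNNCAWWWTGNNAA",
                        target_gene_ids = character(), offset_upstream = 30L,
                        seed = 1L) {
  stop_if_not(inherits(genome, "genome"), "genome must be a genome object")
  targets <- genome$genes[genome$genes$gene_id %in% target_gene_ids, , drop = FALSE]
  stop_if_not(nrow(targets) == length(unique(target_gene_ids)),
              "some target_gene_ids are not annotated in the genome")
  w <- nchar(consensus)
  len <- genome$length
  if (nrow(targets) == 0) {
    return(list(genome = genome,
                sites = data.frame(gene_id = character(), position = integer(),
                                   strand = character(), center = integer(),
                                   site_seq = character(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    seq <- genome$sequence
    out <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      g <- targets[i, ]
      word <- iupac_realize(consensus)
      if (g$strand == "+") {
        pos <- wrap_pos(g$tss - offset_upstream - w, len)
        genomic_word <- word
      } else {
        pos <- wrap_pos(g$tss + offset_upstream + 1, len)
        genomic_word <- revcomp(word)
      }
      site_pos <- wrap_pos(pos + seq.int(0, w - 1), len)
      for (j in seq_len(nrow(genome$genes))) {
        body <- genome$genes[j, ]
        if (any(site_pos >= body$start & site_pos < body$end)) {
          stop(sprintf("planted site for %s collides with gene body %s",
                       g$gene_id, body$gene_id), call. = FALSE)
        }
      }
      seq <- splice_sequence(seq, pos, genomic_word, genome$circular)
      out[[i]] <- data.frame(gene_id = g$gene_id, position = pos,
                             strand = g$strand,
                             center = wrap_pos(pos + w %/% 2, len),
                             site_seq = word, stringsAsFactors = FALSE)
    }
    genome$sequence <- seq
    list(genome = genome, sites = do.call(rbind, out))
  })
}

#' Extract a subsequence with circular wrap
#'
#' @param genome a [genome()] object.
#' @param start 0-based start.
#' @param width width in bases.
#' @return character subsequence of length `width`.
#' @export
genome_subseq <- function(genome, start, width) {
  len <- genome$length
  start <- wrap_pos(start, len)
  if (start + width <= len) {
    substr(genome$sequence, start + 1, start + width)
  } else {
    stop_if_not(genome$circular, "window overhangs a linear genome end")
    paste0(substr(genome$sequence, start + 1, len),
           substr(genome$sequence, 1, width - (len - start)))
  }
}

#' Intergenic sequences of a genome
#'
#' Returns the sequences between consecutive gene bodies (wrapping across
#' the origin on circular genomes); used as the background model for motif
#' discovery and scanning.
#'
#' @param genome a [genome()] object.
#' @return character vector of intergenic sequences.
#' @export
intergenic_sequences <- function(genome) {
  g <- genome$genes[order(genome$genes$start), , drop = FALSE]
  if (nrow(g) == 0) return(genome$sequence)
  starts <- g$end
  ends <- c(g$start[-1], g$start[1] + genome$length)
  widths <- ends - starts
  keep <- widths > 0
  mapply(function(s, w) genome_subseq(genome, s, w),
         starts[keep], widths[keep], USE.NAMES = FALSE)
}

#' Write a genome to FASTA and GFF3
#'
#' @param genome a [genome()] object.
#' @param fasta,gff3 output paths (either may be `NULL` to skip).
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta = NULL, gff3 = NULL) {
  if (!is.null(fasta)) {
    x <- Biostrings::DNAStringSet(genome$sequence)
    names(x) <- genome$name
    Biostrings::writeXStringSet(x, fasta)
  }
  if (!is.null(gff3) && nrow(genome$genes) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$name,
      ranges = IRanges::IRanges(start = genome$genes$start + 1L,
                                end = genome$genes$end),
      strand = genome$genes$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- genome$genes$gene_id
    rtracklayer::export(gr, gff3, format = "gff3")
  }
  invisible(genome)
}

#' Read a genome from FASTA and GFF3
#'
#' Inverse of [write_genome()]: the first FASTA record becomes the
#' chromosome; GFF3 `gene` records (1-based inclusive) are converted back
#' to 0-based half-open intervals, with the TSS recomputed from the strand.
#'
#' @param fasta path to a FASTA file.
#' @param gff3 optional path to a GFF3 annotation.
#' @param circular logical, see [genome()].
#' @return a [genome()] object.
#' @export
read_genome <- function(fasta, gff3 = NULL, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(fasta)
  seq <- as.character(x[[1]])
  genes <- empty_gene_table()
  if (!is.null(gff3)) {
    gr <- rtracklayer::import(gff3, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    start <- GenomicRanges::start(gr) - 1L
    end <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    genes <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gr)$ID),
      start = start, end = end, strand = strand,
      tss = ifelse(strand == "+", start, end - 1L),
      length = end - start, stringsAsFactors = FALSE)
  }
  genome(names(x)[1], seq, genes, circular = circular)
}
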