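# shared fixtures and independent oracle helpers

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# literal reverse complement, independent of the package's revcomp
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           W = "W", S = "S", R = "Y", Y = "R", K = "M", M = "K")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# IUPAC pattern -> regex character classes
iupac_regex <- function(pattern) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
            S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
            D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(sets[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

# brute-force per-position coverage of half-open intervals with wrap
oracle_coverage <- function(intervals, len) {
  v <- numeric(len)
  for (i in seq_len(nrow(intervals))) {
    pos <- seq.int(intervals$start[i], intervals$end[i] - 1L)
    pos <- ((pos %% len) + len) %% len
    for (p in pos) v[p + 1] <- v[p + 1] + 1
  }
  v
}

# a small ready-made planted-motif genome for motif tests
make_planted_promoters <- function(n_seq = 30, seed = 1,
                                   consensus = "TTNNCAWWWTGNNAA",
                                   genome_length = 200000, n_genes = 60) {
  g <- generate_genome(genome_length, n_genes, gc = 0.45, seed = seed)
  targets <- g$genes$gene_id[seq_len(n_seq)]
  pl <- plant_motif(g, consensus, targets, offset_upstream = 30,
                    seed = seed + 1)
  windows <- extract_anchored(pl$genome,
                              pl$genome$genes[pl$genome$genes$gene_id %in% targets, ],
                              from_pos = -60, to_pos = 0)
  bg <- estimate_background(intergenic_sequences(pl$genome))
  list(genome = pl$genome, sites = pl$sites, windows = windows,
       background = bg)
}

# count positions where the IUPAC set of `consensus` is a subset of the
# IUPAC set of `pattern`, over the best ungapped alignment (shifts -3..3);
# pattern positions not covered by the consensus count as mismatches
iupac_subset_matches <- function(consensus, pattern, max_shift = 3) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  pc <- strsplit(toupper(pattern), "")[[1]]
  best <- 0L
  for (cons in c(consensus, oracle_revcomp(consensus))) {
    cc <- strsplit(toupper(cons), "")[[1]]
    for (shift in -max_shift:max_shift) {
      hits <- 0L
      for (i in seq_along(pc)) {
        j <- i + shift
        if (j >= 1 && j <= length(cc) &&
            all(sets[[cc[j]]] %in% sets[[pc[i]]])) {
          hits <- hits + 1L
        }
      }
      best <- max(best, hits)
    }
  }
  best
}
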