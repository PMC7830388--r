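test_that("anchored windows apply the TSS coordinate convention literally", {
  seq <- random_dna(5000, seed = 37)
  genes <- data.frame(gene_id = c("plus", "minus"),
                      start = c(1000L, 3000L), end = c(1400L, 3400L),
                      strand = c("+", "-"),
                      tss = c(1000L, 3399L), length = 400L,
                      stringsAsFactors = FALSE)
  g <- genome("chr", seq, genes)
  set <- extract_anchored(g, from_pos = -150, to_pos = 50)
  expect_equal(unname(nchar(set$sequences)), c(200, 200))
  expect_equal(set$positions, -150:49)
  # plus-strand gene: genomic slice [850, 1050)
  expect_equal(set$sequences[["plus"]], substr(seq, 851, 1050))
  # minus-strand gene, TSS at 3399: window spans genomic [3350, 3550)
  # (r = -150 is genomic 3549, r = +49 is genomic 3350), reverse-complemented
  expect_equal(set$sequences[["minus"]], oracle_revcomp(substr(seq, 3351, 3550)))
  unit <- extract_anchored(g, from_pos = -1, to_pos = 0)
  expect_equal(unit$sequences[["plus"]], substr(seq, 1000, 1000))
})

test_that("minus-strand windows equal a coordinate-walking oracle", {
  g <- generate_genome(20000, 10, seed = 41)
  set <- extract_anchored(g, from_pos = -30, to_pos = 10)
  chars <- strsplit(g$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in which(g$genes$strand == "-")) {
    tss <- g$genes$tss[i]
    # walk outward: relative position r is genomic tss - r, complemented
    oracle <- paste(vapply(-30:9, function(r) {
      comp[[chars[((tss - r) %% 20000) + 1]]]
    }, character(1)), collapse = "")
    expect_equal(set$sequences[[g$genes$gene_id[i]]], oracle)
  }
})

test_that("positional enrichment is zero on identity and antisymmetric", {
  g <- generate_genome(30000, 20, seed = 43)
  a <- extract_anchored(g, g$genes[1:10, ], -50, 10, label = "target")
  b <- extract_anchored(g, g$genes[11:20, ], -50, 10, label = "background")
  self <- positional_enrichment(a, a)
  expect_true(all(self$enrichment == 0))
  ab <- positional_enrichment(a, b)
  ba <- positional_enrichment(b, a)
  expect_equal(ab$enrichment, -ba$enrichment)
  # frequencies at each position sum to 1 (pre-pseudocount raw counts)
  raw <- colSums(ab$freq_target)
  expect_equal(unname(raw), rep(1, ncol(ab$freq_target)), tolerance = 1e-12)
})

test_that("a planted homogeneous position matches a hand count", {
  seqs_t <- c(a = "CAT", b = "CAA", c = "CTT")
  seqs_b <- c(x = "ATA", y = "CGC", z = "GAT", w = "TTG")
  target <- structure(list(sequences = seqs_t, positions = 0:2,
                           from = 0L, to = 3L, label = "t"),
                      class = "anchored_set")
  background <- structure(list(sequences = seqs_b, positions = 0:2,
                               from = 0L, to = 3L, label = "b"),
                          class = "anchored_set")
  enr <- positional_enrichment(target, background, pseudocount = 1)
  # position 1: target all C (3/3), background 1 C of 4
  ft <- (3 + 1) / (3 + 4)
  fb <- (1 + 1) / (4 + 4)
  expect_equal(enr$enrichment["C", 1], log2(ft / fb))
  expect_true(all(enr$enrichment[c("A", "G", "T"), 1] < 0))
})

test_that("the trinucleotide scale expands to a consistent 64-entry map", {
  scale <- synthetic_bendability_scale()
  expect_length(unclass(scale), 64)
  for (tri in names(unclass(scale))) {
    expect_equal(unclass(scale)[[tri]], unclass(scale)[[oracle_revcomp(tri)]])
  }
  bad <- data.frame(trinucleotide = c("AAA", "TTT"), value = c(0.1, 0.2))
  expect_error(trinucleotide_scale(bad), "conflicting")
})

test_that("a homopolymer window gives a flat profile at the scale value", {
  bases <- c("A", "C", "G", "T")
  all_tris <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  toy_df <- data.frame(trinucleotide = all_tris, value = 0)
  toy_df$value[toy_df$trinucleotide %in% c("AAA", "TTT")] <- -0.27
  toy <- trinucleotide_scale(toy_df)
  windows <- structure(list(sequences = c(s1 = strrep("A", 30),
                                          s2 = strrep("A", 30)),
                            positions = -15:14, from = -15L, to = 15L,
                            label = "t"),
                       class = "anchored_set")
  prof <- bendability_profile(windows, toy, span = 5, n_boot = 100, seed = 1)
  expect_equal(unname(prof$mean), rep(-0.27, 28))
  expect_equal(unname(prof$smoothed), rep(-0.27, 28))
})

test_that("unsmoothed means equal a brute-force per-sequence loop", {
  g <- generate_genome(20000, 12, seed = 47)
  windows <- extract_anchored(g, from_pos = -40, to_pos = 20)
  scale <- synthetic_bendability_scale()
  prof <- bendability_profile(windows, scale, span = 11, n_boot = 50, seed = 2)
  vals <- unclass(scale)
  for (j in c(1, 10, 30, 58)) {
    per_seq <- vapply(windows$sequences, function(s)
      vals[[substr(s, j, j + 2)]], numeric(1))
    expect_equal(unname(prof$mean[j]), mean(per_seq))
  }
})

test_that("bootstrap bands are seeded-deterministic and bracket the mean", {
  g <- generate_genome(15000, 10, seed = 53)
  windows <- extract_anchored(g, from_pos = -30, to_pos = 10)
  scale <- synthetic_bendability_scale()
  p1 <- bendability_profile(windows, scale, n_boot = 200, seed = 5)
  p2 <- bendability_profile(windows, scale, n_boot = 200, seed = 5)
  expect_identical(p1$lower, p2$lower)
  expect_identical(p1$upper, p2$upper)
  expect_true(all(p1$lower <= p1$smoothed + 1e-12))
  expect_true(all(p1$upper >= p1$smoothed - 1e-12))
})

test_that("the bootstrap band covers the analytic mean for i.i.d. sequences", {
  set.seed(59)
  scale <- synthetic_bendability_scale()
  seqs <- vapply(1:60, function(i) random_dna(120, gc = 0.5), character(1))
  names(seqs) <- sprintf("s%02d", 1:60)
  windows <- structure(list(sequences = seqs, positions = -60:59,
                            from = -60L, to = 60L, label = "t"),
                       class = "anchored_set")
  prof <- bendability_profile(windows, scale, span = 11, n_boot = 500,
                              seed = 7)
  analytic <- mean(unclass(scale))  # uniform i.i.d. base draw
  covered <- mean(prof$lower <= analytic & prof$upper >= analytic)
  expect_gte(covered, 0.9)
})

test_that("profile comparison localises a planted rigid block", {
  set.seed(61)
  scale <- synthetic_bendability_scale()
  vals <- unclass(scale)
  rigid <- names(sort(vals))[1:6]  # most negative trinucleotide classes
  make_seq <- function(plant) {
    s <- random_dna(200, gc = 0.5)
    if (plant) {
      block <- paste(sample(rigid, 14, replace = TRUE), collapse = "")
      substr(s, 31, 72) <- block  # relative -120..-79 of a -150..+50 window
    }
    s
  }
  t_seqs <- vapply(1:40, function(i) make_seq(TRUE), character(1))
  b_seqs <- vapply(1:40, function(i) make_seq(FALSE), character(1))
  names(t_seqs) <- sprintf("t%02d", 1:40)
  names(b_seqs) <- sprintf("b%02d", 1:40)
  as_set <- function(seqs, label) {
    structure(list(sequences = seqs, positions = -150:49, from = -150L,
                   to = 50L, label = label), class = "anchored_set")
  }
  pt <- bendability_profile(as_set(t_seqs, "t"), scale, n_boot = 200, seed = 11)
  pb <- bendability_profile(as_set(b_seqs, "b"), scale, n_boot = 200, seed = 12)
  cmp <- compare_profiles(pt, pb, n_boot = 200, seed = 13)
  min_pos <- cmp$positions[which.min(cmp$difference)]
  expect_gte(min_pos, -120)
  expect_lte(min_pos, -80)
  self <- compare_profiles(pt, pt, n_boot = 50, seed = 14)
  expect_equal(unname(self$difference), rep(0, length(self$difference)))
})

test_that("difference of means equals mean of per-sequence differences", {
  g <- generate_genome(30000, 16, seed = 67)
  scale <- synthetic_bendability_scale()
  w1 <- extract_anchored(g, g$genes[1:8, ], -40, 20)
  w2 <- extract_anchored(g, g$genes[9:16, ], -40, 20)
  p1 <- bendability_profile(w1, scale, span = 1, n_boot = 50, seed = 1)
  p2 <- bendability_profile(w2, scale, span = 1, n_boot = 50, seed = 1)
  cmp <- compare_profiles(p1, p2, n_boot = 50, seed = 2)
  paired <- colMeans(p1$matrix) - colMeans(p2$matrix)
  expect_equal(unname(cmp$difference), unname(paired))
})

test_that("reverse-complementing windows mirrors the bendability profile", {
  g <- generate_genome(10000, 6, seed = 71)
  scale <- synthetic_bendability_scale()
  w <- extract_anchored(g, from_pos = -25, to_pos = 25)
  w_rc <- w
  w_rc$sequences <- vapply(w$sequences, oracle_revcomp, character(1))
  p <- bendability_profile(w, scale, span = 1, n_boot = 50, seed = 1)
  p_rc <- bendability_profile(w_rc, scale, span = 1, n_boot = 50, seed = 1)
  expect_equal(unname(p_rc$mean), rev(unname(p$mean)))
})
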