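test_that("background estimation is strand-symmetric and matches counts", {
  bg <- estimate_background(strrep("ACGT", 100))
  expect_equal(unname(bg), rep(0.25, 4), tolerance = 1e-3)
  bgA <- estimate_background(strrep("A", 200))
  expect_equal(bgA[["A"]], bgA[["T"]])
  expect_equal(bgA[["C"]], bgA[["G"]])
  s <- random_dna(1000, seed = 3, gc = 0.6)
  bg2 <- estimate_background(s)
  cnt <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  oracle <- (as.numeric(cnt) + as.numeric(cnt)[4:1] + 1) /
    (2 * 1000 + 4)
  expect_equal(unname(bg2), oracle)
  expect_error(estimate_background("ACGT"), "100")
})

test_that("the penalised EM objective never decreases", {
  fx <- make_planted_promoters(n_seq = 15, seed = 5)
  m <- zoops_em(fx$windows$sequences, 15, fx$background, n_starts = 3,
                seed = 4)
  for (tr in m$ll_traces) {
    expect_true(all(diff(tr) >= -1e-8))
  }
})

test_that("an exactly planted word is recovered by ZOOPS EM", {
  # one fixed 15-mer planted in every window
  set.seed(139)
  word <- "TGACCTAGGTTCACA"
  seqs <- vapply(1:30, function(i) {
    s <- random_dna(60, gc = 0.5)
    off <- sample(1:(60 - 15 + 1), 1)
    paste0(substr(s, 1, off - 1), word, substr(s, off + 15, 60))
  }, character(1))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  m <- zoops_em(seqs, 15, bg, n_starts = 5, seed = 11)
  cons <- consensus_iupac(m$theta)
  # allow the one-offset phase ambiguity and reverse-complement
  # representation that EM legitimately converges to
  matches <- iupac_subset_matches(cons, word, max_shift = 1)
  expect_gte(matches, 14)
  expect_gt(m$gamma, 0.8)
})

test_that("the occurrence prior is recovered when half the sequences carry a site", {
  set.seed(149)
  word <- "TGACCTAGGTTCACA"
  seqs <- vapply(1:40, function(i) {
    s <- random_dna(60, gc = 0.5)
    if (i <= 20) {
      off <- sample(1:(60 - 15 + 1), 1)
      s <- paste0(substr(s, 1, off - 1), word, substr(s, off + 15, 60))
    }
    s
  }, character(1))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  m <- zoops_em(seqs, 15, bg, n_starts = 5, seed = 13)
  expect_gte(m$gamma, 0.3)
  expect_lte(m$gamma, 0.7)
})

test_that("EM with one start and a fixed seed is bit-reproducible", {
  fx <- make_planted_promoters(n_seq = 10, seed = 17)
  m1 <- zoops_em(fx$windows$sequences, 12, fx$background, n_starts = 1,
                 seed = 99)
  m2 <- zoops_em(fx$windows$sequences, 12, fx$background, n_starts = 1,
                 seed = 99)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$log_likelihood, m2$log_likelihood)
  expect_error(zoops_em(c("ACGT"), 12, fx$background), "shorter")
})

test_that("motifs found in pure background carry less information than planted ones", {
  # at desk scale EM on noise still overfits some pattern, so the null
  # diagnostic is comparative: background motifs are markedly weaker than
  # a genuinely planted one discovered under identical settings
  ic_per_col <- function(m) mean(apply(m$theta, 2, function(col) {
    2 + sum(ifelse(col > 0, col * log2(col), 0))
  }))
  set.seed(151)
  seqs <- vapply(1:20, function(i) random_dna(60, gc = 0.5), character(1))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  m_null <- choose_width(seqs, bg, widths = c(8, 12, 15), seed = 5,
                         n_starts = 2)
  fx <- make_planted_promoters(n_seq = 20, seed = 151)
  m_planted <- zoops_em(fx$windows$sequences, 15, bg, n_starts = 2, seed = 5)
  expect_lt(ic_per_col(m_null), ic_per_col(m_planted))
  expect_lt(ic_per_col(m_null), 1.1)
  expect_equal(m_null$width_scores$width, c(8, 12, 15))
})

test_that("consensus coding follows the major/pair thresholds", {
  th <- cbind(c(0.95, 0.02, 0.02, 0.01),
              c(0.45, 0.05, 0.05, 0.45),
              c(0.25, 0.25, 0.25, 0.25),
              c(0.1, 0.45, 0.42, 0.03))
  rownames(th) <- c("A", "C", "G", "T")
  expect_equal(consensus_iupac(th), "AWNS")
})

test_that("palindromicity scores symmetry correctly", {
  # perfect IUPAC palindrome: ACGT-style complementary columns
  th <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  rownames(th) <- c("A", "C", "G", "T")
  expect_equal(palindromicity(th), 1.0)
  set.seed(157)
  for (i in 1:5) {
    r <- matrix(runif(4 * 6), 4)
    r <- sweep(r, 2, colSums(r), "/")
    rownames(r) <- c("A", "C", "G", "T")
    rc <- r[4:1, 6:1]
    expect_equal(palindromicity(rc), palindromicity(r))  # involution
    oracle <- 1 - mean(sapply(1:6, function(t)
      0.5 * sum(abs(r[, t] - rev(r[, 7 - t])))))
    expect_equal(palindromicity(r), oracle)
  }
})

test_that("DP tail probabilities equal exhaustive enumeration at w = 6", {
  set.seed(163)
  th <- matrix(runif(24, 0.05, 1), 4)
  th <- sweep(th, 2, colSums(th), "/")
  rownames(th) <- c("A", "C", "G", "T")
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  model <- structure(list(width = 6L, theta = th, background = bg),
                     class = "motif_model")
  dist <- pwm_score_distribution(model, granularity = 0.001)
  # oracle: enumerate all 4^6 words with the same integer scores
  si <- round(log2(th / bg) / 0.001)
  grid <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4, b5 = 1:4,
                      b6 = 1:4)
  word_scores <- numeric(nrow(grid))
  word_probs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    b <- as.integer(grid[r, ])
    word_scores[r] <- sum(si[cbind(b, 1:6)])
    word_probs[r] <- prod(bg[b])
  }
  for (s in unique(word_scores)) {
    oracle_tail <- sum(word_probs[word_scores >= s])
    idx <- s - dist$scores[1] + 1
    expect_lt(abs(dist$tail[idx] - oracle_tail), 1e-9)
  }
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
})

test_that("planted sites are recovered by scanning with zero false positives", {
  fx <- make_planted_promoters(n_seq = 25, seed = 19)
  m <- zoops_em(fx$windows$sequences, 15, fx$background, n_starts = 5,
                seed = 21)
  # scan planted promoters plus motif-free promoters
  free <- vapply(1:25, function(i) random_dna(60, gc = 0.45), character(1))
  names(free) <- sprintf("free_%02d", 1:25)
  hits_planted <- scan_pwm(m, fx$windows$sequences, q_threshold = 0.05)
  hits_free <- scan_pwm(m, free, q_threshold = 0.05)
  # planted sites sit at offset 15 of each 60-base window (-45..-31)
  top <- do.call(rbind, lapply(split(as.data.frame(hits_planted),
                                     hits_planted$seq_id),
                               function(d) d[which.min(d$pvalue), ]))
  expect_gte(length(unique(hits_planted$seq_id)), 24)
  expect_true(all(abs(top$offset - 15) <= 1))
  expect_equal(nrow(hits_free), 0)
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  fx <- make_planted_promoters(n_seq = 12, seed = 23)
  m <- zoops_em(fx$windows$sequences, 15, fx$background, n_starts = 3,
                seed = 25)
  s <- fx$windows$sequences[1]
  names(s) <- "fwd"
  s_rc <- setNames(oracle_revcomp(s), "fwd")
  h1 <- scan_pwm(m, s, q_threshold = 1.0000001)
  h2 <- scan_pwm(m, s_rc, q_threshold = 1.0000001)
  key1 <- sort(paste(h1$offset, h1$strand, round(h1$score, 6)))
  key2 <- sort(paste(60 - 15 - h2$offset,
                     ifelse(h2$strand == "+", "-", "+"),
                     round(h2$score, 6)))
  expect_equal(key1, key2)
  short <- scan_pwm(m, c(tiny = "ACGT"))
  expect_equal(nrow(short), 0)
})

test_that("sequences shorter than the motif yield no hits and N is neutral", {
  th <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  th[, 1] <- c(0.7, 0.1, 0.1, 0.1)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  model <- structure(list(width = 4L, theta = th, background = bg),
                     class = "motif_model")
  h <- scan_pwm(model, c(x = "ANGTA"), q_threshold = 1.0000001)
  expect_equal(nrow(h), 4)  # 2 offsets x 2 strands
  # N contributes zero: score of ANGT differs from AAGT only via column 2
  expect_true(all(is.finite(h$score)))
})

test_that("motif export writes a parseable minimal MEME file", {
  fx <- make_planted_promoters(n_seq = 8, seed = 29)
  m <- zoops_em(fx$windows$sequences, 10, fx$background, n_starts = 2,
                seed = 31)
  f <- tempfile(fileext = ".meme")
  write_meme(m, f)
  lines <- readLines(f)
  expect_match(lines[1], "MEME version")
  expect_true(any(grepl("letter-probability matrix", lines)))
  mat_start <- which(grepl("letter-probability", lines)) + 1
  probs <- read.table(text = lines[mat_start:(mat_start + 9)])
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-4)
  unlink(f)
})
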