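#' Estimate a 0-order background model from intergenic sequence
#'
#' Base frequencies with a +1 pseudocount per base, pooled over both
#' strands so the background is strand-symmetric (A/T and C/G pairs have
#' equal frequency).
#'
#' @param sequences character vector of intergenic DNA sequences.
#' @return named numeric vector of A/C/G/T probabilities summing to 1.
#' @export
estimate_background <- function(sequences) {
  total <- sum(nchar(sequences))
  stop_if_not(total >= 100, "need >= 100 bases of background sequence")
  bases <- unlist(strsplit(toupper(paste(sequences, collapse = "")), "",
                           fixed = TRUE))
  cnt <- table(factor(bases, levels = DNA_BASES))
  # pool both strands: add the reverse-complement counts, then +1 per base
  sym <- as.numeric(cnt) + as.numeric(cnt)[4:1] + 1
  setNames(sym / sum(sym), DNA_BASES)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, gamma %.3f, logLik %.2f\n",
              x$width, x$gamma, x$log_likelihood))
  cat("consensus:", consensus_iupac(x$theta), "\n")
  invisible(x)
}

# encode sequences and precompute, for one width, the stacked window
# base-index matrices for both strands plus bookkeeping vectors
window_matrices <- function(encoded, w) {
  w <- as.integer(w)
  per_seq <- lapply(seq_along(encoded), function(i) {
    e <- encoded[[i]]
    m <- length(e) - w + 1L
    stop_if_not(m >= 1, "sequence shorter than the motif width")
    idx <- sapply(seq_len(w), function(t) e[seq_len(m) + t - 1L])
    idx <- matrix(idx, nrow = m)
    # minus-strand window at the same offset: reverse complement
    idx_rc <- 5L - idx[, w:1, drop = FALSE]
    list(plus = idx, minus = idx_rc, m = m, seq = i)
  })
  windows <- do.call(rbind, lapply(per_seq, function(x) rbind(x$plus, x$minus)))
  seq_of <- unlist(lapply(per_seq, function(x) rep(x$seq, 2L * x$m)))
  m_of <- vapply(per_seq, function(x) x$m, integer(1))
  list(windows = windows, seq_of = seq_of, m = m_of)
}

#' ZOOPS EM motif discovery at a fixed width
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) motif model by
#' expectation-maximisation over the latent site location: each sequence
#' either has no site (probability `1 - gamma`) or exactly one site at
#' some offset on either strand (probability `gamma`, uniform over
#' offsets and strands).  The M-step re-estimates the position
#' probability matrix with a Dirichlet pseudocount of 0.01 and the
#' occurrence prior `gamma`.  The best of `n_starts` seeded
#' initialisations (each seeded from a randomly chosen window of the
#' data) is returned; the per-iteration log-likelihood trace of every
#' start is attached for monotonicity checks.
#'
#' @param sequences character vector of DNA sequences (A/C/G/T), each at
#'   least `w` long.
#' @param w motif width.
#' @param background A/C/G/T probability vector ([estimate_background()]).
#' @param n_starts number of EM restarts (>= 1).
#' @param max_iter iteration cap per start.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param seed integer seed.
#' @param pseudocount Dirichlet pseudocount for the M-step.
#' @return object of class `motif_model`: `width`, `theta` (4 x w,
#'   columns sum to 1), `background`, `gamma`, `log_likelihood` (data
#'   log-likelihood of the winning start), `ll_traces` (per-start,
#'   per-iteration traces of the Dirichlet-penalised EM objective — the
#'   quantity EM guarantees non-decreasing), `n_seqs`.
#' @export
zoops_em <- function(sequences, w, background, n_starts = 5L,
                     max_iter = 200L, tol = 1e-6, seed = 1L,
                     pseudocount = 0.01) {
  stop_if_not(n_starts >= 1, "n_starts must be >= 1")
  encoded <- lapply(sequences, encode_dna)
  stop_if_not(!any(vapply(encoded, anyNA, logical(1))),
              "zoops_em requires pure A/C/G/T sequences")
  wm <- window_matrices(encoded, w)
  n <- length(sequences)
  n_win <- nrow(wm$windows)
  log_bg <- log(background)
  # per-sequence background log-likelihood (constant across iterations)
  bg_const <- sum(vapply(encoded, function(e) sum(log_bg[e]), numeric(1)))
  prior_site <- rep(1 / (2 * wm$m), times = 2L * wm$m)  # 1/(2m_i) per window
  col_of <- rep(seq_len(w), each = n_win)

  run_start <- function(theta0, gamma0) {
    theta <- theta0
    gamma <- gamma0
    obj_old <- -Inf
    ll <- -Inf
    trace <- numeric()
    for (iter in seq_len(max_iter)) {
      log_ratio <- log(theta) - log_bg  # 4 x w
      lr <- exp(rowSums(matrix(log_ratio[cbind(as.vector(wm$windows), col_of)],
                               nrow = n_win)))
      r <- gamma * prior_site * lr
      z <- (1 - gamma) + rowsum(r, wm$seq_of)[, 1]
      ll <- bg_const + sum(log(z))
      # the pseudocounted M-step maximises the Dirichlet-penalised
      # objective, which is the quantity EM makes non-decreasing
      obj <- ll + pseudocount * sum(log(theta))
      trace <- c(trace, obj)
      post <- r / z[wm$seq_of]
      gamma_new <- sum(post) / n
      # weighted base counts per motif column
      cnt <- matrix(pseudocount, 4, w)
      for (t in seq_len(w)) {
        s <- rowsum(post, wm$windows[, t])
        b <- as.integer(rownames(s))
        cnt[b, t] <- cnt[b, t] + s[, 1]
      }
      theta_new <- sweep(cnt, 2, colSums(cnt), "/")
      if (obj - obj_old < tol && iter > 1) {
        theta <- theta_new; gamma <- gamma_new
        break
      }
      obj_old <- obj
      theta <- theta_new
      gamma <- gamma_new
    }
    list(theta = theta, gamma = gamma, ll = ll, trace = trace)
  }

  with_seed(seed, {
    runs <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      # seed theta from a randomly chosen data window
      widx <- sample.int(n_win, 1)
      seed_word <- wm$windows[widx, ]
      theta0 <- matrix(0.4 / 3, 4, w)
      theta0[cbind(seed_word, seq_len(w))] <- 0.6
      runs[[s]] <- run_start(theta0, 0.5)
    }
    best <- which.max(vapply(runs, function(r) r$ll, numeric(1)))
    m <- runs[[best]]
    rownames(m$theta) <- DNA_BASES
    structure(list(width = w, theta = m$theta, background = background,
                   gamma = m$gamma, log_likelihood = m$ll,
                   ll_traces = lapply(runs, function(r) r$trace),
                   n_seqs = n),
              class = "motif_model")
  })
}

#' Width selection for ZOOPS motif discovery
#'
#' Runs [zoops_em()] at every candidate width and picks the model
#' maximising a BIC-style criterion,
#' `logLik - 0.5 * (3w + 1) * log(total scanned positions)`, with a
#' deterministic tie-break towards the smaller width.
#'
#' @param sequences character vector of DNA sequences.
#' @param background A/C/G/T probability vector.
#' @param widths candidate widths; default 8:18.
#' @param seed integer seed (each width gets an independent sub-seed).
#' @param ... passed to [zoops_em()].
#' @return the winning `motif_model`, with a `width_scores` data frame
#'   (`width`, `log_likelihood`, `score`) attached.
#' @export
choose_width <- function(sequences, background, widths = 8:18, seed = 1L, ...) {
  stop_if_not(all(widths <= min(nchar(sequences))),
              "candidate widths exceed the shortest sequence")
  widths <- sort(widths)
  models <- lapply(widths, function(w) {
    zoops_em(sequences, w, background, seed = sub_seed(seed, w), ...)
  })
  score <- vapply(seq_along(widths), function(i) {
    w <- widths[i]
    n_pos <- sum(2 * (nchar(sequences) - w + 1))
    models[[i]]$log_likelihood - 0.5 * (3 * w + 1) * log(n_pos)
  }, numeric(1))
  best <- which.max(score)  # first max -> smallest width on ties
  model <- models[[best]]
  model$width_scores <- data.frame(width = widths,
                                   log_likelihood = vapply(models, function(m)
                                     m$log_likelihood, numeric(1)),
                                   score = score)
  model
}

IUPAC_PAIR_CODES <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                      GT = "K")

#' IUPAC consensus string of a motif matrix
#'
#' Per column: the single base if its probability reaches `major`; the
#' two-base IUPAC code if the top two probabilities sum to at least
#' `pair`; otherwise `N`.
#'
#' @param theta 4 x w column-stochastic matrix (rows A, C, G, T).
#' @param major single-base threshold; default 0.6.
#' @param pair two-base threshold; default 0.8.
#' @return IUPAC string of width `ncol(theta)`.
#' @export
consensus_iupac <- function(theta, major = 0.6, pair = 0.8) {
  paste(apply(theta, 2, function(col) {
    o <- order(col, decreasing = TRUE)
    if (col[o[1]] >= major) return(DNA_BASES[o[1]])
    if (col[o[1]] + col[o[2]] >= pair) {
      key <- paste(sort(DNA_BASES[o[1:2]]), collapse = "")
      return(IUPAC_PAIR_CODES[[key]])
    }
    "N"
  }), collapse = "")
}

#' Palindromicity score of a motif
#'
#' One minus the mean total-variation distance between the motif matrix
#' and its reverse complement (rows complemented, columns reversed);
#' 1 means a perfect palindrome.
#'
#' @param theta 4 x w column-stochastic matrix (rows A, C, G, T).
#' @return score in `[0, 1]`.
#' @export
palindromicity <- function(theta) {
  rc <- theta[4:1, ncol(theta):1, drop = FALSE]
  tv <- 0.5 * colSums(abs(theta - rc))
  1 - mean(tv)
}

# integer log-odds matrix (units of `granularity` bits)
integer_log_odds <- function(model, granularity = 0.001) {
  lo <- log2(model$theta / model$background)
  round(lo / granularity)
}

#' Exact null distribution of integer-discretised PWM scores
#'
#' Dynamic programme over motif columns: the distribution of the total
#' integer log-odds score of a random background word, computed exactly
#' by convolving the per-column score distributions.  Scores are
#' discretised to `granularity` bits.
#'
#' @param model a `motif_model`.
#' @param granularity score grid in bits; default 1/1000.
#' @return list with `scores` (integer grid, ascending), `prob`
#'   (point probabilities) and `tail` (`Pr(S >= s)` per grid point).
#' @export
pwm_score_distribution <- function(model, granularity = 0.001) {
  si <- integer_log_odds(model, granularity)
  w <- ncol(si)
  lo <- sum(apply(si, 2, min))
  hi <- sum(apply(si, 2, max))
  p <- numeric(hi - lo + 1)  # indexed by score - lo
  # start before column 1: probability 1 at score 0, tracked via running bounds
  cur_lo <- 0L
  cur <- 1
  for (t in seq_len(w)) {
    cmin <- min(si[, t]); cmax <- max(si[, t])
    new_lo <- cur_lo + cmin
    new <- numeric(length(cur) + cmax - cmin)
    for (b in 1:4) {
      sh <- si[b, t] - cmin
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * model$background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  list(scores = seq.int(cur_lo, cur_lo + length(cur) - 1L),
       prob = cur,
       tail = rev(cumsum(rev(cur))))
}

#' Scan sequences with a motif model at exact p-values
#'
#' Scores every offset on both strands with the integer-discretised
#' log-odds matrix (`N` bases contribute zero), converts scores to exact
#' p-values under the background via [pwm_score_distribution()], applies
#' Benjamini-Hochberg across all scanned positions, and returns hits
#' below the q threshold sorted by p-value, then sequence id, then
#' offset.
#'
#' @param model a `motif_model`.
#' @param sequences named character vector of sequences over A/C/G/T/N.
#' @param q_threshold FDR threshold; default 0.05.
#' @param granularity score grid in bits; default 1/1000.
#' @return data frame of class `motif_hits`: `seq_id`, `offset`
#'   (0-based), `strand`, `score` (bits), `pvalue`, `qvalue`,
#'   `match` (the matched genomic word, as given).  The number of
#'   scanned positions is attached as attribute `n_scanned`.
#' @export
scan_pwm <- function(model, sequences, q_threshold = 0.05,
                     granularity = 0.001) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  w <- model$width
  si <- integer_log_odds(model, granularity)
  si5 <- rbind(si, 0L)  # 5th row: N scores as zero
  dist <- pwm_score_distribution(model, granularity)
  score_one <- function(enc) {
    m <- length(enc) - w + 1L
    if (m < 1) return(NULL)
    e5 <- ifelse(is.na(enc), 5L, enc)
    plus <- vapply(seq_len(m), function(j)
      sum(si5[cbind(e5[j:(j + w - 1L)], seq_len(w))]), numeric(1))
    e5rc <- ifelse(e5 == 5L, 5L, 5L - e5)
    minus <- vapply(seq_len(m), function(j)
      sum(si5[cbind(rev(e5rc[j:(j + w - 1L)]), seq_len(w))]), numeric(1))
    data.frame(offset = rep(seq_len(m) - 1L, 2L),
               strand = rep(c("+", "-"), each = m),
               score_int = c(plus, minus))
  }
  hits <- lapply(seq_along(sequences), function(i) {
    enc <- encode_dna(sequences[[i]])
    h <- score_one(enc)
    if (is.null(h)) return(NULL)
    h$seq_id <- names(sequences)[i]
    h
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) {
    out <- data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      match = character(), stringsAsFactors = FALSE)
    attr(out, "n_scanned") <- 0L
    class(out) <- c("motif_hits", "data.frame")
    return(out)
  }
  idx <- pmin(pmax(hits$score_int, dist$scores[1]),
              dist$scores[length(dist$scores)]) - dist$scores[1] + 1L
  hits$pvalue <- dist$tail[idx]
  hits$qvalue <- bh_adjust(hits$pvalue)
  n_scanned <- nrow(hits)
  keep <- hits$qvalue < q_threshold
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$pvalue, out$seq_id, out$offset), , drop = FALSE]
  out$score <- out$score_int * granularity
  out$match <- vapply(seq_len(nrow(out)), function(r) {
    substr(sequences[[out$seq_id[r]]], out$offset[r] + 1L, out$offset[r] + w)
  }, character(1))
  out <- out[, c("seq_id", "offset", "strand", "score", "pvalue", "qvalue",
                 "match")]
  rownames(out) <- NULL
  attr(out, "n_scanned") <- n_scanned
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Write a motif model in minimal MEME text format
#'
#' Version header, alphabet, strand and background lines, plus one
#' letter-probability matrix block.
#'
#' @param model a `motif_model`.
#' @param path output path.
#' @param name motif name for the MOTIF line.
#' @return invisibly, `path`.
#' @export
write_meme <- function(model, path, name = "MOTIF_1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, model$background),
                     collapse = " "), "",
               sprintf("MOTIF %s %s", name, consensus_iupac(model$theta)),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model$width, model$n_seqs)), con)
  for (t in seq_len(model$width)) {
    writeLines(paste(sprintf("%.6f", model$theta[, t]), collapse = " "), con)
  }
  invisible(path)
}
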