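#' @importFrom stats median pnorm quantile rbinom rnbinom runif sd setNames
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate alphabet as base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the IUPAC alphabet.  Used
#' internally for strand-aware window extraction and motif symmetry.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else (N) -> NA
encode_dna <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

decode_dna <- function(i) paste(DNA_BASES[i], collapse = "")

# Wrap 0-based positions onto a circular genome of length len
wrap_pos <- function(pos, len) ((pos %% len) + len) %% len

# Derive a reproducible child seed from a master seed and integer tags.
# Small multiplicative hash kept below 2^31 so it is a valid R integer.
sub_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.double(master) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run code with a local RNG state seeded from `seed` (restores state after)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
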