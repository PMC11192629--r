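#' K-mer encoding, decoding and canonicalisation
#'
#' K-mers over the DNA alphabet are encoded as base-4 integers with
#' A = 0, C = 1, G = 2, T = 3 and the leftmost base most significant,
#' so a k-mer maps to a code in `[0, 4^k)`. Codes are held as doubles
#' (exact for k <= 16, well below 2^53). The canonical form of a k-mer
#' is the lexicographically smaller of the sequence and its reverse
#' complement; it is the deduplication convention used throughout the
#' package, since the nullomer universe is closed under reverse
#' complement.
#'
#' @param seq character vector of DNA strings over A/C/G/T
#'   (case-insensitive). Ambiguous bases, including N, are rejected.
#' @return `encode_kmer`: a numeric vector of base-4 codes.
#' @examples
#' encode_kmer("ACGT")           # 27
#' decode_kmer(27, 4)            # "ACGT"
#' canonical_form("GT")          # "AC"
#' @name kmer
NULL

.kmer_digit <- local({
  d <- rep(NA_real_, 128L)
  d[utf8ToInt("A")] <- 0; d[utf8ToInt("C")] <- 1
  d[utf8ToInt("G")] <- 2; d[utf8ToInt("T")] <- 3
  d[utf8ToInt("a")] <- 0; d[utf8ToInt("c")] <- 1
  d[utf8ToInt("g")] <- 2; d[utf8ToInt("t")] <- 3
  d
})

.check_dna <- function(seq, what = "sequence") {
  # zero-length vectors pass through (vectorized ops return empty);
  # empty or NA strings are always rejected
  if (any(is.na(seq)) || any(nchar(seq) == 0L)) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGTacgt]", seq))) {
    stop("ambiguous base in ", what, ": only A/C/G/T allowed", call. = FALSE)
  }
  invisible(seq)
}

#' @rdname kmer
#' @export
encode_kmer <- function(seq) {
  .check_dna(seq, "k-mer")
  k <- nchar(seq)
  if (any(k > 16L)) stop("k-mer longer than 16 bp", call. = FALSE)
  vapply(seq, function(s) {
    d <- .kmer_digit[utf8ToInt(s)]
    sum(d * 4^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname kmer
#' @param code numeric vector of k-mer codes in `[0, 4^k)`.
#' @param k k-mer length in bp (1--16).
#' @export
decode_kmer <- function(code, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 16L) stop("k must be in 1..16", call. = FALSE)
  if (any(code < 0 | code >= 4^k)) stop("code out of range for k", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  cols <- vector("list", k)
  rest <- code
  for (j in k:1) {
    cols[[j]] <- bases[rest %% 4 + 1]
    rest <- rest %/% 4
  }
  do.call(paste0, cols)
}

#' @rdname kmer
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  comp <- chartr("ACGTacgt", "TGCAtgca", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' @rdname kmer
#' @export
canonical_form <- function(seq) {
  rc <- reverse_complement(seq)
  swap <- rc < seq
  seq[swap] <- rc[swap]
  seq
}

# All k-mer window codes of `seq`; windows touching a non-ACGT base are NA.
# Returns numeric(0) when the sequence is shorter than k.
seq_to_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  d <- .kmer_digit[utf8ToInt(seq)]
  nwin <- n - k + 1L
  code <- numeric(nwin)
  for (j in seq_len(k)) {
    code <- code * 4 + d[j:(j + nwin - 1L)]
  }
  code
}

# Reverse-complement a vector of codes arithmetically.
code_revcomp <- function(code, k) {
  rc <- numeric(length(code))
  rest <- code
  for (j in seq_len(k)) {
    rc <- rc * 4 + (3 - rest %% 4)
    rest <- rest %/% 4
  }
  rc
}
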