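#' Presence/absence index of all k-mers of a genome
#'
#' Builds a flat bit-array over the full k-mer space `4^k`: bit `b` is
#' set iff the k-mer with code `b` occurs in the genome on either
#' strand. A k-mer whose bit is unset is a *nullomer* of that genome.
#' Indexing both strands makes the presence set closed under reverse
#' complement, so canonical-form deduplication downstream is
#' well-defined. Windows containing any non-ACGT base (e.g. N) are
#' skipped; lowercase (soft-masked) bases are uppercased and treated as
#' ordinary bases; contigs shorter than k contribute nothing.
#'
#' @param genome a FASTA path, a [Biostrings::DNAStringSet], or a
#'   (named) character vector of contig sequences.
#' @param k k-mer length in bp, 1--16. Memory is `4^k` bits (128 KiB at
#'   k = 10; 512 MiB at the k = 16 cap).
#' @param genome_id free-text identifier stored with the index.
#' @return an object of class `NullomerIndex` with fields `k`,
#'   `presence` (raw bit-array), `genome_id` and `n_present`.
#' @examples
#' idx <- nullomer_index("ACGTACGT", k = 2)
#' idx$n_present                    # 4: AC, CG, GT, TA
#' is_nullomer(idx, c("AC", "AG"))  # FALSE TRUE
#' enumerate_nullomers(idx)         # the 12 absent 2-mers
#' @export
nullomer_index <- function(genome, k, genome_id = "genome") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 16L) stop("k must be in 1..16", call. = FALSE)
  contigs <- as_contigs(genome)
  nbytes <- as.integer(ceiling(4^k / 8))
  presence <- raw(nbytes)
  for (ctg in contigs) {
    fwd <- seq_to_codes(ctg, k)
    fwd <- fwd[!is.na(fwd)]
    if (length(fwd) == 0L) next
    codes <- unique(c(fwd, code_revcomp(fwd, k)))
    presence <- set_bits(presence, codes)
  }
  structure(
    list(k = k, presence = presence, genome_id = as.character(genome_id),
         n_present = count_bits(presence)),
    class = "NullomerIndex"
  )
}

.popcount <- local({
  v <- integer(256L)
  for (i in 0:255) v[i + 1L] <- sum(bitwAnd(i, 2^(0:7)) > 0)
  v
})

set_bits <- function(presence, codes) {
  byte <- codes %/% 8 + 1
  bit <- codes %% 8
  for (b in 0:7) {
    idx <- byte[bit == b]
    if (length(idx)) {
      presence[idx] <- presence[idx] | as.raw(2^b)
    }
  }
  presence
}

get_bits <- function(presence, codes) {
  byte <- as.integer(presence[codes %/% 8 + 1])
  bitwAnd(byte, as.integer(2^(codes %% 8))) > 0L
}

count_bits <- function(presence) {
  sum(.popcount[as.integer(presence) + 1L])
}

#' @exportS3Method base::print
print.NullomerIndex <- function(x, ...) {
  cat(sprintf(
    "NullomerIndex: k=%d, genome='%s', present=%s/%s k-mers (%.4g%% absent)\n",
    x$k, x$genome_id, format(x$n_present, big.mark = ","),
    format(4^x$k, big.mark = ","),
    100 * (1 - x$n_present / 4^x$k)))
  invisible(x)
}

.check_index <- function(index) {
  if (!inherits(index, "NullomerIndex")) {
    stop("expected a NullomerIndex", call. = FALSE)
  }
  invisible(index)
}

#' Query a k-mer against an index
#'
#' @param index a `NullomerIndex`.
#' @param seq character vector of k-mers, each of length `index$k`.
#' @return logical vector: TRUE iff the k-mer is absent from the genome
#'   (on both strands). By reverse-complement closure of the index,
#'   `is_nullomer(s) == is_nullomer(revcomp(s))`.
#' @export
is_nullomer <- function(index, seq) {
  .check_index(index)
  .check_dna(seq, "query k-mer")
  if (any(nchar(seq) != index$k)) {
    stop("query length must equal index k = ", index$k, call. = FALSE)
  }
  !get_bits(index$presence, encode_kmer(seq))
}

#' Number of nullomers of an index
#'
#' `4^k - n_present`; the complement of the presence count.
#' @inheritParams is_nullomer
#' @export
nullomer_count <- function(index) {
  .check_index(index)
  4^index$k - index$n_present
}

# Codes whose presence bit is unset, in increasing code order.
absent_codes <- function(index) {
  bytes <- as.integer(index$presence)
  unset <- lapply(0:255, function(v) which(bitwAnd(v, 2^(0:7)) == 0L) - 1L)
  per_byte <- unset[bytes + 1L]
  lens <- lengths(per_byte)
  codes <- unlist(per_byte, use.names = FALSE) +
    rep(8 * (seq_along(bytes) - 1), lens)
  codes[codes < 4^index$k]
}

#' Enumerate all nullomers of an index
#'
#' @inheritParams is_nullomer
#' @return character vector of every absent k-mer exactly once, in
#'   increasing code (lexicographic) order; its length equals
#'   [nullomer_count()].
#' @export
enumerate_nullomers <- function(index) {
  .check_index(index)
  codes <- absent_codes(index)
  if (length(codes) == 0L) return(character(0))
  decode_kmer(codes, index$k)
}

#' Enumerate all present k-mers of an index
#'
#' The complement of [enumerate_nullomers()]; mainly useful for
#' verification at small k.
#' @inheritParams is_nullomer
#' @export
present_kmers <- function(index) {
  .check_index(index)
  all_codes <- seq_len(4^index$k) - 1
  codes <- all_codes[get_bits(index$presence, all_codes)]
  if (length(codes) == 0L) return(character(0))
  decode_kmer(codes, index$k)
}
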