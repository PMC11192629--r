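# Brute-force reference implementations used as independent oracles.
# These deliberately share no code with the package internals: plain
# substring extraction and set operations only.

# Every k-long substring of `seq` (character scalar) as a vector.
brute_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

brute_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# The set of k-mers present in a genome on both strands, excluding any
# window containing a non-ACGT character.
brute_present_set <- function(contigs, k) {
  wins <- unlist(lapply(unname(contigs), function(ctg) {
    c(brute_windows(ctg, k), brute_windows(brute_revcomp(ctg), k))
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  sort(unique(wins))
}

# All 4^k k-mers (only usable at small k).
brute_all_kmers <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
        1, paste, collapse = "")
}

# Nullomers emerging from a variant, by full-genome reconstruction:
# apply the edit to the whole contig, take the substring set difference
# against the reference, and canonicalise.
brute_emerged <- function(ctg, pos, ref, alt, k) {
  if (ref == "-") {
    mutated <- paste0(substr(ctg, 1, pos), alt,
                      substr(ctg, pos + 1, nchar(ctg)))
  } else {
    mutated <- paste0(substr(ctg, 1, pos - 1), if (alt == "-") "" else alt,
                      substr(ctg, pos + nchar(ref), nchar(ctg)))
  }
  ref_set <- brute_present_set(c(x = ctg), k)
  mut_set <- brute_present_set(c(x = mutated), k)
  new_kmers <- setdiff(mut_set, ref_set)
  canon <- vapply(new_kmers, function(s) {
    rc <- brute_revcomp(s)
    if (s <= rc) s else rc
  }, character(1), USE.NAMES = FALSE)
  sort(unique(canon))
}

# Occurrences of panel k-mers in reads, window by window, both strands.
brute_scan <- function(reads, panel) {
  out <- setNames(integer(length(panel)), panel)
  for (p in panel) {
    rc <- brute_revcomp(p)
    for (r in reads) {
      wins <- brute_windows(toupper(r), nchar(p))
      out[p] <- out[p] + sum(wins == p | (rc != p & wins == rc))
    }
  }
  out
}

random_genome <- function(n, seed) {
  nullorna::generate_genome(n, gc = 0.5, seed = seed)
}

# A toy CountMatrix built directly from a counts matrix.
toy_cm <- function(counts, labels) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- vapply(seq_len(ncol(counts)), function(i) {
      paste(c("A", "C", "G", "T")[(i %% 4) + 1] , i, sep = "_")
    }, character(1))
  }
  structure(list(counts = counts, sample_ids = rownames(counts),
                 nullomers = colnames(counts), labels = labels,
                 normalized = FALSE), class = "CountMatrix")
}
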