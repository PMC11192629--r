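#' SBS96 single-base-substitution channel
#'
#' Labels a SNP by its trinucleotide context, expressed on the
#' pyrimidine strand: when the reference base is A or G, the triplet
#' and the alternate allele are reverse-complemented first, so every
#' substitution falls into one of 6 pyrimidine-centred types (C>A, C>G,
#' C>T, T>A, T>C, T>G) x 16 flank contexts = 96 channels, e.g.
#' `"A[C>T]G"`. The labelling is therefore strand-symmetric.
#'
#' @param genome genome as accepted by [nullomer_index()].
#' @param variant one-row SNP variant data.frame.
#' @return channel label, e.g. `"A[C>T]G"`.
#' @export
classify_sbs96 <- function(genome, variant) {
  if (variant$variant_type[1] != "SNP") {
    stop("SBS96 classification requires a SNP", call. = FALSE)
  }
  contigs <- as_contigs(genome)
  chrom <- as.character(variant$chrom[1])
  if (!chrom %in% names(contigs)) {
    stop("variant contig '", chrom, "' not in genome", call. = FALSE)
  }
  ctg <- contigs[[chrom]]
  pos <- as.integer(variant$pos[1])
  if (pos < 2L || pos > nchar(ctg) - 1L) {
    stop("unclassifiable: no flanking base at contig edge", call. = FALSE)
  }
  triplet <- substr(ctg, pos - 1L, pos + 1L)
  ref <- toupper(variant$ref[1])
  alt <- toupper(variant$alt[1])
  if (substr(triplet, 2L, 2L) != ref) {
    stop("reference mismatch at ", chrom, ":", pos, call. = FALSE)
  }
  sbs96_label(triplet, alt)
}

# Context triplet + alt allele -> pyrimidine-strand label.
sbs96_label <- function(triplet, alt) {
  .check_dna(triplet)
  .check_dna(alt)
  if (nchar(triplet) != 3L || nchar(alt) != 1L) {
    stop("need a 3 bp context and a 1 bp alternate allele", call. = FALSE)
  }
  ref <- substr(triplet, 2L, 2L)
  if (ref == alt) stop("ref and alt alleles are identical", call. = FALSE)
  if (ref %in% c("A", "G")) {
    triplet <- reverse_complement(triplet)
    alt <- reverse_complement(alt)
    ref <- substr(triplet, 2L, 2L)
  }
  paste0(substr(triplet, 1L, 1L), "[", ref, ">", alt, "]",
         substr(triplet, 3L, 3L))
}

#' The complete SBS96 label universe
#'
#' @return character vector of the 96 channel labels in COSMIC order
#'   (substitution type major, 5' then 3' flank minor).
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1L, 1L)
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' ID83 insertion/deletion channel
#'
#' Labels an indel with the 83-channel scheme: 1 bp indels are typed by
#' the affected base on the pyrimidine strand (C or T) and the
#' homopolymer context (deletions: run length of the deleted base in
#' the reference, 1..6+; insertions: identical bases adjacent to the
#' insertion point, 0..5+); longer indels are typed by length (2, 3,
#' 4, 5+) and the number of tandem copies of the indel unit in the
#' reference (deletions 1..6+ including the deleted copy, insertions
#' 0..5+); non-repeat deletions with sequence overlap at the junction
#' are typed by microhomology length (`M:1` .. `M:5`).
#'
#' @inheritParams classify_sbs96
#' @param variant one-row INS or DEL variant data.frame.
#' @return channel label, e.g. `"1:Del:T:6"` or `"3:Del:M:2"`.
#' @export
classify_id83 <- function(genome, variant) {
  type <- variant$variant_type[1]
  if (!type %in% c("INS", "DEL")) {
    stop("ID83 classification requires an INS or DEL", call. = FALSE)
  }
  contigs <- as_contigs(genome)
  chrom <- as.character(variant$chrom[1])
  if (!chrom %in% names(contigs)) {
    stop("variant contig '", chrom, "' not in genome", call. = FALSE)
  }
  ctg <- contigs[[chrom]]
  pos <- as.integer(variant$pos[1])
  if (type == "DEL") {
    unit <- toupper(variant$ref[1])
    len <- nchar(unit)
    if (substr(ctg, pos, pos + len - 1L) != unit) {
      stop("reference mismatch at ", chrom, ":", pos, call. = FALSE)
    }
    left <- substr(ctg, 1L, pos - 1L)
    right <- substr(ctg, pos + len, nchar(ctg))
    if (len == 1L) {
      run <- 1L + run_length(left, unit, "suffix") +
        run_length(right, unit, "prefix")
      base <- if (unit %in% c("A", "G")) reverse_complement(unit) else unit
      return(paste0("1:Del:", base, ":", min(run, 6L)))
    }
    copies <- 1L + unit_copies(left, unit, "suffix") +
      unit_copies(right, unit, "prefix")
    if (copies >= 2L) {
      return(paste0(min(len, 5L), ":Del:R:", min(copies, 6L)))
    }
    mh <- max(overlap_len(unit, right, "prefix"),
              overlap_len(unit, left, "suffix"))
    if (mh >= 1L) {
      return(paste0(min(len, 5L), ":Del:M:", min(mh, len - 1L, 5L)))
    }
    return(paste0(min(len, 5L), ":Del:R:1"))
  }
  # insertion between pos and pos+1
  unit <- toupper(variant$alt[1])
  len <- nchar(unit)
  left <- substr(ctg, 1L, pos)
  right <- substr(ctg, pos + 1L, nchar(ctg))
  if (len == 1L) {
    run <- run_length(left, unit, "suffix") + run_length(right, unit, "prefix")
    base <- if (unit %in% c("A", "G")) reverse_complement(unit) else unit
    return(paste0("1:Ins:", base, ":", min(run, 5L)))
  }
  copies <- unit_copies(left, unit, "suffix") + unit_copies(right, unit, "prefix")
  paste0(min(len, 5L), ":Ins:R:", min(copies, 5L))
}

# Length of the run of `base` at the start/end of `s`.
run_length <- function(s, base, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  n <- nchar(s)
  if (n == 0L) return(0L)
  r <- 0L
  idx <- if (side == "prefix") seq_len(n) else rev(seq_len(n))
  for (i in idx) {
    if (substr(s, i, i) == base) r <- r + 1L else break
  }
  r
}

# Number of whole tandem copies of `unit` at the start/end of `s`.
unit_copies <- function(s, unit, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  len <- nchar(unit)
  n <- nchar(s)
  copies <- 0L
  repeat {
    off <- copies * len
    if (off + len > n) break
    piece <- if (side == "prefix") {
      substr(s, off + 1L, off + len)
    } else {
      substr(s, n - off - len + 1L, n - off)
    }
    if (piece != unit) break
    copies <- copies + 1L
  }
  copies
}

# Longest proper overlap between `unit` and neighbouring sequence:
# prefix mode compares prefixes of `unit` with the start of `s`;
# suffix mode compares suffixes of `unit` with the end of `s`.
overlap_len <- function(unit, s, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  len <- nchar(unit)
  n <- nchar(s)
  best <- 0L
  for (m in seq_len(len - 1L)) {
    if (m > n) break
    a <- if (side == "prefix") substr(unit, 1L, m) else
      substr(unit, len - m + 1L, len)
    b <- if (side == "prefix") substr(s, 1L, m) else substr(s, n - m + 1L, n)
    if (a == b) best <- m
  }
  best
}

#' The complete ID83 label universe
#'
#' @return character vector of the 83 channel labels: 12 one-bp
#'   deletion, 12 one-bp insertion, 24 longer-deletion repeat, 24
#'   longer-insertion repeat, and 11 microhomology-deletion channels.
#' @export
id83_labels <- function() {
  out <- character(0)
  for (b in c("C", "T")) {
    out <- c(out, paste0("1:Del:", b, ":", 1:6))
  }
  for (b in c("C", "T")) {
    out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  }
  for (L in 2:5) out <- c(out, paste0(L, ":Del:R:", 1:6))
  for (L in 2:5) out <- c(out, paste0(L, ":Ins:R:", 0:5))
  # microhomology depth: up to len-1 for 2-4 bp deletions; the 5+ size
  # class reaches M:5 via deletions of 6 bp and longer
  for (L in 2:5) out <- c(out, paste0(L, ":Del:M:", seq_len(if (L == 5L) 5L else L - 1L)))
  out
}
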