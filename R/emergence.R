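#' Sequence window around a somatic variant, with the edit applied
#'
#' Extracts up to `k - 1` bp of reference flank on each side of the
#' edited span and substitutes the alternate allele, following MAF
#' conventions: 1-based inclusive coordinates; substitutions replace
#' `ref` starting at `pos`; deletions (`alt == "-"`) remove `ref`;
#' insertions (`ref == "-"`) place `alt` between `pos` and `pos + 1`.
#' Flanks truncate at contig boundaries. Any k-mer of the mutated
#' sequence that is new to the genome must overlap the edit, so
#' `k - 1` flanks capture every candidate; k-mers lying entirely in
#' unedited flank are reference substrings and are removed downstream
#' by index membership.
#'
#' @param genome genome as accepted by [nullomer_index()].
#' @param variant one-row variant data.frame (columns `chrom`, `pos`,
#'   `ref`, `alt`, `variant_type`; see [read_maf()]).
#' @param k k-mer length in bp.
#' @return the mutated window as a character scalar.
#' @examples
#' mutated_window("AAAAAAAA",
#'   data.frame(chrom = "contig_1", pos = 4, ref = "A", alt = "C",
#'              variant_type = "SNP"), k = 2)   # "ACA"
#' @export
mutated_window <- function(genome, variant, k) {
  contigs <- as_contigs(genome)
  chrom <- as.character(variant$chrom[1])
  if (!chrom %in% names(contigs)) {
    stop("variant contig '", chrom, "' not in genome", call. = FALSE)
  }
  ctg <- contigs[[chrom]]
  pos <- as.integer(variant$pos[1])
  ref <- toupper(as.character(variant$ref[1]))
  alt <- toupper(as.character(variant$alt[1]))
  is_ins <- ref == "-"
  if (is_ins) {
    ref_span <- c(pos + 1L, pos)           # empty span between pos and pos+1
  } else {
    ref_span <- c(pos, pos + nchar(ref) - 1L)
    if (ref_span[2] > nchar(ctg) || pos < 1L) {
      stop("variant coordinates outside contig", call. = FALSE)
    }
    obs <- substr(ctg, ref_span[1], ref_span[2])
    if (obs != ref) {
      stop("reference mismatch at ", chrom, ":", pos,
           " (genome has '", obs, "', variant says '", ref, "')",
           call. = FALSE)
    }
  }
  left <- substr(ctg, max(1L, ref_span[1] - (k - 1L)), ref_span[1] - 1L)
  right <- substr(ctg, ref_span[2] + 1L,
                  min(nchar(ctg), ref_span[2] + (k - 1L)))
  paste0(left, if (alt == "-") "" else alt, right)
}

#' Nullomers emerging from a single somatic variant
#'
#' Scans every k-mer window of the mutated sequence around the variant
#' against the reference nullomer index; the windows that are absent
#' from the reference genome are the nullomers this mutation creates.
#' Results are reported in canonical form (lexicographic minimum of the
#' strand pair) and deduplicated. A variant is called *nullomer
#' emerging* when at least one such k-mer exists. Windows containing an
#' ambiguous base are skipped with a warning.
#'
#' @param index `NullomerIndex` built from `genome` at the desired k.
#' @inheritParams mutated_window
#' @return list with elements `variant` (the input row), `k`,
#'   `emerged` (character vector of canonical nullomers) and
#'   `n_emerged`.
#' @export
emerged_nullomers <- function(index, genome, variant) {
  .check_index(index)
  k <- index$k
  win <- mutated_window(genome, variant, k)
  codes <- seq_to_codes(win, k)
  if (anyNA(codes)) {
    warning("ambiguous base in mutated window at ", variant$chrom[1], ":",
            variant$pos[1], "; affected windows skipped", call. = FALSE)
    codes <- codes[!is.na(codes)]
  }
  codes <- unique(codes)
  hit <- codes[!get_bits(index$presence, codes)]
  emerged <- if (length(hit)) {
    sort(unique(canonical_form(decode_kmer(hit, k))))
  } else {
    character(0)
  }
  list(variant = variant, k = k, emerged = emerged,
       n_emerged = length(emerged))
}

#' Emergence table for a variant cohort
#'
#' Applies [emerged_nullomers()] to every variant at every supplied
#' index (one row per variant x k), attaching the SBS96 channel for
#' SNPs and the ID83 channel for 1 bp+ indels. Per-variant failures
#' (reference mismatch, coordinates off contig) are logged as warnings
#' and the variant is skipped; row order follows input order.
#'
#' @param variants variant data.frame as returned by [read_maf()].
#' @param genome genome as accepted by [nullomer_index()].
#' @param indices a single `NullomerIndex` or list of them (one per k).
#' @return data.frame with one row per (variant, k): `sample_id`,
#'   `cancer_type`, `gene`, `chrom`, `pos`, `variant_type`, `vaf`,
#'   `k`, `channel`, `n_emerged`, `emerged` (comma-separated canonical
#'   nullomers).
#' @export
batch_emergence <- function(variants, genome, indices) {
  if (inherits(indices, "NullomerIndex")) indices <- list(indices)
  lapply(indices, .check_index)
  contigs <- as_contigs(genome)
  empty <- data.frame(
    sample_id = character(0), cancer_type = character(0),
    gene = character(0), chrom = character(0), pos = integer(0),
    variant_type = character(0), vaf = numeric(0), k = integer(0),
    channel = character(0), n_emerged = integer(0), emerged = character(0),
    stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0L) return(empty)
  rows <- vector("list", nrow(variants) * length(indices))
  n_failed <- 0L
  ri <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    channel <- NA_character_
    if (v$variant_type == "SNP") {
      channel <- tryCatch(classify_sbs96(contigs, v),
                          error = function(e) NA_character_)
    } else if (v$variant_type %in% c("INS", "DEL")) {
      channel <- tryCatch(classify_id83(contigs, v),
                          error = function(e) NA_character_)
    }
    vf <- if (!is.null(v$alt_count) && !is.null(v$total_count) &&
              !is.na(v$alt_count) && !is.na(v$total_count) &&
              v$total_count > 0L) {
      v$alt_count / v$total_count
    } else {
      NA_real_
    }
    for (idx in indices) {
      ri <- ri + 1L
      rec <- tryCatch(emerged_nullomers(idx, contigs, v),
                      error = function(e) e)
      if (inherits(rec, "error")) {
        n_failed <- n_failed + 1L
        next
      }
      rows[[ri]] <- data.frame(
        sample_id = v$sample_id,
        cancer_type = if (is.null(v$cancer_type)) NA_character_ else v$cancer_type,
        gene = if (is.null(v$gene)) NA_character_ else v$gene,
        chrom = v$chrom, pos = v$pos,
        variant_type = v$variant_type, vaf = vf, k = idx$k,
        channel = channel, n_emerged = rec$n_emerged,
        emerged = paste(rec$emerged, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (n_failed > 0L) {
    warning(n_failed, " variant/k combination(s) failed and were skipped",
            call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variant allele frequency
#'
#' `alt_count / total_count` per variant.
#' @param variant variant data.frame with `alt_count` and `total_count`.
#' @return numeric vector in \[0, 1\]; NA where counts are unavailable.
#' @export
vaf <- function(variant) {
  a <- variant$alt_count
  t <- variant$total_count
  if (is.null(a) || is.null(t)) {
    return(rep(NA_real_, nrow(variant)))
  }
  if (any(!is.na(t) & t == 0L)) {
    stop("total_count must be positive where present", call. = FALSE)
  }
  ifelse(is.na(a) | is.na(t), NA_real_, a / t)
}

# Split the comma-joined `emerged` column back into a list of vectors.
split_emerged <- function(emerged) {
  out <- strsplit(emerged, ",", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}
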