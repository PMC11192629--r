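#' Count nullomer-panel occurrences in a read set
#'
#' Counts, for every panel k-mer, the total number of (possibly
#' overlapping) occurrences across all reads, matching either the
#' k-mer or its reverse complement (cfRNA library strandedness is not
#' guaranteed, so both strands are screened). A palindromic panel
#' sequence is counted once per window. Read windows containing N
#' never match; reads shorter than k contribute nothing.
#'
#' @param reads a character vector of read sequences, a data.frame
#'   from [read_fastq()], or a FASTQ path.
#' @param panel character vector of same-length ACGT k-mers.
#' @return named integer vector of occurrence counts, one per panel
#'   sequence, in panel order.
#' @examples
#' scan_reads(c("AAACGTAA", "TTTT"), panel = c("ACGT", "AAAA"))
#' @export
scan_reads <- function(reads, panel) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  .check_dna(panel, "panel sequence")
  k <- unique(nchar(panel))
  if (length(k) != 1L) {
    stop("panel sequences must all have the same length", call. = FALSE)
  }
  if (anyDuplicated(panel)) {
    stop("panel contains duplicate sequences", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(panel)), panel)
  if (length(reads) == 0L) {
    warning("empty read set: all counts zero", call. = FALSE)
    return(counts)
  }
  reads <- toupper(reads)
  fwd_codes <- encode_kmer(panel)
  rc_codes <- code_revcomp(fwd_codes, k)
  # one pass over all read windows, then tabulate against the panel codes
  window_codes <- unlist(lapply(reads, seq_to_codes, k = k),
                         use.names = FALSE)
  window_codes <- window_codes[!is.na(window_codes)]
  if (length(window_codes) == 0L) return(counts)
  tab <- table(window_codes)
  lookup <- function(codes) {
    hit <- tab[as.character(codes)]
    ifelse(is.na(hit), 0L, as.integer(hit))
  }
  n_fwd <- lookup(fwd_codes)
  n_rc <- lookup(rc_codes)
  counts[] <- ifelse(fwd_codes == rc_codes, n_fwd, n_fwd + n_rc)
  counts
}

#' Build a samples x nullomers count matrix
#'
#' Runs [scan_reads()] per sample and assembles the raw count matrix
#' the classification pipeline starts from.
#'
#' @param samples named list: one element per sample, each a read set
#'   accepted by [scan_reads()].
#' @param panel nullomer panel (same-length k-mers).
#' @param labels per-sample class, `"cancer"` or `"healthy"`, recycled
#'   names must match `samples`.
#' @return a `CountMatrix`: list with `counts` (integer matrix, samples
#'   in rows), `sample_ids`, `nullomers`, `labels`, `normalized`.
#' @export
build_count_matrix <- function(samples, panel, labels) {
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  labels <- as.character(labels)
  if (length(labels) != length(samples)) {
    stop("need one label per sample", call. = FALSE)
  }
  if (!all(labels %in% c("cancer", "healthy"))) {
    stop("labels must be 'cancer' or 'healthy'", call. = FALSE)
  }
  counts <- t(vapply(samples, scan_reads, integer(length(panel)),
                     panel = panel))
  colnames(counts) <- panel
  rownames(counts) <- names(samples)
  structure(list(counts = counts, sample_ids = names(samples),
                 nullomers = panel, labels = labels, normalized = FALSE),
            class = "CountMatrix")
}

count_matrix <- function(counts, labels, normalized = FALSE) {
  structure(list(counts = counts, sample_ids = rownames(counts),
                 nullomers = colnames(counts), labels = labels,
                 normalized = normalized),
            class = "CountMatrix")
}

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d samples x %d nullomers (%s; %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(table(x$labels), collapse = "/"),
              if (x$normalized) "CPM-normalized" else "raw counts"))
  invisible(x)
}

.check_cm <- function(x) {
  if (!inherits(x, "CountMatrix")) stop("expected a CountMatrix", call. = FALSE)
  invisible(x)
}

#' Zero out low counts
#'
#' Sets every entry less than or equal to `threshold` to zero, the
#' pipeline's guard against spurious low-level matches (default
#' threshold 2, i.e. counts of 1 and 2 are discarded).
#'
#' @param cm a `CountMatrix` of raw counts.
#' @param threshold maximum count treated as noise.
#' @export
zero_low_counts <- function(cm, threshold = 2L) {
  .check_cm(cm)
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be non-negative", call. = FALSE)
  }
  cm$counts[cm$counts <= threshold] <- 0L
  cm
}

#' Drop rarely seen features
#'
#' Removes nullomer columns whose sum of counts across samples is
#' below `min_sum` (default 10); remaining column order is preserved.
#'
#' @param cm a `CountMatrix` (after [zero_low_counts()]).
#' @param min_sum minimum column sum to retain a feature.
#' @export
filter_low_sum <- function(cm, min_sum = 10L) {
  .check_cm(cm)
  keep <- colSums(cm$counts) >= min_sum
  if (!any(keep)) stop("no features remain after filtering", call. = FALSE)
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm$nullomers <- cm$nullomers[keep]
  cm
}

#' Counts-per-million normalization
#'
#' Scales each sample's counts so that the row sums to one million
#' (the edgeR CPM convention, computed per sample over the retained
#' features). All-zero samples are left at zero with a warning.
#'
#' @param cm a filtered `CountMatrix`.
#' @export
cpm_normalize <- function(cm) {
  .check_cm(cm)
  lib <- rowSums(cm$counts)
  zero <- lib == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left unnormalized", call. = FALSE)
  }
  out <- matrix(0, nrow(cm$counts), ncol(cm$counts),
                dimnames = dimnames(cm$counts))
  if (any(!zero)) {
    # edgeR works features x samples; transpose in and out
    out[!zero, ] <- t(edgeR::cpm(t(cm$counts[!zero, , drop = FALSE]),
                                 normalized.lib.sizes = FALSE,
                                 log = FALSE))
  }
  cm$counts <- out
  cm$normalized <- TRUE
  cm
}

#' Total and unique nullomer burden per sample
#'
#' Per-sample totals used for the case-versus-control burden
#' comparison: the summed occurrence count and the number of distinct
#' panel nullomers detected.
#'
#' @param cm a `CountMatrix`.
#' @return data.frame with `sample_id`, `label`, `total_count`,
#'   `n_unique`.
#' @export
sample_burden <- function(cm) {
  .check_cm(cm)
  data.frame(sample_id = cm$sample_ids, label = cm$labels,
             total_count = unname(rowSums(cm$counts)),
             n_unique = unname(rowSums(cm$counts > 0)),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, via [stats::t.test()]; used to compare nullomer burden
#' between cancer and healthy cfRNA samples.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
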