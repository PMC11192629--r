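#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]. Contig names are
#' the first whitespace token of each header; wrapped sequence lines
#' are concatenated; original case is preserved (indexing uppercases on
#' use).
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return named character vector of contig sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  if (!startsWith(first, ">")) {
    stop("missing '>' header in FASTA: ", path, call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write contigs to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bp.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("contig_", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file (plain or gzip).
#' @return a data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tryCatch({
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    out <- data.frame(
      id = sub("\\s.*$", "", names(ss)),
      seq = as.character(ss),
      qual = as.character(S4Vectors::mcols(ss)$qualities),
      stringsAsFactors = FALSE
    )
    if (any(nchar(out$qual) != nchar(out$seq))) {
      stop("sequence/quality length mismatch")
    }
    out
  }, error = function(e) {
    stop("malformed FASTQ '", path, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Write reads to a FASTQ file
#'
#' @param reads character vector of read sequences.
#' @param path output path (a `.gz` suffix gzips the file).
#' @param ids optional read identifiers; generated when NULL.
#' @param quals optional quality strings; constant 'I' when NULL.
#' @export
write_fastq <- function(reads, path, ids = NULL, quals = NULL) {
  ids <- ids %||% paste0("read_", seq_along(reads))
  quals <- quals %||% vapply(nchar(reads),
                             function(n) strrep("I", n), character(1))
  if (any(nchar(quals) != nchar(reads))) {
    stop("quality strings must match read lengths", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", quals), con)
  invisible(path)
}

.maf_required <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                   "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type",
                   "Tumor_Sample_Barcode")

#' Read MAF-style somatic variant records
#'
#' Parses a tab-delimited MAF-style file (1-based coordinates, `-` for
#' the empty allele of pure insertions/deletions, `#` comment lines
#' skipped) into a validated variant table. Rows violating the basic
#' allele invariants (SNP with ref == alt or multi-base alleles, DEL
#' without `alt == "-"`, INS without `ref == "-"`, alt read count
#' exceeding depth) are dropped with a counted warning.
#'
#' @param path path to the MAF-style TSV. Required columns:
#'   Hugo_Symbol, Chromosome, Start_Position, Reference_Allele,
#'   Tumor_Seq_Allele2, Variant_Type, Tumor_Sample_Barcode; optional:
#'   t_alt_count, t_depth, cancer_type.
#' @return data.frame of variants with columns `chrom`, `pos`, `ref`,
#'   `alt`, `variant_type`, `sample_id`, `cancer_type`, `gene`,
#'   `alt_count`, `total_count`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.maf_required, names(df))
  if (length(missing_cols)) {
    stop("MAF is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- data.frame(
    chrom = as.character(df$Chromosome),
    pos = as.integer(df$Start_Position),
    ref = toupper(as.character(df$Reference_Allele)),
    alt = toupper(as.character(df$Tumor_Seq_Allele2)),
    variant_type = toupper(as.character(df$Variant_Type)),
    sample_id = as.character(df$Tumor_Sample_Barcode),
    cancer_type = if ("cancer_type" %in% names(df))
      as.character(df$cancer_type) else NA_character_,
    gene = as.character(df$Hugo_Symbol),
    alt_count = if ("t_alt_count" %in% names(df))
      as.integer(df$t_alt_count) else NA_integer_,
    total_count = if ("t_depth" %in% names(df))
      as.integer(df$t_depth) else NA_integer_,
    stringsAsFactors = FALSE
  )
  ok <- validate_variants(v)
  if (any(!ok)) {
    warning(sum(!ok), " MAF row(s) failed variant validation and were skipped",
            call. = FALSE)
  }
  v[ok, , drop = FALSE]
}

# Row-wise invariant checks for a variant table; returns a logical keep mask.
validate_variants <- function(v) {
  type <- v$variant_type
  ok <- !is.na(v$pos) & v$pos >= 1L & nzchar(v$ref) & nzchar(v$alt) &
    type %in% c("SNP", "DNP", "TNP", "ONP", "INS", "DEL")
  snp <- type == "SNP"
  ok[snp] <- ok[snp] & nchar(v$ref[snp]) == 1L & nchar(v$alt[snp]) == 1L &
    v$ref[snp] != v$alt[snp] & v$ref[snp] != "-" & v$alt[snp] != "-"
  mnp <- type %in% c("DNP", "TNP", "ONP")
  ok[mnp] <- ok[mnp] & v$ref[mnp] != "-" & v$alt[mnp] != "-" &
    nchar(v$ref[mnp]) == nchar(v$alt[mnp])
  del <- type == "DEL"
  ok[del] <- ok[del] & v$alt[del] == "-" & v$ref[del] != "-"
  ins <- type == "INS"
  ok[ins] <- ok[ins] & v$ref[ins] == "-" & v$alt[ins] != "-"
  both <- !is.na(v$alt_count) & !is.na(v$total_count)
  ok[both] <- ok[both] & v$alt_count[both] <= v$total_count[both] &
    v$alt_count[both] >= 0L
  ok & !is.na(ok)
}

#' Write a variant table in MAF-style TSV
#'
#' Inverse of [read_maf()]; round-trips the validated variant columns.
#' @param variants variant data.frame as returned by [read_maf()].
#' @param path output path.
#' @export
write_maf <- function(variants, path) {
  out <- data.frame(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Type = variants$variant_type,
    Tumor_Sample_Barcode = variants$sample_id,
    t_alt_count = variants$alt_count,
    t_depth = variants$total_count,
    cancer_type = variants$cancer_type,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a nullomer panel (one sequence per line)
#'
#' @param path text file, one k-mer per line; blank lines ignored.
#' @export
read_panel <- function(path) {
  x <- readLines(path)
  x <- toupper(trimws(x[nzchar(trimws(x))]))
  if (length(x) == 0L) stop("empty panel file: ", path, call. = FALSE)
  .check_dna(x, "panel sequence")
  x
}

#' @rdname read_panel
#' @param panel character vector of k-mers.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}

.NIX_MAGIC <- "NLIX"

#' Persist / restore a NullomerIndex
#'
#' Binary format: 4-byte magic, int32 k, int32 id length, id bytes,
#' float64 n_present, then the raw little-endian bit-array. Round-trips
#' bit-exactly.
#'
#' @param index a `NullomerIndex`.
#' @param path output path.
#' @export
write_index <- function(index, path) {
  .check_index(index)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.NIX_MAGIC), con)
  writeBin(as.integer(index$k), con, size = 4L, endian = "little")
  id <- charToRaw(index$genome_id)
  writeBin(length(id), con, size = 4L, endian = "little")
  writeBin(id, con)
  writeBin(as.double(index$n_present), con, size = 8L, endian = "little")
  writeBin(index$presence, con)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .NIX_MAGIC)) {
    stop("not a nullomer index file: ", path, call. = FALSE)
  }
  k <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  idlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  genome_id <- rawToChar(readBin(con, "raw", idlen))
  n_present <- readBin(con, "double", 1L, size = 8L, endian = "little")
  presence <- readBin(con, "raw", as.integer(ceiling(4^k / 8)))
  idx <- structure(list(k = k, presence = presence, genome_id = genome_id,
                        n_present = n_present), class = "NullomerIndex")
  if (count_bits(presence) != n_present) {
    stop("corrupt index: bit count does not match header", call. = FALSE)
  }
  idx
}

#' Write tables and metrics with a run manifest
#'
#' Writes each table as TSV ('.' for missing values, 6 significant
#' digits), the metrics list as JSON, and a `manifest.json` echoing the
#' package version and every configuration value supplied, so a run is
#' reproducible from its output directory alone.
#'
#' @param tables named list of data.frames.
#' @param metrics named list of scalar metrics (may be empty).
#' @param out_dir output directory, created if needed.
#' @param config named list of configuration values echoed to the
#'   manifest (seeds, thresholds, paths).
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables = list(), metrics = list(), out_dir,
                         config = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, logical(1)) &
      !vapply(tab, is.integer, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6L)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "nullorna",
    version = as.character(utils::packageVersion("nullorna")),
    config = config
  )
  fp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, fp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp, fp))
}
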