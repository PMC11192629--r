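# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Coerce genome input (FASTA path, Biostrings::DNAStringSet, or named
# character vector) into an uppercase named character vector of contigs.
as_contigs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             grepl("[^ACGTNacgtn]", genome) && file.exists(genome)) {
    seqs <- read_fasta(genome)
  } else if (is.character(genome)) {
    seqs <- genome
    if (length(seqs) == 0L) stop("genome is empty", call. = FALSE)
    if (is.null(names(seqs))) {
      names(seqs) <- if (length(seqs) == 1L) "contig_1" else
        paste0("contig_", seq_along(seqs))
    }
  } else {
    stop("genome must be a FASTA path, DNAStringSet, or character vector",
         call. = FALSE)
  }
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("genome is empty", call. = FALSE)
  }
  toupper(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
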