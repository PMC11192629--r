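#' Generate a random genome
#'
#' Single-contig genome with i.i.d. bases at the requested GC content.
#' Deterministic per seed; the caller's RNG stream is untouched.
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC fraction in \[0, 1\] (default 0.41, roughly the human
#'   genome-wide value).
#' @param seed integer seed.
#' @param name contig name.
#' @return named character vector of length 1 (the contig).
#' @export
generate_genome <- function(length, gc = 0.41, seed = 1L,
                            name = "synthetic_1") {
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("gc must be in [0, 1]", call. = FALSE)
  }
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed(seed, paste(sample(names(p), length, replace = TRUE,
                                      prob = p), collapse = ""))
  stats::setNames(seq, name)
}

#' Specification of a synthetic somatic-variant cohort
#'
#' Emulates a multi-cancer-type WES cohort at toy scale: per patient,
#' a Poisson mutation count at the cancer type's mean; mutation types
#' drawn from a substitution/insertion/deletion simplex; indels of
#' 1--3 bp; sequencing depth and a Beta-distributed allele fraction
#' generating `t_alt_count`/`t_depth`. An optional hypermutator entry
#' multiplies one patient's mutation mean.
#'
#' @param n_cancer_types number of cohorts.
#' @param patients_per_type patients per cohort.
#' @param mutation_mean per-patient Poisson mean, recycled per cancer
#'   type.
#' @param substitution_fraction,insertion_fraction,deletion_fraction
#'   simplex weights over mutation types (must sum to 1).
#' @param hypermutator NULL, or `list(sample = i, multiplier = m)`
#'   multiplying the i-th patient's mutation mean by m.
#' @param vaf_shape1,vaf_shape2 Beta parameters for the latent allele
#'   fraction.
#' @param vaf_shift added to the latent allele fraction of
#'   nullomer-agnostic variants; 0 by default.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_cancer_types = 2L, patients_per_type = 10L,
                        mutation_mean = 30, substitution_fraction = 0.9,
                        insertion_fraction = 0.05, deletion_fraction = 0.05,
                        hypermutator = NULL, vaf_shape1 = 2, vaf_shape2 = 6,
                        vaf_shift = 0, seed = 1L) {
  fr <- c(substitution_fraction, insertion_fraction, deletion_fraction)
  if (abs(sum(fr) - 1) > 1e-8 || any(fr < 0)) {
    stop("mutation-type fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (n_cancer_types < 1L || patients_per_type < 1L || any(mutation_mean <= 0)) {
    stop("counts and mutation means must be positive", call. = FALSE)
  }
  list(n_cancer_types = as.integer(n_cancer_types),
       patients_per_type = as.integer(patients_per_type),
       mutation_mean = rep_len(mutation_mean, n_cancer_types),
       fractions = fr, hypermutator = hypermutator,
       vaf_shape1 = vaf_shape1, vaf_shape2 = vaf_shape2,
       vaf_shift = vaf_shift, seed = as.integer(seed))
}

#' Generate a synthetic somatic-variant cohort
#'
#' Draws a MAF-style variant table against a genome according to a
#' [cohort_spec()]. Reference alleles are read off the genome, so
#' every record passes reference-match validation; genes are assigned
#' by tiling the genome into equal-width blocks.
#'
#' @param genome genome as accepted by [nullomer_index()].
#' @param spec list from [cohort_spec()].
#' @param n_genes number of gene blocks tiling the genome.
#' @return variant data.frame in the layout of [read_maf()].
#' @export
generate_cohort <- function(genome, spec = cohort_spec(), n_genes = 20L) {
  contigs <- as_contigs(genome)
  ctg_name <- names(contigs)[1]
  ctg <- contigs[[1]]
  L <- nchar(ctg)
  if (L < 10L) stop("genome too short to mutate", call. = FALSE)
  gene_width <- ceiling(L / n_genes)
  gene_of <- function(pos) paste0("G", sprintf("%03d", (pos - 1) %/% gene_width + 1))
  types <- c("LUAD", "LIHC", "BRCA", "COAD", "STAD", "SKCM", "PRAD", "GBM")
  with_seed(spec$seed, {
    rows <- list()
    pi <- 0L
    for (ct in seq_len(spec$n_cancer_types)) {
      ct_name <- types[(ct - 1L) %% length(types) + 1L]
      for (p in seq_len(spec$patients_per_type)) {
        pi <- pi + 1L
        mean_i <- spec$mutation_mean[ct]
        if (!is.null(spec$hypermutator) && spec$hypermutator$sample == pi) {
          mean_i <- mean_i * spec$hypermutator$multiplier
        }
        n_mut <- stats::rpois(1L, mean_i)
        if (n_mut == 0L) next
        sample_id <- sprintf("%s-P%03d", ct_name, p)
        kind <- sample(c("SNP", "INS", "DEL"), n_mut, replace = TRUE,
                       prob = spec$fractions)
        for (m in seq_len(n_mut)) {
          depth <- sample(30:200, 1L)
          af <- stats::rbeta(1L, spec$vaf_shape1, spec$vaf_shape2)
          af <- min(max(af + spec$vaf_shift, 0), 1)
          altc <- stats::rbinom(1L, depth, af)
          if (kind[m] == "SNP") {
            pos <- sample(2:(L - 1L), 1L)
            ref <- substr(ctg, pos, pos)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
            vt <- "SNP"
          } else if (kind[m] == "INS") {
            pos <- sample(2:(L - 2L), 1L)
            len <- sample(1:3, 1L)
            ref <- "-"
            alt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            vt <- "INS"
          } else {
            len <- sample(1:3, 1L)
            pos <- sample(2:(L - len - 1L), 1L)
            ref <- substr(ctg, pos, pos + len - 1L)
            alt <- "-"
            vt <- "DEL"
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ctg_name, pos = pos, ref = ref, alt = alt,
            variant_type = vt, sample_id = sample_id, cancer_type = ct_name,
            gene = gene_of(pos), alt_count = altc, total_count = depth,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Specification of a synthetic cfRNA read experiment
#'
#' Case and control samples of fixed-length reads drawn uniformly from
#' a genome; with per-read probability equal to the group's spike
#' rate, a nullomer from the spike panel is embedded at a random
#' offset. Per-base substitution errors (optional) are applied outside
#' the embedded span only, so the embedded signal is never corrupted.
#'
#' @param n_cases,n_controls sample counts.
#' @param reads_per_sample reads per sample.
#' @param read_length read length in bp (>= panel k).
#' @param spike_panel character vector of nullomers to embed.
#' @param case_spike_rate,control_spike_rate per-read embedding
#'   probability per group, in \[0, 1\].
#' @param error_rate per-base substitution probability, in \[0, 1\].
#' @param seed integer seed.
#' @export
read_sim_spec <- function(n_cases = 30L, n_controls = 30L,
                          reads_per_sample = 2000L, read_length = 50L,
                          spike_panel, case_spike_rate = 0.1,
                          control_spike_rate = 0.01, error_rate = 0,
                          seed = 1L) {
  rates <- c(case_spike_rate, control_spike_rate, error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (read_length < max(nchar(spike_panel))) {
    stop("read length must be >= panel k-mer length", call. = FALSE)
  }
  list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
       reads_per_sample = as.integer(reads_per_sample),
       read_length = as.integer(read_length),
       spike_panel = toupper(spike_panel),
       case_spike_rate = case_spike_rate,
       control_spike_rate = control_spike_rate,
       error_rate = error_rate, seed = as.integer(seed))
}

# Occurrences of `kmer` (or its reverse complement) in one read,
# counted window by window — the brute-force reference used to build
# truth tables.
count_in_read <- function(read, kmer) {
  k <- nchar(kmer)
  n <- nchar(read)
  if (n < k) return(0L)
  rc <- reverse_complement(kmer)
  wins <- substring(read, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  sum(wins == kmer | wins == rc)
}

#' Simulate cfRNA read sets with spiked nullomers
#'
#' Implements [read_sim_spec()]. Every panel sequence is verified to be
#' a nullomer of the genome first (a panel member present in the genome
#' is rejected). Embedding uses rejection sampling so that, at zero
#' error rate, each spiked read contains its embedded panel nullomer
#' exactly once and no other panel member; the returned truth table of
#' embedded counts therefore matches a direct scan exactly.
#'
#' @param genome genome as accepted by [nullomer_index()].
#' @param spec list from [read_sim_spec()].
#' @param index optional prebuilt `NullomerIndex` at the panel's k
#'   (built on the fly when NULL).
#' @return list with `samples` (named list of character read vectors),
#'   `labels` (cancer/healthy per sample), `truth` (samples x panel
#'   matrix of embedded counts), `spec`.
#' @export
simulate_reads <- function(genome, spec, index = NULL) {
  contigs <- as_contigs(genome)
  ctg <- contigs[[1]]
  L <- nchar(ctg)
  panel <- spec$spike_panel
  k <- unique(nchar(panel))
  if (length(k) != 1L) {
    stop("spike panel sequences must share one length", call. = FALSE)
  }
  if (is.null(index)) index <- nullomer_index(contigs, k)
  if (!all(is_nullomer(index, panel))) {
    stop("spike panel contains sequence(s) present in the genome: not a nullomer",
         call. = FALSE)
  }
  rl <- spec$read_length
  if (L < rl) stop("genome shorter than the read length", call. = FALSE)
  n_samples <- spec$n_cases + spec$n_controls
  labels <- c(rep("cancer", spec$n_cases), rep("healthy", spec$n_controls))
  ids <- sprintf("%s_%02d", ifelse(labels == "cancer", "case", "ctrl"),
                 c(seq_len(spec$n_cases), seq_len(spec$n_controls)))
  truth <- matrix(0L, n_samples, length(panel),
                  dimnames = list(ids, panel))
  bases <- c("A", "C", "G", "T")
  samples <- with_seed(spec$seed, {
    out <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      rate <- if (labels[s] == "cancer") spec$case_spike_rate else
        spec$control_spike_rate
      starts <- sample(L - rl + 1L, spec$reads_per_sample, replace = TRUE)
      reads <- substring(ctg, starts, starts + rl - 1L)
      spiked <- stats::runif(spec$reads_per_sample) < rate
      emb_off <- rep(NA_integer_, spec$reads_per_sample)
      for (i in which(spiked)) {
        pj <- sample(length(panel), 1L)
        want <- integer(length(panel))
        want[pj] <- 1L
        cand <- NA_character_
        for (try in 1:50) {
          off <- sample(rl - k + 1L, 1L)
          cand <- reads[i]
          substr(cand, off, off + k - 1L) <- panel[pj]
          hits <- vapply(panel, count_in_read, integer(1), read = cand)
          if (identical(unname(hits), want)) break
          cand <- NA_character_
        }
        if (is.na(cand)) {   # fall back to a clean unspiked read
          spiked[i] <- FALSE
          next
        }
        reads[i] <- cand
        emb_off[i] <- off
        truth[s, pj] <- truth[s, pj] + 1L
      }
      if (spec$error_rate > 0) {
        for (i in seq_along(reads)) {
          hit <- which(stats::runif(rl) < spec$error_rate)
          if (!is.na(emb_off[i])) {   # never corrupt the embedded span
            hit <- hit[hit < emb_off[i] | hit > emb_off[i] + k - 1L]
          }
          r <- reads[i]
          for (j in hit) {
            substr(r, j, j) <- sample(setdiff(bases, substr(r, j, j)), 1L)
          }
          reads[i] <- r
        }
      }
      out[[s]] <- reads
    }
    names(out) <- ids
    out
  })
  list(samples = samples, labels = labels, truth = truth, spec = spec)
}
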