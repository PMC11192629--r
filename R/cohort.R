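#' Per-patient emergence summaries
#'
#' Collapses an emergence table (one k) to one row per sample: total
#' mutations, nullomer-emerging mutations, and the number of distinct
#' canonical nullomers the sample created.
#'
#' @param emergence data.frame from [batch_emergence()], restricted to
#'   a single k.
#' @return data.frame with columns `sample_id`, `cancer_type`,
#'   `n_mutations`, `n_emerging_mutations`, `n_distinct_nullomers`.
#' @export
summarize_patients <- function(emergence) {
  stopifnot(is.data.frame(emergence))
  if (nrow(emergence) && length(unique(emergence$k)) > 1L) {
    stop("emergence table spans several k; filter to one k first",
         call. = FALSE)
  }
  ids <- unique(emergence$sample_id)
  out <- lapply(ids, function(s) {
    rows <- emergence[emergence$sample_id == s, , drop = FALSE]
    data.frame(
      sample_id = s,
      cancer_type = rows$cancer_type[1],
      n_mutations = nrow(rows),
      n_emerging_mutations = sum(rows$n_emerged >= 1L),
      n_distinct_nullomers = length(unique(unlist(split_emerged(rows$emerged)))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), cancer_type = character(0),
                      n_mutations = integer(0),
                      n_emerging_mutations = integer(0),
                      n_distinct_nullomers = integer(0))
  }
  out
}

#' Proportion of mutations causing nullomer emergence
#'
#' @inheritParams summarize_patients
#' @param group_by `"global"` for a single pooled proportion or
#'   `"cancer_type"` for one proportion per cohort.
#' @return named numeric vector of proportions in \[0, 1\].
#' @export
emergence_proportion <- function(emergence, group_by = c("global", "cancer_type")) {
  group_by <- match.arg(group_by)
  if (nrow(emergence) == 0L) stop("empty emergence table", call. = FALSE)
  emerging <- emergence$n_emerged >= 1L
  if (group_by == "global") {
    return(c(global = mean(emerging)))
  }
  tapply(emerging, emergence$cancer_type, mean)
}

#' Correlation between mutation burden and nullomer burden
#'
#' Pearson correlation (with the two-sided t-transform p-value) between
#' per-patient mutation counts and distinct-nullomer counts.
#'
#' @param summaries data.frame from [summarize_patients()].
#' @return list with `r`, `p`, `n`.
#' @export
mutation_nullomer_correlation <- function(summaries) {
  x <- summaries$n_mutations
  y <- summaries$n_distinct_nullomers
  if (length(x) < 3L) stop("need at least 3 patients", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort-wide nullomer recurrence
#'
#' One row per canonical nullomer: in how many distinct patients it
#' emerged, the fraction of the cohort, in how many cancer types, and
#' the genes where it arose. Ranked by patient count descending, ties
#' broken lexicographically by nullomer; the ranking is independent of
#' input row order. The fraction denominator is the full cohort size
#' (all samples in the table, or `cohort_size` when the table does not
#' carry every sample).
#'
#' @inheritParams summarize_patients
#' @param cohort_size optional cohort denominator; defaults to the
#'   number of distinct samples in the table.
#' @return data.frame with columns `nullomer`, `n_patients`,
#'   `patient_fraction`, `n_cancer_types`, `genes` (comma-separated).
#' @export
recurrence_table <- function(emergence, cohort_size = NULL) {
  empty <- data.frame(nullomer = character(0), n_patients = integer(0),
                      patient_fraction = numeric(0),
                      n_cancer_types = integer(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(emergence) == 0L) return(empty)
  cohort_size <- cohort_size %||% length(unique(emergence$sample_id))
  lst <- split_emerged(emergence$emerged)
  lens <- lengths(lst)
  keep <- lens > 0L
  if (!any(keep)) return(empty)
  long <- data.frame(
    nullomer = unlist(lst[keep], use.names = FALSE),
    sample_id = rep(emergence$sample_id[keep], lens[keep]),
    cancer_type = rep(emergence$cancer_type[keep], lens[keep]),
    gene = rep(emergence$gene[keep], lens[keep]),
    stringsAsFactors = FALSE)
  by_null <- split(long, long$nullomer)
  out <- data.frame(
    nullomer = names(by_null),
    n_patients = vapply(by_null, function(d) length(unique(d$sample_id)),
                        integer(1)),
    n_cancer_types = vapply(by_null, function(d)
      length(unique(d$cancer_type[!is.na(d$cancer_type)])), integer(1)),
    genes = vapply(by_null, function(d)
      paste(sort(unique(d$gene[!is.na(d$gene)])), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  out$patient_fraction <- out$n_patients / cohort_size
  out <- out[order(-out$n_patients, out$nullomer), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("nullomer", "n_patients", "patient_fraction", "n_cancer_types",
          "genes")]
}

#' Top recurrent nullomers as a screening panel
#'
#' The first `n` nullomers of the ranked recurrence table (all of them
#' if fewer), i.e. the most frequently emerging nullomers across the
#' cohort — the construction used to assemble a cfRNA screening panel.
#'
#' @param recurrence data.frame from [recurrence_table()].
#' @param n panel size (default 100000).
#' @return character vector of nullomers.
#' @export
top_panel <- function(recurrence, n = 100000L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("panel size must be a positive integer", call. = FALSE)
  }
  utils::head(recurrence$nullomer, n)
}

#' Cancer-type specific nullomers
#'
#' A nullomer is specific to a cancer type when it emerged in at least
#' one patient of that type and in no patient of any other type.
#'
#' @inheritParams summarize_patients
#' @return named list mapping each cancer type to its (possibly empty)
#'   sorted vector of specific nullomers.
#' @export
cancer_type_specific <- function(emergence) {
  types <- unique(emergence$cancer_type[!is.na(emergence$cancer_type)])
  if (length(types) < 2L) {
    stop("specificity undefined with fewer than 2 cancer types",
         call. = FALSE)
  }
  lst <- split_emerged(emergence$emerged)
  lens <- lengths(lst)
  keep <- lens > 0L
  long_null <- unlist(lst[keep], use.names = FALSE)
  long_type <- rep(emergence$cancer_type[keep], lens[keep])
  type_sets <- tapply(long_type, long_null,
                      function(x) unique(x[!is.na(x)]))
  specific <- names(type_sets)[lengths(type_sets) == 1L]
  out <- stats::setNames(vector("list", length(types)), sort(types))
  for (t in names(out)) out[[t]] <- character(0)
  for (nl in specific) {
    t <- type_sets[[nl]]
    out[[t]] <- c(out[[t]], nl)
  }
  lapply(out, sort)
}

#' Gene ranking by density of nullomer-emerging mutations
#'
#' Density = number of nullomer-emerging mutations in the gene divided
#' by its coding length in bp; genes absent from the length map are
#' excluded with a warning. Ties are broken alphabetically.
#'
#' @inheritParams summarize_patients
#' @param coding_lengths data.frame with columns `gene` and `length`
#'   (coding bp), or a named numeric vector.
#' @return data.frame with `gene`, `n_emerging`, `coding_length`,
#'   `density`, sorted by density descending.
#' @export
gene_density <- function(emergence, coding_lengths) {
  if (is.data.frame(coding_lengths)) {
    lens <- stats::setNames(coding_lengths$length, coding_lengths$gene)
  } else {
    lens <- coding_lengths
  }
  if (any(lens <= 0)) stop("coding lengths must be positive", call. = FALSE)
  genes <- names(lens)
  em <- emergence[emergence$n_emerged >= 1L, , drop = FALSE]
  missing_genes <- setdiff(unique(em$gene), genes)
  if (length(missing_genes)) {
    warning("gene(s) missing from coding-length map excluded: ",
            paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(em$gene, levels = genes))
  out <- data.frame(
    gene = genes,
    n_emerging = as.integer(counts),
    coding_length = as.numeric(lens),
    stringsAsFactors = FALSE)
  out$density <- out$n_emerging / out$coding_length
  out <- out[order(-out$density, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' VAF comparison between emerging and non-emerging mutations
#'
#' Stratifies variant allele frequencies by whether the mutation
#' created at least one nullomer and compares the two groups with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @inheritParams summarize_patients
#' @param genes optional gene filter (character vector).
#' @return list with `summary` (per-group n, mean, median) and `p`
#'   (NA when either group is empty).
#' @export
vaf_by_emergence <- function(emergence, genes = NULL) {
  tab <- emergence
  if (!is.null(genes)) tab <- tab[tab$gene %in% genes, , drop = FALSE]
  tab <- tab[!is.na(tab$vaf), , drop = FALSE]
  grp <- ifelse(tab$n_emerged >= 1L, "emerging", "non_emerging")
  summ <- do.call(rbind, lapply(c("non_emerging", "emerging"), function(g) {
    v <- tab$vaf[grp == g]
    data.frame(group = g, n = length(v),
               mean_vaf = if (length(v)) mean(v) else NA_real_,
               median_vaf = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  p <- if (all(summ$n > 0L)) {
    stats::wilcox.test(tab$vaf[grp == "emerging"],
                       tab$vaf[grp == "non_emerging"],
                       alternative = "two.sided", exact = NULL)$p.value
  } else {
    NA_real_
  }
  list(summary = summ, p = p)
}
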