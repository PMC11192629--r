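# A hand-built emergence table used across the aggregation tests.
toy_emergence <- function() {
  data.frame(
    sample_id = c("p1", "p1", "p2", "p3", "p3", "p4"),
    cancer_type = c("LUAD", "LUAD", "LUAD", "LIHC", "LIHC", "LIHC"),
    gene = c("TP53", "KRAS", "TP53", "TP53", "EGFR", "KRAS"),
    chrom = "c1", pos = 1:6, variant_type = "SNP",
    vaf = c(0.4, 0.3, 0.5, 0.2, 0.1, 0.6), k = 4L,
    channel = NA_character_,
    n_emerged = c(2L, 1L, 1L, 1L, 0L, 0L),
    emerged = c("AAAC,AACA", "AAAC", "AAAC", "AAGG", "", ""),
    stringsAsFactors = FALSE)
}

test_that("summarize_patients counts mutations and distinct nullomers", {
  s <- summarize_patients(toy_emergence())
  s <- s[order(s$sample_id), ]
  expect_equal(s$n_mutations, c(2L, 1L, 2L, 1L))
  expect_equal(s$n_emerging_mutations, c(2L, 1L, 1L, 0L))
  # p1 emits {AAAC, AACA} twice over -> 2 distinct
  expect_equal(s$n_distinct_nullomers, c(2L, 1L, 1L, 0L))
  expect_true(all(s$n_emerging_mutations <= s$n_mutations))
  expect_identical(s$n_distinct_nullomers == 0L,
                   s$n_emerging_mutations == 0L)
})

test_that("emergence_proportion pools globally and per cancer type", {
  tab <- toy_emergence()
  expect_equal(unname(emergence_proportion(tab)), 4 / 6)
  per <- emergence_proportion(tab, "cancer_type")
  expect_equal(per[["LUAD"]], 1)
  expect_equal(per[["LIHC"]], 1 / 3)
  # group proportions weighted by group size reproduce the global one
  n <- table(tab$cancer_type)
  expect_equal(sum(per[names(n)] * as.numeric(n)) / sum(n),
               unname(emergence_proportion(tab)))
  expect_error(emergence_proportion(tab[0, ]), "empty")
})

test_that("mutation-nullomer correlation handles exact and degenerate cases", {
  s <- data.frame(n_mutations = c(1, 2, 3), n_distinct_nullomers = c(2, 4, 6))
  expect_equal(mutation_nullomer_correlation(s)$r, 1)
  s2 <- data.frame(n_mutations = c(1, 2, 3), n_distinct_nullomers = c(6, 4, 2))
  expect_equal(mutation_nullomer_correlation(s2)$r, -1)
  s3 <- data.frame(n_mutations = c(1, 1, 1), n_distinct_nullomers = c(1, 2, 3))
  expect_error(mutation_nullomer_correlation(s3), "zero variance")
  expect_error(mutation_nullomer_correlation(s[1:2, ]), "3 patients")
})

test_that("per-variant Poisson emergence gives a strong burden correlation", {
  # each variant contributes ~Poisson(2) nullomers; patients differ in
  # mutation burden, so counts track burden tightly
  set.seed(303)
  rows <- do.call(rbind, lapply(1:30, function(p) {
    n_mut <- sample(5:150, 1)    # wide burden range across patients
    emerged <- vapply(seq_len(n_mut), function(m) {
      n_new <- rpois(1, 2)
      if (n_new == 0) return("")
      paste(decode_kmer(sample(0:65535, n_new), 8), collapse = ",")
    }, character(1))
    data.frame(sample_id = sprintf("p%02d", p), cancer_type = "LUAD",
               gene = "G1", chrom = "c1", pos = seq_len(n_mut),
               variant_type = "SNP", vaf = NA_real_, k = 8L,
               channel = NA_character_,
               n_emerged = lengths(strsplit(emerged, ",")) * nzchar(emerged),
               emerged = emerged, stringsAsFactors = FALSE)
  }))
  r <- mutation_nullomer_correlation(summarize_patients(rows))
  expect_gt(r$r, 0.9)
  expect_lt(r$p, 1e-4)
})

test_that("recurrence_table ranks by distinct patients with lexicographic ties", {
  tab <- toy_emergence()
  rec <- recurrence_table(tab, cohort_size = 10)
  expect_equal(rec$nullomer[1], "AAAC")
  expect_equal(rec$n_patients[1], 2L)          # p1 (twice) and p2
  expect_equal(rec$patient_fraction[1], 0.2)   # 2 of the 10-patient cohort
  # AAAC seen in two rows of p1 counts once
  aaca <- rec[rec$nullomer == "AACA", ]
  expect_equal(aaca$n_patients, 1L)
  aagg <- rec[rec$nullomer == "AAGG", ]
  expect_equal(aagg$n_cancer_types, 1L)
  # ties broken lexicographically
  singles <- rec$nullomer[rec$n_patients == 1L]
  expect_identical(singles, sort(singles))
  # order-independence
  shuffled <- tab[sample(nrow(tab)), ]
  expect_identical(recurrence_table(shuffled, cohort_size = 10), rec)
  expect_equal(nrow(recurrence_table(tab[0, ])), 0)
})

test_that("top_panel truncates the ranked table deterministically", {
  rec <- recurrence_table(toy_emergence())
  expect_length(top_panel(rec, 2), 2)
  expect_identical(top_panel(rec, 100), rec$nullomer)
  expect_identical(top_panel(rec, 2), rec$nullomer[1:2])
  expect_error(top_panel(rec, 0), "positive")
})

test_that("cancer_type_specific implements the exclusivity definition", {
  tab <- toy_emergence()
  spec <- cancer_type_specific(tab)
  # AAAC appears in LUAD (p1, p2) only; AACA in LUAD only; AAGG in LIHC only
  expect_setequal(spec$LUAD, c("AAAC", "AACA"))
  expect_setequal(spec$LIHC, "AAGG")
  # a nullomer shared across types belongs to no set
  tab2 <- rbind(tab, data.frame(sample_id = "p9", cancer_type = "LIHC",
                                gene = "TP53", chrom = "c1", pos = 9,
                                variant_type = "SNP", vaf = 0.5, k = 4L,
                                channel = NA_character_, n_emerged = 1L,
                                emerged = "AAAC", stringsAsFactors = FALSE))
  spec2 <- cancer_type_specific(tab2)
  expect_false("AAAC" %in% unlist(spec2))
  # every specific nullomer appears in exactly one set
  all_specific <- unlist(spec)
  expect_equal(anyDuplicated(all_specific), 0L)
  expect_error(cancer_type_specific(tab[tab$cancer_type == "LUAD", ]),
               "fewer than 2")
})

test_that("gene_density ranks genes by emerging mutations per coding bp", {
  tab <- toy_emergence()
  lens <- data.frame(gene = c("TP53", "KRAS", "EGFR"),
                     length = c(1000, 500, 2000))
  gd <- gene_density(tab, lens)
  expect_equal(gd$density[gd$gene == "TP53"], 3 / 1000)
  expect_equal(gd$density[gd$gene == "KRAS"], 1 / 500)
  expect_equal(gd$density[gd$gene == "EGFR"], 0)
  expect_identical(gd$gene[1], "TP53")  # 0.003 > 0.002
  # equal densities order alphabetically
  lens2 <- data.frame(gene = c("TP53", "KRAS"), length = c(1500, 500))
  gd2 <- gene_density(tab, lens2)
  expect_identical(gd2$gene, c("KRAS", "TP53"))
  expect_warning(gene_density(tab, lens[1, ]), "missing")
  expect_error(gene_density(tab, data.frame(gene = "TP53", length = 0)),
               "positive")
})

test_that("vaf_by_emergence summarizes groups and applies Mann-Whitney", {
  # identical groups: no signal
  flat <- toy_emergence()
  flat$vaf <- 0.5
  res <- suppressWarnings(vaf_by_emergence(flat))  # ties: approximate p
  expect_equal(res$summary$median_vaf, c(0.5, 0.5))
  expect_true(is.na(res$p) || res$p > 0.99)  # fully tied: no signal

  # fully separated 3 vs 3: exact two-sided rank-sum p = 2/choose(6,3) = 0.1
  tab <- toy_emergence()
  tab$vaf <- c(0.9, 0.8, 0.85, 0.55, 0.1, 0.2)  # emerging rows 1-4
  tab$n_emerged <- c(1L, 1L, 1L, 0L, 0L, 0L)
  tab$emerged <- c("AAAC", "AAAC", "AAAC", "", "", "")
  res2 <- vaf_by_emergence(tab)
  expect_equal(res2$p, 0.1)
  em <- res2$summary[res2$summary$group == "emerging", ]
  expect_equal(em$median_vaf, 0.85)

  # empty group: summaries only
  allpos <- toy_emergence()
  allpos$n_emerged <- 1L
  res3 <- vaf_by_emergence(allpos)
  expect_true(is.na(res3$p))
})
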