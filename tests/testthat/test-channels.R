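test_that("SBS96 labels are expressed on the pyrimidine strand", {
  g <- c(chr1 = "GACAG")       # C at pos 3 in context ACA
  v <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "T",
                  variant_type = "SNP")
  expect_equal(classify_sbs96(g, v), "A[C>T]A")

  g2 <- c(chr1 = "ATGAC")      # G at pos 3 in context TGA -> revcomp TCA
  v2 <- data.frame(chrom = "chr1", pos = 3, ref = "G", alt = "A",
                   variant_type = "SNP")
  expect_equal(classify_sbs96(g2, v2), "T[C>T]A")
})

test_that("SBS96 classification is strand-symmetric", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    triplet <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    ref <- substr(triplet, 2, 2)
    alt <- sample(setdiff(bases, ref), 1)
    g <- setNames(paste0("A", triplet, "A"), "c")
    v <- data.frame(chrom = "c", pos = 3, ref = ref, alt = alt,
                    variant_type = "SNP")
    # same variant described on the opposite strand
    g_rc <- setNames(reverse_complement(g[[1]]), "c")
    v_rc <- data.frame(chrom = "c", pos = 3, ref = reverse_complement(ref),
                       alt = reverse_complement(alt), variant_type = "SNP")
    expect_equal(classify_sbs96(g, v), classify_sbs96(g_rc, v_rc))
  }
})

test_that("exhaustive SBS96 enumeration yields exactly 96 channels", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(five = bases, ref = bases, three = bases,
                        alt = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  labels <- mapply(function(five, ref, three, alt) {
    g <- setNames(paste0("A", five, ref, three, "A"), "c")
    v <- data.frame(chrom = "c", pos = 3, ref = ref, alt = alt,
                    variant_type = "SNP")
    classify_sbs96(g, v)
  }, combos$five, combos$ref, combos$three, combos$alt)
  expect_equal(length(unique(labels)), 96L)
  expect_setequal(unique(labels), sbs96_labels())
  expect_equal(length(sbs96_labels()), 96L)
})

test_that("SBS96 rejects non-SNPs and contig-edge variants", {
  g <- c(chr1 = "ACGT")
  expect_error(classify_sbs96(g, data.frame(chrom = "chr1", pos = 2,
                                            ref = "C", alt = "-",
                                            variant_type = "DEL")), "SNP")
  expect_error(classify_sbs96(g, data.frame(chrom = "chr1", pos = 1,
                                            ref = "A", alt = "C",
                                            variant_type = "SNP")),
               "unclassifiable")
})

test_that("ID83 labels 1 bp indels by pyrimidine base and homopolymer run", {
  g <- c(c1 = "ATTTTTTGCA")          # run of six T
  del <- data.frame(chrom = "c1", pos = 4, ref = "T", alt = "-",
                    variant_type = "DEL")
  expect_equal(classify_id83(g, del), "1:Del:T:6")

  g2 <- c(c1 = "ACGCA")              # insertion of T with no adjacent T
  ins <- data.frame(chrom = "c1", pos = 2, ref = "-", alt = "T",
                    variant_type = "INS")
  expect_equal(classify_id83(g2, ins), "1:Ins:T:0")

  # purine events are reported on the pyrimidine strand
  g3 <- c(c1 = "TCAAAGG")            # deletion of A in a 3-run -> T channel
  del3 <- data.frame(chrom = "c1", pos = 4, ref = "A", alt = "-",
                     variant_type = "DEL")
  expect_equal(classify_id83(g3, del3), "1:Del:T:3")

  # run-length categories cap at 6+ (del) and 5+ (ins)
  g4 <- c(c1 = paste0("A", strrep("C", 9), "G"))
  del4 <- data.frame(chrom = "c1", pos = 5, ref = "C", alt = "-",
                     variant_type = "DEL")
  expect_equal(classify_id83(g4, del4), "1:Del:C:6")
  ins4 <- data.frame(chrom = "c1", pos = 5, ref = "-", alt = "C",
                     variant_type = "INS")
  expect_equal(classify_id83(g4, ins4), "1:Ins:C:5")
})

test_that("ID83 labels longer indels by repeat and microhomology context", {
  # CA deleted from (CA)x3: 3 tandem copies
  g <- c(c1 = "TTCACACATT")
  del <- data.frame(chrom = "c1", pos = 3, ref = "CA", alt = "-",
                    variant_type = "DEL")
  expect_equal(classify_id83(g, del), "2:Del:R:3")

  # TC inserted right after the existing TC copy at positions 2-3
  ins <- data.frame(chrom = "c1", pos = 3, ref = "-", alt = "TC",
                    variant_type = "INS")
  expect_equal(classify_id83(g, ins), "2:Ins:R:1")

  # deletion of TAG whose prefix TA recurs after the junction: 2 bp homology
  g2 <- c(c1 = "GGCTAGTACC")
  del2 <- data.frame(chrom = "c1", pos = 4, ref = "TAG", alt = "-",
                     variant_type = "DEL")
  expect_equal(classify_id83(g2, del2), "3:Del:M:2")

  # no repeat, no homology
  g3 <- c(c1 = "GGGGTACGGG")
  del3 <- data.frame(chrom = "c1", pos = 5, ref = "TAC", alt = "-",
                     variant_type = "DEL")
  expect_equal(classify_id83(g3, del3), "3:Del:R:1")

  expect_error(classify_id83(g, data.frame(chrom = "c1", pos = 3, ref = "C",
                                           alt = "T", variant_type = "SNP")),
               "INS or DEL")
})

test_that("the ID83 label universe has exactly 83 channels and is closed", {
  labs <- id83_labels()
  expect_equal(length(labs), 83L)
  expect_equal(anyDuplicated(labs), 0L)
  # 12 + 12 one-bp, 24 + 24 repeat, 11 microhomology
  expect_equal(sum(grepl("^1:Del", labs)), 12L)
  expect_equal(sum(grepl("^1:Ins", labs)), 12L)
  expect_equal(sum(grepl("Del:R", labs)), 24L)
  expect_equal(sum(grepl("Ins:R", labs)), 24L)
  expect_equal(sum(grepl("Del:M", labs)), 11L)

  # random indels always classify into the universe
  set.seed(31)
  g <- random_genome(3000, seed = 44)
  for (i in 1:100) {
    if (runif(1) < 0.5) {
      len <- sample(1:7, 1)
      pos <- sample(seq(2, nchar(g[[1]]) - len - 1), 1)
      v <- data.frame(chrom = names(g), pos = pos,
                      ref = substr(g[[1]], pos, pos + len - 1), alt = "-",
                      variant_type = "DEL")
    } else {
      len <- sample(1:7, 1)
      pos <- sample(seq(2, nchar(g[[1]]) - 2), 1)
      v <- data.frame(chrom = names(g), pos = pos, ref = "-",
                      alt = paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""),
                      variant_type = "INS")
    }
    expect_true(classify_id83(g, v) %in% labs)
  }
})
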