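test_that("FASTA reading normalizes U to T, concatenates wrapped lines and keeps duplicates", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU"), p)
  fa <- read_fasta(p)
  expect_equal(fa$id, "a")
  expect_equal(fa$sequence, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "GGG"), p)
  fa <- read_fasta(p)
  expect_equal(nrow(fa), 2L)
  expect_equal(fa$sequence[1], "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), p)
  expect_warning(fa <- read_fasta(p), "duplicate")
  expect_equal(nrow(fa), 2L)

  writeLines(c(">x", "ACGT", ">y", ""), p)
  expect_error(read_fasta(p), "empty sequence")
})

test_that("FASTQ reading accepts 4-line records and reports malformed records by index", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  fq <- read_fastq(p)
  expect_equal(fq$id, "r1")
  expect_equal(fq$sequence, "ACGT")
  expect_equal(fq$quality, "IIII")

  # '+' line carrying a repeated id is part of the dialect
  writeLines(c("@r1", "ACGT", "+r1", "IIII"), p)
  expect_equal(nrow(read_fastq(p)), 1L)

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACG"), p)
  expect_error(read_fastq(p), "record 2")

  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(read_fastq(p), "length mismatch")
})

test_that("FASTA/FASTQ writers round-trip through the readers", {
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c("s1", "s2"), c("ACGTACGT", "TTTTCCCC"), p)
  fa <- read_fasta(p)
  expect_equal(fa$sequence, c("ACGTACGT", "TTTTCCCC"))

  q <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c("r1", "r2"), c("ACGT", "GGTTAA"), q)
  fq <- read_fastq(q)
  expect_equal(fq$sequence, c("ACGT", "GGTTAA"))
  expect_equal(fq$quality, c("????", "??????"))
})

test_that("miRNA name codec parses and formats every grammar form", {
  m <- parse_mirna_name("osa-miR1432-5p_R+1")
  expect_equal(m$base, "osa-miR1432-5p")
  expect_equal(m$right_offset, 1L)
  expect_equal(m$arm, "5p")

  m <- parse_mirna_name("osa-miR160a-5p_R-1_1ss20CT")
  expect_equal(m$right_offset, -1L)
  expect_equal(m$substitutions,
               data.frame(pos = 20L, ref = "C", obs = "T",
                          stringsAsFactors = FALSE))

  m <- parse_mirna_name("osa-miR1436_L+3_1ss5CT")
  expect_equal(m$left_offset, 3L)
  expect_equal(m$substitutions$pos, 5L)

  m <- parse_mirna_name("osa-miR159a.1")
  expect_equal(m$base, "osa-miR159a.1")
  expect_equal(m$left_offset, 0L)
  expect_equal(nrow(m$substitutions), 0L)

  m <- parse_mirna_name("PC-5p-11519_1490")
  expect_equal(m$base, "PC-5p-11519")
  expect_equal(m$candidate_id, "1490")
  expect_equal(m$arm, "5p")

  m <- parse_mirna_name("osa-miR1320-5p_L-1R+1")
  expect_equal(m$left_offset, -1L)
  expect_equal(m$right_offset, 1L)

  m <- parse_mirna_name("osa-MIR2118l-p5")
  expect_equal(m$arm, "5p")

  # multiple substitutions
  m <- parse_mirna_name("x_2ss5CT12GA")
  expect_equal(m$substitutions$pos, c(5L, 12L))
  expect_equal(m$substitutions$obs, c("T", "A"))

  expect_error(parse_mirna_name("osa-miR1_bogus"), "bogus")
  expect_error(parse_mirna_name("osa-miR1_1ss5C"), "1ss5C")
})

test_that("name codec round-trips on randomly composed variant names", {
  set.seed(11)
  bases <- c("osa-miR9001-5p", "zma-miR123-3p", "osa-MIR55-p5",
             "bdi-miR5054", "osa-miR159a.1")
  for (i in 1:200) {
    base <- sample(bases, 1)
    lo <- sample(-3:3, 1)
    ro <- sample(-3:3, 1)
    k <- sample(0:2, 1)
    subs <- if (k > 0) {
      data.frame(pos = sort(sample(2:20, k)),
                 ref = sample(c("A", "C", "G", "T"), k, TRUE),
                 obs = sample(c("A", "C", "G", "T"), k, TRUE),
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
    nm <- mirna_name(base, lo, ro, subs)
    s <- format_mirna_name(nm)
    back <- parse_mirna_name(s)
    expect_equal(format_mirna_name(back), s)
    expect_equal(back$left_offset, lo)
    expect_equal(back$right_offset, ro)
  }
})

test_that("TE annotation readers apply the coordinate conventions", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttransposable_element\t1\t100\t.\t+\t.\tID=te1;te_class=I;te_type=Ty3-gypsy",
               "chr1\tsrc\ttransposable_element\t201\t300\t.\t-\t.\tID=te2;te_class=II;te_type=En/Spm"),
             g)
  te <- read_te_annotation(g, "gff3")
  expect_equal(te$start, c(0L, 200L))
  expect_equal(te$end, c(100L, 300L))
  expect_equal(te$te_type, c("Ty3-gypsy", "En/Spm"))

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tte1\t0\t+\tI\tTy3-gypsy", b)
  te2 <- read_te_annotation(b, "bed")
  expect_equal(te2$start, 0L)
  expect_equal(te2$end, 100L)

  # missing te_type defaults to unclassified
  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttransposable_element\t1\t100\t.\t+\t.\tID=te1;te_class=I"),
             g)
  expect_equal(read_te_annotation(g, "gff3")$te_type, "unclassified")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\ttransposable_element\t1\t100\t.\t+\t.\tID=te1;te_class=III"),
             g)
  expect_error(read_te_annotation(g, "gff3"), "allowed")
})

test_that("GFF3 writing and reading are mutually inverse on random loci", {
  set.seed(5)
  types <- data.frame(
    te_class = c("I", "I", "II", "II"),
    te_type = c("Ty3-gypsy", "LINE", "En/Spm", "hAT"),
    stringsAsFactors = FALSE)
  pick <- sample(1:4, 20, TRUE)
  starts <- sort(sample(0:10000, 20))
  te <- data.frame(chrom = "chr1", start = starts,
                   end = starts + sample(50:300, 20, TRUE),
                   strand = sample(c("+", "-"), 20, TRUE),
                   te_class = types$te_class[pick],
                   te_type = types$te_type[pick],
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_te_gff3(te, p)
  back <- read_te_annotation(p, "gff3")
  rownames(back) <- NULL
  expect_equal(back, te)
})

test_that("count tables round-trip with the raw/normalized flag", {
  x <- data.frame(id = c("b", "a"), L1 = c(1L, 2L), L2 = c(0L, 5L),
                  stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(x, p, "raw")
  back <- read_count_table(p)
  expect_equal(attr(back, "kind"), "raw")
  expect_equal(back$id, c("a", "b"))  # lexicographic order
  expect_equal(back$L2, c(5L, 0L))

  write_count_table(x[0, ], p, "normalized")
  back <- read_count_table(p)
  expect_equal(nrow(back), 0L)
  expect_equal(attr(back, "kind"), "normalized")
})
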