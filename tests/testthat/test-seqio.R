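test_that("span_length handles linear, wrapping and degenerate spans", {
  expect_identical(span_length(1294959, 1307485, 2847757, "linear"), 12527L)
  expect_identical(span_length(95, 5, 100, "circular"), 11L)
  expect_identical(span_length(7, 7, 100, "linear"), 1L)
  expect_identical(span_length(7, 7, 100, "circular"), 1L)
  expect_error(span_length(0, 5, 10, "linear"), "out of range")
  expect_error(span_length(9, 2, 10, "linear"), "linear")
})

test_that("complementary circular spans conserve total length", {
  set.seed(41)
  L <- 5000L
  for (i in 1:20) {
    a <- sample.int(L, 1)
    b <- sample.int(L, 1)
    if (a == (b %% L) + 1L) next  # avoid the empty complement edge
    s1 <- span_length(a, b, L, "circular")
    b2 <- (b %% L) + 1L
    a2 <- ((a - 2L) %% L) + 1L
    s2 <- span_length(b2, a2, L, "circular")
    expect_identical(s1 + s2, L)
  }
})

test_that("gc_percent excludes N and is invariant under revcomp and rotation", {
  expect_identical(gc_percent("GCGC"), 100)
  expect_identical(gc_percent("ATAT"), 0)
  expect_identical(gc_percent("GCATN"), 50)
  expect_error(gc_percent("NNNN"), "no A/C/G/T")
  g <- make_genome(4000, 0.63, seed = 5)
  expect_identical(gc_percent(g), gc_percent(revcomp(g)))
  expect_identical(gc_percent(g), gc_percent(rotate_seq(g, 1234)))
})

test_that("genome records validate coordinates, sorting and topology", {
  ft <- data.frame(kind = "CDS", start = c(50L, 10L), stop = c(82L, 21L),
                   strand = "+", locus_tag = c("b", "a"), product = "p")
  rec <- genome_record("r", strrep("ACGT", 30), "linear", ft)
  expect_identical(rec$features$locus_tag, c("a", "b"))
  expect_error(genome_record("r", "ACGT", "linear",
                             data.frame(kind = "CDS", start = 1L, stop = 9L,
                                        strand = "+", locus_tag = "x",
                                        product = "")),
               "outside")
  # wrap-around feature only on circular records
  wrap <- data.frame(kind = "misc", start = 100L, stop = 5L, strand = "+",
                     locus_tag = "w", product = "")
  expect_error(genome_record("r", strrep("ACGT", 30), "linear", wrap), "wrap")
  expect_silent(genome_record("r", strrep("ACGT", 30), "circular", wrap))
  # non-multiple-of-3 CDS on a linear record warns but is kept
  off <- data.frame(kind = "CDS", start = 1L, stop = 10L, strand = "+",
                    locus_tag = "x", product = "")
  expect_warning(r2 <- genome_record("r", strrep("ACGT", 30), "linear", off),
                 "divisible by 3")
  expect_identical(nrow(r2$features), 1L)
})

test_that("GenBank write/read round-trips a featured record", {
  lys <- build_lysogen(host_length = 4000, element_length = 2000, seed = 3)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(lys$host, path)
  back <- read_genbank(path)
  expect_identical(back$seq, lys$host$seq)
  expect_identical(back$topology, lys$host$topology)
  expect_identical(back$features, lys$host$features)
  # circular record with a wrapping feature survives too
  wrap <- data.frame(kind = "misc", start = 1990L, stop = 12L, strand = "-",
                     locus_tag = "w", product = "wrapper")
  circ <- genome_record("circ", lys$element$seq, "circular",
                        rbind(lys$element$features, wrap))
  write_genbank(circ, path)
  back2 <- read_genbank(path)
  expect_identical(back2$seq, circ$seq)
  expect_identical(back2$features, circ$features)
})

test_that("GenBank reader tolerates featureless records and flags bad files", {
  rec <- genome_record("bare", make_genome(300, 0.5, seed = 2), "circular")
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_identical(nrow(back$features), 0L)
  expect_identical(back$seq, rec$seq)
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("garbage", "more garbage"), bad)
  expect_error(read_genbank(bad), "LOCUS")
})

test_that("FASTA and FASTQ round-trip through Biostrings", {
  recs <- list(genome_record("a", "ACGTACGTAA", "linear"),
               genome_record("b", strrep("GATTACA", 10), "linear"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa, all = TRUE)
  expect_identical(vapply(back, `[[`, "", "seq"),
                   vapply(recs, `[[`, "", "seq"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(r1 = "ACGTACGTACGT", r2 = "GGGCCCAAATTT")
  write_fastq(reads, fq)
  expect_identical(read_fastq(fq), reads)
  # empty read set gives an empty, readable file
  write_fastq(character(), fq)
  expect_identical(length(readLines(fq)), 0L)
})

test_that("GFF3 output re-imports to the same feature table", {
  lys <- build_lysogen(host_length = 4000, element_length = 2000, seed = 9)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(lys$host, path)
  ft <- read_gff_features(path)
  expect_identical(ft$start, lys$host$features$start)
  expect_identical(ft$stop, lys$host$features$stop)
  expect_identical(ft$kind, lys$host$features$kind)
  expect_identical(ft$locus_tag, lys$host$features$locus_tag)
  expect_identical(ft$product, lys$host$features$product)
})

test_that("feature_seq and translate_cds honour strand and wrap", {
  seq <- paste0("ATGAAACCCGGGTAA", strrep("C", 30))
  ft <- data.frame(kind = "CDS", start = 1L, stop = 15L, strand = "+",
                   locus_tag = "fwd", product = "")
  rec <- genome_record("r", seq, "linear", ft)
  expect_identical(translate_cds(rec, "fwd"), "MKPG")
  # same CDS encoded on the minus strand
  seq2 <- paste0(strrep("C", 30), revcomp("ATGAAACCCGGGTAA"))
  ft2 <- data.frame(kind = "CDS", start = 31L, stop = 45L, strand = "-",
                    locus_tag = "rev", product = "")
  rec2 <- genome_record("r2", seq2, "linear", ft2)
  expect_identical(translate_cds(rec2, "rev"), "MKPG")
  # wrap-around span on a circular record
  rec3 <- genome_record("r3", "GGGTAACCCCCCATGAAACCC", "circular")
  expect_identical(span_seq(rec3, 13L, 6L), "ATGAAACCCGGGTAA")
})
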