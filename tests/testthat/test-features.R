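toy_record <- function(starts, stops, L = 100L, topology = "linear") {
  n <- length(starts)
  ft <- data.frame(kind = "CDS", start = as.integer(starts),
                   stop = as.integer(stops), strand = "+",
                   locus_tag = sprintf("g%02d", seq_len(n)), product = "")
  suppressWarnings(genome_record("toy", strrep("A", L), topology, ft))
}

test_that("spacing stats count overlapping and close genes once each", {
  # hand-enumerated 3-gene layout: g1-g2 overlap at bp 9; g2-g3 gap is
  # 32 - 21 - 1 = 10, so g3 is close and g2 stays counted as overlapping
  st <- spacing_stats(toy_record(c(1, 9, 32), c(9, 21, 40)))
  expect_identical(st$n_genes, 3L)
  expect_identical(st$n_overlapping_genes, 2L)
  expect_identical(st$n_close_genes, 1L)
  expect_identical(st$gaps, c(-1L, 10L))
  # a gap of 11 is no longer close
  st2 <- spacing_stats(toy_record(c(1, 20, 40), c(9, 28, 60)))
  expect_identical(st2$n_overlapping_genes, 0L)
  expect_identical(st2$n_close_genes, 2L)   # 20-9-1 = 10 counts both genes
  st3 <- spacing_stats(toy_record(c(1, 21), c(9, 40)))
  expect_identical(st3$n_close_genes, 0L)   # gap 11
  # single CDS
  st4 <- spacing_stats(toy_record(10, 30))
  expect_identical(st4$n_overlapping_genes, 0L)
  expect_identical(st4$n_close_genes, 0L)
})

test_that("circular adjacency includes the wrap-around pair", {
  st <- spacing_stats(toy_record(c(5, 50), c(20, 98), L = 100L,
                                 topology = "circular"))
  # wrap gap: 100 - 98 + 5 - 1 = 6 -> both genes close
  expect_identical(st$gaps[length(st$gaps)], 6L)
  expect_identical(st$n_close_genes, 2L)
})

test_that("spacing stats reproduce the published gene architecture of a real
           45 kb halovirus annotation", {
  st <- spacing_stats(hardycor1_features(), record_length = 45142L,
                      topology = "circular")
  expect_identical(st$n_genes, 53L)
  expect_identical(st$n_overlapping_genes, 27L)
  expect_identical(st$n_close_genes, 13L)
})

test_that("cxxc_scan reports all (possibly overlapping) CxxC starts", {
  expect_identical(cxxc_scan("CAACAAC"), c(1L, 4L))
  expect_identical(cxxc_scan("MAAAA"), integer())
  expect_identical(cxxc_scan("CCCCC"), c(1L, 2L))
  expect_identical(cxxc_scan("MCEFCGHCKLC"), c(2L, 5L, 8L))
})

test_that("longest_common_prefix is symmetric and bounded", {
  expect_identical(longest_common_prefix("MNANT", "MNANT"), 5L)
  expect_identical(longest_common_prefix("ABC", "XBC"), 0L)
  expect_identical(longest_common_prefix("MNANTAAA", "MNANTGGG"), 5L)
  for (i in 1:10) {
    a <- paste(sample(LETTERS[1:4], 20, replace = TRUE), collapse = "")
    b <- paste(sample(LETTERS[1:4], 15, replace = TRUE), collapse = "")
    expect_identical(longest_common_prefix(a, b), longest_common_prefix(b, a))
    expect_lte(longest_common_prefix(a, b), 15L)
  }
  expect_error(longest_common_prefix("", "A"), "non-empty")
})

test_that("find_direct_repeats recovers planted tandem repeats", {
  unit <- make_genome(50, 0.5, seed = 101)
  seq <- paste0("ACGT", unit, unit)
  hits <- find_direct_repeats(seq, min_len = 20)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$unit_length, 50L)
  expect_identical(hits$copy1_start, 5L)
  expect_identical(hits$copy2_start, 55L)
  expect_true(hits$tandem)
  # separated copies are not tandem
  seq2 <- paste0(unit, strrep("T", 37), unit)
  hits2 <- find_direct_repeats(seq2, min_len = 20)
  expect_false(hits2$tandem[1])
  expect_error(find_direct_repeats(seq, min_len = 4), ">= 8")
})

test_that("find_direct_repeats equals the O(n^2) diagonal oracle", {
  for (seed in 1:8) {
    g <- make_genome(600, 0.4, seed = seed)  # AT-rich: repeats arise by chance
    # plant one extra repeat to guarantee signal
    unit <- substr(g, 101, 140)
    g <- paste0(g, unit)
    got <- find_direct_repeats(g, min_len = 12)
    want <- oracle_direct_repeats(g, min_len = 12)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("find_slippery detects planted X XXY YYZ heptamers on both strands", {
  # CDS with GGGAAAT planted 19 nt before its end, mirroring the conserved
  # position upstream of tape-measure genes
  body <- paste0("ATG", strrep("GCA", 40), "GGGAAAT", "GC",
                 strrep("GCA", 4), "TGA")
  L <- nchar(body)
  pre <- strrep("C", 50)
  rec <- genome_record("s", paste0(pre, body, strrep("C", 20)), "linear",
                       data.frame(kind = "CDS", start = 51L,
                                  stop = 50L + L, strand = "+",
                                  locus_tag = "cds1", product = ""))
  hits <- find_slippery(rec, "cds1", tail_codons = 30)
  expect_identical(hits$heptamer, "GGGAAAT")
  expect_identical(hits$start, 50L + 3L + 120L + 1L)
  expect_true(hits$is_3prime_most)
  # same CDS on the minus strand: genome coordinate of the + strand interval
  rc <- paste0(strrep("C", 20), revcomp(body), strrep("C", 50))
  rec2 <- genome_record("s2", rc, "linear",
                        data.frame(kind = "CDS", start = 21L,
                                   stop = 20L + L, strand = "-",
                                   locus_tag = "cds1", product = ""))
  hits2 <- find_slippery(rec2, "cds1", tail_codons = 30)
  expect_identical(hits2$heptamer, "GGGAAAT")
  # re-extract at the reported + strand coordinate: must be the rc heptamer
  expect_identical(substr(rc, hits2$start, hits2$start + 6L),
                   revcomp("GGGAAAT"))
  # X == Y heptamers do not qualify
  rec3 <- genome_record("s3", "ATGAAATAA", "linear",
                        data.frame(kind = "CDS", start = 1L, stop = 9L,
                                   strand = "+", locus_tag = "c", product = ""))
  expect_identical(nrow(find_slippery(rec3, "c")), 0L)
  expect_error(find_slippery(rec3, "nope"), "locus_tag")
})

test_that("every reported heptamer re-matches the slippery predicate in place", {
  for (seed in 1:5) {
    lys <- build_lysogen(host_length = 4000, element_length = 2000, seed = seed)
    rec <- lys$host
    hits <- find_slippery(rec, "SYN_int_h", tail_codons = 60)
    if (!nrow(hits)) next
    for (i in seq_len(nrow(hits))) {
      h <- substr(rec$seq, hits$start[i], hits$start[i] + 6L)
      cs <- strsplit(if (identical(rec$features$strand[
        rec$features$locus_tag == "SYN_int_h"], "-")) revcomp(h) else h,
        "")[[1]]
      expect_true(cs[1] == cs[2] && cs[2] == cs[3] &&
                  cs[4] == cs[5] && cs[5] == cs[6] && cs[1] != cs[4])
    }
  }
})

test_that("tape-measure tail length follows the configured regression", {
  expect_identical(tmp_tail_length(703), 84)
  expect_identical(tmp_tail_length(138), 0)
  expect_identical(tmp_tail_length(1000), 129)
  expect_identical(tmp_tail_length(703, slope = 0.2, intercept = 0), 140)
})

test_that("protein length from CDS span removes the stop codon", {
  expect_identical(protein_len_from_cds(17894, 20005), 703L)
  expect_identical(protein_len_from_cds(1, 6), 1L)
  expect_identical(protein_len_from_cds(2337, 3560), 407L)
  expect_error(protein_len_from_cds(1, 7), "multiple of 3")
  # the public annotation table is internally consistent
  ft <- hardycor1_features()
  plens <- mapply(protein_len_from_cds, ft$start, ft$stop)
  expect_true(all(plens == (ft$stop - ft$start + 1) / 3 - 1))
  expect_identical(plens[ft$locus_tag == "HrrHc1_120"][[1]], 703L)
})
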