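test_that("find_att_core returns the longest shared tRNA suffix", {
  lys <- build_lysogen(att_len = 15, seed = 21)
  trna <- feature_seq(lys$host, "SYN_trna")
  hit <- find_att_core(trna, lys$element)
  expect_identical(hit$length, 15L)
  expect_identical(hit$core, lys$truth$att_core)
  expect_identical(hit$positions, lys$truth$attp_pos)
  expect_false(hit$ambiguous)
  # default construction uses the canonical 13 bp core
  lys13 <- build_lysogen(seed = 22)
  hit13 <- find_att_core(feature_seq(lys13$host, "SYN_trna"), lys13$element)
  expect_identical(hit13$length, 13L)
  # a tRNA with no match in the element yields NULL
  none <- find_att_core(strrep("T", 40), lys$element)
  expect_null(none)
})

test_that("find_att_core flags ambiguous placements and searches across the origin", {
  core <- "ACCGAGGCAAGGC"
  elem_seq <- paste0(core, strrep("T", 200), core, strrep("T", 200))
  elem <- genome_record("amb", elem_seq, "circular")
  hit <- find_att_core(paste0(strrep("G", 30), core), elem)
  expect_true(hit$ambiguous)
  expect_identical(sort(hit$positions), c(1L, 214L))
  # core straddling the origin is still found (circular search)
  elem2 <- genome_record("wrap",
                         paste0(substr(core, 6, 13), strrep("T", 100),
                                substr(core, 1, 5)),
                         "circular")
  hit2 <- find_att_core(paste0(strrep("G", 30), core), elem2)
  expect_identical(hit2$core, core)
  expect_identical(hit2$positions, 109L)
})

test_that("integrate and excise are exact inverses on synthetic lysogens", {
  for (seed in 1:10) {
    lys <- build_lysogen(host_length = 6000, element_length = 2500,
                         seed = seed)
    tr <- lys$truth
    exc <- excise_element(lys$host, tr$attL_start, tr$attR_start, tr$att_len)
    expect_identical(exc$element$seq, lys$element$seq)
    # the host's lifted CDS annotations land at the element's own coordinates
    exc_cds <- exc$element$features[exc$element$features$kind == "CDS", ]
    expect_identical(exc_cds$start, lys$element$features$start)
    expect_identical(exc_cds$stop, lys$element$features$stop)
    # restored host has lost exactly one element length and keeps one core
    expect_identical(genome_length(exc$host),
                     genome_length(lys$host) - tr$element_length)
    expect_identical(provirseq:::count_occurrences(exc$host$seq, tr$att_core),
                     1L)
    re <- integrate_element(exc$host, tr$attL_start + tr$att_len - 1L,
                            exc$element, tr$att_core)
    expect_identical(re$seq, lys$host$seq)
    expect_identical(re$features, lys$host$features)
  }
})

test_that("integration validates its geometry preconditions", {
  lys <- build_lysogen(host_length = 6000, element_length = 2500, seed = 31)
  tr <- lys$truth
  exc <- excise_element(lys$host, tr$attL_start, tr$attR_start, tr$att_len)
  # length conservation
  expect_identical(genome_length(integrate_element(
    exc$host, tr$attL_start + tr$att_len - 1L, exc$element, tr$att_core)),
    genome_length(exc$host) + tr$element_length)
  # att core absent or duplicated in the element
  expect_error(integrate_element(exc$host, tr$attL_start + tr$att_len - 1L,
                                 exc$element, "AAAAAAAAAAAAA"),
               "exactly once")
  dup <- genome_record("dup", paste0(exc$element$seq, tr$att_core,
                                     strrep("A", 50)), "circular")
  expect_error(integrate_element(exc$host, tr$attL_start + tr$att_len - 1L,
                                 dup, tr$att_core), "exactly once")
  # site not ending with the core
  expect_error(integrate_element(exc$host, tr$attL_start - 100L,
                                 exc$element, tr$att_core), "att core")
  # unequal repeats refuse to excise
  expect_error(excise_element(lys$host, tr$attL_start, tr$attR_start - 3L,
                              tr$att_len), "not identical")
  # degenerate excision: identical tandem cores with nothing between them
  tandem <- genome_record("t", paste0(tr$att_core, tr$att_core,
                                      strrep("A", 40)), "linear")
  expect_error(excise_element(tandem, 1L, 1L + tr$att_len, tr$att_len),
               "degenerate")
})

test_that("the planted bridging CDS is recovered and splits across the junction", {
  for (seed in c(3, 8, 15)) {
    lys <- build_lysogen(seed = seed)
    tr <- lys$truth
    br <- find_bridging_cds(lys$element, tr$attp_pos)
    expect_false(is.null(br))
    expect_identical(br$start, tr$bridging_orf$start)
    expect_identical(br$stop, tr$bridging_orf$stop)
    expect_identical(br$length, tr$bridging_orf$length)
    expect_identical(br$downstream_cds, "SYN_cxxc")
    expect_false(br$cxxc_warning)
    # provirus form: 5' piece ends at the element end (attR side),
    # 3' piece resumes at the origin (attL side)
    expect_identical(unname(br$provirus_form$five_prime),
                     c(tr$bridging_orf$start, tr$element_length))
    expect_identical(unname(br$provirus_form$three_prime),
                     c(1L, tr$bridging_orf$stop))
    # split-ORF property: in the integrated host, translation from the ORF
    # start reaches the end of the provirus without meeting a stop codon
    orf_host_start <- tr$provirus_end - tr$element_length + tr$bridging_orf$start
    seg <- substr(lys$host$seq, orf_host_start, tr$provirus_end)
    codons <- substring(seg, seq(1, nchar(seg) - 2, 3),
                        seq(3, nchar(seg), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("bridging scan rejects ORFs that do not span attP", {
  lys <- build_lysogen(seed = 40)
  tr <- lys$truth
  # an attP claimed inside the integrase CDS cannot be spanned by a
  # qualifying ORF (the ORF must start after the integrase stop)
  inside_int <- lys$element$features$start[
    lys$element$features$locus_tag == "SYN_int"] + 10L
  expect_null(find_bridging_cds(lys$element, inside_int))
  expect_error(find_bridging_cds(genome_record("bare", lys$element$seq,
                                               "circular"), tr$attp_pos),
               "integrase")
})

test_that("bridging scan works on minus-strand integrase layouts", {
  lys <- build_lysogen(seed = 55)
  tr <- lys$truth
  flipped <- provirseq:::revcomp_record(lys$element)
  n <- genome_length(lys$element)
  attp_flipped <- n - (tr$attp_pos + tr$att_len - 1L) + 1L
  br <- find_bridging_cds(flipped$record, attp_flipped)
  expect_false(is.null(br))
  expect_identical(br$strand, "-")
  expect_identical(br$length, tr$bridging_orf$length)
})

test_that("att core positions are rotation-invariant on circular elements", {
  lys <- build_lysogen(seed = 61)
  tr <- lys$truth
  trna <- feature_seq(lys$host, "SYN_trna")
  for (shift in c(500L, 2500L)) {
    rot <- genome_record("rot", rotate_seq(lys$element$seq, shift), "circular")
    hit <- find_att_core(trna, rot)
    expect_identical(hit$length, tr$att_len)
    # position maps back to the planted one under the rotation
    expect_identical(((hit$positions + shift - 2L) %% genome_length(rot)) + 1L,
                     tr$attp_pos)
  }
})
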