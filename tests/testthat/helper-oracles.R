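# Independent brute-force oracles and shared fixtures for the test suite.

# naive sliding-window k-mer counter (the oracle count_kmers is checked
# against); returns the full 4^k named vector like count_kmers does
naive_count_kmers <- function(seq, k, topology) {
  seq <- toupper(seq)
  if (topology == "circular" && k > 1L) {
    seq <- paste0(seq, substr(seq, 1L, k - 1L))
  }
  n <- nchar(seq)
  words <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  bases <- c("A", "C", "G", "T")
  all_kmers <- sort(do.call(paste0,
    expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)[rev(seq_len(k))]))
  tab <- table(factor(words, levels = all_kmers))
  out <- as.integer(tab)
  names(out) <- all_kmers
  out
}

# O(n^2) maximal exact direct repeat oracle: for every offset d, scan the
# diagonal of matches and emit maximal runs >= min_len
oracle_direct_repeats <- function(seq, min_len) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  n <- length(chars)
  res <- list()
  for (d in seq_len(n - 1L)) {
    m <- n - d
    if (m < min_len) break
    eq <- chars[seq_len(m)] == chars[seq_len(m) + d] &
      chars[seq_len(m)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_len)
    for (i in runs) {
      res[[length(res) + 1L]] <- c(r$lengths[i], starts[i], starts[i] + d)
    }
  }
  if (!length(res)) {
    return(data.frame(unit_length = integer(), copy1_start = integer(),
                      copy2_start = integer(), tandem = logical()))
  }
  m <- do.call(rbind, res)
  out <- data.frame(unit_length = m[, 1L], copy1_start = m[, 2L],
                    copy2_start = m[, 3L],
                    tandem = m[, 3L] == m[, 2L] + m[, 1L])
  out[order(-out$unit_length, out$copy1_start, out$copy2_start), ,
      drop = FALSE]
}

# Hardycor1 CDS coordinate table (public annotation of MT152698), as a
# feature table; the genome is 45,142 bp and circular
hardycor1_features <- function() {
  path <- system.file("extdata", "hardycor1_cds.tsv", package = "provirseq")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(kind = "CDS", start = tab$start, stop = tab$stop,
             strand = tab$strand, locus_tag = tab$locus_tag,
             product = tab$product, stringsAsFactors = FALSE)
}

# host with two integrated proviruses, for multi-provirus screens; returns
# the host record, both element records, and per-provirus truth coordinates
make_double_lysogen <- function(seed) {
  lysA <- build_lysogen(host_length = 12000, element_length = 4000,
                        att_len = 13, seed = seed)
  lysB <- build_lysogen(host_length = 12000, element_length = 4000,
                        att_len = 13, seed = seed + 1000L)
  hostA <- lysA$host
  trA <- lysA$truth
  trB <- lysB$truth
  # splice lysogen B's tRNA downstream of provirus A, then integrate B there
  insert_at <- trA$provirus_end + 2000L
  trnaB <- feature_seq(lysB$host, "SYN_trna")
  spliced <- paste0(substr(hostA$seq, 1, insert_at), trnaB,
                    substr(hostA$seq, insert_at + 1L, genome_length(hostA)))
  pre <- genome_record("SYN_double", spliced, "linear", hostA$features)
  siteB <- insert_at + nchar(trnaB)
  host2 <- integrate_element(pre, siteB, lysB$element, trB$att_core)
  provB_start <- siteB - trB$att_len + 1L
  provB_end <- siteB + trB$element_length
  list(host = host2, elements = list(lysA$element, lysB$element),
       table = data.frame(
         provirus_id = c("provA", "provB"),
         start = c(trA$provirus_start, provB_start),
         end = c(trA$provirus_end, provB_end),
         core_len = c(trA$att_len, trB$att_len),
         stringsAsFactors = FALSE))
}
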