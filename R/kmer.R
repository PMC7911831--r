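# Circular-genome k-mer census, Markov-odds under-representation, and
# palindromic-motif absence reports.
#
# Small virus genomes under pressure from host restriction-modification
# systems deplete the recognition motifs of host endonucleases, most of which
# are short palindromes. Absence (count 0) and strong under-representation
# (Markov odds well below 1) of 4-6 bp motifs are the signals summarised here.

#' Count k-mers on the forward strand
#'
#' Circular sequences contribute `L` windows (the census wraps the origin);
#' linear sequences `L - k + 1`. Windows containing `N` are skipped, so on a
#' circular genome without `N` the counts sum exactly to `L`.
#'
#' @param seq Nucleotide string.
#' @param k Word size, 1..8.
#' @param topology `"circular"` or `"linear"`.
#' @return Named integer vector over all `4^k` k-mers.
#' @examples
#' count_kmers("AAAA", 4, "circular")["AAAA"]  # 4
#' @export
count_kmers <- function(seq, k, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  seq <- toupper(seq)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must be in 1..8")
  if (k > nchar(seq)) stop("k exceeds sequence length")
  if (topology == "circular" && k > 1L) {
    seq <- paste0(seq, substr(seq, 1L, k - 1L))
  }
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
}

#' Maximal-order Markov odds ratio of a tetramer
#'
#' The observed tetramer count divided by its expectation under the
#' maximal-order (second-order) Markov model fitted from the same census:
#' `rho(w1w2w3w4) = N(w1w2w3w4) * N(w2w3) / (N(w1w2w3) * N(w2w3w4))`.
#' Values well below 1 indicate avoidance. Undefined (any denominator count
#' zero) yields `NA`.
#'
#' @param counts4,counts3,counts2 Named count vectors from [count_kmers()]
#'   with `k = 4, 3, 2` on the same sequence.
#' @param motif A tetramer.
#' @return The odds ratio (unrounded); tables conventionally print 2 decimals.
#' @export
markov_odds <- function(counts4, counts3, counts2, motif) {
  motif <- toupper(motif)
  if (nchar(motif) != 4L) stop("motif must be a tetramer")
  pre <- substr(motif, 1L, 3L)
  suf <- substr(motif, 2L, 4L)
  mid <- substr(motif, 2L, 3L)
  denom <- as.numeric(counts3[[pre]]) * as.numeric(counts3[[suf]])
  if (is.na(denom) || denom == 0) return(NA_real_)
  as.numeric(counts4[[motif]]) * as.numeric(counts2[[mid]]) / denom
}

#' Enumerate self-complementary (palindromic) k-mers
#'
#' A DNA palindrome equals its own reverse complement, which requires even
#' length; there are `4^(k/2)` of them.
#'
#' @param k Even word size, <= 8.
#' @return Character vector in lexicographic order.
#' @examples
#' palindromic_kmers(2)  # AT CG GC TA
#' @export
palindromic_kmers <- function(k) {
  k <- as.integer(k)
  if (k %% 2L != 0L) stop("k must be even: odd-length DNA palindromes do not exist")
  if (k > 8L) stop("k must be <= 8")
  half <- k %/% 2L
  bases <- c("A", "C", "G", "T")
  halves <- do.call(paste0, expand.grid(rep(list(bases), half))[rev(seq_len(half))])
  full <- vapply(halves, function(h) paste0(h, revcomp_half(h)), "")
  sort(unname(full))
}

revcomp_half <- function(h) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(h, "")[[1L]]]), collapse = "")
}

#' Motif-avoidance report for a genome
#'
#' Two-stage census. Stage 1 (tetramers): absent motifs are the zero-count
#' 4-mers; under-represented motifs have Markov odds in `(0, odds_threshold]`.
#' Stage 2 (palindromic 6-mers): of the 64 self-complementary 6-mers, those
#' containing an absent or under-represented tetramer as a substring are
#' excluded (their absence is already explained by the core); the zero-count
#' remainder is reported.
#'
#' @param record A `genome_record`. Lengths under 4096 bp trigger a warning,
#'   since chance absences then dominate.
#' @param odds_threshold Upper bound on the Markov odds for a motif to count
#'   as under-represented (default 0.15).
#' @param pool_strands Add reverse-complement-strand counts to the census
#'   (default `FALSE`: forward strand of the deposited sequence only; the
#'   headline absences are palindromes, so they are strand-invariant).
#' @param collapse_iupac Also report absent palindromic 6-mer pairs collapsed
#'   into R/Y IUPAC families (presentation only; the concrete list is always
#'   returned).
#' @return An object of class `kmer_avoidance_report`: list with `k4_counts`,
#'   `odds`, `absent_tetramers`, `under_represented_tetramers`,
#'   `absent_palindromic_6mers`, `excluded_6mers` (with the triggering core),
#'   and optionally `absent_6mer_families`.
#' @export
avoidance_report <- function(record, odds_threshold = 0.15,
                             pool_strands = FALSE, collapse_iupac = FALSE) {
  if (genome_length(record) < 4096L) {
    warning("genome shorter than 4096 bp: chance absences will dominate")
  }
  census <- function(k) {
    cts <- count_kmers(record$seq, k, record$topology)
    if (pool_strands) {
      cts <- cts + count_kmers(revcomp(record$seq), k, record$topology)
    }
    cts
  }
  c4 <- census(4L); c3 <- census(3L); c2 <- census(2L); c6 <- census(6L)

  absent <- names(c4)[c4 == 0L]
  present <- names(c4)[c4 > 0L]
  odds <- vapply(present, function(m) markov_odds(c4, c3, c2, m), 0)
  under <- names(odds)[!is.na(odds) & odds > 0 & odds <= odds_threshold]

  bad_cores <- c(absent, under)
  pal6 <- palindromic_kmers(6L)
  trigger <- vapply(pal6, function(m) {
    hit <- bad_cores[vapply(bad_cores, function(b) grepl(b, m, fixed = TRUE), NA)]
    if (length(hit)) hit[1L] else NA_character_
  }, "")
  excluded <- data.frame(motif = pal6[!is.na(trigger)],
                         core = trigger[!is.na(trigger)],
                         row.names = NULL, stringsAsFactors = FALSE)
  eligible <- pal6[is.na(trigger)]
  absent6 <- eligible[c6[eligible] == 0L]

  out <- list(
    k4_counts = c4,
    odds = odds,
    absent_tetramers = sort(absent),
    under_represented_tetramers = sort(under),
    absent_palindromic_6mers = sort(absent6),
    excluded_6mers = excluded,
    odds_threshold = odds_threshold,
    pool_strands = pool_strands
  )
  if (collapse_iupac) out$absent_6mer_families <- collapse_ry_families(absent6)
  class(out) <- "kmer_avoidance_report"
  out
}

# Collapse pairs of palindromic 6-mers that differ only at the central
# complementary position pair (3,4), one pair being (G,C) and the other (A,T),
# into an R/Y family such as CTRYAG. Presentation only.
collapse_ry_families <- function(motifs) {
  if (length(motifs) < 2L) return(motifs)
  keyed <- vapply(motifs, function(m) {
    paste0(substr(m, 1L, 2L), "..", substr(m, 5L, 6L))
  }, "")
  out <- character()
  used <- rep(FALSE, length(motifs))
  for (i in seq_along(motifs)) {
    if (used[i]) next
    partner <- which(!used & keyed == keyed[i] & seq_along(motifs) != i)
    collapsed <- FALSE
    for (j in partner) {
      c3 <- c(substr(motifs[i], 3L, 3L), substr(motifs[j], 3L, 3L))
      if (setequal(c3, c("G", "A"))) {
        out <- c(out, paste0(substr(motifs[i], 1L, 2L), "RY",
                             substr(motifs[i], 5L, 6L)))
        used[c(i, j)] <- TRUE
        collapsed <- TRUE
        break
      }
    }
    if (!collapsed) {
      out <- c(out, motifs[i])
      used[i] <- TRUE
    }
  }
  sort(out)
}

#' @export
print.kmer_avoidance_report <- function(x, ...) {
  cat("<kmer_avoidance_report>\n")
  cat("  absent tetramers:          ",
      paste(x$absent_tetramers, collapse = ", "), "\n")
  cat("  under-represented (<= ", x$odds_threshold, "): ",
      paste(sprintf("%s=%.2f", x$under_represented_tetramers,
                    x$odds[x$under_represented_tetramers]), collapse = ", "),
      "\n", sep = "")
  cat("  absent palindromic 6-mers: ",
      paste(x$absent_palindromic_6mers, collapse = ", "), "\n")
  invisible(x)
}
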