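# Gene-architecture statistics and small motif/feature analytics: CDS spacing
# and overlap counts, CxxC scanning, exact direct repeats, -1 frameshift
# slippery heptamers, tape-measure tail-length prediction.

#' CDS spacing and overlap statistics
#'
#' For consecutive CDS pairs in coordinate order (with the wrap-around pair
#' included on circular records), the gap is `next_start - prev_stop - 1`.
#' A pair overlaps when the intervals intersect (gap <= -1); typical virus
#' genomes fuse stop and start codons with 1-4 bp overlaps. Each gene is
#' counted once: overlapping if it intersects either neighbour, otherwise
#' close if its smallest neighbour gap is 1..10 bp.
#'
#' @param record A `genome_record` with at least one CDS, or a feature data
#'   frame (then `record_length` and `topology` must be given).
#' @param record_length,topology Only used when `record` is a feature table.
#' @return List with `n_genes`, `n_overlapping_genes`, `n_close_genes`, and
#'   `gaps` (the pairwise gap vector, genome order).
#' @export
spacing_stats <- function(record, record_length = NULL, topology = NULL) {
  if (inherits(record, "genome_record")) {
    ft <- record$features
    record_length <- genome_length(record)
    topology <- record$topology
  } else {
    ft <- record
    if (is.null(record_length) || is.null(topology)) {
      stop("record_length and topology required with a bare feature table")
    }
  }
  cds <- ft[ft$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features")
  cds <- cds[order(cds$start, cds$stop), , drop = FALSE]
  n <- nrow(cds)
  if (n == 1L) {
    return(list(n_genes = 1L, n_overlapping_genes = 0L, n_close_genes = 0L,
                gaps = integer()))
  }
  gaps <- cds$start[-1L] - cds$stop[-n] - 1L
  if (topology == "circular") {
    gaps <- c(gaps, record_length - cds$stop[n] + cds$start[1L] - 1L)
  }
  # gap i sits between gene i and gene i+1 (last gap wraps to gene 1)
  overlapping <- rep(FALSE, n)
  close_nb <- rep(FALSE, n)
  npairs <- length(gaps)
  for (i in seq_len(npairs)) {
    a <- i
    b <- if (i == n) 1L else i + 1L
    if (gaps[i] <= -1L) {
      overlapping[c(a, b)] <- TRUE
    } else if (gaps[i] >= 1L && gaps[i] <= 10L) {
      close_nb[c(a, b)] <- TRUE
    }
  }
  close_nb <- close_nb & !overlapping
  list(n_genes = n,
       n_overlapping_genes = sum(overlapping),
       n_close_genes = sum(close_nb),
       gaps = gaps)
}

#' Scan a protein for CxxC motifs
#'
#' Positions `i` with cysteine at `i` and `i + 3`; overlapping hits are all
#' reported. CxxC pairs are the signature of zinc-finger-like domains common
#' in small halovirus proteins.
#'
#' @param protein Amino-acid string (one-letter code).
#' @return Integer vector of 1-based motif start positions.
#' @examples
#' cxxc_scan("CAACAAC")  # 1 4
#' @export
cxxc_scan <- function(protein) {
  b <- strsplit(toupper(protein), "")[[1L]]
  n <- length(b)
  if (n < 4L) return(integer())
  idx <- seq_len(n - 3L)
  idx[b[idx] == "C" & b[idx + 3L] == "C"]
}

#' Length of the identical N-terminal prefix of two proteins
#' @param protA,protB Non-empty amino-acid strings.
#' @return Number of identical leading residues.
#' @export
longest_common_prefix <- function(protA, protB) {
  if (!nzchar(protA) || !nzchar(protB)) stop("both proteins must be non-empty")
  a <- strsplit(protA, "")[[1L]]
  b <- strsplit(protB, "")[[1L]]
  m <- min(length(a), length(b))
  neq <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(neq)) neq[1L] - 1L else m
}

#' Find maximal exact direct repeats
#'
#' All pairs of identical substrings of length >= `min_len` that cannot be
#' extended in either direction. Seeds of length `min_len` are hashed, seed
#' pairs extended outward, and duplicates collapsed; `tandem` flags adjacent
#' copies (`copy2_start == copy1_start + unit_length`).
#'
#' @param seq Nucleotide string (treated as linear).
#' @param min_len Minimum repeat unit length (>= 8).
#' @return Data frame with `unit_length`, `copy1_start`, `copy2_start`,
#'   `tandem`, sorted by decreasing unit length.
#' @export
find_direct_repeats <- function(seq, min_len = 20L) {
  min_len <- as.integer(min_len)
  if (min_len < 8L) stop("min_len must be >= 8")
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(unit_length = integer(), copy1_start = integer(),
                      copy2_start = integer(), tandem = logical())
  if (n < 2L * 1L || n < min_len + 1L) return(empty)
  starts <- seq_len(n - min_len + 1L)
  seeds <- substring(seq, starts, starts + min_len - 1L)
  keep <- !grepl("N", seeds, fixed = TRUE)
  starts <- starts[keep]; seeds <- seeds[keep]
  groups <- split(starts, seeds)
  groups <- groups[lengths(groups) > 1L]
  if (!length(groups)) return(empty)
  chars <- strsplit(seq, "")[[1L]]
  seen <- new.env(hash = TRUE)
  res <- list()
  for (g in groups) {
    g <- sort(g)
    for (i in seq_len(length(g) - 1L)) {
      for (j in (i + 1L):length(g)) {
        p <- g[i]; q <- g[j]
        # extend left
        while (p > 1L && q > 1L && chars[p - 1L] == chars[q - 1L] &&
               chars[p - 1L] != "N") {
          p <- p - 1L; q <- q - 1L
        }
        # extend right
        len <- min_len + (g[i] - p)
        while (p + len <= n && q + len <= n &&
               chars[p + len] == chars[q + len] && chars[p + len] != "N") {
          len <- len + 1L
        }
        if (q - p < 1L) next
        key <- paste(p, q, len, sep = ":")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        res[[length(res) + 1L]] <- c(len, p, q)
      }
    }
  }
  if (!length(res)) return(empty)
  m <- do.call(rbind, res)
  out <- data.frame(unit_length = m[, 1L], copy1_start = m[, 2L],
                    copy2_start = m[, 3L],
                    tandem = m[, 3L] == m[, 2L] + m[, 1L])
  out <- out[out$unit_length >= min_len, , drop = FALSE]
  out <- out[order(-out$unit_length, out$copy1_start, out$copy2_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find -1 frameshift slippery heptamers near the end of a CDS
#'
#' Scans the 3'-terminal `tail_codons * 3` nt of the coding strand for
#' heptamers of the form `X XXY YYZ` (positions 1-3 one base X, positions 4-6
#' one base Y, X != Y; Z unconstrained). Such sites permit -1 programmed
#' ribosomal frameshifting into the downstream overlapping gene, the
#' conserved arrangement for the tail-chaperone pair upstream of tape measure
#' protein genes in tailed viruses.
#'
#' @param record A `genome_record`.
#' @param cds Locus tag of the CDS to scan.
#' @param tail_codons How many 3'-terminal codons to scan (default 30).
#' @return Data frame with `start` (genome coordinate of the heptamer on the
#'   plus-strand representation), `heptamer` (coding strand), `containing_cds`
#'   and `is_3prime_most`.
#' @export
find_slippery <- function(record, cds, tail_codons = 30L) {
  tail_codons <- as.integer(tail_codons)
  if (tail_codons < 1L) stop("tail_codons must be >= 1")
  feat <- get_feature(record, cds)
  cseq <- feature_seq(record, feat)
  nc <- nchar(cseq)
  tail_nt <- min(nc, tail_codons * 3L)
  tail_start <- nc - tail_nt + 1L
  tail <- substr(cseq, tail_start, nc)
  b <- strsplit(tail, "")[[1L]]
  hits <- integer()
  for (i in seq_len(max(0L, length(b) - 6L))) {
    x <- b[i]; y <- b[i + 3L]
    if (x != "N" && y != "N" && x != y &&
        b[i + 1L] == x && b[i + 2L] == x &&
        b[i + 4L] == y && b[i + 5L] == y) {
      hits <- c(hits, i)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), heptamer = character(),
                      containing_cds = character(), is_3prime_most = logical()))
  }
  off <- tail_start - 1L + hits            # 1-based offset within the CDS
  gstart <- if (identical(feat$strand, "-")) {
    feat$stop - (off + 6L) + 1L
  } else {
    feat$start + off - 1L
  }
  hept <- substring(tail, hits, hits + 6L)
  data.frame(start = gstart, heptamer = hept,
             containing_cds = feat$locus_tag,
             is_3prime_most = seq_along(hits) == length(hits))
}

#' Predicted tail length from tape measure protein size
#'
#' Siphovirus tail length scales linearly with the length of the tape measure
#' protein; the regression used here is `L = slope * aa + intercept` nm,
#' reported as `floor(L)` (clamped at 0). The default coefficients
#' (0.15 nm per residue, -20.7 nm offset) are arguments, not constants, since
#' published fits vary slightly.
#'
#' @param tmp_aa Tape measure protein length in residues.
#' @param slope nm per residue.
#' @param intercept nm offset.
#' @return Predicted tail length in whole nm.
#' @examples
#' tmp_tail_length(703)  # 84
#' @export
tmp_tail_length <- function(tmp_aa, slope = 0.15, intercept = -20.7) {
  max(0, floor(slope * tmp_aa + intercept))
}

#' Protein length implied by a CDS span
#'
#' `(stop - start + 1) / 3 - 1`: one codon is the stop.
#'
#' @param start,stop 1-based inclusive CDS coordinates; the span must be a
#'   multiple of 3.
#' @return Residue count.
#' @examples
#' protein_len_from_cds(17894, 20005)  # 703
#' @export
protein_len_from_cds <- function(start, stop) {
  span <- as.integer(stop) - as.integer(start) + 1L
  if (span %% 3L != 0L) stop("CDS span ", span, " is not a multiple of 3")
  span %/% 3L - 1L
}
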