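# Genome records, coordinate arithmetic, and standard-format I/O.
#
# All coordinates are 1-based inclusive (GenBank convention). On circular
# records a feature may wrap the origin, encoded as start > stop.

VALID_BASES <- c("A", "C", "G", "T", "N")
FEATURE_KINDS <- c("CDS", "tRNA", "repeat_region", "misc")

#' Construct a genome record
#'
#' A genome record bundles a nucleotide sequence with its topology and an
#' ordered feature table. It is the unit every analysis in the package
#' consumes.
#'
#' @param id Accession-like identifier.
#' @param seq Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param topology `"circular"` or `"linear"`.
#' @param features A data frame with columns `kind`, `start`, `stop`,
#'   `strand`, `locus_tag`, `product`, or `NULL` for none. Rows are sorted by
#'   `start` on construction. `kind` must be one of `CDS`, `tRNA`,
#'   `repeat_region`, `misc`. Wrap-around features (start > stop) are only
#'   allowed on circular records.
#' @return An object of class `genome_record`.
#' @examples
#' rec <- genome_record("toy", "ACGTACGTAC", "circular")
#' genome_length(rec)
#' @export
genome_record <- function(id, seq, topology = c("linear", "circular"),
                          features = NULL) {
  topology <- match.arg(topology)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("sequence contains non-ACGTN characters: ", substr(bad, 1, 10))
  }
  features <- normalize_features(features, nchar(seq), topology)
  structure(
    list(id = as.character(id), seq = seq, topology = topology,
         features = features),
    class = "genome_record"
  )
}

empty_features <- function() {
  data.frame(kind = character(), start = integer(), stop = integer(),
             strand = character(), locus_tag = character(),
             product = character(), stringsAsFactors = FALSE)
}

normalize_features <- function(features, len, topology) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  need <- c("kind", "start", "stop", "strand", "locus_tag", "product")
  missing_cols <- setdiff(need, names(features))
  for (col in missing_cols) {
    features[[col]] <- if (col %in% c("start", "stop")) NA_integer_ else ""
  }
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$stop <- as.integer(features$stop)
  features$kind <- ifelse(features$kind %in% FEATURE_KINDS,
                          features$kind, "misc")
  if (any(features$start < 1L | features$start > len |
          features$stop < 1L | features$stop > len)) {
    stop("feature coordinates outside [1, ", len, "]")
  }
  wraps <- features$start > features$stop
  if (any(wraps) && topology != "circular") {
    stop("wrap-around feature (start > stop) on a linear record")
  }
  if (topology == "linear") {
    cds <- features$kind == "CDS"
    span <- features$stop - features$start + 1L
    off <- cds & (span %% 3L != 0L)
    if (any(off)) {
      warning("CDS with span not divisible by 3 on a linear record: ",
              paste(features$locus_tag[off], collapse = ", "))
    }
  }
  features <- features[order(features$start, features$stop), , drop = FALSE]
  rownames(features) <- NULL
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$seq), x$topology, nrow(x$features)))
  invisible(x)
}

#' Sequence length of a genome record
#' @param record A `genome_record`.
#' @return Integer length in bp.
#' @export
genome_length <- function(record) nchar(record$seq)

#' Length of a 1-based inclusive span, with circular wrap
#'
#' On a linear record (or a non-wrapping span) the length is
#' `stop - start + 1`. On a circular record a wrapping span (`stop < start`)
#' runs through the origin: `record_length - start + 1 + stop`.
#'
#' @param start,stop 1-based inclusive coordinates.
#' @param record_length Total record length in bp.
#' @param topology `"linear"` or `"circular"`.
#' @return Span length in bp.
#' @examples
#' span_length(1294959, 1307485, 2847757, "linear")  # 12527
#' span_length(95, 5, 100, "circular")               # 11
#' @export
span_length <- function(start, stop, record_length,
                        topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  start <- as.integer(start); stop <- as.integer(stop)
  record_length <- as.integer(record_length)
  if (any(c(start, stop) < 1L) || any(c(start, stop) > record_length)) {
    stop("coordinates out of range [1, ", record_length, "]")
  }
  if (stop >= start) {
    stop - start + 1L
  } else if (topology == "circular") {
    record_length - start + 1L + stop
  } else {
    stop("stop < start on a linear record")
  }
}

#' G+C content as a percentage
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. Rounded half-up to one decimal, matching how genome tables
#' report G+C.
#'
#' @param seq Nucleotide string.
#' @return Percentage, one decimal.
#' @examples
#' gc_percent("GCGC")  # 100
#' gc_percent("ATAT")  # 0
#' @export
gc_percent <- function(seq) {
  seq <- toupper(seq)
  counts <- base_counts(seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence has no A/C/G/T bases")
  pct <- 100 * sum(counts[c("G", "C")]) / denom
  floor(pct * 10 + 0.5) / 10
}

base_counts <- function(seq) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  counts[c("A", "C", "G", "T", "N")]
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string (may contain N).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

revcomp_many <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Rotate a circular sequence so position `start` becomes position 1
#' @param seq Nucleotide string (treated as circular).
#' @param start New origin, 1-based.
#' @return Rotated string of the same length.
#' @export
rotate_seq <- function(seq, start) {
  n <- nchar(seq)
  start <- ((start - 1L) %% n) + 1L
  if (start == 1L) return(seq)
  paste0(substr(seq, start, n), substr(seq, 1L, start - 1L))
}

#' Extract the subsequence covered by a span (wrap-aware)
#' @param record A `genome_record`.
#' @param start,stop 1-based inclusive coordinates; `start > stop` wraps the
#'   origin on circular records.
#' @return Nucleotide string.
#' @export
span_seq <- function(record, start, stop) {
  n <- genome_length(record)
  if (any(c(start, stop) < 1L) || any(c(start, stop) > n)) {
    stop("coordinates out of range")
  }
  if (stop >= start) {
    substr(record$seq, start, stop)
  } else {
    if (record$topology != "circular") stop("wrapping span on linear record")
    paste0(substr(record$seq, start, n), substr(record$seq, 1L, stop))
  }
}

#' Coding-strand sequence of a feature
#'
#' Extracts the span of a feature (wrap-aware) and reverse-complements it for
#' minus-strand features, so the result reads 5' to 3' on the coding strand.
#'
#' @param record A `genome_record`.
#' @param feature One row of the record's feature table, or a locus_tag.
#' @return Nucleotide string.
#' @export
feature_seq <- function(record, feature) {
  if (is.character(feature)) feature <- get_feature(record, feature)
  s <- span_seq(record, feature$start, feature$stop)
  if (identical(feature$strand, "-")) revcomp(s) else s
}

get_feature <- function(record, locus_tag) {
  idx <- which(record$features$locus_tag == locus_tag)
  if (length(idx) == 0L) stop("no feature with locus_tag '", locus_tag, "'")
  record$features[idx[1L], , drop = FALSE]
}

#' Translate a CDS feature to protein
#'
#' Uses the standard genetic code; the trailing stop codon, if present, is
#' removed. Alternative starts (GTG/TTG) are reported as the residue they
#' encode, not forced to M, since motif scans downstream do not depend on the
#' initiator.
#'
#' @param record A `genome_record`.
#' @param locus_tag CDS identifier.
#' @return Amino-acid string.
#' @export
translate_cds <- function(record, locus_tag) {
  nt <- feature_seq(record, locus_tag)
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

## ---- FASTA / FASTQ ---------------------------------------------------------

#' Read the first (or only) sequence of a FASTA file as a genome record
#' @param path FASTA file.
#' @param topology Topology to assign (FASTA does not carry one).
#' @return A `genome_record` (first sequence) or a list of them if
#'   `all = TRUE`.
#' @param all Return all sequences as a list.
#' @export
read_fasta <- function(path, topology = c("linear", "circular"), all = FALSE) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  recs <- lapply(seq_along(ss), function(i) {
    genome_record(ids[i], as.character(ss[[i]]), topology)
  })
  if (all) recs else recs[[1L]]
}

#' Write genome records to FASTA
#' @param records A `genome_record` or list of them.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(ss) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of reads
#' @param path FASTQ file (uncompressed or gzipped).
#' @return Named character vector; names are read ids.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write reads to FASTQ with placeholder qualities
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @param qual Single quality character applied to every base (default "I",
#'   Phred Q40 in Sanger encoding).
#' @export
write_fastq <- function(reads, path, qual = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    quals <- vapply(nchar(reads), function(n) strrep(qual, n), "")
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", quals), con, sep = "\n")
  }
  invisible(path)
}

## ---- GenBank flat files ----------------------------------------------------

#' Read a GenBank flat file
#'
#' Minimal flat-file reader covering the fields the analyses need: LOCUS
#' (length and topology), FEATURES (CDS, tRNA, repeat_region; anything else
#' becomes `misc`) with `complement()` and origin-wrapping
#' `join(a..L,1..b)` locations, `/locus_tag` and `/product` qualifiers, and
#' the ORIGIN sequence.
#'
#' @param path GenBank flat file.
#' @return A `genome_record` with features in coordinate order.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed GenBank file (no LOCUS line): ", path)
  locus <- lines[locus_i[1L]]
  topology <- if (grepl("\\bcircular\\b", locus, ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1L]])), "\\s+")[[1L]][1L]
    if (!is.na(acc) && nzchar(acc)) id <- acc
  }

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    stop("malformed GenBank file (no ORIGIN block): ", path)
  }
  seq_lines <- lines[(origin_i[1L] + 1L):length(lines)]
  end_i <- grep("^//", seq_lines)
  if (length(end_i)) seq_lines <- seq_lines[seq_len(end_i[1L] - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop("malformed GenBank file (empty ORIGIN): ", path)

  features <- parse_genbank_features(lines, origin_i[1L], path)
  genome_record(id, seq, topology, features)
}

parse_genbank_features <- function(lines, origin_i, path) {
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i) == 0L) return(NULL)
  block <- lines[(feat_i[1L] + 1L):(origin_i - 1L)]
  # a new feature starts at column 6 (5 spaces + key); qualifiers at column 22
  starts <- grep("^ {5}\\S", block)
  if (length(starts) == 0L) return(NULL)
  ends <- c(starts[-1L] - 1L, length(block))
  rows <- lapply(seq_along(starts), function(i) {
    chunk <- block[starts[i]:ends[i]]
    head_line <- chunk[1L]
    key <- sub("^ {5}(\\S+).*$", "\\1", head_line)
    loc <- trimws(sub("^ {5}\\S+\\s+", "", head_line))
    # location may continue over lines until the first /qualifier
    extra <- chunk[-1L]
    qual_start <- grep("^ +/", extra)
    loc_cont <- if (length(qual_start)) extra[seq_len(qual_start[1L] - 1L)] else extra
    loc <- paste0(loc, paste(trimws(loc_cont), collapse = ""))
    parsed <- parse_gb_location(loc)
    if (is.null(parsed)) {
      stop("cannot parse feature location '", loc, "' in ", path)
    }
    quals <- paste(trimws(extra), collapse = " ")
    row <- data.frame(
      kind = if (key %in% FEATURE_KINDS) key else
        if (key == "source") NA_character_ else "misc",
      start = parsed$start, stop = parsed$stop, strand = parsed$strand,
      locus_tag = gb_qualifier(quals, "locus_tag"),
      product = gb_qualifier(quals, "product"),
      stringsAsFactors = FALSE
    )
    row
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$kind), , drop = FALSE]   # drop the source feature
  if (nrow(out) == 0L) NULL else out
}

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1L]]
    m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
    if (any(vapply(m, length, 0L) != 3L)) return(NULL)
    a <- as.integer(vapply(m, `[[`, "", 2L))
    b <- as.integer(vapply(m, `[[`, "", 3L))
    # origin-wrapping join(a..L, 1..b) encoded as start > stop
    return(list(start = a[1L], stop = b[length(b)], strand = strand))
  }
  m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1L]]
  if (length(m) == 3L) {
    return(list(start = as.integer(m[2L]), stop = as.integer(m[3L]),
                strand = strand))
  }
  m <- regmatches(loc, regexec("^(\\d+)$", loc))[[1L]]
  if (length(m) == 2L) {
    p <- as.integer(m[2L])
    return(list(start = p, stop = p, strand = strand))
  }
  NULL
}

gb_qualifier <- function(quals, name) {
  pat <- paste0("/", name, "=\"([^\"]*)\"")
  m <- regmatches(quals, regexec(pat, quals))[[1L]]
  if (length(m) == 2L) m[2L] else ""
}

#' Write a genome record as a GenBank flat file
#'
#' Emits the subset of the format [read_genbank()] consumes, so
#' write-then-read round-trips to an identical record.
#'
#' @param record A `genome_record`.
#' @param path Output file.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- genome_length(record)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-1980",
                     record$id, n, record$topology), con)
  writeLines(sprintf("DEFINITION  %s.", record$id), con)
  writeLines(sprintf("ACCESSION   %s", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  ft <- record$features
  if (nrow(ft)) {
    for (i in seq_len(nrow(ft))) {
      f <- ft[i, ]
      key <- if (f$kind == "misc") "misc_feature" else f$kind
      loc <- if (f$start > f$stop) {
        sprintf("join(%d..%d,1..%d)", f$start, n, f$stop)
      } else {
        sprintf("%d..%d", f$start, f$stop)
      }
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      if (nzchar(f$locus_tag)) {
        writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag), con)
      }
      if (nzchar(f$product)) {
        writeLines(sprintf("                     /product=\"%s\"", f$product), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$seq)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- GFF3 ------------------------------------------------------------------

#' Read features from a GFF3 file
#'
#' Alternative feature source to GenBank. Types `CDS`, `tRNA` and
#' `repeat_region` are kept as-is; everything else becomes `misc`. The
#' `product` column is taken from the `product` attribute (falling back to
#' `Name`), `locus_tag` from `locus_tag` (falling back to `ID`).
#'
#' @param path GFF3 file.
#' @return Feature data frame suitable for [genome_record()].
#' @export
read_gff_features <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  md <- S4Vectors::mcols(gr)
  pick <- function(col, alt) {
    v <- if (col %in% names(md)) as.character(md[[col]]) else rep(NA_character_, length(gr))
    a <- if (alt %in% names(md)) as.character(md[[alt]]) else rep(NA_character_, length(gr))
    v[is.na(v) | !nzchar(v)] <- a[is.na(v) | !nzchar(v)]
    v[is.na(v)] <- ""
    v
  }
  data.frame(
    kind = ifelse(as.character(md$type) %in% FEATURE_KINDS,
                  as.character(md$type), "misc"),
    start = BiocGenerics::start(gr),
    stop = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    locus_tag = pick("locus_tag", "ID"),
    product = pick("product", "Name"),
    stringsAsFactors = FALSE
  )
}

#' Write a feature table as GFF3
#' @param record A `genome_record` whose features are written.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(record, path, source = "provirseq") {
  ft <- record$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", record$id,
                     genome_length(record)), con)
  if (nrow(ft)) {
    type <- ifelse(ft$kind == "misc", "misc_feature", ft$kind)
    attrs <- sprintf("ID=%s", ifelse(nzchar(ft$locus_tag), ft$locus_tag,
                                     sprintf("feat%03d", seq_len(nrow(ft)))))
    has_lt <- nzchar(ft$locus_tag)
    attrs[has_lt] <- paste0(attrs[has_lt], ";locus_tag=", ft$locus_tag[has_lt])
    has_p <- nzchar(ft$product)
    attrs[has_p] <- paste0(attrs[has_p], ";product=", ft$product[has_p])
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       record$id, source, type, ft$start, ft$stop,
                       ft$strand, ifelse(type == "CDS", "0", "."), attrs), con)
  }
  invisible(path)
}
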