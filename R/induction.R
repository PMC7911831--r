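# Detection of active (induced) proviruses from sequencing evidence:
# circular contigs, junction-spanning reads, and coverage elevation.
#
# An integrated element that excises and replicates leaves three read-level
# signals in a stock: the excised circle assembles as a circular contig;
# reads span the attP junction (the joined termini of the circle), a sequence
# absent from the intact chromosome; and read depth over the provirus region
# rises above the chromosomal background.

#' Detect terminal-overlap circularity of a contig
#'
#' Assemblers emit circular molecules as linear contigs whose start is
#' repeated at the end. The contig is circular when its prefix of at least
#' `min_overlap` bp recurs as a suffix; the unit sequence trims one overlap
#' copy.
#'
#' @param contig Nucleotide string (length > 2 * min_overlap).
#' @param min_overlap Minimum exact terminal overlap in bp (default 20;
#'   chance 20-mer overlaps are vanishingly unlikely).
#' @return List with `is_circular`, `overlap` (bp, 0 if none), and `unit`
#'   (trimmed sequence if circular, otherwise the input).
#' @export
detect_circular_contig <- function(contig, min_overlap = 20L) {
  contig <- toupper(contig)
  n <- nchar(contig)
  if (n <= 2L * min_overlap) stop("contig must be longer than 2 * min_overlap")
  probe <- substr(contig, 1L, min_overlap)
  hits <- unlist(gregexpr(probe, contig, fixed = TRUE))
  hits <- hits[hits > n %/% 2L]          # candidate suffix anchors only
  for (p in sort(hits, decreasing = FALSE)) {
    o <- n - p + 1L
    if (o < min_overlap) next
    if (substr(contig, 1L, o) == substr(contig, p, n)) {
      return(list(is_circular = TRUE, overlap = o,
                  unit = substr(contig, 1L, n - o)))
    }
  }
  list(is_circular = FALSE, overlap = 0L, unit = contig)
}

#' Junction sequences diagnostic for excision
#'
#' From an integrated host and provirus coordinates, builds the two sequences
#' whose presence in reads distinguishes the excised state: the attP junction
#' (last `flank` bp of the excised circle joined to its first `flank` bp —
#' the joined termini) and the attB junction (host flank, the single
#' remaining att core, host flank, as left after excision). The attP junction
#' occurs only in the circularized element; the attB junction only in the
#' restored (element-free) host.
#'
#' @param host Integrated host `genome_record`.
#' @param provirus_start First base of attL.
#' @param provirus_end Last base of attR.
#' @param core_len att core length in bp.
#' @param flank Flank length on each side of the junction point (> 0,
#'   <= half the provirus length).
#' @return List with `attP` (length `2 * flank`) and `attB`
#'   (length `2 * flank + core_len`); both carry the junction midpoint at
#'   their centre.
#' @export
junction_sequences <- function(host, provirus_start, provirus_end, core_len,
                               flank = 50L) {
  if (flank < 1L) stop("flank must be >= 1")
  span <- provirus_end - provirus_start + 1L
  if (flank > span %/% 2L) stop("flank larger than half the provirus length")
  exc <- excise_element(host, provirus_start, provirus_end - core_len + 1L,
                        core_len)
  circ <- exc$element$seq
  m <- nchar(circ)
  attP <- paste0(substr(circ, m - flank + 1L, m), substr(circ, 1L, flank))
  rh <- exc$host$seq
  attB_start <- provirus_start - flank
  attB_end <- provirus_start + core_len - 1L + flank
  if (attB_start < 1L || attB_end > nchar(rh)) {
    stop("flank extends beyond the host ends around attB")
  }
  attB <- substr(rh, attB_start, attB_end)
  list(attP = attP, attB = attB)
}

#' Count reads spanning a junction
#'
#' A read counts when it (or its reverse complement) contains the exact
#' `2 * min_anchor`-mer centred on the junction point, i.e. it anchors at
#' least `min_anchor` bp on each side. Each read is counted once.
#'
#' @param reads Character vector of read sequences (named or not).
#' @param junction Junction sequence with the junction point at its centre
#'   (length >= 2 * min_anchor).
#' @param min_anchor Minimum anchor on each side of the junction (default 20).
#' @return Integer count.
#' @export
count_spanning_reads <- function(reads, junction, min_anchor = 20L) {
  junction <- toupper(junction)
  jl <- nchar(junction)
  if (jl < 2L * min_anchor) stop("junction shorter than 2 * min_anchor")
  if (!length(reads)) return(0L)
  mid <- jl %/% 2L
  key <- substr(junction, mid - min_anchor + 1L, mid + min_anchor)
  key_rc <- revcomp(key)
  hit <- grepl(key, reads, fixed = TRUE) | grepl(key_rc, reads, fixed = TRUE)
  sum(hit)
}

#' Read-depth ratio of the provirus region versus the rest of the host
#'
#' Depth is estimated by exact placement of one unique 31-mer anchor per read
#' (the read centre, or its reverse complement) onto the host: only host
#' 31-mers that occur once are used, which sidesteps the att duplication.
#' Bases inside the att cores are excluded from both means. Depth =
#' placed reads x read length / region length.
#'
#' @param reads Character vector of reads (uniform length assumed for the
#'   depth scaling; the modal length is used).
#' @param host Integrated host `genome_record`.
#' @param provirus_start,provirus_end Provirus span (attL start .. attR end).
#' @param core_len att core length excluded at both ends (default 0).
#' @param k Anchor length (default 31).
#' @param exclude Optional list of `c(start, end)` host spans masked from the
#'   outside (background) mean — e.g. other candidate proviruses, whose own
#'   elevation would otherwise inflate the background.
#' @return List with `inside`, `outside` (mean depths), and `ratio`
#'   (`inside / outside`; `Inf` when outside is 0, 0 when no reads map
#'   inside).
#' @export
coverage_ratio <- function(reads, host, provirus_start, provirus_end,
                           core_len = 0L, k = 31L, exclude = list()) {
  if (!length(reads)) stop("no reads supplied")
  n <- genome_length(host)
  span <- provirus_end - provirus_start + 1L
  if (span >= n) stop("host length must exceed the provirus span")
  hseq <- host$seq
  starts <- seq_len(n - k + 1L)
  kmers <- substring(hseq, starts, starts + k - 1L)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  kmers[dup] <- NA_character_

  rl <- as.integer(stats::median(nchar(reads)))
  if (rl < k) stop("reads shorter than the anchor length")
  mid_off <- (rl - k) %/% 2L
  anchors <- substr(reads, mid_off + 1L, mid_off + k)
  pos <- match(anchors, kmers)
  miss <- is.na(pos)
  if (any(miss)) {
    pos[miss] <- match(revcomp_many(anchors[miss]), kmers)
  }
  placed <- pos[!is.na(pos)]
  if (!length(placed)) stop("no reads could be placed on the host")
  midpoints <- placed + k %/% 2L

  core1 <- c(provirus_start, provirus_start + core_len - 1L)
  core2 <- c(provirus_end - core_len + 1L, provirus_end)
  in_core <- core_len > 0L &
    ((midpoints >= core1[1L] & midpoints <= core1[2L]) |
     (midpoints >= core2[1L] & midpoints <= core2[2L]))
  inside <- midpoints >= provirus_start & midpoints <= provirus_end & !in_core
  outside <- (midpoints < provirus_start | midpoints > provirus_end)

  inside_len <- span - 2L * core_len
  outside_len <- n - span
  for (ex in exclude) {
    lo <- max(ex[1L], 1L); hi <- min(ex[2L], n)
    if (hi < lo) next
    masked <- outside & midpoints >= lo & midpoints <= hi
    outside <- outside & !masked
    # only the part of the mask actually outside the provirus shrinks the
    # background length
    ov_in <- max(0L, min(hi, provirus_end) - max(lo, provirus_start) + 1L)
    outside_len <- outside_len - (hi - lo + 1L - ov_in)
  }
  if (outside_len <= 0L) stop("exclusion masks removed the whole background")
  depth_in <- sum(inside) * rl / inside_len
  depth_out <- sum(outside) * rl / outside_len
  ratio <- if (depth_out == 0) {
    if (depth_in == 0) 0 else Inf
  } else depth_in / depth_out
  list(inside = depth_in, outside = depth_out, ratio = ratio,
       n_placed = length(placed))
}

#' Classify induction evidence
#'
#' \describe{
#'   \item{induced}{attP junction reads >= `junction_min` and coverage ratio
#'     >= `ratio_min`: the element excises and replicates.}
#'   \item{excision-only}{attP junction reads >= `junction_min` but ratio
#'     below `ratio_min`: excision detected at low copy (the patchy-coverage
#'     pattern).}
#'   \item{silent}{no junction evidence.}
#' }
#' The defaults (2 junction reads, ratio 5) are conventions: induced elements
#' in real stocks show coverage tens to thousands of times the chromosomal
#' background, so 5 is conservative.
#'
#' @param attP_junction_reads Count of reads spanning the attP junction.
#' @param ratio Inside/outside coverage ratio.
#' @param junction_min,ratio_min Thresholds.
#' @return One of `"induced"`, `"excision-only"`, `"silent"`.
#' @export
classify_induction <- function(attP_junction_reads, ratio,
                               junction_min = 2L, ratio_min = 5) {
  if (attP_junction_reads >= junction_min) {
    if (!is.na(ratio) && ratio >= ratio_min) "induced" else "excision-only"
  } else {
    "silent"
  }
}

#' Assemble induction evidence for one candidate provirus
#'
#' Convenience wrapper running [junction_sequences()],
#' [count_spanning_reads()] and [coverage_ratio()] and classifying the
#' result.
#'
#' @param reads Character vector of reads.
#' @param host Integrated host `genome_record`.
#' @param provirus_start,provirus_end Provirus span (attL start .. attR end).
#' @param core_len att core length.
#' @param flank Junction flank (default 50).
#' @param min_anchor Junction anchor (default 20).
#' @param junction_min,ratio_min Classification thresholds.
#' @param provirus_id Identifier copied into the result.
#' @param exclude Spans masked from the coverage background (see
#'   [coverage_ratio()]).
#' @return List of class `induction_evidence`.
#' @export
induction_evidence <- function(reads, host, provirus_start, provirus_end,
                               core_len, flank = 50L, min_anchor = 20L,
                               junction_min = 2L, ratio_min = 5,
                               provirus_id = "provirus", exclude = list()) {
  jx <- junction_sequences(host, provirus_start, provirus_end, core_len, flank)
  attP_n <- count_spanning_reads(reads, jx$attP, min_anchor)
  attB_n <- count_spanning_reads(reads, jx$attB, min_anchor)
  cov <- coverage_ratio(reads, host, provirus_start, provirus_end, core_len,
                        exclude = exclude)
  out <- list(
    provirus_id = provirus_id,
    attP_junction_reads = attP_n,
    attB_junction_reads = attB_n,
    coverage_inside = cov$inside,
    coverage_outside = cov$outside,
    ratio = cov$ratio,
    call = classify_induction(attP_n, cov$ratio, junction_min, ratio_min)
  )
  class(out) <- "induction_evidence"
  out
}

#' @export
print.induction_evidence <- function(x, ...) {
  cat(sprintf(
    "<induction_evidence> %s: attP reads %d, attB reads %d, depth %.1fx / %.1fx (ratio %.2f) -> %s\n",
    x$provirus_id, x$attP_junction_reads, x$attB_junction_reads,
    x$coverage_inside, x$coverage_outside, x$ratio, x$call))
  invisible(x)
}
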