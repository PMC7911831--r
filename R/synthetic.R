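# Synthetic genomes, lysogens and read sets with a truth ledger.
#
# The generator emulates the data the analyses assume: GC-controlled random
# genomes with selected k-mers depleted to zero; a host contig carrying a
# provirus integrated at a tRNA gene with a duplicated att core (attL/attR);
# and read sets drawn from mixtures of host chromosome, excised circular
# element, and circularly permuted terminally redundant virions. All
# randomness flows through an explicit seed; equal seeds give byte-identical
# output.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate an i.i.d. random genome with controlled GC content
#'
#' Bases drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same string.
#' @return Nucleotide string.
#' @export
make_genome <- function(length, gc = 0.6, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  withr::with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Deplete motifs from a sequence
#'
#' Breaks every occurrence of each motif (and its reverse complement) on the
#' circularly-read sequence by substituting one base near the middle of the
#' occurrence, then re-scans until no occurrence remains. Length is
#' unchanged; edits are minimal (one substitution per surviving occurrence
#' per sweep).
#'
#' @param seq Nucleotide string (treated as circular).
#' @param motifs Character vector of k-mers, each of length <= 8.
#' @param seed Integer seed controlling the replacement bases.
#' @return Sequence of the same length free of all motifs on both strands.
#' @export
deplete_motifs <- function(seq, motifs, seed = 1L) {
  if (!length(motifs)) stop("motifs must be non-empty")
  motifs <- toupper(motifs)
  if (any(nchar(motifs) > 8L)) stop("motifs longer than 8 bp not supported")
  targets <- unique(c(motifs, vapply(motifs, revcomp, "")))
  n <- nchar(seq)
  maxk <- max(nchar(targets))
  chars <- strsplit(seq, "")[[1L]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  withr::with_seed(seed, {
    for (sweep in seq_len(100L)) {
      s <- paste(chars, collapse = "")
      ext <- paste0(s, substr(s, 1L, maxk - 1L))
      pos <- integer()
      for (m in targets) {
        mi <- unlist(gregexpr(m, ext, fixed = TRUE))
        mi <- mi[mi > 0L & mi <= n]
        if (length(mi)) {
          pos <- c(pos, ((mi + nchar(m) %/% 2L - 1L) %% n) + 1L)
        }
      }
      if (!length(pos)) return(s)
      pos <- unique(pos)
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(alt[[b]], 1L), "")
    }
    stop("motif depletion did not reach a fixed point in 100 sweeps")
  })
}

# stop-free codon supply over {A,C,G}: no T means no TAA/TAG/TGA in any frame
random_tfree <- function(n_bases) {
  paste(sample(c("A", "C", "G"), n_bases, replace = TRUE), collapse = "")
}

# a CDS of n_codons coding codons (no internal stops), ATG start, given stop
make_cds_seq <- function(n_codons, stop_codon = "TGA") {
  paste0("ATG", random_tfree(3L * (n_codons - 1L)), stop_codon)
}

# protein-coding CDS carrying n_motifs CxxC motifs
make_cxxc_cds <- function(n_motifs = 2L, spacer_codons = 4L) {
  motif <- function() paste0("TGC", random_tfree(6L), "TGC")
  body <- paste(vapply(seq_len(n_motifs), function(i) {
    paste0(motif(), random_tfree(3L * spacer_codons))
  }, ""), collapse = "")
  paste0("ATG", random_tfree(9L), body, "TAA")
}

#' Build a synthetic lysogen
#'
#' Constructs a host contig carrying a provirus integrated at a synthetic
#' tRNA gene, the corresponding circular element, and a truth ledger. The
#' geometry follows tRNA-integration convention: the att core is the
#' 3'-terminal `att_len` bases of the tRNA; the element begins just after the
#' tRNA 3' end (attL) and ends with its own att copy (attR). The element
#' carries, on one strand, an integrase-like CDS, an unannotated bridging ORF
#' that spans the attP junction, and a CDS whose product holds two CxxC
#' motifs — the layout in which attP sits inside a coding sequence that is
#' split in the provirus state.
#'
#' The circular element record uses the canonical rotation with the att core
#' as its final `att_len` bases, so the attP junction is the origin.
#'
#' att cores and planted ORF bodies are drawn from `{A, C, G}` so that no
#' reading frame across the junction can contain a stop codon — a synthetic
#' simplification that keeps the planted bridging ORF well-defined.
#'
#' @param host_length Host contig length in bp, excluding the element
#'   (default 20000: the analyses are local to the integration region, so a
#'   contig-scale context suffices).
#' @param element_length Circular element length in bp (default 6000; must be
#'   >= 3 * att_len and >= 2000 to hold the planted gene layout).
#' @param att_len att core length in bp (default 13).
#' @param gc Background GC fraction (default 0.6).
#' @param seed Integer seed.
#' @return List with `host` (integrated `genome_record`, linear, with tRNA,
#'   attL/attR and lifted CDS features), `element` (circular
#'   `genome_record`), and `truth` (ledger: seed, provirus coordinates, att
#'   core, tRNA locus, planted CDS/ORF coordinates).
#' @export
build_lysogen <- function(host_length = 20000L, element_length = 6000L,
                          att_len = 13L, gc = 0.6, seed = 1L) {
  host_length <- as.integer(host_length)
  element_length <- as.integer(element_length)
  att_len <- as.integer(att_len)
  if (att_len < 8L) stop("att_len must be >= 8")
  if (element_length < 3L * att_len) stop("element_length must be >= 3 * att_len")
  if (element_length < 2000L) stop("element_length must be >= 2000 to hold the planted genes")
  if (host_length < 2000L) stop("host_length must be >= 2000")
  withr::with_seed(seed, {
    for (attempt in seq_len(20L)) {
      lys <- try(build_lysogen_once(host_length, element_length, att_len, gc,
                                    seed), silent = TRUE)
      if (!inherits(lys, "try-error")) return(lys)
    }
    stop("could not build a collision-free lysogen in 20 attempts")
  })
}

# one construction attempt; signals an error on (astronomically rare) chance
# att-core collisions so the caller can redraw
build_lysogen_once <- function(host_length, element_length, att_len, gc, seed) {
    att_core <- random_tfree(att_len)

    # --- element, canonical rotation: att core occupies the final att_len bases
    integrase <- make_cds_seq(160L)                       # 483 nt
    gap1 <- random_tfree(30L)
    # bridging ORF: starts after gap1, runs through the att core at the end of
    # the element, wraps the origin, and stops shortly after.
    pre_att <- random_tfree(120L)
    post_att <- random_tfree(80L)
    bridge_body_len <- 3L + 120L + att_len + 80L          # ATG + body
    pad <- (3L - (bridge_body_len %% 3L)) %% 3L
    post_att <- paste0(post_att, random_tfree(pad))
    bridge_head <- paste0("ATG", pre_att)                 # up to element end
    bridge_tail <- paste0(post_att, "TGA")                # after the origin
    gap2 <- random_tfree(8L)
    cxxc <- make_cxxc_cds(2L)

    tail_block <- paste0(integrase, gap1, bridge_head, att_core)  # ends element
    head_block <- paste0(bridge_tail, gap2, cxxc)                  # starts element
    filler_len <- element_length - nchar(tail_block) - nchar(head_block)
    if (filler_len < 0L) stop("element_length too small for planted layout")
    filler <- make_genome(max(filler_len, 1L), gc,
                          seed = sample.int(2^31 - 1L, 1L))
    if (filler_len == 0L) filler <- ""
    else filler <- substr(filler, 1L, filler_len)
    element_seq <- paste0(head_block, filler, tail_block)
    stopifnot(nchar(element_seq) == element_length)

    # coordinates within the canonical element
    head_off <- nchar(head_block)
    fill_off <- head_off + nchar(filler)
    int_start <- fill_off + 1L
    int_stop <- fill_off + nchar(integrase)
    bridge_start <- int_stop + nchar(gap1) + 1L
    bridge_stop <- nchar(bridge_tail)                      # wraps: start > stop
    cxxc_start <- nchar(bridge_tail) + nchar(gap2) + 1L
    cxxc_stop <- cxxc_start + nchar(cxxc) - 1L
    attp_pos <- element_length - att_len + 1L

    # the att core must occur exactly once in the circular element
    if (count_occurrences(paste0(element_seq,
                                 substr(element_seq, 1L, att_len - 1L)),
                          att_core) != 1L) {
      stop("chance att-core collision in element")
    }

    element_features <- data.frame(
      kind = c("CDS", "CDS"),
      start = c(int_start, cxxc_start),
      stop = c(int_stop, cxxc_stop),
      strand = c("+", "+"),
      locus_tag = c("SYN_int", "SYN_cxxc"),
      product = c("integrase", "CxxC motif protein"),
      stringsAsFactors = FALSE
    )
    element <- genome_record("SYN_element", element_seq, "circular",
                             element_features)

    # --- host: left flank + tRNA (ends with att core) + element + right flank
    # the base preceding the core in the tRNA must differ from the base
    # preceding attP in the element, so the att core is the *maximal* shared
    # suffix (find_att_core would otherwise report a longer core)
    trna_len <- 72L
    elem_prev <- substr(element_seq, element_length - att_len,
                        element_length - att_len)
    trna_body <- random_tfree(trna_len - att_len)
    last_ok <- setdiff(c("A", "C", "G"), elem_prev)
    substr(trna_body, nchar(trna_body), nchar(trna_body)) <-
      sample(last_ok, 1L)
    trna_seq <- paste0(trna_body, att_core)
    insert_at <- host_length %/% 2L
    left <- make_genome(insert_at, gc, seed = sample.int(2^31 - 1L, 1L))
    right <- make_genome(host_length - insert_at - trna_len, gc,
                         seed = sample.int(2^31 - 1L, 1L))
    # scrub chance att-core occurrences from the flanks
    left <- scrub_motif(left, att_core)
    right <- scrub_motif(right, att_core)
    host_seq <- paste0(left, trna_seq, element_seq, right)
    if (count_occurrences(host_seq, att_core) != 2L) {
      stop("chance att-core collision in host")
    }

    trna_start <- insert_at + 1L
    trna_stop <- insert_at + trna_len
    attL_start <- trna_stop - att_len + 1L
    prov_start <- attL_start                    # provirus span includes attL
    elem_offset <- trna_stop                    # element occupies offset+1 ..
    attR_start <- elem_offset + element_length - att_len + 1L
    prov_end <- elem_offset + element_length    # = attR end

    lift <- function(pos) elem_offset + pos
    host_features <- data.frame(
      kind = c("tRNA", "misc", "misc", "CDS", "CDS"),
      start = c(trna_start, attL_start, attR_start,
                lift(int_start), lift(cxxc_start)),
      stop = c(trna_stop, attL_start + att_len - 1L, attR_start + att_len - 1L,
               lift(int_stop), lift(cxxc_stop)),
      strand = c("+", "+", "+", "+", "+"),
      locus_tag = c("SYN_trna", "SYN_attL", "SYN_attR", "SYN_int_h", "SYN_cxxc_h"),
      product = c("tRNA-Pro", "attL", "attR", "integrase", "CxxC motif protein"),
      stringsAsFactors = FALSE
    )
    host <- genome_record("SYN_host", host_seq, "linear", host_features)

    truth <- list(
      seed = seed,
      att_core = att_core,
      att_len = att_len,
      trna_locus = "SYN_trna",
      trna_start = trna_start, trna_stop = trna_stop,
      host_insertion_pos = trna_stop,
      attL_start = attL_start, attR_start = attR_start,
      provirus_start = prov_start, provirus_end = prov_end,
      element_length = element_length,
      attp_pos = attp_pos,
      integrase = list(locus_tag = "SYN_int", start = int_start, stop = int_stop),
      cxxc = list(locus_tag = "SYN_cxxc", start = cxxc_start, stop = cxxc_stop),
      bridging_orf = list(start = bridge_start, stop = bridge_stop,
                          length = element_length - bridge_start + 1L + bridge_stop)
    )
    list(host = host, element = element, truth = truth)
}

count_occurrences <- function(s, motif) {
  hits <- unlist(gregexpr(motif, s, fixed = TRUE))
  sum(hits > 0L)
}

# replace chance occurrences of a motif by editing its middle base
scrub_motif <- function(seq, motif) {
  repeat {
    hit <- regexpr(motif, seq, fixed = TRUE)[[1L]]
    if (hit < 1L) return(seq)
    pos <- hit + nchar(motif) %/% 2L
    cur <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
}

#' Simulate reads from a mixture of templates
#'
#' Each read picks a template with probability proportional to its weight,
#' then a position according to the template's topology mode:
#' \describe{
#'   \item{circular}{start uniform on `1..L`; reads wrap the origin.}
#'   \item{headful}{a virion is first cut at a uniform rotation with 5%
#'     terminal redundancy (fraction 1.05 of the genome), and the read drawn
#'     uniformly from that virion — the circularly permuted, terminally
#'     redundant population produced by headful packaging.}
#'   \item{linear}{start uniform on `1..L - read_len + 1`, no wrap.}
#' }
#' Strand is chosen uniformly; qualities are a Q40 placeholder. An optional
#' uniform substitution rate is exposed but defaults to 0 (exact matching is
#' assumed downstream).
#'
#' @param templates List of `list(record=, mode=, weight=)` entries; `mode`
#'   one of `"circular"`, `"headful"`, `"linear"`.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (shorter than every template).
#' @param seed Integer seed.
#' @param error_rate Per-base substitution probability (default 0).
#' @return List with `reads` (named character vector) and `truth` (data frame:
#'   id, template, mode, start, strand).
#' @export
simulate_reads <- function(templates, n_reads, read_len = 100L, seed = 1L,
                           error_rate = 0) {
  stopifnot(length(templates) >= 1L)
  lens <- vapply(templates, function(t) genome_length(t$record), 0L)
  if (any(read_len >= lens)) stop("read_len must be shorter than every template")
  weights <- vapply(templates, function(t) as.numeric(t$weight), 0)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be nonnegative, one positive")
  if (n_reads == 0L) {
    return(list(reads = setNames(character(), character()),
                truth = data.frame(id = character(), template = character(),
                                   mode = character(), start = integer(),
                                   strand = character())))
  }
  withr::with_seed(seed, {
    tpl_idx <- sample.int(length(templates), n_reads, replace = TRUE,
                          prob = weights / sum(weights))
    starts <- integer(n_reads)
    seqs <- character(n_reads)
    for (ti in unique(tpl_idx)) {
      sel <- which(tpl_idx == ti)
      tpl <- templates[[ti]]
      L <- lens[ti]
      s <- tpl$record$seq
      mode <- match.arg(tpl$mode, c("circular", "headful", "linear"))
      if (mode == "circular") {
        st <- sample.int(L, length(sel), replace = TRUE)
        ext <- paste0(s, substr(s, 1L, read_len - 1L))
        seqs[sel] <- substring(ext, st, st + read_len - 1L)
      } else if (mode == "headful") {
        Lv <- round(1.05 * L)
        rot <- sample.int(L, length(sel), replace = TRUE)
        u <- sample.int(Lv - read_len + 1L, length(sel), replace = TRUE)
        g <- rot + u - 1L
        ext <- strrep_seq(s, g + read_len - 1L)
        seqs[sel] <- substring(ext, g, g + read_len - 1L)
        st <- ((g - 1L) %% L) + 1L
      } else {
        st <- sample.int(L - read_len + 1L, length(sel), replace = TRUE)
        seqs[sel] <- substring(s, st, st + read_len - 1L)
      }
      starts[sel] <- st
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp_many(seqs[flip])
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, "", rate = error_rate, USE.NAMES = FALSE)
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    tpl_ids <- vapply(templates, function(t) t$record$id, "")
    modes <- vapply(templates, function(t) t$mode, "")
    truth <- data.frame(
      id = ids, template = tpl_ids[tpl_idx], mode = modes[tpl_idx],
      start = starts, strand = strand, stringsAsFactors = FALSE
    )
    list(reads = setNames(seqs, ids), truth = truth)
  })
}

strrep_seq <- function(s, min_len) {
  reps <- ceiling(min_len / nchar(s))
  strrep(s, max(reps, 1L))
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  for (i in hit) {
    cur <- substr(seq, i, i)
    substr(seq, i, i) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  seq
}

#' Simulate a sequencing stock from a lysogen
#'
#' Mixes the integrated host contig with free circular copies of the element.
#' `copy_ratio` is the number of excised circular element copies per host
#' chromosome copy, so the expected inside/outside coverage ratio of the
#' provirus region is `copy_ratio + 1` (the integrated copy always
#' contributes once). Read counts are set so the chromosomal background
#' reaches `coverage`x mean depth.
#'
#' @param lysogen Output of [build_lysogen()].
#' @param copy_ratio Free element copies per chromosome copy (>= 0).
#' @param coverage Target chromosomal depth (default 50).
#' @param read_len Read length (default 100).
#' @param seed Integer seed.
#' @return As [simulate_reads()], plus `n_reads` used.
#' @export
simulate_stock <- function(lysogen, copy_ratio, coverage = 50, read_len = 100L,
                           seed = 1L) {
  if (copy_ratio < 0) stop("copy_ratio must be >= 0")
  Lh <- genome_length(lysogen$host)
  Le <- genome_length(lysogen$element)
  w_host <- Lh
  w_elem <- copy_ratio * Le
  n_reads <- as.integer(round(coverage * (Lh + copy_ratio * Le) / read_len))
  templates <- list(list(record = lysogen$host, mode = "linear", weight = w_host))
  if (copy_ratio > 0) {
    templates <- c(templates, list(list(record = lysogen$element,
                                        mode = "circular", weight = w_elem)))
  }
  out <- simulate_reads(templates, n_reads, read_len, seed)
  out$n_reads <- n_reads
  out
}

#' Write a synthetic truth ledger as JSON
#' @param truth Truth list (e.g. from [build_lysogen()]).
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
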