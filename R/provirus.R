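# att-core detection against tRNA 3' ends, integrate/excise coordinate
# arithmetic, and the bridging-CDS scanner on circularized elements.
#
# Integrative elements of archaea typically use the 3' end of a host tRNA
# gene as the att core: the core is duplicated on integration (attL ends the
# tRNA, attR closes the element), and a single copy remains on the circular
# element (attP) and on the restored host (attB).

#' Find the att core: the longest tRNA 3'-suffix present in an element
#'
#' Searches the circular element (forward strand) for the longest suffix of
#' the tRNA gene sequence that occurs exactly; that shared sequence is the
#' att core.
#'
#' @param trna_seq tRNA gene sequence (coding strand, 3' end last).
#' @param element A circular `genome_record`.
#' @param min_len Minimum acceptable core length (default 8; shorter matches
#'   are indistinguishable from chance).
#' @return `NULL` if no suffix of at least `min_len` occurs; otherwise a list
#'   with `core`, `length`, `positions` (1-based starts in the element) and
#'   `ambiguous` (TRUE when the longest core occurs more than once).
#' @export
find_att_core <- function(trna_seq, element, min_len = 8L) {
  trna_seq <- toupper(trna_seq)
  if (min_len < 8L) stop("min_len must be >= 8")
  if (nchar(trna_seq) < min_len) stop("tRNA sequence shorter than min_len")
  n <- genome_length(element)
  tl <- nchar(trna_seq)
  search_len <- min(tl, n)
  ext <- paste0(element$seq, substr(element$seq, 1L, search_len - 1L))
  for (len in seq(search_len, min_len)) {
    suffix <- substr(trna_seq, tl - len + 1L, tl)
    if (grepl("N", suffix, fixed = TRUE)) next
    hits <- unlist(gregexpr(suffix, ext, fixed = TRUE))
    hits <- hits[hits > 0L & hits <= n]
    if (length(hits)) {
      return(list(core = suffix, length = len, positions = as.integer(hits),
                  ambiguous = length(hits) > 1L))
    }
  }
  NULL
}

#' Integrate a circular element into a host at a tRNA 3' end
#'
#' The element is linearized at its single att core and inserted just after
#' `site` (the 3'-terminal base of the tRNA, which must end with the att
#' core) so that the core is duplicated: attL ends the tRNA and attR closes
#' the inserted element. Host feature coordinates downstream of the insertion
#' are lifted; element features are lifted into the host.
#'
#' @param host A `genome_record`.
#' @param site Host coordinate of the tRNA 3'-terminal base.
#' @param element A circular `genome_record` containing `att_core` exactly once.
#' @param att_core The att core sequence.
#' @return The integrated host `genome_record` (length = host + element).
#' @export
integrate_element <- function(host, site, element, att_core) {
  att_core <- toupper(att_core)
  core_len <- nchar(att_core)
  if (element$topology != "circular") stop("element must be circular")
  n_e <- genome_length(element)
  ext <- paste0(element$seq, substr(element$seq, 1L, core_len - 1L))
  hits <- unlist(gregexpr(att_core, ext, fixed = TRUE))
  hits <- hits[hits > 0L & hits <= n_e]
  if (length(hits) != 1L) {
    stop("att core must occur exactly once in the element (found ",
         length(hits), ")")
  }
  if (!identical(substr(host$seq, site - core_len + 1L, site), att_core)) {
    stop("host sequence at the integration site does not end with the att core")
  }
  # canonical rotation: att core becomes the final core_len bases
  canon <- rotate_seq(element$seq, ((hits + core_len - 1L) %% n_e) + 1L)
  shift_into_canon <- function(pos) ((pos - (hits + core_len) ) %% n_e) + 1L
  new_seq <- paste0(substr(host$seq, 1L, site), canon,
                    substr(host$seq, site + 1L, genome_length(host)))

  hf <- host$features
  if (nrow(hf)) {
    bump <- function(p) ifelse(p > site, p + n_e, p)
    hf$start <- bump(hf$start); hf$stop <- bump(hf$stop)
  }
  ef <- element$features
  if (nrow(ef)) {
    ef$start <- site + shift_into_canon(ef$start)
    ef$stop <- site + shift_into_canon(ef$stop)
  }
  genome_record(host$id, new_seq, host$topology, rbind(hf, ef))
}

#' Excise an integrated provirus
#'
#' Cuts out the element between the duplicated att cores: the circular
#' element is `[attL_start .. attR_start + core_len - 1]` minus one core
#' copy, returned in the canonical rotation (att core last, so the attP
#' junction is the origin); the restored host keeps a single core (attB).
#'
#' @param host Integrated host `genome_record`.
#' @param attL_start,attR_start 1-based starts of the two identical cores.
#' @param core_len Core length in bp.
#' @return List with `element` (circular `genome_record`) and `host`
#'   (restored `genome_record`). Features inside the excised span are moved to
#'   the element; features outside are kept with shifted coordinates.
#' @export
excise_element <- function(host, attL_start, attR_start, core_len) {
  n <- genome_length(host)
  core_len <- as.integer(core_len)
  if (attR_start <= attL_start) stop("attR must lie right of attL")
  attL <- substr(host$seq, attL_start, attL_start + core_len - 1L)
  attR <- substr(host$seq, attR_start, attR_start + core_len - 1L)
  if (!identical(attL, attR)) stop("att repeats are not identical")
  elem_len <- attR_start - attL_start
  if (elem_len <= core_len) stop("degenerate excision: no element between cores")
  excise_from <- attL_start + core_len          # first base after attL
  excise_to <- attR_start + core_len - 1L       # last base of attR
  element_seq <- substr(host$seq, excise_from, excise_to)
  host_seq <- paste0(substr(host$seq, 1L, excise_from - 1L),
                     substr(host$seq, excise_to + 1L, n))

  hf <- host$features
  inside <- hf$start >= excise_from & hf$stop <= excise_to
  ef <- hf[inside, , drop = FALSE]
  if (nrow(ef)) {
    ef$start <- ef$start - excise_from + 1L
    ef$stop <- ef$stop - excise_from + 1L
  }
  keep <- hf[!inside & !(hf$start >= excise_from & hf$start <= excise_to), ,
             drop = FALSE]
  if (nrow(keep)) {
    shift <- function(p) ifelse(p > excise_to, p - elem_len, p)
    keep$start <- shift(keep$start); keep$stop <- shift(keep$stop)
  }
  list(
    element = genome_record(paste0(host$id, "_element"), element_seq,
                            "circular", if (nrow(ef)) ef else NULL),
    host = genome_record(host$id, host_seq, host$topology,
                         if (nrow(keep)) keep else NULL)
  )
}

#' Find a bridging CDS spanning the attP junction of a circular element
#'
#' On the strand of the annotated integrase, scans for open reading frames
#' (starts ATG/GTG/TTG, stops TAA/TAG/TGA, length >= `min_orf`) that begin
#' within `max_gap` bp downstream of the integrase stop, span `attP_pos`, and
#' end within `max_gap` bp of (or overlapping) the next annotated downstream
#' CDS. The downstream CDS is expected to encode a protein with at least two
#' CxxC motifs; when it does not, the hit is still returned with
#' `cxxc_warning = TRUE`. The longest qualifying ORF wins ties.
#'
#' Because such an ORF spans the att core, integration splits it: the
#' returned `provirus_form` gives the two pieces it leaves in the provirus
#' state (5' piece ending at attR, 3' piece starting after attL).
#'
#' @param element Circular `genome_record` with an annotated integrase CDS
#'   (product containing "integrase", or locus tag given via `integrase`).
#' @param attp_pos 1-based element coordinate of the first base of the att
#'   core.
#' @param integrase Optional locus tag of the integrase CDS.
#' @param max_gap Maximum spacing in bp (default 100).
#' @param min_orf Minimum ORF length in nt (default 150).
#' @param starts Allowed start codons.
#' @return `NULL` or a list with `start`, `stop` (element coordinates;
#'   `start > stop` means the ORF wraps the origin), `length`, `strand`,
#'   `provirus_form` (list of two `c(start, stop)` pieces in element
#'   coordinates), `downstream_cds`, `cxxc_warning`.
#' @export
find_bridging_cds <- function(element, attp_pos, integrase = NULL,
                              max_gap = 100L, min_orf = 150L,
                              starts = c("ATG", "GTG", "TTG")) {
  if (element$topology != "circular") stop("element must be circular")
  ft <- element$features
  cds <- ft[ft$kind == "CDS", , drop = FALSE]
  if (is.null(integrase)) {
    idx <- grep("integrase", cds$product, ignore.case = TRUE)
    if (!length(idx)) stop("no integrase CDS annotated on the element")
    int_feat <- cds[idx[1L], , drop = FALSE]
  } else {
    int_feat <- get_feature(element, integrase)
  }
  n <- genome_length(element)
  if (identical(int_feat$strand, "-")) {
    # canonicalize to the plus strand by reverse-complementing the element
    flipped <- revcomp_record(element)
    res <- find_bridging_cds(flipped$record, flipped$map(attp_pos + 0L),
                             integrase = int_feat$locus_tag,
                             max_gap = max_gap, min_orf = min_orf,
                             starts = starts)
    return(flip_bridging_result(res, n))
  }

  int_stop_pos <- int_feat$stop
  ext <- paste0(element$seq, element$seq, element$seq)  # scan circularly
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  cand_starts <- int_stop_pos + seq_len(max_gap)
  for (s in cand_starts) {
    codon <- substr(ext, s, s + 2L)
    if (!(codon %in% starts)) next
    # walk codons to the first stop
    pos <- s + 3L
    orf_stop <- NA_integer_
    while (pos + 2L <= s + n) {
      cd <- substr(ext, pos, pos + 2L)
      if (cd %in% stops) { orf_stop <- pos + 2L; break }
      pos <- pos + 3L
    }
    if (is.na(orf_stop)) next
    orf_len <- orf_stop - s + 1L
    if (orf_len < min_orf) next
    # must span the attP position (circular containment)
    s_mod <- ((s - 1L) %% n) + 1L
    attp_unwrapped <- if (attp_pos >= s_mod) attp_pos else attp_pos + n
    spans_attp <- (s_mod <= attp_unwrapped) && (attp_unwrapped <= s_mod + orf_len - 1L)
    if (!spans_attp) next
    # next downstream CDS (other than the integrase), circular order
    ds <- next_downstream_cds(cds, int_feat, orf_stop, n)
    if (is.null(ds)) next
    if (ds$gap > max_gap) next
    if (is.null(best) || orf_len > best$length) {
      cxxc_n <- tryCatch(
        length(cxxc_scan(translate_cds(element, ds$locus_tag))),
        error = function(e) 0L
      )
      best <- list(
        start = s_mod,
        stop = ((orf_stop - 1L) %% n) + 1L,
        length = orf_len,
        strand = "+",
        downstream_cds = ds$locus_tag,
        cxxc_warning = cxxc_n < 2L
      )
    }
  }
  if (is.null(best)) return(NULL)
  best$provirus_form <- split_orf_coords(best$start, best$stop, attp_pos, n)
  if (!is.null(best$cxxc_warning) && best$cxxc_warning) {
    warning("downstream CDS ", best$downstream_cds,
            " carries fewer than two CxxC motifs")
  }
  best
}

# Nearest CDS downstream of the ORF stop in circular order, allowing the CDS
# to start up to `slack` bp before the stop (overlap). Returns the feature row
# with a `gap` column: bases between ORF stop and CDS start (negative or zero
# when they overlap or abut).
next_downstream_cds <- function(cds, int_feat, orf_stop, n, slack = 200L) {
  others <- cds[cds$locus_tag != int_feat$locus_tag & cds$strand ==
                  int_feat$strand, , drop = FALSE]
  if (!nrow(others)) return(NULL)
  stop_mod <- ((orf_stop - 1L) %% n) + 1L
  d <- (others$start - stop_mod + slack) %% n
  best <- which.min(d)
  out <- others[best, , drop = FALSE]
  out$gap <- d[best] - slack - 1L
  out
}

split_orf_coords <- function(start, stop, attp_pos, n) {
  # In the provirus, the circle is opened at the end of the att core
  # (canonical origin when attp_pos + core - 1 == n). The ORF spans attP, so
  # piece 1 runs start..n (ending at attR) and piece 2 runs 1..stop (starting
  # after attL) whenever the ORF wraps; a non-wrapping ORF splits at the core.
  if (start > stop) {
    list(five_prime = c(start = start, stop = n),
         three_prime = c(start = 1L, stop = stop))
  } else {
    list(five_prime = c(start = start, stop = attp_pos - 1L),
         three_prime = c(start = attp_pos, stop = stop))
  }
}

revcomp_record <- function(record) {
  n <- genome_length(record)
  seq <- revcomp(record$seq)
  ft <- record$features
  if (nrow(ft)) {
    new_start <- n - ft$stop + 1L
    new_stop <- n - ft$start + 1L
    ft$start <- new_start; ft$stop <- new_stop
    ft$strand <- ifelse(ft$strand == "-", "+", "-")
  }
  list(record = genome_record(record$id, seq, record$topology, ft),
       map = function(pos) n - pos + 1L)
}

flip_bridging_result <- function(res, n) {
  if (is.null(res)) return(NULL)
  flip <- function(p) n - p + 1L
  out <- res
  out$start <- flip(res$start)
  out$stop <- flip(res$stop)
  out$strand <- "-"
  out$provirus_form <- lapply(res$provirus_form, function(piece) {
    c(start = flip(unname(piece["stop"])), stop = flip(unname(piece["start"])))
  })
  out
}
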