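# Combined per-genome characterization report and stock screening, plus the
# JSON/TSV surfaces the command-line entry point exposes.

#' Run configuration
#'
#' Bundles the tunables of a run so every report can embed them; equal
#' configurations on equal inputs give byte-identical reports (the timestamp
#' is off by default for that reason).
#'
#' @param window Skew window in bp.
#' @param k Tetramer census size (fixed at 4; recorded for provenance).
#' @param odds_threshold Under-representation threshold.
#' @param repeat_min_len Minimum repeat unit length.
#' @param flank,min_anchor,junction_min,ratio_min Induction parameters.
#' @param seed Seed recorded for any stochastic step.
#' @param timestamp Optional timestamp string (`NULL` by default).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(window = 45L, k = 4L, odds_threshold = 0.15,
                       repeat_min_len = 100L, flank = 50L, min_anchor = 20L,
                       junction_min = 2L, ratio_min = 5, seed = 1L,
                       timestamp = NULL) {
  out <- list(window = window, k = k, odds_threshold = odds_threshold,
              repeat_min_len = repeat_min_len, flank = flank,
              min_anchor = min_anchor, junction_min = junction_min,
              ratio_min = ratio_min, seed = seed,
              version = as.character(utils::packageVersion("provirseq")),
              timestamp = timestamp)
  class(out) <- "run_config"
  out
}

#' Combined characterization report for one genome
#'
#' Aggregates the sequence-level analyses: length and G+C, the
#' motif-avoidance report, the cumulative AT-skew extremum, CDS spacing
#' statistics, a CxxC census over annotated CDS, direct repeats, and (when a
#' locus is named in `slippery_cds`) slippery-site hits.
#'
#' @param record A `genome_record`.
#' @param config A [run_config()].
#' @param slippery_cds Optional locus tag to scan for slippery heptamers.
#' @return A list of class `genome_report`; serialize with
#'   [write_report_json()].
#' @export
run_genome_report <- function(record, config = run_config(),
                              slippery_cds = NULL) {
  av <- avoidance_report(record, odds_threshold = config$odds_threshold)
  skew <- at_skew_profile(record, config$window)
  has_cds <- any(record$features$kind == "CDS")
  spacing <- if (has_cds) spacing_stats(record) else NULL
  cxxc <- if (has_cds) cxxc_census(record) else NULL
  repeats <- find_direct_repeats(record$seq, config$repeat_min_len)
  slippery <- if (!is.null(slippery_cds)) {
    find_slippery(record, slippery_cds)
  } else NULL
  out <- list(
    id = record$id,
    length = genome_length(record),
    topology = record$topology,
    gc_percent = gc_percent(record$seq),
    absent_tetramers = av$absent_tetramers,
    under_represented_tetramers = av$under_represented_tetramers,
    absent_palindromic_6mers = av$absent_palindromic_6mers,
    skew_inflection = skew_inflection(skew),
    spacing = if (is.null(spacing)) list(absent = TRUE) else
      spacing[c("n_genes", "n_overlapping_genes", "n_close_genes")],
    cxxc_census = cxxc,
    repeats = repeats,
    slippery = slippery,
    config = unclass(config)
  )
  class(out) <- "genome_report"
  out
}

# per-CDS CxxC motif counts; proteins that fail to translate are skipped
cxxc_census <- function(record) {
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  cds <- cds[nzchar(cds$locus_tag), , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  counts <- vapply(cds$locus_tag, function(lt) {
    aa <- tryCatch(translate_cds(record, lt), error = function(e) NA_character_)
    if (is.na(aa)) NA_integer_ else length(cxxc_scan(aa))
  }, 0L)
  data.frame(locus_tag = cds$locus_tag, n_cxxc = unname(counts),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("<genome_report> %s: %d bp (%s), GC %.1f%%\n", x$id, x$length,
              x$topology, x$gc_percent))
  cat("  absent tetramers:", paste(x$absent_tetramers, collapse = ", "), "\n")
  cat("  cumulative AT-skew maximum at nt", x$skew_inflection, "\n")
  if (is.null(x$spacing$absent)) {
    cat(sprintf("  CDS: %d genes, %d overlapping, %d close (<=10 bp)\n",
                x$spacing$n_genes, x$spacing$n_overlapping_genes,
                x$spacing$n_close_genes))
  }
  invisible(x)
}

#' Serialize a report (or any result list) as JSON
#' @param report List to serialize.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
  }
  if (!is.data.frame(x)) x <- unclass(x)
  x
}

#' Screen a read stock for induced proviruses
#'
#' One evidence row per candidate provirus. Candidates with coordinates that
#' fail (e.g. unequal att repeats) are skipped with a warning rather than
#' aborting the screen.
#'
#' @param reads Character vector of reads (e.g. from [read_fastq()]).
#' @param host Integrated host `genome_record`.
#' @param provirus_table Data frame with columns `provirus_id`, `start`
#'   (attL start), `end` (attR end), `core_len`.
#' @param config A [run_config()].
#' @return Data frame with one row per screened provirus: junction read
#'   counts, coverage depths, ratio, and the call.
#' @export
run_stock_screen <- function(reads, host, provirus_table,
                             config = run_config()) {
  if (!length(reads)) stop("empty read set: nothing to screen")
  need <- c("provirus_id", "start", "end", "core_len")
  if (!all(need %in% names(provirus_table))) {
    stop("provirus_table must have columns ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(provirus_table)), function(i) {
    p <- provirus_table[i, ]
    # other candidates are masked from this candidate's coverage background,
    # so one induced provirus does not hide another
    others <- lapply(setdiff(seq_len(nrow(provirus_table)), i), function(j) {
      c(provirus_table$start[j], provirus_table$end[j])
    })
    ev <- tryCatch(
      induction_evidence(reads, host, p$start, p$end, p$core_len,
                         flank = config$flank, min_anchor = config$min_anchor,
                         junction_min = config$junction_min,
                         ratio_min = config$ratio_min,
                         provirus_id = p$provirus_id, exclude = others),
      error = function(e) {
        warning("skipping ", p$provirus_id, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(ev)) return(NULL)
    data.frame(provirus_id = ev$provirus_id,
               attP_junction_reads = ev$attP_junction_reads,
               attB_junction_reads = ev$attB_junction_reads,
               coverage_inside = ev$coverage_inside,
               coverage_outside = ev$coverage_outside,
               ratio = ev$ratio, call = ev$call,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    return(data.frame(provirus_id = character(),
                      attP_junction_reads = integer(),
                      attB_junction_reads = integer(),
                      coverage_inside = numeric(),
                      coverage_outside = numeric(),
                      ratio = numeric(), call = character()))
  }
  do.call(rbind, rows)
}

#' Write a data frame as a single-header TSV
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
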