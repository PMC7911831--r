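# Windowed nucleotide-skew profiling of circular genomes.
#
# Cumulative AT-skew over non-overlapping tiling windows; the global extremum
# of the cumulative series marks the major inflection where gene orientation
# typically switches on small tailed-virus genomes.

#' Windowed AT-skew profile
#'
#' Per non-overlapping window of `window` bp, skew = `(A - T) / (A + T)`;
#' windows with no A or T contribute 0 so the cumulative sum stays defined.
#' The final partial window is discarded.
#'
#' @param record A `genome_record`.
#' @param window Window size in bp (default 45).
#' @return An object of class `skew_profile`: list with `window`,
#'   `coordinates` (window start positions), `values`, and `cumulative`
#'   (exact prefix sums of `values`).
#' @export
at_skew_profile <- function(record, window = 45L) {
  w <- window_matrix(record$seq, window)
  a <- colSums(w == "A")
  t <- colSums(w == "T")
  denom <- a + t
  values <- ifelse(denom == 0, 0, (a - t) / pmax(denom, 1L))
  new_skew_profile(record, window, values)
}

#' Windowed GC-content track
#'
#' Per non-overlapping window, the fraction of G+C bases among A/C/G/T bases
#' in the window (N excluded; all-N windows contribute 0).
#'
#' @inheritParams at_skew_profile
#' @return A `skew_profile` whose `values` are GC fractions.
#' @export
gc_track <- function(record, window = 45L) {
  w <- window_matrix(record$seq, window)
  gc <- colSums(w == "G" | w == "C")
  acgt <- colSums(w != "N")
  values <- ifelse(acgt == 0, 0, gc / pmax(acgt, 1L))
  new_skew_profile(record, window, values)
}

window_matrix <- function(seq, window) {
  window <- as.integer(window)
  n <- nchar(seq)
  if (window < 1L) stop("window must be >= 1")
  if (n < window) stop("sequence shorter than one window")
  nw <- n %/% window
  chars <- strsplit(substr(seq, 1L, nw * window), "")[[1L]]
  matrix(chars, nrow = window)
}

new_skew_profile <- function(record, window, values) {
  structure(
    list(id = record$id, window = as.integer(window),
         coordinates = as.integer(seq(1L, by = window, length.out = length(values))),
         values = as.numeric(values),
         cumulative = cumsum(as.numeric(values))),
    class = "skew_profile"
  )
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %s: %d windows of %d bp; cumulative range [%.2f, %.2f]\n",
              x$id, length(x$values), x$window,
              min(x$cumulative), max(x$cumulative)))
  invisible(x)
}

#' Coordinate of the global maximum of the cumulative skew
#'
#' Reports the start coordinate of the window where the cumulative series
#' peaks (ties broken toward the smallest coordinate). Descriptive only; no
#' replication-origin call is implied.
#'
#' @param profile A `skew_profile`.
#' @return Window start coordinate (1-based).
#' @export
skew_inflection <- function(profile) {
  if (!length(profile$values)) stop("empty profile")
  profile$coordinates[which.max(profile$cumulative)]
}
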