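# Exact tandem-repeat detection: maximal runs of 1-6 bp units, total length
# >= max(4, 2 units), rotational phases collapsed to one canonical class.

#' Canonical rotation of a repeat unit
#'
#' Rotational phases of a unit describe the same tandem repeat (ACAC and CACA
#' are both repeats of the CA unit); the class label is the lexicographically
#' smallest rotation.
#'
#' @param unit repeat unit string.
#' @param merge_complement also consider rotations of the reverse complement,
#'   so that e.g. `(A)n` and `(T)n` share a class label.
#' @return The canonical unit string.
#' @export
canonical_rotation <- function(unit, merge_complement = FALSE) {
  u <- toupper(unit)
  n <- nchar(u)
  rot <- vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(u, k + 1L, n), substr(u, 1L, k))
  }, character(1L))
  if (merge_complement) {
    rc <- revcomp(u)
    rot <- c(rot, vapply(seq_len(n) - 1L, function(k) {
      paste0(substr(rc, k + 1L, n), substr(rc, 1L, k))
    }, character(1L)))
  }
  min(rot)
}

#' Smallest period of an integer-coded segment
#' @keywords internal
smallest_period <- function(code) {
  n <- length(code)
  for (p in seq_len(n - 1L)) {
    if (all(code[seq_len(n - p)] == code[seq_len(n - p) + p])) return(p)
  }
  n
}

#' Find tandem repeats
#'
#' Detects maximal head-to-tail repetitions of 1-6 bp units. A run qualifies if
#' its total length is at least `max(min_total, 2 * unit length)` (at least two
#' full units). The class label is the lexicographically smallest rotation of
#' the unit; a homopolymer run is reported once, under its 1 bp unit, never
#' additionally as a 2 bp repeat (smallest-period rule). Overlaps between runs
#' of different unit lengths are resolved greedily -- longest run first, then
#' leftmost, then shortest unit -- and remaining candidates are trimmed to the
#' uncovered bases (kept if the trimmed piece still qualifies), so no base is
#' counted twice. `N` breaks runs.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param max_unit maximum unit length (bp).
#' @param min_total minimum total run length (bp).
#' @param merge_complements report classes with forward/reverse-complement
#'   units merged (a reporting option; detection is strand-specific).
#' @return Data frame with chrom, start, end (0-based half-open), class, unit,
#'   unit_length.
#' @export
find_tandem_repeats <- function(genome, max_unit = 6L, min_total = 4L,
                                merge_complements = FALSE) {
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1L) {
    genome <- c(seq = genome)
  }
  genome <- as_genome(genome)
  out <- lapply(names(genome), function(ch) {
    tr <- scan_chromosome_trs(seq_to_code(genome[[ch]]), max_unit, min_total)
    if (nrow(tr) == 0L) return(NULL)
    tr$chrom <- ch
    tr
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      class = character(0), unit = character(0),
                      unit_length = integer(0)))
  }
  out$class <- vapply(out$unit, function(u) {
    paste0("(", canonical_rotation(u, merge_complement = merge_complements), ")n")
  }, character(1L))
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "class", "unit", "unit_length")]
  rownames(out) <- NULL
  out
}

#' @keywords internal
scan_chromosome_trs <- function(code, max_unit, min_total) {
  L <- length(code)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_length = integer(0))
  if (L < min_total) return(empty)

  # collect maximal period-u runs whose smallest period is exactly u
  cand <- list()
  for (u in seq_len(min(max_unit, L - 1L))) {
    m <- code[seq_len(L - u)] == code[seq_len(L - u) + u]
    m[is.na(m)] <- FALSE
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]                 # first matching position (1-based)
      e <- ends[j] + u               # last base of the run
      len <- e - s + 1L
      if (len < max(min_total, 2L * u)) next
      if (smallest_period(code[s:e]) != u) next
      cand[[length(cand) + 1L]] <- c(s, e, u)
    }
  }
  if (length(cand) == 0L) return(empty)
  cm <- do.call(rbind, cand)
  len <- cm[, 2L] - cm[, 1L] + 1L
  cm <- cm[order(-len, cm[, 1L], cm[, 3L]), , drop = FALSE]

  covered <- logical(L)
  o_start <- integer(0); o_end <- integer(0); o_unit <- character(0)
  for (i in seq_len(nrow(cm))) {
    s <- cm[i, 1L]; e <- cm[i, 2L]
    free <- !covered[s:e]
    if (!any(free)) next
    r <- rle(free)
    pe <- cumsum(r$lengths); ps <- pe - r$lengths + 1L
    for (j in which(r$values)) {
      a <- s + ps[j] - 1L; b <- s + pe[j] - 1L
      p <- smallest_period(code[a:b])   # trimming can expose a smaller period
      if ((b - a + 1L) < max(min_total, 2L * p)) next
      covered[a:b] <- TRUE
      o_start <- c(o_start, a - 1L); o_end <- c(o_end, b)  # 0-based half-open
      o_unit <- c(o_unit, code_to_seq(code[a:(a + p - 1L)]))
    }
  }
  if (length(o_start) == 0L) return(empty)
  data.frame(start = o_start, end = o_end, unit = o_unit,
             unit_length = nchar(o_unit))
}

#' Per-class tandem-repeat base-coverage tracks
#'
#' @param trs output of [find_tandem_repeats()].
#' @param lengths named chromosome lengths.
#' @param resolution bin width (bp).
#' @param classes restrict to these classes (default: all present).
#' @return Named list of [binned_track()]s, one per TR class.
#' @export
tr_coverage_tracks <- function(trs, lengths, resolution = 1000L, classes = NULL) {
  classes <- classes %||% sort(unique(trs$class))
  out <- lapply(classes, function(cl) {
    coverage_track(trs[trs$class == cl, , drop = FALSE], lengths, resolution)
  })
  stats::setNames(out, classes)
}
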