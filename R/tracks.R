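# Fixed-resolution binned genomic tracks and dinucleotide/nucleotide counting.

#' Construct a binned track
#'
#' A binned track stores one value per fixed-width bin per chromosome, together
#' with the fraction of valid (non-ambiguous, unmasked) bases per bin. Bins
#' whose valid fraction falls below 0.5 are flagged invalid and carry `NA`
#' values rather than silent zeros.
#'
#' @param values named list (per chromosome) of numeric bin values.
#' @param valid named list of per-bin valid fractions in `[0, 1]`.
#' @param resolution bin width (bp).
#' @param lengths named chromosome lengths (bp).
#' @return A `binned_track` object.
#' @export
binned_track <- function(values, valid, resolution, lengths) {
  stopifnot(is.list(values), is.list(valid),
            identical(names(values), names(valid)),
            identical(names(values), names(lengths)))
  for (ch in names(values)) {
    nb <- ceiling(lengths[[ch]] / resolution)
    if (length(values[[ch]]) != nb || length(valid[[ch]]) != nb) {
      stop("chromosome ", ch, ": expected ", nb, " bins")
    }
    if (any(valid[[ch]] < 0 | valid[[ch]] > 1)) stop("valid fraction outside [0,1]")
  }
  structure(list(values = values, valid = valid,
                 resolution = as.integer(resolution),
                 lengths = lengths),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- sum(vapply(x$values, length, integer(1L)))
  cat("<binned_track> ", length(x$values), " chromosome(s), ", nb,
      " bins at ", x$resolution, " bp\n", sep = "")
  invisible(x)
}

#' Number of bins per chromosome at a resolution
#' @keywords internal
n_bins <- function(lengths, resolution) ceiling(lengths / resolution)

#' Count nucleotides and dinucleotides in fixed-width bins
#'
#' Overlapping dinucleotides are counted on the forward strand. The
#' dinucleotide spanning positions `(i, i+1)` is assigned to the bin containing
#' `i`, so the dinucleotide bridging two bins belongs to the left bin and every
#' genomic dinucleotide is counted exactly once: a fully valid interior bin has
#' `sum(n_XY) == resolution`. Dinucleotides containing `N` are skipped; the
#' per-bin valid fraction is the fraction of non-`N` bases. Bins with valid
#' fraction below 0.5 are flagged invalid.
#'
#' @param genome named character vector of chromosome sequences (A/C/G/T/N,
#'   case-insensitive). Other characters raise an error naming the position.
#' @param resolution bin width in bp (default 1000).
#' @return A `dinuc_tracks` object: per chromosome, an integer matrix of the 16
#'   dinucleotide counts (`bins x 16`, columns AA..TT), a `bins x 4` nucleotide
#'   count matrix, and the per-bin valid fraction.
#' @export
count_dinucleotides <- function(genome, resolution = 1000L) {
  genome <- as_genome(genome)
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 2L)
  lens <- chrom_lengths(genome)
  di <- list(); nuc <- list(); valid <- list()
  for (ch in names(genome)) {
    code <- seq_to_code(genome[[ch]])
    L <- length(code)
    nb <- ceiling(L / resolution)
    bin <- (seq_len(L) - 1L) %/% resolution  # 0-based bin of each base

    ok <- !is.na(code)
    nm <- matrix(tabulate(bin[ok] * 4L + code[ok], nb * 4L),
                 nb, 4L, byrow = TRUE, dimnames = list(NULL, .BASES))

    a <- code[-L]; b <- code[-1L]
    keep <- !is.na(a) & !is.na(b)
    dcode <- (a[keep] - 1L) * 4L + b[keep]
    dbin <- bin[seq_len(L - 1L)][keep]
    dm <- matrix(tabulate(dbin * 16L + dcode, nb * 16L),
                 nb, 16L, byrow = TRUE, dimnames = list(NULL, .DINUCS))

    binlen <- pmin(resolution, L - (seq_len(nb) - 1L) * resolution)
    di[[ch]] <- dm
    nuc[[ch]] <- nm
    valid[[ch]] <- rowSums(nm) / binlen
  }
  structure(list(di = di, nuc = nuc, valid = valid,
                 resolution = resolution, lengths = lens),
            class = "dinuc_tracks")
}

#' @export
print.dinuc_tracks <- function(x, ...) {
  cat("<dinuc_tracks> ", length(x$di), " chromosome(s) at ",
      x$resolution, " bp\n", sep = "")
  invisible(x)
}

#' Extract one dinucleotide (or nucleotide) count track
#'
#' @param dinucs a `dinuc_tracks` (or expectation) object.
#' @param what a dinucleotide (`"AC"`) or single base (`"A"`).
#' @return A [binned_track()] of per-bin counts; invalid bins are `NA`.
#' @export
track_of <- function(dinucs, what) {
  src <- if (nchar(what) == 2L) dinucs$di else dinucs$nuc
  if (!(what %in% colnames(src[[1L]]))) stop("unknown track: ", what)
  values <- lapply(names(src), function(ch) {
    v <- as.numeric(src[[ch]][, what])
    v[dinucs$valid[[ch]] < 0.5] <- NA_real_
    v
  })
  names(values) <- names(src)
  binned_track(values, dinucs$valid, dinucs$resolution, dinucs$lengths)
}

#' Base-coverage track of a set of intervals
#'
#' The value of each bin is the number of bases covered by the union of the
#' intervals (overlaps flattened) intersected with the bin.
#'
#' @param intervals data frame with chrom, start, end (0-based half-open).
#' @param lengths named chromosome lengths (bp).
#' @param resolution bin width (bp).
#' @param valid optional named list of valid fractions to attach (defaults to
#'   fully valid).
#' @return A [binned_track()].
#' @export
coverage_track <- function(intervals, lengths, resolution = 1000L, valid = NULL) {
  check_intervals(intervals)
  resolution <- as.integer(resolution)
  values <- list(); vl <- list()
  for (ch in names(lengths)) {
    L <- lengths[[ch]]
    nb <- ceiling(L / resolution)
    sel <- intervals$chrom == ch
    s <- pmax(intervals$start[sel], 0L)
    e <- pmin(intervals$end[sel], L)
    keep <- e > s
    cov <- IRanges::coverage(
      IRanges::reduce(IRanges::IRanges(start = s[keep] + 1L, end = e[keep])),
      width = L)
    starts <- seq.int(1L, by = resolution, length.out = nb)
    widths <- pmin(resolution, L - starts + 1L)
    values[[ch]] <- as.numeric(sum(IRanges::Views(
      cov, IRanges::IRanges(start = starts, width = widths))))
    vl[[ch]] <- if (is.null(valid)) rep(1, nb) else valid[[ch]]
  }
  binned_track(values, vl, resolution, lengths)
}

#' Invalidate gap-rich bins
#'
#' Bins whose valid fraction is below the threshold (sequencing gaps, masked
#' regions such as centromeres) get `NA` values.
#'
#' @param track a [binned_track()].
#' @param threshold minimum valid fraction to retain a bin.
#' @return The masked track.
#' @export
mask_gaps <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "binned_track"))
  for (ch in names(track$values)) {
    track$values[[ch]][track$valid[[ch]] < threshold] <- NA_real_
  }
  track
}

#' Genome-wide vector of bin values
#' @param track a [binned_track()].
#' @return Numeric vector, concatenated over chromosomes.
#' @export
track_values <- function(track) {
  unlist(track$values, use.names = FALSE)
}

#' Export a binned track as bedGraph
#'
#' Invalid (`NA`) bins are omitted, as bedGraph has no missing-value encoding.
#'
#' @param track a [binned_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- length(v)
    start <- (seq_len(nb) - 1L) * track$resolution
    end <- pmin(start + track$resolution, track$lengths[[ch]])
    keep <- !is.na(v)
    data.frame(chrom = ch, start = start[keep], end = end[keep], value = v[keep])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
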