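# Shared constants and low-level sequence helpers.

#' The four DNA bases, in the fixed order used throughout the package
#' @keywords internal
.BASES <- c("A", "C", "G", "T")

#' The 16 dinucleotides in row-major (first base slow) order: AA, AC, ..., TT
#' @keywords internal
.DINUCS <- paste0(rep(.BASES, each = 4L), .BASES)

#' Derive a child RNG seed from a master seed and a stream key
#'
#' Every stochastic operation in the synthetic-data module draws its seed from
#' the master seed and a stream key (operation name plus ordinal), so that a
#' stage can be regenerated independently of the others.
#'
#' @param master integer master seed.
#' @param key character stream key, e.g. `"insert_repeats:1"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(master) * 48271 + h * 16807) %% 2147483647)
}

#' Encode a DNA string as integer codes A=1, C=2, G=3, T=4 (N and other
#' ambiguity codes become NA)
#' @keywords internal
seq_to_code <- function(x) {
  r <- charToRaw(toupper(x))
  code <- integer(length(r))
  code[r == charToRaw("A")] <- 1L
  code[r == charToRaw("C")] <- 2L
  code[r == charToRaw("G")] <- 3L
  code[r == charToRaw("T")] <- 4L
  bad <- code == 0L & r != charToRaw("N")
  if (any(bad)) {
    stop("non-IUPAC character '", rawToChar(r[which(bad)[1L]]),
         "' at position ", which(bad)[1L])
  }
  code[code == 0L] <- NA_integer_
  code
}

#' @keywords internal
code_to_seq <- function(code) {
  out <- .BASES[code]
  out[is.na(code)] <- "N"
  paste0(out, collapse = "")
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

#' Reverse complement of a dinucleotide label (vectorised)
#' @keywords internal
revcomp_dinuc <- function(xy) {
  vapply(xy, revcomp, character(1L), USE.NAMES = FALSE)
}

#' Validate a genome object (named list/vector of DNA strings)
#' @keywords internal
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (is.list(genome)) genome <- unlist(genome)
  stopifnot(is.character(genome), length(genome) >= 1L)
  if (is.null(names(genome)) || any(names(genome) == "")) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  genome
}

#' @keywords internal
chrom_lengths <- function(genome) {
  vapply(as_genome(genome), nchar, integer(1L))
}

#' Validate an interval data frame (0-based half-open)
#' @keywords internal
check_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns chrom, start, end")
  }
  if (nrow(x) > 0L && any(x$end < x$start)) {
    stop(what, ": negative-length interval (end < start)")
  }
  x
}

#' Weighted mean / variance with reliability weights
#'
#' Variance uses the standard reliability-weight (frequency-corrected)
#' denominator `sum(w) - sum(w^2)/sum(w)`.
#' @keywords internal
weighted_stats <- function(x, w) {
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  n <- length(x)
  if (n == 0L) return(list(mean = NA_real_, var = NA_real_, weight = 0, n = 0L))
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  v <- if (denom > 0) sum(w * (x - m)^2) / denom else if (n == 1L) NA_real_ else 0
  list(mean = m, var = v, weight = sw, n = n)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
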