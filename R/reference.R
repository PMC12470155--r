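# Closed-form null expectations: zero-order (nucleotide-shuffled) dinucleotide
# content and first-order (dinucleotide-preserving) tandem-repeat content, plus
# the uniform/global-mean reference.

#' Zero-order Markov expectation of a dinucleotide count
#'
#' `E[n_XY] = n_X * n_Y / L_seq`: the expected count of dinucleotide XY after
#' random shuffling of the nucleotides of a sequence of valid length `L_seq`
#' with nucleotide counts `n_X`, `n_Y`.
#'
#' @param n_x,n_y nucleotide counts.
#' @param l_seq valid sequence length.
#' @return Expected count (NA where `l_seq` is 0).
#' @export
expected_dinucleotide_count <- function(n_x, n_y, l_seq) {
  ifelse(l_seq > 0, n_x * n_y / l_seq, NA_real_)
}

#' First-order Markov expectation of tandem-repeat content
#'
#' `E[n_XY, n>=2] = n_XY^2 * n_YX / (n_X * n_Y)`: the expected number of start
#' positions of two-unit (XY)2 occurrences (total length 4; longer runs
#' contribute multiple starts) in a first-order chain with the given
#' dinucleotide and nucleotide counts. Homopolymer classes (X == Y) degenerate
#' to `n_XX^3 / n_X^2`. By continuity the expectation is 0 whenever
#' `n_XY == 0`, even if the denominator vanishes.
#'
#' @param n_xy,n_yx dinucleotide counts of XY and of the back-step YX.
#' @param n_x,n_y nucleotide counts.
#' @return Expected count (NA where the denominator is 0 but `n_xy > 0`).
#' @export
expected_tr_count <- function(n_xy, n_yx, n_x, n_y) {
  den <- n_x * n_y
  ifelse(n_xy == 0, 0, ifelse(den > 0, n_xy^2 * n_yx / den, NA_real_))
}

#' Per-bin zero-order expectations for all 16 dinucleotides
#'
#' Applies `E[n_XY] = n_X * n_Y / L_seq` per bin, with `n_X` the bin's own
#' empirical nucleotide counts and `L_seq` its valid (non-N) length. The
#' result has the same shape as a `dinuc_tracks` object, so [track_of()] and
#' [apply_model()] work on it unchanged -- that is how reference property
#' tracks are built.
#'
#' @param dinucs a `dinuc_tracks` object.
#' @return A `dinuc_tracks`-shaped object of expected counts.
#' @export
expected_dinucleotides <- function(dinucs) {
  di <- lapply(names(dinucs$nuc), function(ch) {
    nm <- dinucs$nuc[[ch]]
    L <- rowSums(nm)
    e <- (nm[, rep(1:4, each = 4L), drop = FALSE] *
            nm[, rep(1:4, 4L), drop = FALSE]) / ifelse(L > 0, L, NA_real_)
    colnames(e) <- .DINUCS
    e
  })
  names(di) <- names(dinucs$nuc)
  structure(list(di = di, nuc = dinucs$nuc, valid = dinucs$valid,
                 resolution = dinucs$resolution, lengths = dinucs$lengths,
                 order = 0L),
            class = "dinuc_tracks")
}

#' Per-bin first-order expectations for all 16 tandem-repeat classes
#'
#' Applies `E[n_XY, n>=2] = n_XY^2 * n_YX / (n_X * n_Y)` per bin from the
#' bin's own empirical dinucleotide and nucleotide counts.
#'
#' @param dinucs a `dinuc_tracks` object.
#' @return A `dinuc_tracks`-shaped object whose `di` matrices hold the
#'   expected (XY)2-start counts per bin (columns AA..TT).
#' @export
expected_tandem_repeats <- function(dinucs) {
  X <- rep(1:4, each = 4L); Y <- rep(1:4, 4L)
  rev_idx <- (Y - 1L) * 4L + X
  di <- lapply(names(dinucs$di), function(ch) {
    dm <- dinucs$di[[ch]][, .DINUCS, drop = FALSE]
    nm <- dinucs$nuc[[ch]]
    e <- matrix(NA_real_, nrow(dm), 16L, dimnames = list(NULL, .DINUCS))
    for (k in 1:16) {
      e[, k] <- expected_tr_count(dm[, k], dm[, rev_idx[k]], nm[, X[k]], nm[, Y[k]])
    }
    e
  })
  names(di) <- names(dinucs$di)
  structure(list(di = di, nuc = dinucs$nuc, valid = dinucs$valid,
                 resolution = dinucs$resolution, lengths = dinucs$lengths,
                 order = 1L),
            class = "dinuc_tracks")
}

#' Genomic mean and standard deviation of a track
#'
#' The uniform-distribution reference: valid-fraction-weighted mean and SD of a
#' binned quantity over all valid bins of the genome.
#'
#' @param track a [binned_track()].
#' @return `list(mean, sd, weight, n)`.
#' @export
global_reference <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  v <- track_values(track)
  w <- unlist(track$valid, use.names = FALSE)
  st <- weighted_stats(v, w)
  if (st$n == 0L) stop("no valid bins")
  if (st$n < 2L) stop("need at least 2 valid bins")
  list(mean = st$mean, sd = sqrt(st$var), weight = st$weight, n = st$n)
}
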