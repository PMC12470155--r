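# Anchor-centered environment profiles: distance-indexed weighted mean and
# variance of a binned track around annotation anchors, with annotation
# interiors masked so only the true environment contributes.

#' Per-bin masked fraction from a set of interval lists
#' @keywords internal
masked_fraction <- function(mask_list, lengths, resolution) {
  out <- list()
  for (ch in names(lengths)) {
    L <- lengths[[ch]]
    nb <- ceiling(L / resolution)
    sel <- lapply(mask_list, function(m) {
      m <- m[m$chrom == ch, , drop = FALSE]
      IRanges::IRanges(start = pmax(m$start, 0L) + 1L, end = pmin(m$end, L))
    })
    ir <- IRanges::reduce(do.call(c, c(sel, list(IRanges::IRanges()))))
    ir <- ir[IRanges::width(ir) > 0L]
    cov <- IRanges::coverage(ir, width = L)
    starts <- seq.int(1L, by = resolution, length.out = nb)
    widths <- pmin(resolution, L - starts + 1L)
    covered <- as.numeric(sum(IRanges::Views(
      cov, IRanges::IRanges(start = starts, width = widths))))
    out[[ch]] <- covered / widths
  }
  out
}

#' Shared profiling engine over one or more value tracks with common weights
#'
#' All tracks are aggregated with the same per-bin weights, which makes any
#' linear combination of input tracks profile to the same linear combination
#' of output profiles, exactly -- the property that the influence
#' decomposition relies on.
#'
#' @param values_list list of per-track value lists (each: chrom -> numeric).
#' @param weight named list (chrom -> numeric) of per-bin weights (0 = unused).
#' @param anchors data frame chrom/start/end.
#' @param resolution,half_width bp.
#' @param ref_point "midpoint", "start" or "end".
#' @return list(distance, mean (offsets x tracks), variance, weight, n,
#'   n_anchors_used)
#' @keywords internal
profile_engine <- function(values_list, weight, anchors, resolution, half_width,
                           ref_point = "midpoint") {
  K <- as.integer(half_width %/% resolution)
  noff <- 2L * K + 1L
  nt <- length(values_list)
  SW <- numeric(noff); SW2 <- numeric(noff); N <- numeric(noff)
  SWV <- matrix(0, noff, nt); SWV2 <- matrix(0, noff, nt)
  used <- 0L
  for (ch in unique(anchors$chrom)) {
    if (!(ch %in% names(weight))) next
    w <- weight[[ch]]
    nb <- length(w)
    vm <- vapply(values_list, function(v) v[[ch]], numeric(nb))
    if (is.null(dim(vm))) vm <- matrix(vm, nrow = nb)
    bad <- rowSums(is.na(vm)) > 0L
    w[bad] <- 0
    vm[is.na(vm)] <- 0
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    ref <- switch(ref_point,
                  midpoint = (a$start + a$end) / 2,
                  start = a$start,
                  end = a$end)
    cb <- pmin(pmax(floor(ref / resolution), 0L), nb - 1L) + 1L  # 1-based bin
    used <- used + nrow(a)
    idx <- outer(cb, (-K):K, `+`)
    inb <- idx >= 1L & idx <= nb
    ii <- idx[inb]
    off <- col(idx)[inb]
    wv <- w[ii]
    pos <- wv > 0
    if (!any(pos)) next
    ii <- ii[pos]; off <- off[pos]; wv <- wv[pos]
    addv <- function(x) {  # vector or matrix, grouped by offset
      t <- rowsum(x, off)
      rows <- as.integer(rownames(t))
      if (is.matrix(x)) {
        out <- matrix(0, noff, ncol(x)); out[rows, ] <- t
      } else {
        out <- numeric(noff); out[rows] <- t
      }
      out
    }
    SW <- SW + addv(wv)
    SW2 <- SW2 + addv(wv^2)
    N <- N + addv(rep(1, length(wv)))
    xv <- vm[ii, , drop = FALSE]
    SWV <- SWV + addv(wv * xv)
    SWV2 <- SWV2 + addv(wv * xv^2)
  }
  mean <- sweep(SWV, 1L, ifelse(SW > 0, SW, NA_real_), `/`)
  denom <- SW - ifelse(SW > 0, SW2 / SW, 0)
  variance <- (SWV2 - SWV * mean)
  variance <- sweep(variance, 1L, ifelse(denom > 0, denom, NA_real_), `/`)
  variance[!is.na(variance) & variance < 0] <- 0  # numeric noise on constant tracks
  list(distance = ((-K):K) * resolution, mean = mean, variance = variance,
       weight = SW, n = N, n_anchors_used = used)
}

#' Environment profile of a track around anchors
#'
#' For every anchor, the track is read outward in both directions from the
#' anchor's reference point, at the track's resolution, out to `half_width`.
#' The interiors of the anchors themselves and of any annotation in `mask`
#' are masked: a bin overlapped by masked intervals loses the overlapped
#' fraction of its weight, and bins with masked fraction above
#' `discard_threshold` are discarded entirely (this removes the clustering
#' bias of nearby annotations). Remaining bins are weighted by their unmasked
#' valid fraction. Per distance, a weighted mean and variance (reliability
#' weights) are pooled over all anchors; distances running off a chromosome
#' end contribute nothing.
#'
#' @param track a [binned_track()].
#' @param anchors data frame with chrom, start, end (0-based half-open).
#' @param half_width maximum distance D from the anchor (bp, default 1e6).
#' @param mask data frame or list of data frames of annotation intervals whose
#'   interiors must not contribute.
#' @param mask_anchors also mask the anchor intervals themselves (default TRUE).
#' @param discard_threshold discard bins with masked fraction above this.
#' @param ref_point `"midpoint"` (default), `"start"` or `"end"` of the anchor
#'   interval.
#' @return An `environment_profile`: list with distance (bp), mean, variance,
#'   weight (sum of unmasked fractions), n (contributing anchors per distance),
#'   resolution and anchor count.
#' @export
environment_profile <- function(track, anchors, half_width = 1e6, mask = NULL,
                                mask_anchors = TRUE, discard_threshold = 0.5,
                                ref_point = c("midpoint", "start", "end")) {
  ref_point <- match.arg(ref_point)
  stopifnot(inherits(track, "binned_track"))
  check_intervals(anchors, "anchors")
  if (!(discard_threshold > 0 && discard_threshold < 1)) {
    stop("discard threshold must be in (0, 1)")
  }
  if (half_width %% track$resolution != 0) {
    stop("half_width must be a multiple of the track resolution")
  }
  anchors <- anchors[anchors$chrom %in% names(track$values), , drop = FALSE]
  if (nrow(anchors) == 0L) stop("no usable anchors on the track's chromosomes")
  if (half_width >= max(track$lengths)) {
    warning("half_width exceeds every chromosome; profile is truncated at the ends")
  }
  w <- profile_weights(track, anchors, mask, mask_anchors, discard_threshold)
  eng <- profile_engine(list(track$values), w, anchors, track$resolution,
                        half_width, ref_point)
  structure(list(distance = eng$distance,
                 mean = as.numeric(eng$mean[, 1L]),
                 variance = as.numeric(eng$variance[, 1L]),
                 weight = eng$weight, n = eng$n,
                 resolution = track$resolution,
                 half_width = half_width,
                 n_anchors = eng$n_anchors_used),
            class = "environment_profile")
}

#' Per-bin profile weights: unmasked fraction times valid fraction
#' @keywords internal
profile_weights <- function(track, anchors, mask, mask_anchors, discard_threshold) {
  mask_list <- list()
  if (mask_anchors) mask_list <- c(mask_list, list(anchors))
  if (!is.null(mask)) {
    if (is.data.frame(mask)) mask <- list(mask)
    mask_list <- c(mask_list, mask)
  }
  mf <- if (length(mask_list) > 0L) {
    masked_fraction(mask_list, track$lengths, track$resolution)
  } else {
    lapply(track$values, function(v) numeric(length(v)))
  }
  out <- list()
  for (ch in names(track$values)) {
    wch <- (1 - mf[[ch]]) * track$valid[[ch]]
    wch[mf[[ch]] > discard_threshold] <- 0
    wch[track$valid[[ch]] < 0.5] <- 0
    out[[ch]] <- wch
  }
  out
}

#' @export
print.environment_profile <- function(x, ...) {
  cat("<environment_profile> ", length(x$distance), " distances (+/-",
      x$half_width, " bp at ", x$resolution, " bp), ", x$n_anchors,
      " anchors\n", sep = "")
  invisible(x)
}

#' Export a profile as TSV
#' @param profile an [environment_profile()].
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(distance = profile$distance, mean = profile$mean,
               variance = profile$variance, weight = profile$weight,
               n = profile$n),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
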