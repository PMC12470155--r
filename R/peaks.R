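# Central peak/dip detection in environment profiles: far-distance baseline,
# outward expansion from distance 0 until significance is lost, and peak
# significance relative to a reference (null-model) profile.

#' Far-distance baseline of an environment profile
#'
#' Pools all distances beyond `min_distance` (both sides) into a weighted mean
#' and standard deviation, assuming anchors no longer influence the
#' environment out there. The standard error of the baseline mean is
#' `sd / sqrt(bins pooled)`.
#'
#' @param profile an [environment_profile()].
#' @param min_distance distances with `|d| > min_distance` are pooled
#'   (default 8e5 bp).
#' @return `list(mean, sd, se, min_distance, n_bins)`.
#' @export
estimate_baseline <- function(profile, min_distance = 8e5) {
  stopifnot(inherits(profile, "environment_profile"))
  if (min_distance >= profile$half_width) {
    stop("min_distance must be below the profile half-width")
  }
  far <- abs(profile$distance) > min_distance
  st <- weighted_stats(profile$mean[far], profile$weight[far])
  if (st$n < 10L) stop("too few far-distance bins (", st$n, ") for a baseline")
  list(mean = st$mean, sd = sqrt(st$var), se = sqrt(st$var) / sqrt(st$n),
       min_distance = min_distance, n_bins = st$n)
}

#' Call the central peak or dip of an environment profile
#'
#' The z statistic at distance d is
#' `z(d) = (mean(d) - baseline mean) / sqrt(SE(d)^2 + baseline SE^2)` with
#' `SE(d) = sqrt(variance(d) / weight(d))`. A peak is detected iff
#' `|z(0)| > z_threshold`; the significant span is grown outward from 0,
#' stopping independently left and right at the first bin that is not
#' significant (or, with `gap_tolerance = g`, after more than `g` consecutive
#' non-significant bins). The height is the maximum |deviation| from the
#' baseline over the span; the width bounds are the outermost significant
#' distances.
#'
#' @param profile an [environment_profile()].
#' @param baseline from [estimate_baseline()] (computed on the same profile).
#' @param z_threshold significance threshold (default 2).
#' @param gap_tolerance number of consecutive non-significant bins tolerated
#'   during expansion (default 0: a single one terminates).
#' @return A `peak_call`: list with detected, sign (+1 peak / -1 dip / 0),
#'   height (>= 0), apex_distance, width (c(min, max) distance, bp), z_center,
#'   z_apex, u (profile SE at the apex bin, or at the center if undetected)
#'   and the baseline.
#' @export
call_peak <- function(profile, baseline, z_threshold = 2, gap_tolerance = 0L) {
  stopifnot(inherits(profile, "environment_profile"))
  c0 <- which(profile$distance == 0L)
  se <- sqrt(profile$variance / profile$weight)
  if (is.na(profile$mean[c0]) || is.na(se[c0])) {
    stop("undefined mean or variance at the profile center")
  }
  z <- (profile$mean - baseline$mean) / sqrt(se^2 + baseline$se^2)
  sig <- !is.na(z) & abs(z) > z_threshold
  detected <- sig[c0]
  if (!detected) {
    out <- list(detected = FALSE, sign = 0L, height = 0,
                apex_distance = NA_real_, width = c(NA_real_, NA_real_),
                z_center = z[c0], z_apex = z[c0], u = se[c0],
                baseline = baseline, z_threshold = z_threshold)
    return(structure(out, class = "peak_call"))
  }
  expand <- function(step) {
    last_sig <- c0; i <- c0; gaps <- 0L
    repeat {
      i <- i + step
      if (i < 1L || i > length(z)) break
      if (sig[i]) { last_sig <- i; gaps <- 0L } else {
        gaps <- gaps + 1L
        if (gaps > gap_tolerance) break
      }
    }
    last_sig
  }
  lo <- expand(-1L)
  hi <- expand(+1L)
  span <- lo:hi
  dev <- profile$mean[span] - baseline$mean
  apex <- span[which.max(abs(dev))]
  out <- list(detected = TRUE,
              sign = if (profile$mean[c0] >= baseline$mean) 1L else -1L,
              height = max(abs(dev), na.rm = TRUE),
              apex_distance = profile$distance[apex],
              width = c(profile$distance[lo], profile$distance[hi]),
              z_center = z[c0], z_apex = z[apex], u = se[apex],
              baseline = baseline, z_threshold = z_threshold)
  structure(out, class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  if (!x$detected) {
    cat("<peak_call> no significant central peak (z(0) = ",
        round(x$z_center, 2), ")\n", sep = "")
  } else {
    cat("<peak_call> ", if (x$sign > 0) "peak" else "dip",
        ", height ", signif(x$height, 4),
        " at d = ", x$apex_distance,
        ", width [", x$width[1L], ", ", x$width[2L], "] bp",
        ", z(0) = ", round(x$z_center, 2), "\n", sep = "")
  }
  invisible(x)
}

#' Significance of a peak relative to a reference peak
#'
#' Compares the signed empirical peak height with the signed height of the
#' corresponding peak in a reference (e.g. Markov null-model) profile:
#' `sigma_rel = (h_emp - h_ref) / sqrt(u_emp^2 + u_ref^2)`. An undetected
#' reference peak contributes height 0 with the uncertainty of its center bin.
#' This cancels peaks explained by local nucleotide or G+C content when the
#' reference is the zero-order expectation profile.
#'
#' @param empirical,reference `peak_call` objects from [call_peak()], called on
#'   profiles over the same anchors and track category.
#' @return Signed sigma value.
#' @export
relative_significance <- function(empirical, reference) {
  stopifnot(inherits(empirical, "peak_call"), inherits(reference, "peak_call"))
  h_e <- empirical$sign * empirical$height
  h_r <- reference$sign * reference$height
  (h_e - h_r) / sqrt(empirical$u^2 + reference$u^2)
}
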