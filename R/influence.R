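# Influence decomposition: attribute a property peak to individual
# dinucleotides and to repeat classes via an exact linear decomposition of the
# apex-minus-baseline deviation.

#' Partition dinucleotide counts by repeat class
#'
#' A dinucleotide at positions `(i, i+1)` belongs to a partition iff both
#' bases lie inside one of that partition's intervals; otherwise it counts as
#' "outside". Overlaps between partitions are resolved by precedence: the
#' FIRST partition in the list wins (the conventional order puts transposon
#' families before tandem-repeat classes). Counts are conserved exactly:
#' summing all partitions plus "outside" reproduces [count_dinucleotides()].
#'
#' @param genome named character vector of sequences.
#' @param partitions named list of interval data frames (chrom, start, end),
#'   highest precedence first, e.g.
#'   `list(AluLike = ..., "(CA)n" = ...)`.
#' @param resolution bin width (bp).
#' @return A `partitioned_dinucs` object: `total` (a `dinuc_tracks`), and
#'   `parts` -- a named list (partition, plus `"outside"`) of per-chromosome
#'   `bins x 16` count matrices.
#' @export
partition_dinucleotides <- function(genome, partitions, resolution = 1000L) {
  genome <- as_genome(genome)
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  for (p in partitions) check_intervals(p, "partition")
  total <- count_dinucleotides(genome, resolution)
  np <- length(partitions)
  parts <- lapply(seq_len(np + 1L), function(i) list())
  names(parts) <- c(names(partitions), "outside")
  for (ch in names(genome)) {
    code <- seq_to_code(genome[[ch]])
    L <- length(code)
    nb <- ceiling(L / resolution)
    pid <- integer(L)
    for (p in rev(seq_len(np))) {  # lowest precedence first, higher overwrites
      iv <- partitions[[p]]
      iv <- iv[iv$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        s <- max(iv$start[r], 0L); e <- min(iv$end[r], L)
        if (e > s) pid[(s + 1L):e] <- p
      }
    }
    a <- code[-L]; b <- code[-1L]
    keep <- !is.na(a) & !is.na(b)
    dcode <- (a - 1L) * 4L + b
    dbin <- (seq_len(L - 1L) - 1L) %/% resolution
    dpart <- ifelse(pid[-L] == pid[-1L], pid[-L], 0L)  # straddlers -> outside
    for (p in seq_len(np + 1L)) {
      code_p <- if (p <= np) p else 0L
      sel <- keep & dpart == code_p
      parts[[p]][[ch]] <- matrix(
        tabulate(dbin[sel] * 16L + dcode[sel], nb * 16L),
        nb, 16L, byrow = TRUE, dimnames = list(NULL, .DINUCS))
    }
  }
  structure(list(total = total, parts = parts,
                 resolution = as.integer(resolution),
                 lengths = chrom_lengths(genome)),
            class = "partitioned_dinucs")
}

#' Decompose a property peak into dinucleotide and repeat influences
#'
#' Builds the property profile around the anchors, calls its central peak, and
#' decomposes the apex-minus-baseline deviation linearly:
#' `contribution(XY) = m_XY * (f_XY(apex) - f_XY(baseline))`, where `f_XY` is
#' the per-bin dinucleotide count (`sum` mode) or fraction (`mean` mode)
#' profiled with exactly the same weights as the property track. The signed
#' contributions therefore sum to the signed peak height exactly in both
#' modes; the residual is reported anyway for transparency. With partitioned
#' counts, each repeat class receives
#' `contribution(p) = sum_XY m_XY * (f^p_XY(apex) - f^p_XY(baseline))`, and
#' the partition contributions sum to the dinucleotide totals exactly.
#'
#' Relative influences are reported under two normalisations, column-labelled:
#' `rel_abs_pct` = |contribution| / sum over dinucleotides of |contribution| x
#' 100 (sums to 100 over the dinucleotide partition; repeat classes use the
#' same denominator so both categories share one scale), and `pct_of_peak` =
#' signed contribution / signed height x 100.
#'
#' @param model a [property_model()].
#' @param dinucs a `dinuc_tracks` from [count_dinucleotides()], or a
#'   `partitioned_dinucs` from [partition_dinucleotides()] (required for
#'   repeat influences).
#' @param anchors data frame chrom/start/end.
#' @param half_width,mask,mask_anchors,discard_threshold,ref_point passed to
#'   the profiling engine (see [environment_profile()]).
#' @param baseline_min_distance far-distance threshold for the baseline (bp).
#' @param z_threshold,gap_tolerance passed to [call_peak()].
#' @param mode `"mean"` (default) or `"sum"` property normalisation.
#' @param merge_complements report dinucleotides grouped with their reverse
#'   complements (AA/TT etc.), summing signed contributions.
#' @return An `influence_result`: list with `peak`, `profile` (property
#'   profile), `dinucleotides` and `repeats` data frames, `residual`,
#'   `signed_height`, `mode`. If no peak is detected the tables are empty.
#' @export
influence_decomposition <- function(model, dinucs, anchors, half_width = 1e6,
                                    mask = NULL, mask_anchors = TRUE,
                                    discard_threshold = 0.5,
                                    ref_point = "midpoint",
                                    baseline_min_distance = 8e5,
                                    z_threshold = 2, gap_tolerance = 0L,
                                    mode = c("mean", "sum"),
                                    merge_complements = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "property_model"))
  parts <- NULL
  if (inherits(dinucs, "partitioned_dinucs")) {
    parts <- dinucs$parts
    dinucs <- dinucs$total
  }
  check_intervals(anchors, "anchors")
  m <- model$values[.DINUCS]
  np <- length(parts)

  # assemble value tracks: property, 16 dinucleotide, np x 16 partition tracks
  chroms <- names(dinucs$di)
  nt <- 1L + 16L + np * 16L
  values_list <- lapply(seq_len(nt), function(i) list())
  for (ch in chroms) {
    di <- dinucs$di[[ch]][, .DINUCS, drop = FALSE]
    tot <- rowSums(di)
    bad <- dinucs$valid[[ch]] < 0.5
    den <- if (mode == "mean") ifelse(tot > 0, tot, NA_real_) else 1
    prop <- as.numeric(di %*% m) / den
    prop[bad] <- NA_real_
    values_list[[1L]][[ch]] <- prop
    for (j in 1:16) {
      v <- di[, j] / den
      v[bad] <- NA_real_
      values_list[[1L + j]][[ch]] <- v
    }
    if (np > 0L) {
      for (p in seq_len(np)) {
        dip <- parts[[p]][[ch]]
        for (j in 1:16) {
          v <- dip[, j] / den
          v[bad] <- NA_real_
          values_list[[1L + 16L * p + j]][[ch]] <- v
        }
      }
    }
  }

  proto <- binned_track(values_list[[1L]], dinucs$valid, dinucs$resolution,
                        dinucs$lengths)
  w <- profile_weights(proto, anchors, mask, mask_anchors, discard_threshold)
  eng <- profile_engine(values_list, w, anchors, dinucs$resolution, half_width,
                        ref_point)

  prop_profile <- structure(
    list(distance = eng$distance, mean = as.numeric(eng$mean[, 1L]),
         variance = as.numeric(eng$variance[, 1L]), weight = eng$weight,
         n = eng$n, resolution = dinucs$resolution, half_width = half_width,
         n_anchors = eng$n_anchors_used),
    class = "environment_profile")
  bl <- estimate_baseline(prop_profile, baseline_min_distance)
  peak <- call_peak(prop_profile, bl, z_threshold, gap_tolerance)

  empty <- data.frame(feature = character(0), contribution = numeric(0),
                      rel_abs_pct = numeric(0), pct_of_peak = numeric(0))
  if (!peak$detected) {
    message("no significant central peak; influence tables are empty")
    return(structure(list(peak = peak, profile = prop_profile,
                          dinucleotides = empty, repeats = empty,
                          residual = NA_real_, signed_height = 0, mode = mode),
                     class = "influence_result"))
  }

  # baselines for every track over the same far offsets with the same weights
  far <- abs(eng$distance) > baseline_min_distance & eng$weight > 0
  Wf <- eng$weight[far]
  base <- colSums(eng$mean[far, , drop = FALSE] * Wf) / sum(Wf)
  apex <- which(eng$distance == peak$apex_distance)
  apex_mean <- eng$mean[apex, ]
  delta <- apex_mean - base

  signed_height <- delta[1L]
  contrib <- m * delta[1L + 1:16]
  names(contrib) <- .DINUCS
  denom_abs <- sum(abs(contrib))

  di_tab <- data.frame(feature = .DINUCS, contribution = as.numeric(contrib),
                       stringsAsFactors = FALSE)
  if (merge_complements) {
    grp <- vapply(.DINUCS, function(d) {
      rc <- revcomp(d)
      if (rc == d) d else paste(sort(c(d, rc)), collapse = "/")
    }, character(1L))
    agg <- rowsum(di_tab$contribution, grp)
    di_tab <- data.frame(feature = rownames(agg), contribution = as.numeric(agg),
                         stringsAsFactors = FALSE)
    denom_abs_rep <- denom_abs          # repeat scale stays on the 16-dinuc total
    denom_abs <- sum(abs(di_tab$contribution))
  } else {
    denom_abs_rep <- denom_abs
  }
  di_tab$rel_abs_pct <- 100 * abs(di_tab$contribution) / denom_abs
  di_tab$pct_of_peak <- 100 * di_tab$contribution / signed_height
  di_tab <- di_tab[order(-abs(di_tab$contribution)), ]
  rownames(di_tab) <- NULL

  rep_tab <- empty
  if (np > 0L) {
    rc <- vapply(seq_len(np), function(p) {
      sum(m * delta[1L + 16L * p + 1:16])
    }, numeric(1L))
    rep_tab <- data.frame(feature = names(parts)[seq_len(np)],
                          contribution = rc, stringsAsFactors = FALSE)
    rep_tab$rel_abs_pct <- 100 * abs(rep_tab$contribution) / denom_abs_rep
    rep_tab$pct_of_peak <- 100 * rep_tab$contribution / signed_height
    rep_tab <- rep_tab[order(-abs(rep_tab$contribution)), ]
    rownames(rep_tab) <- NULL
  }

  structure(list(peak = peak, profile = prop_profile,
                 dinucleotides = di_tab, repeats = rep_tab,
                 residual = signed_height - sum(contrib),
                 signed_height = as.numeric(signed_height), mode = mode),
            class = "influence_result")
}

#' @export
print.influence_result <- function(x, ...) {
  cat("<influence_result> mode = ", x$mode, "\n", sep = "")
  print(x$peak)
  if (nrow(x$dinucleotides) > 0L) {
    cat("top dinucleotide influences:\n")
    print(utils::head(x$dinucleotides, 5L), digits = 3)
  }
  if (nrow(x$repeats) > 0L) {
    cat("repeat influences:\n")
    print(x$repeats, digits = 3)
  }
  invisible(x)
}

#' Dinucleotide influences on a property peak
#'
#' Convenience wrapper around [influence_decomposition()] returning the
#' dinucleotide table.
#' @inheritParams influence_decomposition
#' @param ... passed to [influence_decomposition()].
#' @export
dinucleotide_influence <- function(model, dinucs, anchors, ...) {
  influence_decomposition(model, dinucs, anchors, ...)$dinucleotides
}

#' Repeat-class influences on a property peak
#'
#' Convenience wrapper around [influence_decomposition()]; requires
#' partitioned counts. The "outside" partition is included, so partition
#' contributions sum to the total dinucleotide contribution.
#' @inheritParams influence_decomposition
#' @param ... passed to [influence_decomposition()].
#' @export
repeat_influence <- function(model, dinucs, anchors, ...) {
  if (!inherits(dinucs, "partitioned_dinucs")) {
    stop("repeat_influence needs partitioned counts from partition_dinucleotides()")
  }
  influence_decomposition(model, dinucs, anchors, ...)$repeats
}
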