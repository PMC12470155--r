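# Synthetic genomes with known ground truth: background sequence, tandem-repeat
# and transposon-like insertions, and anchor annotations whose flanks carry a
# programmable dinucleotide enrichment profile.

#' Specify a synthetic genome background
#'
#' The background is sampled i.i.d. from `base_freq`, or from a first-order
#' Markov chain if a 4x4 row-stochastic `transition` matrix is given.
#'
#' @param lengths named integer vector of chromosome lengths (bp).
#' @param base_freq numeric(4) nucleotide frequencies (A, C, G, T), summing to 1.
#' @param transition optional 4x4 row-stochastic transition matrix; overrides
#'   `base_freq` for sampling (the stationary distribution becomes the
#'   background nucleotide composition).
#' @param seed integer master seed.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(lengths, base_freq = rep(0.25, 4), transition = NULL, seed = 1L) {
  lengths <- unlist(lengths)
  base_freq <- as.numeric(unlist(base_freq))
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  stopifnot(all(lengths >= 1))
  if (!is.null(transition)) {
    stopifnot(is.matrix(transition), dim(transition) == c(4L, 4L), all(transition >= 0))
    if (any(abs(rowSums(transition) - 1) > 1e-9)) {
      stop("transition matrix rows must sum to 1")
    }
  } else {
    stopifnot(length(base_freq) == 4L)
    if (any(base_freq < 0) || abs(sum(base_freq) - 1) > 1e-9) {
      stop("base_freq must be nonnegative and sum to 1")
    }
  }
  structure(list(lengths = lengths, base_freq = base_freq,
                 transition = transition, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic background genome
#'
#' Deterministic given the spec's seed: the same spec always yields byte-identical
#' sequences. Each chromosome uses its own derived RNG stream, so chromosomes can
#' be regenerated independently.
#'
#' @param spec a [genome_spec()].
#' @return Named character vector of chromosome sequences.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  out <- character(length(spec$lengths))
  names(out) <- names(spec$lengths)
  for (i in seq_along(spec$lengths)) {
    L <- spec$lengths[[i]]
    with_seed(derive_seed(spec$seed, paste0("generate_genome:", i)), {
      code <- if (is.null(spec$transition)) {
        sample.int(4L, L, replace = TRUE, prob = spec$base_freq)
      } else {
        sample_markov(L, spec$transition)
      }
      out[i] <- code_to_seq(code)
    })
  }
  out
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Stationary distribution of a 4-state transition matrix
#' @keywords internal
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Sample a first-order Markov chain over the 4 bases
#' @keywords internal
sample_markov <- function(n, P, init = NULL) {
  cum <- t(apply(P, 1L, cumsum))
  pi0 <- init %||% stationary_distribution(P)
  x <- integer(n)
  u <- stats::runif(n)
  x[1L] <- 1L + findInterval(u[1L], cumsum(pi0)[1:3])
  if (n > 1L) {
    for (i in 2:n) {
      cs <- cum[x[i - 1L], ]
      x[i] <- 1L + (u[i] > cs[1L]) + (u[i] > cs[2L]) + (u[i] > cs[3L])
    }
  }
  x
}

#' Convert a target dinucleotide distribution into a first-order chain
#'
#' Given a 16-vector of target dinucleotide frequencies (row-major AA..TT),
#' returns the transition matrix `P[x, y] = q[x, y] / rowSums(q)[x]`, its exact
#' stationary nucleotide distribution, and the stationary dinucleotide
#' distribution `pi_x * P[x, y]` the sampled sequence will exhibit.
#' @keywords internal
dinuc_chain <- function(q) {
  Q <- matrix(q / sum(q), 4L, 4L, byrow = TRUE,
              dimnames = list(.BASES, .BASES))
  rs <- rowSums(Q)
  if (any(rs == 0)) {  # unreachable state: give it a uniform row, it has mass 0
    Q[rs == 0, ] <- 0.25 * 1e-12
    rs <- rowSums(Q)
  }
  P <- Q / rs
  pi0 <- stationary_distribution(P)
  list(P = P, pi = pi0, dinuc = as.vector(t(pi0 * P)))
}

# ---------------------------------------------------------------------------
# Repeat insertion

#' Synthetic transposon-family consensus sequences
#'
#' Deterministically generated stand-ins with family-typical composition:
#' `AluLike` is G+C- and AG-rich (~300 bp), `L1Like` is A+T-rich (~600 bp).
#' These are synthetic sequences, not biological consensi.
#'
#' @param family `"AluLike"` or `"L1Like"`.
#' @return A DNA string.
#' @export
synthetic_consensus <- function(family = c("AluLike", "L1Like")) {
  family <- match.arg(family)
  if (family == "AluLike") {
    # transitions favouring G/C and AG steps
    P <- matrix(c(0.10, 0.20, 0.55, 0.15,
                  0.20, 0.35, 0.25, 0.20,
                  0.20, 0.30, 0.35, 0.15,
                  0.15, 0.30, 0.40, 0.15), 4L, 4L, byrow = TRUE)
    len <- 300L; key <- 101L
  } else {
    P <- matrix(c(0.45, 0.10, 0.10, 0.35,
                  0.35, 0.15, 0.10, 0.40,
                  0.35, 0.15, 0.15, 0.35,
                  0.40, 0.10, 0.10, 0.40), 4L, 4L, byrow = TRUE)
    len <- 600L; key <- 202L
  }
  with_seed(key, code_to_seq(sample_markov(len, P)))
}

#' Specify a repeat insertion
#'
#' @param unit tandem-repeat unit (1-6 bp) for TR insertions, e.g. `"CA"`.
#' @param consensus consensus sequence for interspersed insertions, or one of
#'   `"AluLike"` / `"L1Like"` for the bundled synthetic consensi.
#' @param copies number of insertions.
#' @param length insertion length in bp: a single number, or `c(min, max)` for
#'   a uniform range. Defaults to 10 units (TR) or the consensus length.
#' @param placement `"uniform"`, or `"flank_biased"` to enrich placements near
#'   anchors (requires `anchors` in [insert_repeats()]).
#' @param bias enrichment factor for flank-biased placement.
#' @param bias_width distance from anchor centers (bp) that counts as "near".
#' @param class optional class label; defaults to the canonical TR class or the
#'   consensus family name.
#' @return A `repeat_spec` object.
#' @export
repeat_spec <- function(unit = NULL, consensus = NULL, copies = 1L, length = NULL,
                        placement = c("uniform", "flank_biased"), bias = 1,
                        bias_width = NULL, class = NULL) {
  placement <- match.arg(placement)
  if (!is.null(length)) length <- as.integer(unlist(length))
  if (is.null(unit) == is.null(consensus)) {
    stop("give exactly one of `unit` or `consensus`")
  }
  if (!is.null(unit)) {
    unit <- toupper(unit)
    if (nchar(unit) < 1L || nchar(unit) > 6L) stop("TR unit length must be 1-6 bp")
    if (is.null(length)) length <- 10L * nchar(unit)
    if (min(length) < 4L || min(length) < 2L * nchar(unit)) {
      stop("inserted TR total length must be >= max(4, 2 * unit length)")
    }
    if (is.null(class)) class <- paste0("(", canonical_rotation(unit), ")n")
  } else {
    if (consensus %in% c("AluLike", "L1Like")) {
      if (is.null(class)) class <- consensus
      consensus <- synthetic_consensus(consensus)
    } else {
      consensus <- toupper(consensus)
      if (is.null(class)) class <- "consensus"
    }
    if (is.null(length)) length <- nchar(consensus)
  }
  stopifnot(copies >= 0, all(length >= 1), bias > 0)
  structure(list(unit = unit, consensus = consensus, copies = as.integer(copies),
                 length = as.integer(length), placement = placement, bias = bias,
                 bias_width = bias_width, class = class),
            class = "repeat_spec")
}

#' Insert repeats into a genome by substitution
#'
#' Insertions overwrite the existing sequence, so chromosome lengths and all
#' other coordinates are unchanged. Placements never overlap each other, nor
#' any interval in `avoid`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param spec a [repeat_spec()].
#' @param seed integer seed for placement and length sampling.
#' @param anchors optional anchor intervals (data frame chrom/start/end) used by
#'   flank-biased placement.
#' @param avoid optional data frame of intervals that must not be overwritten.
#' @return `list(genome, intervals)`: the modified genome and a BED-like truth
#'   data frame (chrom, start, end, class) of every insertion.
#' @export
insert_repeats <- function(genome, spec, seed = 1L, anchors = NULL, avoid = NULL) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "repeat_spec"))
  lens <- chrom_lengths(genome)
  intervals <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), class = character(0))
  if (spec$copies == 0L) return(list(genome = genome, intervals = intervals))
  if (max(spec$length) > max(lens)) stop("insertion longer than every chromosome")
  if (!is.null(avoid)) check_intervals(avoid, "avoid")

  placed <- if (is.null(avoid)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else avoid[, c("chrom", "start", "end")]

  bias_centers <- NULL
  if (spec$placement == "flank_biased") {
    if (is.null(anchors)) stop("flank_biased placement needs `anchors`")
    check_intervals(anchors, "anchors")
    bias_centers <- split((anchors$start + anchors$end) / 2, anchors$chrom)
    bw <- spec$bias_width %||% 10000L
  }

  with_seed(derive_seed(seed, "insert_repeats:1"), {
    rows <- vector("list", spec$copies)
    for (k in seq_len(spec$copies)) {
      len <- if (length(spec$length) == 2L) {
        sample(spec$length[1L]:spec$length[2L], 1L)
      } else spec$length[1L]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        ci <- sample.int(length(genome), 1L, prob = pmax(lens - len + 1, 0))
        chrom <- names(genome)[ci]
        if (lens[ci] < len) next
        pos <- sample.int(lens[ci] - len + 1L, 1L) - 1L  # 0-based start
        if (!is.null(bias_centers)) {
          cc <- bias_centers[[chrom]]
          near <- !is.null(cc) && any(abs(pos + len / 2 - cc) <= bw)
          # rejection sampling: accept non-near placements with prob 1/bias
          if (!near && stats::runif(1L) > 1 / spec$bias) next
        }
        hit <- placed$chrom == chrom & placed$start < pos + len & placed$end > pos
        if (any(hit)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place insertion ", k, " without overlap")
      ins <- if (!is.null(spec$unit)) {
        substr(strrep(spec$unit, ceiling(len / nchar(spec$unit))), 1L, len)
      } else {
        substr(strrep(spec$consensus, ceiling(len / nchar(spec$consensus))), 1L, len)
      }
      substr(genome[[chrom]], pos + 1L, pos + len) <- ins
      placed <- rbind(placed, data.frame(chrom = chrom, start = pos, end = pos + len))
      rows[[k]] <- data.frame(chrom = chrom, start = pos, end = pos + len,
                              class = spec$class)
    }
    intervals <- do.call(rbind, rows)
  })
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  list(genome = genome, intervals = intervals)
}

# ---------------------------------------------------------------------------
# Anchor placement with flank enrichment

#' Specify anchors with dinucleotide-enriched flanks
#'
#' Flanks within `width` of each anchor center are resampled from a first-order
#' Markov chain whose stationary dinucleotide distribution equals the genome
#' background scaled by the enrichment factors; the enrichment decays with
#' distance according to `shape` ("triangular": factor `1 + (f-1)*(1-|d|/width)`;
#' "flat": constant `f` within the support).
#'
#' @param n number of anchors.
#' @param anchor_length anchor interval length (bp), must be >= 1.
#' @param width flank support half-width W (bp).
#' @param enrichment named numeric vector of multiplicative factors for
#'   dinucleotides (e.g. `c(CC = 1.5, GG = 1.5)`).
#' @param nuc_enrichment named numeric factors for single bases (e.g.
#'   `c(G = 1.5, C = 1.5)`); expands to `g_XY = g_X * g_Y`, i.e. an enrichment
#'   that keeps dinucleotides at their zero-order (nucleotide-shuffled)
#'   proportions.
#' @param shape `"triangular"` or `"flat"` decay of the factors over the support.
#' @param step distance discretisation of the enrichment profile and of the
#'   returned truth record (bp).
#' @return An `anchor_spec` object.
#' @export
anchor_spec <- function(n, anchor_length, width, enrichment = NULL,
                        nuc_enrichment = NULL, shape = c("triangular", "flat"),
                        step = 1000L) {
  shape <- match.arg(shape)
  if (!is.null(enrichment)) enrichment <- unlist(enrichment)
  if (!is.null(nuc_enrichment)) nuc_enrichment <- unlist(nuc_enrichment)
  stopifnot(n >= 1, width >= step)
  if (anchor_length < 1) stop("anchor length must be >= 1")
  if (!is.null(enrichment)) {
    stopifnot(!is.null(names(enrichment)), all(names(enrichment) %in% .DINUCS))
    if (any(enrichment <= 0)) stop("enrichment factors must be > 0")
  }
  if (!is.null(nuc_enrichment)) {
    stopifnot(!is.null(names(nuc_enrichment)), all(names(nuc_enrichment) %in% .BASES))
    if (any(nuc_enrichment <= 0)) stop("enrichment factors must be > 0")
  }
  structure(list(n = as.integer(n), anchor_length = as.integer(anchor_length),
                 width = as.integer(width), enrichment = enrichment,
                 nuc_enrichment = nuc_enrichment, shape = shape,
                 step = as.integer(step)),
            class = "anchor_spec")
}

#' Enrichment factors per dinucleotide at a given distance
#' @keywords internal
enrichment_at <- function(spec, d) {
  g <- stats::setNames(rep(1, 16L), .DINUCS)
  decay <- if (spec$shape == "triangular") max(0, 1 - abs(d) / spec$width) else
    as.numeric(abs(d) <= spec$width)
  if (!is.null(spec$enrichment)) {
    g[names(spec$enrichment)] <- 1 + (spec$enrichment - 1) * decay
  }
  if (!is.null(spec$nuc_enrichment)) {
    gn <- stats::setNames(rep(1, 4L), .BASES)
    gn[names(spec$nuc_enrichment)] <- 1 + (spec$nuc_enrichment - 1) * decay
    g <- g * rep(gn, each = 4L) * rep(gn, 4L)  # g_XY = g_X * g_Y, row-major
  }
  g
}

#' Place anchors and resample their flanks with dinucleotide enrichment
#'
#' Anchors (with their full flank support) never overlap each other. The
#' returned truth record holds, per distance bin, the exact stationary
#' dinucleotide distribution of the sampling chain -- the analytic profile that
#' downstream environment profiling is expected to recover.
#'
#' @param genome named character vector of chromosome sequences.
#' @param spec an [anchor_spec()].
#' @param seed integer seed.
#' @return `list(genome, anchors, truth)` where `anchors` is a data frame
#'   (chrom, start, end, name) and `truth` a list with `distance` (bin centers,
#'   bp, signed), `dinuc_freq` (bins x 16 matrix) and `background` (16-vector).
#' @export
place_anchors <- function(genome, spec, seed = 1L) {
  genome <- as_genome(genome)
  stopifnot(inherits(spec, "anchor_spec"))
  lens <- chrom_lengths(genome)
  if (spec$width >= min(lens) / 4) {
    stop("flank support must be < chromosome length / 4")
  }
  half <- spec$width + ceiling(spec$anchor_length / 2)

  # background dinucleotide distribution of the genome as given
  q0 <- rep(0, 16L)
  for (s in genome) {
    code <- seq_to_code(s)
    a <- code[-length(code)]; b <- code[-1L]
    keep <- !is.na(a) & !is.na(b)
    q0 <- q0 + tabulate((a[keep] - 1L) * 4L + b[keep], 16L)
  }
  q0 <- q0 / sum(q0)
  names(q0) <- .DINUCS

  # per-|distance|-bin sampling chains and their stationary dinucleotide truth
  nb <- ceiling(spec$width / spec$step)
  centers <- (seq_len(nb) - 0.5) * spec$step
  chains <- lapply(centers, function(d) dinuc_chain(q0 * enrichment_at(spec, d)))

  anchors <- NULL
  with_seed(derive_seed(seed, "place_anchors:1"), {
    placed <- data.frame(chrom = character(0), lo = numeric(0), hi = numeric(0))
    rows <- vector("list", spec$n)
    for (k in seq_len(spec$n)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        ci <- sample.int(length(genome), 1L, prob = lens)
        chrom <- names(genome)[ci]
        center <- sample.int(lens[ci] - 2L * half, 1L) + half  # 1-based center
        lo <- center - half; hi <- center + half
        same <- placed$chrom == chrom
        if (any(same & placed$lo < hi & placed$hi > lo)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place anchor ", k, " without flank overlap")
      placed <- rbind(placed, data.frame(chrom = chrom, lo = lo, hi = hi))
      rows[[k]] <- data.frame(chrom = chrom, center = center)
    }
    pos <- do.call(rbind, rows)

    # resample each flank window with the position-dependent chain
    cums <- lapply(chains, function(ch) t(apply(ch$P, 1L, cumsum)))
    for (k in seq_len(spec$n)) {
      chrom <- pos$chrom[k]; center <- pos$center[k]
      from <- center - spec$width; to <- center + spec$width - 1L
      npos <- to - from + 1L
      d <- abs((from:to) - center + 0.5)
      binid <- pmin(nb, floor(d / spec$step) + 1L)
      u <- stats::runif(npos)
      x <- integer(npos)
      x[1L] <- 1L + findInterval(u[1L], cumsum(chains[[binid[1L]]]$pi)[1:3])
      for (i in 2:npos) {
        cs <- cums[[binid[i]]][x[i - 1L], ]
        x[i] <- 1L + (u[i] > cs[1L]) + (u[i] > cs[2L]) + (u[i] > cs[3L])
      }
      substr(genome[[chrom]], from, to) <- code_to_seq(x)
    }
    anchors <- data.frame(
      chrom = pos$chrom,
      start = as.integer(pos$center - 1L - floor(spec$anchor_length / 2)),
      end = as.integer(pos$center - 1L - floor(spec$anchor_length / 2) +
                         spec$anchor_length),
      name = paste0("anchor", seq_len(spec$n))
    )
  })
  o <- order(anchors$chrom, anchors$start)
  anchors <- anchors[o, , drop = FALSE]
  rownames(anchors) <- NULL

  freq <- t(vapply(chains, function(ch) ch$dinuc, numeric(16L)))
  colnames(freq) <- .DINUCS
  truth <- list(
    distance = c(-rev(centers), centers),
    dinuc_freq = rbind(freq[rev(seq_len(nb)), , drop = FALSE], freq),
    background = q0,
    width = spec$width, step = spec$step
  )
  list(genome = genome, anchors = anchors, truth = truth)
}

# ---------------------------------------------------------------------------
# I/O

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data frame with chrom, start, end and optionally a name/class column.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  nm <- intervals$name %||% intervals$class %||% rep(".", nrow(intervals))
  utils::write.table(
    data.frame(intervals$chrom, intervals$start, intervals$end, nm),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a machine-readable truth record as JSON
#' @param truth a list (e.g. from [place_anchors()]).
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
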