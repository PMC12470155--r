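# Independent oracles used to cross-check the package's counting, scanning and
# null-model code. These are deliberately naive implementations that share no
# code with the package internals.

BASES <- c("A", "C", "G", "T")
DINUCS <- paste0(rep(BASES, each = 4), BASES)

# position-by-position dinucleotide scanner (character based)
naive_dinuc_counts <- function(seq, resolution) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  nb <- ceiling(L / resolution)
  out <- matrix(0L, nb, 16, dimnames = list(NULL, DINUCS))
  for (i in seq_len(L - 1)) {
    d <- paste0(s[i], s[i + 1])
    if (d %in% DINUCS) {
      b <- (i - 1) %/% resolution + 1
      out[b, d] <- out[b, d] + 1L
    }
  }
  out
}

# brute-force tandem-repeat scanner: tests every (start, unit-length) pair,
# keeps maximal runs with smallest-period units, applies the same
# longest-first/leftmost/shortest-unit greedy with trimming as the contract
# requires. Interval coordinates 0-based half-open.
brute_force_trs <- function(seq, max_unit = 6, min_total = 4) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  min_period <- function(a, b) {
    for (p in seq_len(b - a)) {
      ok <- TRUE
      for (i in a:(b - p)) if (is.na(s[i]) || s[i] != s[i + p] ||
                               s[i] == "N") { ok <- FALSE; break }
      if (ok) return(p)
    }
    b - a + 1
  }
  cand <- list()
  for (u in seq_len(min(max_unit, L - 1))) {
    for (st in seq_len(L)) {
      # extend the period-u run starting at st as far as possible
      en <- st + u - 1
      if (en > L) break
      while (en + 1 <= L && s[en + 1] != "N" && s[en + 1 - u] != "N" &&
             s[en + 1] == s[en + 1 - u]) en <- en + 1
      len <- en - st + 1
      if (len < max(min_total, 2 * u)) next
      if (any(s[st:en] == "N")) next
      if (st > 1 && s[st - 1] != "N" && en - u >= st - 1 &&
          s[st - 1] == s[st - 1 + u]) next  # not leftmost-maximal
      if (min_period(st, en) != u) next
      cand[[length(cand) + 1]] <- c(st, en, u)
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0), unit = character(0))
  if (length(cand) == 0) return(empty)
  cm <- unique(do.call(rbind, cand))
  len <- cm[, 2] - cm[, 1] + 1
  cm <- cm[order(-len, cm[, 1], cm[, 3]), , drop = FALSE]
  covered <- logical(L)
  rows <- list()
  for (i in seq_len(nrow(cm))) {
    idx <- cm[i, 1]:cm[i, 2]
    free <- idx[!covered[idx]]
    if (length(free) == 0) next
    # contiguous free segments
    br <- c(0, which(diff(free) > 1), length(free))
    for (k in seq_len(length(br) - 1)) {
      a <- free[br[k] + 1]; b <- free[br[k + 1]]
      p <- min_period(a, b)
      if ((b - a + 1) < max(min_total, 2 * p)) next
      covered[a:b] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        start = a - 1, end = b, unit = paste(s[a:(a + p - 1)], collapse = ""))
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# independent first-order Markov sequence simulator (integer codes 1..4)
oracle_markov_seq <- function(L, P, start_probs = NULL) {
  if (is.null(start_probs)) {
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    start_probs <- v / sum(v)
  }
  x <- integer(L)
  x[1] <- sample.int(4, 1, prob = start_probs)
  for (i in 2:L) x[i] <- sample.int(4, 1, prob = P[x[i - 1], ])
  x
}

# overlapping start count of (XY)2 = XYXY for every ordered dinucleotide
oracle_quad_starts <- function(x) {
  L <- length(x)
  dc <- (x[-L] - 1) * 4 + x[-1]
  ok <- x[1:(L - 3)] == x[3:(L - 1)] & x[2:(L - 2)] == x[4:L]
  tabulate(dc[1:(L - 3)][ok], 16)
}

# construct an environment_profile object directly from per-distance stats
synthetic_profile <- function(mean, variance = 1, weight = 1,
                              resolution = 1000) {
  n <- length(mean)
  stopifnot(n %% 2 == 1)
  K <- (n - 1) / 2
  structure(list(distance = (-K:K) * resolution,
                 mean = mean,
                 variance = rep_len(variance, n),
                 weight = rep_len(weight, n),
                 n = rep_len(10, n),
                 resolution = resolution,
                 half_width = K * resolution,
                 n_anchors = 10),
            class = "environment_profile")
}

random_seq <- function(L, prob = rep(0.25, 4)) {
  paste(sample(BASES, L, replace = TRUE, prob = prob), collapse = "")
}
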