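# Bootstrap Pearson correlation between two genomic maps, with a
# position-shuffled null and a sigma significance level.

#' Bootstrap correlation between two binned tracks
#'
#' Per repetition, `k` jointly valid bin positions are sampled genome-wide
#' (uniformly, with replacement) and a Pearson coefficient is computed over the
#' two k-vectors; the mean and SD over `reps` repetitions summarise the
#' empirical correlation. The null repeats the identical procedure on copies
#' of the maps whose valid-bin values have been independently position
#' shuffled (alignment destroyed, marginal distributions preserved). The
#' significance is
#' `sigma = (r_mean_emp - r_mean_shuf) / sqrt(sd_emp^2 + sd_shuf^2)`.
#'
#' @param map_a,map_b [binned_track()]s on the same chromosomes and resolution.
#' @param reps repetitions (default 50).
#' @param k positions per repetition (default 50).
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param max_retries resampling attempts when a sampled vector has zero
#'   variance.
#' @return A `correlation_result`: list with r_mean, r_sd, shuffled_mean,
#'   shuffled_sd, sigma, reps, k, n_bins.
#' @export
bootstrap_correlation <- function(map_a, map_b, reps = 50L, k = 50L,
                                  seed = NULL, max_retries = 100L) {
  stopifnot(inherits(map_a, "binned_track"), inherits(map_b, "binned_track"))
  if (!identical(names(map_a$values), names(map_b$values)) ||
      map_a$resolution != map_b$resolution) {
    stop("maps must share chromosome set and resolution")
  }
  stopifnot(reps >= 2L, k >= 3L)
  a <- track_values(map_a)
  b <- track_values(map_b)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < k) stop("fewer than k jointly valid bins")

  run <- function(x, y) {
    r <- numeric(reps)
    for (i in seq_len(reps)) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(length(x), k, replace = TRUE)
        if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
        if (try == max_retries) stop("zero variance in sampled vectors")
      }
      r[i] <- stats::cor(x[idx], y[idx])
    }
    r
  }
  body <- function() {
    r_emp <- run(a, b)
    r_shuf <- run(sample(a), sample(b))
    list(r_emp = r_emp, r_shuf = r_shuf)
  }
  res <- if (is.null(seed)) body() else with_seed(derive_seed(seed, "bootstrap_correlation"), body())
  sigma <- (mean(res$r_emp) - mean(res$r_shuf)) /
    sqrt(stats::var(res$r_emp) + stats::var(res$r_shuf))
  structure(list(r_mean = mean(res$r_emp), r_sd = stats::sd(res$r_emp),
                 shuffled_mean = mean(res$r_shuf),
                 shuffled_sd = stats::sd(res$r_shuf),
                 sigma = sigma, reps = reps, k = k, n_bins = length(a)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> r = ", round(x$r_mean, 3), " +/- ",
      round(x$r_sd, 3), " (shuffled ", round(x$shuffled_mean, 3), " +/- ",
      round(x$shuffled_sd, 3), "), sigma = ", round(x$sigma, 2),
      ", ", x$reps, " x ", x$k, " over ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}
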