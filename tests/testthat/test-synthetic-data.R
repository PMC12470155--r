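test_that("generate_genome matches its spec composition and is deterministic", {
  spec <- genome_spec(c(chr1 = 100000L), seed = 1)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1, g2)
  freqs <- table(factor(strsplit(g1[["chr1"]], "")[[1]], levels = BASES)) / 100000
  expect_true(all(abs(freqs - 0.25) < 0.01))

  # degenerate distribution
  g <- generate_genome(genome_spec(c(chr1 = 1000L), base_freq = c(1, 0, 0, 0)))
  expect_identical(g[["chr1"]], strrep("A", 1000))

  expect_error(genome_spec(c(chr1 = 1000L), base_freq = c(0.5, 0.5, 0.5, -0.5)),
               "sum to 1")
  expect_error(genome_spec(c(chr1 = 1000L),
                           transition = matrix(0.3, 4, 4)), "sum to 1")
})

test_that("markov backgrounds reproduce their stationary composition", {
  P <- matrix(c(.4, .2, .2, .2,
                .2, .4, .2, .2,
                .2, .2, .4, .2,
                .2, .2, .2, .4), 4, 4, byrow = TRUE)
  g <- generate_genome(genome_spec(c(chr1 = 50000L), transition = P, seed = 4))
  freqs <- table(factor(strsplit(g[["chr1"]], "")[[1]], levels = BASES)) / 50000
  expect_true(all(abs(freqs - 0.25) < 0.02))  # stationary is uniform here
})

test_that("insert_repeats overwrites in place and records exact truth", {
  g <- generate_genome(genome_spec(c(chr1 = 20000L), seed = 2))
  sp <- repeat_spec(unit = "CA", copies = 10, length = 20)
  out <- insert_repeats(g, sp, seed = 7)
  expect_identical(chrom_lengths(out$genome), chrom_lengths(g))
  expect_equal(nrow(out$intervals), 10)
  expect_true(all(out$intervals$end - out$intervals$start == 20))
  # truth-recoverability: the recorded intervals contain exactly the TR array
  for (i in seq_len(10)) {
    piece <- substr(out$genome[["chr1"]], out$intervals$start[i] + 1,
                    out$intervals$end[i])
    expect_identical(piece, strrep("CA", 10))
  }
  # no overlap among insertions
  iv <- out$intervals[order(out$intervals$start), ]
  expect_true(all(diff(iv$start) >= 20))

  # zero copies leave the genome untouched
  out0 <- insert_repeats(g, repeat_spec(unit = "CA", copies = 0), seed = 7)
  expect_identical(out0$genome, g)
  expect_equal(nrow(out0$intervals), 0)

  expect_error(insert_repeats(g, repeat_spec(unit = "CA", copies = 1,
                                             length = 50000), seed = 1),
               "longer than every chromosome")
})

test_that("AluLike insertions raise global AG dinucleotide counts", {
  g <- generate_genome(genome_spec(c(chr1 = 60000L), seed = 3))
  count_ag <- function(genome) {
    sum(count_dinucleotides(genome, 1000L)$di$chr1[, "AG"])
  }
  before <- count_ag(g)
  out <- insert_repeats(g, repeat_spec(consensus = "AluLike", copies = 50,
                                       length = 300), seed = 5)
  expect_gt(count_ag(out$genome), before)
})

test_that("place_anchors keeps coordinates stable and honours constraints", {
  g <- generate_genome(genome_spec(c(chr1 = 200000L, chr2 = 200000L), seed = 6))
  sp <- anchor_spec(n = 15, anchor_length = 30, width = 3000,
                    enrichment = c(CC = 1.5, GG = 1.5), step = 500)
  out <- place_anchors(g, sp, seed = 1)
  expect_identical(chrom_lengths(out$genome), chrom_lengths(g))
  expect_equal(nrow(out$anchors), 15)
  # anchors + flank supports never overlap
  for (ch in unique(out$anchors$chrom)) {
    a <- out$anchors[out$anchors$chrom == ch, ]
    ctr <- sort((a$start + a$end) / 2)
    if (length(ctr) > 1) expect_true(all(diff(ctr) >= 2 * 3000))
  }
  # determinism: byte-identical rerun
  out2 <- place_anchors(g, sp, seed = 1)
  expect_identical(out$genome, out2$genome)
  expect_identical(out$anchors, out2$anchors)

  expect_error(anchor_spec(n = 5, anchor_length = 0, width = 2000),
               "anchor length")
  expect_error(anchor_spec(n = 5, anchor_length = 30, width = 2000,
                           enrichment = c(CC = -1)), "> 0")
  expect_error(place_anchors(g, anchor_spec(n = 5, anchor_length = 30,
                                            width = 60000), seed = 1),
               "chromosome length / 4")
})

test_that("flank resampling realises the recorded dinucleotide truth", {
  set.seed(11)
  g <- generate_genome(genome_spec(c(chr1 = 400000L), seed = 11))
  sp <- anchor_spec(n = 30, anchor_length = 30, width = 3000,
                    enrichment = c(CC = 1.5), step = 1000)
  out <- place_anchors(g, sp, seed = 2)
  # measure CC frequency in the innermost distance bin across anchors and
  # compare with the truth record (binomial 3 SE)
  ctr <- floor((out$anchors$start + out$anchors$end) / 2)
  counts <- 0; tot <- 0
  for (k in seq_len(nrow(out$anchors))) {
    win <- substr(out$genome[["chr1"]], ctr[k] - 999, ctr[k] + 1000)
    s <- strsplit(win, "")[[1]]
    d <- paste0(s[-length(s)], s[-1])
    counts <- counts + sum(d == "CC")
    tot <- tot + length(d)
  }
  p_hat <- counts / tot
  idx <- which(out$truth$distance == 500)  # |d| in (0, 1000]
  p_true <- out$truth$dinuc_freq[idx, "CC"]
  se <- sqrt(p_true * (1 - p_true) / tot)
  expect_lt(abs(p_hat - p_true), 3 * se)
  # enrichment got realised at all: clearly above the 1/16 background
  expect_gt(p_hat, 1 / 16 + 3 * se)

  # null enrichment: flanks indistinguishable from background
  sp0 <- anchor_spec(n = 30, anchor_length = 30, width = 3000,
                     enrichment = c(CC = 1), step = 1000)
  out0 <- place_anchors(g, sp0, seed = 3)
  expect_true(all(abs(out0$truth$dinuc_freq - 1 / 16) < 0.005))
})

test_that("derived RNG streams are stable and within integer range", {
  s1 <- derive_seed(123, "op:1")
  expect_identical(s1, derive_seed(123, "op:1"))
  expect_false(s1 == derive_seed(123, "op:2"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("FASTA and BED round-trips preserve the synthetic truth", {
  g <- generate_genome(genome_spec(c(chrA = 5000L, chrB = 3000L), seed = 9))
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  expect_identical(read_genome_fasta(fa), g)

  iv <- data.frame(chrom = "chrA", start = c(10L, 100L), end = c(20L, 150L),
                   class = "x")
  bed <- tempfile(fileext = ".bed")
  write_bed(iv, bed)
  back <- read_annotations(bed, "bed")
  expect_identical(back$x$start, iv$start)
  expect_identical(back$x$end, iv$end)
})
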