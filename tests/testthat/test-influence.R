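# Shared fixture: a synthetic world with CC/GG-enriched anchor flanks, an
# AluLike transposon biased into the flanks and two uniformly placed TRs.
influence_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- generate_genome(genome_spec(c(chr1 = 300000L, chr2 = 300000L), seed = 20))
    pa <- place_anchors(g, anchor_spec(n = 40, anchor_length = 30, width = 3000,
                                       enrichment = c(CC = 1.5, GG = 1.5),
                                       step = 500), seed = 21)
    alu <- insert_repeats(pa$genome,
                          repeat_spec(consensus = "AluLike", copies = 60,
                                      length = c(250, 300),
                                      placement = "flank_biased", bias = 4,
                                      bias_width = 3000),
                          seed = 22, anchors = pa$anchors,
                          avoid = pa$anchors[, c("chrom", "start", "end")])
    ca <- insert_repeats(alu$genome,
                         repeat_spec(unit = "CA", copies = 40, length = 30),
                         seed = 23,
                         avoid = rbind(pa$anchors[, c("chrom", "start", "end")],
                                       alu$intervals[, c("chrom", "start", "end")]))
    parts <- list(
      AluLike = alu$intervals[, c("chrom", "start", "end")],
      `(AC)n` = ca$intervals[, c("chrom", "start", "end")]
    )
    cache <<- list(genome = ca$genome, anchors = pa$anchors, parts = parts)
    cache
  }
})

test_that("dinucleotide partitioning conserves counts exactly", {
  w <- influence_world()
  pd <- partition_dinucleotides(w$genome, w$parts, 100L)
  for (ch in names(pd$total$di)) {
    tot <- Reduce(`+`, lapply(pd$parts, function(p) p[[ch]]))
    expect_identical(unname(tot), unname(pd$total$di[[ch]]), info = ch)
  }
})

test_that("partition assignment follows construction and precedence", {
  # a (CA)10 array: all its internal CA/AC steps belong to the TR partition
  g <- c(chr1 = paste0(strrep("G", 5000), strrep("CA", 10), strrep("G", 4980)))
  iv <- data.frame(chrom = "chr1", start = 5000L, end = 5020L)
  pd <- partition_dinucleotides(g, list(`(AC)n` = iv), 10000L)
  expect_equal(unname(pd$parts[["(AC)n"]]$chr1[1, "CA"]), 10)
  expect_equal(unname(pd$parts[["(AC)n"]]$chr1[1, "AC"]), 9)
  expect_equal(unname(pd$parts$outside$chr1[1, "CA"]), 0)

  # without repeats everything is outside
  pd0 <- partition_dinucleotides(g, list(none = iv[0, ]), 10000L)
  expect_identical(unname(pd0$parts$outside$chr1), unname(pd0$total$di$chr1))

  # precedence: an overlapping transposon interval wins over the TR interval
  pd2 <- partition_dinucleotides(
    g, list(Alu = data.frame(chrom = "chr1", start = 5000L, end = 5010L),
            `(AC)n` = iv), 10000L)
  expect_equal(sum(pd2$parts$Alu$chr1), 9)       # 10 bases -> 9 steps
  expect_equal(sum(pd2$parts[["(AC)n"]]$chr1), 9) # remaining 10 bases
})

test_that("contributions add up exactly to the signed peak height", {
  w <- influence_world()
  pd <- partition_dinucleotides(w$genome, w$parts, 100L)
  roll <- load_model_table()[["Roll (94)"]]
  for (mode in c("sum", "mean")) {
    res <- influence_decomposition(roll, pd, w$anchors, half_width = 6000,
                                   baseline_min_distance = 4000, mode = mode)
    expect_true(res$peak$detected)
    expect_equal(sum(res$dinucleotides$contribution), res$signed_height,
                 tolerance = 1e-9)
    expect_lt(abs(res$residual), 1e-9)
    # repeat partitions (incl. outside) add up to the same total
    expect_equal(sum(res$repeats$contribution), res$signed_height,
                 tolerance = 1e-9)
    # relative influences on the dinucleotide partition sum to 100
    expect_equal(sum(res$dinucleotides$rel_abs_pct), 100, tolerance = 0.1)
    expect_true(all(abs(res$dinucleotides$rel_abs_pct) <= 100))
  }
})

test_that("the decomposition recovers the programmed drivers", {
  w <- influence_world()
  pd <- partition_dinucleotides(w$genome, w$parts, 100L)
  roll <- load_model_table()[["Roll (94)"]]
  res <- influence_decomposition(roll, pd, w$anchors, half_width = 6000,
                                 baseline_min_distance = 4000)
  expect_equal(res$peak$sign, 1L)
  expect_setequal(res$dinucleotides$feature[1:2], c("CC", "GG"))
  # the flank-biased AluLike family outranks the uniformly placed TR
  rep_tab <- res$repeats
  expect_gt(rep_tab$contribution[rep_tab$feature == "AluLike"],
            abs(rep_tab$contribution[rep_tab$feature == "(AC)n"]))
})

test_that("complement grouping commutes with normalisation", {
  w <- influence_world()
  pd <- partition_dinucleotides(w$genome, w$parts, 100L)
  roll <- load_model_table()[["Roll (94)"]]
  plain <- influence_decomposition(roll, pd, w$anchors, half_width = 6000,
                                   baseline_min_distance = 4000)
  merged <- influence_decomposition(roll, pd, w$anchors, half_width = 6000,
                                    baseline_min_distance = 4000,
                                    merge_complements = TRUE)
  tab <- plain$dinucleotides
  cc_gg <- sum(tab$contribution[tab$feature %in% c("CC", "GG")])
  m <- merged$dinucleotides
  expect_equal(m$contribution[m$feature == "CC/GG"], cc_gg, tolerance = 1e-12)
  expect_equal(sum(m$contribution), sum(tab$contribution), tolerance = 1e-12)
  expect_equal(sum(m$rel_abs_pct), 100, tolerance = 0.1)
})

test_that("single-driver models attribute everything to their dinucleotide", {
  # model sensitive to AA only; anchors enriched in AA
  g <- generate_genome(genome_spec(c(chr1 = 300000L), seed = 24))
  pa <- place_anchors(g, anchor_spec(n = 20, anchor_length = 30, width = 2000,
                                     enrichment = c(AA = 1.8), step = 500),
                      seed = 25)
  dt <- count_dinucleotides(pa$genome, 100L)
  m_aa <- property_model(99, "AAonly", setNames(c(1, rep(0, 15)), DINUCS))
  res <- influence_decomposition(m_aa, dt, pa$anchors, half_width = 5000,
                                 baseline_min_distance = 3000, mode = "sum")
  expect_true(res$peak$detected)
  tab <- res$dinucleotides
  expect_equal(tab$feature[1], "AA")
  expect_equal(tab$rel_abs_pct[1], 100)
  expect_equal(sum(abs(tab$contribution[tab$feature != "AA"])), 0)
})

test_that("an undetected peak yields empty tables with a notice", {
  g <- generate_genome(genome_spec(c(chr1 = 300000L), seed = 26))
  anchors <- data.frame(chrom = "chr1",
                        start = seq(20000L, 280000L, by = 20000L),
                        end = seq(20000L, 280000L, by = 20000L) + 30L)
  dt <- count_dinucleotides(g, 100L)
  roll <- load_model_table()[["Roll (94)"]]
  expect_message(
    res <- influence_decomposition(roll, dt, anchors, half_width = 5000,
                                   baseline_min_distance = 3000),
    "no significant central peak")
  expect_equal(nrow(res$dinucleotides), 0)
  expect_false(res$peak$detected)
})

test_that("repeat_influence requires partitioned counts", {
  g <- generate_genome(genome_spec(c(chr1 = 50000L), seed = 27))
  dt <- count_dinucleotides(g, 100L)
  expect_error(repeat_influence(load_model_table()[["Roll (94)"]], dt,
                                data.frame(chrom = "chr1", start = 1000L,
                                           end = 1030L)),
               "partition")
})
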