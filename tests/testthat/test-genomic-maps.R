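test_that("dinucleotide counting matches direct enumeration", {
  dt <- suppressWarnings(count_dinucleotides(c(chr1 = "ACACAC"), 1000L))
  expect_equal(unname(dt$di$chr1[1, "AC"]), 3)
  expect_equal(unname(dt$di$chr1[1, "CA"]), 2)
  expect_equal(sum(dt$di$chr1), 5)

  dt <- suppressWarnings(count_dinucleotides(c(chr1 = "AAAA"), 1000L))
  expect_equal(unname(dt$di$chr1[1, "AA"]), 3)

  set.seed(7)
  s <- random_seq(1000)
  dt <- suppressWarnings(count_dinucleotides(c(chr1 = s), 1000L))
  expect_equal(sum(dt$di$chr1), 999)
})

test_that("counting agrees exactly with the naive scanner on random sequences", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_seq(200)
    dt <- suppressWarnings(count_dinucleotides(c(chr1 = s), 50L))
    expect_identical(unname(dt$di$chr1), unname(naive_dinuc_counts(s, 50)),
                     info = paste("sequence", i))
  }
})

test_that("bin-bridging dinucleotides go to the left bin", {
  set.seed(1)
  s <- random_seq(3000)
  dt <- count_dinucleotides(c(chr1 = s), 100L)
  # every interior bin carries exactly `resolution` dinucleotides
  expect_true(all(rowSums(dt$di$chr1)[1:29] == 100))
  expect_equal(sum(dt$di$chr1[30, ]), 99)
  # and the bridging dinucleotide is the one the naive scanner assigns
  expect_identical(unname(dt$di$chr1), unname(naive_dinuc_counts(s, 100)))
})

test_that("N handling breaks dinucleotides and flags gap bins", {
  s <- paste0(strrep("A", 40), strrep("N", 70), strrep("C", 90))
  dt <- suppressWarnings(count_dinucleotides(c(chr1 = s), 100L))
  expect_equal(unname(dt$di$chr1[1, "AA"]), 39)
  expect_equal(unname(dt$di$chr1[1, "AC"]), 0)     # broken by the N run
  expect_equal(dt$valid$chr1, c(0.4, 0.9))
  tr <- track_of(dt, "AA")
  expect_true(is.na(tr$values$chr1[1]))    # valid fraction < 0.5 -> invalid
  expect_false(is.na(tr$values$chr1[2]))

  expect_error(count_dinucleotides(c(chr1 = "ACGX")), "position 4")
})

test_that("coverage_track uses flattened-union base coverage", {
  lens <- c(chr1 = 3000L)
  one <- data.frame(chrom = "chr1", start = 100L, end = 300L)
  tr <- coverage_track(one, lens, 1000L)
  expect_equal(tr$values$chr1, c(200, 0, 0))

  dup <- rbind(one, one)
  expect_equal(coverage_track(dup, lens, 1000L)$values$chr1, c(200, 0, 0))

  split_iv <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  expect_equal(coverage_track(split_iv, lens, 1000L)$values$chr1, c(100, 100, 0))

  expect_error(coverage_track(data.frame(chrom = "chr1", start = 10L, end = 5L),
                              lens, 1000L), "negative-length")
})

test_that("coverage conservation holds exactly for random interval sets", {
  set.seed(5)
  lens <- c(chr1 = 10000L)
  for (i in 1:20) {
    st <- sample.int(9000, 30)
    iv <- data.frame(chrom = "chr1", start = st,
                     end = st + sample.int(500, 30))
    iv$end <- pmin(iv$end, 10000L)
    tr <- coverage_track(iv, lens, 700L)
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end))
    expect_equal(sum(tr$values$chr1), sum(IRanges::width(ir)))
  }
})

test_that("mask_gaps invalidates gap-rich bins only", {
  s <- paste0(strrep("N", 1000), strrep("A", 400), strrep("N", 600),
              strrep("G", 1000))
  dt <- suppressWarnings(count_dinucleotides(c(chr1 = s), 1000L))
  tr <- binned_track(lapply(dt$valid, function(v) as.numeric(seq_along(v))),
                     dt$valid, 1000L, dt$lengths)
  m <- mask_gaps(tr)
  expect_true(is.na(m$values$chr1[1]))   # all N
  expect_true(is.na(m$values$chr1[2]))   # 40% valid < 0.5
  expect_false(is.na(m$values$chr1[3]))
  m6 <- mask_gaps(tr, threshold = 0.3)
  expect_false(is.na(m6$values$chr1[2])) # 40% valid retained at 0.3
})

test_that("annotation dialects normalise to 0-based half-open", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tTADborder", bed)
  ann <- read_annotations(bed, "bed")
  expect_equal(ann$TADborder$start, 999)
  expect_equal(ann$TADborder$end, 2000)

  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "test", "enhancer", "1000", "2000", ".", "+", ".",
                   'gene_id "g1";', sep = "\t"), gtf)
  ann <- read_annotations(gtf, "gtf")
  expect_equal(ann$enhancer$start, 999)
  expect_equal(ann$enhancer$end, 2000)

  rmo <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    "  463  1.3  0.6  1.7  chr1        1001     1300    (0)    +  AluYa5         SINE/Alu                 1  300    (0)     1",
    "  220 11.4  0.0  0.0  chr1        5001     5500  (100)    C  L1MA4          LINE/L1                300    1    (0)     2"),
    rmo)
  ann <- read_annotations(rmo, "repeatmasker_out")
  expect_named(ann, c("Alu", "L1"))
  expect_equal(ann$Alu$start, 1000)
  expect_equal(ann$Alu$end, 1300)
  expect_equal(ann$L1$strand, "-")

  bad <- tempfile(fileext = ".out")
  writeLines(c("h", "h", "h", "only three fields here"), bad)
  expect_error(read_annotations(bad, "repeatmasker_out"), "line 4")
  expect_error(read_annotations(bed, "vcf"), "arg")
})

test_that("GenBank gene features are extracted with converted coordinates", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       chrT                 9000 bp    DNA     linear   CON 01-JAN-2020",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..9000",
    "     gene            1000..2000",
    '                     /gene="gA"',
    "     gene            complement(3000..4000)",
    '                     /gene="gB"',
    "     mRNA            1000..2000",
    "ORIGIN",
    "//"), gb)
  ann <- read_annotations(gb, "genbank")
  expect_named(ann, "gene")
  expect_equal(ann$gene$start, c(999, 2999))
  expect_equal(ann$gene$end, c(2000, 4000))
  expect_equal(ann$gene$strand, c("+", "-"))
})

test_that("bedGraph export round-trips values for valid bins", {
  set.seed(3)
  s <- random_seq(5000)
  dt <- count_dinucleotides(c(chr1 = s), 500L)
  tr <- track_of(dt, "AC")
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, bg)
  back <- utils::read.table(bg)
  expect_equal(nrow(back), 10)
  expect_equal(back$V4, tr$values$chr1)
  expect_equal(back$V2, seq(0, 4500, by = 500))
})
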