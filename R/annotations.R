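# Interval annotation import. All coordinates are normalised to 0-based
# half-open, whatever the source dialect uses.

#' Read interval annotations
#'
#' Supported dialects and their category sources:
#' * `bed` (0-based half-open, native): category from the name column when
#'   present, else the `category` argument.
#' * `gtf` (1-based inclusive): category from the feature-type column
#'   (e.g. Ensembl regulatory build types such as `enhancer`,
#'   `CTCF_binding_site`).
#' * `genbank` (1-based inclusive): features of the keys in `features`
#'   (default `"gene"`) from a GenBank flat file.
#' * `repeatmasker_out` (1-based inclusive): RepeatMasker annotation files;
#'   category is the repeat family derived from the class/family column
#'   (`SINE/Alu` -> `Alu`, `LINE/L1` -> `L1`, otherwise the class string).
#'
#' @param path annotation file.
#' @param dialect one of `"bed"`, `"gtf"`, `"genbank"`, `"repeatmasker_out"`.
#' @param category fallback category label for dialects without one.
#' @param features GenBank feature keys to extract.
#' @return An annotation set: named list of data frames (chrom, start, end,
#'   strand), one per category.
#' @export
read_annotations <- function(path, dialect = c("bed", "gtf", "genbank",
                                               "repeatmasker_out"),
                             category = NULL, features = "gene") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dialect <- match.arg(dialect)
  df <- switch(dialect,
               bed = read_bed_file(path, category),
               gtf = read_gtf_file(path),
               genbank = read_genbank_features(path, features),
               repeatmasker_out = read_repeatmasker_out(path))
  split(df[, c("chrom", "start", "end", "strand")], df$category)
}

#' @keywords internal
read_bed_file <- function(path, category = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  name <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name) else
    rep(category %||% "region", length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = name, stringsAsFactors = FALSE)
}

#' @keywords internal
read_gtf_file <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = as.character(gr$type), stringsAsFactors = FALSE)
}

#' Minimal GenBank flat-file feature parser
#'
#' Extracts features with simple `start..end` or `complement(start..end)`
#' locations from the FEATURES table. `join(...)` locations are reduced to
#' their outer span. Coordinates are converted from 1-based inclusive to
#' 0-based half-open.
#' @keywords internal
read_genbank_features <- function(path, features = "gene") {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  recs <- c(locus, length(lines) + 1L)
  rows <- list()
  for (ri in seq_along(locus)) {
    block <- lines[recs[ri]:(recs[ri + 1L] - 1L)]
    chrom <- strsplit(trimws(sub("^LOCUS", "", block[1L])), "\\s+")[[1L]][1L]
    fstart <- grep("^FEATURES", block)
    if (length(fstart) == 0L) next
    fend <- grep("^(ORIGIN|CONTIG|//)", block)
    fend <- if (length(fend) > 0L) min(fend[fend > fstart]) - 1L else length(block)
    fb <- block[(fstart + 1L):fend]
    keys <- grepl("^ {5}\\S", fb)
    for (i in which(keys)) {
      key <- strsplit(trimws(fb[i]), "\\s+")[[1L]]
      if (length(key) < 2L || !(key[1L] %in% features)) next
      loc <- key[2L]
      j <- i + 1L  # location may continue on following lines
      while (j <= length(fb) && !keys[j] && !grepl("/", fb[j], fixed = TRUE)) {
        loc <- paste0(loc, trimws(fb[j])); j <- j + 1L
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
      if (length(nums) < 2L) {
        stop("cannot parse location '", loc, "' in ", path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = min(nums) - 1L, end = max(nums),
        strand = strand, category = key[1L], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      category = character(0)))
  }
  do.call(rbind, rows)
}

#' RepeatMasker .out parser (3 header lines, whitespace-delimited)
#' @keywords internal
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^\\s*SW", lines[1L])) {
    lines <- lines[-(1:min(3L, length(lines)))]
  }
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 11L) {
      stop("malformed RepeatMasker line ", i + 3L, " in ", path)
    }
    s <- suppressWarnings(as.integer(f[6L])); e <- suppressWarnings(as.integer(f[7L]))
    if (is.na(s) || is.na(e)) {
      stop("malformed RepeatMasker coordinates on line ", i + 3L, " in ", path)
    }
    fam <- f[11L]
    category <- if (grepl("Alu", fam)) "Alu" else if (grepl("L1", fam)) "L1" else fam
    data.frame(chrom = f[5L], start = s - 1L, end = e,
               strand = if (f[9L] %in% c("C", "-")) "-" else "+",
               category = category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
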