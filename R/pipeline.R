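# End-to-end orchestration: synthetic genome (or FASTA input) -> maps ->
# property tracks -> null references -> environment profiles -> peaks ->
# correlations -> influence tables, from a single config with one master seed.

#' Default pipeline configuration
#'
#' A small two-chromosome synthetic design with CC/GG-enriched anchor flanks,
#' one AluLike-biased transposon family and two TR insertions; all values can
#' be overridden via [run_pipeline()]'s config.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    resolution = 100L,
    outdir = NULL,
    mode = "mean",
    genome = list(lengths = c(chr1 = 300000L, chr2 = 300000L),
                  base_freq = rep(0.25, 4L)),
    anchors = list(n = 40L, anchor_length = 30L, width = 3000L,
                   enrichment = c(CC = 1.5, GG = 1.5), shape = "triangular",
                   step = 500L),
    repeats = list(
      list(consensus = "AluLike", copies = 60L, length = c(250L, 300L),
           placement = "flank_biased", bias = 4, bias_width = 3000L),
      list(unit = "CA", copies = 40L, length = c(20L, 40L)),
      list(unit = "A", copies = 40L, length = c(10L, 30L))
    ),
    models = c("Roll (94)", "Twist (1)"),
    profile = list(half_width = 6000L, discard_threshold = 0.5),
    peaks = list(baseline_min_distance = 4000L, z_threshold = 2),
    correlation = list(reps = 50L, k = 50L)
  )
}

#' Run the full analysis pipeline
#'
#' Stages: (1) build or load the genome; (2) count nucleotides/dinucleotides
#' and detect tandem repeats; (3) apply the selected property models,
#' empirically and to the zero-order reference expectations; (4) profile each
#' property around the anchors with interior masking; (5) estimate baselines
#' and call central peaks, with significance relative to the reference
#' profile; (6) bootstrap-correlate property maps with the anchor coverage
#' map; (7) decompose each detected peak into dinucleotide and repeat-class
#' influences. Deterministic given the master seed. If `outdir` is set, all
#' tables are written as TSV plus a JSON run manifest.
#'
#' @param config named list (see [default_config()]) or path to a YAML file
#'   with the same structure; partial configs are merged over the defaults.
#' @return A result bundle: list with genome, truth, anchors, repeats, tracks,
#'   profiles, peak table, correlation table, influence results and manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  # structured blocks are replaced wholesale, not merged element-wise
  for (block in c("repeats", "models", "anchors")) {
    if (!is.null(config[[block]])) cfg[[block]] <- config[[block]]
  }
  res <- as.integer(cfg$resolution)

  # --- stage 1: genome -------------------------------------------------------
  if (!is.null(cfg$fasta)) {
    if (!file.exists(cfg$fasta)) stop("FASTA not found: ", cfg$fasta)
    genome <- read_genome_fasta(cfg$fasta)
    truth <- NULL
    if (is.null(cfg$anchor_bed)) stop("FASTA input needs `anchor_bed`")
    anchors <- do.call(rbind, unname(read_annotations(cfg$anchor_bed, "bed",
                                                      category = "anchor")))
    repeat_truth <- NULL
  } else {
    gs <- do.call(genome_spec, c(cfg$genome, list(seed = cfg$seed)))
    genome <- generate_genome(gs)
    asp <- do.call(anchor_spec, cfg$anchors)
    pa <- place_anchors(genome, asp, seed = derive_seed(cfg$seed, "anchors"))
    genome <- pa$genome
    anchors <- pa$anchors
    truth <- pa$truth
    repeat_truth <- NULL
    if (length(cfg$repeats) > 0L) {
      ivs <- list()
      for (i in seq_along(cfg$repeats)) {
        rs <- do.call(repeat_spec, cfg$repeats[[i]])
        ir <- insert_repeats(genome, rs, seed = derive_seed(cfg$seed, paste0("repeats:", i)),
                             anchors = anchors,
                             avoid = rbind(do.call(rbind, ivs),
                                           anchors[, c("chrom", "start", "end")]))
        genome <- ir$genome
        ivs[[i]] <- ir$intervals[, c("chrom", "start", "end")]
        repeat_truth <- rbind(repeat_truth, ir$intervals)
      }
    }
  }
  lens <- chrom_lengths(genome)
  if (any(lens < 10L * res)) {
    warning("chromosome shorter than 10 bins at resolution ", res)
  }

  # --- stage 2: maps ---------------------------------------------------------
  dinucs <- count_dinucleotides(genome, res)
  trs <- find_tandem_repeats(genome)
  anchor_cov <- coverage_track(anchors, lens, res)

  # --- stage 3: property tracks (empirical + zero-order reference) -----------
  models <- load_model_table(cfg$model_table)
  sel <- unlist(cfg$models %||% names(models))
  missing_models <- setdiff(sel, names(models))
  if (length(missing_models) > 0L) {
    stop("unknown model(s): ", paste(missing_models, collapse = ", "))
  }
  models <- models[sel]
  expect0 <- expected_dinucleotides(dinucs)
  tracks <- lapply(models, apply_model, dinucs = dinucs, mode = cfg$mode)
  ref_tracks <- lapply(models, apply_model, dinucs = expect0, mode = cfg$mode)

  # --- stages 4-5: profiles and peaks ---------------------------------------
  hw <- cfg$profile$half_width
  peak_rows <- list()
  profiles <- list()
  for (nm in names(models)) {
    prof <- environment_profile(tracks[[nm]], anchors, half_width = hw,
                                discard_threshold = cfg$profile$discard_threshold)
    ref_prof <- environment_profile(ref_tracks[[nm]], anchors, half_width = hw,
                                    discard_threshold = cfg$profile$discard_threshold)
    bl <- estimate_baseline(prof, cfg$peaks$baseline_min_distance)
    ref_bl <- estimate_baseline(ref_prof, cfg$peaks$baseline_min_distance)
    pk <- call_peak(prof, bl, cfg$peaks$z_threshold)
    ref_pk <- call_peak(ref_prof, ref_bl, cfg$peaks$z_threshold)
    profiles[[nm]] <- list(empirical = prof, reference = ref_prof)
    peak_rows[[nm]] <- data.frame(
      model = nm, detected = pk$detected, sign = pk$sign, height = pk$height,
      width_lo = pk$width[1L], width_hi = pk$width[2L],
      z_center = pk$z_center, sigma_rel = relative_significance(pk, ref_pk))
  }
  peak_table <- do.call(rbind, peak_rows)
  rownames(peak_table) <- NULL

  # --- stage 6: correlations -------------------------------------------------
  corr_rows <- lapply(names(models), function(nm) {
    cr <- bootstrap_correlation(tracks[[nm]], anchor_cov,
                                reps = cfg$correlation$reps,
                                k = cfg$correlation$k,
                                seed = derive_seed(cfg$seed, paste0("corr:", nm)))
    data.frame(model = nm, map = "anchor coverage", r_mean = cr$r_mean,
               r_sd = cr$r_sd, sigma = cr$sigma)
  })
  correlation_table <- do.call(rbind, corr_rows)

  # --- stage 7: influence decomposition --------------------------------------
  # representative selection: the most abundant TR classes by base coverage
  n_classes <- cfg$influence$n_tr_classes %||% 12L
  cov_by_class <- sort(tapply(trs$end - trs$start, trs$class, sum), decreasing = TRUE)
  keep <- names(cov_by_class)[seq_len(min(n_classes, length(cov_by_class)))]
  part_list <- split(trs[, c("chrom", "start", "end")], trs$class)[keep]
  if (!is.null(repeat_truth)) {
    fam <- split(repeat_truth[, c("chrom", "start", "end")], repeat_truth$class)
    tr_only <- setdiff(names(part_list), names(fam))
    part_list <- c(fam, part_list[tr_only])  # transposons take precedence
  }
  partitioned <- partition_dinucleotides(genome, part_list, res)
  influences <- lapply(models, function(mod) {
    influence_decomposition(mod, partitioned, anchors, half_width = hw,
                            discard_threshold = cfg$profile$discard_threshold,
                            baseline_min_distance = cfg$peaks$baseline_min_distance,
                            z_threshold = cfg$peaks$z_threshold,
                            mode = cfg$mode)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dinuscape")),
    seed = cfg$seed, resolution = res,
    chromosomes = as.list(lens),
    n_anchors = nrow(anchors), n_tandem_repeats = nrow(trs),
    models = names(models), mode = cfg$mode,
    parameters = cfg[c("profile", "peaks", "correlation")])

  bundle <- list(genome = genome, anchors = anchors, truth = truth,
                 repeat_truth = repeat_truth, tandem_repeats = trs,
                 dinucs = dinucs, tracks = tracks, ref_tracks = ref_tracks,
                 anchor_coverage = anchor_cov, profiles = profiles,
                 peak_table = peak_table,
                 correlation_table = correlation_table,
                 influences = influences, manifest = manifest)

  if (!is.null(cfg$outdir)) write_bundle(bundle, cfg$outdir)
  bundle
}

#' Write pipeline outputs as diffable TSV/JSON
#' @keywords internal
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(bundle$peak_table, "peaks.tsv")
  w(bundle$correlation_table, "correlations.tsv")
  w(bundle$tandem_repeats, "tandem_repeats.tsv")
  write_bed(bundle$anchors, file.path(outdir, "anchors.bed"))
  for (nm in names(bundle$influences)) {
    inf <- bundle$influences[[nm]]
    tag <- gsub("[^A-Za-z0-9]+", "_", nm)
    w(inf$dinucleotides, paste0("influence_dinucleotides_", tag, ".tsv"))
    if (nrow(inf$repeats) > 0L) {
      w(inf$repeats, paste0("influence_repeats_", tag, ".tsv"))
    }
    write_profile_tsv(inf$profile, file.path(outdir, paste0("profile_", tag, ".tsv")))
  }
  for (nm in names(bundle$tracks)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_bedgraph(bundle$tracks[[nm]], file.path(outdir, paste0("track_", tag, ".bedgraph")))
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
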