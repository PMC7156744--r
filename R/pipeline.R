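#' Default pipeline configuration
#'
#' A single flat configuration with explicit seeds for every stochastic
#' stage and the analysis thresholds used throughout the package: log2
#' enrichment threshold 2 (4-fold), motif p-value cutoff 0.00077, summit
#' window +/-50 bp. The default problem size (1 Mb genome, 50 planted
#' sites, two replicates) is a desk-scale emulation of a full bacterial
#' ChIP experiment; the null size defaults to 1e5 samples and can be raised
#' to the full 1e6 used for final calibration.
#'
#' @param ... Named overrides of any default field.
#' @return A named list of class `nap_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome_fasta = NULL,          # path; NULL -> synthetic genome
    genome_length = 1e6,
    gc = 0.69,
    motif_meme = NULL,            # path; NULL -> example direct repeat
    n_sites = 50,
    min_spacing = 500,
    mean_depth = 30,
    enrichment_at_sites = 8,
    fragment_len_range = c(200, 400),
    read_len = 150,
    intergenic_fraction = 0.10,
    mean_gene_len = 1000,
    threshold_log2 = 2,
    min_width = 20,
    merge_gap = 30,
    pvalue = 0.00077,
    null_n = 1e5,
    window = 50,
    top_n = 100,
    epsilon = 0.01,
    seed_genome = 101, seed_sites = 102, seed_chip_rep1 = 103,
    seed_chip_rep2 = 104, seed_annotation = 105, seed_null = 106,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("nap_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a flat YAML file of [pipeline_config()] fields.
#' @return An `nap_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full simulate/enrich/scan/annotate pipeline
#'
#' Orchestrates the stages end to end: obtain a genome (file or synthetic),
#' obtain a motif (MEME file or the synthetic direct repeat), plant sites,
#' simulate two replicate IP/input coverage pairs, compute log2 enrichment
#' per replicate, call peaks on replicate 1, calibrate the Monte-Carlo
#' score null, scan both strands at the score threshold attaining the
#' configured p-value, and summarize motif association and genic/intergenic
#' location. All intermediate artifacts are written to `out_dir` and listed
#' in a checksum manifest; the run is deterministic given the seeds.
#'
#' @param config An `nap_config`, a YAML path, or named overrides via
#'   [pipeline_config()].
#' @param out_dir Output directory (overrides `config$out_dir`); created if
#'   missing.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `report` (an `nap_peak_report`), `peaks`,
#'   `hits`, `replicate_r2`, `truth_sites`, `score_threshold` and
#'   `manifest` (tibble of emitted files with md5 checksums).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "nap_config"))
  out_dir <- out_dir %||% config$out_dir %||%
    abort("out_dir must be given (argument or config field)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[napscan] ", ...)

  say("parameters: log2 threshold = ", config$threshold_log2,
      ", p-value = ", config$pvalue, ", summit window = +/-", config$window,
      " bp, null n = ", format(config$null_n), ", GC = ", config$gc)

  # --- genome ---------------------------------------------------------
  genome <- if (!is.null(config$genome_fasta)) {
    say("reading genome from ", config$genome_fasta)
    read_fasta(config$genome_fasta)[1, ]
  } else {
    say("generating ", format(config$genome_length), " bp genome at GC ",
        config$gc)
    generate_genome(config$genome_length, gc = config$gc,
                    seed = config$seed_genome)
  }

  # --- motif ----------------------------------------------------------
  motif <- if (!is.null(config$motif_meme)) {
    say("reading motif from ", config$motif_meme)
    read_meme(config$motif_meme)
  } else {
    example_direct_repeat_motif(gc = config$gc)
  }
  write_meme(motif, file.path(out_dir, "motif.meme"))

  # --- planted sites + coverage --------------------------------------
  planted <- plant_sites(genome, motif, n_sites = config$n_sites,
                         min_spacing = config$min_spacing,
                         seed = config$seed_sites)
  genome <- planted$genome
  say("planted ", nrow(planted$sites), " sites")
  write_fasta(genome, file.path(out_dir, "genome.fasta"))
  write_sites_bed(planted$sites, file.path(out_dir, "truth_sites.bed"),
                  seq_id = genome$id, width = motif$width)

  reps <- lapply(c(config$seed_chip_rep1, config$seed_chip_rep2), function(s) {
    simulate_chip_coverage(
      genome, planted$sites, mean_depth = config$mean_depth,
      fragment_len_range = config$fragment_len_range,
      read_len = config$read_len,
      enrichment_at_sites = config$enrichment_at_sites,
      seed = s, motif_width = motif$width
    )
  })
  enr <- lapply(reps, function(r) compute_log2_enrichment(r$ip, r$input))
  for (i in seq_along(reps)) {
    write_bedgraph(reps[[i]]$ip, file.path(out_dir, paste0("ip_rep", i, ".bedgraph")))
    write_bedgraph(reps[[i]]$input, file.path(out_dir, paste0("input_rep", i, ".bedgraph")))
    write_bedgraph(enr[[i]], file.path(out_dir, paste0("log2_rep", i, ".bedgraph")))
  }
  r2 <- replicate_r2(enr[[1]], enr[[2]])
  say("replicate R^2 = ", round(r2, 3))

  # --- peaks ----------------------------------------------------------
  peaks <- call_peaks(enr[[1]], threshold_log2 = config$threshold_log2,
                      min_width = config$min_width,
                      merge_gap = config$merge_gap)
  say(nrow(peaks), " peaks at log2 >= ", config$threshold_log2)
  write_peaks(peaks, file.path(out_dir, "peaks.bed"),
              file.path(out_dir, "peaks.tsv"))

  # --- motif scan with Monte-Carlo calibration ------------------------
  null <- sample_null_scores(motif, gc = config$gc, n = config$null_n,
                             seed = config$seed_null,
                             epsilon = config$epsilon)
  thr <- threshold_for_pvalue(null, config$pvalue)
  say("score threshold ", round(thr, 3), " bits at p <= ", config$pvalue)
  hits <- scan_sequence(genome, motif, score_threshold = thr,
                        epsilon = config$epsilon, null = null)
  say(nrow(hits), " motif hits genome-wide")
  write_hits(hits, file.path(out_dir, "hits.bed"),
             file.path(out_dir, "hits.tsv"))

  # --- annotation + report -------------------------------------------
  genes <- simulate_annotation(genome,
                               intergenic_fraction = config$intergenic_fraction,
                               mean_gene_len = config$mean_gene_len,
                               seed = config$seed_annotation)
  write_gff(genes, file.path(out_dir, "genes.gff3"))
  top_n <- if (nrow(peaks) > 0) min(config$top_n, nrow(peaks)) else NULL
  report <- summarize_report(peaks, hits, genes, window = config$window,
                             top_n = top_n)
  report_tbl <- tidy(report)
  report_tbl$replicate_r2 <- r2
  utils::write.table(report_tbl, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  per_peak <- select(report$per_peak, -"motif_hits")
  utils::write.table(per_peak, file.path(out_dir, "per_peak.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("wrote ", nrow(manifest), " files to ", out_dir)

  invisible(list(
    report = report, peaks = peaks, hits = hits, replicate_r2 = r2,
    truth_sites = planted$sites, score_threshold = thr, manifest = manifest
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
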