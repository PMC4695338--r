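# -- end-to-end experiment runners -----------------------------------------

#' Build or load a run configuration
#'
#' A run configuration bundles everything needed to regenerate an
#' experiment byte-identically: the global seed (expanded into per-stage
#' sub-seeds by stage name), genome geometry, the new-MAC sample
#' definitions (label, contamination fraction, retained-fraction map), and
#' ChIP parameters.
#'
#' @param seed Global integer seed.
#' @param genome Named list of overrides for [sim_params()] geometry
#'   (`genome_size`, `n_chrom`, `n_ies`, `ies_fraction`,
#'   `ies_length_range`, `min_gap`).
#' @param sequencing Named list of overrides (`depth`, `read_length`).
#' @param samples List of sample definitions, each a list with `label`,
#'   `contamination`, and `retained` (scalar or named map over IES ids).
#' @param chip Named list with `enrichment` and `background`.
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, genome = list(), sequencing = list(),
                       samples = list(
                         list(label = "WT", contamination = 0.05,
                              retained = 0),
                         list(label = "KO", contamination = 0.05,
                              retained = 1)),
                       chip = list(enrichment = 8, background = 1)) {
  labels <- vapply(samples, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_param("sample labels must be unique")
  structure(list(seed = as.integer(seed), genome = genome,
                 sequencing = sequencing, samples = samples, chip = chip),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML path with keys `seed`, `genome`, `sequencing`,
#'   `samples`, `chip`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), c("seed", "genome",
                                              "sequencing", "samples",
                                              "chip"))])
}

config_params <- function(config, contamination = 0, elimination = NULL) {
  do.call(sim_params, c(list(seed = config$seed,
                             contamination = contamination,
                             elimination = elimination),
                        config$genome, config$sequencing))
}

write_log <- function(path, lines) {
  writeLines(c(sprintf("tetelim %s | R %s",
                       as.character(utils::packageVersion("tetelim")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               lines), path)
  invisible(path)
}

#' Run the elimination experiment end to end
#'
#' Generates the genome, simulates the MIC reference and every configured
#' new-MAC sample, computes per-IES retention indices, and writes the full
#' artifact bundle (genome FASTA, annotation BED, read BEDs, per-sample RI
#' TSVs, a summary TSV, and a log). Deterministic given the configuration;
#' elimination maps referencing unknown IES ids fail before any read is
#' simulated.
#'
#' @param config A [run_config()] (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `genome`, per-sample
#'   `retention` tables, the `summary` data frame and output `paths`.
#' @export
run_elimination_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- generate_genome(config_params(config))
  # validate every sample's elimination map before simulating anything
  elim <- lapply(config$samples, function(s)
    elimination_profile(genome, s$retained))

  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    bed = file.path(out_dir, "annotation.bed"),
    summary = file.path(out_dir, "ri_summary.tsv"),
    log = file.path(out_dir, "run.log")
  )
  write_genome_fasta(genome, paths$fasta)
  write_annotation_bed(genome, paths$bed)

  mic_params <- config_params(config)
  mic_reads <- simulate_wgs(genome, mic_params, "MIC")
  mic_bed <- file.path(out_dir, "reads_MIC.bed")
  write_reads_bed(mic_reads, mic_bed)
  mic_cov <- count_reads(mic_reads, genome, sample = "MIC")

  log_lines <- c(sprintf("seed %d; genome %d bp, %d IESs", config$seed,
                         genome$genome_length, length(ies_ids(genome))),
                 sprintf("MIC reference: %d reads", length(mic_reads)))
  summary_rows <- list()
  retention <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    params <- config_params(config, contamination = s$contamination,
                            elimination = elim[[i]])
    params$seed <- stage_seed(config$seed, paste0("sample_", s$label))
    reads <- simulate_wgs(genome, params, "newMAC")
    rb <- file.path(out_dir, sprintf("reads_%s.bed", s$label))
    write_reads_bed(reads, rb)
    cov <- count_reads(reads, genome, sample = s$label)
    rt <- retention_index(cov, mic_cov)
    retention[[s$label]] <- rt
    write_retention_tsv(rt, file.path(out_dir,
                                      sprintf("ri_%s.tsv", s$label)))
    sm <- summarize_ri(rt)
    summary_rows[[s$label]] <- data.frame(
      sample = s$label, contamination = s$contamination,
      n_ies = sm$n, median_ri = sm$median, q1 = sm$q1, q3 = sm$q3,
      frac_below_0.1 = sm$frac_below[["0.1"]],
      frac_above_0.1 = sm$frac_above[["0.1"]]
    )
    log_lines <- c(log_lines,
                   sprintf("sample %s: %d reads, %d IESs dropped (zero ref)",
                           s$label, length(reads),
                           length(attr(rt, "dropped"))))
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_log(paths$log, log_lines)
  invisible(list(genome = genome, retention = retention, summary = summary,
                 paths = paths))
}

#' Run the ChIP metagene experiment end to end
#'
#' Generates the genome, simulates IP/input read sets, computes the
#' windowed fold-enrichment track and the modeled-IES metagene, and writes
#' bedGraph, metagene TSV and a log.
#'
#' @param config A [run_config()] (or YAML path); `config$chip` supplies
#'   `enrichment` and `background` (both missing is an error), and may
#'   supply `window`, `pseudocount`, `length_filter`, `body_bins`,
#'   `flank_bp`, `flank_bins`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `track`, `metagene` and `paths`.
#' @export
run_chip_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$chip$enrichment))
    stop_param("config$chip$enrichment is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chip <- config$chip

  genome <- generate_genome(config_params(config))
  reads <- simulate_chip(genome, config_params(config),
                         enrichment = chip$enrichment,
                         background = chip$background %||% 1)
  win <- genome_windows(genome, chip$window %||% 50L)
  ip_cov <- count_reads(reads$ip, win, sample = "IP")
  in_cov <- count_reads(reads$input, win, sample = "input")
  track <- fold_enrichment(ip_cov, in_cov,
                           pseudocount = chip$pseudocount %||% 0.5)
  mg <- modeled_ies(track, genome,
                    length_filter = chip$length_filter %||% c(1000, 5000),
                    body_bins = chip$body_bins %||% 50L,
                    flank_bp = chip$flank_bp %||% 2000L,
                    flank_bins = chip$flank_bins %||% 50L)
  paths <- list(bedgraph = file.path(out_dir, "fold_enrichment.bedGraph"),
                metagene = file.path(out_dir, "metagene.tsv"),
                log = file.path(out_dir, "run.log"))
  export_bedgraph(track, paths$bedgraph)
  write_metagene_tsv(mg, paths$metagene)
  write_log(paths$log, c(
    sprintf("seed %d; enrichment %g, background %g", config$seed,
            chip$enrichment, chip$background %||% 1),
    sprintf("metagene over %d loci (%d dropped for flanks)",
            attr(mg, "n_loci"), attr(mg, "n_dropped_flank"))))
  invisible(list(track = track, metagene = mg, paths = paths))
}
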