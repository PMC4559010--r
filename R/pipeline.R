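#' Pipeline configuration
#'
#' Bundles every stage's parameters with paths and the mandatory seed for
#' the stochastic stages.
#'
#' @param out_dir Output directory (created if absent).
#' @param genome_length Synthetic genome length, bp (used when no FASTA is
#'   given).
#' @param fasta Optional input FASTA path; overrides genome simulation.
#' @param depth Molecule fold-coverage to simulate.
#' @param gc GC content for the synthetic genome.
#' @param target_label_density Planted label density per 100 kb.
#' @param digest A `digest_params`.
#' @param noise A `noise_model`.
#' @param length_model A `molecule_length_model`.
#' @param assembly An `assembly_params`.
#' @param align An `align_params`.
#' @param seed RNG seed (required).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, genome_length = 1e6, fasta = NULL,
                            depth = 60, gc = 0.4, target_label_density = 11,
                            digest = digest_params(), noise = noise_model(),
                            length_model = molecule_length_model(),
                            assembly = assembly_params(),
                            align = align_params(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  structure(list(out_dir = out_dir, genome_length = genome_length,
                 fasta = fasta, depth = depth, gc = gc,
                 target_label_density = target_label_density,
                 digest = digest, noise = noise, length_model = length_model,
                 assembly = assembly, align = align, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the whole-genome mapping pipeline
#'
#' Executes digest -> simulate -> assemble -> align -> stats on a synthetic
#' (or supplied) genome, writing every artifact plus a manifest with the
#' configuration hash, so identical configurations reproduce identical
#' outputs byte for byte.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$fasta)) {
    genome <- read_fasta(config$fasta)[[1]]
  } else {
    sim <- simulate_genome(config$genome_length, gc = config$gc,
                           target_label_density = config$target_label_density,
                           seed = config$seed, params = config$digest)
    genome <- sim$record
    write_fasta(list(genome), p("genome.fa"))
  }

  dig <- digest_sequences(list(genome), config$digest)
  write_cmap(dig$maps, p("digest.cmap"))

  ds <- generate_dataset(genome, depth = config$depth, params = config$digest,
                         length_model = config$length_model,
                         noise = config$noise, seed = config$seed)
  write_bnx(ds$bnx, p("molecules.bnx"))
  write.table(ds$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  asm <- assemble(ds$bnx, config$assembly)
  write_cmap(asm$maps, p("maps.cmap"))

  ba <- batch_align(asm$maps, dig$maps, config$align)
  if (!is.null(ba$table))
    write.table(ba$table, p("alignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

  stats <- summary_table(list(molecules = ds$bnx, maps = asm$maps))
  write.table(stats, p("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dens <- label_density_stats(ds$bnx)

  cfg_file <- p("config.json")
  jsonlite::write_json(list(
    seed = config$seed, depth = config$depth,
    genome_length = genome$length, gc = config$gc,
    target_label_density = config$target_label_density,
    motif = config$digest$motif,
    resolution_bp = config$digest$resolution_bp,
    noise = unclass(config$noise)), cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    files = c("genome.fa", "digest.cmap", "molecules.bnx", "truth.tsv",
              "maps.cmap", "alignments.tsv", "summary.tsv"),
    file_hashes = unname(tools::md5sum(Filter(file.exists, c(
      p("genome.fa"), p("digest.cmap"), p("molecules.bnx"), p("truth.tsv"),
      p("maps.cmap"), p("alignments.tsv"), p("summary.tsv"))))),
    n_molecules = length(ds$bnx), n_maps = length(asm$maps),
    overall_label_density = dens$overall,
    frac_thorough = ba$summary$frac_thorough)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genome = genome, digest = dig, dataset = ds, assembly = asm,
                 alignments = ba, summary = stats,
                 manifest = p("manifest.json")))
}
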