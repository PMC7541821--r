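#' Load a pipeline run configuration from YAML
#'
#' The file mirrors [run_config()]: top-level stage parameters plus either a
#' `sim:` block (fields as in [sim_config()], per-lineage maps as named
#' lists) or an `inputs:` block of file paths.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    s <- y$sim
    num_map <- function(x) if (is.null(x)) NULL else unlist(x)
    args <- list()
    for (nm in c("seed", "virus_concentration", "drop_volume",
                 "n_virus_genomes", "n_bacterial_genomes", "n_euk_genomes",
                 "ssdna_fraction", "within_cluster_ani", "ssdna_length_max",
                 "external_coverage", "viral_metagenome_size",
                 "bacterial_metagenome_size"))
      if (!is.null(s[[nm]])) args[[nm]] <- s[[nm]]
    for (nm in c("n_sags_per_lineage", "lineage_grazing_rate",
                 "bacterial_prey_prob", "plastidic", "fragments_per_genome",
                 "host_contig_range"))
      if (!is.null(s[[nm]])) args[[nm]] <- num_map(s[[nm]])
    if (!is.null(s$contig_length_range))
      args$contig_length_range <- lapply(s$contig_length_range, unlist)
    if (!is.null(s$evidence_noise)) args$evidence_noise <- s$evidence_noise
    sim <- do.call(sim_config, args)
  }
  top <- y[setdiff(names(y), c("sim", "inputs"))]
  args <- c(list(sim = sim, inputs = y$inputs), top)
  do.call(run_config, args)
}
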