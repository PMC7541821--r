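#' Simulation configuration for a synthetic SAG community
#'
#' Defines the study conditions emulated by the generator: per-lineage SAG
#' counts, lineage-specific mean numbers of ingested (grazed) viruses per
#' cell, bacterial prey probabilities, the free-virus concentration and
#' droplet sample volume governing accidental co-sorting, genome pool sizes,
#' within-virus-cluster sequence identity (ANI), per-class contig length
#' ranges, and false-positive / false-negative rates for the synthetic
#' evidence channels.
#'
#' Defaults mirror a Gulf-of-Maine-like survey: six protist lineages with the
#' observed SAG counts; mean grazed-virus loads of 28 (Choanozoa-like) and
#' 5.7 (Picozoa-like) viruses per cell with low rates elsewhere; free viruses
#' at 0.05 per pL (surface sea water carries roughly 0.01-0.1 viruses per pL)
#' in 21 pL sorted drops; planted virus clusters at 98% ANI; ssDNA virus
#' genomes below 10 kb.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param n_sags_per_lineage named integer vector, SAGs per lineage.
#' @param lineage_grazing_rate named numeric vector, mean ingested viruses
#'   per cell (Poisson mean), same names as `n_sags_per_lineage`.
#' @param bacterial_prey_prob named numeric vector in \[0,1\], probability a
#'   SAG carries bacterial prey contigs.
#' @param plastidic named logical vector, whether the lineage is plastidic.
#' @param virus_concentration free viral particles per pL of sorted sample.
#' @param drop_volume sorted droplet sample volume in pL.
#' @param n_virus_genomes,n_bacterial_genomes,n_euk_genomes genome pool sizes.
#' @param ssdna_fraction fraction of the virus pool that is ssDNA.
#' @param within_cluster_ani nucleotide identity between planted copies of
#'   the same virus genome, in (0.95, 1\].
#' @param contig_length_range named list of length-2 bp ranges for classes
#'   `eukaryote`, `bacterium`, `dsDNA_phage`, `ssDNA_virus`.
#' @param fragments_per_genome named integer vector: contigs per eukaryote /
#'   bacterial genome.
#' @param host_contig_range length-2 integer range of host contigs per SAG.
#' @param evidence_noise list with `fp` and `fn` rates in \[0,1\] applied per
#'   evidence channel.
#' @param ssdna_length_max bp cap used by the ssDNA rule (and respected by
#'   the generated ssDNA genome lengths).
#' @param external_coverage fraction of dsDNA phage contigs that receive an
#'   external viral-category call (emulating partial screening coverage).
#' @param viral_metagenome_size,bacterial_metagenome_size total read counts
#'   of the two recruitment channels.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_sags_per_lineage = c(Choanozoa = 13L, Picozoa = 9L, Chlorophyta = 51L,
                           Cercozoa = 30L, Stramenopiles = 91L, Alveolata = 97L),
    lineage_grazing_rate = c(Choanozoa = 28, Picozoa = 5.7, Chlorophyta = 1,
                             Cercozoa = 0.9, Stramenopiles = 0.5, Alveolata = 0.2),
    bacterial_prey_prob = c(Choanozoa = 0.4, Picozoa = 0.4, Chlorophyta = 0.2,
                            Cercozoa = 0.4, Stramenopiles = 0.2, Alveolata = 0.2),
    plastidic = c(Choanozoa = FALSE, Picozoa = FALSE, Chlorophyta = TRUE,
                  Cercozoa = FALSE, Stramenopiles = TRUE, Alveolata = FALSE),
    virus_concentration = 0.05,
    drop_volume = 21,
    n_virus_genomes = 40L,
    n_bacterial_genomes = 8L,
    n_euk_genomes = 24L,
    ssdna_fraction = 0.4,
    within_cluster_ani = 0.98,
    contig_length_range = list(eukaryote = c(2000L, 12000L),
                               bacterium = c(2000L, 12000L),
                               dsDNA_phage = c(5000L, 60000L),
                               ssDNA_virus = c(1000L, 8000L)),
    fragments_per_genome = c(eukaryote = 6L, bacterium = 4L),
    host_contig_range = c(2L, 6L),
    evidence_noise = list(fp = 0.02, fn = 0.05),
    ssdna_length_max = 10000L,
    external_coverage = 0.3,
    viral_metagenome_size = 2e6,
    bacterial_metagenome_size = 3e6) {

  lineages <- names(n_sags_per_lineage)
  if (is.null(lineages) || any(lineages == ""))
    stop("n_sags_per_lineage must be a named vector")
  for (nm in c("lineage_grazing_rate", "bacterial_prey_prob", "plastidic")) {
    v <- get(nm)
    missing_l <- setdiff(lineages, names(v))
    if (length(missing_l) > 0)
      stop(sprintf("%s missing lineages: %s", nm,
                   paste(missing_l, collapse = ", ")))
  }
  if (any(n_sags_per_lineage < 0)) stop("SAG counts must be non-negative")
  if (any(lineage_grazing_rate < 0)) stop("grazing rates must be non-negative")
  if (any(bacterial_prey_prob < 0 | bacterial_prey_prob > 1))
    stop("bacterial_prey_prob must lie in [0, 1]")
  if (virus_concentration < 0) stop("virus_concentration must be non-negative")
  if (drop_volume <= 0) stop("drop_volume must be positive")
  if (any(c(n_virus_genomes, n_bacterial_genomes, n_euk_genomes) < 0))
    stop("genome pool counts must be non-negative")
  if (within_cluster_ani <= 0 || within_cluster_ani > 1)
    stop("within_cluster_ani must lie in (0, 1]")
  for (cls in names(contig_length_range)) {
    r <- contig_length_range[[cls]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop(sprintf("invalid contig length range for class %s", cls))
  }
  if (any(unlist(evidence_noise) < 0) || any(unlist(evidence_noise) > 1))
    stop("evidence noise rates must lie in [0, 1]")
  if (ssdna_fraction < 0 || ssdna_fraction > 1)
    stop("ssdna_fraction must lie in [0, 1]")

  structure(list(
    seed = as.integer(seed),
    n_sags_per_lineage = n_sags_per_lineage,
    lineage_grazing_rate = lineage_grazing_rate[lineages],
    bacterial_prey_prob = bacterial_prey_prob[lineages],
    plastidic = plastidic[lineages],
    virus_concentration = virus_concentration,
    drop_volume = drop_volume,
    n_virus_genomes = as.integer(n_virus_genomes),
    n_bacterial_genomes = as.integer(n_bacterial_genomes),
    n_euk_genomes = as.integer(n_euk_genomes),
    ssdna_fraction = ssdna_fraction,
    within_cluster_ani = within_cluster_ani,
    contig_length_range = contig_length_range,
    fragments_per_genome = fragments_per_genome,
    host_contig_range = as.integer(host_contig_range),
    evidence_noise = evidence_noise,
    ssdna_length_max = as.integer(ssdna_length_max),
    external_coverage = external_coverage,
    viral_metagenome_size = viral_metagenome_size,
    bacterial_metagenome_size = bacterial_metagenome_size
  ), class = "sim_config")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mutate a sequence to a target average nucleotide identity
#'
#' Per-site substitution at rate `1 - target_ani`; a substituted base is
#' always different from the original, so the realised identity concentrates
#' tightly around `target_ani`. Length is preserved.
#'
#' @param sequence nucleotide string (non-empty).
#' @param target_ani target identity in (0, 1\].
#' @return mutated sequence of the same length.
#' @export
mutate_to_ani <- function(sequence, target_ani) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a non-empty string")
  if (target_ani <= 0 || target_ani > 1) stop("target_ani must lie in (0, 1]")
  if (target_ani == 1) return(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < (1 - target_ani))
  if (length(hit) > 0) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    repl <- vapply(bases[hit], function(b) {
      ch <- alt[[b]]
      if (is.null(ch)) b else ch[sample.int(3L, 1L)]
    }, character(1), USE.NAMES = FALSE)
    bases[hit] <- repl
  }
  paste(bases, collapse = "")
}

# LCA labels assigned to virus pool genomes; dsDNA phages are mostly tailed
# (Caudovirales) with a minority of large eukaryote-infecting viruses, ssDNA
# viruses split between bacteriophage Microviridae and CRESS DNA viruses.
.virus_lca_pool <- list(
  dsDNA_phage = c(Caudovirales = 0.8, Phycodnaviridae = 0.2),
  ssDNA_virus = c(Microviridae = 0.6, CRESS = 0.4)
)

#' Generate the source genome pool
#'
#' Eukaryote and bacterial genomes are produced directly as sets of canonical
#' contig-sized fragments (uniform random nucleotides); each virus genome is
#' a single sequence. The first fragment of every bacterial genome carries
#' the 16S marker flag. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `genome_pool`: list with `meta` (data.frame:
#'   seq_id, genome_id, class, lca, has_16s, length) and `seqs` (named
#'   character vector).
#' @export
generate_genome_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  meta <- list(); seqs <- list()

  frag_block <- function(prefix, n_genomes, class, n_frag, len_range, mark_16s) {
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("%s%02d", prefix, g)
      for (f in seq_len(n_frag)) {
        sid <- sprintf("%s_f%d", gid, f)
        len <- sample(len_range[1]:len_range[2], 1L)
        seqs[[sid]] <<- random_dna(len)
        meta[[length(meta) + 1L]] <<- data.frame(
          seq_id = sid, genome_id = gid, class = class,
          lca = NA_character_, has_16s = mark_16s && f == 1L,
          length = len, stringsAsFactors = FALSE)
      }
    }
  }
  frag_block("EUK", config$n_euk_genomes, "eukaryote",
             config$fragments_per_genome[["eukaryote"]],
             config$contig_length_range$eukaryote, FALSE)
  frag_block("BAC", config$n_bacterial_genomes, "bacterium",
             config$fragments_per_genome[["bacterium"]],
             config$contig_length_range$bacterium, TRUE)

  n_vir <- config$n_virus_genomes
  n_ss <- round(n_vir * config$ssdna_fraction)
  vir_class <- c(rep("dsDNA_phage", n_vir - n_ss), rep("ssDNA_virus", n_ss))
  for (g in seq_len(n_vir)) {
    gid <- sprintf("VIR%02d", g)
    cls <- vir_class[g]
    len_range <- config$contig_length_range[[cls]]
    if (cls == "ssDNA_virus")
      len_range[2] <- min(len_range[2], config$ssdna_length_max - 1L)
    len <- sample(len_range[1]:len_range[2], 1L)
    probs <- .virus_lca_pool[[cls]]
    lca <- sample(names(probs), 1L, prob = probs)
    seqs[[gid]] <- random_dna(len)
    meta[[length(meta) + 1L]] <- data.frame(
      seq_id = gid, genome_id = gid, class = cls, lca = lca,
      has_16s = FALSE, length = len, stringsAsFactors = FALSE)
  }

  meta <- do.call(rbind, meta)
  structure(list(meta = meta, seqs = unlist(seqs)), class = "genome_pool")
}

#' Bacterial reference contig set
#'
#' The canonical bacterial genome fragments, playing the role of contigs from
#' sequenced bacterial reference SAGs that protist contigs are sketched
#' against.
#'
#' @param pool a [generate_genome_pool()] result.
#' @return named character vector of sequences (names are reference contig ids).
#' @export
reference_contigs <- function(pool) {
  stopifnot(inherits(pool, "genome_pool"))
  keep <- pool$meta$class == "bacterium"
  pool$seqs[pool$meta$seq_id[keep]]
}

#' Simulate a set of SAGs with planted truth
#'
#' Per SAG: host contigs copied from one lineage-assigned eukaryote genome;
#' bacterial prey contigs with the lineage's prey probability; grazed virus
#' contigs with count ~ Poisson(lineage grazing rate); co-sorted virus
#' contigs with count ~ Poisson(virus_concentration x drop_volume). Every
#' planted virus or prey contig is an ANI-mutated copy of a pool genome, so
#' the same source planted in different SAGs forms a near-identical cluster;
#' the truth table records the origin class, source genome, cluster id and
#' acquisition channel of every contig.
#'
#' @param config a [sim_config()].
#' @param pool a [generate_genome_pool()] result from the same config.
#' @param seed RNG seed for this draw (defaults to `config$seed + 1`).
#' @return object of class `sag_simulation`: list with `sags` (data.frame:
#'   sag_id, lineage, plastidic), `contigs` (named character vector), `truth`
#'   (data.frame: contig_id, sag_id, origin_class, source_genome_id,
#'   cluster_id, acquisition).
#' @export
simulate_sag_set <- function(config, pool, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(pool, "genome_pool"))
  set.seed(seed)
  lineages <- names(config$n_sags_per_lineage)
  euk_ids <- unique(pool$meta$genome_id[pool$meta$class == "eukaryote"])
  bac_ids <- unique(pool$meta$genome_id[pool$meta$class == "bacterium"])
  vir_ids <- pool$meta$seq_id[pool$meta$class %in% c("dsDNA_phage", "ssDNA_virus")]
  if (length(euk_ids) < length(lineages))
    stop("need at least one eukaryote genome per lineage")
  # round-robin partition of host genomes across lineages
  euk_lineage <- lineages[((seq_along(euk_ids) - 1L) %% length(lineages)) + 1L]
  frag_of <- split(pool$meta$seq_id, pool$meta$genome_id)

  lambda_cosort <- config$virus_concentration * config$drop_volume
  # each planted copy diverges from the source by half the target divergence,
  # so any two cluster members sit at ~within_cluster_ani pairwise identity
  ani <- 1 - (1 - config$within_cluster_ani) / 2

  sag_rows <- list(); truth_rows <- list(); contig_seqs <- list()
  sag_n <- 0L
  for (ln in lineages) {
    host_pool <- euk_ids[euk_lineage == ln]
    if (length(host_pool) == 0L) stop(sprintf("no host genomes for lineage %s", ln))
    for (i in seq_len(config$n_sags_per_lineage[[ln]])) {
      sag_n <- sag_n + 1L
      sag_id <- sprintf("SAG%04d", sag_n)
      sag_rows[[sag_n]] <- data.frame(
        sag_id = sag_id, lineage = ln,
        plastidic = config$plastidic[[ln]], stringsAsFactors = FALSE)
      cidx <- 0L
      add_contig <- function(seq, origin, source_genome, cluster, acq) {
        cidx <<- cidx + 1L
        cid <- sprintf("%s_c%03d", sag_id, cidx)
        contig_seqs[[cid]] <<- seq
        truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
          contig_id = cid, sag_id = sag_id, origin_class = origin,
          source_genome_id = source_genome, cluster_id = cluster,
          acquisition = acq, stringsAsFactors = FALSE)
      }
      # host
      hg <- if (length(host_pool) == 1L) host_pool else sample(host_pool, 1L)
      frs <- frag_of[[hg]]
      hr <- config$host_contig_range
      n_host <- if (hr[1] == hr[2]) hr[1] else sample(hr[1]:hr[2], 1L)
      n_host <- min(n_host, length(frs))
      picked <- if (length(frs) == 1L) frs else sample(frs, n_host)
      for (fr in picked)
        add_contig(pool$seqs[[fr]], "eukaryote", hg, fr, "host")
      # bacterial prey
      if (length(bac_ids) > 0 &&
          stats::runif(1) < config$bacterial_prey_prob[[ln]]) {
        bg <- if (length(bac_ids) == 1L) bac_ids else sample(bac_ids, 1L)
        bfr <- frag_of[[bg]]
        n_prey <- sample(1:3, 1L)
        bpicked <- if (length(bfr) == 1L) bfr else sample(bfr, min(n_prey, length(bfr)))
        for (fr in bpicked)
          add_contig(mutate_to_ani(pool$seqs[[fr]], ani),
                     "bacterium", bg, fr, "prey")
      }
      # viruses: grazed + co-sorted
      n_graze <- stats::rpois(1L, config$lineage_grazing_rate[[ln]])
      n_cosort <- stats::rpois(1L, lambda_cosort)
      n_v <- n_graze + n_cosort
      if (n_v > 0L) {
        if (length(vir_ids) == 0L)
          stop("virus planting requested but virus pool is empty")
        acqs <- c(rep("grazed_virus", n_graze), rep("cosort", n_cosort))
        vg <- sample(vir_ids, n_v, replace = TRUE)
        for (j in seq_len(n_v)) {
          cls <- pool$meta$class[match(vg[j], pool$meta$seq_id)]
          add_contig(mutate_to_ani(pool$seqs[[vg[j]]], ani),
                     cls, vg[j], vg[j], acqs[j])
        }
      }
    }
  }
  structure(list(
    sags = do.call(rbind, sag_rows),
    contigs = unlist(contig_seqs),
    truth = do.call(rbind, truth_rows)
  ), class = "sag_simulation")
}

n_orfs_for <- function(len) pmax(1L, len %/% 900L)

.viral_descriptions <- c(
  "major capsid protein", "terminase large subunit", "phage portal protein",
  "tail fiber protein", "prophage integrase", "baseplate assembly protein",
  "virion structural protein", "podovirus DNA maturase",
  "myovirus sheath protein", "siphovirus tape measure protein",
  "lysis inhibitor", "head morphogenesis protein",
  "putative virus replication initiator")

.nonviral_descriptions <- c(
  "hypothetical protein", "ABC transporter ATP-binding protein",
  "ribosomal protein S12", "cytochrome c oxidase subunit I",
  "DNA polymerase family B", "actin-related protein",
  "tubulin beta chain", "elongation factor 1-alpha",
  "glyceraldehyde-3-phosphate dehydrogenase", "histone H2A")

#' Emit noisy evidence tables for a simulated SAG set
#'
#' Emulates the downstream outputs of external annotation tools: ORF hit
#' tables in BLAST-tabular style (nr and RefSeq-bacteria subject classes),
#' metagenome read-recruitment counts, ssDNA-virus alignment hits, external
#' viral-category calls, per-ORF viral LCA labels, 16S marker flags, and a
#' nucleotide-verification call per contig. Viral-origin contigs receive
#' viral-term nr hits at rate `1 - fn`; non-viral contigs at rate `fp`;
#' analogous noise applies to the other channels. ssDNA-virus contigs are
#' deliberately invisible to the ORF/recruitment viral channels (their real
#' counterparts were missed by those screens) and are covered by the ssDNA
#' alignment channel instead.
#'
#' @param sim a [simulate_sag_set()] result.
#' @param pool the [generate_genome_pool()] used to build `sim`.
#' @param config the [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return object of class `evidence_set`: list of data.frames `orf_hits`,
#'   `recruitment`, `ssdna_hits`, `external_viral`, `vog_lca`, `marker_16s`,
#'   `nt_check`.
#' @export
emit_evidence_tables <- function(sim, pool, config, seed = config$seed + 2L) {
  stopifnot(inherits(sim, "sag_simulation"), inherits(pool, "genome_pool"),
            inherits(config, "sim_config"))
  set.seed(seed)
  truth <- sim$truth
  cids <- names(sim$contigs)
  missing_truth <- setdiff(cids, truth$contig_id)
  if (length(missing_truth) > 0)
    stop(sprintf("missing truth row for contig %s", missing_truth[1]))
  fp <- config$evidence_noise$fp
  fn <- config$evidence_noise$fn

  lens <- nchar(sim$contigs)
  origin <- truth$origin_class[match(cids, truth$contig_id)]
  src <- truth$source_genome_id[match(cids, truth$contig_id)]
  src_frag <- truth$cluster_id[match(cids, truth$contig_id)]
  lca <- pool$meta$lca[match(src, pool$meta$genome_id)]

  orf_rows <- vector("list", length(cids))
  vog_rows <- list()
  for (ci in seq_along(cids)) {
    cid <- cids[ci]
    n_orf <- n_orfs_for(lens[ci])
    is_ds <- origin[ci] == "dsDNA_phage"
    is_vir <- origin[ci] %in% c("dsDNA_phage", "ssDNA_virus")
    p_viral_hit <- if (is_ds) 1 - fn else fp
    viral_orf <- stats::runif(n_orf) < p_viral_hit
    desc <- ifelse(viral_orf,
                   sample(.viral_descriptions, n_orf, replace = TRUE),
                   sample(.nonviral_descriptions, n_orf, replace = TRUE))
    rank <- ifelse(viral_orf, sample.int(10L, n_orf, replace = TRUE), 1L)
    nr <- data.frame(
      contig_id = cid, orf_index = seq_len(n_orf), hit_rank = rank,
      hit_description = desc,
      percent_identity = round(stats::runif(n_orf, 60, 100), 1),
      alignment_fraction = round(stats::runif(n_orf, 0.5, 1), 3),
      evalue = 1e-20, bitscore = round(stats::runif(n_orf, 80, 400), 1),
      subject_class = "nr", stringsAsFactors = FALSE)
    rs <- NULL
    if (origin[ci] == "bacterium") {
      qual <- stats::runif(n_orf) < (1 - fn)
      rs <- data.frame(
        contig_id = cid, orf_index = seq_len(n_orf), hit_rank = 1L,
        hit_description = "bacterial reference protein",
        percent_identity = round(ifelse(qual, stats::runif(n_orf, 55, 95),
                                        stats::runif(n_orf, 20, 45)), 1),
        alignment_fraction = round(ifelse(qual, stats::runif(n_orf, 0.76, 0.98),
                                          stats::runif(n_orf, 0.30, 0.70)), 3),
        evalue = 1e-15, bitscore = round(stats::runif(n_orf, 60, 300), 1),
        subject_class = "refseq_bacteria", stringsAsFactors = FALSE)
    } else {
      spur <- which(stats::runif(n_orf) < fp)
      if (length(spur) > 0) {
        rs <- data.frame(
          contig_id = cid, orf_index = spur, hit_rank = 1L,
          hit_description = "bacterial reference protein",
          percent_identity = round(stats::runif(length(spur), 55, 95), 1),
          alignment_fraction = round(stats::runif(length(spur), 0.76, 0.98), 3),
          evalue = 1e-15, bitscore = round(stats::runif(length(spur), 60, 300), 1),
          subject_class = "refseq_bacteria", stringsAsFactors = FALSE)
      }
    }
    orf_rows[[ci]] <- if (is.null(rs)) nr else rbind(nr, rs)
    if (is_vir) {
      lab <- ifelse(stats::runif(n_orf) < (1 - fn), lca[ci], "none")
      vog_rows[[length(vog_rows) + 1L]] <- data.frame(
        contig_id = cid, orf_index = seq_len(n_orf), lca_label = lab,
        stringsAsFactors = FALSE)
    }
  }
  orf_hits <- do.call(rbind, orf_rows)
  vog_lca <- if (length(vog_rows) > 0) do.call(rbind, vog_rows) else
    data.frame(contig_id = character(), orf_index = integer(),
               lca_label = character(), stringsAsFactors = FALSE)

  # recruitment: viral-origin dsDNA contigs are virome-enriched; everything
  # else (incl. ssDNA, which translated-read virome recruitment missed in the
  # emulated screens) leans to the bacterial channel
  is_ds_all <- origin == "dsDNA_phage"
  kb <- lens / 1000
  v_mean <- ifelse(is_ds_all, 20 * kb, 0.5 * kb)
  b_mean <- ifelse(is_ds_all, 1 * kb, 10 * kb)
  recruitment <- data.frame(
    contig_id = cids,
    viral_reads = stats::rpois(length(cids), v_mean),
    bacterial_reads = stats::rpois(length(cids), b_mean),
    viral_metagenome_size = config$viral_metagenome_size,
    bacterial_metagenome_size = config$bacterial_metagenome_size,
    contig_length = lens, stringsAsFactors = FALSE)

  # ssDNA alignment hits: two non-overlapping spans covering ~30% for true
  # ssDNA contigs; a spurious ~25% span at rate fp elsewhere
  ss_rows <- list()
  for (ci in seq_along(cids)) {
    if (origin[ci] == "ssDNA_virus") {
      if (stats::runif(1) < (1 - fn)) {
        l <- lens[ci]
        ss_rows[[length(ss_rows) + 1L]] <- data.frame(
          contig_id = cids[ci],
          subject_id = paste0("ssdna_ref_", src[ci]),
          evalue = 1e-10,
          span_start = c(1L, floor(0.45 * l)),
          span_end = c(floor(0.15 * l), floor(0.60 * l)),
          stringsAsFactors = FALSE)
      }
    } else if (stats::runif(1) < fp) {
      l <- lens[ci]
      ss_rows[[length(ss_rows) + 1L]] <- data.frame(
        contig_id = cids[ci], subject_id = "ssdna_ref_spurious",
        evalue = 1e-8, span_start = 1L, span_end = floor(0.25 * l),
        stringsAsFactors = FALSE)
    }
  }
  ssdna_hits <- if (length(ss_rows) > 0) do.call(rbind, ss_rows) else
    data.frame(contig_id = character(), subject_id = character(),
               evalue = numeric(), span_start = integer(),
               span_end = integer(), stringsAsFactors = FALSE)

  # external viral-category calls (partial coverage)
  ext_rows <- list()
  for (ci in seq_along(cids)) {
    if (is_ds_all[ci]) {
      if (stats::runif(1) < config$external_coverage * (1 - fn))
        ext_rows[[length(ext_rows) + 1L]] <- data.frame(
          contig_id = cids[ci], category = sample(1:2, 1L),
          stringsAsFactors = FALSE)
    } else if (stats::runif(1) < fp) {
      ext_rows[[length(ext_rows) + 1L]] <- data.frame(
        contig_id = cids[ci], category = 3L, stringsAsFactors = FALSE)
    }
  }
  external_viral <- if (length(ext_rows) > 0) do.call(rbind, ext_rows) else
    data.frame(contig_id = character(), category = integer(),
               stringsAsFactors = FALSE)

  # 16S marker flags: contigs derived from marker-carrying bacterial fragments
  has16 <- pool$meta$has_16s[match(src_frag, pool$meta$seq_id)]
  has16[is.na(has16)] <- FALSE
  marker_16s <- data.frame(contig_id = cids[has16], stringsAsFactors = FALSE)

  nt_check <- data.frame(
    contig_id = cids,
    nt_verification = ifelse(origin == "bacterium", "bacterial", "unknown"),
    stringsAsFactors = FALSE)

  structure(list(orf_hits = orf_hits, recruitment = recruitment,
                 ssdna_hits = ssdna_hits, external_viral = external_viral,
                 vog_lca = vog_lca, marker_16s = marker_16s,
                 nt_check = nt_check),
            class = "evidence_set")
}

#' Write per-SAG FASTA files
#'
#' One FASTA per SAG, headers `>{sag_id}|{contig_id}`, wrapped at 80 columns.
#'
#' @param sim a [simulate_sag_set()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_sag_fastas <- function(sim, dir) {
  stopifnot(inherits(sim, "sag_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in sim$sags$sag_id) {
    cids <- sim$truth$contig_id[sim$truth$sag_id == sid]
    path <- file.path(dir, paste0(sid, ".fasta"))
    con <- file(path, "w")
    for (cid in cids) {
      writeLines(paste0(">", sid, "|", cid), con)
      seq <- sim$contigs[[cid]]
      starts <- seq(1L, nchar(seq), by = 80L)
      writeLines(substring(seq, starts, pmin(starts + 79L, nchar(seq))), con)
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a directory of per-SAG FASTA files
#'
#' Headers must follow `>{sag_id}|{contig_id}`.
#'
#' @param dir directory containing `.fasta` files.
#' @return list with `contigs` (named character vector) and `truth`-style
#'   mapping data.frame (contig_id, sag_id).
#' @export
read_sag_fastas <- function(dir) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  seqs <- character(0); map <- list()
  for (f in files) {
    ss <- Biostrings::readDNAStringSet(f)
    hdr <- strsplit(names(ss), "|", fixed = TRUE)
    cid <- vapply(hdr, `[`, character(1), 2)
    sid <- vapply(hdr, `[`, character(1), 1)
    x <- as.character(ss)
    names(x) <- cid
    seqs <- c(seqs, x)
    map[[length(map) + 1L]] <- data.frame(contig_id = cid, sag_id = sid,
                                          stringsAsFactors = FALSE)
  }
  list(contigs = seqs, mapping = do.call(rbind, map))
}
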