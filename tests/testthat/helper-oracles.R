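# Brute-force oracles and small fixture builders shared across tests.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# exhaustive canonical k-mer set of a sequence (strings, deduplicated)
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  km <- km[grepl("^[ACGT]+$", km)]
  if (length(km) == 0) return(character(0))
  rc <- vapply(km, revcomp, character(1), USE.NAMES = FALSE)
  unique(pmin(km, rc))
}

exact_jaccard <- function(a, b, k) {
  sa <- canonical_kmers(a, k); sb <- canonical_kmers(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# pairwise identity of two equal-length sequences
seq_identity <- function(a, b) {
  mean(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
}

# small, fast synthetic community configuration
small_sim_config <- function(seed = 11L, fp = 0, fn = 0, ...) {
  args <- list(
    seed = seed,
    n_sags_per_lineage = c(Choanozoa = 8L, Picozoa = 8L, Alveolata = 8L),
    lineage_grazing_rate = c(Choanozoa = 4, Picozoa = 2, Alveolata = 0.3),
    bacterial_prey_prob = c(Choanozoa = 0.5, Picozoa = 0.5, Alveolata = 0.3),
    plastidic = c(Choanozoa = FALSE, Picozoa = FALSE, Alveolata = FALSE),
    virus_concentration = 0.02, drop_volume = 21,
    n_virus_genomes = 12L, n_bacterial_genomes = 4L, n_euk_genomes = 6L,
    contig_length_range = list(eukaryote = c(1500L, 5000L),
                               bacterium = c(1500L, 5000L),
                               dsDNA_phage = c(2000L, 15000L),
                               ssDNA_virus = c(1000L, 5000L)),
    evidence_noise = list(fp = fp, fn = fn))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# minimal sequence-light config for count-level Monte Carlo experiments
count_sim_config <- function(seed, lineages, grazing, conc = 0, prey = NULL) {
  n <- stats::setNames(rep(50L, length(lineages)), lineages)
  gr <- stats::setNames(grazing, lineages)
  pr <- if (is.null(prey)) stats::setNames(rep(0, length(lineages)), lineages)
        else stats::setNames(prey, lineages)
  pl <- stats::setNames(rep(FALSE, length(lineages)), lineages)
  sim_config(
    seed = seed, n_sags_per_lineage = n, lineage_grazing_rate = gr,
    bacterial_prey_prob = pr, plastidic = pl,
    virus_concentration = conc, drop_volume = 21,
    n_virus_genomes = 6L, n_bacterial_genomes = 2L,
    n_euk_genomes = max(6L, length(lineages)),
    contig_length_range = list(eukaryote = c(60L, 100L),
                               bacterium = c(60L, 100L),
                               dsDNA_phage = c(60L, 100L),
                               ssDNA_virus = c(60L, 100L)),
    fragments_per_genome = c(eukaryote = 2L, bacterium = 2L),
    host_contig_range = c(1L, 2L))
}

# exhaustive Mann-Whitney null by enumeration of all rank assignments
mw_exact_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n, n1)
  U_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# modularity of a membership vector on a weighted undirected graph
modularity_direct <- function(g, membership) {
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}
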