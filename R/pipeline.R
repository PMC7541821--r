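#' Pipeline run configuration
#'
#' Bundles either a synthetic-community [sim_config()] or paths to real
#' inputs, plus every stage parameter. Exactly one of `sim` / `inputs` must
#' be supplied.
#'
#' @param sim a [sim_config()] for synthetic mode, or NULL.
#' @param inputs named list of paths for real mode: `fasta_dir`, `orf_hits`,
#'   `recruitment`, `ssdna_hits`, `external_viral`, `vog_lca`, `marker_16s`,
#'   `nt_check`, `taxonomy`, optional `bacterial_ref_fasta`, optional
#'   `training`.
#' @param k,s,hash_seed sketching parameters (defaults 21, 1000, 42).
#' @param mash_threshold network / bacterial-reference distance cutoff
#'   (inclusive; default 0.05, i.e. ~95% ANI).
#' @param knn_k,alpha,p_thresh,top_n classifier parameters.
#' @param clustering "louvain" or "components" (single linkage).
#' @param viral_frac_min cluster viral-member fraction threshold (default
#'   0.25, inclusive).
#' @param min_freq LCA modal-frequency threshold (default 0.25).
#' @param phage_lineages cluster LCA labels counted as bacteriophage.
#' @param seed master seed for the run.
#' @param out_dir optional output directory; when set, every stage table and
#'   `report.json` are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       k = 21L, s = 1000L, hash_seed = 42L,
                       mash_threshold = 0.05,
                       knn_k = 5L, alpha = 0.05, p_thresh = 0.5, top_n = 10L,
                       clustering = c("louvain", "components"),
                       viral_frac_min = 0.25, min_freq = 0.25,
                       phage_lineages = c("Caudovirales", "Microviridae"),
                       seed = 1L, out_dir = NULL) {
  clustering <- match.arg(clustering)
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of sim (synthetic mode) or inputs (real mode) required")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (mash_threshold < 0 || mash_threshold > 1)
    stop("mash_threshold must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (viral_frac_min < 0 || viral_frac_min > 1)
    stop("viral_frac_min must lie in [0, 1]")
  structure(list(sim = sim, inputs = inputs, k = as.integer(k),
                 s = as.integer(s), hash_seed = as.integer(hash_seed),
                 mash_threshold = mash_threshold, knn_k = as.integer(knn_k),
                 alpha = alpha, p_thresh = p_thresh, top_n = as.integer(top_n),
                 clustering = clustering, viral_frac_min = viral_frac_min,
                 min_freq = min_freq, phage_lineages = phage_lineages,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  sprintf("%.0f", cpp_hash_string(as.character(json), 0))
}

#' Run the full SAG contamination-triage pipeline
#'
#' Executes, in order: synthetic community generation (synthetic mode) or
#' input loading (real mode); contig sketching; per-contig evidence assembly
#' and classification; the contig similarity network with community
#' clustering, cluster categorisation, identity propagation and viral LCA
#' labels; SAG filtering; per-SAG summaries; association statistics
#' (contingency chi-square per flag, ANOVA + Tukey letters on viral contig
#' counts); and the co-sorting expectation report. In synthetic mode the
#' planted truth is carried through and classification performance against
#' it is included. Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param cfg a [run_config()].
#' @return object of class `run_report`: list with elements `sags`,
#'   `mapping`, `evidence`, `calls`, `distances`, `membership`,
#'   `categorized`, `retained_sags`, `interphylum`, `summary`, `tests`,
#'   `cosort`, `performance` (synthetic mode), `report` (the JSON-ready
#'   summary).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$sim)) {
    pool <- generate_genome_pool(cfg$sim)
    sim <- simulate_sag_set(cfg$sim, pool)
    evidence <- emit_evidence_tables(sim, pool, cfg$sim)
    contigs <- sim$contigs
    mapping <- sim$truth[, c("contig_id", "sag_id")]
    sag_taxa <- sim$sags
    refs <- reference_contigs(pool)
    truth <- sim$truth
    training <- default_training_set()
    cosort_conc <- cfg$sim$virus_concentration
    cosort_vol <- cfg$sim$drop_volume
  } else {
    inp <- cfg$inputs
    for (req in c("fasta_dir", "orf_hits", "recruitment", "ssdna_hits",
                  "external_viral", "vog_lca", "nt_check", "taxonomy")) {
      if (is.null(inp[[req]]) || !file.exists(inp[[req]]))
        stop(sprintf("input stage: missing required input '%s'", req))
    }
    fa <- read_sag_fastas(inp$fasta_dir)
    contigs <- fa$contigs
    mapping <- fa$mapping
    evidence <- list(
      orf_hits = parse_hits_tsv(inp$orf_hits),
      recruitment = utils::read.delim(inp$recruitment, stringsAsFactors = FALSE),
      ssdna_hits = utils::read.delim(inp$ssdna_hits, stringsAsFactors = FALSE),
      external_viral = utils::read.delim(inp$external_viral,
                                         stringsAsFactors = FALSE),
      vog_lca = utils::read.delim(inp$vog_lca, stringsAsFactors = FALSE),
      marker_16s = if (!is.null(inp$marker_16s) && file.exists(inp$marker_16s))
        utils::read.delim(inp$marker_16s, stringsAsFactors = FALSE) else
          data.frame(contig_id = character(), stringsAsFactors = FALSE),
      nt_check = utils::read.delim(inp$nt_check, stringsAsFactors = FALSE))
    sag_taxa <- utils::read.delim(inp$taxonomy, stringsAsFactors = FALSE)
    refs <- if (!is.null(inp$bacterial_ref_fasta)) {
      ss <- Biostrings::readDNAStringSet(inp$bacterial_ref_fasta)
      stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    } else character(0)
    truth <- NULL
    training <- if (!is.null(inp$training))
      utils::read.delim(inp$training, stringsAsFactors = FALSE) else
        default_training_set()
    cosort_conc <- 0.05; cosort_vol <- 21
  }

  # sketching
  all_seqs <- c(contigs, refs)
  sketches <- sketch_contigs(all_seqs, k = cfg$k, s = cfg$s,
                             hash_seed = cfg$hash_seed)
  records <- pairwise_distances(sketches, threshold = cfg$mash_threshold)

  ref_ids <- names(refs)
  lens <- stats::setNames(nchar(contigs), names(contigs))
  ev_tab <- build_contig_evidence(
    names(contigs), lens, evidence,
    ref_records = records, bacterial_ref_ids = ref_ids,
    training = training, knn_k = cfg$knn_k, top_n = cfg$top_n,
    mash_threshold = cfg$mash_threshold)
  calls <- classify_contigs(ev_tab, p_thresh = cfg$p_thresh, alpha = cfg$alpha)

  node_meta <- rbind(
    data.frame(contig_id = names(contigs),
               sag_id = mapping$sag_id[match(names(contigs), mapping$contig_id)],
               source_type = "protist", stringsAsFactors = FALSE),
    if (length(ref_ids) > 0)
      data.frame(contig_id = ref_ids, sag_id = "bacterial_reference",
                 source_type = "bacterial_ref", stringsAsFactors = FALSE))
  g <- build_contig_graph(records, node_meta, threshold = cfg$mash_threshold)
  membership <- detect_clusters(g, seed = cfg$seed, method = cfg$clustering)
  categorized <- categorize_clusters(
    membership, calls, node_meta,
    ref16s_ids = evidence$marker_16s$contig_id,
    vog_lca = evidence$vog_lca,
    viral_frac_min = cfg$viral_frac_min, min_freq = cfg$min_freq)
  retained <- filter_sags(categorized$contigs, mapping)
  ip <- interphylum_clusters(categorized, mapping, sag_taxa)
  summary <- build_summary(retained, categorized, mapping, sag_taxa, ip,
                           phage_lineages = cfg$phage_lineages)

  tests <- list()
  for (flag in c("has_virus", "has_bacteriophage", "has_interphylum_virus")) {
    tests[[flag]] <- tryCatch({
      tab <- contingency_by_taxon(summary, flag)
      chi_square_test(tab)[c("statistic", "dof", "p_value", "n")]
    }, error = function(e) list(statistic = NA, dof = NA, p_value = NA,
                                n = NA, note = conditionMessage(e)))
  }
  counts_by_taxon <- split(summary$n_viral_contigs, summary$taxon)
  counts_by_taxon <- counts_by_taxon[lengths(counts_by_taxon) > 0]
  anova_res <- tryCatch({
    a <- one_way_anova(unname(counts_by_taxon))
    tk <- tukey_hsd(counts_by_taxon, alpha = 0.05)
    list(anova = a, tukey_letters = tk$letters)
  }, error = function(e) list(note = conditionMessage(e)))

  cosort <- cosort_bounds(
    cosort_vol, c(0.01, 0.1),
    observed_prevalence = stats::setNames(
      vapply(split(summary$has_virus, summary$taxon), mean, numeric(1)),
      names(split(summary$has_virus, summary$taxon))))

  performance <- NULL
  if (!is.null(truth)) {
    truth_cat <- c(eukaryote = "eukaryote", bacterium = "bacterial",
                   dsDNA_phage = "viral", ssDNA_virus = "viral")[
                     truth$origin_class]
    pred <- categorized$contigs$category[match(truth$contig_id,
                                               categorized$contigs$contig_id)]
    performance <- classification_performance(truth_cat, pred)
  }

  prevalence <- vapply(split(summary$has_virus, summary$taxon), mean,
                       numeric(1))
  report <- list(
    tool = "virlink",
    version = as.character(utils::packageVersion("virlink")),
    config_hash = config_hash(cfg),
    n_sags = length(unique(mapping$sag_id)),
    n_sags_retained = length(retained),
    n_contigs = length(contigs),
    n_clusters = nrow(categorized$clusters),
    prevalence_by_taxon = as.list(prevalence),
    contingency_tests = tests,
    anova = anova_res,
    interphylum_clusters = ip$interphylum$cluster_id,
    cosort_lambda = cosort$table$lambda,
    cosort_p_at_least_one = cosort$table$p_at_least_one,
    performance = performance)

  out <- structure(list(
    sags = sag_taxa, mapping = mapping, evidence = evidence,
    contig_evidence = ev_tab, calls = calls, distances = records,
    membership = membership, categorized = categorized,
    retained_sags = retained, interphylum = ip, summary = summary,
    tests = tests, anova = anova_res, cosort = cosort, truth = truth,
    performance = performance, report = report), class = "run_report")

  if (!is.null(cfg$out_dir)) write_run_outputs(out, cfg$out_dir)
  out
}

#' Per-class precision/recall and macro F1
#'
#' @param truth,pred character vectors of true and predicted categories.
#' @return list with per-class precision, recall, F1 and `macro_f1`.
#' @export
classification_performance <- function(truth, pred) {
  classes <- sort(unique(truth))
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      0 else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1)
  })
  names(per) <- classes
  list(per_class = per,
       macro_f1 = mean(vapply(per, `[[`, numeric(1), "f1")),
       accuracy = mean(truth == pred))
}

#' Parse an ORF hit table
#'
#' Reads the tab-separated ORF hit dialect (columns contig_id, orf_index,
#' hit_rank, hit_description, percent_identity, alignment_fraction, evalue,
#' bitscore, subject_class), validating types and ranges; malformed rows are
#' reported with their line number. Write and re-read round-trips to an
#' identical table.
#'
#' @param path TSV file with a header row.
#' @return data.frame.
#' @export
parse_hits_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("contig_id", "orf_index", "hit_rank", "hit_description",
           "percent_identity", "alignment_fraction", "evalue", "bitscore",
           "subject_class")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(df)
  bad <- function(cond, what) {
    w <- which(cond)
    if (length(w) > 0)
      stop(sprintf("%s at line %d of %s", what, w[1] + 1L, path))
  }
  bad(is.na(df$percent_identity) | df$percent_identity < 0 |
        df$percent_identity > 100, "percent_identity outside [0, 100]")
  bad(is.na(df$alignment_fraction) | df$alignment_fraction < 0 |
        df$alignment_fraction > 1, "alignment_fraction outside [0, 1]")
  bad(is.na(df$evalue) | df$evalue < 0, "negative or missing e-value")
  bad(is.na(df$hit_rank) | df$hit_rank < 1, "hit_rank below 1")
  df
}

#' @rdname parse_hits_tsv
#' @param df hit table to write.
#' @export
write_hits_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every stage output of a pipeline run
#'
#' Emits the stage tables (`contig_calls.tsv`, `distances.tsv`,
#' `clusters.tsv`, `interphylum.tsv`, `network_edges.tsv`, `summary.tsv`,
#' `table1.tsv`) plus `report.json` under `dir`.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls_out <- merge(run$calls,
                     run$contig_evidence[, c("contig_id", "viral_orf_fraction",
                                             "recruitment_ratio",
                                             "knn_probability", "knn_pvalue")],
                     by = "contig_id", sort = TRUE)
  write_tsv_plain(calls_out, file.path(dir, "contig_calls.tsv"))
  write_tsv_plain(run$distances, file.path(dir, "distances.tsv"))
  cl <- merge(run$categorized$contigs,
              run$categorized$clusters[, c("cluster_id", "lca_label")],
              by = "cluster_id", sort = TRUE)
  write_tsv_plain(cl, file.path(dir, "clusters.tsv"))
  write_tsv_plain(run$interphylum$interphylum, file.path(dir, "interphylum.tsv"))
  write_tsv_plain(run$interphylum$edges, file.path(dir, "network_edges.tsv"))
  write_tsv_plain(run$summary, file.path(dir, "summary.tsv"))
  t1 <- do.call(rbind, lapply(names(run$tests), function(nm) {
    t <- run$tests[[nm]]
    data.frame(test = nm, statistic = as.numeric(t$statistic),
               dof = as.numeric(t$dof), p_value = as.numeric(t$p_value),
               n = as.numeric(t$n), stringsAsFactors = FALSE)
  }))
  write_tsv_plain(t1, file.path(dir, "table1.tsv"))
  write_report(run$report, file.path(dir, "report.json"))
  invisible(dir)
}

#' Write the machine-readable run report
#'
#' Stable key order (as constructed), floats rounded to six significant
#' digits, includes the tool version and config hash; identical runs write
#' byte-identical JSON.
#'
#' @param report the `report` element of a [run_pipeline()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  rounded <- rapply(report, function(x)
    if (is.double(x)) signif(x, 6) else x, how = "replace")
  jsonlite::write_json(rounded, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
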