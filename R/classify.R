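#' Viral gene description lexicon
#'
#' Terms whose presence (as a whole word, with an optional plural suffix) in
#' an ORF hit description marks the hit as putatively viral. The conventional
#' screening list of phage/virus structural and lytic terms, deduplicated.
#'
#' @return character vector of lexicon terms.
#' @export
viral_term_lexicon <- function() {
  c("phage", "virus", "prophage", "terminase", "t4-like", "lambda-like",
    "mu-like", "capsid", "tail", "fiber", "lambdoid", "portal", "virion",
    "lysis", "podovirus", "podo-like", "head", "baseplate", "myovirus",
    "siphovirus", "structural")
}

# Whole-word, case-insensitive matcher with optional (e)s plural, so that
# e.g. "viruses of archaea" matches the term "virus".
matches_viral_term <- function(descriptions, lexicon = viral_term_lexicon()) {
  esc <- gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", lexicon, perl = TRUE)
  pat <- paste0("\\b(", paste(esc, collapse = "|"), ")(es|s)?\\b")
  grepl(pat, descriptions, ignore.case = TRUE, perl = TRUE)
}

#' Fraction of viral ORFs on a contig
#'
#' An ORF counts as viral if any of its nr-class hits with rank at most
#' `top_n` carries a lexicon term in its description. Returns the fraction of
#' the contig's ORFs that are viral, or `NA` if the contig has no ORFs with
#' nr-class hits (undefined, not zero).
#'
#' @param hits ORF hit table (data.frame with columns contig_id, orf_index,
#'   hit_rank, hit_description, percent_identity, alignment_fraction,
#'   subject_class).
#' @param contig_id contig to score.
#' @param lexicon viral term list; default [viral_term_lexicon()].
#' @param top_n hit-rank cutoff (default 10).
#' @return fraction in \[0,1\], or NA.
#' @export
viral_orf_fraction <- function(hits, contig_id, lexicon = viral_term_lexicon(),
                               top_n = 10L) {
  stopifnot(top_n >= 1L)
  h <- hits[hits$contig_id == contig_id & hits$subject_class == "nr", ,
            drop = FALSE]
  if (nrow(h) == 0L) return(NA_real_)
  viral <- h$hit_rank <= top_n & matches_viral_term(h$hit_description, lexicon)
  orf_viral <- tapply(viral, h$orf_index, any)
  mean(orf_viral)
}

#' Standardised virome-vs-bacterial recruitment ratio
#'
#' log10 of the pseudocounted, per-million-scaled ratio of reads recruited
#' from the viral metagenome versus the bacterial metagenome. Positive values
#' indicate virome enrichment; equal per-million recruitment gives 0.
#'
#' @param viral_reads,bacterial_reads read counts recruited to the contig.
#' @param viral_metagenome_size,bacterial_metagenome_size total reads in each
#'   metagenome (must be positive).
#' @return log10 ratio (vectorised).
#' @export
recruitment_ratio <- function(viral_reads, bacterial_reads,
                              viral_metagenome_size,
                              bacterial_metagenome_size) {
  if (any(viral_metagenome_size <= 0) || any(bacterial_metagenome_size <= 0))
    stop("metagenome sizes must be positive")
  log10(((viral_reads + 1) / (viral_metagenome_size / 1e6)) /
          ((bacterial_reads + 1) / (bacterial_metagenome_size / 1e6)))
}

#' k-nearest-neighbour viral score
#'
#' Features (viral ORF fraction, recruitment ratio) are z-scored using the
#' training set's means and standard deviations; neighbours are found under
#' the Euclidean metric. Ties at the k-th distance are resolved by taking all
#' tied points and renormalising. The probability is the fraction of
#' neighbours labelled viral; the p-value is the exact binomial upper-tail
#' probability of at least the observed number of viral neighbours under the
#' training-set viral base rate.
#'
#' @param point numeric length-2: (viral_orf_fraction, recruitment_ratio).
#' @param training data.frame with columns `viral_orf_fraction`,
#'   `recruitment_ratio`, `label` (values "viral"/"nonviral").
#' @param k number of neighbours (1 <= k <= nrow(training)).
#' @return list with `probability` and `p_value`.
#' @export
knn_viral_score <- function(point, training, k = 5L) {
  stopifnot(is.numeric(point), length(point) == 2L)
  if (k < 1L || k > nrow(training)) stop("k must lie in [1, nrow(training)]")
  labs <- training$label
  if (!all(c("viral", "nonviral") %in% labs))
    stop("training set must contain both labels")
  X <- cbind(training$viral_orf_fraction, training$recruitment_ratio)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) stop("zero feature standard deviation in training set")
  Z <- scale(X, center = mu, scale = sdv)
  z <- (point - mu) / sdv
  d <- sqrt((Z[, 1] - z[1])^2 + (Z[, 2] - z[2])^2)
  kth <- sort(d, partial = k)[k]
  sel <- which(d <= kth)   # includes all points tied at the k-th distance
  n_considered <- length(sel)
  n_viral <- sum(labs[sel] == "viral")
  base_rate <- mean(labs == "viral")
  p_value <- stats::pbinom(n_viral - 1L, n_considered, base_rate,
                           lower.tail = FALSE)
  list(probability = n_viral / n_considered, p_value = p_value)
}

#' ssDNA-virus flag from alignment coverage
#'
#' TRUE iff the contig is shorter than `max_len` and the union of aligned
#' spans from hits with e-value below `evalue_max` covers at least
#' `min_cover` of the contig length (overlapping spans merged before
#' summing).
#'
#' @param spans data.frame with columns `span_start`, `span_end`, `evalue`
#'   (rows are this contig's ssDNA alignment hits; may be empty).
#' @param contig_length contig length in bp.
#' @param max_len length cap in bp (default 10000).
#' @param min_cover minimum covered fraction (default 0.2).
#' @param evalue_max e-value cutoff (default 1e-5).
#' @return logical.
#' @export
ssdna_flag <- function(spans, contig_length, max_len = 10000L,
                       min_cover = 0.2, evalue_max = 1e-5) {
  if (contig_length >= max_len) return(FALSE)
  if (nrow(spans) == 0L) return(FALSE)
  if (any(spans$span_start < 0 | spans$span_end < 0))
    stop("negative alignment spans")
  if (any(spans$span_end > contig_length))
    stop("alignment span beyond contig end")
  s <- spans[spans$evalue < evalue_max, , drop = FALSE]
  if (nrow(s) == 0L) return(FALSE)
  s <- s[order(s$span_start), , drop = FALSE]
  covered <- 0; cur_s <- s$span_start[1]; cur_e <- s$span_end[1]
  if (nrow(s) > 1L) for (i in 2:nrow(s)) {
    if (s$span_start[i] <= cur_e) {
      cur_e <- max(cur_e, s$span_end[i])
    } else {
      covered <- covered + (cur_e - cur_s + 1)
      cur_s <- s$span_start[i]; cur_e <- s$span_end[i]
    }
  }
  covered <- covered + (cur_e - cur_s + 1)
  (covered / contig_length) >= min_cover
}

#' Bacterial call by reference-sketch match
#'
#' TRUE iff any distance record links the contig to a bacterial reference
#' contig at a Mash distance at or below the threshold.
#'
#' @param records data.frame of distance records (`contig_a`, `contig_b`,
#'   `distance`).
#' @param contig_id contig to test.
#' @param bacterial_ref_ids character vector of reference contig ids.
#' @param threshold inclusive distance cutoff (default 0.05).
#' @return logical.
#' @export
bacterial_by_reference <- function(records, contig_id, bacterial_ref_ids,
                                   threshold = 0.05) {
  if (nrow(records) == 0L) return(FALSE)
  hit <- (records$contig_a == contig_id & records$contig_b %in% bacterial_ref_ids) |
         (records$contig_b == contig_id & records$contig_a %in% bacterial_ref_ids)
  any(hit & records$distance <= threshold)
}

#' Bacterial call by ORF majority against bacterial reference proteins
#'
#' TRUE iff strictly more than half of the contig's ORFs have a
#' RefSeq-bacteria hit with identity above 50 and alignment fraction above
#' 0.75, and the nucleotide-level verification of the contig is "bacterial"
#' (ruling out organellar sequence).
#'
#' @param hits ORF hit table (see [viral_orf_fraction()]).
#' @param contig_id contig to test.
#' @param nt_verification one of "bacterial", "organellar", "unknown".
#' @return logical.
#' @export
bacterial_by_orf_majority <- function(hits, contig_id, nt_verification) {
  h <- hits[hits$contig_id == contig_id, , drop = FALSE]
  if (nrow(h) == 0L) return(FALSE)
  n_orf <- length(unique(h$orf_index))
  b <- h[h$subject_class == "refseq_bacteria" &
           h$percent_identity > 50 & h$alignment_fraction > 0.75, , drop = FALSE]
  n_bact <- length(unique(b$orf_index))
  (n_bact / n_orf > 0.5) && identical(nt_verification, "bacterial")
}

#' Assemble per-contig evidence
#'
#' Computes the full evidence bundle for every contig from the raw evidence
#' tables plus the reference-sketch distance records: viral ORF fraction,
#' recruitment ratio, kNN viral probability and p-value, external viral
#' category, ssDNA flag, both bacterial flags and the nt verification call.
#'
#' @param contig_ids contigs to score.
#' @param contig_lengths named lengths (bp) for `contig_ids`.
#' @param evidence an `evidence_set` (or equivalently named list of tables).
#' @param ref_records distance records against the bacterial reference set
#'   (may be empty).
#' @param bacterial_ref_ids reference contig ids.
#' @param training training set for the kNN score.
#' @param knn_k neighbours for the kNN score.
#' @param top_n hit-rank cutoff for the viral ORF fraction.
#' @param mash_threshold inclusive distance cutoff for the reference rule.
#' @param ssdna_max_len,ssdna_min_cover,ssdna_evalue_max ssDNA rule knobs.
#' @return data.frame, one row per contig (class `contig_evidence`).
#' @export
build_contig_evidence <- function(contig_ids, contig_lengths, evidence,
                                  ref_records = NULL,
                                  bacterial_ref_ids = character(0),
                                  training = default_training_set(),
                                  knn_k = 5L, top_n = 10L,
                                  mash_threshold = 0.05,
                                  ssdna_max_len = 10000L,
                                  ssdna_min_cover = 0.2,
                                  ssdna_evalue_max = 1e-5) {
  if (is.null(ref_records))
    ref_records <- data.frame(contig_a = character(), contig_b = character(),
                              distance = numeric(), stringsAsFactors = FALSE)
  rec <- evidence$recruitment
  ext <- evidence$external_viral
  nt <- evidence$nt_check
  out <- vector("list", length(contig_ids))
  for (i in seq_along(contig_ids)) {
    cid <- contig_ids[i]
    len <- contig_lengths[[cid]]
    vf <- viral_orf_fraction(evidence$orf_hits, cid, top_n = top_n)
    ri <- match(cid, rec$contig_id)
    rr <- if (is.na(ri)) NA_real_ else
      recruitment_ratio(rec$viral_reads[ri], rec$bacterial_reads[ri],
                        rec$viral_metagenome_size[ri],
                        rec$bacterial_metagenome_size[ri])
    if (!is.na(vf) && !is.na(rr)) {
      kn <- knn_viral_score(c(vf, rr), training, k = knn_k)
    } else {
      kn <- list(probability = NA_real_, p_value = NA_real_)
    }
    ei <- match(cid, ext$contig_id)
    ext_cat <- if (is.na(ei)) "none" else as.character(ext$category[ei])
    spans <- evidence$ssdna_hits[evidence$ssdna_hits$contig_id == cid, ,
                                 drop = FALSE]
    ssf <- ssdna_flag(spans, len, max_len = ssdna_max_len,
                      min_cover = ssdna_min_cover,
                      evalue_max = ssdna_evalue_max)
    ni <- match(cid, nt$contig_id)
    ntv <- if (is.na(ni)) "unknown" else nt$nt_verification[ni]
    out[[i]] <- data.frame(
      contig_id = cid,
      viral_orf_fraction = vf,
      recruitment_ratio = rr,
      knn_probability = kn$probability,
      knn_pvalue = kn$p_value,
      external_viral_category = ext_cat,
      ssdna_flag = ssf,
      bacterial_by_reference = bacterial_by_reference(
        ref_records, cid, bacterial_ref_ids, threshold = mash_threshold),
      bacterial_by_orf_majority = bacterial_by_orf_majority(
        evidence$orf_hits, cid, ntv),
      nt_verification = ntv,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("contig_evidence", class(res))
  res
}

#' Classify contigs from their evidence bundles
#'
#' Rule order mirrors the screening narrative, with viral evidence taking
#' precedence: a contig is viral if its kNN probability exceeds `p_thresh`
#' with p-value at most `alpha`, or its external viral category is 1 or 2, or
#' its ssDNA flag is set; otherwise bacterial if either bacterial rule fired;
#' otherwise eukaryote. The `basis` column records every rule that fired.
#'
#' @param evidence a [build_contig_evidence()] data.frame.
#' @param p_thresh kNN probability threshold (default 0.5, exclusive).
#' @param alpha kNN p-value threshold (default 0.05, inclusive).
#' @return data.frame with columns `contig_id`, `category`, `basis`.
#' @export
classify_contigs <- function(evidence, p_thresh = 0.5, alpha = 0.05) {
  n <- nrow(evidence)
  category <- character(n); basis <- character(n)
  for (i in seq_len(n)) {
    e <- evidence[i, ]
    fired <- character(0)
    if (!is.na(e$knn_probability) && !is.na(e$knn_pvalue) &&
        e$knn_probability > p_thresh && e$knn_pvalue <= alpha)
      fired <- c(fired, "knn_viral")
    if (e$external_viral_category %in% c("1", "2"))
      fired <- c(fired, "external_viral_category")
    if (isTRUE(e$ssdna_flag)) fired <- c(fired, "ssdna")
    if (length(fired) > 0) {
      category[i] <- "viral"
    } else {
      if (isTRUE(e$bacterial_by_reference))
        fired <- c(fired, "bacterial_by_reference")
      if (isTRUE(e$bacterial_by_orf_majority))
        fired <- c(fired, "bacterial_by_orf_majority")
      category[i] <- if (length(fired) > 0) "bacterial" else "eukaryote"
    }
    basis[i] <- paste(fired, collapse = ",")
  }
  data.frame(contig_id = evidence$contig_id, category = category,
             basis = basis, stringsAsFactors = FALSE)
}

#' Default kNN training set
#'
#' Built once from a small noiseless synthetic community with a fixed
#' internal seed: dsDNA phage contigs labelled viral, eukaryote and bacterial
#' contigs labelled nonviral (ssDNA viruses are excluded: the emulated
#' ORF/recruitment screens are blind to them, as their real counterparts
#' were). Users analysing real data should supply their own curated training
#' set on the same feature transform.
#'
#' @param n_per_label maximum points retained per label (default 100).
#' @return data.frame with columns `viral_orf_fraction`, `recruitment_ratio`,
#'   `label`.
#' @export
default_training_set <- function(n_per_label = 100L) {
  cached <- .virlink_cache$training
  if (!is.null(cached) && identical(attr(cached, "n_per_label"), n_per_label))
    return(cached)
  cfg <- sim_config(
    seed = 1009L,
    n_sags_per_lineage = c(TrainA = 15L, TrainB = 15L),
    lineage_grazing_rate = c(TrainA = 4, TrainB = 4),
    bacterial_prey_prob = c(TrainA = 0.8, TrainB = 0.8),
    plastidic = c(TrainA = FALSE, TrainB = TRUE),
    virus_concentration = 0, drop_volume = 21,
    n_virus_genomes = 10L, n_bacterial_genomes = 4L, n_euk_genomes = 6L,
    ssdna_fraction = 0,
    contig_length_range = list(eukaryote = c(1500L, 4000L),
                               bacterium = c(1500L, 4000L),
                               dsDNA_phage = c(2000L, 10000L),
                               ssDNA_virus = c(1000L, 2000L)),
    evidence_noise = list(fp = 0, fn = 0))
  pool <- generate_genome_pool(cfg)
  sim <- simulate_sag_set(cfg, pool)
  ev <- emit_evidence_tables(sim, pool, cfg)
  cids <- names(sim$contigs)
  origin <- sim$truth$origin_class[match(cids, sim$truth$contig_id)]
  vf <- vapply(cids, function(cid) viral_orf_fraction(ev$orf_hits, cid),
               numeric(1))
  rec <- ev$recruitment
  rr <- recruitment_ratio(rec$viral_reads, rec$bacterial_reads,
                          rec$viral_metagenome_size,
                          rec$bacterial_metagenome_size)[match(cids, rec$contig_id)]
  label <- ifelse(origin == "dsDNA_phage", "viral", "nonviral")
  df <- data.frame(viral_orf_fraction = vf, recruitment_ratio = rr,
                   label = label, stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), ]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$label),
                        function(ix) utils::head(ix, n_per_label)))
  df <- df[sort(keep), ]
  rownames(df) <- NULL
  attr(df, "n_per_label") <- n_per_label
  .virlink_cache$training <- df
  df
}

.virlink_cache <- new.env(parent = emptyenv())
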