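#' Per-SAG summary table
#'
#' One row per retained SAG: taxon, plastidic flag, whether the SAG contains
#' any viral contig, any bacteriophage contig (a viral contig whose cluster
#' LCA falls in `phage_lineages`), any inter-phylum viral contig, any
#' bacterial contig, and the number of distinct viral contigs.
#'
#' @param retained_sags SAG ids retained by [filter_sags()].
#' @param categorized [categorize_clusters()] output.
#' @param mapping data.frame (contig_id, sag_id) for protist contigs.
#' @param sag_taxa data.frame (sag_id, lineage, plastidic); SAGs missing from
#'   it get taxon "unidentified".
#' @param interphylum [interphylum_clusters()] output (or NULL).
#' @param phage_lineages cluster LCA labels counted as bacteriophage.
#'   Default Caudovirales (tailed dsDNA phages) and Microviridae (ssDNA
#'   phages).
#' @return data.frame of class `sag_summary`.
#' @export
build_summary <- function(retained_sags, categorized, mapping, sag_taxa,
                          interphylum = NULL,
                          phage_lineages = c("Caudovirales", "Microviridae")) {
  contigs <- categorized$contigs
  clusters <- categorized$clusters
  cl_lca <- clusters$lca_label[match(contigs$cluster_id, clusters$cluster_id)]
  ip_cl <- if (!is.null(interphylum)) interphylum$interphylum$cluster_id else
    character(0)
  rows <- vector("list", length(retained_sags))
  for (i in seq_along(retained_sags)) {
    sid <- retained_sags[i]
    cids <- mapping$contig_id[mapping$sag_id == sid]
    ix <- match(cids, contigs$contig_id)
    ix <- ix[!is.na(ix)]
    cat <- contigs$category[ix]
    lca <- cl_lca[ix]
    cl <- contigs$cluster_id[ix]
    viral <- cat == "viral"
    ti <- match(sid, sag_taxa$sag_id)
    rows[[i]] <- data.frame(
      sag_id = sid,
      taxon = if (is.na(ti)) "unidentified" else sag_taxa$lineage[ti],
      plastidic = if (is.na(ti) || is.null(sag_taxa$plastidic)) NA else
        sag_taxa$plastidic[ti],
      has_virus = any(viral),
      has_bacteriophage = any(viral & lca %in% phage_lineages),
      has_interphylum_virus = any(viral & cl %in% ip_cl),
      has_bacteria = any(cat == "bacterial"),
      n_viral_contigs = sum(viral),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("sag_summary", class(res))
  res
}

#' Contingency table of a summary flag by taxon
#'
#' Counts TRUE/FALSE per taxon for one of the logical summary columns. Taxa
#' with zero sampled SAGs are dropped (never kept as zero rows, which would
#' create zero marginals).
#'
#' @param summary a [build_summary()] data.frame.
#' @param flag one of "has_virus", "has_bacteriophage",
#'   "has_interphylum_virus", "has_bacteria".
#' @return integer matrix with taxa as rows and columns `TRUE`, `FALSE`.
#' @export
contingency_by_taxon <- function(summary, flag = "has_virus") {
  stopifnot(flag %in% names(summary))
  f <- factor(summary[[flag]], levels = c(TRUE, FALSE))
  tab <- table(summary$taxon, f)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), c("TRUE", "FALSE")))
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic sum((O - E)^2 / E) with expected counts from the
#' row and column marginals, dof = (r-1)(c-1), upper-tail p-value, and no
#' continuity correction regardless of table size.
#'
#' @param tab integer matrix (at least 2 rows and 2 columns, all cells >= 0).
#' @return list with `statistic`, `dof`, `p_value`, `expected`, `n`.
#' @examples
#' chi_square_test(rbind(c(20, 10), c(10, 20)))$statistic  # 20/3
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0)) stop("cells must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) {
    bad <- which(rs == 0)[1]
    stop(sprintf("zero marginal in row %s",
                 if (is.null(rownames(tab))) bad else rownames(tab)[bad]))
  }
  if (any(cs == 0)) {
    bad <- which(cs == 0)[1]
    stop(sprintf("zero marginal in column %s",
                 if (is.null(colnames(tab))) bad else colnames(tab)[bad]))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected,
       n = sum(tab))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square ratio over the supplied groups.
#' When every group has zero internal variance but the means differ, the F
#' statistic is infinite and is returned as `Inf` with `p_value` 0.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n > groups).
#' @return list with `F`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one value")
  n <- sum(lengths(groups))
  kg <- length(groups)
  if (n <= kg) stop("total n must exceed the number of groups")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_len(kg), lengths(groups)))
  a <- suppressWarnings(stats::anova(stats::lm(value ~ grp)))
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  dfb <- a$Df[1]; dfw <- a$Df[2]
  if (ssw <= 1e-10 * max(1, ssb)) {
    if (ssb > 1e-10) return(list(F = Inf, df_between = dfb,
                                 df_within = dfw, p_value = 0))
    return(list(F = 0, df_between = dfb, df_within = dfw, p_value = 1))
  }
  list(F = a$`F value`[1], df_between = dfb, df_within = dfw,
       p_value = a$`Pr(>F)`[1])
}

#' Tukey HSD with compact letter display
#'
#' Studentised-range pairwise comparisons (via [stats::TukeyHSD()]) followed
#' by a deterministic greedy letter assembly: every non-significant pair is
#' placed into a shared letter set, each set is extended with all further
#' groups non-significant against every member (in input order), and groups
#' sharing no letter differ at `alpha`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha family-wise significance level (default 0.05).
#' @return list with `pairwise` (data.frame: group_a, group_b, diff, p_adj,
#'   significant) and `letters` (data.frame: group, mean, letters).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  gnames <- names(groups)
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(gnames, lengths(groups)), levels = gnames)
  fit <- stats::aov(value ~ grp)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pair <- data.frame(group_a = vapply(cmp, `[`, character(1), 2),
                     group_b = vapply(cmp, `[`, character(1), 1),
                     diff = tk[, "diff"], p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  pair$significant <- pair$p_adj < alpha
  rownames(pair) <- NULL

  k <- length(gnames)
  sig <- matrix(FALSE, k, k, dimnames = list(gnames, gnames))
  for (r in seq_len(nrow(pair)))
    sig[pair$group_a[r], pair$group_b[r]] <-
      sig[pair$group_b[r], pair$group_a[r]] <- pair$significant[r]

  sets <- list()
  in_common_set <- function(i, j) {
    any(vapply(sets, function(s) i %in% s && j %in% s, logical(1)))
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!sig[i, j] && !in_common_set(i, j)) {
      s <- c(i, j)
      for (g in setdiff(seq_len(k), s))
        if (!any(sig[g, s])) s <- sort(c(s, g))
      sets[[length(sets) + 1L]] <- s
    }
  }
  lonely <- setdiff(seq_len(k), unlist(sets))
  for (g in lonely) sets[[length(sets) + 1L]] <- g
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letter_of <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  list(pairwise = pair,
       letters = data.frame(group = gnames,
                            mean = vapply(groups, mean, numeric(1)),
                            letters = letter_of,
                            stringsAsFactors = FALSE))
}

#' Mann-Whitney U test
#'
#' U for the first sample from midrank rank sums. The two-sided p-value is
#' exact whenever n1*n2 <= `exact_limit`: the full permutation null of U
#' under the observed (possibly tied) pooled values is computed by dynamic
#' programming over doubled midranks, which reproduces exhaustive
#' enumeration of all rank assignments. Larger samples use the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit use the exact null when n1*n2 is at most this
#'   (default 400).
#' @return list with `U` (for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 400L) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 * n2 <= exact_limit) {
    m <- min(n1, n2)
    r2 <- as.integer(round(2 * r))   # doubled midranks are integers
    maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
    # dp[i+1, s+1] = number of size-i subsets of the doubled ranks with sum s
    dp <- matrix(0, nrow = m + 1L, ncol = maxsum + 1L)
    dp[1L, 1L] <- 1
    for (v in r2) {
      upper <- min(m, nrow(dp) - 1L)
      for (i in upper:1L) {
        src <- seq_len(maxsum + 1L - v)
        dp[i + 1L, src + v] <- dp[i + 1L, src + v] + dp[i, src]
      }
    }
    counts <- dp[m + 1L, ]
    sums <- (seq_along(counts) - 1L) / 2       # undouble
    u_all <- sums - m * (m + 1) / 2            # U of the smaller sample
    dev <- abs(u_all - mu)
    dev_obs <- abs(U - mu)
    p <- sum(counts[dev >= dev_obs - 1e-9]) / sum(counts)
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  tie <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Published contingency tables for SAG virus prevalence
#'
#' The literature-reported contingency tables of virus presence by protist
#' taxon used as worked examples and reference inputs: Gulf of Maine
#' (contains virus, contains bacteriophage, contains inter-phylum virus; six
#' taxa) and Mediterranean (contains virus, contains bacteriophage; three
#' taxa), with the statistic each source printed. The GoM bacteriophage and
#' inter-phylum tables are flagged: their printed statistics do not match a
#' plain Pearson recomputation of their own printed cells.
#'
#' @return named list of integer matrices; each carries attributes
#'   `printed_statistic`, `printed_dof` and `consistent` (whether the printed
#'   statistic matches plain Pearson recomputation of the printed cells).
#' @export
published_contingency_tables <- function() {
  mk <- function(cells, taxa, stat, dof, consistent) {
    m <- matrix(as.integer(cells), ncol = 2, byrow = TRUE,
                dimnames = list(taxa, c("TRUE", "FALSE")))
    attr(m, "printed_statistic") <- stat
    attr(m, "printed_dof") <- dof
    attr(m, "consistent") <- consistent
    m
  }
  gom_taxa <- c("Alveolata", "Stramenopile", "Chlorophyta/Prasinophyta",
                "Cercozoa", "Choanozoa", "Picozoa")
  med_taxa <- c("Stramenopile", "Chlorophyta/Prasinophyta", "Haptophyta")
  list(
    gom_contains_virus = mk(c(22, 75, 36, 55, 32, 19, 14, 16, 13, 0, 9, 0),
                            gom_taxa, 54.12, 5L, TRUE),
    gom_contains_bacteriophage = mk(c(16, 81, 25, 66, 24, 27, 8, 22, 13, 0, 8, 1),
                                    gom_taxa, 56.54, 5L, FALSE),
    gom_contains_interphylum = mk(c(7, 90, 8, 83, 8, 43, 4, 26, 13, 0, 8, 1),
                                  gom_taxa, 107.43, 5L, FALSE),
    med_contains_virus = mk(c(19, 22, 15, 26, 2, 7), med_taxa, 2.07, 2L, TRUE),
    med_contains_bacteriophage = mk(c(8, 33, 7, 34, 1, 8), med_taxa, 0.37, 2L,
                                    TRUE)
  )
}
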