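#' Build the contig similarity graph
#'
#' Undirected graph whose nodes are contigs (protist SAG contigs plus
#' bacterial reference contigs) and whose edges are pairs at a Mash distance
#' at or below the threshold, weighted by 1 - distance. Contigs without any
#' qualifying pair are kept as isolated nodes. Node order is canonicalised
#' (sorted contig ids) so downstream community detection is reproducible.
#'
#' @param records distance records ([pairwise_distances()] output).
#' @param node_meta data.frame with columns `contig_id`, `sag_id`,
#'   `source_type` ("protist" or "bacterial_ref") covering every node.
#' @param threshold inclusive Mash distance cutoff (default 0.05).
#' @return an igraph object with vertex attributes `sag_id`, `source_type`.
#' @export
build_contig_graph <- function(records, node_meta, threshold = 0.05) {
  stopifnot(all(c("contig_id", "sag_id", "source_type") %in% names(node_meta)))
  unknown <- setdiff(c(records$contig_a, records$contig_b), node_meta$contig_id)
  if (length(unknown) > 0)
    stop(sprintf("distance record references unknown contig: %s", unknown[1]))
  keep <- records$distance <= threshold & records$contig_a != records$contig_b
  edges <- records[keep, , drop = FALSE]
  verts <- node_meta[order(node_meta$contig_id),
                     c("contig_id", "sag_id", "source_type")]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$contig_a, to = edges$contig_b,
                   weight = 1 - edges$distance, distance = edges$distance,
                   stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Detect contig clusters
#'
#' Louvain modularity optimisation (default) with a fixed RNG seed on the
#' canonically ordered graph, or plain connected components, which
#' reproduces single-linkage clustering. Every node lands in exactly one
#' cluster and clusters never span connected components; isolated nodes form
#' singleton clusters. Cluster ids are renumbered by their smallest member
#' contig id so labels are stable.
#'
#' @param g graph from [build_contig_graph()].
#' @param seed RNG seed for the community search (default 1).
#' @param method "louvain" or "components".
#' @return data.frame with columns `contig_id`, `cluster_id`.
#' @export
detect_clusters <- function(g, seed = 1L, method = c("louvain", "components")) {
  method <- match.arg(method)
  ids <- igraph::V(g)$name
  if (length(ids) == 0L)
    return(data.frame(contig_id = character(), cluster_id = character(),
                      stringsAsFactors = FALSE))
  if (method == "louvain") {
    set.seed(seed)
    w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
    memb <- igraph::membership(igraph::cluster_louvain(g, weights = w))
  } else {
    memb <- igraph::components(g)$membership
  }
  first_id <- tapply(ids, memb, min)
  rank <- match(memb, names(sort(first_id)))
  data.frame(contig_id = ids,
             cluster_id = sprintf("CL%04d", rank),
             stringsAsFactors = FALSE)
}

#' Viral LCA label for one contig
#'
#' Takes the per-ORF LCA labels of a viral contig (ORFs without a hit carry
#' label "none") and returns the most represented label if its frequency
#' over all ORFs reaches `min_freq`, otherwise the generic label "Viral".
#' "none" is never returned; ties between equally frequent labels are broken
#' lexicographically. A contig with zero ORFs is labelled "Viral".
#'
#' @param lca_labels character vector of per-ORF labels.
#' @param min_freq minimum modal frequency (default 0.25, inclusive).
#' @return a single label.
#' @export
assign_contig_lca <- function(lca_labels, min_freq = 0.25) {
  if (length(lca_labels) == 0L) return("Viral")
  n <- length(lca_labels)
  tab <- table(lca_labels[lca_labels != "none"])
  if (length(tab) == 0L) return("Viral")
  tab <- sort(tab, decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  best <- sort(top)[1]
  if (tab[[best]] / n >= min_freq) best else "Viral"
}

#' Categorise clusters and propagate identities
#'
#' A cluster is viral if at least `viral_frac_min` of its member contigs were
#' called viral; otherwise bacterial if it contains a bacterial reference
#' contig, a member carrying a bacterial 16S marker, or a member flagged
#' bacterial by the ORF-majority rule; otherwise eukaryote. The cluster
#' category is propagated back to every member contig. Viral clusters
#' additionally receive an LCA label: each member contig is labelled via
#' [assign_contig_lca()] and the cluster takes the most frequent informative
#' member label (falling back to "Viral").
#'
#' @param membership [detect_clusters()] output.
#' @param calls [classify_contigs()] output covering every protist member.
#' @param node_meta node metadata as in [build_contig_graph()].
#' @param ref16s_ids contig ids carrying bacterial 16S markers.
#' @param vog_lca per-ORF LCA table (contig_id, orf_index, lca_label).
#' @param viral_frac_min viral member fraction threshold (default 0.25,
#'   inclusive).
#' @param min_freq LCA modal frequency threshold (default 0.25).
#' @return list with `clusters` (cluster_id, n_members, n_sags,
#'   viral_fraction, category, lca_label) and `contigs` (contig_id,
#'   cluster_id, category): the propagated per-contig categories.
#' @export
categorize_clusters <- function(membership, calls, node_meta,
                                ref16s_ids = character(0),
                                vog_lca = NULL,
                                viral_frac_min = 0.25, min_freq = 0.25) {
  call_of <- calls$category[match(membership$contig_id, calls$contig_id)]
  src <- node_meta$source_type[match(membership$contig_id, node_meta$contig_id)]
  is_ref <- src == "bacterial_ref"
  missing_call <- membership$contig_id[is.na(call_of) & !is_ref]
  if (length(missing_call) > 0)
    stop(sprintf("no contig call for %s", missing_call[1]))
  call_of[is_ref] <- "reference"
  bact_orf <- calls$contig_id[grepl("bacterial_by_orf_majority", calls$basis)]

  sag_of <- node_meta$sag_id[match(membership$contig_id, node_meta$contig_id)]
  cl_ids <- sort(unique(membership$cluster_id))
  rows <- vector("list", length(cl_ids))
  contig_cat <- character(nrow(membership))
  for (i in seq_along(cl_ids)) {
    cl <- cl_ids[i]
    sel <- membership$cluster_id == cl
    members <- membership$contig_id[sel]
    vf <- mean(call_of[sel] == "viral")
    if (vf >= viral_frac_min) {
      cat <- "viral"
    } else if (any(is_ref[sel]) || any(members %in% ref16s_ids) ||
               any(members %in% bact_orf)) {
      cat <- "bacterial"
    } else {
      cat <- "eukaryote"
    }
    lca <- NA_character_
    if (cat == "viral") {
      if (!is.null(vog_lca) && nrow(vog_lca) > 0) {
        member_lca <- vapply(members, function(cid) {
          assign_contig_lca(vog_lca$lca_label[vog_lca$contig_id == cid],
                            min_freq = min_freq)
        }, character(1))
        informative <- member_lca[member_lca != "Viral"]
        lca <- if (length(informative) > 0) {
          tab <- sort(table(informative), decreasing = TRUE)
          sort(names(tab)[tab == max(tab)])[1]
        } else "Viral"
      } else {
        lca <- "Viral"
      }
    }
    contig_cat[sel] <- cat
    rows[[i]] <- data.frame(
      cluster_id = cl, n_members = sum(sel),
      n_sags = length(unique(sag_of[sel])),
      viral_fraction = vf, category = cat, lca_label = lca,
      stringsAsFactors = FALSE)
  }
  list(clusters = do.call(rbind, rows),
       contigs = data.frame(contig_id = membership$contig_id,
                            cluster_id = membership$cluster_id,
                            category = contig_cat,
                            stringsAsFactors = FALSE))
}

#' Filter SAGs that retain eukaryotic sequence
#'
#' SAGs whose contigs were all identified as viral or bacterial are dropped;
#' a SAG is retained iff at least one of its contigs carries the eukaryote
#' category after propagation.
#'
#' @param contig_categories propagated per-contig categories
#'   (`contigs` element of [categorize_clusters()]).
#' @param mapping data.frame (contig_id, sag_id) for protist contigs.
#' @return character vector of retained SAG ids.
#' @export
filter_sags <- function(contig_categories, mapping) {
  cat_of <- contig_categories$category[match(mapping$contig_id,
                                             contig_categories$contig_id)]
  keep <- tapply(cat_of == "eukaryote", mapping$sag_id, any)
  sort(names(keep)[keep])
}

#' Inter-phylum viral clusters
#'
#' Viral clusters whose member contigs occur in SAGs of at least two
#' distinct identified phyla. SAGs with taxon "unidentified" never count
#' toward the phylum tally but are still listed among the cluster's SAGs.
#' Also returns the bipartite SAG-virus edge list for network plots.
#'
#' @param categorized [categorize_clusters()] output.
#' @param mapping data.frame (contig_id, sag_id) for protist contigs.
#' @param sag_taxa data.frame (sag_id, lineage); missing SAGs are treated as
#'   "unidentified".
#' @return list with `interphylum` (cluster_id, lca_label, n_phyla, phyla,
#'   sags) and `edges` (sag_id, cluster_id).
#' @export
interphylum_clusters <- function(categorized, mapping, sag_taxa) {
  clusters <- categorized$clusters
  contigs <- categorized$contigs
  viral_cl <- clusters$cluster_id[clusters$category == "viral"]
  edge_rows <- list(); ip_rows <- list()
  for (cl in viral_cl) {
    members <- contigs$contig_id[contigs$cluster_id == cl]
    sags <- unique(stats::na.omit(
      mapping$sag_id[match(members, mapping$contig_id)]))
    if (length(sags) == 0L) next
    taxa <- sag_taxa$lineage[match(sags, sag_taxa$sag_id)]
    taxa[is.na(taxa)] <- "unidentified"
    for (s in sags)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        sag_id = s, cluster_id = cl, stringsAsFactors = FALSE)
    identified <- unique(taxa[taxa != "unidentified"])
    if (length(identified) >= 2L) {
      lca <- clusters$lca_label[clusters$cluster_id == cl]
      ip_rows[[length(ip_rows) + 1L]] <- data.frame(
        cluster_id = cl, lca_label = lca,
        n_phyla = length(identified),
        phyla = paste(sort(identified), collapse = ";"),
        sags = paste(sort(sags), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  empty_ip <- data.frame(cluster_id = character(), lca_label = character(),
                         n_phyla = integer(), phyla = character(),
                         sags = character(), stringsAsFactors = FALSE)
  empty_e <- data.frame(sag_id = character(), cluster_id = character(),
                        stringsAsFactors = FALSE)
  list(interphylum = if (length(ip_rows) > 0) do.call(rbind, ip_rows) else empty_ip,
       edges = if (length(edge_rows) > 0) do.call(rbind, edge_rows) else empty_e)
}
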