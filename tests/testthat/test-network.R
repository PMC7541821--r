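meta_for <- function(ids, sag = "S1", type = "protist") {
  data.frame(contig_id = ids, sag_id = sag, source_type = type,
             stringsAsFactors = FALSE)
}

rec_df <- function(a, b, d) {
  data.frame(contig_a = a, contig_b = b, jaccard = 1 - d, distance = d,
             stringsAsFactors = FALSE)
}

test_that("graph construction keeps isolated nodes and the inclusive cutoff", {
  meta <- meta_for(c("a", "b", "c"))
  g0 <- build_contig_graph(rec_df(character(0), character(0), numeric(0)), meta)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)
  g1 <- build_contig_graph(rec_df("a", "b", 0.05), meta)
  expect_equal(igraph::ecount(g1), 1)
  g2 <- build_contig_graph(rec_df("a", "b", 0.051), meta)
  expect_equal(igraph::ecount(g2), 0)
  expect_error(build_contig_graph(rec_df("a", "zz", 0.01), meta), "unknown")
})

test_that("community detection separates disjoint cliques and isolates", {
  ids <- c(paste0("x", 1:4), paste0("y", 1:4), "lone")
  pairs1 <- t(utils::combn(paste0("x", 1:4), 2))
  pairs2 <- t(utils::combn(paste0("y", 1:4), 2))
  rec <- rec_df(c(pairs1[, 1], pairs2[, 1]), c(pairs1[, 2], pairs2[, 2]), 0.01)
  g <- build_contig_graph(rec, meta_for(ids))
  memb <- detect_clusters(g, seed = 1)
  expect_setequal(memb$contig_id, ids)
  cl_of <- stats::setNames(memb$cluster_id, memb$contig_id)
  expect_equal(length(unique(cl_of[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(cl_of[paste0("y", 1:4)])), 1)
  expect_false(cl_of[["x1"]] == cl_of[["y1"]])
  expect_false(cl_of[["lone"]] %in% cl_of[c(paste0("x", 1:4), paste0("y", 1:4))])
  # single-linkage mode gives the same partition here
  memb_cc <- detect_clusters(g, method = "components")
  expect_identical(memb_cc[order(memb_cc$contig_id), ],
                   memb[order(memb$contig_id), ])
})

test_that("Louvain matches exhaustive modularity maximisation on a bridged instance", {
  # two planted 8-cliques joined by one spurious edge
  ids <- c(paste0("p", 1:8), paste0("q", 1:8))
  pp <- t(utils::combn(paste0("p", 1:8), 2))
  qq <- t(utils::combn(paste0("q", 1:8), 2))
  rec <- rbind(rec_df(pp[, 1], pp[, 2], 0.01),
               rec_df(qq[, 1], qq[, 2], 0.01),
               rec_df("p1", "q1", 0.05))
  g <- build_contig_graph(rec, meta_for(ids))
  memb <- detect_clusters(g, seed = 1)
  cl_of <- stats::setNames(memb$cluster_id, memb$contig_id)
  expect_equal(length(unique(cl_of[paste0("p", 1:8)])), 1)
  expect_equal(length(unique(cl_of[paste0("q", 1:8)])), 1)
  expect_false(cl_of[["p1"]] == cl_of[["q1"]])
  # exhaustive search over all bipartitions of the 16 nodes
  vnames <- igraph::V(g)$name
  n <- length(vnames)
  best_q <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    v <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)]) + 1L
    q <- modularity_direct(g, v)
    if (q > best_q) best_q <- q
  }
  louvain_q <- modularity_direct(
    g, as.integer(factor(memb$cluster_id[match(vnames, memb$contig_id)])))
  expect_gte(louvain_q, best_q - 1e-12)
  # determinism under a fixed seed
  expect_identical(detect_clusters(g, seed = 1), detect_clusters(g, seed = 1))
})

test_that("cluster categorisation follows the viral-fraction and bacterial rules", {
  memb <- data.frame(contig_id = c("a", "b", "c", "d"), cluster_id = "CL0001",
                     stringsAsFactors = FALSE)
  calls <- function(viral_ids, basis = "") {
    data.frame(contig_id = c("a", "b", "c", "d"),
               category = ifelse(c("a", "b", "c", "d") %in% viral_ids,
                                 "viral", "eukaryote"),
               basis = basis, stringsAsFactors = FALSE)
  }
  meta <- meta_for(c("a", "b", "c", "d"))
  # 1 of 4 viral -> viral (inclusive 25%)
  r <- categorize_clusters(memb, calls("a"), meta)
  expect_equal(r$clusters$category, "viral")
  expect_true(all(r$contigs$category == "viral"))  # propagation
  # 0 viral but a bacterial reference member -> bacterial
  meta2 <- meta; meta2$source_type[4] <- "bacterial_ref"
  r2 <- categorize_clusters(memb, calls(character(0)), meta2)
  expect_equal(r2$clusters$category, "bacterial")
  # 1 of 5 viral (20%), no bacterial evidence -> eukaryote
  memb5 <- rbind(memb, data.frame(contig_id = "e", cluster_id = "CL0001"))
  calls5 <- rbind(calls("a"), data.frame(contig_id = "e",
                                         category = "eukaryote", basis = ""))
  r3 <- categorize_clusters(memb5, calls5, meta_for(c("a", "b", "c", "d", "e")))
  expect_equal(r3$clusters$category, "eukaryote")
  # 16S marker member -> bacterial
  r4 <- categorize_clusters(memb, calls(character(0)), meta,
                            ref16s_ids = "c")
  expect_equal(r4$clusters$category, "bacterial")
  # missing call -> error
  expect_error(categorize_clusters(memb, calls("a")[-1, ], meta), "no contig call")
})

test_that("categorisation is idempotent under re-running", {
  memb <- data.frame(contig_id = c("a", "b", "c"), cluster_id = "CL0001")
  calls <- data.frame(contig_id = c("a", "b", "c"),
                      category = c("viral", "eukaryote", "eukaryote"),
                      basis = c("ssdna", "", ""), stringsAsFactors = FALSE)
  meta <- meta_for(c("a", "b", "c"))
  r1 <- categorize_clusters(memb, calls, meta)
  # feed the propagated categories back in as calls
  calls2 <- data.frame(contig_id = r1$contigs$contig_id,
                       category = r1$contigs$category,
                       basis = "", stringsAsFactors = FALSE)
  r2 <- categorize_clusters(memb, calls2, meta)
  expect_identical(r1$contigs$category, r2$contigs$category)
  expect_identical(r1$clusters$category, r2$clusters$category)
})

test_that("contig LCA takes the modal label at 25% frequency else 'Viral'", {
  expect_equal(assign_contig_lca(c("Caudovirales", "Caudovirales",
                                   "Microviridae", "none")), "Caudovirales")
  expect_equal(assign_contig_lca(c("A", "B", "C", "D", "E")), "Viral")
  expect_equal(assign_contig_lca("Microviridae"), "Microviridae")
  expect_equal(assign_contig_lca(character(0)), "Viral")
  expect_equal(assign_contig_lca(rep("none", 4)), "Viral")
  # 'none' dilutes the denominator
  expect_equal(assign_contig_lca(c("Caudovirales", rep("none", 4))), "Viral")
})

test_that("SAG filtering retains only SAGs with eukaryotic contigs", {
  cats <- data.frame(contig_id = c("a", "b", "c", "d"),
                     cluster_id = "CL0001",
                     category = c("viral", "viral", "eukaryote", "viral"),
                     stringsAsFactors = FALSE)
  mapping <- data.frame(contig_id = c("a", "b", "c", "d"),
                        sag_id = c("S1", "S1", "S2", "S2"),
                        stringsAsFactors = FALSE)
  expect_equal(filter_sags(cats, mapping), "S2")
  empty <- mapping[0, ]
  expect_equal(length(filter_sags(cats, empty)), 0)
})

test_that("inter-phylum detection needs two identified phyla", {
  clusters <- data.frame(cluster_id = c("CL0001", "CL0002", "CL0003"),
                         n_members = 3, n_sags = 3, viral_fraction = 1,
                         category = "viral", lca_label = "Caudovirales",
                         stringsAsFactors = FALSE)
  contigs <- data.frame(
    contig_id = paste0("c", 1:9),
    cluster_id = rep(c("CL0001", "CL0002", "CL0003"), each = 3),
    category = "viral", stringsAsFactors = FALSE)
  mapping <- data.frame(contig_id = paste0("c", 1:9),
                        sag_id = paste0("S", c(1, 2, 3, 4, 5, 6, 7, 8, 9)),
                        stringsAsFactors = FALSE)
  taxa <- data.frame(
    sag_id = paste0("S", 1:9),
    lineage = c("Choanozoa", "Picozoa", "Choanozoa",   # CL0001: 2 phyla
                "Choanozoa", "Choanozoa", "Choanozoa", # CL0002: 1 phylum
                "Choanozoa", "unidentified", "unidentified"), # CL0003
    stringsAsFactors = FALSE)
  ip <- interphylum_clusters(list(clusters = clusters, contigs = contigs),
                             mapping, taxa)
  expect_equal(ip$interphylum$cluster_id, "CL0001")
  expect_equal(ip$interphylum$n_phyla, 2)
  # unidentified SAGs are listed in the edges but do not count
  e3 <- ip$edges[ip$edges$cluster_id == "CL0003", ]
  expect_setequal(e3$sag_id, c("S7", "S8", "S9"))
})
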