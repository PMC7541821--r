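mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(contig_id = r$cid, orf_index = r$orf, hit_rank = r$rank,
               hit_description = r$desc,
               percent_identity = if (is.null(r$pid)) 80 else r$pid,
               alignment_fraction = if (is.null(r$af)) 0.9 else r$af,
               evalue = 1e-10, bitscore = 100,
               subject_class = if (is.null(r$cls)) "nr" else r$cls,
               stringsAsFactors = FALSE)
  }))
}

test_that("viral ORF fraction counts lexicon hits within the rank cutoff", {
  h <- mk_hits(
    list(cid = "c", orf = 1, rank = 3, desc = "major capsid protein"),
    list(cid = "c", orf = 2, rank = 1, desc = "hypothetical protein"),
    list(cid = "c", orf = 3, rank = 2, desc = "capsid assembly chaperone"),
    list(cid = "c", orf = 4, rank = 1, desc = "ribosomal protein"))
  expect_equal(viral_orf_fraction(h, "c"), 0.5)
  # a viral term only beyond the top-10 ranks does not count
  h11 <- mk_hits(list(cid = "c", orf = 1, rank = 11, desc = "capsid protein"),
                 list(cid = "c", orf = 1, rank = 1, desc = "hypothetical"))
  expect_equal(viral_orf_fraction(h11, "c"), 0)
  expect_equal(viral_orf_fraction(h11, "c", top_n = 11), 1)
  # plural forms of lexicon terms match as whole words
  hp <- mk_hits(list(cid = "c", orf = 1, rank = 1, desc = "viruses of archaea"))
  expect_equal(viral_orf_fraction(hp, "c"), 1)
  # substrings inside larger words do not
  hs <- mk_hits(list(cid = "c", orf = 1, rank = 1, desc = "forehead protein"),
                list(cid = "c", orf = 2, rank = 1, desc = "retailing enzyme"))
  expect_equal(viral_orf_fraction(hs, "c"), 0)
  # a contig with no nr-class ORF hits is undefined, not zero
  expect_true(is.na(viral_orf_fraction(h, "absent")))
})

test_that("recruitment ratio is a pseudocounted per-million log ratio", {
  expect_equal(recruitment_ratio(9, 9, 1e6, 1e6), 0)
  expect_equal(recruitment_ratio(99, 9, 1e6, 1e6), 1)
  expect_equal(recruitment_ratio(0, 0, 1e6, 1e6), 0)
  # per-million scaling: same counts, 10x deeper bacterial metagenome
  expect_equal(recruitment_ratio(9, 9, 1e6, 1e7), 1)
  expect_error(recruitment_ratio(1, 1, 0, 1e6), "positive")
})

test_that("kNN viral score counts neighbours and evaluates the binomial tail", {
  tr <- data.frame(
    viral_orf_fraction = c(1, 0.9, 0.8, 0.05, 0.1, 0),
    recruitment_ratio = c(1.5, 1.2, 1.0, -1, -1.2, -0.8),
    label = c("viral", "viral", "viral", "nonviral", "nonviral", "nonviral"),
    stringsAsFactors = FALSE)
  r1 <- knn_viral_score(c(1, 1.5), tr, k = 1)
  expect_equal(r1$probability, 1)
  r3 <- knn_viral_score(c(0.5, 0.2), tr, k = 3)
  expect_true(r3$probability %in% c(0, 1/3, 2/3, 1))
  # five viral neighbours at base rate 1/2 give p = 0.5^5
  tr10 <- data.frame(
    viral_orf_fraction = c(seq(0.9, 1, length.out = 5), seq(0, 0.1, length.out = 5)),
    recruitment_ratio = c(rep(1, 5), rep(-1, 5)),
    label = rep(c("viral", "nonviral"), each = 5), stringsAsFactors = FALSE)
  r5 <- knn_viral_score(c(0.95, 1), tr10, k = 5)
  expect_equal(r5$probability, 1)
  expect_equal(r5$p_value, 0.5^5)
  expect_error(knn_viral_score(c(0, 0), tr10, k = 11), "k must lie")
})

test_that("kNN probability is invariant under affine feature rescaling", {
  set.seed(41)
  tr <- data.frame(
    viral_orf_fraction = stats::runif(30),
    recruitment_ratio = stats::rnorm(30),
    label = sample(c("viral", "nonviral"), 30, TRUE), stringsAsFactors = FALSE)
  if (!all(c("viral", "nonviral") %in% tr$label)) tr$label[1:2] <- c("viral", "nonviral")
  q <- c(0.4, 0.3)
  base <- knn_viral_score(q, tr, k = 5)
  tr2 <- tr
  tr2$viral_orf_fraction <- 100 * tr$viral_orf_fraction - 7
  tr2$recruitment_ratio <- 0.01 * tr$recruitment_ratio + 3
  q2 <- c(100 * q[1] - 7, 0.01 * q[2] + 3)
  resc <- knn_viral_score(q2, tr2, k = 5)
  expect_equal(resc$probability, base$probability)
  expect_equal(resc$p_value, base$p_value)
})

test_that("ssDNA rule merges spans, applies the e-value and length caps", {
  sp <- function(s, e, ev = 1e-6) data.frame(span_start = s, span_end = e,
                                             evalue = ev)
  expect_true(ssdna_flag(sp(1, 250), 1000))
  expect_false(ssdna_flag(sp(1, 150), 1000))
  expect_false(ssdna_flag(sp(1, 6000), 12000))          # length cap
  expect_false(ssdna_flag(sp(1, 250, ev = 1e-4), 1000)) # e-value cutoff
  # overlapping spans are merged before summing
  two <- rbind(sp(1, 150), sp(100, 220))
  expect_true(ssdna_flag(two, 1000))   # union 220 >= 200
  expect_false(ssdna_flag(rbind(sp(1, 150), sp(50, 150)), 1000))
  expect_error(ssdna_flag(sp(-5, 100), 1000), "negative")
})

test_that("ssDNA rule is monotone: qualifying hits never flip true to false", {
  set.seed(42)
  for (rep in 1:25) {
    len <- sample(2000:9000, 1)
    n <- sample(1:4, 1)
    st <- sample.int(len - 100, n)
    en <- pmin(len, st + sample(50:2000, n, replace = TRUE))
    spans <- data.frame(span_start = st, span_end = en, evalue = 1e-8)
    before <- ssdna_flag(spans, len)
    extra_start <- sample.int(len - 100, 1)
    extra <- rbind(spans, data.frame(span_start = extra_start,
                                     span_end = min(len, extra_start + 500),
                                     evalue = 1e-9))
    if (before) expect_true(ssdna_flag(extra, len))
  }
})

test_that("bacterial reference rule uses an inclusive distance threshold", {
  rec <- function(d) data.frame(contig_a = "c", contig_b = "ref1",
                                distance = d, stringsAsFactors = FALSE)
  refs <- c("ref1", "ref2")
  expect_true(bacterial_by_reference(rec(0.04), "c", refs))
  expect_true(bacterial_by_reference(rec(0.05), "c", refs))
  expect_false(bacterial_by_reference(rec(0.06), "c", refs))
  # symmetric storage direction also matches
  rev <- data.frame(contig_a = "ref1", contig_b = "c", distance = 0.01)
  expect_true(bacterial_by_reference(rev, "c", refs))
  none <- data.frame(contig_a = character(), contig_b = character(),
                     distance = numeric())
  expect_false(bacterial_by_reference(none, "c", refs))
})

test_that("bacterial ORF-majority rule needs a strict majority and nt confirmation", {
  mk <- function(n_qual, n_total, cid = "c") {
    nr <- mk_hits(list(cid = cid, orf = 1, rank = 1, desc = "hypothetical"))
    nr <- nr[rep(1, n_total), ]
    nr$orf_index <- seq_len(n_total)
    qual <- nr[seq_len(n_qual), ]
    qual$subject_class <- "refseq_bacteria"
    qual$percent_identity <- 70
    qual$alignment_fraction <- 0.9
    rbind(nr, qual)
  }
  expect_true(bacterial_by_orf_majority(mk(3, 4), "c", "bacterial"))
  expect_false(bacterial_by_orf_majority(mk(2, 4), "c", "bacterial"))  # exactly 50%
  expect_false(bacterial_by_orf_majority(mk(4, 4), "c", "organellar"))
  expect_false(bacterial_by_orf_majority(mk(4, 4), "c", "unknown"))
  # sub-threshold identity or coverage does not qualify
  weak <- mk(4, 4)
  weak$percent_identity[weak$subject_class == "refseq_bacteria"] <- 45
  expect_false(bacterial_by_orf_majority(weak, "c", "bacterial"))
})

test_that("contig calls apply viral > bacterial > eukaryote precedence", {
  ev <- function(knn_p = NA, knn_pv = NA, ext = "none", ss = FALSE,
                 bref = FALSE, borf = FALSE) {
    data.frame(contig_id = "c", viral_orf_fraction = 0.5,
               recruitment_ratio = 0, knn_probability = knn_p,
               knn_pvalue = knn_pv, external_viral_category = ext,
               ssdna_flag = ss, bacterial_by_reference = bref,
               bacterial_by_orf_majority = borf, nt_verification = "unknown",
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_contigs(ev(ext = "2"))$category, "viral")
  expect_equal(classify_contigs(ev(ext = "3"))$category, "eukaryote")
  expect_equal(classify_contigs(ev(knn_p = 0.9, knn_pv = 0.01))$category, "viral")
  expect_equal(classify_contigs(ev(knn_p = 0.9, knn_pv = 0.2))$category, "eukaryote")
  expect_equal(classify_contigs(ev(knn_p = 0.4, knn_pv = 0.01))$category, "eukaryote")
  expect_equal(classify_contigs(ev(bref = TRUE))$category, "bacterial")
  expect_equal(classify_contigs(ev(borf = TRUE))$category, "bacterial")
  both <- classify_contigs(ev(ss = TRUE, bref = TRUE))
  expect_equal(both$category, "viral")  # viral evidence takes precedence
  expect_equal(both$basis, "ssdna")
  none <- classify_contigs(ev())
  expect_equal(none$category, "eukaryote")
  expect_equal(none$basis, "")
})

test_that("category calls are exhaustive and mutually exclusive", {
  grid <- expand.grid(knn = c(NA, 0.2, 0.9), pv = c(NA, 0.01, 0.5),
                      ext = c("none", "1", "3"), ss = c(TRUE, FALSE),
                      bref = c(TRUE, FALSE), borf = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  evd <- data.frame(contig_id = paste0("g", seq_len(nrow(grid))),
                    viral_orf_fraction = 0.5, recruitment_ratio = 0,
                    knn_probability = grid$knn, knn_pvalue = grid$pv,
                    external_viral_category = grid$ext, ssdna_flag = grid$ss,
                    bacterial_by_reference = grid$bref,
                    bacterial_by_orf_majority = grid$borf,
                    nt_verification = "bacterial", stringsAsFactors = FALSE)
  calls <- classify_contigs(evd)
  expect_true(all(calls$category %in% c("viral", "bacterial", "eukaryote")))
  expect_equal(nrow(calls), nrow(grid))
  expect_true(all(calls$basis[calls$category != "eukaryote"] != ""))
})

test_that("the default training set is balanced, cached and reproducible", {
  tr <- default_training_set()
  expect_true(all(c("viral", "nonviral") %in% tr$label))
  expect_lte(max(table(tr$label)), 100)
  expect_identical(tr, default_training_set())
  # noiseless features separate the labels completely
  expect_true(all(tr$viral_orf_fraction[tr$label == "viral"] == 1))
  expect_true(all(tr$viral_orf_fraction[tr$label == "nonviral"] == 0))
})
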