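#' MinHash sketching and Mash-style distances
#'
#' A bottom-s MinHash sketcher over canonical k-mers, replacing an external
#' MASH binary with an in-package implementation that can be verified against
#' a brute-force exact Jaccard oracle. A k-mer is canonicalised to the
#' lexicographic minimum of itself and its reverse complement (k must be odd
#' so a k-mer never equals its own reverse complement); k-mers containing
#' non-ACGT symbols are skipped. Hash values are 53-bit (exactly representable
#' as R doubles), seeded, and deterministic.
#'
#' @param sequence single nucleotide string (case-insensitive).
#' @param k odd k-mer length in 11..31. Default 21.
#' @param s sketch size (number of smallest hash values retained). Default 1000.
#' @param hash_seed integer seed mixed into the hash function. Default 42.
#' @param contig_id optional identifier stored in the sketch.
#' @return An object of class `kmer_sketch`: a list with `contig_id`, `k`,
#'   `s`, `hash_seed`, `hashes` (strictly increasing numeric vector of the
#'   min(s, n_distinct) smallest hash values), `n_distinct` (distinct
#'   canonical k-mers in the sequence) and `seq_length`.
#' @examples
#' sk <- sketch("ACGTACGTACGTACGTACGTACGTACGT", k = 11, s = 50)
#' sk$n_distinct
#' @export
sketch <- function(sequence, k = 21L, s = 1000L, hash_seed = 42L,
                   contig_id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  k <- as.integer(k); s <- as.integer(s)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 11L || k > 31L) stop("k must be in [11, 31]")
  if (s < 1L) stop("sketch size s must be >= 1")
  if (nchar(sequence) < k) stop("sequence shorter than k")
  res <- cpp_sketch(sequence, k, s, as.double(hash_seed))
  structure(
    list(contig_id = contig_id, k = k, s = s, hash_seed = as.integer(hash_seed),
         hashes = res$hashes, n_distinct = as.integer(res$n_distinct),
         seq_length = nchar(sequence)),
    class = "kmer_sketch"
  )
}

#' Sketch a set of contigs
#'
#' @param seqs named character vector of nucleotide sequences.
#' @inheritParams sketch
#' @return list of [sketch()] objects, named by contig id.
#' @export
sketch_contigs <- function(seqs, k = 21L, s = 1000L, hash_seed = 42L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- lapply(seq_along(seqs), function(i) {
    sketch(seqs[[i]], k = k, s = s, hash_seed = hash_seed,
           contig_id = names(seqs)[i])
  })
  names(out) <- names(seqs)
  out
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("kmer_sketch %s: k=%d s=%d |hashes|=%d n_distinct=%d len=%d\n",
              x$contig_id, x$k, x$s, length(x$hashes), x$n_distinct,
              x$seq_length))
  invisible(x)
}

#' Estimate the Jaccard index from two sketches
#'
#' Mash's merged-sketch estimator: among the s smallest hash values of the
#' union of the two sketches, the fraction present in both. When s is at
#' least the size of the union of the two canonical k-mer sets, the estimate
#' equals the exact Jaccard index.
#'
#' @param a,b `kmer_sketch` objects with identical `k` and `hash_seed`.
#' @return Jaccard estimate in \[0, 1\].
#' @export
jaccard_estimate <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k) stop("sketches have different k")
  if (a$hash_seed != b$hash_seed) stop("sketches have different hash seeds")
  s <- min(a$s, b$s)
  cpp_jaccard(a$hashes, b$hashes, as.integer(s))[1]
}

#' Mash distance from a Jaccard estimate
#'
#' d = -(1/k) * log(2j / (1 + j)), capped at 1; j = 0 maps to the cap 1.
#' For closely related sequences d approximates 1 - ANI.
#'
#' @param j Jaccard estimate in \[0, 1\].
#' @param k k-mer length used for the sketches.
#' @return distance in \[0, 1\].
#' @examples
#' mash_distance(1, 21)      # 0
#' mash_distance(1 / 3, 21)  # log(2)/21
#' @export
mash_distance <- function(j, k = 21L) {
  if (any(is.na(j)) || any(j < 0) || any(j > 1)) stop("j must be in [0, 1]")
  d <- ifelse(j == 0, 1, pmin(1, pmax(0, -log(2 * j / (1 + j)) / k)))
  d
}

#' All-vs-all Mash distances below a threshold
#'
#' Computes the Mash distance for every unordered pair of sketches and keeps
#' pairs at or below `threshold`. Each retained pair appears once, with
#' `contig_a` < `contig_b`; the relation is symmetric and self-pairs are
#' never emitted.
#'
#' @param sketches list of `kmer_sketch` objects sharing `k` and `hash_seed`.
#' @param threshold maximum Mash distance to keep (default 0.05, the
#'   conventional ~95% ANI cutoff).
#' @return data.frame with columns `contig_a`, `contig_b`, `jaccard`,
#'   `distance`.
#' @export
pairwise_distances <- function(sketches, threshold = 0.05) {
  if (length(sketches) == 0L) {
    return(data.frame(contig_a = character(), contig_b = character(),
                      jaccard = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  ks <- vapply(sketches, function(x) x$k, integer(1))
  seeds <- vapply(sketches, function(x) x$hash_seed, integer(1))
  if (length(unique(ks)) != 1L) stop("all sketches must share k")
  if (length(unique(seeds)) != 1L) stop("all sketches must share hash_seed")
  ids <- vapply(sketches, function(x) x$contig_id, character(1))
  s <- min(vapply(sketches, function(x) x$s, integer(1)))
  res <- cpp_pairwise(lapply(sketches, `[[`, "hashes"),
                      as.integer(s), ks[1], as.double(threshold))
  data.frame(contig_a = ids[res$i], contig_b = ids[res$j],
             jaccard = res$jaccard, distance = res$distance,
             stringsAsFactors = FALSE)
}

#' Write / read sketches as JSON lines
#'
#' One sketch per line: contig_id, k, s, hash_seed, n_distinct, seq_length,
#' hashes.
#'
#' @param sketches list of `kmer_sketch` objects.
#' @param path output file.
#' @return `write_sketches` returns `path` invisibly; `read_sketches` a list
#'   of `kmer_sketch` objects.
#' @export
write_sketches <- function(sketches, path) {
  lines <- vapply(sketches, function(x) {
    jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    structure(list(contig_id = x$contig_id, k = as.integer(x$k),
                   s = as.integer(x$s), hash_seed = as.integer(x$hash_seed),
                   hashes = as.numeric(x$hashes),
                   n_distinct = as.integer(x$n_distinct),
                   seq_length = as.integer(x$seq_length)),
              class = "kmer_sketch")
  })
  names(out) <- vapply(out, `[[`, character(1), "contig_id")
  out
}
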