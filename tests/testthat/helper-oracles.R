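# Independent brute-force oracles. These deliberately avoid the package's
# own data paths: naive sorts, substring scans, path enumeration and a
# second dynamic-programming implementation of Smith-Waterman.

# all ancestors of a HOG by walking the parent column of the raw table
oracle_path_to_root <- function(hogs, id) {
  path <- id
  p <- hogs$parent_id[match(id, hogs$id)]
  while (!is.na(p)) {
    path <- c(path, p)
    p <- hogs$parent_id[match(p, hogs$id)]
  }
  path
}

oracle_is_ancestor <- function(hogs, a, b) {
  a %in% oracle_path_to_root(hogs, b)[-1]
}

# deepest common element of root-ward paths
oracle_lca <- function(hogs, ids) {
  paths <- lapply(ids, function(i) rev(oracle_path_to_root(hogs, i)))
  common <- Reduce(function(p, q) p[seq_len(min(length(p), length(q)))][
    p[seq_len(min(length(p), length(q)))] == q[seq_len(min(length(p), length(q)))]],
    paths)
  common[length(common)]
}

# every distinct canonical k-mer of a sequence, by direct window enumeration
oracle_kmers <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < k) return(character(0))
  w <- vapply(seq_len(length(chars) - k + 1),
              function(i) paste(chars[i:(i + k - 1)], collapse = ""), "")
  ok <- vapply(seq_len(length(chars) - k + 1),
               function(i) all(chars[i:(i + k - 1)] %in% aa_alphabet()),
               TRUE)
  unique(w[ok])
}

# proteins containing a k-mer, by substring scan
oracle_occurrences <- function(db, kmer) {
  hit <- vapply(db$proteins$sequence, function(s)
    grepl(kmer, s, fixed = TRUE), TRUE)
  sort(db$proteins$id[hit])
}

# full k-mer table by substring scan + per-(k-mer, family) LCA;
# returns data.frame(kmer, family_id, ancestral_hog_id) sorted
oracle_kmer_table <- function(db, k, hogs_df) {
  rows <- list()
  for (i in seq_len(nrow(db$proteins))) {
    for (w in oracle_kmers(db$proteins$sequence[i], k)) {
      rows[[length(rows) + 1]] <- data.frame(
        kmer = w, hog = db$proteins$hog_id[i], stringsAsFactors = FALSE)
    }
  }
  d <- unique(do.call(rbind, rows))
  fam <- vapply(d$hog, function(h) {
    p <- oracle_path_to_root(hogs_df, h); p[length(p)]
  }, "")
  d$family_id <- fam
  out <- do.call(rbind, lapply(split(d, paste(d$kmer, d$family_id)),
    function(g) data.frame(kmer = g$kmer[1], family_id = g$family_id[1],
                           ancestral_hog_id = oracle_lca(hogs_df,
                                                         unique(g$hog)),
                           stringsAsFactors = FALSE)))
  out <- out[order(out$kmer, out$family_id), ]
  rownames(out) <- NULL
  out
}

# second, independent Smith-Waterman implementation: full-matrix affine DP.
# gap of length L costs open + L * extend; score floored at 0.
oracle_sw <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in the row direction
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_aa <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
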