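#' Suffix array over the concatenated reference proteins
#'
#' All reference sequences are concatenated with one terminal sentinel per
#' protein; the sentinel sorts before every residue, so no k-mer window ever
#' spans two proteins. The array is built by prefix doubling (O(n log n)
#' radix orderings) and is used as an intermediate while grouping identical
#' k-mers during table construction; it is not serialized with the database.
#'
#' @param db a [reference_db()].
#' @return An object of class `suffix_array` with components `codes`
#'   (integer text; 0 = sentinel), `chars` (code -> character map, so
#'   `chars[codes]` recovers the text, sentinel excluded), `sa` (1-based
#'   suffix start offsets in lexicographic order), `owner` (per-position
#'   protein index) and `protein_ids`.
#' @export
build_suffix_array <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$proteins) == 0L) stop("empty database")
  seqs <- db$proteins$sequence
  lens <- nchar(seqs)
  chars_by_prot <- strsplit(seqs, "")
  all_chars <- unlist(chars_by_prot, use.names = FALSE)
  alpha <- sort(unique(all_chars), method = "radix")

  n_prot <- length(seqs)
  total <- sum(lens) + n_prot
  codes <- integer(total)
  owner <- integer(total)
  stops <- cumsum(lens + 1L)
  starts <- stops - lens
  for (i in seq_len(n_prot)) {
    codes[starts[i]:(stops[i] - 1L)] <- match(chars_by_prot[[i]], alpha)
    owner[starts[i]:stops[i]] <- i
  }
  # sentinel positions keep code 0

  sa <- suffix_order(codes)
  structure(list(codes = codes, chars = alpha, sa = sa, owner = owner,
                 protein_ids = db$proteins$id, starts = starts),
            class = "suffix_array")
}

#' @export
print.suffix_array <- function(x, ...) {
  cat("<suffix_array> text length ", length(x$codes), " (",
      length(x$protein_ids), " proteins + sentinels)\n", sep = "")
  invisible(x)
}

## prefix-doubling suffix sort on an integer text (any codes)
suffix_order <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(1L)
  rk <- match(codes, sort(unique(codes)))
  h <- 1L
  repeat {
    key2 <- c(rk[-seq_len(h)], rep(0L, min(h, n)))
    ord <- order(rk, key2, method = "radix")
    r1 <- rk[ord]
    r2 <- key2[ord]
    newr <- cumsum(c(1L, (r1[-1L] != r1[-n]) | (r2[-1L] != r2[-n])))
    rk[ord] <- newr
    if (newr[n] == n) return(ord)
    h <- 2L * h
    if (h >= n) return(order(rk, method = "radix"))
  }
}

## lexicographic comparison of the suffix at `pos` against k-mer codes `kc`
## (codes in sa$codes space); returns -1 / 0 / 1
suffix_cmp <- function(sa, pos, kc) {
  n <- length(sa$codes)
  for (j in seq_along(kc)) {
    p <- pos + j - 1L
    cj <- if (p > n) -1L else sa$codes[p]
    if (cj < kc[j]) return(-1L)
    if (cj > kc[j]) return(1L)
  }
  0L
}

#' Proteins containing a k-mer, via binary search on the suffix array
#'
#' All suffixes starting with the same k-mer sit consecutively in the array,
#' so the matching range is found with two binary searches; no linear scan.
#'
#' @param sa a [build_suffix_array()] result.
#' @param kmer amino-acid string.
#' @return sorted character vector of protein ids with at least one
#'   occurrence (a protein with several occurrences is reported once);
#'   empty when the k-mer is absent.
#' @export
kmer_occurrences <- function(sa, kmer) {
  kc <- match(strsplit(toupper(kmer), "")[[1]], sa$chars)
  if (anyNA(kc)) return(character(0))
  n <- length(sa$sa)
  ## lower bound: first i with suffix(sa[i]) >= kmer
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (suffix_cmp(sa, sa$sa[mid], kc) < 0L) lo <- mid + 1L else hi <- mid
  }
  first <- lo
  ## upper bound: first i with suffix(sa[i]) > kmer
  hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (suffix_cmp(sa, sa$sa[mid], kc) <= 0L) lo <- mid + 1L else hi <- mid
  }
  if (first >= lo) return(character(0))
  sort(unique(sa$protein_ids[sa$owner[sa$sa[first:(lo - 1L)]]]))
}
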