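#' Encode a k-mer as an integer
#'
#' Base-20 positional code over the alphabetically ordered canonical
#' alphabet: `code = sum_i rank(kmer[i]) * 20^(k-1-i)` with 0-based ranks,
#' so `AA -> 0`, `AC -> 1`, ..., `YY -> 20^k - 1`. Bijective on canonical
#' k-mers.
#'
#' @param kmer character vector of k-mers (all the same length, canonical
#'   residues only).
#' @param alphabet ordered alphabet (default [aa_alphabet()]).
#' @return integer vector of codes in `[0, 20^k)`.
#' @examples
#' encode_kmer(c("AA", "AC"))  # 0 1
#' @export
encode_kmer <- function(kmer, alphabet = aa_alphabet()) {
  kmer <- toupper(as.character(kmer))
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("k-mers must all have the same length")
  if (k < 1L || k > 7L) stop("k must be in [1, 7]")
  A <- length(alphabet)
  m <- matrix(match(unlist(strsplit(kmer, ""), use.names = FALSE), alphabet) - 1L,
              nrow = k)
  if (anyNA(m)) stop("non-canonical residue in k-mer(s): ",
                     paste(kmer[colSums(is.na(m)) > 0], collapse = ", "))
  as.integer(colSums(m * A^((k - 1):0)))
}

#' Decode a k-mer integer code
#' @param code integer code(s) from [encode_kmer()].
#' @param k k-mer length.
#' @inheritParams encode_kmer
#' @return character vector of k-mers.
#' @export
decode_kmer <- function(code, k, alphabet = aa_alphabet()) {
  A <- length(alphabet)
  stopifnot(all(code >= 0), all(code < A^k))
  out <- matrix("", nrow = k, ncol = length(code))
  rest <- as.double(code)
  for (i in k:1) {
    out[i, ] <- alphabet[rest %% A + 1]
    rest <- rest %/% A
  }
  apply(out, 2, paste, collapse = "")
}

## per-window k-mer codes of an integer-coded text (rank 1..A canonical, else
## 0/NA); windows containing a non-canonical code or running past the end get
## NA
window_codes <- function(codes, k, A = 20L) {
  r <- ifelse(codes >= 1L & codes <= A, codes - 1L, NA_integer_)
  n <- length(r)
  acc <- rep(0, n)
  for (j in 0:(k - 1L)) {
    shifted <- c(r[(1L + j):n], rep(NA_integer_, j))
    acc <- acc * A + shifted   # NA propagates
  }
  if (k > 1L) acc[max(1L, n - k + 2L):n] <- NA
  as.integer(acc)
}

#' Build the evolutionarily informed k-mer table
#'
#' For every (k-mer, family) pair such that at least one member of the family
#' contains the k-mer, the table stores exactly one entry: the family plus
#' the k-mer's ancestral HOG, i.e. the last common ancestor of the most
#' specific HOGs of the members containing it ([lca_hog()]). Entries are laid
#' out in compressed sparse row style: a flat buffer sorted by k-mer code
#' then family, addressed through row pointers keyed by the sorted set of
#' occurring codes (see [kmer_index()] for the dense index array).
#'
#' @param db a [reference_db()].
#' @param k k-mer length; defaults to `db$k`.
#' @return An object of class `kmer_table`: `k`, `codes` (sorted distinct
#'   k-mer codes), `row_ptr` (0-based CSR offsets, length
#'   `length(codes) + 1`), `fam`/`hog` (per-entry family index and ancestral
#'   HOG index), `family_ids`, `hierarchy`, and the count statistics
#'   `m_family` (table entries per family), `m_hog` (entries attributed
#'   exactly to each HOG) and `m_hog_subtree` (entries attributed within each
#'   HOG's subtree).
#' @export
build_kmer_table <- function(db, k = db$k) {
  stopifnot(inherits(db, "reference_db"))
  k <- as.integer(k)
  sa <- build_suffix_array(db)
  h <- db$hierarchy

  canon <- match(sa$chars, db$alphabet)      # char code -> canonical rank
  text_rank <- rep(NA_integer_, length(sa$codes))
  nz <- sa$codes > 0L
  text_rank[nz] <- canon[sa$codes[nz]]       # NA at sentinels/non-canonical
  wc <- window_codes(text_rank, k, A = length(db$alphabet))

  ord <- sa$sa[!is.na(wc[sa$sa])]            # suffix-array order, valid only
  prot <- sa$owner[ord]
  hog_idx <- match(db$proteins$hog_id, h$ids)[prot]
  fam_idx <- h$family[hog_idx]
  root_idx <- sort(unique(h$family))
  family_ids <- h$ids[root_idx]

  dt <- data.table::data.table(code = wc[ord],
                               fam = match(fam_idx, root_idx),
                               hog = hog_idx)
  dt <- unique(dt)

  ## vectorised per-(code, family) LCA through ancestor-at-level columns
  A <- ancestor_level_matrix(h)
  lmax <- ncol(A) - 1L
  acols <- paste0("a", 0:lmax)
  for (l in 0:lmax) {
    v <- A[dt$hog, l + 1L]
    v[is.na(v)] <- -1L
    data.table::set(dt, j = acols[l + 1L], value = v)
  }
  data.table::setkey(dt, code, fam)
  gmin <- dt[, lapply(.SD, min), by = c("code", "fam"), .SDcols = acols]
  gmax <- dt[, lapply(.SD, max), by = c("code", "fam"), .SDcols = acols]

  ng <- nrow(gmin)
  lev <- rep(0L, ng)
  alive <- rep(TRUE, ng)
  for (l in seq_len(lmax)) {
    cmn <- alive & gmin[[acols[l + 1L]]] == gmax[[acols[l + 1L]]] &
      gmin[[acols[l + 1L]]] != -1L
    lev <- lev + as.integer(cmn)
    alive <- cmn
  }
  Mmin <- as.matrix(gmin[, acols, with = FALSE])
  anc <- Mmin[cbind(seq_len(ng), lev + 1L)]

  codes <- gmin$code
  ucodes <- unique(codes)
  counts <- data.table::data.table(code = codes)[, .N, by = "code"]$N
  row_ptr <- c(0L, cumsum(counts))

  m_family <- tabulate(gmin$fam, nbins = length(family_ids))
  names(m_family) <- family_ids
  m_hog <- tabulate(anc, nbins = length(h$ids))
  m_sub <- m_hog
  for (i in order(h$depth, decreasing = TRUE)) {
    p <- h$parent[i]
    if (!is.na(p)) m_sub[p] <- m_sub[p] + m_sub[i]
  }
  names(m_hog) <- h$ids
  names(m_sub) <- h$ids

  structure(list(k = k, alphabet = db$alphabet,
                 codes = ucodes, row_ptr = row_ptr,
                 fam = gmin$fam, hog = anc,
                 family_ids = family_ids, hierarchy = h,
                 m_family = m_family, m_hog = m_hog, m_hog_subtree = m_sub,
                 n_proteins = nrow(db$proteins)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("<kmer_table> k = ", x$k, "; ", length(x$codes),
      " distinct k-mers; ", length(x$fam), " entries across ",
      length(x$family_ids), " families\n", sep = "")
  invisible(x)
}

#' Dense CSR index array of a k-mer table
#'
#' The index has `A^k + 1` offsets: entries of the k-mer with integer code
#' `w` occupy buffer positions `index[w + 1] .. index[w + 2]` (0-based
#' half-open interval `[index[w], index[w+1])`). Materialised on demand;
#' refuses alphabets where the array would be unreasonably large.
#'
#' @param table a [build_kmer_table()] result.
#' @return integer vector of length `A^k + 1`.
#' @export
kmer_index <- function(table) {
  A <- length(table$alphabet)
  size <- A^table$k
  if (size > 2^25)
    stop("dense index would need ", size + 1,
         " offsets; use the keyed row pointers instead")
  counts <- integer(size)
  counts[table$codes + 1L] <- diff(table$row_ptr)
  c(0L, cumsum(counts))
}

#' Table entries of one k-mer
#' @param table a [build_kmer_table()] result.
#' @param kmer amino-acid string of length `table$k`.
#' @return data.frame with columns `family_id`, `ancestral_hog_id` (zero rows
#'   when the k-mer has no entry).
#' @export
kmer_entries <- function(table, kmer) {
  code <- encode_kmer(kmer, table$alphabet)
  stopifnot(nchar(kmer) == table$k)
  i <- findInterval(code, table$codes)
  if (i == 0L || table$codes[i] != code)
    return(data.frame(family_id = character(0),
                      ancestral_hog_id = character(0)))
  rows <- (table$row_ptr[i] + 1L):table$row_ptr[i + 1L]
  data.frame(family_id = table$family_ids[table$fam[rows]],
             ancestral_hog_id = table$hierarchy$ids[table$hog[rows]],
             stringsAsFactors = FALSE)
}

## all table rows matching a set of query codes: data.frame(code, fam, hog)
match_entries <- function(codes, table) {
  if (!length(codes))
    return(list(code = integer(0), fam = integer(0), hog = integer(0)))
  i <- findInterval(codes, table$codes)
  hit <- i > 0L & table$codes[pmax(i, 1L)] == codes
  i <- i[hit]
  lens <- table$row_ptr[i + 1L] - table$row_ptr[i]
  rows <- sequence(lens, from = table$row_ptr[i] + 1L)
  list(code = rep(codes[hit], lens),
       fam = table$fam[rows],
       hog = table$hog[rows])
}
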