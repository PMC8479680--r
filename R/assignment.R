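#' K-mer profile of a query sequence
#'
#' Distinct canonical k-mers of the query with their window positions;
#' windows containing non-canonical residues are skipped. A sequence shorter
#' than `k` yields an empty profile (`n = 0`), which downstream produces no
#' assignment rather than an error.
#'
#' @param sequence amino-acid string.
#' @param k k-mer length.
#' @param query_id optional identifier carried through to results.
#' @return An object of class `query_profile`: `codes` (sorted distinct
#'   k-mer codes), `n = length(codes)`, `positions` (data.frame `pos`,
#'   `code`, one row per occurrence), `length` (residue count), `k`.
#' @export
profile_query <- function(sequence, k, query_id = NA_character_) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  alpha <- aa_alphabet()
  if (len < k) {
    return(structure(list(query_id = query_id, codes = integer(0), n = 0L,
                          positions = data.frame(pos = integer(0),
                                                 code = integer(0)),
                          length = len, k = as.integer(k)),
                     class = "query_profile"))
  }
  r <- match(strsplit(sequence, "")[[1]], alpha)
  wc <- window_codes(r, as.integer(k), A = length(alpha))
  pos <- which(!is.na(wc))
  structure(list(query_id = query_id,
                 codes = sort(unique(wc[pos])),
                 n = length(unique(wc[pos])),
                 positions = data.frame(pos = pos, code = wc[pos]),
                 length = len, k = as.integer(k)),
            class = "query_profile")
}

#' @export
print.query_profile <- function(x, ...) {
  cat("<query_profile> ", if (!is.na(x$query_id)) paste0(x$query_id, ": "),
      x$length, " aa, ", x$n, " distinct ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Coarse alignment-free family similarities
#'
#' For each family with at least one matching table entry, `x` counts the
#' distinct query k-mers having an entry for that family.
#'
#' @param profile a [profile_query()] result.
#' @param table a [build_kmer_table()] built with the same `k`.
#' @return data.frame with columns `family_id`, `x`, ordered by `family_id`.
#' @export
coarse_family_hits <- function(profile, table) {
  stopifnot(profile$k == table$k)
  me <- match_entries(profile$codes, table)
  x <- tabulate(me$fam, nbins = length(table$family_ids))
  keep <- which(x >= 1L)
  data.frame(family_id = table$family_ids[keep], x = x[keep],
             stringsAsFactors = FALSE)
}

## score = max(0, (x - E)/(n - E)), E = n * p, p = 1 - (1 - A^-k)^m:
## the excess of matched k-mers over the chance expectation for a reference
## k-mer set of size m, normalised to [0, 1] by the query's k-mer count
excess_score <- function(x, n, m, k, A = 20L, clamp = TRUE) {
  p <- 1 - (1 - A^(-k))^m
  E <- n * p
  raw <- ifelse(n > 0 & n > E, (x - E) / (n - E), 0)
  if (clamp) raw <- pmax(0, raw)
  names(raw) <- names(x)
  raw
}

#' Family-level excess-similarity score
#'
#' Normalizes a coarse hit count into `[0, 1]`, accounting for the query's
#' k-mer count `n` and the family's table size `m` (number of distinct k-mers
#' with an entry for the family): `score = max(0, (x - E)/(n - E))` with
#' `E = n * (1 - (1 - 20^-k)^m)` the chance-level expectation.
#'
#' @param hit one or more rows as returned by [coarse_family_hits()].
#' @inheritParams coarse_family_hits
#' @return numeric vector of scores in `[0, 1]`, one per row of `hit`.
#' @export
family_score <- function(hit, profile, table) {
  m <- table$m_family[hit$family_id]
  excess_score(hit$x, profile$n, m, table$k, A = length(table$alphabet))
}

#' Assign a query to a family (root-HOG)
#'
#' Excess-similarity scores are computed for the `top_n` families with the highest
#' coarse similarity (ties at the cutoff all included); the best-scoring
#' family is returned if its score reaches `theta_family`. Score ties break
#' to the smallest family id.
#'
#' @inheritParams coarse_family_hits
#' @param theta_family family-level score threshold in `[0, 1]`.
#' @param top_n number of candidate families scored (default 100).
#' @return list with `family_id` (`NA` when unassigned), `score` (best
#'   candidate score, 0 when there were no hits) and `candidates`
#'   (data.frame `family_id`, `x`, `score`).
#' @export
assign_family <- function(profile, table, theta_family = 0.05, top_n = 100L) {
  hits <- coarse_family_hits(profile, table)
  if (nrow(hits) == 0L)
    return(list(family_id = NA_character_, score = 0,
                candidates = data.frame(family_id = character(0),
                                        x = integer(0), score = numeric(0))))
  if (nrow(hits) > top_n) {
    cutoff <- sort(hits$x, decreasing = TRUE)[top_n]
    hits <- hits[hits$x >= cutoff, , drop = FALSE]
  }
  hits$score <- family_score(hits, profile, table)
  best <- hits[order(-hits$score, hits$family_id), , drop = FALSE][1L, ]
  list(family_id = if (best$score >= theta_family) best$family_id
                   else NA_character_,
       score = best$score,
       candidates = hits)
}

#' Per-HOG subtree hit counts within an assigned family
#'
#' `x_h` counts the distinct query k-mers whose table entry for the family
#' has its ancestral HOG inside `subtree(h)` (`h` included); at the root this
#' equals the family's coarse count, and counts are non-increasing from
#' parent to child.
#'
#' @inheritParams coarse_family_hits
#' @param family_id assigned family (root-HOG id).
#' @return named integer vector over the family's HOGs (increasing depth).
#' @export
subtree_hit_counts <- function(profile, table, family_id) {
  h <- table$hierarchy
  fam_i <- match(family_id, table$family_ids)
  if (is.na(fam_i)) stop("unknown family: ", family_id)
  me <- match_entries(profile$codes, table)
  hogs <- me$hog[me$fam == fam_i]
  cnt <- tabulate(hogs, nbins = length(h$ids))
  sub <- subtree_indices(h, hog_index(h, family_id))
  for (i in sub[order(h$depth[sub], decreasing = TRUE)]) {
    p <- h$parent[i]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[i]
  }
  sub <- sub[order(h$depth[sub])]
  stats::setNames(cnt[sub], h$ids[sub])
}

#' Refine a family assignment to a subfamily (sub-HOG)
#'
#' Every non-root HOG `h` of the family gets a subfamily score capturing the
#' excess of similarity relative to its parent:
#' `s_h = (x_h - E_h) / (x_parent - E_h)`, where `x_h` is the subtree-
#' specific hit count, `x_parent` the parent's, and
#' `E_h = x_parent * m_h / m_parent` the chance expectation under the null
#' that the query belongs to the parent but not to `h` - a query matching
#' the parent's subtree at random would hit `h`'s entries in proportion to
#' their share of the parent's. `s_h` is therefore the fraction of the
#' parent's similarity that persists into `h` beyond that share, comparable
#' across depths and insensitive to query length. The root-to-leaf path maximising the summed (clamped)
#' scores is selected (ties to the lexicographically smallest leaf), and the
#' assignment descends along it while the child's score excess reaches
#' `theta_sub`, falling back to the root-HOG when the first child already
#' fails. Scores of HOGs under different parents are not compared.
#'
#' @inheritParams subtree_hit_counts
#' @param theta_sub subfamily-level score threshold; larger values penalize
#'   specific subfamilies more and so make assignments more conservative.
#' @return list with `subfamily_id`, `score` (subfamily score, or the family
#'   score when the root is reported), `family_score`, and `path`
#'   (data.frame `hog_id`, `s_raw`, `s` for the selected path's non-root
#'   HOGs, root first).
#' @export
assign_subfamily <- function(profile, table, family_id, theta_sub = 0.1) {
  h <- table$hierarchy
  k <- table$k
  A <- length(table$alphabet)
  x <- subtree_hit_counts(profile, table, family_id)
  fam_score <- excess_score(x[[family_id]], profile$n,
                            table$m_family[[family_id]], k, A)
  ids <- names(x)
  if (length(ids) == 1L) {
    return(list(subfamily_id = family_id, score = fam_score,
                family_score = fam_score,
                path = data.frame(hog_id = character(0), s_raw = numeric(0),
                                  s = numeric(0))))
  }
  m <- table$m_hog_subtree[ids]
  idx0 <- hog_index(h, ids)
  parent_ids <- ifelse(is.na(h$parent[idx0]), NA_character_,
                       h$ids[h$parent[idx0]])
  x_parent <- x[parent_ids]
  m_parent <- m[parent_ids]
  E_h <- x_parent * m / pmax(m_parent, 1L)
  denom <- pmax(x_parent - E_h, 1e-9)
  s_raw <- stats::setNames(as.numeric((x - E_h) / denom), ids)
  ## no shared k-mer with the subtree (or nothing left to apportion under
  ## the parent) means no support for descending, whatever E_h says
  s_raw[profile$n == 0 | x == 0 |
          (!is.na(x_parent) & x_parent == 0)] <- -1
  s <- stats::setNames(pmax(0, s_raw), ids)
  s_raw[[family_id]] <- s[[family_id]] <- NA_real_  # root has no subfamily score

  ## summed path scores, computed root-down (ids are in increasing depth)
  idx <- hog_index(h, ids)
  ps <- stats::setNames(numeric(length(ids)), ids)
  for (j in seq_along(ids)[-1L]) {
    parent_id <- h$ids[h$parent[idx[j]]]
    ps[j] <- ps[[parent_id]] + s[[ids[j]]]
  }
  is_leaf <- lengths(h$children[idx]) == 0L
  leaves <- ids[is_leaf]
  best_leaf <- leaves[order(-ps[leaves], leaves)][1L]

  path_ids <- root_path(h, best_leaf, include_root = FALSE)
  node <- family_id
  for (child in path_ids) {
    if (is.na(s_raw[[child]]) || s_raw[[child]] < theta_sub) break
    node <- child
  }
  list(subfamily_id = node,
       score = if (node == family_id) fam_score else s[[node]],
       family_score = fam_score,
       path = data.frame(hog_id = path_ids,
                         s_raw = unname(s_raw[path_ids]),
                         s = unname(s[path_ids]),
                         stringsAsFactors = FALSE))
}

#' Overlap score of a query with its assigned family
#'
#' Fraction of query residues covered by at least one window of a k-mer that
#' (a) has a table entry for the family and (b) occurs exactly once in the
#' query. Low values flag partial (e.g. domain-level) matches.
#'
#' @inheritParams subtree_hit_counts
#' @return numeric fraction in `[0, 1]`.
#' @export
overlap_score <- function(profile, table, family_id) {
  if (profile$length == 0L) return(0)
  fam_i <- match(family_id, table$family_ids)
  me <- match_entries(profile$codes, table)
  fam_codes <- me$code[me$fam == fam_i]
  occ <- table(profile$positions$code)
  once <- as.integer(names(occ)[occ == 1L])
  use <- profile$positions[profile$positions$code %in% intersect(fam_codes, once),
                           "pos"]
  if (!length(use)) return(0)
  covered <- unique(rep(use, each = profile$k) +
                      rep(0:(profile$k - 1L), times = length(use)))
  length(covered) / profile$length
}

#' Assign a set of query proteins to families and subfamilies
#'
#' End-to-end search: each query is profiled, assigned to the best-scoring
#' family (if any reaches `theta_family`), refined to a subfamily and given
#' an overlap score. Results keep the input order.
#'
#' @param queries FASTA path, named character vector of sequences, or
#'   data.frame with columns `id`, `sequence`.
#' @param table a [build_kmer_table()] result.
#' @param theta_family,theta_sub score thresholds, see [assign_family()] and
#'   [assign_subfamily()].
#' @param top_n candidate families scored per query.
#' @return data.frame with columns `query_id`, `family_id`, `family_score`,
#'   `subfamily_id`, `subfamily_score`, `overlap_score` plus a list-column
#'   `path` holding each query's scored root-to-leaf path (for threshold
#'   sweeps in validation). Unassigned queries carry `NA` ids.
#' @export
search_queries <- function(queries, table, theta_family = 0.05,
                           theta_sub = 0.1, top_n = 100L) {
  q <- as_query_set(queries)
  res <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    prof <- profile_query(q$sequence[i], table$k, query_id = q$id[i])
    fam <- assign_family(prof, table, theta_family = theta_family,
                         top_n = top_n)
    if (is.na(fam$family_id)) {
      res[[i]] <- list(query_id = q$id[i], family_id = NA_character_,
                       family_score = fam$score,
                       subfamily_id = NA_character_,
                       subfamily_score = NA_real_, overlap_score = NA_real_,
                       path = data.frame(hog_id = character(0),
                                         s_raw = numeric(0), s = numeric(0)))
    } else {
      sub <- assign_subfamily(prof, table, fam$family_id,
                              theta_sub = theta_sub)
      res[[i]] <- list(query_id = q$id[i], family_id = fam$family_id,
                       family_score = fam$score,
                       subfamily_id = sub$subfamily_id,
                       subfamily_score = sub$score,
                       overlap_score = overlap_score(prof, table,
                                                     fam$family_id),
                       path = sub$path)
    }
  }
  out <- data.frame(
    query_id = vapply(res, `[[`, "", "query_id"),
    family_id = vapply(res, `[[`, "", "family_id"),
    family_score = vapply(res, `[[`, 0, "family_score"),
    subfamily_id = vapply(res, `[[`, "", "subfamily_id"),
    subfamily_score = vapply(res, `[[`, 0, "subfamily_score"),
    overlap_score = vapply(res, `[[`, 0, "overlap_score"),
    stringsAsFactors = FALSE)
  out$path <- lapply(res, `[[`, "path")
  out
}

as_query_set <- function(queries) {
  if (is.data.frame(queries)) {
    stopifnot(all(c("id", "sequence") %in% names(queries)))
    data.frame(id = as.character(queries$id),
               sequence = as.character(queries$sequence),
               stringsAsFactors = FALSE)
  } else if (is.character(queries) && length(queries) == 1L &&
             file.exists(queries)) {
    read_protein_fasta(queries)[, c("id", "sequence")]
  } else if (is.character(queries)) {
    if (is.null(names(queries))) stop("query sequences must be named")
    data.frame(id = names(queries), sequence = unname(queries),
               stringsAsFactors = FALSE)
  } else stop("unsupported query input")
}

#' Write assignment results as TSV
#'
#' Columns `query_id family_id family_score subfamily_id subfamily_score
#' overlap_score`; scores with 6 decimal places, `NA` for unassigned.
#'
#' @param results a [search_queries()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  out <- data.frame(query_id = results$query_id,
                    family_id = ifelse(is.na(results$family_id), "NA",
                                       results$family_id),
                    family_score = fmt(results$family_score),
                    subfamily_id = ifelse(is.na(results$subfamily_id), "NA",
                                          results$subfamily_id),
                    subfamily_score = fmt(results$subfamily_score),
                    overlap_score = fmt(results$overlap_score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
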