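#' Alignment parameters for the closest-sequence baseline
#'
#' Field-standard defaults: BLOSUM62 with affine gap penalties, a gap of
#' length L costing `gap_open + L * gap_extend` (NCBI convention, identical
#' to the Biostrings `gapOpening`/`gapExtension` semantics).
#'
#' @param matrix substitution matrix name available in Biostrings
#'   (`"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`, ...).
#' @param gap_open,gap_extend nonnegative penalties.
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  sub <- get(matrix, envir = e)
  structure(list(matrix = matrix, sub = sub, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("<alignment_params> ", x$matrix, ", gap open ", x$gap_open,
      ", extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

## sequence -> 0-based indices into the substitution matrix rows; residues
## absent from the matrix map to X (present in all BLOSUM/PAM matrices)
sw_encode <- function(sequence, params) {
  rn <- rownames(params$sub)
  i <- match(strsplit(toupper(sequence), "")[[1]], rn)
  i[is.na(i)] <- match("X", rn)
  i - 1L
}

#' Smith-Waterman local alignment score
#'
#' Exact affine-gap dynamic programming; guaranteed to find the highest
#' scoring local match. Empty sequences score 0, as does any pair whose best
#' local alignment is empty.
#'
#' @param a,b amino-acid strings.
#' @param params an [alignment_params()] object.
#' @return numeric alignment score (>= 0).
#' @export
smith_waterman_score <- function(a, b, params = alignment_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  cpp_sw_score(sw_encode(a, params), sw_encode(b, params), params$sub,
               params$gap_open, params$gap_extend)
}

#' Closest reference sequence(s) by Smith-Waterman score
#'
#' Brute-force argmax of the exact local alignment score over all reference
#' proteins; ties break deterministically to the smallest protein id.
#'
#' @param queries FASTA path, named character vector, or data.frame with
#'   `id`, `sequence`.
#' @param db a [reference_db()].
#' @param params an [alignment_params()] object.
#' @return data.frame `query_id`, `closest_id`, `score`.
#' @export
closest_sequences <- function(queries, db, params = alignment_params()) {
  q <- as_query_set(queries)
  refs <- lapply(db$proteins$sequence, sw_encode, params = params)
  ord <- order(db$proteins$id)      # ties resolve to smallest id
  refs <- refs[ord]
  ids <- db$proteins$id[ord]
  out <- data.frame(query_id = q$id, closest_id = NA_character_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(q))) {
    sc <- cpp_sw_scores(sw_encode(q$sequence[i], params), refs, params$sub,
                        params$gap_open, params$gap_extend)
    j <- which.max(sc)              # first max = smallest id
    out$closest_id[i] <- ids[j]
    out$score[i] <- sc[j]
  }
  out
}

#' @rdname closest_sequences
#' @param query a single amino-acid string.
#' @return `closest_sequence()`: the closest protein's id.
#' @export
closest_sequence <- function(query, db, params = alignment_params()) {
  closest_sequences(data.frame(id = "q", sequence = query), db,
                    params)$closest_id
}

#' The four configuration labels
#' @return character vector of the labels in their conventional order.
#' @export
configuration_labels <- function() {
  c("true_subfamily", "over_specific", "under_specific", "wrong_path")
}

#' Classify a (query, closest-sequence) pair within a family
#'
#' Compares the query's true most specific HOG with the closest sequence's
#' most specific HOG: `true_subfamily` when they are the same;
#' `over_specific` when the query's HOG is (strictly) ancestral to the
#' closest sequence's; `under_specific` when the closest sequence's HOG is
#' ancestral to the query's; `wrong_path` when the two HOGs sit in different
#' parts of the family tree. Exhaustive and mutually exclusive. Pairs from
#' different families are an error - family misassignment is handled
#' upstream.
#'
#' @param true_hog,closest_hog HOG ids in the same family.
#' @param hierarchy a [hog_hierarchy()].
#' @return one of [configuration_labels()].
#' @export
classify_configuration <- function(true_hog, closest_hog, hierarchy) {
  if (hog_family(hierarchy, true_hog) != hog_family(hierarchy, closest_hog))
    stop("HOGs in different families: ", true_hog, " vs ", closest_hog)
  if (true_hog == closest_hog) return("true_subfamily")
  if (is_ancestor(hierarchy, true_hog, closest_hog)) return("over_specific")
  if (is_ancestor(hierarchy, closest_hog, true_hog)) return("under_specific")
  "wrong_path"
}

#' Published amino-acid background frequencies
#'
#' The UniProtKB/Swiss-Prot residue composition table (percent frequencies of
#' the 20 canonical residues, ~2020 releases), renormalized to sum to 1; the
#' default background for random negative queries and simulated root
#' sequences.
#'
#' @return named numeric vector over [aa_alphabet()], summing to 1.
#' @export
uniprot_aa_freqs <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
         G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
         M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
         S = 6.63, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Simulated random negative queries
#'
#' Random proteins with residues drawn i.i.d. from a stated background
#' frequency vector and lengths copied from the positive query set, so each
#' negative matches a positive in length.
#'
#' @param aa_freqs named frequency vector over [aa_alphabet()], summing to 1
#'   (tolerance 1e-9).
#' @param lengths integer vector of sequence lengths (those of the positives).
#' @param seed integer seed; same seed, same records.
#' @return data.frame `id`, `species` (`NA`), `sequence`.
#' @export
make_random_negatives <- function(aa_freqs = uniprot_aa_freqs(), lengths,
                                  seed = 1L) {
  stopifnot(setequal(names(aa_freqs), aa_alphabet()))
  if (abs(sum(aa_freqs) - 1) > 1e-9)
    stop("aa_freqs must sum to 1 (got ", sum(aa_freqs), ")")
  aa_freqs <- aa_freqs[aa_alphabet()]
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(aa_alphabet(), L, replace = TRUE, prob = aa_freqs),
          collapse = ""), "")
  data.frame(id = sprintf("negrand_%04d", seq_along(lengths)),
             species = NA_character_, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Clade-specific negative queries
#'
#' Emulates contamination / horizontal transfer: each negative is drawn from
#' a distinct donor family outside the taxonomic scope of the reference
#' families (the donor database must share no family with the reference).
#'
#' @param donor_db a [reference_db()] whose families are disjoint from the
#'   reference families under test.
#' @param n number of negatives; at most the number of donor families.
#' @param seed integer seed.
#' @return data.frame of donor proteins (`id`, `species`, `sequence`,
#'   `donor_family`), one per selected family.
#' @export
make_clade_negatives <- function(donor_db, n, seed = 1L) {
  h <- donor_db$hierarchy
  fams <- hog_family(h, donor_db$proteins$hog_id)
  ufam <- sort(unique(fams))
  if (n > length(ufam))
    stop("requested ", n, " negatives but only ", length(ufam),
         " donor families")
  set.seed(seed)
  pick_fams <- sample(ufam, n)
  rows <- vapply(pick_fams, function(f) {
    cand <- which(fams == f)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, 0L)
  out <- donor_db$proteins[rows, c("id", "species", "sequence")]
  out$donor_family <- pick_fams
  rownames(out) <- NULL
  out
}

pr_curve <- function(curve, n_pos = NA_integer_, n_neg = NA_integer_,
                     counts = NULL) {
  f1 <- ifelse(curve$precision + curve$recall == 0, 0,
               2 * curve$precision * curve$recall /
                 (curve$precision + curve$recall))
  curve$f1 <- f1
  i <- which.max(f1)
  structure(list(curve = curve, f1_max = f1[i],
                 threshold_f1max = curve$threshold[i],
                 n_pos = n_pos, n_neg = n_neg, counts = counts),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$curve), " thresholds; F1_max = ",
      sprintf("%.4f", x$f1_max), " at threshold ",
      sprintf("%.4f", x$threshold_f1max), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.pr_curve <- function(x, ...) x$curve

#' Family-level precision/recall validation
#'
#' For each score threshold t: false positives are negative queries assigned
#' to any family with score >= t plus positive queries assigned to a wrong
#' family with score >= t; positives assigned to their true family split into
#' true positives (score >= t) and false negatives; wrong-family and
#' unassigned positives always count as false negatives (they are missing
#' from their family of origin at every threshold), so recall is
#' TP / number of positives.
#'
#' @param results data.frame `query_id`, `family_id` (assigned, `NA` when
#'   unassigned), `score` (e.g. [search_queries()] output with `family_score`
#'   renamed, or any method's scored family calls).
#' @param truth data.frame `query_id`, `family_id` (true family; `NA` marks a
#'   negative query).
#' @param thresholds score grid; defaults to the sorted set of observed
#'   scores of assigned queries (exact curve, no discretization).
#' @return a `pr_curve` object with `f1_max` and its threshold.
#' @export
family_validation <- function(results, truth, thresholds = NULL) {
  m <- merge(results[, c("query_id", "family_id", "score")],
             stats::setNames(truth[, c("query_id", "family_id")],
                             c("query_id", "true_family")),
             by = "query_id")
  if (nrow(m) != nrow(results)) stop("truth missing for some queries")
  if (anyNA(m$score[!is.na(m$family_id)])) stop("assigned query without score")
  is_neg <- is.na(m$true_family)
  assigned <- !is.na(m$family_id)
  s_negassigned <- m$score[is_neg & assigned]
  s_correct <- m$score[!is_neg & assigned & m$family_id == m$true_family]
  s_wrong <- m$score[!is_neg & assigned & m$family_id != m$true_family]
  n_pos_unassigned <- sum(!is_neg & !assigned)
  if (is.null(thresholds))
    thresholds <- sort(unique(m$score[assigned]))
  counts <- vapply(thresholds, function(t) {
    TP <- sum(s_correct >= t)
    FP <- sum(s_negassigned >= t) + sum(s_wrong >= t)
    FN <- sum(s_correct < t) + length(s_wrong) + n_pos_unassigned
    c(TP, FP, FN)
  }, numeric(3))
  TP <- counts[1, ]; FP <- counts[2, ]; FN <- counts[3, ]
  curve <- data.frame(threshold = thresholds,
                      precision = ifelse(TP + FP == 0, 1, TP / (TP + FP)),
                      recall = ifelse(TP + FN == 0, 1, TP / (TP + FN)))
  pr_curve(curve, n_pos = sum(!is_neg), n_neg = sum(is_neg),
           counts = data.frame(threshold = thresholds, TP = TP, FP = FP,
                               FN = FN))
}

#' Positive queries counted as family-level true positives at F1_max
#'
#' Helper for the subfamily analyses, which are restricted to the queries a
#' method assigned to the correct family at its family-level F1_max
#' threshold (intersect across methods before comparing them).
#'
#' @inheritParams family_validation
#' @return character vector of query ids.
#' @export
family_tps <- function(results, truth, thresholds = NULL) {
  pr <- family_validation(results, truth, thresholds)
  m <- merge(results[, c("query_id", "family_id", "score")],
             stats::setNames(truth[, c("query_id", "family_id")],
                             c("query_id", "true_family")),
             by = "query_id")
  ok <- !is.na(m$true_family) & !is.na(m$family_id) &
    m$family_id == m$true_family & m$score >= pr$threshold_f1max
  m$query_id[ok]
}

## per-query path material for the subfamily curves:
## pred ids/raw scores along the chosen root path (non-root), true non-root
## path, common prefix length
subfamily_paths <- function(results, truth, hierarchy) {
  m <- match(results$query_id, truth$query_id)
  if (anyNA(m)) stop("truth missing for queries: ",
                     paste(results$query_id[is.na(m)], collapse = ", "))
  true_hog <- truth$hog_id[m]
  lapply(seq_len(nrow(results)), function(i) {
    fam <- results$family_id[i]
    if (is.na(fam)) stop("subfamily validation on unassigned query: ",
                         results$query_id[i])
    if (hog_family(hierarchy, true_hog[i]) != fam)
      stop("query ", results$query_id[i],
           " assigned outside its true family; filter to family TPs first")
    if (!is.null(results$path)) {
      p <- results$path[[i]]
      pred_ids <- p$hog_id
      pred_s <- p$s_raw
    } else {
      pred_ids <- root_path(hierarchy, results$subfamily_id[i],
                            include_root = FALSE)
      pred_s <- rep(results$subfamily_score[i], length(pred_ids))
    }
    t_ids <- root_path(hierarchy, true_hog[i], include_root = FALSE)
    cpl <- 0L
    while (cpl < min(length(pred_ids), length(t_ids)) &&
           pred_ids[cpl + 1L] == t_ids[cpl + 1L]) cpl <- cpl + 1L
    list(pred_s = pred_s, prefix_min = cummin(if (length(pred_s)) pred_s
                                              else numeric(0)),
         cpl = cpl, tlen = length(t_ids), plen = length(pred_ids))
  })
}

#' Subfamily-level precision/recall validation
#'
#' Implicit mode treats an assignment to a subfamily as implying its parental
#' subfamilies: with P the non-root HOGs from root to prediction and T those
#' from root to truth, each query contributes `|P intersect T|` true
#' positives, `|P \\ T|` false positives and `|T \\ P|` false negatives; no
#' credit is given for the root-HOG itself, since only within-family
#' placement is assessed. Stringent mode gives no reward for partial
#' correctness: an exactly right prediction is one TP, a root-level
#' prediction with a deeper truth is one FN, and any other wrong prediction
#' is one FP plus one FN.
#'
#' At threshold t a query's prediction is the deepest HOG on its stored
#' root-to-leaf path whose ancestors (itself included) all have raw score
#' >= t - i.e. the descent rule of [assign_subfamily()] swept over t.
#'
#' @param results [search_queries()] output (uses the `path` list-column), or
#'   any data.frame with `query_id`, `family_id`, `subfamily_id`,
#'   `subfamily_score` (flat scores, e.g. a closest-sequence method where
#'   every node on the path inherits the alignment score). Queries must
#'   already be restricted to family-level true positives.
#' @param truth data.frame `query_id`, `hog_id` (true most specific HOG).
#' @param hierarchy the full [hog_hierarchy()] (must contain the true HOGs,
#'   which leave-one-out pruning may have removed from the reference).
#' @param mode `"implicit"` or `"stringent"`.
#' @param thresholds score grid; defaults to the sorted set of observed path
#'   scores.
#' @return a `pr_curve` object.
#' @export
subfamily_validation <- function(results, truth, hierarchy,
                                 mode = c("implicit", "stringent"),
                                 thresholds = NULL) {
  mode <- match.arg(mode)
  pp <- subfamily_paths(results, truth, hierarchy)
  if (is.null(thresholds)) {
    obs <- unlist(lapply(pp, `[[`, "pred_s"), use.names = FALSE)
    thresholds <- sort(unique(obs[is.finite(obs)]))
    if (!length(thresholds)) thresholds <- 0
  }
  nq <- length(pp)
  lmax <- max(c(1L, vapply(pp, `[[`, 0L, "plen")))
  PM <- matrix(-Inf, nrow = nq, ncol = lmax)
  for (i in seq_len(nq))
    if (pp[[i]]$plen > 0L) PM[i, seq_len(pp[[i]]$plen)] <- pp[[i]]$prefix_min
  cpl <- vapply(pp, `[[`, 0L, "cpl")
  tlen <- vapply(pp, `[[`, 0L, "tlen")
  counts <- vapply(thresholds, function(t) {
    pd <- rowSums(PM >= t)
    cp <- pmin(pd, cpl)
    if (mode == "implicit") {
      c(sum(cp), sum(pd - cp), sum(tlen - cp))
    } else {
      eq <- pd == tlen & cp == pd
      c(sum(eq), sum(!eq & pd > 0), sum(!eq & pd == 0 & tlen > 0) +
          sum(!eq & pd > 0))
    }
  }, numeric(3))
  TP <- counts[1, ]; FP <- counts[2, ]; FN <- counts[3, ]
  curve <- data.frame(threshold = thresholds,
                      precision = ifelse(TP + FP == 0, 1, TP / (TP + FP)),
                      recall = ifelse(TP + FN == 0, 1, TP / (TP + FN)))
  pr_curve(curve, n_pos = nq,
           counts = data.frame(threshold = thresholds, TP = TP, FP = FP,
                               FN = FN))
}

#' Closest-sequence configuration frequencies
#'
#' Runs the Smith-Waterman closest-sequence oracle for each query against a
#' leave-one-out reference database and tabulates the four configurations of
#' [classify_configuration()] over the queries whose closest sequence lies in
#' their own family; queries whose closest sequence falls in a different
#' family are family-level errors, excluded from the denominator and
#' reported in the attributes.
#'
#' @param queries data.frame `id`, `sequence`, `hog_id` (true most specific
#'   HOG, from the truth labels).
#' @param db the leave-one-out [reference_db()].
#' @param params an [alignment_params()].
#' @param hierarchy hierarchy containing both the query and reference HOGs
#'   (default `db$hierarchy`; pass the full truth hierarchy when
#'   leave-one-out pruning removed query-specific HOGs).
#' @param closest optional precomputed [closest_sequences()] result.
#' @return named numeric vector over [configuration_labels()], summing to 1;
#'   attributes `n_used`, `n_other_family` and `details` (per-query
#'   data.frame).
#' @export
configuration_frequencies <- function(queries, db,
                                      params = alignment_params(),
                                      hierarchy = db$hierarchy,
                                      closest = NULL) {
  if (is.null(closest)) closest <- closest_sequences(queries, db, params)
  stopifnot(identical(closest$query_id, queries$id))
  closest_hog <- most_specific_hog(db, closest$closest_id)
  same_fam <- hog_family(hierarchy, queries$hog_id) ==
    hog_family(hierarchy, closest_hog)
  lab <- rep(NA_character_, nrow(queries))
  for (i in which(same_fam))
    lab[i] <- classify_configuration(queries$hog_id[i], closest_hog[i],
                                     hierarchy)
  freq <- table(factor(lab[same_fam], levels = configuration_labels()))
  out <- as.numeric(freq) / max(1L, sum(same_fam))
  names(out) <- configuration_labels()
  attr(out, "n_used") <- sum(same_fam)
  attr(out, "n_other_family") <- sum(!same_fam)
  attr(out, "details") <- data.frame(query_id = queries$id,
                                     true_hog = queries$hog_id,
                                     closest_id = closest$closest_id,
                                     closest_hog = closest_hog,
                                     score = closest$score,
                                     same_family = same_fam,
                                     configuration = lab,
                                     stringsAsFactors = FALSE)
  out
}
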