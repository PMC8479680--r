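test_that("Smith-Waterman matches an independent DP oracle and Biostrings", {
  params <- alignment_params()
  # identical sequences: sum of diagonal substitution scores
  s <- "ACDEFGHIKLMNPQRSTVWY"
  diag_sum <- sum(blosum62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(smith_waterman_score(s, s, params), diag_sum)
  # empty local alignment scores 0
  expect_equal(smith_waterman_score("WWWW", "GGGG", params), 0)
  expect_equal(smith_waterman_score("", "ACD", params), 0)
  # 200 random pairs against the second DP implementation
  set.seed(61)
  for (i in 1:200) {
    a <- random_aa(sample(5:60, 1))
    b <- random_aa(sample(5:60, 1))
    expect_equal(smith_waterman_score(a, b, params),
                 oracle_sw(a, b, blosum62))
  }
  # spot-check a third, independent implementation on longer pairs
  for (i in 1:20) {
    a <- random_aa(120); b <- random_aa(120)
    bio <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = blosum62,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    expect_equal(smith_waterman_score(a, b, params), max(0, bio))
  }
})

test_that("closest sequence is the SW argmax with deterministic ties", {
  fx <- small_fixture(seed = 33, n_families = 3)
  db <- fx$ref_db
  params <- alignment_params()
  # a reference protein's closest sequence is itself
  some <- db$proteins[sample(nrow(db$proteins), 5), ]
  cs <- closest_sequences(some[, c("id", "sequence")], db, params)
  expect_equal(cs$closest_id, some$id)
  # duplicated sequences tie -> smallest id wins
  dupdb <- reference_db(
    data.frame(id = c("b", "a"), species = "S",
               sequence = "ACDEFGHIKL", hog_id = "H"),
    data.frame(id = "H", parent_id = NA), k = 2)
  expect_equal(closest_sequence("ACDEFGHIKL", dupdb, params), "a")
  # leave-one-out: a removed protein is never its own closest sequence
  q <- fx$queries[1:3, ]
  cs2 <- closest_sequences(q[, c("id", "sequence")], db, params)
  expect_false(any(cs2$closest_id %in% q$id))
})

test_that("configuration classification matches its definition exactly", {
  hogs <- data.frame(id = c("F", "F.1", "F.2", "F.1.1", "G"),
                     parent_id = c(NA, "F", "F", "F.1", NA))
  h <- hog_hierarchy(hogs)
  expect_equal(classify_configuration("F.1", "F.1", h), "true_subfamily")
  expect_equal(classify_configuration("F.1", "F.1.1", h), "over_specific")
  expect_equal(classify_configuration("F.1.1", "F.1", h), "under_specific")
  expect_equal(classify_configuration("F.1", "F.2", h), "wrong_path")
  expect_error(classify_configuration("F.1", "G", h), "different families")
  # brute-force re-derivation over all ordered pairs of a random family
  hogs30 <- random_hogs(n = 30, n_roots = 1, seed = 71)
  h30 <- hog_hierarchy(hogs30)
  for (a in hogs30$id) {
    for (b in hogs30$id) {
      want <- if (a == b) "true_subfamily"
        else if (oracle_is_ancestor(hogs30, a, b)) "over_specific"
        else if (oracle_is_ancestor(hogs30, b, a)) "under_specific"
        else "wrong_path"
      expect_equal(classify_configuration(a, b, h30), want)
    }
  }
})

test_that("random negatives reproduce the stated composition and lengths", {
  freqs <- uniprot_aa_freqs()
  lens <- c(300, 500, 700)
  neg <- make_random_negatives(freqs, lens, seed = 5)
  expect_equal(nchar(neg$sequence), lens)
  neg2 <- make_random_negatives(freqs, lens, seed = 5)
  expect_identical(neg, neg2)
  # empirical frequencies of a large sample within 3 sigma per residue
  big <- make_random_negatives(freqs, rep(10000, 20), seed = 6)
  res <- table(factor(strsplit(paste(big$sequence, collapse = ""), "")[[1]],
                      levels = aa_alphabet()))
  n <- sum(res)
  for (a in aa_alphabet()) {
    p <- freqs[[a]]
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(res[[a]] - n * p), 3.3 * sigma)
  }
  expect_error(make_random_negatives(freqs * 2, lens), "sum to 1")
})

test_that("clade negatives draw one protein from each distinct donor family", {
  donor <- small_fixture(seed = 35, n_families = 4)$full_db
  n_fam <- sum(is.na(donor$hierarchy$parent))
  neg <- make_clade_negatives(donor, n_fam, seed = 2)
  expect_equal(length(unique(neg$donor_family)), n_fam)
  expect_equal(nrow(neg), n_fam)
  expect_error(make_clade_negatives(donor, n_fam + 1), "donor families")
  # donor ids are disjoint from an unrelated reference database
  ref <- standard_db(seed = 36)$db
  expect_length(intersect(neg$id, ref$proteins$id), 0L)
})

test_that("family validation reproduces hand-counted toys", {
  # perfect method: precision = recall = 1 everywhere
  res <- data.frame(query_id = c("q1", "q2", "n1"),
                    family_id = c("F", "G", NA),
                    score = c(1, 1, NA))
  truth <- data.frame(query_id = c("q1", "q2", "n1"),
                      family_id = c("F", "G", NA))
  pr <- family_validation(res, truth)
  expect_true(all(pr$curve$precision == 1))
  expect_true(all(pr$curve$recall == 1))
  expect_equal(pr$f1_max, 1)

  # hand-counted toy: 3 positives (2 correct at .9/.4, 1 wrong at .8),
  # 1 negative at .7; at t = .5: TP=1, FP=2, FN=2
  res2 <- data.frame(query_id = c("p1", "p2", "p3", "n1"),
                     family_id = c("F", "F", "H", "F"),
                     score = c(.9, .4, .8, .7))
  truth2 <- data.frame(query_id = c("p1", "p2", "p3", "n1"),
                       family_id = c("F", "F", "G", NA))
  pr2 <- family_validation(res2, truth2, thresholds = 0.5)
  expect_equal(pr2$curve$precision, 1 / 3)
  expect_equal(pr2$curve$recall, 1 / 3)
  # recall non-increasing across the default grid
  pr3 <- family_validation(res2, truth2)
  expect_true(all(diff(pr3$curve$recall) <= 0))
})

test_that("subfamily validation counts the worked alcohol-dehydrogenase case", {
  # family "adh" with sub-HOG adh.1 and its children adh.1.B / adh.1.C
  hogs <- data.frame(id = c("adh", "adh.1", "adh.1.B", "adh.1.C"),
                     parent_id = c(NA, "adh", "adh.1", "adh.1"))
  h <- hog_hierarchy(hogs)
  res <- data.frame(query_id = "q", family_id = "adh",
                    subfamily_id = "adh.1.B", subfamily_score = 0.9,
                    stringsAsFactors = FALSE)
  truth <- data.frame(query_id = "q", hog_id = "adh.1.C",
                      stringsAsFactors = FALSE)
  imp <- subfamily_validation(res, truth, h, mode = "implicit",
                              thresholds = 0)
  # predicted path adh.1 -> adh.1.B vs true adh.1 -> adh.1.C:
  # one TP for the shared parent, one FP, one FN; root never rewarded
  expect_equal(imp$curve$precision, 1 / 2)
  expect_equal(imp$curve$recall, 1 / 2)
  str <- subfamily_validation(res, truth, h, mode = "stringent",
                              thresholds = 0)
  expect_equal(str$curve$precision, 0)   # TP=0, FP=1, FN=1
  expect_equal(str$curve$recall, 0)
  # exactly right prediction at depth 3: a three-level chain
  hogs3 <- data.frame(id = c("r", "r.1", "r.1.1", "r.1.1.1"),
                      parent_id = c(NA, "r", "r.1", "r.1.1"))
  h3 <- hog_hierarchy(hogs3)
  resd <- data.frame(query_id = "q", family_id = "r",
                     subfamily_id = "r.1.1.1", subfamily_score = 1)
  trd <- data.frame(query_id = "q", hog_id = "r.1.1.1")
  imp3 <- subfamily_validation(resd, trd, h3, mode = "implicit",
                               thresholds = 0.5)
  expect_equal(imp3$curve$precision, 1)  # TP=3, FP=0, FN=0
  expect_equal(imp3$curve$recall, 1)
  # a root-level prediction with a deeper truth: stringent FN only
  resr <- data.frame(query_id = "q", family_id = "r",
                     subfamily_id = "r", subfamily_score = 1)
  strr <- subfamily_validation(resr, trd, h3, mode = "stringent",
                               thresholds = 0.5)
  expect_equal(strr$curve$precision, 1)  # no prediction made: TP+FP = 0
  expect_equal(strr$curve$recall, 0)
})

test_that("implicit TP+FN per query equals the true path depth", {
  fx <- small_fixture(seed = 37)
  tab <- build_kmer_table(fx$ref_db)
  res <- search_queries(fx$queries[, c("id", "sequence")], tab,
                        theta_family = 0, theta_sub = 0)
  truth <- data.frame(query_id = fx$queries$id, hog_id = fx$queries$hog_id)
  keep <- !is.na(res$family_id) &
    res$family_id == fx$queries$family_id[match(res$query_id, fx$queries$id)]
  res <- res[keep, ]
  truth <- truth[truth$query_id %in% res$query_id, ]
  h <- fx$truth$hierarchy
  tlen_sum <- sum(hog_depth(h, truth$hog_id))
  # TP + FN = sum of true path depths at every threshold (implicit mode)
  pr2 <- subfamily_validation(res, truth, h, mode = "implicit")
  expect_true(all(pr2$counts$TP + pr2$counts$FN == tlen_sum))
  expect_true(all(diff(pr2$curve$recall) <= 1e-12))
  expect_true(all(pr2$curve$precision >= 0 & pr2$curve$precision <= 1))
  # stringent mode: TP + FP at most 1 per query
  pr3 <- subfamily_validation(res, truth, h, mode = "stringent")
  expect_true(all(pr3$counts$TP + pr3$counts$FP <= nrow(res)))
})

test_that("configuration frequencies sum to 1 and behave without duplications", {
  # no duplications -> no sub-HOGs -> always true_subfamily
  fx0 <- make_fixture(sim_params(n_families = 3, n_species = 4,
                                 duplication_rate = 0, root_length = 80,
                                 seed = 41), k = 6)
  expect_true(all(hog_depth(fx0$truth$hierarchy,
                            fx0$truth$hierarchy$ids) == 0L))
  freq0 <- configuration_frequencies(
    fx0$queries[, c("id", "sequence", "hog_id")], fx0$ref_db,
    hierarchy = fx0$truth$hierarchy)
  expect_equal(sum(freq0), 1)
  expect_equal(unname(freq0["true_subfamily"]), 1)
  # with duplications the four fractions still sum to 1 exactly
  fx <- small_fixture(seed = 43)
  freq <- configuration_frequencies(
    fx$queries[, c("id", "sequence", "hog_id")], fx$ref_db,
    hierarchy = fx$truth$hierarchy)
  expect_equal(sum(freq), 1)
  details <- attr(freq, "details")
  expect_equal(nrow(details), nrow(fx$queries))
})
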