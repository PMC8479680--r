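test_that("query profiling skips short sequences and bad windows", {
  p <- profile_query("AAA", 2)
  expect_equal(p$n, 1L)
  expect_equal(decode_kmer(p$codes, 2), "AA")
  expect_equal(p$positions$pos, c(1L, 2L))

  p2 <- profile_query("AXXA", 2)
  expect_equal(p2$n, 0L)
  p3 <- profile_query("AC", 6)
  expect_equal(p3$n, 0L)

  set.seed(51)
  for (i in 1:100) {
    L <- sample(3:40, 1)
    s <- random_aa(L, alphabet = c(aa_alphabet(), "X"))
    k <- sample(2:4, 1)
    expect_equal(profile_query(s, k)$n, length(oracle_kmers(s, k)))
  }
})

test_that("coarse family hits equal brute-force k-mer set intersections", {
  std <- standard_db(seed = 7, k = 3, len = 60)
  db <- std$db
  tab <- build_kmer_table(db)
  h <- tab$hierarchy
  fam_kmers <- lapply(tab$family_ids, function(f) {
    members <- db$proteins$sequence[hog_family(h, db$proteins$hog_id) == f]
    unique(unlist(lapply(members, oracle_kmers, k = 3)))
  })
  names(fam_kmers) <- tab$family_ids
  for (i in sample(nrow(db$proteins), 8)) {
    prof <- profile_query(db$proteins$sequence[i], 3)
    hits <- coarse_family_hits(prof, tab)
    qk <- oracle_kmers(db$proteins$sequence[i], 3)
    for (f in tab$family_ids) {
      want <- length(intersect(qk, fam_kmers[[f]]))
      got <- hits$x[hits$family_id == f]
      expect_equal(if (length(got)) got else 0L, want)
    }
  }
  # no shared k-mer -> empty hit list
  expect_equal(nrow(coarse_family_hits(profile_query("WWWWWWWW", 3), tab)),
               0L)
})

test_that("family score behaves at its limits and increases with x", {
  # perfect match: x = n with small expectation -> exactly 1
  hit <- data.frame(family_id = "F", x = 50L)
  prof <- list(n = 50L)
  tab <- list(m_family = c(F = 1e4), k = 6L, alphabet = aa_alphabet())
  expect_equal(family_score(hit, prof, tab), 1)
  # chance level: x ~ E -> ~0
  p <- 1 - (1 - 20^-6)^1e4
  E <- 50 * p
  expect_lt(family_score(data.frame(family_id = "F", x = round(E)),
                         prof, tab), 0.01)
  # strict monotonicity in x over the admissible range
  xs <- ceiling(E):50
  sc <- family_score(data.frame(family_id = "F", x = xs), prof, tab)
  expect_true(all(diff(sc) > 0))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("family assignment finds the home family of every self-query", {
  std <- standard_db(seed = 7, k = 3, len = 60)
  db <- std$db
  tab <- build_kmer_table(db)
  h <- tab$hierarchy
  for (i in seq_len(nrow(db$proteins))) {
    prof <- profile_query(db$proteins$sequence[i], 3)
    fam <- assign_family(prof, tab, theta_family = 0)
    expect_equal(fam$family_id, hog_family(h, db$proteins$hog_id[i]))
    expect_equal(max(fam$candidates$score), fam$score)
  }
  # n = 0 and threshold-dominates cases
  expect_true(is.na(assign_family(profile_query("A", 3), tab)$family_id))
  prof <- profile_query(db$proteins$sequence[1], 3)
  expect_true(is.na(assign_family(prof, tab, theta_family = 1.01)$family_id))
})

test_that("subtree hit counts are monotone and partition the family count", {
  fx <- small_fixture(seed = 13)
  tab <- build_kmer_table(fx$ref_db)
  h <- tab$hierarchy
  for (i in sample(nrow(fx$ref_db$proteins), 12)) {
    prof <- profile_query(fx$ref_db$proteins$sequence[i], 6)
    fam <- assign_family(prof, tab, theta_family = 0)$family_id
    x <- subtree_hit_counts(prof, tab, fam)
    ids <- names(x)
    for (id in ids[-1]) {
      parent <- h$ids[h$parent[match(id, h$ids)]]
      expect_lte(x[[id]], x[[parent]])
    }
    # exact per-HOG counts partition the family's coarse count
    me <- hogmapper:::match_entries(prof$codes, tab)
    fam_i <- match(fam, tab$family_ids)
    expect_equal(unname(x[[fam]]), sum(me$fam == fam_i))
  }
})

test_that("subfamily refinement follows thresholds and the chosen path", {
  fx <- small_fixture(seed = 17)
  tab <- build_kmer_table(fx$ref_db)
  db <- fx$ref_db
  for (i in sample(nrow(db$proteins), 15)) {
    prof <- profile_query(db$proteins$sequence[i], 6)
    fam <- assign_family(prof, tab, theta_family = 0)$family_id
    # theta above 1 always reports the root
    hi <- assign_subfamily(prof, tab, fam, theta_sub = 1.01)
    expect_equal(hi$subfamily_id, fam)
    # theta 0 self-query reaches the true most specific HOG whenever some
    # k-mer maps exactly to it
    lo <- assign_subfamily(prof, tab, fam, theta_sub = 0)
    truth <- db$proteins$hog_id[i]
    me <- hogmapper:::match_entries(prof$codes, tab)
    exact <- sum(tab$hierarchy$ids[me$hog] == truth &
                   tab$family_ids[me$fam] == fam)
    if (truth != fam && exact > 0) expect_equal(lo$subfamily_id, truth)
    # threshold monotonicity: deeper theta never deepens the assignment
    mid <- assign_subfamily(prof, tab, fam, theta_sub = 0.3)
    expect_lte(hog_depth(tab$hierarchy, mid$subfamily_id),
               hog_depth(tab$hierarchy, lo$subfamily_id))
  }
})

test_that("overlap score measures unique-k-mer coverage", {
  std <- standard_db(seed = 7, k = 3, len = 60)
  tab <- build_kmer_table(std$db)
  h <- tab$hierarchy
  # exact copy of a reference member with all-unique k-mers -> 1
  i <- which(!vapply(std$db$proteins$sequence, function(s) {
    w <- strsplit(s, "")[[1]]
    any(duplicated(vapply(seq_len(length(w) - 2),
                          function(j) paste(w[j:(j + 2)], collapse = ""), "")))
  }, TRUE))[1]
  prof <- profile_query(std$db$proteins$sequence[i], 3)
  fam <- hog_family(h, std$db$proteins$hog_id[i])
  expect_equal(overlap_score(prof, tab, fam), 1)
  # no shared k-mer -> 0
  prof0 <- profile_query(paste(rep("W", 30), collapse = ""), 3)
  expect_equal(overlap_score(prof0, tab, fam), 0)
  # half-chimera: first half from a member, second half random (k = 6 table)
  fx <- small_fixture(seed = 19, n_families = 3)
  tab6 <- build_kmer_table(fx$ref_db)
  set.seed(99)
  donor <- fx$ref_db$proteins[1, ]
  half <- substr(donor$sequence, 1, 100)
  chim <- paste0(substr(paste0(half, random_aa(200)), 1, 100),
                 random_aa(100))
  profc <- profile_query(chim, 6)
  ov <- overlap_score(profc, tab6, hog_family(fx$ref_db$hierarchy,
                                              donor$hog_id))
  expect_gte(ov, 0.4)
  expect_lte(ov, 0.6)
})

test_that("end-to-end search is ordered, complete and threshold-consistent", {
  fx <- small_fixture(seed = 23)
  tab <- build_kmer_table(fx$ref_db)
  refs <- fx$ref_db$proteins
  res <- search_queries(refs[1:10, c("id", "sequence")], tab,
                        theta_family = 0, theta_sub = 0.1)
  expect_equal(res$query_id, refs$id[1:10])
  expect_equal(nrow(res), 10L)
  expect_true(all(res$family_score >= 0 & res$family_score <= 1))
  # raising theta_family never increases the number of assigned queries
  res_hi <- search_queries(refs[1:10, c("id", "sequence")], tab,
                           theta_family = 0.5, theta_sub = 0.1)
  expect_lte(sum(!is.na(res_hi$family_id)), sum(!is.na(res$family_id)))
  # empty query set
  empty <- search_queries(refs[0, c("id", "sequence")], tab)
  expect_equal(nrow(empty), 0L)
  # TSV writer emits 6-decimal scores and NA for unassigned
  tmp <- withr::local_tempfile(fileext = ".tsv")
  res$family_id[1] <- NA
  write_results(res, tmp)
  out <- read.delim(tmp, colClasses = "character", na.strings = character(0))
  expect_equal(out$family_id[1], "NA")
  expect_match(out$family_score[2], "^[0-9]+\\.[0-9]{6}$")
})

test_that("self-query path safety holds on the whole small fixture", {
  fx <- small_fixture(seed = 29)
  tab <- build_kmer_table(fx$full_db)
  db <- fx$full_db
  h <- tab$hierarchy
  for (i in seq_len(nrow(db$proteins))) {
    prof <- profile_query(db$proteins$sequence[i], 6)
    fam <- assign_family(prof, tab, theta_family = 0)$family_id
    truth <- db$proteins$hog_id[i]
    expect_equal(fam, hog_family(h, truth))
    sub <- assign_subfamily(prof, tab, fam, theta_sub = 0.1)$subfamily_id
    onpath <- sub == truth || is_ancestor(h, sub, truth)
    expect_true(onpath)
  }
})
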