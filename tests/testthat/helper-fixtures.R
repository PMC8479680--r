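# Hand-built and randomized fixtures, all constructed in code.

# three-HOG family of Fig-2B shape: green root with orange/purple children
fig2b_db <- function() {
  hogs <- data.frame(id = c("green", "orange", "purple"),
                     parent_id = c(NA, "green", "green"))
  prot <- data.frame(
    id = c("o1", "p1", "p2"),
    species = c("A", "B", "C"),
    # "AC" occurs in both sub-HOGs; "DE" only in orange; "GH" only in purple
    sequence = c("ACDEF", "ACGHI", "MGHAC"),
    hog_id = c("orange", "purple", "purple"),
    stringsAsFactors = FALSE)
  reference_db(prot, hogs, k = 2)
}

# 3-family / 40-protein randomized database with nested sub-HOGs and
# deterministic membership; the "standard fixture" for oracle-equivalence
standard_db <- function(seed = 7, k = 3, len = 60) {
  set.seed(seed)
  hogs <- data.frame(
    id = c("A", "A.1", "A.2", "A.1.1", "A.1.2",
           "B", "B.1", "B.2",
           "C"),
    parent_id = c(NA, "A", "A", "A.1", "A.1",
                  NA, "B", "B",
                  NA),
    stringsAsFactors = FALSE)
  leaf_pool <- c("A", "A.2", "A.1.1", "A.1.2", "B", "B.1", "B.2", "C")
  n <- 40
  prot <- data.frame(
    id = sprintf("pr%02d", seq_len(n)),
    species = sample(paste0("S", 1:5), n, replace = TRUE),
    sequence = vapply(seq_len(n), function(i) random_aa(len), ""),
    hog_id = sample(leaf_pool, n, replace = TRUE),
    stringsAsFactors = FALSE)
  # plant shared motifs so k-mers recur across members of the same family
  motif <- c(A = "WWYYWW", B = "MMHHMM", C = "FFPPFF")
  fam <- substr(prot$hog_id, 1, 1)
  prot$sequence <- paste0(motif[fam], prot$sequence)
  list(db = reference_db(prot, hogs, k = k), hogs = hogs)
}

# random 50-HOG forest for ancestor/LCA property tests
random_hogs <- function(n = 50, n_roots = 3, seed = 11) {
  set.seed(seed)
  id <- sprintf("h%02d", seq_len(n))
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > n_roots) parent[i] <- id[sample(i - 1, 1)]
  }
  data.frame(id = id, parent_id = parent, stringsAsFactors = FALSE)
}

small_fixture <- function(seed = 3, n_families = 5, n_species = 5, ...) {
  make_fixture(sim_params(n_families = n_families, n_species = n_species,
                          root_length = 100, seed = seed, ...), k = 6)
}
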