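#' Simulation parameters for synthetic gene families
#'
#' The generator emulates the evolutionary structure the classifier assumes:
#' families arise on a shared clock-like species tree (a coalescent tree
#' rescaled to unit root-to-tip depth); gene duplications fall on gene-tree
#' branches as a Poisson birth process and each duplication spawns a pair of
#' nested sub-HOGs (nesting capped at `depth_max`); after a duplication both
#' daughter lineages evolve faster by `rate_boost` and one of them faster
#' still by `asymmetry`, reflecting the accelerated and often asymmetric
#' evolution of duplicated proteins. Substitutions are i.i.d. across sites:
#' along a branch of length t under rate multiplier r_m, each site
#' substitutes with probability `1 - exp(-subst_rate * r_m * t)` to a residue
#' drawn from the background frequencies.
#'
#' Defaults: 50 families over 8 species, one expected duplication per
#' lineage per unit time, 150-residue roots, 0.3 expected substitutions per
#' site from root to tip, clock-like rates (`rate_boost = asymmetry = 1`),
#' no indels. The substitution rate is calibrated to the regime the method
#' targets - a held-out proteome from within the phylum of the references,
#' where family-level assignment is highly accurate: with the query lineage
#' diverging at age 0.6, queries sit ~0.36 substitutions/site from the
#' backbone, so enough 6-mers survive for alignment-free matching, while
#' post-duplication acceleration still erodes them locally.
#'
#' @param n_families,n_species integers (`n_species >= 3`).
#' @param duplication_rate expected duplications per gene lineage per unit
#'   tree depth.
#' @param depth_max maximum sub-HOG nesting depth.
#' @param root_length root sequence length (residues).
#' @param subst_rate expected substitutions per site per unit tree depth.
#' @param rate_boost post-duplication rate multiplier (>= 1), applied to both
#'   daughters until the next speciation.
#' @param asymmetry additional multiplier (>= 1) for one randomly chosen
#'   daughter.
#' @param indel_rate expected indel events per site per unit tree depth.
#' @param seed integer; fixes all randomness of [make_fixture()].
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_families = 50L, n_species = 8L,
                       duplication_rate = 1, depth_max = 3L,
                       root_length = 150L, subst_rate = 0.3,
                       rate_boost = 1, asymmetry = 1, indel_rate = 0,
                       seed = 1L) {
  stopifnot(n_families >= 1L, n_species >= 3L, duplication_rate >= 0,
            depth_max >= 0L, root_length >= 1L, subst_rate >= 0,
            rate_boost >= 1, asymmetry >= 1, indel_rate >= 0)
  structure(list(n_families = as.integer(n_families),
                 n_species = as.integer(n_species),
                 duplication_rate = duplication_rate,
                 depth_max = as.integer(depth_max),
                 root_length = as.integer(root_length),
                 subst_rate = subst_rate, rate_boost = rate_boost,
                 asymmetry = asymmetry, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$n_families, " families x ", x$n_species,
      " species; dup rate ", x$duplication_rate, ", depth_max ", x$depth_max,
      "; subst ", x$subst_rate, ", boost ", x$rate_boost, ", asymmetry ",
      x$asymmetry, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Clock-like species tree with a designated early-diverging query lineage
#'
#' Mirrors how subfamily benchmarks sample their held-out proteomes
#' (platypus, spotted gar, amphioxus): a well-sampled reference backbone
#' plus one early-diverging lineage with no close relative. The tree is
#' ultrametric with unit root-to-tip depth: `S1` is the query-designate,
#' diverging from the backbone at age `query_age`; `S2` is a deep reference
#' outgroup on the other side of the root; `S3..Sn` form a random
#' coalescent ingroup of depth `ingroup_frac * query_age` (drawn from the
#' caller's RNG stream). Duplications older than `query_age` give `S1`
#' proteins nested true HOGs; duplications inside the ingroup found
#' sub-HOGs that the `S1` lineage predates.
#'
#' @param n_species number of tips (>= 3).
#' @param query_age divergence age of the `S1` lineage (fraction of tree
#'   depth).
#' @param ingroup_frac ingroup depth as a fraction of `query_age`.
#' @return an `ape::phylo` object (ultrametric, unit depth).
#' @export
species_tree <- function(n_species, query_age = 0.6, ingroup_frac = 0.75) {
  stopifnot(n_species >= 3L, query_age > 0, query_age < 1,
            ingroup_frac > 0, ingroup_frac < 1)
  n_in <- n_species - 2L
  d_in <- query_age * ingroup_frac
  if (n_in == 1L) {
    ## lone ingroup tip attaches directly at the query-divergence node
    nwk <- sprintf("((S3:%.10f,S1:%.10f):%.10f,S2:1.0);",
                   query_age, query_age, 1 - query_age)
  } else {
    tr <- ape::rcoal(n_in, tip.label = sprintf("S%d", seq_len(n_in) + 2L))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
      d_in
    ing <- sub(";$", "", ape::write.tree(tr))
    nwk <- sprintf("((%s:%.10f,S1:%.10f):%.10f,S2:1.0);",
                   ing, query_age - d_in, query_age, 1 - query_age)
  }
  ape::read.tree(text = nwk)
}

#' Simulate one gene family along a species tree
#'
#' A single gene lineage enters the species tree at its root; duplications
#' occur as a Poisson process of rate `duplication_rate` along gene-tree
#' branches (suppressed once the lineage's HOG has reached `depth_max`
#' nesting). Every duplication creates two sub-HOGs nested in the current
#' HOG; every speciation carries each lineage into both descendant species
#' with its HOG unchanged, and every extant gene is labelled with its most
#' specific HOG. Sub-HOG ids extend the parent id (`F0001`, `F0001.1`,
#' `F0001.1.2`, ...).
#'
#' @param params a [sim_params()].
#' @param family_id root-HOG id for this family.
#' @param tree species tree from [species_tree()]; generated on the fly if
#'   missing.
#' @param family_seed optional integer; when given, seeds the RNG first.
#' @return list with `family_id`, `hogs` (data.frame `id`, `parent_id`,
#'   `depth`), `genes` (data.frame `id`, `species`, `hog_id`, `segment`),
#'   and `segments` (the gene tree as branch segments: `id`, `parent`,
#'   `length`, `mult` rate multiplier, `n_dup` count of duplication nodes).
#' @export
simulate_family <- function(params, family_id = "F0001", tree = NULL,
                            family_seed = NULL) {
  if (!is.null(family_seed)) set.seed(family_seed)
  if (is.null(tree)) tree <- species_tree(params$n_species)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  env <- new.env()
  env$seg_parent <- integer(0); env$seg_len <- numeric(0)
  env$seg_mult <- numeric(0)
  env$hog_id <- family_id; env$hog_parent <- NA_character_
  env$hog_depth <- 0L; env$hog_nchild <- 0L
  env$gene_species <- character(0); env$gene_hog <- integer(0)
  env$gene_seg <- integer(0)
  env$n_dup <- 0L

  new_seg <- function(parent, len, mult) {
    env$seg_parent <- c(env$seg_parent, parent)
    env$seg_len <- c(env$seg_len, len)
    env$seg_mult <- c(env$seg_mult, mult)
    length(env$seg_len)
  }
  new_hog <- function(parent_i) {
    env$hog_nchild[parent_i] <- env$hog_nchild[parent_i] + 1L
    id <- paste0(env$hog_id[parent_i], ".", env$hog_nchild[parent_i])
    env$hog_id <- c(env$hog_id, id)
    env$hog_parent <- c(env$hog_parent, env$hog_id[parent_i])
    env$hog_depth <- c(env$hog_depth, env$hog_depth[parent_i] + 1L)
    env$hog_nchild <- c(env$hog_nchild, 0L)
    length(env$hog_id)
  }

  children_edges <- function(node) which(tree$edge[, 1] == node)

  at_node <- function(node, hog_i, seg) {
    if (node <= ntip) {
      env$gene_species <- c(env$gene_species, tree$tip.label[node])
      env$gene_hog <- c(env$gene_hog, hog_i)
      env$gene_seg <- c(env$gene_seg, seg)
    } else {
      for (e in children_edges(node))
        along_edge(e, tree$edge.length[e], hog_i, 1, seg)
    }
  }

  along_edge <- function(edge, t_left, hog_i, mult, parent_seg) {
    repeat {
      can_dup <- params$duplication_rate > 0 &&
        env$hog_depth[hog_i] < params$depth_max
      w <- if (can_dup) stats::rexp(1L, params$duplication_rate) else Inf
      if (w < t_left) {
        seg <- new_seg(parent_seg, w, mult)
        env$n_dup <- env$n_dup + 1L
        ## HOGs are delimited by speciation events: a duplication on a
        ## terminal branch leaves in-paralogs in the same HOG (no taxonomic
        ## level exists below it), while an internal-branch duplication
        ## founds two nested sub-HOGs
        terminal <- tree$edge[edge, 2] <= ntip
        if (terminal) {
          c1 <- hog_i; c2 <- hog_i
        } else {
          c1 <- new_hog(hog_i); c2 <- new_hog(hog_i)
        }
        fast_first <- stats::runif(1L) < 0.5
        m1 <- params$rate_boost * if (fast_first) params$asymmetry else 1
        m2 <- params$rate_boost * if (fast_first) 1 else params$asymmetry
        t_left <- t_left - w
        along_edge(edge, t_left, c1, m1, seg)
        along_edge(edge, t_left, c2, m2, seg)
        return(invisible())
      } else {
        seg <- new_seg(parent_seg, t_left, mult)
        at_node(tree$edge[edge, 2], hog_i, seg)
        return(invisible())
      }
    }
  }

  root_seg <- new_seg(NA_integer_, 0, 1)
  at_node(root, 1L, root_seg)

  genes <- data.frame(species = env$gene_species,
                      hog_id = env$hog_id[env$gene_hog],
                      segment = env$gene_seg, stringsAsFactors = FALSE)
  genes <- genes[order(genes$species, genes$segment), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(genes)), genes$species, FUN = seq_along)
  genes$id <- sprintf("%s_%s_g%d", family_id, genes$species, idx)
  rownames(genes) <- NULL

  list(family_id = family_id,
       hogs = data.frame(id = env$hog_id, parent_id = env$hog_parent,
                         depth = env$hog_depth, stringsAsFactors = FALSE),
       genes = genes[, c("id", "species", "hog_id", "segment")],
       segments = data.frame(id = seq_along(env$seg_len),
                             parent = env$seg_parent, length = env$seg_len,
                             mult = env$seg_mult),
       n_dup = env$n_dup)
}

mutate_sequence <- function(res, p_sub, freqs, alphabet) {
  hit <- stats::runif(length(res)) < p_sub
  if (any(hit))
    res[hit] <- sample(alphabet, sum(hit), replace = TRUE, prob = freqs)
  res
}

apply_indels <- function(res, n_events, freqs, alphabet) {
  for (i in seq_len(n_events)) {
    L <- sample(1:3, 1L)
    if (stats::runif(1L) < 0.5 && length(res) > L) {      # deletion
      at <- sample(length(res) - L + 1L, 1L)
      res <- res[-(at:(at + L - 1L))]
    } else {                                               # insertion
      at <- sample(length(res) + 1L, 1L)
      res <- append(res, sample(alphabet, L, replace = TRUE, prob = freqs),
                    after = at - 1L)
    }
  }
  res
}

#' Evolve sequences along a simulated gene tree
#'
#' The root sequence is drawn i.i.d. from `freqs`; along each branch segment
#' every site substitutes with probability `1 - exp(-subst_rate * mult *
#' length)` to a residue drawn from `freqs` (which may resample the same
#' residue), and indel events (1-3 residues, insertion or deletion) occur
#' with expectation `indel_rate * mult * length` per site.
#'
#' @param sim a [simulate_family()] result.
#' @param params the [sim_params()] used to simulate it.
#' @param freqs background residue frequencies (default [uniprot_aa_freqs()]).
#' @return named character vector: one sequence per extant gene.
#' @export
evolve_sequences <- function(sim, params, freqs = uniprot_aa_freqs()) {
  alphabet <- aa_alphabet()
  freqs <- freqs[alphabet]
  segs <- sim$segments
  seqs <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {        # parents precede children
    res <- if (is.na(segs$parent[i]))
      sample(alphabet, params$root_length, replace = TRUE, prob = freqs)
    else seqs[[segs$parent[i]]]
    d <- segs$mult[i] * segs$length[i]
    res <- mutate_sequence(res, 1 - exp(-params$subst_rate * d), freqs,
                           alphabet)
    if (params$indel_rate > 0) {
      n_ev <- stats::rpois(1L, params$indel_rate * length(res) * d)
      if (n_ev > 0L) res <- apply_indels(res, n_ev, freqs, alphabet)
    }
    seqs[[i]] <- res
  }
  out <- vapply(sim$genes$segment, function(s)
    paste(seqs[[s]], collapse = ""), "")
  names(out) <- sim$genes$id
  out
}

#' Generate a complete benchmark fixture with known truth
#'
#' Simulates `n_families` gene families on one shared species tree,
#' designates one species as the query proteome, and splits the data
#' leave-one-out style: the reference database excludes the query species
#' (with unobservable HOGs pruned, via [remove_species()]), the query set
#' contains exactly that species, and the truth records every protein's
#' species, family and most specific HOG against the *full* hierarchy.
#' Deterministic: the same `params$seed` reproduces byte-identical files.
#'
#' @param params a [sim_params()].
#' @param out_dir optional directory; when given, writes `ref.fasta`,
#'   `hierarchy.tsv`, `queries.fasta` and `truth.tsv` there.
#' @param query_species species label to hold out; defaults to `"S1"`, the
#'   designated early-diverging lineage of [species_tree()].
#' @param k k-mer length recorded in the reference database.
#' @return list with `ref_db` (leave-one-out [reference_db()]), `full_db`
#'   (all species), `queries` (data.frame `id`, `species`, `sequence`,
#'   `hog_id`, `family_id`), `truth` (list: `proteins`, `hierarchy`,
#'   `species_tree`), `params`, and `paths` when files were written.
#' @export
make_fixture <- function(params = sim_params(), out_dir = NULL,
                         query_species = "S1", k = 6L) {
  set.seed(params$seed)
  tree <- species_tree(params$n_species)
  prot <- vector("list", params$n_families)
  hogs <- vector("list", params$n_families)
  for (f in seq_len(params$n_families)) {
    fam_id <- sprintf("F%04d", f)
    sim <- simulate_family(params, fam_id, tree,
                           family_seed = params$seed + 7919L * f)
    seqs <- evolve_sequences(sim, params)
    prot[[f]] <- data.frame(id = sim$genes$id, species = sim$genes$species,
                            sequence = unname(seqs[sim$genes$id]),
                            hog_id = sim$genes$hog_id,
                            stringsAsFactors = FALSE)
    hogs[[f]] <- sim$hogs
  }
  proteins <- do.call(rbind, prot)
  hog_df <- do.call(rbind, hogs)
  full_db <- reference_db(proteins, hog_df[, c("id", "parent_id")], k = k)
  ref_db <- remove_species(full_db, query_species)
  hier <- full_db$hierarchy
  queries <- proteins[proteins$species == query_species, , drop = FALSE]
  queries$family_id <- hog_family(hier, queries$hog_id)
  rownames(queries) <- NULL

  truth <- list(proteins = data.frame(protein_id = proteins$id,
                                      species = proteins$species,
                                      family_id = hog_family(hier,
                                                             proteins$hog_id),
                                      hog_id = proteins$hog_id,
                                      stringsAsFactors = FALSE),
                hierarchy = hier, species_tree = tree)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(ref_fasta = file.path(out_dir, "ref.fasta"),
                  hierarchy = file.path(out_dir, "hierarchy.tsv"),
                  queries_fasta = file.path(out_dir, "queries.fasta"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_protein_fasta(ref_db$proteins, paths$ref_fasta)
    write_hierarchy_tsv(ref_db, paths$hierarchy)
    write_protein_fasta(queries, paths$queries_fasta)
    utils::write.table(truth$proteins, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(ref_db = ref_db, full_db = full_db, queries = queries, truth = truth,
       params = params, paths = paths)
}
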