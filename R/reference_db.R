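#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in alphabetical order. K-mer integer encoding
#' ranks residues by this ordering, so `AA -> 0`, `AC -> 1`, ...
#' @return character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a reference database
#'
#' The reference database couples a set of proteins with the HOG hierarchy
#' that organizes them into families (root-HOGs) and subfamilies (sub-HOGs).
#' Sequences are uppercased but otherwise stored verbatim; k-mer windows
#' containing a non-canonical residue (X, B, Z, J, U, O, `*`, gaps, ...) are
#' skipped during indexing and querying rather than recoded.
#'
#' @param proteins data.frame with columns `id`, `species`, `sequence`,
#'   `hog_id` (the protein's most specific HOG).
#' @param hogs data.frame passed to [hog_hierarchy()], or an existing
#'   `hog_hierarchy` object.
#' @param k k-mer length used when indexing this database (integer >= 2).
#' @return An object of class `reference_db` with components `proteins`
#'   (data.frame), `hierarchy`, `k`, `alphabet`.
#' @export
reference_db <- function(proteins, hogs, k = 6L) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "species", "sequence", "hog_id") %in% names(proteins)))
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 7L)
    stop("k must be an integer in [2, 7] (20^k must fit a 32-bit code)")
  hierarchy <- if (inherits(hogs, "hog_hierarchy")) hogs else hog_hierarchy(hogs)
  proteins <- data.frame(id = as.character(proteins$id),
                         species = as.character(proteins$species),
                         sequence = toupper(as.character(proteins$sequence)),
                         hog_id = as.character(proteins$hog_id),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(proteins$id))
    stop("duplicated protein id(s): ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  if (any(nchar(proteins$sequence) < 1L))
    stop("empty sequence for protein(s): ",
         paste(proteins$id[nchar(proteins$sequence) < 1L], collapse = ", "))
  miss <- !(proteins$hog_id %in% hierarchy$ids)
  if (any(miss))
    stop("protein(s) mapped to unknown HOG: ",
         paste(paste0(proteins$id[miss], "->", proteins$hog_id[miss]),
               collapse = ", "))
  structure(list(proteins = proteins, hierarchy = hierarchy,
                 k = k, alphabet = aa_alphabet()),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x$proteins), " proteins / ",
      length(unique(x$proteins$species)), " species; ",
      n_hogs(x$hierarchy), " HOGs in ",
      sum(is.na(x$hierarchy$parent)), " families; k = ", x$k, "\n", sep = "")
  invisible(x)
}

parse_fasta_species <- function(headers) {
  m <- regmatches(headers, regexpr("species=\\S+", headers))
  out <- rep(NA_character_, length(headers))
  hit <- grepl("species=\\S+", headers)
  out[hit] <- sub("^species=", "", m)
  out
}

read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  data.frame(id = ids,
             species = parse_fasta_species(headers),
             sequence = as.character(aa),
             stringsAsFactors = FALSE)
}

write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(is.na(proteins$species), proteins$id,
                      paste0(proteins$id, " species=", proteins$species))
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' Read a HOG hierarchy table
#'
#' The flat TSV carries two kinds of rows (in one file or two): 2-column
#' protein rows `protein_id<TAB>hog_id` and 3-column HOG rows
#' `hog_id<TAB>parent_hog_id|NA<TAB>level`. Lines starting with `#` are
#' comments.
#'
#' @param path path(s) to the TSV file(s).
#' @return list with data.frames `memberships` (`protein_id`, `hog_id`) and
#'   `hogs` (`id`, `parent_id`, `level`).
#' @export
read_hierarchy_tsv <- function(path) {
  lines <- unlist(lapply(path, readLines), use.names = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L))
    stop("malformed hierarchy line(s): ",
         paste(utils::head(lines[nf < 2L | nf > 3L], 3), collapse = " | "))
  prot <- fields[nf == 2L]
  hog <- fields[nf == 3L]
  memberships <- data.frame(
    protein_id = vapply(prot, `[`, "", 1L),
    hog_id = vapply(prot, `[`, "", 2L),
    stringsAsFactors = FALSE)
  hogs <- data.frame(
    id = vapply(hog, `[`, "", 1L),
    parent_id = vapply(hog, `[`, "", 2L),
    level = vapply(hog, `[`, "", 3L),
    stringsAsFactors = FALSE)
  hogs$parent_id[hogs$parent_id %in% c("NA", "")] <- NA_character_
  hogs$level[hogs$level %in% c("NA", "")] <- NA_character_
  list(memberships = memberships, hogs = hogs)
}

#' Write a HOG hierarchy table
#' @param db a [reference_db()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy_tsv <- function(db, path) {
  h <- db$hierarchy
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein_id\thog_id", con)
  writeLines(paste(db$proteins$id, db$proteins$hog_id, sep = "\t"), con)
  writeLines("# hog_id\tparent_hog_id\tlevel", con)
  parent <- ifelse(is.na(h$parent), "NA", h$ids[h$parent])
  level <- ifelse(is.na(h$level), "NA", h$level)
  writeLines(paste(h$ids, parent, level, sep = "\t"), con)
  invisible(path)
}

#' Load a reference database from FASTA and hierarchy files
#'
#' @param fasta_paths one or more FASTA files of reference proteins; the
#'   record id is the protein id and the description may carry
#'   `species=<label>`.
#' @param hierarchy_path hierarchy TSV path(s), see [read_hierarchy_tsv()].
#' @param k k-mer length to record in the database.
#' @return a validated [reference_db()].
#' @export
load_reference <- function(fasta_paths, hierarchy_path, k = 6L) {
  prot <- do.call(rbind, lapply(fasta_paths, read_protein_fasta))
  tab <- read_hierarchy_tsv(hierarchy_path)
  hog_id <- tab$memberships$hog_id[match(prot$id, tab$memberships$protein_id)]
  if (anyNA(hog_id))
    stop("no protein->HOG mapping for: ",
         paste(prot$id[is.na(hog_id)], collapse = ", "))
  prot$hog_id <- hog_id
  db <- reference_db(prot, tab$hogs, k = k)
  n_noncanon <- sum(vapply(strsplit(db$proteins$sequence, ""),
                           function(s) sum(!(s %in% db$alphabet)), 0L))
  if (n_noncanon > 0L)
    message("load_reference: ", n_noncanon,
            " non-canonical residue(s) retained; k-mer windows over them",
            " will be skipped")
  db
}

## number of member proteins anywhere in each HOG's subtree
subtree_member_counts <- function(db) {
  h <- db$hierarchy
  cnt <- tabulate(match(db$proteins$hog_id, h$ids), nbins = length(h$ids))
  for (i in order(h$depth, decreasing = TRUE)) {
    p <- h$parent[i]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

#' Remove one species from a reference database
#'
#' Used by the leave-one-out benchmark protocol: the proteins of the query
#' species are removed from the reference before the k-mer table is built.
#' HOGs left with no member protein anywhere in their subtree are pruned;
#' surviving HOGs keep their ids, parents and family assignment.
#'
#' @param db a [reference_db()].
#' @param species species label present in `db`.
#' @return a new `reference_db` without that species.
#' @export
remove_species <- function(db, species) {
  stopifnot(inherits(db, "reference_db"))
  if (!(species %in% db$proteins$species))
    stop("unknown species: ", species)
  keep_prot <- db$proteins$species != species
  db2 <- db
  db2$proteins <- db$proteins[keep_prot, , drop = FALSE]
  rownames(db2$proteins) <- NULL
  cnt <- subtree_member_counts(db2)
  h <- db$hierarchy
  keep <- cnt >= 1L
  hogs <- data.frame(id = h$ids[keep],
                     parent_id = ifelse(is.na(h$parent[keep]), NA_character_,
                                        h$ids[h$parent[keep]]),
                     level = h$level[keep],
                     stringsAsFactors = FALSE)
  ## a kept HOG's parent is always kept too (counts are subtree sums)
  reference_db(db2$proteins, hogs, k = db$k)
}

#' Most specific HOG of a reference protein
#' @param db a [reference_db()].
#' @param protein_id protein identifier(s).
#' @return character vector of HOG ids.
#' @export
most_specific_hog <- function(db, protein_id) {
  i <- match(as.character(protein_id), db$proteins$id)
  if (anyNA(i))
    stop("unknown protein id(s): ",
         paste(protein_id[is.na(i)], collapse = ", "))
  db$proteins$hog_id[i]
}

#' Serialize a reference database (and optionally its k-mer table)
#'
#' Single binary container with a versioned header, as written by the
#' `hogmapper mkdb` command.
#'
#' @param db a [reference_db()].
#' @param path output file.
#' @param table optional [build_kmer_table()] result to store alongside.
#' @return `path`, invisibly.
#' @export
write_db <- function(db, path, table = NULL) {
  obj <- list(format = "hogmapper-db", version = 1L, db = db, table = table)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a serialized reference database
#' @param path file written by [write_db()].
#' @return list with components `db` and `table` (`NULL` if absent).
#' @export
read_db <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hogmapper-db"))
    stop("not a hogmapper database file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported database version: ", obj$version)
  obj[c("db", "table")]
}
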