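#' Build a HOG hierarchy
#'
#' A HOG (hierarchical orthologous group) hierarchy is a forest: every family
#' (root-HOG) is the root of a tree whose internal nesting records gene
#' duplication events, so each nested HOG is a subfamily of its parent.
#'
#' @param hogs data.frame with columns `id`, `parent_id` (`NA` for a
#'   root-HOG) and optionally `level` (a taxonomic label).
#' @return An object of class `hog_hierarchy` with components
#'   `ids`, `parent` (index, `NA` at roots), `family` (index of the root-HOG),
#'   `depth` (0 at roots), `level`, and `children` (list of child indices,
#'   ordered by id).
#' @examples
#' h <- hog_hierarchy(data.frame(id = c("F1", "F1.1", "F1.2"),
#'                               parent_id = c(NA, "F1", "F1")))
#' hog_depth(h, "F1.1")
#' @export
hog_hierarchy <- function(hogs) {
  stopifnot(is.data.frame(hogs), all(c("id", "parent_id") %in% names(hogs)))
  ids <- as.character(hogs$id)
  if (anyDuplicated(ids))
    stop("duplicated HOG id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(ids)
  parent_id <- as.character(hogs$parent_id)
  parent_id[!is.na(parent_id) & parent_id %in% c("NA", "")] <- NA_character_
  parent <- match(parent_id, ids)
  bad <- !is.na(parent_id) & is.na(parent)
  if (any(bad))
    stop("unknown parent HOG id(s): ",
         paste(unique(parent_id[bad]), collapse = ", "))
  if (any(!is.na(parent) & parent == seq_len(n)))
    stop("HOG cannot be its own parent: ",
         paste(ids[!is.na(parent) & parent == seq_len(n)], collapse = ", "))

  ## depth/family by propagation from the roots; anything never reached sits on
  ## a cycle of parent links
  depth <- rep(NA_integer_, n)
  family <- rep(NA_integer_, n)
  roots <- which(is.na(parent))
  depth[roots] <- 0L
  family[roots] <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- which(parent %in% frontier & is.na(depth))
    if (!length(nxt)) break
    depth[nxt] <- depth[parent[nxt]] + 1L
    family[nxt] <- family[parent[nxt]]
    frontier <- nxt
  }
  if (anyNA(depth))
    stop("cyclic parent links among HOGs: {",
         paste(sort(ids[is.na(depth)]), collapse = ", "), "}")

  children <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  children <- lapply(children, function(i) i[order(ids[i])])

  level <- if ("level" %in% names(hogs)) as.character(hogs$level)
           else rep(NA_character_, n)
  structure(list(ids = ids, parent = parent, family = family,
                 depth = depth, level = level, children = children),
            class = "hog_hierarchy")
}

#' @export
print.hog_hierarchy <- function(x, ...) {
  cat("<hog_hierarchy> ", length(x$ids), " HOGs in ",
      sum(is.na(x$parent)), " families; max depth ", max(x$depth), "\n", sep = "")
  invisible(x)
}

hog_index <- function(hierarchy, ids) {
  i <- match(as.character(ids), hierarchy$ids)
  if (anyNA(i))
    stop("unknown HOG id(s): ",
         paste(unique(ids[is.na(i)]), collapse = ", "))
  i
}

#' Number of HOGs in a hierarchy
#' @param hierarchy a [hog_hierarchy()] object.
#' @return integer count.
#' @export
n_hogs <- function(hierarchy) length(hierarchy$ids)

#' Depth of a HOG below its root-HOG
#' @inheritParams n_hogs
#' @param hog_id HOG identifier(s).
#' @return integer vector; 0 for a root-HOG.
#' @export
hog_depth <- function(hierarchy, hog_id) {
  hierarchy$depth[hog_index(hierarchy, hog_id)]
}

#' Family (root-HOG) of a HOG
#' @inheritParams hog_depth
#' @return character vector of root-HOG ids.
#' @export
hog_family <- function(hierarchy, hog_id) {
  hierarchy$ids[hierarchy$family[hog_index(hierarchy, hog_id)]]
}

#' Strict ancestor test between two HOGs
#'
#' `TRUE` iff `a` lies on the parent path from `b` up to its root-HOG,
#' with `a != b`. HOGs in different families are never ancestors of one
#' another. The strictness convention keeps the four closest-sequence
#' configurations mutually exclusive; express "ancestral or equal" as
#' `is_ancestor(h, a, b) || a == b` at call sites.
#'
#' @inheritParams n_hogs
#' @param a,b HOG ids.
#' @return logical scalar.
#' @export
is_ancestor <- function(hierarchy, a, b) {
  ia <- hog_index(hierarchy, a)
  ib <- hog_index(hierarchy, b)
  if (ia == ib) return(FALSE)
  p <- hierarchy$parent[ib]
  while (!is.na(p)) {
    if (p == ia) return(TRUE)
    p <- hierarchy$parent[p]
  }
  FALSE
}

## indices of h and all its ancestors, root last
ancestor_path <- function(hierarchy, i) {
  path <- i
  p <- hierarchy$parent[i]
  while (!is.na(p)) {
    path <- c(path, p)
    p <- hierarchy$parent[p]
  }
  path
}

#' HOG ids on the path from the root-HOG down to a HOG
#' @inheritParams hog_depth
#' @param include_root keep the root-HOG itself (default `TRUE`).
#' @return character vector, root first.
#' @export
root_path <- function(hierarchy, hog_id, include_root = TRUE) {
  p <- rev(ancestor_path(hierarchy, hog_index(hierarchy, hog_id)))
  if (!include_root) p <- p[-1]
  hierarchy$ids[p]
}

## all indices in subtree(i), i included
subtree_indices <- function(hierarchy, i) {
  out <- i
  frontier <- i
  while (length(frontier)) {
    kids <- unlist(hierarchy$children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' HOG ids in the subtree rooted at a HOG (the HOG included)
#' @inheritParams hog_depth
#' @return character vector.
#' @export
subtree_hogs <- function(hierarchy, hog_id) {
  hierarchy$ids[subtree_indices(hierarchy, hog_index(hierarchy, hog_id))]
}

#' Last common ancestor of a set of HOGs within one family
#'
#' The deepest HOG whose subtree contains every input HOG (each HOG counts as
#' lying within its own subtree). This is the rule that attributes a k-mer,
#' within a family, to the subfamily where it most plausibly arose: treating
#' repeated occurrences as homology rather than homoplasy is conservative, in
#' that errors fall toward more ancestral (more general) HOGs.
#'
#' @inheritParams n_hogs
#' @param hog_ids nonempty vector of HOG ids, all in the same family.
#' @return a single HOG id.
#' @export
lca_hog <- function(hierarchy, hog_ids) {
  idx <- unique(hog_index(hierarchy, hog_ids))
  if (!length(idx)) stop("lca_hog() needs at least one HOG id")
  if (length(unique(hierarchy$family[idx])) > 1L)
    stop("lca_hog() across families: ",
         paste(unique(hierarchy$ids[hierarchy$family[idx]]), collapse = ", "))
  a <- idx[1]
  for (b in idx[-1]) {
    while (hierarchy$depth[a] > hierarchy$depth[b]) a <- hierarchy$parent[a]
    while (hierarchy$depth[b] > hierarchy$depth[a]) b <- hierarchy$parent[b]
    while (a != b) { a <- hierarchy$parent[a]; b <- hierarchy$parent[b] }
  }
  hierarchy$ids[a]
}

## ancestor-at-level matrix: row h, column L+1 = index of h's ancestor at depth
## L (NA when depth(h) < L); used for vectorised per-group LCA in the table
## build
ancestor_level_matrix <- function(hierarchy) {
  n <- length(hierarchy$ids)
  lmax <- max(hierarchy$depth)
  A <- matrix(NA_integer_, nrow = n, ncol = lmax + 1L)
  A[cbind(seq_len(n), hierarchy$depth + 1L)] <- seq_len(n)
  ord <- order(hierarchy$depth)  # parents before children
  for (i in ord) {
    p <- hierarchy$parent[i]
    if (!is.na(p)) {
      d <- hierarchy$depth[i]
      A[i, seq_len(d)] <- A[p, seq_len(d)]
    }
  }
  A
}
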