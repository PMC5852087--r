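#' Rooted taxonomy with ranked, named nodes
#'
#' A `taxonomy_tree` holds a rooted taxonomy in the NCBI style: integer taxon
#' ids, a parent pointer per node, a rank label and a scientific name. The
#' root is its own parent (as in `nodes.dmp`). Ranks along any root-to-leaf
#' path must be non-repeating and follow the canonical order
#' root > domain > phylum > class > order > family > genus > species.
#'
#' @param nodes data.frame with columns `taxid` (integer), `parent` (integer),
#'   `rank` (character) and `name` (character).
#' @return An object of class `taxonomy_tree`.
#' @examples
#' tr <- taxonomy_tree(data.frame(
#'   taxid = c(1L, 2L, 3L),
#'   parent = c(1L, 1L, 2L),
#'   rank = c("root", "domain", "phylum"),
#'   name = c("root", "Bacteria", "Pseudomonadota")))
#' tax_lineage(tr, 3L)
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("taxid", "parent", "rank", "name") %in% names(nodes)))
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)
  if (anyDuplicated(nodes$taxid))
    stop("duplicated taxon ids in taxonomy")
  tree <- structure(
    list(nodes = nodes[order(nodes$taxid), , drop = FALSE]),
    class = "taxonomy_tree")
  validate_taxonomy(tree)
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root '%s'\n",
              nrow(x$nodes), x$nodes$name[x$nodes$taxid == tax_root(x)]))
  rk <- table(x$nodes$rank)
  cat("  ranks:", paste(sprintf("%s=%d", names(rk), rk), collapse = ", "), "\n")
  invisible(x)
}

TAX_RANKS <- c("root", "domain", "phylum", "class", "order",
               "family", "genus", "species")

#' Root taxon id of a taxonomy
#' @param tree taxonomy_tree
#' @return integer taxid
#' @export
tax_root <- function(tree) {
  tree$nodes$taxid[tree$nodes$taxid == tree$nodes$parent]
}

#' Validate taxonomy structure
#'
#' Checks the invariants: a single root that is its own parent, all parents
#' present, no cycles, and ranks strictly descending along every path.
#' Called by the constructor; exported for use on trees read from disk.
#'
#' @param tree taxonomy_tree
#' @return invisibly TRUE; stops on violation
#' @export
validate_taxonomy <- function(tree) {
  nd <- tree$nodes
  roots <- nd$taxid[nd$taxid == nd$parent]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root (its own parent); found ",
         length(roots))
  if (!all(nd$parent %in% nd$taxid))
    stop("taxonomy has parent ids that are not nodes")
  rank_idx <- match(nd$rank, TAX_RANKS)
  if (anyNA(rank_idx))
    stop("unknown rank labels: ",
         paste(unique(nd$rank[is.na(rank_idx)]), collapse = ", "))
  # cycle + rank-order check by walking every node to the root
  parent_of <- stats::setNames(nd$parent, nd$taxid)
  rank_of <- stats::setNames(rank_idx, nd$taxid)
  n <- nrow(nd)
  for (t in nd$taxid) {
    cur <- t
    steps <- 0L
    while (parent_of[[as.character(cur)]] != cur) {
      p <- parent_of[[as.character(cur)]]
      if (rank_of[[as.character(p)]] >= rank_of[[as.character(cur)]])
        stop("rank order violated between taxid ", cur, " and parent ", p)
      cur <- p
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", t)
    }
  }
  invisible(TRUE)
}

tax_index <- function(tree, taxid) {
  i <- match(as.integer(taxid), tree$nodes$taxid)
  if (anyNA(i))
    stop("unknown taxon id(s): ",
         paste(taxid[is.na(i)], collapse = ", "))
  i
}

#' Ancestors of a taxon, root first
#'
#' Returns the root-to-taxon path including the taxon itself.
#'
#' @param tree taxonomy_tree
#' @param taxid single taxon id
#' @return integer vector of taxids, root first, `taxid` last
#' @export
tax_ancestors <- function(tree, taxid) {
  tax_index(tree, taxid)
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$taxid)
  path <- as.integer(taxid)
  cur <- as.integer(taxid)
  repeat {
    p <- parent_of[[as.character(cur)]]
    if (p == cur) break
    path <- c(p, path)
    cur <- p
  }
  path
}

#' @rdname tax_ancestors
#' @export
tax_depth <- function(tree, taxid) length(tax_ancestors(tree, taxid)) - 1L

#' Rank, name and lineage accessors
#' @param tree taxonomy_tree
#' @param taxid taxon id(s)
#' @return `tax_rank`/`tax_name`: character vector; `tax_lineage`: a single
#'   "; "-separated lineage string from the domain down.
#' @export
tax_rank <- function(tree, taxid) tree$nodes$rank[tax_index(tree, taxid)]

#' @rdname tax_rank
#' @export
tax_name <- function(tree, taxid) tree$nodes$name[tax_index(tree, taxid)]

#' @rdname tax_rank
#' @export
tax_lineage <- function(tree, taxid) {
  path <- tax_ancestors(tree, taxid)
  path <- path[path != tax_root(tree)]
  paste(tax_name(tree, path), collapse = "; ")
}

#' Ancestor of a taxon at a given rank
#'
#' Lifts a taxon to the requested rank. If the taxon's own assignment is
#' already above that rank (e.g. an order-level taxon lifted to family),
#' there is no such ancestor and `NA` is returned.
#'
#' @param tree taxonomy_tree
#' @param taxid single taxon id
#' @param rank one of domain/phylum/class/order/family/genus/species
#' @return taxid of the ancestor at `rank`, or `NA_integer_`
#' @export
tax_ancestor_at_rank <- function(tree, taxid, rank) {
  rank <- match.arg(rank, TAX_RANKS[-1])
  path <- tax_ancestors(tree, taxid)
  hit <- path[tax_rank(tree, path) == rank]
  if (length(hit)) hit[[1L]] else NA_integer_
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node that is ancestor-or-self of every input taxon. Computed
#' by lifting the deeper of two nodes to equal depth and then climbing both
#' in lockstep, folded over the set; the operation is associative, so the
#' fold order does not affect the result.
#'
#' @param taxa non-empty vector of taxon ids, all present in `tree`
#' @param tree taxonomy_tree
#' @return a single taxid
#' @export
lca <- function(taxa, tree) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("lca() needs at least one taxon")
  tax_index(tree, taxa)   # errors on unknown ids
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$taxid)
  depth_of <- function(t) tax_depth(tree, t)
  lca2 <- function(a, b) {
    da <- depth_of(a); db <- depth_of(b)
    while (da > db) { a <- parent_of[[as.character(a)]]; da <- da - 1L }
    while (db > da) { b <- parent_of[[as.character(b)]]; db <- db - 1L }
    while (a != b) {
      a <- parent_of[[as.character(a)]]
      b <- parent_of[[as.character(b)]]
    }
    a
  }
  Reduce(lca2, taxa)
}

#' Read and write NCBI-style taxonomy dumps
#'
#' `write_taxdump()` emits `nodes.dmp` and `names.dmp` in the NCBI taxonomy
#' dump dialect (fields separated by `\t|\t`, rows terminated `\t|`); names
#' are written with name class "scientific name". `read_taxdump()` parses the
#' same dialect back into a [taxonomy_tree()]; only scientific names are kept.
#'
#' @param tree taxonomy_tree
#' @param dir directory to write `nodes.dmp` and `names.dmp` into
#' @return `write_taxdump`: invisibly the two file paths; `read_taxdump`: a
#'   taxonomy_tree
#' @export
write_taxdump <- function(tree, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nd <- tree$nodes
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nd$taxid, nd$parent, nd$rank),
             nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     nd$taxid, nd$name),
             names_path)
  invisible(c(nodes = nodes_path, names = names_path))
}

#' @rdname write_taxdump
#' @param nodes_path,names_path paths to `nodes.dmp` / `names.dmp`
#' @export
read_taxdump <- function(nodes_path, names_path) {
  split_dmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nrec <- split_dmp(readLines(nodes_path))
  nodes <- data.frame(
    taxid = as.integer(vapply(nrec, `[[`, "", 1L)),
    parent = as.integer(vapply(nrec, `[[`, "", 2L)),
    rank = vapply(nrec, `[[`, "", 3L))
  mrec <- split_dmp(readLines(names_path))
  nm <- data.frame(
    taxid = as.integer(vapply(mrec, `[[`, "", 1L)),
    name = vapply(mrec, `[[`, "", 2L),
    class = vapply(mrec, function(r) r[[length(r)]], ""))
  nm <- nm[nm$class == "scientific name", ]
  nodes$name <- nm$name[match(nodes$taxid, nm$taxid)]
  taxonomy_tree(nodes)
}
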