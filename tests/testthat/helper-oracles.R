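# Independent oracles and random-instance generators for property tests.
# These deliberately re-derive results by the most literal route available
# (full root-path intersection, rule-by-rule hit filtering) and share no
# code with the package implementation.

# Deepest common element of the full root-to-node paths.
oracle_lca <- function(taxa, tree) {
  nd <- tree$nodes
  parent <- stats::setNames(nd$parent, nd$taxid)
  path_of <- function(t) {
    p <- t
    while (parent[[as.character(t)]] != t) {
      t <- parent[[as.character(t)]]
      p <- c(p, t)
    }
    p
  }
  paths <- lapply(unique(as.integer(taxa)), path_of)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(t) length(path_of(t)), integer(1))
  common[which.max(depths)]
}

# Literal re-application of the filter rules followed by oracle_lca.
oracle_assign <- function(hits, tree, min_bitscore = 50, min_len = 100,
                          top_fraction = 0.10, max_evalue = 1e-4) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  h <- h[h$bitscore > min_bitscore, , drop = FALSE]
  h <- h[h$length > min_len, , drop = FALSE]
  if (nrow(h) > 0)
    h <- h[h$bitscore >= (1 - top_fraction) * max(h$bitscore), , drop = FALSE]
  if (nrow(h) == 0) return(NA_integer_)
  oracle_lca(h$staxid, tree)
}

# Random ranked tree with at most ~max_nodes nodes: each node at one rank
# spawns 1-3 children at the next rank until the budget runs out.
random_ranked_tree <- function(max_nodes = 50) {
  ranks <- c("root", "domain", "phylum", "class", "order",
             "family", "genus", "species")
  nodes <- data.frame(taxid = 1L, parent = 1L, rank = "root", name = "root")
  frontier <- 1L
  nid <- 1L
  for (r in ranks[-1]) {
    nxt <- integer()
    for (p in frontier) {
      for (k in seq_len(sample(1:3, 1))) {
        if (nid >= max_nodes) break
        nid <- nid + 1L
        nodes <- rbind(nodes, data.frame(
          taxid = nid, parent = p, rank = r,
          name = sprintf("%s_%d", r, nid)))
        nxt <- c(nxt, nid)
      }
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  taxonomy_tree(nodes)
}

# Random hit table for one query over the taxa of `tree`: scores straddle
# every filter threshold.
random_hits <- function(tree, n = NULL, q = "q1") {
  if (is.null(n)) n <- sample(0:20, 1)
  if (n == 0)
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      staxid = integer()))
  taxa <- sample(tree$nodes$taxid, n, replace = TRUE)
  len <- sample(50:400, n, replace = TRUE)
  data.frame(qseqid = q,
             sseqid = sprintf("s%d", seq_len(n)),
             pident = runif(n, 70, 100),
             length = len, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = 10^-runif(n, 0, 10),      # some exceed the 1e-4 ceiling
             bitscore = runif(n, 20, 300),
             staxid = taxa)
}

# Small fixed lineage used across unit tests:
# root(1) > Bacteria(2) > phyla 3,4 > ... > species 10,11 (sisters), 12.
fixture_tree <- function() {
  taxonomy_tree(data.frame(
    taxid = 1:12,
    parent = c(1L, 1L, 2L, 2L, 3L, 5L, 6L, 7L, 7L, 8L, 8L, 9L),
    rank = c("root", "domain", "phylum", "phylum", "class", "order",
             "family", "genus", "genus", "species", "species", "species"),
    name = c("root", "Bacteria", "PhyA", "PhyB", "ClaA", "OrdA",
             "FamA", "GenA", "GenB", "SpA1", "SpA2", "SpB1")))
}

make_hit <- function(q = "c1", taxid = 10L, bitscore = 200, len = 150L,
                     evalue = 1e-10, sseqid = "s") {
  data.frame(qseqid = q, sseqid = sseqid, pident = 98, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue,
             bitscore = bitscore, staxid = taxid)
}
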