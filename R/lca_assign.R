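# Filtered-LCA taxonomic assignment of contigs from homology hit tables,
# MEGAN-style but with the stricter parameterisation used for assembled
# metatranscriptomes: absolute bitscore and alignment-length floors, an
# e-value ceiling, and a top-percent band below the best hit, applied before
# the lowest-common-ancestor reduction; a second hit table (e.g. a blastn
# re-search) is consulted only for contigs the first pass left unassigned.

#' Filter the homology hits of one query
#'
#' Keeps hits that pass, in order: e-value at most `max_evalue`; bitscore
#' strictly exceeding `min_bitscore`; alignment length strictly exceeding
#' `min_len` nucleotides; and score within `top_fraction` of the best
#' surviving hit (inclusive at the bound, so the best hit always survives).
#' The top-percent band is measured on bitscore by default
#' (`top_metric = "bitscore"`, the MEGAN top-percent convention); setting
#' `top_metric = "length"` instead bands on alignment length relative to the
#' longest surviving alignment. The result is canonically sorted by
#' descending bitscore then subject id, so the outcome is independent of
#' input order.
#'
#' @param hits data.frame of hits for a single query (columns qseqid,
#'   sseqid, bitscore, length, evalue, staxid at minimum)
#' @param min_bitscore absolute bitscore floor; only hits exceeding it are
#'   considered (default 50)
#' @param min_len alignment-length floor in nucleotides, strict (default 100)
#' @param top_fraction maximum allowed deviation from the best hit
#'   (default 0.10)
#' @param max_evalue e-value ceiling (default 1e-4)
#' @param top_metric "bitscore" or "length": the quantity the top band is
#'   measured on
#' @return the surviving hits, canonically sorted
#' @export
filter_hits <- function(hits, min_bitscore = 50, min_len = 100,
                        top_fraction = 0.10, max_evalue = 1e-4,
                        top_metric = c("bitscore", "length")) {
  top_metric <- match.arg(top_metric)
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$qseqid)) > 1L)
    stop("filter_hits() expects hits of a single query")
  keep <- hits$evalue <= max_evalue &
    hits$bitscore > min_bitscore &
    hits$length > min_len
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits)) {
    m <- hits[[top_metric]]
    hits <- hits[m >= (1 - top_fraction) * max(m), , drop = FALSE]
  }
  hits[order(-hits$bitscore, hits$sseqid), , drop = FALSE]
}

#' Assign one contig by filtered LCA
#'
#' Applies [filter_hits()] and reduces the surviving hits' subject taxa to
#' their lowest common ancestor. Hits whose taxon id is absent from the tree
#' (deleted or merged ids) are dropped with a warning rather than failing
#' the contig. With no surviving hits the contig is unassigned.
#'
#' @param hits data.frame of hits for one query
#' @param tree a [taxonomy_tree()]
#' @inheritParams filter_hits
#' @return one-row data.frame: contig_id, taxid (NA if unassigned),
#'   n_hits (surviving hits)
#' @export
assign_contig <- function(hits, tree, min_bitscore = 50, min_len = 100,
                          top_fraction = 0.10, max_evalue = 1e-4,
                          top_metric = "bitscore") {
  contig <- if (nrow(hits)) hits$qseqid[1] else NA_character_
  known <- hits$staxid %in% tree$nodes$taxid
  if (any(!known)) {
    warning("dropping ", sum(!known), " hit(s) with unknown taxon ids for ",
            contig)
    hits <- hits[known, , drop = FALSE]
  }
  surv <- filter_hits(hits, min_bitscore = min_bitscore, min_len = min_len,
                      top_fraction = top_fraction, max_evalue = max_evalue,
                      top_metric = top_metric)
  if (nrow(surv) == 0L)
    return(data.frame(contig_id = contig, taxid = NA_integer_, n_hits = 0L))
  data.frame(contig_id = contig,
             taxid = lca(surv$staxid, tree),
             n_hits = nrow(surv))
}

#' Two-pass taxonomic assignment of a contig set
#'
#' Assigns every contig from the first-pass hit table; contigs that remain
#' unassigned (no hits, or no hits surviving the filters) are re-evaluated
#' against the second-pass table with identical filters — mirroring a
#' megablast search backed by a blastn re-search of the leftovers. The
#' `pass` label records which table produced each assignment ("first",
#' "second" or "none").
#'
#' @param pass1_hits,pass2_hits hit tables over many queries (column
#'   qseqid distinguishes contigs); `pass2_hits` may be NULL
#' @param tree a [taxonomy_tree()]
#' @param contigs optional character vector of contig ids to report on;
#'   defaults to all contigs appearing in either table
#' @inheritParams filter_hits
#' @return data.frame: contig_id, taxid, rank, name, lineage, pass, n_hits
#' @export
two_pass_assign <- function(pass1_hits, pass2_hits = NULL, tree,
                            contigs = NULL, min_bitscore = 50, min_len = 100,
                            top_fraction = 0.10, max_evalue = 1e-4,
                            top_metric = "bitscore") {
  if (is.null(contigs))
    contigs <- unique(c(pass1_hits$qseqid, pass2_hits$qseqid))
  one_pass <- function(tab, contig) {
    h <- tab[tab$qseqid == contig, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(contig_id = contig, taxid = NA_integer_, n_hits = 0L))
    assign_contig(h, tree, min_bitscore = min_bitscore, min_len = min_len,
                  top_fraction = top_fraction, max_evalue = max_evalue,
                  top_metric = top_metric)
  }
  rows <- lapply(contigs, function(cg) {
    a <- one_pass(pass1_hits, cg)
    a$pass <- "first"
    if (is.na(a$taxid) && !is.null(pass2_hits)) {
      a <- one_pass(pass2_hits, cg)
      a$pass <- "second"
    }
    if (is.na(a$taxid)) a$pass <- "none"
    a$contig_id <- cg
    a
  })
  out <- do.call(rbind, rows)
  assigned <- !is.na(out$taxid)
  out$rank <- NA_character_; out$name <- NA_character_
  out$lineage <- NA_character_
  out$rank[assigned] <- tax_rank(tree, out$taxid[assigned])
  out$name[assigned] <- tax_name(tree, out$taxid[assigned])
  out$lineage[assigned] <- vapply(out$taxid[assigned], function(t)
    tax_lineage(tree, t), "")
  out[c("contig_id", "taxid", "rank", "name", "lineage", "pass", "n_hits")]
}
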