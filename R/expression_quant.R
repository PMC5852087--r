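#' Count reads per gene from alignment records
#'
#' Counts primary, mapped alignments only (secondary and supplementary
#' records are ignored). Each read is credited to the gene with the largest
#' overlap on its contig; reads that tie between genes or overlap no gene
#' are left uncounted, approximating unambiguous-assignment counting without
#' fractional counts. Counting is unstranded. Depth is the mean aligned
#' coverage: the sum of credited read lengths divided by gene length.
#'
#' @param alignments data.frame of alignment records with columns qname,
#'   flag, rname, pos and either qwidth or seq (read length source); use
#'   [read_sam()] for SAM files or [reads_to_alignments()] for simulator
#'   output. Alignments to contigs absent from `genes` are skipped with a
#'   message.
#' @param genes data.frame of gene calls: locus_tag, contig_id, start, end
#'   (1-based inclusive)
#' @return `coverage_table` data.frame: locus_tag, contig_id, length, count,
#'   depth
#' @export
count_reads <- function(alignments, genes) {
  a <- alignments
  if (is.null(a$qwidth)) a$qwidth <- nchar(a$seq)
  primary <- bitwAnd(a$flag, 4L) == 0L &      # mapped
    bitwAnd(a$flag, 256L) == 0L &             # not secondary
    bitwAnd(a$flag, 2048L) == 0L              # not supplementary
  a <- a[primary, , drop = FALSE]
  known <- a$rname %in% genes$contig_id
  if (any(!known)) {
    message("count_reads: skipping ", sum(!known),
            " alignment(s) to contigs without gene calls")
    a <- a[known, , drop = FALSE]
  }
  out <- data.frame(locus_tag = genes$locus_tag,
                    contig_id = genes$contig_id,
                    length = genes$end - genes$start + 1L,
                    count = 0L, depth = 0)
  if (nrow(a)) {
    rd <- GenomicRanges::GRanges(a$rname,
                                 IRanges::IRanges(a$pos, width = a$qwidth))
    gn <- GenomicRanges::GRanges(genes$contig_id,
                                 IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(rd, gn)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rd)[S4Vectors::queryHits(ov)],
        IRanges::ranges(gn)[S4Vectors::subjectHits(ov)]))
      best <- tapply(w, S4Vectors::queryHits(ov), max)
      qh <- S4Vectors::queryHits(ov)
      is_best <- w == best[as.character(qh)]
      n_best <- tapply(is_best, qh, sum)
      credit <- is_best & n_best[as.character(qh)] == 1L   # ties discarded
      gi <- S4Vectors::subjectHits(ov)[credit]
      cnt <- table(gi)
      out$count[as.integer(names(cnt))] <- as.integer(cnt)
      bases <- tapply(a$qwidth[qh[credit]], gi, sum)
      out$depth[as.integer(names(bases))] <-
        as.numeric(bases) / out$length[as.integer(names(bases))]
    }
  }
  out
}

#' Taxon-level mRNA relative-abundance profile
#'
#' Attributes each gene's read count to its contig's assigned taxon lifted
#' to the requested rank, and expresses the result as percentages of all
#' counted reads — the transcript-level community profile. Counts on contigs
#' that are unassigned, or assigned above the requested rank, fall into the
#' "unclassified" bucket. By default the profile is computed on read counts;
#' `use = "depth"` profiles length-normalised coverage instead.
#'
#' @param coverage a coverage table from [count_reads()]
#' @param assignments data.frame from [two_pass_assign()] (contig_id, taxid)
#' @param tree a [taxonomy_tree()]
#' @param rank rank at which to profile (default "family")
#' @param use "count" (default) or "depth"
#' @return data.frame: taxid (NA for unclassified), name, percent; percents
#'   sum to 100
#' @export
taxon_profile <- function(coverage, assignments, tree, rank = "family",
                          use = c("count", "depth")) {
  use <- match.arg(use)
  rank <- match.arg(rank, TAX_RANKS[-1])
  x <- coverage[[use]]
  total <- sum(x)
  if (total <= 0) stop("no counted reads to profile")
  contig_tax <- stats::setNames(assignments$taxid, assignments$contig_id)
  tax <- contig_tax[coverage$contig_id]
  lift <- rep(NA_integer_, length(tax))
  known <- !is.na(tax)
  lift[known] <- vapply(tax[known], function(t)
    tax_ancestor_at_rank(tree, t, rank), integer(1))
  key <- ifelse(is.na(lift), "unclassified", as.character(lift))
  agg <- tapply(x, key, sum)
  out <- data.frame(
    taxid = suppressWarnings(as.integer(names(agg))),
    name = ifelse(names(agg) == "unclassified", "unclassified",
                  NA_character_),
    percent = 100 * as.numeric(agg) / total)
  known_tax <- !is.na(out$taxid)
  out$name[known_tax] <- tax_name(tree, out$taxid[known_tax])
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
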