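#' Quality-trim a read from both ends
#'
#' Removes bases one at a time from the 5' end while their quality is below
#' `min_q`, then likewise from the 3' end; interior bases are never touched
#' (single-base stepwise trimming, PRINSEQ `trim_qual` window-1 semantics).
#' Idempotent; may return an empty read.
#'
#' @param sequence read sequence (single string)
#' @param qualities integer Phred scores, one per base
#' @param min_q minimum end quality to keep a base (default 30)
#' @return list with `sequence` and `qualities` of the trimmed read
#' @examples
#' trim_ends("ACGT", c(10, 35, 35, 10))   # keeps "CG"
#' @export
trim_ends <- function(sequence, qualities, min_q = 30L) {
  stopifnot(nchar(sequence) == length(qualities))
  ok <- qualities >= min_q
  if (!any(ok))
    return(list(sequence = "", qualities = integer()))
  first <- which.max(ok)
  last <- length(ok) + 1L - which.max(rev(ok))
  list(sequence = substr(sequence, first, last),
       qualities = qualities[first:last])
}

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Quality-control a single read
#'
#' Applies [trim_ends()], then tests the trimmed read against four filters in
#' a fixed order: minimum length, minimum mean quality, nucleotide alphabet
#' (IUPAC codes only, case-insensitive), and N count. The first failing
#' filter provides the rejection reason; a kept read passes all four. The
#' mean-quality test is computed on the trimmed read. N is IUPAC-legal but
#' counts toward the N limit.
#'
#' @param sequence,qualities read sequence and integer Phred scores
#' @param min_len minimum post-trim length in bp (default 40)
#' @param min_mean_q minimum mean quality of the trimmed read (default 30)
#' @param max_n maximum number of N bases tolerated (default 3: reads with
#'   more than three Ns are discarded)
#' @param min_q end-trim quality threshold passed to [trim_ends()]
#' @return list: `kept` (logical), `sequence`/`qualities` of the trimmed
#'   read, and `reason` ("none", "min_length", "mean_quality", "non_iupac"
#'   or "too_many_n")
#' @export
qc_read <- function(sequence, qualities, min_len = 40L, min_mean_q = 30L,
                    max_n = 3L, min_q = 30L) {
  tr <- trim_ends(sequence, qualities, min_q)
  n <- nchar(tr$sequence)
  reason <- "none"
  chars <- if (n) strsplit(toupper(tr$sequence), "")[[1]] else character()
  if (n < min_len) reason <- "min_length"
  else if (mean(tr$qualities) < min_mean_q) reason <- "mean_quality"
  else if (!all(chars %in% IUPAC_NT)) reason <- "non_iupac"
  else if (sum(chars == "N") > max_n) reason <- "too_many_n"
  list(kept = reason == "none",
       sequence = tr$sequence, qualities = tr$qualities, reason = reason)
}

#' Phred+33 quality string <-> integer scores
#' @param quality quality string(s)
#' @return `phred_scores`: list of integer vectors (or a vector for a single
#'   string); `phred_string`: character string
#' @export
phred_scores <- function(quality) {
  out <- lapply(quality, function(q) utf8ToInt(q) - 33L)
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname phred_scores
#' @param scores integer Phred scores
#' @export
phred_string <- function(scores) intToUtf8(scores + 33L)

#' Quality-control a read set
#'
#' Vectorised driver over a FASTQ-style data.frame (as returned by
#' [read_fastq()]): trims and filters every read and tallies rejection
#' reasons.
#'
#' @param reads data.frame with read_id, sequence, quality (Phred+33)
#' @inheritParams qc_read
#' @return list: `kept` (data.frame of surviving trimmed reads), `rejected`
#'   (read_id + reason), `summary` (counts per verdict)
#' @export
qc_reads <- function(reads, min_len = 40L, min_mean_q = 30L, max_n = 3L,
                     min_q = 30L) {
  res <- lapply(seq_len(nrow(reads)), function(i)
    qc_read(reads$sequence[i], phred_scores(reads$quality[i]),
            min_len = min_len, min_mean_q = min_mean_q,
            max_n = max_n, min_q = min_q))
  kept <- vapply(res, `[[`, TRUE, "kept")
  reason <- vapply(res, `[[`, "", "reason")
  out_kept <- data.frame(
    read_id = reads$read_id[kept],
    sequence = vapply(res[kept], `[[`, "", "sequence"),
    quality = vapply(res[kept], function(r) phred_string(r$qualities), ""))
  summary <- as.data.frame(table(reason = factor(
    reason, levels = c("none", "min_length", "mean_quality",
                       "non_iupac", "too_many_n"))),
    responseName = "reads")
  list(kept = out_kept,
       rejected = data.frame(read_id = reads$read_id[!kept],
                             reason = reason[!kept]),
       summary = summary)
}

#' QC a FASTQ file end to end
#'
#' Reads `infile`, applies [qc_reads()], writes surviving trimmed reads to
#' `outfile` and (optionally) the per-read rejection reasons as TSV.
#'
#' @param infile,outfile FASTQ paths
#' @param report_file optional TSV path for the rejection report
#' @inheritParams qc_read
#' @return the summary data.frame, invisibly
#' @export
qc_fastq <- function(infile, outfile, report_file = NULL, min_len = 40L,
                     min_mean_q = 30L, max_n = 3L, min_q = 30L) {
  res <- qc_reads(read_fastq(infile), min_len = min_len,
                  min_mean_q = min_mean_q, max_n = max_n, min_q = min_q)
  write_fastq(res$kept$sequence, res$kept$quality, res$kept$read_id, outfile)
  if (!is.null(report_file))
    utils::write.table(res$rejected, report_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  message(sprintf("qc_fastq: kept %d / %d reads",
                  nrow(res$kept), sum(res$summary$reads)))
  invisible(res$summary)
}
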