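# File-format front doors. Parsing of the standard formats is delegated to
# Biostrings (FASTA/FASTQ), Rsamtools (SAM via BAM conversion) and
# rtracklayer (GFF3); only the NCBI taxdump dialect (taxonomy.R) and the
# headerless BLAST tabular layout are handled directly.

#' Read a FASTQ file leniently
#'
#' Reads FASTQ (Phred+33) without restricting the sequence alphabet, so that
#' reads carrying non-IUPAC characters reach the QC stage and are rejected
#' there rather than breaking the parser.
#'
#' @param path FASTQ file
#' @return data.frame with read_id, sequence, quality
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq",
                                  with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Write sequences with qualities as FASTQ (Phred+33)
#' @param sequences,qualities,ids character vectors of equal length
#' @param path output file
#' @return invisibly `path`
#' @export
write_fastq <- function(sequences, qualities, ids, path) {
  x <- Biostrings::BStringSet(stats::setNames(sequences, ids))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' Read/write contig FASTA
#' @param path FASTA file
#' @return `read_fasta`: named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Read and write gene calls as GFF3
#'
#' Gene calls are CDS features with 1-based inclusive coordinates; the
#' feature `ID` attribute carries the locus tag. The strand column is
#' preserved.
#'
#' @param genes data.frame with locus_tag, contig_id, start, end, strand
#' @param path GFF3 file
#' @return `read_gene_calls`: data.frame of gene calls
#' @export
write_gene_calls <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "CDS", phase = 0L, ID = genes$locus_tag)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_calls
#' @export
read_gene_calls <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  data.frame(locus_tag = gr$ID,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write alignment records as SAM
#'
#' Minimal single-end SAM: mapped records get MAPQ 42 and an all-match
#' CIGAR; unmapped records (flag 4) keep `*` placeholders.
#'
#' @param alignments data.frame from [reads_to_alignments()] (qname, flag,
#'   rname, pos, seq, qual)
#' @param contigs data.frame with contig_id and length (for `@SQ` headers)
#' @param path output SAM
#' @return invisibly `path`
#' @export
write_sam <- function(alignments, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id, contigs$length))
  a <- alignments
  mapped <- bitwAnd(a$flag, 4L) == 0L
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  a$qname, a$flag,
                  ifelse(mapped, a$rname, "*"),
                  ifelse(mapped, a$pos, 0L),
                  ifelse(mapped, 42L, 0L),
                  ifelse(mapped, sprintf("%dM", nchar(a$seq)), "*"),
                  a$seq, a$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Converts through BAM with Rsamtools so flags, CIGARs and header are
#' interpreted by htslib rather than ad hoc parsing.
#'
#' @param path SAM file (header required)
#' @return data.frame with qname, flag, rname, pos, qwidth
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth")))[[1]]
  data.frame(qname = b$qname, flag = b$flag,
             rname = as.character(b$rname), pos = b$pos, qwidth = b$qwidth)
}

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "staxid")

#' Read and write BLAST tabular hit tables
#'
#' The 12 standard outfmt-6 columns extended with a 13th subject-taxon-id
#' column (`staxid`), headerless and tab-separated. `columns` allows
#' alternative column orders as long as the standard names are used.
#'
#' @param path TSV file
#' @param columns column names, in file order
#' @return `read_hit_table`: data.frame of hits
#' @export
read_hit_table <- function(path, columns = HIT_COLUMNS) {
  stopifnot(all(HIT_COLUMNS %in% columns))
  h <- utils::read.table(path, sep = "\t", col.names = columns,
                         stringsAsFactors = FALSE)
  h[HIT_COLUMNS]
}

#' @rdname read_hit_table
#' @param hits data.frame with the columns of `HIT_COLUMNS`
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
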