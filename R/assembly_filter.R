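#' Low-complexity statistics for one contig
#'
#' Computes the four statistics used to flag degenerate assembly products:
#' the maximum single-base fraction, the G+C fraction, the A+T fraction, and
#' the longest homopolymer run. A contig fails when any single base exceeds
#' 90% of its length, G+C or A+T exceeds 90%, or a homopolymer run reaches
#' 50 bases (fractions strictly greater-than; run length inclusive).
#' Handling is case-insensitive; ambiguity codes (N etc.) count in the
#' length denominator but never toward a base tally or a run, so ambiguity
#' alone can never trigger removal. All statistics are invariant under
#' reverse complement.
#'
#' @param sequence contig sequence (non-empty)
#' @return list: `max_base_fraction`, `gc_fraction`, `at_fraction`,
#'   `max_run`, `pass` flag and `failed` rule labels (subset of
#'   "single_base", "gc", "at", "homopolymer")
#' @export
complexity_report <- function(sequence) {
  if (!nzchar(sequence)) stop("empty contig sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), 0L)
  runs <- rle(chars)
  acgt_runs <- runs$lengths[runs$values %in% c("A", "C", "G", "T")]
  max_run <- if (length(acgt_runs)) max(acgt_runs) else 0L
  rep <- list(
    max_base_fraction = max(cnt) / n,
    gc_fraction = (cnt[["G"]] + cnt[["C"]]) / n,
    at_fraction = (cnt[["A"]] + cnt[["T"]]) / n,
    max_run = max_run)
  failed <- c(
    if (rep$max_base_fraction > 0.9) "single_base",
    if (rep$gc_fraction > 0.9) "gc",
    if (rep$at_fraction > 0.9) "at",
    if (rep$max_run >= 50L) "homopolymer")
  rep$failed <- as.character(failed)
  rep$pass <- length(failed) == 0L
  rep
}

#' Partition contigs by the low-complexity filter
#'
#' Applies [complexity_report()] to every contig and splits the collection
#' into kept and removed sets, preserving input order. Idempotent on its
#' kept output.
#'
#' @param contigs named character vector of contig sequences (names are
#'   contig ids); a `DNAStringSet` is accepted
#' @return list: `kept` (named character vector), `removed` (data.frame with
#'   contig_id, the four statistics and the failing rules collapsed with
#'   ";"), and `report` (the same data.frame for all contigs plus `pass`)
#' @export
filter_contigs <- function(contigs) {
  contigs <- stats::setNames(as.character(contigs), names(contigs))
  if (!length(contigs))
    return(list(kept = character(), removed = data.frame(), report = data.frame()))
  reps <- lapply(contigs, complexity_report)
  report <- data.frame(
    contig_id = names(contigs),
    max_base_fraction = vapply(reps, `[[`, 0, "max_base_fraction"),
    gc_fraction = vapply(reps, `[[`, 0, "gc_fraction"),
    at_fraction = vapply(reps, `[[`, 0, "at_fraction"),
    max_run = vapply(reps, function(r) as.integer(r$max_run), 0L),
    pass = vapply(reps, `[[`, TRUE, "pass"),
    failed = vapply(reps, function(r) paste(r$failed, collapse = ";"), ""),
    row.names = NULL)
  list(kept = contigs[report$pass],
       removed = report[!report$pass, , drop = FALSE],
       report = report)
}

#' Format a systematic locus tag
#'
#' Locus tags follow the "contig-{kmer}_{contig#}_{gene#}" scheme: the
#' assembler's k-mer run, the contig number, and the gene's ordinal on that
#' contig. Tags are rendered lowercase; comparisons elsewhere in the package
#' are case-insensitive.
#'
#' @param kmer assembler k-mer size (e.g. 100)
#' @param contig_index contig number (0-based in assembler output)
#' @param gene_index gene ordinal on the contig
#' @return locus tag string, e.g. `"contig-100_5019_1"`
#' @examples
#' format_locus_tag(100, 5019, 1)
#' @export
format_locus_tag <- function(kmer, contig_index, gene_index) {
  if (any(c(kmer, contig_index, gene_index) < 0))
    stop("locus tag components must be non-negative")
  sprintf("contig-%d_%d_%d",
          as.integer(kmer), as.integer(contig_index), as.integer(gene_index))
}
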