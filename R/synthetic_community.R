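#' Generate a synthetic taxonomy for a mock consortium
#'
#' Builds a fully ranked taxonomy (root > domain > phylum > class > order >
#' family > genus > species) for a bacterial mock community. All families sit
#' under one domain; with two or more families they are split across two
#' phyla so that genuinely "wrong clade" decoy hits exist for the classifier
#' to reject. Each family carries its own class and order, each genus two
#' species, so sister taxa exist at both the genus and the family level.
#'
#' The topology is fully determined by the two counts; `seed` is accepted for
#' interface symmetry with the other simulators and reserved for future
#' name randomisation.
#'
#' @param n_families number of families (>= 1)
#' @param genera_per_family genera in each family (>= 1)
#' @param seed integer random seed
#' @return a [taxonomy_tree()]
#' @examples
#' tr <- generate_taxonomy(3, 2, seed = 7)
#' tr
#' @export
generate_taxonomy <- function(n_families, genera_per_family, seed = 1L) {
  if (n_families < 1 || genera_per_family < 1)
    stop("n_families and genera_per_family must be positive")
  rows <- list(
    data.frame(taxid = 1L, parent = 1L, rank = "root", name = "root"),
    data.frame(taxid = 2L, parent = 1L, rank = "domain", name = "Bacteria"))
  nid <- 2L
  new_node <- function(parent, rank, name) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<-
      data.frame(taxid = nid, parent = parent, rank = rank, name = name)
    nid
  }
  n_phyla <- if (n_families >= 2) 2L else 1L
  phyla <- vapply(seq_len(n_phyla), function(p)
    new_node(2L, "phylum", sprintf("Phylum_%d", p)), integer(1))
  for (f in seq_len(n_families)) {
    ph <- phyla[((f - 1L) %% n_phyla) + 1L]
    cl <- new_node(ph, "class", sprintf("Class_%d", f))
    or <- new_node(cl, "order", sprintf("Order_%d", f))
    fa <- new_node(or, "family", sprintf("Family_%d", f))
    for (g in seq_len(genera_per_family)) {
      ge <- new_node(fa, "genus", sprintf("Genus_%d_%d", f, g))
      for (s in 1:2)
        new_node(ge, "species", sprintf("Species_%d_%d_%d", f, g, s))
    }
  }
  taxonomy_tree(do.call(rbind, rows))
}

#' Generate a mock consortium with ground truth
#'
#' Samples a community over the species of `tree`: one designated taxon (from
#' the first family) receives abundance `dominance`, emulating a consortium
#' dominated by a single family; the remainder is split among the other taxa
#' with random Gamma weights. Per-gene expression is log-normal with median 1
#' and shape `expression_sigma`. Each taxon's genes are laid out on contigs
#' (several genes per contig, 50 bp spacers, forward strand); the designated
#' taxon carries a co-localised aromatic-degradation gene cluster (abcA,
#' abcD, bzlA, bamB) on one contig, the abcA/abcD pair sharing one function
#' so that multi-locus functions exist downstream. The cluster is highly
#' transcribed: its expression draws are scaled by `cluster_boost`,
#' emulating a degradation operon that dominates its host's transcriptome.
#' All other genes get housekeeping KO labels.
#'
#' @param tree a [taxonomy_tree()]
#' @param n_taxa number of community members (<= species in tree); members
#'   are picked round-robin across families so `n_taxa` families are
#'   represented when enough families exist
#' @param dominance abundance fraction of the designated taxon, in (0, 1)
#' @param expression_sigma log-normal shape of per-gene expression (>= 0)
#' @param seed integer random seed
#' @param genes_per_taxon genes simulated per community member
#' @param gene_length_range min/max gene length in bp
#' @param cluster_boost expression multiplier for the degradation cluster
#' @return a `community_truth` list: `tree`, `taxa` (abundances), `genes`
#'   (locus tags, coordinates, expression, function ids), `contigs`
#'   (sequences), `rrna_seq` (decoy rRNA) and the parameters used
#' @export
generate_community <- function(tree, n_taxa, dominance = 0.30,
                               expression_sigma = 1, seed = 1L,
                               genes_per_taxon = 20,
                               gene_length_range = c(300, 1500),
                               cluster_boost = 10) {
  if (dominance <= 0 || dominance >= 1)
    stop("dominance must be strictly between 0 and 1")
  if (expression_sigma < 0) stop("expression_sigma must be >= 0")
  sp <- tree$nodes$taxid[tree$nodes$rank == "species"]
  if (n_taxa > length(sp))
    stop("n_taxa exceeds the number of species in the taxonomy")
  set.seed(seed)

  fam <- vapply(sp, function(t) tax_ancestor_at_rank(tree, t, "family"),
                integer(1))
  # round-robin across families: one species per family, then wrap
  ord <- order(ave(seq_along(sp), fam, FUN = seq_along), fam)
  members <- sp[ord][seq_len(n_taxa)]

  if (n_taxa == 1L) {
    abund <- 1
  } else {
    w <- stats::rgamma(n_taxa - 1L, shape = 2)
    abund <- c(dominance, (1 - dominance) * w / sum(w))
  }
  taxa <- data.frame(
    taxid = members,
    name = tax_name(tree, members),
    family = vapply(members, function(t)
      tax_ancestor_at_rank(tree, t, "family"), integer(1)),
    abundance = abund,
    designated = seq_len(n_taxa) == 1L)
  taxa$family_name <- tax_name(tree, taxa$family)

  cluster <- data.frame(
    gene_label = c("abcA", "abcD", "bzlA", "bamB"),
    fun_id = c("4.1.1.98", "4.1.1.98", "6.2.1.25", "1.3.7.8"))

  genes <- list(); contigs <- list()
  contig_idx <- 0L
  genes_per_contig <- 4L
  for (i in seq_len(n_taxa)) {
    tx <- taxa$taxid[i]
    len <- round(stats::runif(genes_per_taxon,
                              gene_length_range[1], gene_length_range[2]))
    expr <- stats::rlnorm(genes_per_taxon, meanlog = 0,
                          sdlog = expression_sigma)
    lab <- sprintf("hk_%d_%d", i, seq_len(genes_per_taxon))
    fun <- sprintf("K%05d", ((seq_len(genes_per_taxon) - 1L) %% 10L) + 1L)
    if (taxa$designated[i]) {
      k <- nrow(cluster)
      lab[seq_len(k)] <- cluster$gene_label
      fun[seq_len(k)] <- cluster$fun_id
      expr[seq_len(k)] <- expr[seq_len(k)] * cluster_boost
    }
    chunks <- split(seq_len(genes_per_taxon),
                    (seq_len(genes_per_taxon) - 1L) %/% genes_per_contig)
    for (ch in chunks) {
      cid <- sprintf("contig-100_%d", contig_idx)
      spacer <- 50L
      starts <- spacer + 1L + c(0L, cumsum(len[ch] + spacer))[seq_along(ch)]
      ends <- starts + len[ch] - 1L
      clen <- ends[length(ch)] + spacer
      contigs[[length(contigs) + 1L]] <- data.frame(
        contig_id = cid, taxid = tx, length = clen,
        sequence = paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                         collapse = ""))
      genes[[length(genes) + 1L]] <- data.frame(
        locus_tag = vapply(seq_along(ch), function(j)
          format_locus_tag(100L, contig_idx, j), ""),
        taxid = tx, contig_id = cid,
        start = starts, end = ends, strand = "+",
        length = len[ch], expression = expr[ch],
        fun_id = fun[ch], gene_label = lab[ch])
      contig_idx <- contig_idx + 1L
    }
  }
  truth <- structure(list(
    tree = tree,
    taxa = taxa,
    genes = do.call(rbind, genes),
    contigs = do.call(rbind, contigs),
    rrna_seq = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                     collapse = ""),
    params = list(n_taxa = n_taxa, dominance = dominance,
                  expression_sigma = expression_sigma, seed = seed)),
    class = "community_truth")
  stopifnot(abs(sum(truth$taxa$abundance) - 1) < 1e-9,
            all(truth$genes$expression > 0))
  truth
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("community_truth: %d taxa, %d genes on %d contigs\n",
              nrow(x$taxa), nrow(x$genes), nrow(x$contigs)))
  cat(sprintf("  designated: %s (abundance %.2f)\n",
              x$taxa$name[x$taxa$designated],
              x$taxa$abundance[x$taxa$designated]))
  invisible(x)
}

gene_sequences <- function(truth) {
  cs <- stats::setNames(truth$contigs$sequence, truth$contigs$contig_id)
  substring(cs[truth$genes$contig_id], truth$genes$start, truth$genes$end)
}

#' Simulate an mRNA read set from a mock consortium
#'
#' Reads are drawn from genes with probability proportional to taxon
#' abundance x gene expression x gene length, with the expression-by-length
#' weights normalised within each taxon so that a taxon's expected share of
#' the mRNA pool equals its abundance (relative abundance in transcript
#' profiles is defined on the mRNA pool). Gene length enters the weight so
#' both count-based and coverage-based quantification can be checked
#' against the truth. Each read
#' is a substring of its source gene; substitution errors are placed
#' per base at `error_rate`, with quality Phred 38 for correct bases and
#' Phred 8 at error positions. A binomial fraction `rrna_fraction` of reads
#' is drawn from a decoy rRNA sequence and flagged, emulating residual rRNA
#' carry-over after depletion. Single-end reads only; no indels.
#'
#' @param truth a `community_truth` from [generate_community()]
#' @param n_reads total reads to simulate (mRNA + rRNA)
#' @param read_length read length in bp (default 150, HiSeq-style); genes
#'   shorter than this are excluded from sampling with a warning
#' @param error_rate per-base substitution probability in [0, 1)
#' @param rrna_fraction expected fraction of rRNA contaminant reads in [0, 1)
#' @param seed integer random seed
#' @return a `simulated_reads` object: data.frame `reads` with read_id,
#'   sequence, quality (Phred+33), true source_gene/taxid/contig_id,
#'   1-based contig_pos and is_rrna flag, plus the parameters used
#' @export
simulate_reads <- function(truth, n_reads, read_length = 150L,
                           error_rate = 0.001, rrna_fraction = 0.03,
                           seed = 1L) {
  stopifnot(read_length >= 1, error_rate >= 0, error_rate < 1,
            rrna_fraction >= 0, rrna_fraction < 1)
  set.seed(seed)
  g <- truth$genes
  gseq <- gene_sequences(truth)
  ab <- stats::setNames(truth$taxa$abundance, truth$taxa$taxid)
  w <- g$expression * g$length
  short <- g$length < read_length
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than the read length were excluded")
    w[short] <- 0
  }
  w <- w / stats::ave(w, g$taxid, FUN = sum)          # within-taxon share
  w <- as.numeric(ab[as.character(g$taxid)]) * w
  if (n_reads == 0L)
    return(structure(list(reads = data.frame(
      read_id = character(), sequence = character(), quality = character(),
      source_gene = character(), taxid = integer(), contig_id = character(),
      contig_pos = integer(), is_rrna = logical()),
      params = list(n_reads = 0L, read_length = read_length,
                    error_rate = error_rate, rrna_fraction = rrna_fraction,
                    seed = seed)),
      class = "simulated_reads"))

  n_rrna <- stats::rbinom(1L, n_reads, rrna_fraction)
  n_mrna <- n_reads - n_rrna
  gi <- sample.int(nrow(g), n_mrna, replace = TRUE, prob = w)
  local_start <- 1L + floor(stats::runif(n_mrna) *
                              (g$length[gi] - read_length + 1L))
  seqs <- substring(gseq[gi], local_start, local_start + read_length - 1L)
  rs <- if (n_rrna > 0) {
    rlen <- nchar(truth$rrna_seq)
    st <- 1L + floor(stats::runif(n_rrna) * (rlen - read_length + 1L))
    substring(truth$rrna_seq, st, st + read_length - 1L)
  } else character()
  all_seqs <- c(seqs, rs)

  mutate_reads <- function(sq, rate) {
    qual <- strrep(rawToChar(as.raw(38L + 33L)), nchar(sq))
    if (rate > 0) {
      nerr <- stats::rbinom(length(sq), nchar(sq), rate)
      hit <- which(nerr > 0)
      bases <- c("A", "C", "G", "T")
      qlow <- rawToChar(as.raw(8L + 33L))
      for (j in hit) {
        pos <- sample.int(nchar(sq[j]), nerr[j])
        for (p in pos) {
          orig <- substr(sq[j], p, p)
          substr(sq[j], p, p) <- sample(setdiff(bases, orig), 1L)
          substr(qual[j], p, p) <- qlow
        }
      }
    }
    list(seq = sq, qual = qual)
  }
  mq <- mutate_reads(all_seqs, error_rate)

  reads <- data.frame(
    read_id = "",
    sequence = mq$seq,
    quality = mq$qual,
    source_gene = c(g$locus_tag[gi], rep(NA_character_, n_rrna)),
    taxid = c(g$taxid[gi], rep(NA_integer_, n_rrna)),
    contig_id = c(g$contig_id[gi], rep(NA_character_, n_rrna)),
    contig_pos = c(g$start[gi] + local_start - 1L, rep(NA_integer_, n_rrna)),
    is_rrna = rep(c(FALSE, TRUE), c(n_mrna, n_rrna)))
  reads <- reads[sample.int(n_reads), , drop = FALSE]
  reads$read_id <- sprintf("read_%07d", seq_len(n_reads))
  rownames(reads) <- NULL
  structure(list(reads = reads,
                 params = list(n_reads = n_reads, read_length = read_length,
                               error_rate = error_rate,
                               rrna_fraction = rrna_fraction, seed = seed)),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d reads (%d rRNA-flagged), length %d\n",
              nrow(x$reads), sum(x$reads$is_rrna), x$params$read_length))
  invisible(x)
}

#' Perfect alignments of simulated reads to their source contigs
#'
#' The simulator emits contigs directly rather than assembling them, so the
#' true alignment of every mRNA read is known; rRNA decoy reads are emitted
#' as unmapped records. The result feeds [count_reads()] directly or can be
#' written with [write_sam()].
#'
#' @param sim a `simulated_reads` object
#' @return data.frame of alignment records (qname, flag, rname, pos, seq,
#'   qual); flag 0 = mapped forward, 4 = unmapped
#' @export
reads_to_alignments <- function(sim) {
  r <- sim$reads
  data.frame(
    qname = r$read_id,
    flag = ifelse(r$is_rrna, 4L, 0L),
    rname = ifelse(r$is_rrna, NA_character_, r$contig_id),
    pos = ifelse(r$is_rrna, NA_integer_, r$contig_pos),
    seq = r$sequence,
    qual = r$quality)
}

#' Simulate a BLAST-style homology hit table with known truth
#'
#' Every contig receives a strong top hit to its true species (bitscore
#' uniform in 150-300, alignment length > 100), one or two corroborating
#' hits to sister species within the same family at 91-100% of the top
#' bitscore, and — with probability `decoy_rate` — a decoy hit to a taxon in
#' the wrong clade whose bitscore is either at most 50 or between 50% and 85%
#' of the top. The decoy placement straddles every classifier filter
#' threshold, so a correct filtered-LCA must discard all decoys.
#'
#' @param contig_truth data.frame with columns `contig_id` and `taxid` (true
#'   source species, present in `tree`)
#' @param tree a [taxonomy_tree()]
#' @param decoy_rate probability a contig receives a decoy hit, in [0, 1]
#' @param seed integer random seed
#' @param n_sister sister hits per contig (capped by available sister species)
#' @return data.frame of hits in 13-column BLAST outfmt-6 layout (qseqid,
#'   sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore, staxid)
#' @export
simulate_hit_table <- function(contig_truth, tree, decoy_rate = 0.2,
                               seed = 1L, n_sister = 2L) {
  stopifnot(all(c("contig_id", "taxid") %in% names(contig_truth)),
            decoy_rate >= 0, decoy_rate <= 1)
  tax_index(tree, contig_truth$taxid)
  set.seed(seed)
  sp <- tree$nodes$taxid[tree$nodes$rank == "species"]
  fam_of <- stats::setNames(
    vapply(sp, function(t) tax_ancestor_at_rank(tree, t, "family"),
           integer(1)), sp)
  phy_of <- stats::setNames(
    vapply(sp, function(t) tax_ancestor_at_rank(tree, t, "phylum"),
           integer(1)), sp)

  one_hit <- function(q, taxid, bitscore, len, pident, evalue) {
    mm <- round(len * (1 - pident / 100))
    data.frame(qseqid = q,
               sseqid = sprintf("ref_%d_%d", taxid,
                                sample.int(.Machine$integer.max %/% 2, 1L)),
               pident = round(pident, 2), length = len, mismatch = mm,
               gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
               evalue = evalue, bitscore = round(bitscore, 1), staxid = taxid)
  }
  out <- vector("list", nrow(contig_truth))
  for (i in seq_len(nrow(contig_truth))) {
    q <- contig_truth$contig_id[i]
    tx <- contig_truth$taxid[i]
    top_bs <- stats::runif(1, 150, 300)
    hits <- list(one_hit(q, tx, top_bs, round(stats::runif(1, 120, 500)),
                         stats::runif(1, 95, 100), 10^-stats::runif(1, 30, 80)))
    sisters <- sp[fam_of[as.character(sp)] == fam_of[as.character(tx)] &
                    sp != tx]
    if (length(sisters) && n_sister > 0) {
      for (s in sample(sisters, min(n_sister, length(sisters))))
        hits[[length(hits) + 1L]] <-
          one_hit(q, s, top_bs * stats::runif(1, 0.91, 1.0),
                  round(stats::runif(1, 120, 500)),
                  stats::runif(1, 85, 95), 10^-stats::runif(1, 20, 60))
    }
    if (decoy_rate > 0 && stats::runif(1) < decoy_rate) {
      far <- sp[phy_of[as.character(sp)] != phy_of[as.character(tx)]]
      if (!length(far)) far <- sp[fam_of[as.character(sp)] !=
                                    fam_of[as.character(tx)]]
      if (length(far)) {
        d <- if (length(far) == 1L) far else sample(far, 1L)
        bs <- if (stats::runif(1) < 0.5) stats::runif(1, 20, 50)
              else top_bs * stats::runif(1, 0.50, 0.85)
        hits[[length(hits) + 1L]] <-
          one_hit(q, d, bs, round(stats::runif(1, 50, 400)),
                  stats::runif(1, 70, 90), 10^-stats::runif(1, 5, 30))
      }
    }
    out[[i]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write all simulator outputs in their standard on-disk formats
#'
#' Emits the mock consortium as the file set a real study would start from:
#' reads as FASTQ (Phred+33), contigs as FASTA, gene calls as GFF3 (1-based
#' inclusive), alignments as SAM, hit tables as headerless 13-column TSV,
#' the taxonomy as nodes.dmp/names.dmp, and the truth tables (taxon
#' abundances, gene truth) as TSV.
#'
#' @param truth a `community_truth`
#' @param sim a `simulated_reads` (optional)
#' @param hits a hit table from [simulate_hit_table()] (optional)
#' @param dir output directory (created if needed)
#' @return invisibly, a named vector of the files written
#' @export
write_community <- function(truth, dir, sim = NULL, hits = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  p <- file.path(dir, "contigs.fasta")
  write_fasta(stats::setNames(truth$contigs$sequence, truth$contigs$contig_id), p)
  files["contigs"] <- p
  p <- file.path(dir, "genes.gff3")
  write_gene_calls(truth$genes, p)
  files["genes"] <- p
  write_taxdump(truth$tree, dir)
  files["nodes"] <- file.path(dir, "nodes.dmp")
  files["names"] <- file.path(dir, "names.dmp")
  p <- file.path(dir, "taxon_abundance.tsv")
  utils::write.table(truth$taxa, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["abundance"] <- p
  p <- file.path(dir, "gene_truth.tsv")
  utils::write.table(truth$genes, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["gene_truth"] <- p
  if (!is.null(sim)) {
    p <- file.path(dir, "reads.fastq")
    write_fastq(sim$reads$sequence, sim$reads$quality, sim$reads$read_id, p)
    files["reads"] <- p
    p <- file.path(dir, "alignments.sam")
    write_sam(reads_to_alignments(sim), truth$contigs, p)
    files["alignments"] <- p
  }
  if (!is.null(hits)) {
    p <- file.path(dir, "hits.tsv")
    write_hit_table(hits, p)
    files["hits"] <- p
  }
  invisible(files)
}
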