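genes2 <- data.frame(locus_tag = c("gA", "gB"),
                     contig_id = "c1",
                     start = c(1L, 101L), end = c(100L, 200L))

aln <- function(qname, flag = 0L, rname = "c1", pos = 1L, width = 100L)
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             qwidth = width)

# vectorised family lift tolerating NA (rRNA reads)
tax_ancestor_at_rank_vec <- function(tree, taxids) {
  vapply(taxids, function(t)
    if (is.na(t)) NA_integer_ else tax_ancestor_at_rank(tree, t, "family"),
    integer(1))
}

test_that("reads are credited to the gene with the largest overlap", {
  # fully inside gene A
  cov <- count_reads(aln("r1", pos = 1L, width = 50L), genes2)
  expect_identical(cov$count, c(1L, 0L))
  expect_equal(cov$depth, c(50 / 100, 0))

  # 60 bp on A, 40 bp on B -> A only
  cov <- count_reads(aln("r1", pos = 41L), genes2)
  expect_identical(cov$count, c(1L, 0L))

  # exact tie 50/50 -> uncounted
  cov <- count_reads(aln("r1", pos = 51L), genes2)
  expect_identical(cov$count, c(0L, 0L))
  expect_true(all(cov$depth == 0))          # depth 0 iff count 0

  # no overlap at all -> uncounted
  cov <- count_reads(aln("r1", pos = 201L, width = 50L), genes2)
  expect_identical(sum(cov$count), 0L)
})

test_that("only primary mapped alignments are counted", {
  a <- rbind(aln("r1", flag = 4L),        # unmapped
             aln("r2", flag = 256L),      # secondary
             aln("r3", flag = 2048L))     # supplementary
  expect_identical(sum(count_reads(a, genes2)$count), 0L)

  expect_message(
    cov <- count_reads(rbind(aln("r1"), aln("r2", rname = "nope")), genes2),
    "skipping")
  expect_identical(sum(cov$count), 1L)
})

test_that("counting through a SAM file matches counting records directly", {
  tr <- generate_taxonomy(3, 2, seed = 12)
  truth <- generate_community(tr, 3, seed = 12)
  sim <- simulate_reads(truth, 400, error_rate = 0.01, rrna_fraction = 0.05,
                        seed = 12)
  a <- reads_to_alignments(sim)
  direct <- count_reads(a, truth$genes)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, truth$contigs, sam)
  via_sam <- count_reads(read_sam(sam), truth$genes)
  expect_identical(via_sam$count, direct$count)
  expect_equal(via_sam$depth, direct$depth)
  # conservation: counted reads never exceed primary mapped reads
  expect_lte(sum(direct$count), sum(bitwAnd(a$flag, 4L) == 0L))
})

test_that("taxon profiles aggregate counts at the requested rank", {
  tr <- fixture_tree()
  genes <- data.frame(locus_tag = c("g1", "g2", "g3"),
                      contig_id = c("c1", "c2", "c3"),
                      start = 1L, end = 300L)
  coverage <- data.frame(locus_tag = genes$locus_tag,
                         contig_id = genes$contig_id,
                         length = 300L,
                         count = c(30L, 70L, 0L),
                         depth = c(15, 35, 0))
  asn <- data.frame(contig_id = c("c1", "c2", "c3"),
                    taxid = c(10L, 12L, NA))
  prof <- taxon_profile(coverage, asn, tr, rank = "genus")
  expect_equal(sum(prof$percent), 100, tolerance = 1e-6)
  expect_equal(prof$percent[prof$name == "GenA"], 30)
  expect_equal(prof$percent[prof$name == "GenB"], 70)

  # all reads under one family
  prof_f <- taxon_profile(coverage, asn, tr, rank = "family")
  expect_equal(prof_f$percent[prof_f$name == "FamA"], 100)

  # assignment above the requested rank goes to unclassified
  asn2 <- data.frame(contig_id = c("c1", "c2", "c3"),
                     taxid = c(10L, 7L, NA))     # c2 at family level
  prof_g <- taxon_profile(coverage, asn2, tr, rank = "genus")
  expect_equal(prof_g$percent[prof_g$name == "unclassified"], 70)
  expect_equal(sum(prof_g$percent), 100, tolerance = 1e-6)
})

test_that("rank-level profile recovers simulator truth within sampling error", {
  tr <- generate_taxonomy(4, 2, seed = 33)
  truth <- generate_community(tr, 4, dominance = 0.4, seed = 33)
  sim <- simulate_reads(truth, 8000, error_rate = 0, rrna_fraction = 0,
                        seed = 33)
  cov <- count_reads(reads_to_alignments(sim), truth$genes)
  hits <- simulate_hit_table(truth$contigs[c("contig_id", "taxid")], tr,
                             decoy_rate = 0.2, seed = 33)
  asn <- two_pass_assign(hits, NULL, tr)
  prof <- taxon_profile(cov, asn, tr, rank = "family")
  fam <- truth$taxa$family_name[truth$taxa$designated]
  truth_share <- mean(tax_ancestor_at_rank_vec(tr, sim$reads$taxid) ==
                        truth$taxa$family[truth$taxa$designated])
  got <- prof$percent[prof$name == fam] / 100
  expect_lt(abs(got - truth_share), 3 * sqrt(0.4 * 0.6 / 8000) + 1e-9)
})
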