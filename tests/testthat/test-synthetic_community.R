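test_that("generated taxonomies are valid, complete and deterministic", {
  tr1 <- generate_taxonomy(1, 1, seed = 0)
  sp <- tr1$nodes$taxid[tr1$nodes$rank == "species"]
  expect_length(sp, 2L)                       # one genus, two species
  expect_identical(lca(sp[1], tr1), sp[1])    # lca of a species with itself

  expect_identical(generate_taxonomy(3, 2, seed = 7),
                   generate_taxonomy(3, 2, seed = 7))

  tr <- generate_taxonomy(3, 2, seed = 7)
  # every species reaches a family by explicitly walking parents
  parent <- stats::setNames(tr$nodes$parent, tr$nodes$taxid)
  rank <- stats::setNames(tr$nodes$rank, tr$nodes$taxid)
  for (s in tr$nodes$taxid[tr$nodes$rank == "species"]) {
    cur <- s; seen_family <- FALSE
    while (parent[[as.character(cur)]] != cur) {
      cur <- parent[[as.character(cur)]]
      if (rank[[as.character(cur)]] == "family") seen_family <- TRUE
    }
    expect_true(seen_family)
  }
  expect_error(generate_taxonomy(0, 1), "positive")
})

test_that("community truth honours dominance, sigma and determinism", {
  tr <- generate_taxonomy(4, 2, seed = 1)
  truth <- generate_community(tr, 4, dominance = 0.30, seed = 9)
  expect_equal(truth$taxa$abundance[truth$taxa$designated], 0.30)
  expect_equal(sum(truth$taxa$abundance), 1, tolerance = 1e-12)
  expect_true(all(truth$genes$expression > 0))
  # each gene belongs to exactly one taxon and one contig
  expect_false(anyDuplicated(truth$genes$locus_tag) > 0)

  sigma0 <- generate_community(tr, 4, dominance = 0.30,
                               expression_sigma = 0, seed = 9,
                               cluster_boost = 1)
  for (tx in sigma0$taxa$taxid)
    expect_true(all(sigma0$genes$expression[sigma0$genes$taxid == tx] == 1))

  expect_identical(generate_community(tr, 4, seed = 3),
                   generate_community(tr, 4, seed = 3))
  expect_error(generate_community(tr, 4, dominance = 1.2), "dominance")
  expect_error(generate_community(tr, 99, dominance = 0.3), "n_taxa")
})

test_that("the degradation cluster is co-localised on one contig", {
  tr <- generate_taxonomy(3, 2, seed = 2)
  truth <- generate_community(tr, 3, seed = 2)
  cl <- truth$genes[truth$genes$gene_label %in%
                      c("abcA", "abcD", "bzlA", "bamB"), ]
  expect_identical(nrow(cl), 4L)
  expect_length(unique(cl$contig_id), 1L)
  expect_identical(unique(cl$taxid), truth$taxa$taxid[truth$taxa$designated])
  expect_true(all(diff(cl$start) > 0))        # ordered along the contig
})

test_that("error-free reads are exact substrings at their recorded positions", {
  tr <- generate_taxonomy(3, 2, seed = 4)
  truth <- generate_community(tr, 3, seed = 4)
  sim <- simulate_reads(truth, 500, error_rate = 0, rrna_fraction = 0,
                        seed = 11)
  expect_identical(nrow(sim$reads), 500L)
  cs <- stats::setNames(truth$contigs$sequence, truth$contigs$contig_id)
  with(sim$reads, for (i in seq_len(10)) {
    expect_identical(sequence[i],
                     substr(cs[[contig_id[i]]], contig_pos[i],
                            contig_pos[i] + nchar(sequence[i]) - 1L))
  })
  # every read's true gene exists in the truth
  expect_true(all(sim$reads$source_gene %in% truth$genes$locus_tag))
  expect_true(all(nchar(sim$reads$sequence) == nchar(sim$reads$quality)))
})

test_that("rRNA contamination count is binomial and reads conserve totals", {
  tr <- generate_taxonomy(3, 2, seed = 4)
  truth <- generate_community(tr, 3, seed = 4)
  sim <- simulate_reads(truth, 10000, error_rate = 0, rrna_fraction = 0.05,
                        seed = 21)
  n_rrna <- sum(sim$reads$is_rrna)
  expect_lt(abs(n_rrna - 500), 3 * sqrt(10000 * 0.05 * 0.95))
  expect_identical(sum(sim$reads$is_rrna) + sum(!sim$reads$is_rrna), 10000L)
  # error positions carry lowered quality
  err <- simulate_reads(truth, 300, error_rate = 0.05, rrna_fraction = 0,
                        seed = 3)
  q <- unlist(phred_scores(err$reads$quality))
  expect_setequal(unique(q), c(38L, 8L))
})

test_that("read sampling follows a 3:1 expression ratio at equal lengths", {
  tr <- generate_taxonomy(1, 1, seed = 6)
  truth <- generate_community(tr, 1, seed = 6, genes_per_taxon = 2,
                              gene_length_range = c(600, 600),
                              cluster_boost = 1)
  truth$genes$expression <- c(3, 1)
  sim <- simulate_reads(truth, 50000, error_rate = 0, rrna_fraction = 0,
                        seed = 13)
  counts <- table(sim$reads$source_gene)[truth$genes$locus_tag]
  p_hat <- counts[[1]] / 50000
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 50000))
})

test_that("simulator output files are byte-identical under a fixed seed", {
  tr <- generate_taxonomy(2, 1, seed = 8)
  truth <- generate_community(tr, 2, seed = 8)
  sim <- simulate_reads(truth, 200, seed = 8)
  hits <- simulate_hit_table(truth$contigs[c("contig_id", "taxid")], tr,
                             decoy_rate = 0.3, seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_community(truth, d1, sim = sim, hits = hits)
  write_community(truth, d2, sim = sim, hits = hits)
  for (f in c("reads.fastq", "contigs.fasta", "genes.gff3", "hits.tsv",
              "nodes.dmp", "names.dmp", "gene_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and regenerating from the same seeds gives the same reads
  sim2 <- simulate_reads(truth, 200, seed = 8)
  expect_identical(sim$reads, sim2$reads)
})

test_that("hit tables place the truth on top and decoys below the filters", {
  tr <- generate_taxonomy(4, 2, seed = 5)
  truth <- generate_community(tr, 4, seed = 5)
  ct <- truth$contigs[c("contig_id", "taxid")]

  hits <- simulate_hit_table(ct, tr, decoy_rate = 0, seed = 5)
  for (cg in ct$contig_id) {
    a <- assign_contig(hits[hits$qseqid == cg, ], tr)
    true_path <- tax_ancestors(tr, ct$taxid[ct$contig_id == cg])
    expect_true(a$taxid %in% true_path)       # assignment on the true lineage
  }

  # a contig given only its top hit resolves to the true species
  solo <- simulate_hit_table(ct[1, ], tr, decoy_rate = 0, seed = 5,
                             n_sister = 0)
  expect_identical(nrow(solo), 1L)
  expect_identical(solo$staxid, ct$taxid[1])
  expect_true(all(solo$length > 100 & solo$bitscore >= 150))

  # decoys sit below the absolute floor or below 90% of the top bitscore
  hd <- simulate_hit_table(ct, tr, decoy_rate = 1, seed = 5)
  fam_of <- function(t) tax_ancestor_at_rank(tr, t, "family")
  for (cg in ct$contig_id) {
    h <- hd[hd$qseqid == cg, ]
    truefam <- fam_of(ct$taxid[ct$contig_id == cg])
    decoy <- vapply(h$staxid, fam_of, integer(1)) != truefam
    if (any(decoy)) {
      top <- max(h$bitscore[!decoy])
      expect_true(all(h$bitscore[decoy] <= 50 |
                        h$bitscore[decoy] < 0.9 * top))
    }
  }
})
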