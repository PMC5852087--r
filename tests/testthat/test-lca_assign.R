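test_that("hit filters use the documented strict/inclusive boundaries", {
  tr <- fixture_tree()
  h <- rbind(make_hit(bitscore = 50, sseqid = "at_floor"),        # == 50: out
             make_hit(bitscore = 50.1, sseqid = "just_above"),
             make_hit(bitscore = 200, len = 100L, sseqid = "len100"),
             make_hit(bitscore = 200, len = 101L, sseqid = "len101"),
             make_hit(bitscore = 180, evalue = 1e-3, sseqid = "bad_e"))
  f <- filter_hits(h)
  expect_setequal(f$sseqid, c("len101"))  # 50.1 dropped by 10% band off 200

  # three hits 200/185/170: 170 falls below 0.9 x 200
  h3 <- rbind(make_hit(bitscore = 200, sseqid = "a"),
              make_hit(bitscore = 185, sseqid = "b"),
              make_hit(bitscore = 170, sseqid = "c"))
  expect_setequal(filter_hits(h3)$sseqid, c("a", "b"))

  # the band is inclusive at exactly 90% of the best
  h90 <- rbind(make_hit(bitscore = 200, sseqid = "top"),
               make_hit(bitscore = 180, sseqid = "edge"))
  expect_setequal(filter_hits(h90)$sseqid, c("top", "edge"))

  empty <- filter_hits(make_hit()[0, ])
  expect_identical(nrow(empty), 0L)

  mixed <- rbind(make_hit(q = "c1"), make_hit(q = "c2"))
  expect_error(filter_hits(mixed), "single query")
})

test_that("the top band can be measured on alignment length instead", {
  h <- rbind(make_hit(bitscore = 100, len = 400L, sseqid = "long"),
             make_hit(bitscore = 300, len = 200L, sseqid = "short"))
  # bitscore banding keeps only the high scorer; length banding only the long
  expect_identical(filter_hits(h)$sseqid, "short")
  expect_identical(filter_hits(h, top_metric = "length")$sseqid, "long")
})

test_that("contig assignment composes filtering and LCA", {
  tr <- fixture_tree()
  low <- rbind(make_hit(bitscore = 30), make_hit(bitscore = 45))
  a <- assign_contig(low, tr)
  expect_true(is.na(a$taxid)); expect_identical(a$n_hits, 0L)

  one <- make_hit(taxid = 10L)
  expect_identical(assign_contig(one, tr)$taxid, 10L)

  sis <- rbind(make_hit(taxid = 10L, bitscore = 200),
               make_hit(taxid = 11L, bitscore = 195, sseqid = "s2"))
  expect_identical(assign_contig(sis, tr)$taxid, 8L)   # their genus
  # a sub-threshold hit to another phylum changes nothing
  sis_plus <- rbind(sis, make_hit(taxid = 4L, bitscore = 20, sseqid = "junk"))
  expect_identical(assign_contig(sis_plus, tr)$taxid, 8L)

  unknown <- rbind(one, make_hit(taxid = 999L, sseqid = "gone"))
  expect_warning(a2 <- assign_contig(unknown, tr), "unknown taxon")
  expect_identical(a2$taxid, 10L)
})

test_that("two-pass assignment consults the second table only for leftovers", {
  tr <- fixture_tree()
  p1 <- rbind(make_hit(q = "c1", taxid = 10L),
              make_hit(q = "c2", taxid = 11L, bitscore = 30))  # filtered out
  p2 <- rbind(make_hit(q = "c1", taxid = 12L),   # must be ignored
              make_hit(q = "c2", taxid = 8L))
  res <- two_pass_assign(p1, p2, tr, contigs = c("c1", "c2", "c3"))
  expect_identical(res$taxid[res$contig_id == "c1"], 10L)
  expect_identical(res$pass[res$contig_id == "c1"], "first")
  expect_identical(res$taxid[res$contig_id == "c2"], 8L)
  expect_identical(res$pass[res$contig_id == "c2"], "second")
  expect_true(is.na(res$taxid[res$contig_id == "c3"]))
  expect_identical(res$pass[res$contig_id == "c3"], "none")
  expect_identical(res$rank[res$contig_id == "c1"], "species")
})

test_that("assignment agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:300) {
    tr <- random_ranked_tree(50)
    h <- random_hits(tr)
    got <- if (nrow(h)) assign_contig(h, tr)$taxid else NA_integer_
    want <- oracle_assign(h, tr)
    expect_identical(got, want)
  }
})

test_that("assignments are invariant to hit order and sub-threshold additions", {
  set.seed(55)
  for (i in 1:40) {
    tr <- random_ranked_tree(40)
    h <- random_hits(tr, n = sample(1:15, 1))
    base <- assign_contig(h, tr)$taxid
    perm <- assign_contig(h[sample(nrow(h)), , drop = FALSE], tr)$taxid
    expect_identical(perm, base)
    # add an irrelevant hit: at/below the bitscore floor or past the ceiling
    junk <- make_hit(q = "q1", taxid = sample(tr$nodes$taxid, 1),
                     bitscore = sample(c(10, 50), 1), sseqid = "junk")
    junk$evalue <- sample(c(1e-10, 1e-2), 1)
    if (junk$evalue > 1e-4) junk$bitscore <- 300
    expect_identical(assign_contig(rbind(h, junk), tr)$taxid, base)
  }
})

test_that("hit tables round-trip through the 13-column tabular format", {
  tr <- fixture_tree()
  h <- rbind(make_hit(q = "c1", taxid = 10L),
             make_hit(q = "c2", taxid = 12L, bitscore = 77.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(h, p)
  h2 <- read_hit_table(p)
  expect_equal(h2$bitscore, h$bitscore)
  expect_identical(h2$staxid, h$staxid)
  # alternative column order
  cols <- c("qseqid", "staxid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  h3 <- h2[, cols]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(h3, p2, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  expect_equal(read_hit_table(p2, columns = cols)$bitscore, h$bitscore)
})
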