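#!/usr/bin/env Rscript
# Two-pass filtered-LCA taxonomic assignment: per contig, keep hits with
# e-value <= 1e-4, bitscore > 50, alignment length > 100 nt and bitscore
# within 10% of the best, then take the lowest common ancestor of the
# surviving subject taxa. Contigs the first hit table cannot place are
# re-evaluated against the second table with identical filters.

suppressMessages(library(mtxpipe))
dir.create("results/taxonomy", showWarnings = FALSE, recursive = TRUE)

tree <- read_taxdump("results/mock/nodes.dmp", "results/mock/names.dmp")
pass1 <- read_hit_table("results/mock/hits_pass1.tsv")
pass2 <- read_hit_table("results/mock/hits_pass2.tsv")
contigs <- names(read_fasta("results/contigs/contigs.kept.fasta"))

asn <- two_pass_assign(pass1, pass2, tree, contigs = contigs)
message(sprintf("assigned %d/%d contigs (%d in pass 1, %d in pass 2)",
                sum(!is.na(asn$taxid)), nrow(asn),
                sum(asn$pass == "first"), sum(asn$pass == "second")))
print(table(rank = asn$rank, useNA = "ifany"))
write.table(asn, "results/taxonomy/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
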