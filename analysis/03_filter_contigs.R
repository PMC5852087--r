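#!/usr/bin/env Rscript
# Low-complexity contig removal: drop contigs that are >90% a single base,
# >90% GC or AT, or contain a homopolymer run of 50+ bases.

suppressMessages(library(mtxpipe))
dir.create("results/contigs", showWarnings = FALSE, recursive = TRUE)

contigs <- read_fasta("results/mock/contigs.fasta")
res <- filter_contigs(contigs)
message(sprintf("contigs: %d in, %d kept, %d removed",
                length(contigs), length(res$kept), nrow(res$removed)))
if (nrow(res$removed))
  message("removal reasons: ",
          paste(unique(res$removed$failed), collapse = ", "))
write_fasta(res$kept, "results/contigs/contigs.kept.fasta")
write.table(res$report, "results/contigs/complexity_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
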