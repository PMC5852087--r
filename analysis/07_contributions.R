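#!/usr/bin/env Rscript
# The per-locus relative contribution to function (each locus's share of its
# function's total depth) and the pathway-step relative-abundance report
# (percent of all counted reads, log10-scaled for display, zero steps
# excluded).

suppressMessages(library(mtxpipe))
dir.create("results/contribution", showWarnings = FALSE, recursive = TRUE)

g <- read.delim("results/mock/gene_truth.tsv")
cov <- read.delim("results/expression/coverage.tsv")
asn <- read.delim("results/taxonomy/assignments.tsv")

expr <- data.frame(fun_id = g$fun_id, locus_tag = g$locus_tag,
                   expression = cov$depth[match(g$locus_tag, cov$locus_tag)])
ct <- contribution(expr[expr$expression > 0, ])

# Table-1-style report: gene label, locus tag, taxon of the contig, percent
report <- data.frame(
  gene = g$gene_label[match(ct$locus_tag, g$locus_tag)],
  locus_tag = ct$locus_tag,
  taxon = asn$name[match(g$contig_id[match(ct$locus_tag, g$locus_tag)],
                         asn$contig_id)],
  fun_id = ct$fun_id,
  contribution_pct = round(ct$contribution))
write.table(report, "results/contribution/contribution_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("cluster locus contributions:")
print(report[report$gene %in% c("abcA", "abcD", "bzlA", "bamB"), ],
      row.names = FALSE)

steps <- read.delim("results/annotation/pathway_steps.tsv")
sa <- step_abundance(
  stats::setNames(steps$total_count,
                  paste(steps$pathway, steps$step_label, sep = ":")),
  grand_total = sum(cov$count))
write.table(sa, "results/contribution/step_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("step abundances: %d steps, %d with non-zero abundance",
                nrow(sa), sum(sa$included)))
print(sa[sa$included, ], row.names = FALSE)
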