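#!/usr/bin/env Rscript
# Read quality control: trim both ends to quality 30, then keep reads that
# are >= 40 bp, have mean quality >= 30, use only IUPAC characters and carry
# at most three Ns.

suppressMessages(library(mtxpipe))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

summary <- qc_fastq("results/mock/reads.fastq",
                    "results/qc/reads.clean.fastq",
                    report_file = "results/qc/rejections.tsv")
print(summary)
write.table(summary, "results/qc/qc_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("clean reads: results/qc/reads.clean.fastq")
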