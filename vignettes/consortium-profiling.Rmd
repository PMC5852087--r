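---
title: "Profiling a mock microbial consortium: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a mock microbial consortium: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxpipe)
```

mtxpipe implements the computational core of an assembly-based
metatranscriptomic study of a mixed microbial community — the kind of
consortium in which one family dominates transcription (for example a
benzene-degrading, nitrate-reducing culture dominated by *Peptococcaceae*)
and the question is which organisms transcribe which degradation genes, and
how strongly. External tools (rRNA removal, assembly, gene prediction, read
mapping, BLAST searches, orthology and domain annotation) are consumed
through their standard file formats; everything bespoke — the filtering
rules, the taxonomic classifier, the quantification conventions and the
contribution statistic — is implemented and tested here.

This vignette documents the methods, their assumptions, and the design
choices made where the conventions were genuinely open.

## Read quality control

A read is trimmed base by base from the 5' end while quality is below 30,
then likewise from the 3' end (window-1 trimming; interior bases are never
removed). The trimmed read is kept only if it is at least 40 bp, has mean
quality at least 30, contains only IUPAC nucleotide codes, and carries at
most three Ns. Rejection reasons are reported in that fixed order, so a
read failing several filters is reported under the first.

Two conventions here are choices rather than givens. First, the mean-quality
test is evaluated on the *trimmed* read, mirroring the trim-then-filter
order of the usual QC tool chain; a pre-trim mean would reject reads whose
only weakness is a bad tail that trimming removes. Second, N is treated as
IUPAC-legal (it is an ambiguity code) and only the dedicated N-count filter
limits it. An empty post-trim read is reported as a length failure.

```{r}
qc_read(strrep("A", 40), rep(40L, 40))$kept
qc_read(paste0(strrep("N", 4), strrep("A", 56)), rep(40L, 60))$reason
```

## Contig low-complexity filter

Assemblies of rRNA-depleted transcriptomes accumulate degenerate contigs.
A contig is removed when more than 90% of its bases are one nucleotide,
more than 90% are G+C or more than 90% are A+T, or it contains a
homopolymer run of 50 or more bases. The fraction tests are strict
(exactly 0.90 passes) and the run test inclusive (exactly 50 fails),
following the rule text literally. Ambiguity codes count toward length but
never toward a base tally or a run: ambiguity alone cannot remove a contig.
"More than 90% GC or AT" is read as two tests, G+C > 0.9 or A+T > 0.9, and
the single-base rule as the maximum over the four bases (equivalent to a
per-base test at thresholds above 0.5). All four statistics are invariant
under reverse complement.

Predicted genes are named `contig-{kmer}_{contig#}_{gene#}`
(`format_locus_tag()`); tags are rendered lowercase and compared
case-insensitively, since upstream tools mix casings.

## Filtered-LCA taxonomic assignment

Contigs are classified from BLAST-style tabular hits carrying subject taxon
ids. Per contig, hits pass four filters: e-value at most 1e-4 (applied
first, as the search-time ceiling), bitscore strictly above 50, alignment
length strictly above 100 nucleotides, and score within 10% of the best
surviving hit. The survivors' taxa are reduced to their lowest common
ancestor in a ranked taxonomy; no surviving hits means unassigned. A second
hit table (a blastn re-search in the original workflow) is consulted only
for contigs the first pass could not place, with identical filters.

Open conventions, and how they were fixed:

* "did not deviate more than 10% from the longest hit" is ambiguous between
  bitscore and alignment length. The top-percent band is measured on
  **bitscore** by default, the convention of the MEGAN classifier this
  procedure descends from; `top_metric = "length"` selects the alternative
  reading.
* "exceeding" and "more than" are strict inequalities; the derived
  top-percent bound is inclusive (`>= 0.9 x best`) so the best hit always
  survives its own band.
* Hits with taxon ids absent from the tree (deleted/merged ids) are dropped
  with a warning rather than failing the contig.
* No minimum-support rule is applied (none is part of this parameterisation),
  and the several reference databases of a real search are modelled as one
  table per pass — provenance is not a filter.

The implementation is verified against an independent brute-force oracle
(literal rule-by-rule filtering plus full root-path intersection) on 1000
random tree/hit-table instances, and is invariant to hit order and to the
addition of sub-threshold hits.

```{r}
tr <- generate_taxonomy(3, 2, seed = 7)
hits <- simulate_hit_table(data.frame(contig_id = "c1",
                                      taxid = tr$nodes$taxid[
                                        tr$nodes$rank == "species"][1]),
                           tr, decoy_rate = 1, seed = 7)
assign_contig(hits, tr)
```

## Expression quantification

Gene-level counting consumes SAM records (through Rsamtools, so flags are
interpreted by htslib) and GFF3 gene calls. Only primary mapped alignments
count; each read is credited to the gene with the largest overlap on its
contig, and reads that tie exactly or overlap no gene are discarded rather
than fractionally split. Counting is unstranded, as no strandedness
convention is part of the emulated protocol. Depth is the sum of credited
read lengths divided by gene length.

Taxon profiles attribute each gene's count to its contig's assignment
lifted to a requested rank (family by default). Assignments above that rank
and unassigned contigs fall into an explicit "unclassified" bucket, and the
profile — including that bucket — sums to 100%. Profiles use raw read
counts by default (transcript abundance at mRNA level); `use = "depth"`
profiles length-normalised coverage instead, since it is genuinely unclear
which convention a given study used.

## Functional annotation and pathway mapping

Three annotation sources merge into one per-locus function map with
provenance: a KO table, an EC table, and ECs derived by text-matching
domain names against an enzyme-name lookup. Matching normalises both sides
(lowercase, punctuation stripped, whitespace collapsed) and is exact by
default; a token-set mode (order-insensitive word multiset) approximates
fuzzier mining. Exact matching was chosen as the default because it cannot
hallucinate an EC the lookup does not contain; the original study's
text-mining rules live in supporting material that is not reproduced here,
so both modes are documented as interpretations. Malformed EC strings are
skipped with a warning, never silently kept.

Pathway definitions ship as an editable TSV
(`inst/extdata/pathway_steps.tsv`) covering anaerobic benzene activation by
carboxylation (abcA/abcD/bzlA) and hydroxylation (ppsABC/ppcC/hcrA),
benzoyl-CoA dearomatisation (bamBCDEI, bcrA/badF/bzdQ), modified
beta-oxidation (bzdWXY), the lower pathway to acetyl-CoA
(pimE/pimB/acd/gcdBCH/pcaF), aerobic oxygenase routes (tmo, dmp) and the
nitrogen cycle (nar/nir/nor/nos/nrf/nif/amo). The identifiers are curated
placeholders at the usual KO/EC granularity and are meant to be edited for
any serious reuse, as is the small enzyme-name lookup
(`enzyme_names_synthetic.tsv`), which is a synthetic stand-in for a full
enzyme-name database. A locus whose identifiers intersect several steps
contributes to all of them and is flagged ambiguous — the question-mark
convention of pathway figures — rather than being forced into one step.

## Contribution to function and step abundance

The contribution of a locus to a function is its expression as a percentage
of the function's total: two equally expressed loci each contribute 50%.
Contributions are scale-invariant, permutation-invariant and sum to 100 per
function. The default expression value is length-normalised depth, which
removes gene-length bias between loci of one function (and makes the
estimator unbiased even when the loci differ in length); raw counts are
supported by passing them as the expression column. Reports round to whole
percents; internal values keep full precision. A locus assigned to several
functions contributes its full expression to each — ambiguity is flagged,
not split.

Pathway-step abundance is each step's expression total as a percentage of
all counted reads, displayed as log10 with zero-abundance steps excluded
(zeros cannot be drawn on a log axis).

```{r}
contribution(data.frame(fun_id = "f", locus_tag = c("a", "b"),
                        expression = c(30, 10)))
```

## The synthetic consortium generator

Every stage above is validated end to end on a generated mock consortium
with full ground truth, since the original sequencing data and reference
databases are far beyond desk scale.

* **Taxonomy**: a fully ranked tree, families split across two phyla (so
  wrong-clade decoys exist), two species per genus (so sister taxa exist at
  genus and family level).
* **Community**: one designated taxon receives the dominance fraction
  (default 0.30, matching a consortium whose dominant family sits at
  roughly a fifth to a third of the mRNA pool); the rest is split by Gamma
  weights. Per-gene expression is log-normal with median 1 and shape
  `expression_sigma` (default 1), a heavy-tailed model consistent with
  contribution tables spanning orders of magnitude. The designated taxon
  carries a co-localised abcA/abcD/bzlA/bamB cluster on one contig, boosted
  10-fold in expression — the emulated system's degradation cluster is
  highly transcribed — with abcA/abcD sharing one function so multi-locus
  functions exist downstream.
* **Reads**: single-end 150 bp (the emulated platform's read length),
  substitution errors only at `error_rate` (default 0.001), quality 38 at
  correct bases and 8 at errors (straddling the trim threshold of 30), and
  a binomial `rrna_fraction` (default 0.03, inside the 0.3–6.9% residual
  rRNA range of real libraries) of flagged decoy rRNA reads. Sampling
  weights are taxon abundance times expression-by-length normalised within
  each taxon: abundance is thereby *defined* as a taxon's share of the mRNA
  pool, which is what a transcript-level relative-abundance profile
  measures. Without that normalisation the realised share of a taxon would
  drift with its particular expression draws and "dominance 0.30" would not
  mean a 30% profile.
* **Hit tables**: per contig a true-species top hit (bitscore uniform in
  150–300, length over 100), sister hits at 91–100% of the top, and decoys
  in the wrong clade at either bitscore ≤ 50 or 50–85% of the top — every
  score lands on a designed side of every filter threshold.

What the generator does **not** emulate: indels, paired ends, strand
structure, chimeric or fragmented assembly (contigs are emitted, not
assembled), quality-score degradation along the read, taxon-specific codon
or GC structure, and homology that crosses family boundaries. Passing tests
therefore demonstrate the correctness of the rules and statistics, not
robustness to assembly artefacts or to divergent-reference classification —
those depend on upstream tools this package deliberately does not run.

## Problem sizes and numerical conventions

The packaged analysis scripts simulate 6 families, 6 taxa, 120 genes and
20,000 reads; the test suite's recovery checks use 50,000 reads, where the
dominant family's profile is expected within 2 percentage points of truth
and a 3:1 two-locus expression ratio recovers 75%/25% contributions at
whole-percent rounding. Stochastic checks use 3-sigma binomial/multinomial
bounds. All simulators take explicit integer seeds and are deterministic
given one (file outputs are byte-identical). Ties in read-to-gene
assignment are discarded, not split; ties in hit sorting break by subject
id; degenerate inputs (empty read after trimming, empty hit set, zero-total
function) take the documented non-error paths.

## Limitations

The classifier assumes one consistent taxonomy for all hit tables; the
pathway and enzyme-name tables are small curated scaffolds, not databases;
counting does not handle spliced or clipped CIGARs beyond their reported
query width; and no attempt is made to reproduce any real study's numbers,
which depend on sequencing data and reference databases outside desk scale.
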