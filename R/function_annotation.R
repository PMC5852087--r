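#' Normalise an enzyme or domain name for text matching
#'
#' Lowercases, strips punctuation and collapses whitespace, so that
#' "Benzoate-CoA ligase" and "benzoate-CoA  ligase." compare equal.
#'
#' @param x character vector of names
#' @return normalised character vector
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Derive EC numbers by matching domain names against an enzyme-name table
#'
#' Text-mines functional domain names (e.g. from a protein-domain scan)
#' against a curated enzyme-name-to-EC lookup. In the default `"exact"` mode
#' a locus gains an EC when a normalised domain name equals a normalised
#' enzyme name; `"token"` mode compares the word multiset instead, so word
#' order does not matter ("ligase, benzoate-CoA" still matches). Exact mode
#' is deliberately conservative: it cannot invent an EC that the lookup does
#' not spell out.
#'
#' @param domain_names data.frame with locus_tag and domain_name
#' @param enzyme_names data.frame with name and ec
#' @param mode "exact" (default) or "token"
#' @return data.frame: locus_tag, ec, provenance ("name-match"); one row per
#'   distinct (locus, EC) pair
#' @export
match_domain_names <- function(domain_names, enzyme_names,
                               mode = c("exact", "token")) {
  mode <- match.arg(mode)
  if (!nrow(enzyme_names) || !nzchar(enzyme_names$name[1]) &&
      nrow(enzyme_names) == 1L)
    stop("enzyme name table is empty")
  key <- function(x) {
    n <- normalize_name(x)
    if (mode == "token")
      n <- vapply(strsplit(n, " "), function(w)
        paste(sort(w), collapse = " "), "")
    n
  }
  dk <- key(domain_names$domain_name)
  ek <- key(enzyme_names$name)
  i <- match(dk, ek)
  hit <- !is.na(i)
  out <- unique(data.frame(locus_tag = domain_names$locus_tag[hit],
                           ec = enzyme_names$ec[i[hit]],
                           provenance = rep("name-match", sum(hit))))
  rownames(out) <- NULL
  out
}

EC_PATTERN <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Merge functional annotations into a per-locus function map
#'
#' Unions KO assignments, directly assigned EC numbers and text-mined EC
#' numbers into one long table with provenance. Malformed EC strings are
#' skipped with a warning. The same identifier reached by several routes is
#' kept once per (locus, id, provenance), so provenance is never lost, and
#' the output is sorted so the result does not depend on input order.
#'
#' @param ko_table data.frame with locus_tag and ko (e.g. "K00632"); may be
#'   NULL
#' @param ec_table data.frame with locus_tag and ec; may be NULL
#' @param name_match_ec output of [match_domain_names()]; may be NULL
#' @return `function_map` data.frame: locus_tag, type ("KO"/"EC"), id,
#'   provenance ("ko-table"/"ec-table"/"name-match")
#' @export
merge_annotations <- function(ko_table = NULL, ec_table = NULL,
                              name_match_ec = NULL) {
  parts <- list()
  if (!is.null(ko_table) && nrow(ko_table))
    parts[[length(parts) + 1L]] <- data.frame(
      locus_tag = ko_table$locus_tag, type = "KO", id = ko_table$ko,
      provenance = "ko-table")
  add_ec <- function(tab, prov) {
    if (is.null(tab) || !nrow(tab)) return()
    bad <- !grepl(EC_PATTERN, tab$ec)
    if (any(bad)) {
      warning("skipping ", sum(bad), " malformed EC number(s): ",
              paste(utils::head(unique(tab$ec[bad]), 3), collapse = ", "))
      tab <- tab[!bad, , drop = FALSE]
    }
    if (!nrow(tab)) return()
    parts[[length(parts) + 1L]] <<- data.frame(
      locus_tag = tab$locus_tag, type = "EC", id = tab$ec, provenance = prov)
  }
  add_ec(ec_table, "ec-table")
  add_ec(name_match_ec, "name-match")
  if (!length(parts))
    return(structure(data.frame(locus_tag = character(), type = character(),
                                id = character(), provenance = character()),
                     class = c("function_map", "data.frame")))
  out <- unique(do.call(rbind, parts))
  out <- out[order(out$locus_tag, out$type, out$id, out$provenance), ]
  rownames(out) <- NULL
  structure(out, class = c("function_map", "data.frame"))
}

#' Pathway-step definitions
#'
#' Reads a pathway definition table: one row per step with the pathway id,
#' step order, a display label (gene symbol) and the comma-separated KO/EC
#' identifiers accepted for that step. The packaged default
#' (`extdata/pathway_steps.tsv`) covers anaerobic benzene activation
#' (carboxylation, hydroxylation), benzoyl-CoA dearomatisation, modified
#' beta-oxidation, the lower pathway, aerobic oxygenase routes and the
#' nitrogen cycle. It is a curated, editable scaffold — users profiling a
#' different system should supply their own table.
#'
#' @param path TSV with columns pathway, step_index, step_label,
#'   identifiers; defaults to the packaged table
#' @return data.frame with those columns plus `id_list` (split identifiers)
#' @export
read_pathway_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pathway_steps.tsv", package = "mtxpipe",
                        mustWork = TRUE)
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "step_index", "step_label", "identifiers")
                %in% names(p)),
            all(nzchar(p$identifiers)))
  p$id_list <- strsplit(p$identifiers, ",")
  p
}

#' Map annotated loci onto pathway steps
#'
#' A locus contributes to a step when its function identifiers (KO or EC)
#' intersect the step's accepted identifiers. A locus may legitimately
#' contribute to several steps — e.g. subunits of one enzyme class sharing
#' an EC — and is then flagged ambiguous, mirroring the question-mark
#' convention for overlapping assignments in pathway diagrams. If a coverage
#' table is supplied, each contributing locus carries its read count and
#' depth and steps are totalled.
#'
#' @param functions a `function_map` from [merge_annotations()]
#' @param pathways a table from [read_pathway_definitions()]
#' @param coverage optional coverage table from [count_reads()]
#' @return list: `loci` (one row per pathway step x contributing locus, with
#'   `ambiguous` flag) and `steps` (per-step locus counts and expression
#'   totals; steps with no loci have zero totals)
#' @export
map_to_pathways <- function(functions, pathways, coverage = NULL) {
  fm <- functions
  rows <- lapply(seq_len(nrow(pathways)), function(i) {
    loci <- unique(fm$locus_tag[fm$id %in% pathways$id_list[[i]]])
    if (!length(loci)) return(NULL)
    data.frame(pathway = pathways$pathway[i],
               step_index = pathways$step_index[i],
               step_label = pathways$step_label[i],
               locus_tag = loci)
  })
  loci <- do.call(rbind, rows)
  if (is.null(loci))
    loci <- data.frame(pathway = character(), step_index = integer(),
                       step_label = character(), locus_tag = character())
  n_steps <- if (nrow(loci))
    stats::ave(seq_len(nrow(loci)), loci$locus_tag, FUN = length)
  else integer()
  loci$ambiguous <- n_steps > 1L
  loci$count <- rep(NA_integer_, nrow(loci))
  loci$depth <- rep(NA_real_, nrow(loci))
  if (!is.null(coverage) && nrow(loci)) {
    i <- match(loci$locus_tag, coverage$locus_tag)
    loci$count <- coverage$count[i]
    loci$depth <- coverage$depth[i]
  }
  steps <- pathways[c("pathway", "step_index", "step_label")]
  key <- paste(steps$pathway, steps$step_index)
  lkey <- paste(loci$pathway, loci$step_index)
  steps$n_loci <- as.integer(table(factor(lkey, levels = key)))
  sum_by <- function(v) {
    s <- tapply(v, factor(lkey, levels = key), sum)
    ifelse(is.na(s), 0, as.numeric(s))
  }
  if (nrow(loci)) {
    steps$total_count <- sum_by(loci$count)
    steps$total_depth <- sum_by(loci$depth)
  } else {
    steps$total_count <- 0; steps$total_depth <- 0
  }
  list(loci = loci, steps = steps)
}
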