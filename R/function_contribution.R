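#' Relative contribution of each locus to its function
#'
#' For every function, the contribution of a locus is its expression as a
#' percentage of the function's total expression: with two equally expressed
#' loci on one function, each contributes 50%. Contributions within a
#' function always sum to 100 and are invariant under rescaling all of a
#' function's expression values by a positive constant. Functions whose
#' total expression is zero are omitted with a message. The expression value
#' is typically length-normalised depth (reads per base, removing
#' gene-length bias between loci of one function) but raw counts work
#' identically; a locus assigned to several functions contributes its full
#' expression to each.
#'
#' @param expr data.frame with columns fun_id, locus_tag and expression
#'   (non-negative)
#' @return `contribution_table` data.frame: fun_id, locus_tag, expression,
#'   contribution (percent, full precision)
#' @examples
#' contribution(data.frame(fun_id = "f", locus_tag = c("a", "b"),
#'                         expression = c(10, 10)))
#' @export
contribution <- function(expr) {
  stopifnot(all(c("fun_id", "locus_tag", "expression") %in% names(expr)))
  if (any(expr$expression < 0)) stop("expression values must be non-negative")
  totals <- tapply(expr$expression, expr$fun_id, sum)
  dead <- names(totals)[totals == 0]
  if (length(dead)) {
    message("contribution: omitting ", length(dead),
            " function(s) with zero total expression")
    expr <- expr[!expr$fun_id %in% dead, , drop = FALSE]
  }
  out <- expr[c("fun_id", "locus_tag", "expression")]
  out$contribution <- 100 * out$expression /
    as.numeric(totals[out$fun_id])
  out <- out[order(out$fun_id, -out$contribution, out$locus_tag), ]
  rownames(out) <- NULL
  structure(out, class = c("contribution_table", "data.frame"))
}

#' Pathway-step relative abundance with log display scaling
#'
#' Expresses each step's expression total as a percentage of all counted
#' mRNA reads and attaches the log10 display value used for bar plots on a
#' log axis. Steps at or below `floor` (zero by default) are marked excluded
#' and get no display value — zeros cannot be drawn on a log scale.
#'
#' @param step_counts named numeric vector (or the `steps` data.frame from
#'   [map_to_pathways()], whose `total_count` is used) of per-step totals
#' @param grand_total total counted reads; must be positive and at least
#'   every step total
#' @param floor abundances at or below this percentage are excluded from
#'   display (default 0: only exact zeros drop out)
#' @return data.frame: step, abundance (percent), display (log10 of
#'   abundance; NA when excluded), included
#' @export
step_abundance <- function(step_counts, grand_total, floor = 0) {
  if (is.data.frame(step_counts))
    step_counts <- stats::setNames(
      step_counts$total_count,
      paste(step_counts$pathway, step_counts$step_label, sep = ":"))
  if (grand_total <= 0) stop("grand_total must be positive")
  if (any(step_counts > grand_total))
    stop("step counts cannot exceed the grand total")
  abundance <- 100 * step_counts / grand_total
  included <- abundance > floor
  data.frame(step = names(step_counts),
             abundance = as.numeric(abundance),
             display = ifelse(included, log10(abundance), NA_real_),
             included = included,
             row.names = NULL)
}
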