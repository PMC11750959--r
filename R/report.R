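#' Aggregate a run's results into one cross-checked report
#'
#' Collects the per-context DMC and DMR tallies, the annotated-DMR
#' category breakdown, the DEG filter tally and the promoter-DMR/DEG
#' quadrant summary into one object, recomputing every total from its
#' parts. Inconsistent inputs (e.g. a DMR context absent from the DMC
#' table, or quadrant counts that do not add up to the number of linked
#' pairs) raise an error rather than producing a report that disagrees
#' with itself.
#'
#' @param dmcs optional `dmc_result` from [call_dmcs()].
#' @param dmrs optional `dmr_result` from [call_dmrs()].
#' @param annotated_dmrs optional annotated DMR table from
#'   [assign_dmr_features()].
#' @param degs optional filtered DEG table from [filter_degs()].
#' @param quadrants optional result of [classify_quadrants()].
#' @return object of class `aggregate_report`: a list of tally tables
#'   plus recomputed totals.
#' @export
aggregate_report <- function(dmcs = NULL, dmrs = NULL, annotated_dmrs = NULL,
                             degs = NULL, quadrants = NULL) {
  rep <- list()
  contexts <- c("CG", "CHG", "CHH")
  if (!is.null(dmcs)) {
    k <- dmcs[dmcs$retained, , drop = FALSE]
    by_ctx <- vapply(contexts, function(cx) sum(k$context == cx), integer(1L))
    rep$dmc <- list(by_context = by_ctx, total = sum(by_ctx),
                    n_testable = sum(dmcs$testable))
    if (rep$dmc$total != nrow(k))
      stop("DMC context labels outside CG/CHG/CHH: totals do not reconcile")
  }
  if (!is.null(dmrs)) {
    if (!all(dmrs$context %in% contexts))
      stop("DMR table contains contexts other than CG/CHG/CHH")
    if (!is.null(dmcs) && !all(dmrs$context %in% dmcs$context))
      stop("DMR context absent from the DMC table: inputs are from ",
           "different runs")
    by_ctx <- vapply(contexts, function(cx) sum(dmrs$context == cx), integer(1L))
    dir_tab <- table(factor(dmrs$direction, c("hyper", "hypo", "weak")))
    rep$dmr <- list(by_context = by_ctx, total = sum(by_ctx),
                    by_direction = as.vector(dir_tab),
                    direction_levels = names(dir_tab))
    if (sum(dir_tab) != nrow(dmrs))
      stop("DMR direction labels do not cover every region")
  }
  if (!is.null(annotated_dmrs)) {
    cat_tab <- table(annotated_dmrs$category)
    rep$annotation <- list(by_category = as.vector(cat_tab),
                           categories = names(cat_tab),
                           total = sum(cat_tab))
    if (!is.null(dmrs) && rep$annotation$total != nrow(dmrs))
      stop("annotated DMR count (", rep$annotation$total,
           ") differs from the DMR table (", nrow(dmrs), ")")
  }
  if (!is.null(degs)) {
    k <- degs[degs$is_deg, , drop = FALSE]
    rep$deg <- list(n_deg = nrow(k),
                    n_up = sum(k$deg_direction == "up"),
                    n_down = sum(k$deg_direction == "down"),
                    n_tested = nrow(degs))
    tally <- attr(degs, "tally")
    if (!is.null(tally) && tally[["total"]] != rep$deg$n_deg)
      stop("DEG tally attribute disagrees with the filtered rows")
    if (rep$deg$n_up + rep$deg$n_down != rep$deg$n_deg)
      stop("DEG table contains zero log2 fold changes after filtering")
  }
  if (!is.null(quadrants)) {
    s <- quadrants$summary
    if (sum(s$quadrant_counts) != s$classified)
      stop("quadrant counts do not add up to the number of classified pairs")
    rep$quadrants <- s
  }
  class(rep) <- "aggregate_report"
  rep
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("Aggregate report\n")
  if (!is.null(x$dmc)) {
    cat("  DMCs:", x$dmc$total,
        sprintf("(%s)", paste(names(x$dmc$by_context), x$dmc$by_context,
                              sep = "=", collapse = ", ")),
        "of", x$dmc$n_testable, "testable loci\n")
  }
  if (!is.null(x$dmr)) {
    cat("  DMRs:", x$dmr$total,
        sprintf("(%s)", paste(names(x$dmr$by_context), x$dmr$by_context,
                              sep = "=", collapse = ", ")), "\n")
    cat("  DMR direction:",
        paste(x$dmr$direction_levels, x$dmr$by_direction,
              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$annotation))
    cat("  DMR categories:",
        paste(x$annotation$categories, x$annotation$by_category,
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$deg))
    cat("  DEGs:", x$deg$n_deg, "(up", x$deg$n_up, ", down",
        x$deg$n_down, ")\n")
  if (!is.null(x$quadrants)) {
    cat("  Promoter-DMR x DEG pairs:", x$quadrants$classified, "\n")
    cat("   ", paste(names(x$quadrants$quadrant_counts),
                     x$quadrants$quadrant_counts,
                     sep = "=", collapse = ", "), "\n")
    cat("    negative correlation:", x$quadrants$n_negative,
        ", positive:", x$quadrants$n_positive, "\n")
  }
  invisible(x)
}
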