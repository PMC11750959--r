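#' Construct a per-cytosine count table
#'
#' Holds, for every cytosine locus, the methylated and total read counts of
#' each sample, together with the sequence context (CG, CHG, CHH or
#' unknown) and a sample-to-group mapping (e.g. G- vs G+).
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `context`.
#' @param meth,total integer matrices (loci x samples) of methylated and
#'   total counts; column names are sample names.
#' @param samples data.frame with columns `sample`, `group`.
#' @return object of class `cytosine_count_table`.
#' @export
cytosine_count_table <- function(loci, meth, total, samples) {
  loci <- as.data.frame(loci)
  samples <- as.data.frame(samples)
  meth <- as.matrix(meth); total <- as.matrix(total)
  stopifnot(nrow(meth) == nrow(loci), nrow(total) == nrow(loci),
            ncol(meth) == nrow(samples), ncol(total) == nrow(samples))
  if (!all(loci$context %in% c("CG", "CHG", "CHH", "unknown")))
    stop("unknown context token: ",
         paste(unique(setdiff(loci$context, c("CG", "CHG", "CHH", "unknown"))),
               collapse = ", "))
  if (!all(loci$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(meth > total))
    stop("methylated count exceeds total count at locus row(s): ",
         paste(utils::head(which(rowSums(meth > total) > 0), 5L), collapse = ", "))
  if (any(meth < 0) || any(total < 0)) stop("negative counts")
  colnames(meth) <- colnames(total) <- samples$sample
  ord <- order(loci$chrom, loci$pos, loci$strand)
  structure(list(loci = loci[ord, , drop = FALSE],
                 meth = meth[ord, , drop = FALSE],
                 total = total[ord, , drop = FALSE],
                 samples = samples),
            class = "cytosine_count_table")
}

#' @export
print.cytosine_count_table <- function(x, ...) {
  cat("Cytosine count table:", nrow(x$loci), "loci x", nrow(x$samples),
      "samples\n")
  cat("  contexts:", paste(names(table(x$loci$context)),
                           table(x$loci$context), collapse = ", "), "\n")
  cat("  groups:", paste(names(table(x$samples$group)),
                         table(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

normalize_context <- function(ctx) {
  ctx <- toupper(ctx)
  ctx[ctx == "CPG"] <- "CG"
  ctx[!ctx %in% c("CG", "CHG", "CHH")] <- "unknown"
  ctx
}

#' Load Bismark-style cytosine reports into one count table
#'
#' Each input file is a TSV with columns chrom, position (1-based), strand,
#' count methylated, count unmethylated, context, trinucleotide (no
#' header). Files are merged on (chrom, pos, strand); loci missing from a
#' sample get total count 0 for that sample.
#'
#' @param paths character vector of file paths, named by sample.
#' @param groups named character vector mapping sample name to group.
#' @return a [cytosine_count_table()].
#' @export
load_cytosine_report <- function(paths, groups) {
  if (is.null(names(paths))) stop("paths must be named by sample")
  if (!all(names(paths) %in% names(groups)))
    stop("every sample needs a group in `groups`")
  per_sample <- lapply(names(paths), function(s) {
    df <- utils::read.table(paths[[s]], sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "pos", "strand",
                                          "meth", "unmeth", "context",
                                          "trinucleotide")[1:7],
                            fill = TRUE)
    if (any(df$meth < 0 | df$unmeth < 0))
      stop("negative count in sample ", s)
    raw_ctx <- toupper(df$context)
    bad <- !raw_ctx %in% c("CG", "CPG", "CHG", "CHH", "UNKNOWN", "CN", "")
    if (any(bad))
      stop("unknown context token '", df$context[which(bad)[1L]],
           "' in sample ", s)
    df$context <- normalize_context(df$context)
    key <- paste(df$chrom, df$pos, df$strand)
    if (anyDuplicated(key))
      stop("duplicated (chrom, pos, strand) in sample ", s)
    pos_strand <- paste(df$chrom, df$pos)
    df$key <- key; df$pos_key <- pos_strand
    df
  })
  names(per_sample) <- names(paths)
  # strand consistency: a (chrom, pos) must not flip strand between samples
  all_pos <- unique(do.call(rbind, lapply(per_sample, function(d)
    d[, c("pos_key", "strand")])))
  if (anyDuplicated(all_pos$pos_key))
    stop("inconsistent strand at locus ",
         all_pos$pos_key[duplicated(all_pos$pos_key)][1L],
         " across samples")
  keys <- unique(unlist(lapply(per_sample, `[[`, "key")))
  first <- do.call(rbind, lapply(per_sample, function(d)
    d[, c("key", "chrom", "pos", "strand", "context")]))
  ctx_by_key <- tapply(first$context, first$key, function(v) unique(v))
  multi <- vapply(ctx_by_key, length, integer(1L)) > 1L
  if (any(multi))
    stop("inconsistent context at locus ", names(ctx_by_key)[multi][1L])
  first <- first[!duplicated(first$key), ]
  rownames(first) <- first$key
  loci <- first[keys, c("chrom", "pos", "strand", "context")]
  meth <- matrix(0L, length(keys), length(paths),
                 dimnames = list(keys, names(paths)))
  total <- meth
  for (s in names(paths)) {
    d <- per_sample[[s]]
    meth[d$key, s] <- d$meth
    total[d$key, s] <- d$meth + d$unmeth
  }
  rownames(loci) <- NULL
  cytosine_count_table(loci, meth, total,
                       data.frame(sample = names(paths),
                                  group = unname(groups[names(paths)]),
                                  stringsAsFactors = FALSE))
}

#' Per-sample methylation summary from aggregate counts
#'
#' The bisulfite-report arithmetic: the overall percentage of methylated
#' cytosines is 100 times the number of methylated calls (all contexts,
#' including unknown) over the total number of cytosines analysed, and the
#' apparent conversion rate is its complement to 100.
#'
#' @param counts data.frame with columns `sample`, `total_analyzed`,
#'   `meth_cg`, `meth_chg`, `meth_chh`, `meth_unknown`.
#' @return the input with `percent_mC_overall` and `conversion_rate`
#'   columns added (both in percent; they sum to 100 exactly).
#' @export
methylation_count_report <- function(counts) {
  need <- c("sample", "total_analyzed", "meth_cg", "meth_chg", "meth_chh",
            "meth_unknown")
  if (!all(need %in% names(counts)))
    stop("missing column(s): ", paste(setdiff(need, names(counts)), collapse = ", "))
  if (any(counts$total_analyzed <= 0))
    stop("zero total coverage for sample(s): ",
         paste(counts$sample[counts$total_analyzed <= 0], collapse = ", "))
  meth_all <- counts$meth_cg + counts$meth_chg + counts$meth_chh +
    counts$meth_unknown
  counts$percent_mC_overall <- 100 * meth_all / counts$total_analyzed
  counts$conversion_rate <- 100 - counts$percent_mC_overall
  counts
}

#' Global methylation levels per sample
#'
#' For each sample: the overall percent of methylated cytosine calls
#' across all contexts (including unknown), the apparent conversion rate
#' (its complement), and count-weighted percent methylation within the CG,
#' CHG and CHH contexts.
#'
#' @param table a [cytosine_count_table()].
#' @return data.frame with one row per sample: `sample`, `group`,
#'   `percent_mC_overall`, `conversion_rate`, `percent_cg`, `percent_chg`,
#'   `percent_chh`.
#' @export
global_methylation_levels <- function(table) {
  stopifnot(inherits(table, "cytosine_count_table"))
  if (nrow(table$loci) == 0L) stop("empty count table")
  ctx <- table$loci$context
  agg <- data.frame(sample = table$samples$sample,
                    total_analyzed = colSums(table$total),
                    meth_cg = colSums(table$meth[ctx == "CG", , drop = FALSE]),
                    meth_chg = colSums(table$meth[ctx == "CHG", , drop = FALSE]),
                    meth_chh = colSums(table$meth[ctx == "CHH", , drop = FALSE]),
                    meth_unknown = colSums(table$meth[ctx == "unknown", , drop = FALSE]),
                    stringsAsFactors = FALSE)
  rep <- methylation_count_report(agg)
  pct_ctx <- function(context) {
    sel <- ctx == context
    tot <- colSums(table$total[sel, , drop = FALSE])
    ifelse(tot > 0, 100 * colSums(table$meth[sel, , drop = FALSE]) / tot, NA_real_)
  }
  data.frame(sample = table$samples$sample, group = table$samples$group,
             percent_mC_overall = rep$percent_mC_overall,
             conversion_rate = rep$conversion_rate,
             percent_cg = pct_ctx("CG"), percent_chg = pct_ctx("CHG"),
             percent_chh = pct_ctx("CHH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample names belonging to a group
#' @param table a [cytosine_count_table()].
#' @param group group label.
#' @return character vector of sample names; errors when the group is
#'   empty.
#' @export
group_samples <- function(table, group) {
  s <- table$samples$sample[table$samples$group == group]
  if (length(s) == 0L) stop("empty group '", group, "'")
  s
}

#' Moving-average smoothing of methylation levels
#'
#' Per locus, the smoothed level is the pooled proportion (sum of
#' methylated over sum of total counts) over the group's samples and all
#' loci of the same context within a window of `window_bp` centred on the
#' locus. Smoothing never pools across contexts (or chromosomes). Loci
#' with zero pooled coverage in the window are flagged untestable.
#'
#' @param table a [cytosine_count_table()].
#' @param group group label to pool.
#' @param window_bp window width in bp (default 500, a standard smoothing
#'   span for WGBS data).
#' @return data.frame: loci columns plus `level` (in `[0, 1]` or NA) and
#'   `testable`.
#' @export
smooth_methylation <- function(table, group, window_bp = 500) {
  stopifnot(window_bp > 0)
  samples <- group_samples(table, group)
  m <- rowSums(table$meth[, samples, drop = FALSE])
  t <- rowSums(table$total[, samples, drop = FALSE])
  sm <- windowed_sums(table$loci, cbind(m, t), window_bp)
  level <- ifelse(sm[, 2L] > 0, sm[, 1L] / sm[, 2L], NA_real_)
  out <- table$loci
  out$level <- level
  out$testable <- sm[, 2L] > 0
  rownames(out) <- NULL
  out
}

# windowed sums of one or more per-locus count columns, within
# (chrom, context), window centred on each position; loci assumed sorted
windowed_sums <- function(loci, values, window_bp) {
  values <- as.matrix(values)
  out <- matrix(NA_real_, nrow(values), ncol(values))
  half <- window_bp / 2
  grp <- paste(loci$chrom, loci$context, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- loci$pos[idx]
    o <- order(pos)
    pos_s <- pos[o]
    cs <- apply(values[idx[o], , drop = FALSE], 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(values))
    cs <- rbind(0, cs)
    lo <- findInterval(pos_s - half, pos_s, left.open = TRUE)   # first index - 1
    hi <- findInterval(pos_s + half, pos_s)
    out[idx[o], ] <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  out
}

#' Beta-binomial dispersion estimates per locus
#'
#' Method-of-moments estimate of the beta-binomial dispersion (intra-class
#' correlation) from the replicate counts of one group, shrunk towards the
#' context-wide median dispersion with a weight proportional to the locus
#' coverage against a prior pseudo-coverage. With a single replicate the
#' dispersion cannot be estimated; the prior value is returned for every
#' locus with a warning.
#'
#' @param table a [cytosine_count_table()].
#' @param group group label.
#' @param context optional context filter; default all loci.
#' @param prior_coverage pseudo-coverage weighting the shrinkage target
#'   (default 100 reads).
#' @param prior fallback dispersion when nothing is estimable (default
#'   0.05, a typical WGBS replicate overdispersion).
#' @return data.frame: loci columns plus `dispersion_raw`, `dispersion`
#'   (shrunken, in `[0, 1)`), `coverage`, `flagged` (TRUE when the prior
#'   was substituted, e.g. zero coverage).
#' @export
estimate_dispersion <- function(table, group, context = NULL,
                                prior_coverage = 100, prior = 0.05) {
  samples <- group_samples(table, group)
  keep <- if (is.null(context)) rep(TRUE, nrow(table$loci)) else
    table$loci$context %in% context
  loci <- table$loci[keep, , drop = FALSE]
  X <- table$meth[keep, samples, drop = FALSE]
  N <- table$total[keep, samples, drop = FALSE]
  k_cov <- rowSums(N > 0)
  W <- rowSums(N)
  if (length(samples) < 2L) {
    warning("single replicate in group '", group,
            "': falling back to the prior dispersion")
    out <- loci
    out$dispersion_raw <- NA_real_
    out$dispersion <- prior
    out$coverage <- W
    out$flagged <- TRUE
    rownames(out) <- NULL
    return(out)
  }
  P <- ifelse(N > 0, X / N, NA_real_)
  phat <- ifelse(W > 0, rowSums(X) / W, NA_real_)
  S <- rowSums(N * (P - phat)^2, na.rm = TRUE)
  sumsq <- rowSums(N^2)
  denom_var <- phat * (1 - phat)
  # E[S] = p(1-p) * [(k - 1) + rho * (W - k - (sum n^2 - W)/W)]
  coefr <- W - k_cov - (sumsq - W) / W
  rho <- (S / pmax(denom_var, 1e-8) - (k_cov - 1)) / pmax(coefr, 1e-8)
  rho[!is.finite(rho) | denom_var < 1e-8 | k_cov < 2L | coefr <= 0] <- NA_real_
  rho <- pmin(pmax(rho, 0), 0.99)
  raw <- rho
  out_list <- split(seq_len(nrow(loci)), loci$context)
  disp <- rep(NA_real_, nrow(loci))
  for (idx in out_list) {
    med <- stats::median(raw[idx], na.rm = TRUE)
    if (!is.finite(med)) med <- prior
    r <- ifelse(is.na(raw[idx]), med, raw[idx])
    disp[idx] <- (W[idx] * r + prior_coverage * med) / (W[idx] + prior_coverage)
  }
  disp <- pmin(pmax(disp, 0), 0.99)
  out <- loci
  out$dispersion_raw <- raw
  out$dispersion <- disp
  out$coverage <- W
  out$flagged <- W == 0 | is.na(raw)
  rownames(out) <- NULL
  out
}
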