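#' Metagene methylation profile
#'
#' Pools per-cytosine counts into a fixed-width binned profile over a
#' feature class: `flank_bins` upstream bins covering `flank_bp` before
#' the feature, `body_bins` bins over the feature body rescaled to unit
#' length, and `flank_bins` downstream bins. Minus-strand features are
#' mirrored so bin 1 is always the 5' end. The bin value is the pooled
#' proportion (sum of methylated over sum of total counts across all
#' features) per context and group. Flank bins that fall outside the
#' chromosome (before position 1, or past the declared chromosome length)
#' are reported as missing (NA), not zero.
#'
#' @param table a [cytosine_count_table()].
#' @param features data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`, and optionally `class` (default
#'   `"gene"`).
#' @param flank_bp flank width in bp (default 2000).
#' @param body_bins,flank_bins number of bins for the body and each flank.
#' @param groups group labels to profile (default: all groups present).
#' @return data.frame: `class`, `context`, `group`, `bin` (1-based across
#'   upstream, body, downstream), `zone`, `level`, `n_meth`, `n_total`.
#' @export
metagene_profile <- function(table, features, flank_bp = 2000,
                             body_bins = 20, flank_bins = 10,
                             groups = unique(table$samples$group)) {
  stopifnot(flank_bp > 0, body_bins > 0, flank_bins > 0)
  features <- as.data.frame(features)
  if (nrow(features) == 0L) stop("empty feature set")
  if (!"class" %in% names(features)) features$class <- "gene"
  if (!all(features$strand %in% c("+", "-")))
    stop("features need strand '+' or '-'")
  chrom_len <- attr(table, "chrom_lengths")
  nbins <- 2L * flank_bins + body_bins
  bw <- flank_bp / flank_bins

  loci <- table$loci
  pos_by_chrom <- split(seq_len(nrow(loci)), loci$chrom)
  gm <- lapply(groups, function(g)
    rowSums(table$meth[, group_samples(table, g), drop = FALSE]))
  gt <- lapply(groups, function(g)
    rowSums(table$total[, group_samples(table, g), drop = FALSE]))
  names(gm) <- names(gt) <- groups

  contexts <- c("CG", "CHG", "CHH")
  sum_m <- array(0, dim = c(length(unique(features$class)), length(contexts),
                            length(groups), nbins),
                 dimnames = list(unique(features$class), contexts, groups, NULL))
  sum_t <- sum_m
  covered <- array(FALSE, dim = dim(sum_m)[c(1L, 4L)],
                   dimnames = list(unique(features$class), NULL))

  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    ii <- pos_by_chrom[[f$chrom]]
    if (is.null(ii)) next
    lo <- f$start - flank_bp; hi <- f$end + flank_bp
    sel <- ii[loci$pos[ii] >= lo & loci$pos[ii] <= hi &
                loci$context[ii] %in% contexts]
    # genomic extent of each bin, to mark truncated flank bins as present
    # only where the genome exists
    chrom_max <- if (!is.null(chrom_len) && f$chrom %in% names(chrom_len))
      chrom_len[[f$chrom]] else Inf
    bin_lo <- c(f$start - (flank_bins:1) * bw,
                f$start + (seq_len(body_bins) - 1L) * (f$end - f$start + 1) / body_bins,
                f$end + (seq_len(flank_bins) - 1L) * bw + 1)
    bin_hi <- c(bin_lo[1:flank_bins] + bw - 1,
                f$start + seq_len(body_bins) * (f$end - f$start + 1) / body_bins - 1e-9,
                bin_lo[flank_bins + body_bins + seq_len(flank_bins)] + bw - 1)
    exists_bin <- bin_hi >= 1 & bin_lo <= chrom_max
    if (f$strand == "-") exists_bin <- rev(exists_bin)
    covered[f$class, ] <- covered[f$class, ] | exists_bin

    if (length(sel) > 0L) {
      p <- loci$pos[sel]
      bin <- integer(length(p))
      up <- p < f$start
      dn <- p > f$end
      body <- !up & !dn
      bin[up] <- flank_bins - floor((f$start - p[up] - 1) / bw)
      rel <- (p[body] - f$start) / (f$end - f$start + 1)
      bin[body] <- flank_bins + pmin(body_bins, floor(rel * body_bins) + 1L)
      bin[dn] <- flank_bins + body_bins +
        pmin(flank_bins, floor((p[dn] - f$end - 1) / bw) + 1L)
      if (f$strand == "-") bin <- nbins + 1L - bin
      ctx <- loci$context[sel]
      for (g in groups) {
        mm <- gm[[g]][sel]; tt <- gt[[g]][sel]
        for (cx in unique(ctx)) {
          cs <- ctx == cx
          sm <- tapply(mm[cs], bin[cs], sum)
          st <- tapply(tt[cs], bin[cs], sum)
          b <- as.integer(names(sm))
          sum_m[f$class, cx, g, b] <- sum_m[f$class, cx, g, b] + sm
          sum_t[f$class, cx, g, b] <- sum_t[f$class, cx, g, b] + st
        }
      }
    }
  }

  grid <- expand.grid(class = dimnames(sum_m)[[1L]], context = contexts,
                      group = groups, bin = seq_len(nbins),
                      stringsAsFactors = FALSE)
  grid$zone <- ifelse(grid$bin <= flank_bins, "upstream",
                      ifelse(grid$bin <= flank_bins + body_bins, "body",
                             "downstream"))
  grid$n_meth <- mapply(function(cl, cx, g, b) sum_m[cl, cx, g, b],
                        grid$class, grid$context, grid$group, grid$bin)
  grid$n_total <- mapply(function(cl, cx, g, b) sum_t[cl, cx, g, b],
                         grid$class, grid$context, grid$group, grid$bin)
  has_bin <- mapply(function(cl, b) covered[cl, b], grid$class, grid$bin)
  grid$level <- ifelse(has_bin & grid$n_total > 0,
                       grid$n_meth / grid$n_total, NA_real_)
  grid
}
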