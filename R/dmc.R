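#' Default DMC retention thresholds
#'
#' Minimum absolute methylation difference per context (0.1 for CG and
#' CHG, 0.07 for CHH) and the posterior-probability threshold (0.9999).
#' @return named list with `diff` and `p_post`.
#' @export
dmc_thresholds <- function() {
  list(diff = c(CG = 0.1, CHG = 0.1, CHH = 0.07), p_post = 0.9999)
}

#' Call differentially methylated cytosines (smoothed Wald test)
#'
#' For every testable locus (coverage in at least one replicate of each
#' group) the two group methylation means are estimated by moving-average
#' smoothing ([smooth_methylation()]), the beta-binomial sampling variance
#' of each group mean is computed from the per-sample sequencing depths
#' and the shrunken dispersion ([estimate_dispersion()]), and a Wald
#' statistic `diff / se` is formed for the difference
#' `diff = mean(group1) - mean(group2)` (group1 is the treatment, e.g.
#' glucose-poor G-, so positive differences are hyper-methylation in the
#' treatment). The posterior probability that the group means differ is
#' the two-sided normal approximation `1 - 2 * pnorm(-abs(stat))`. A locus
#' is retained as a DMC when `abs(diff)` exceeds the context threshold
#' (0.1 for CG/CHG, 0.07 for CHH) and the posterior probability exceeds
#' 0.9999.
#'
#' @param table a [cytosine_count_table()].
#' @param group1,group2 group labels; the difference is group1 - group2.
#' @param thresholds list as returned by [dmc_thresholds()].
#' @param window_bp smoothing window (default 500 bp).
#' @param prior_coverage,prior passed to [estimate_dispersion()].
#' @return data.frame of class `dmc_result`: loci columns plus `mu1`,
#'   `mu2`, `diff`, `se`, `stat`, `p_post`, `testable`, `retained`, and
#'   the per-locus group dispersions `disp1`/`disp2`. The group labels
#'   and the posterior-probability threshold are recorded as attributes
#'   `groups` and `p_post_threshold` for [call_dmrs()]'s region
#'   confirmation.
#' @export
call_dmcs <- function(table, group1 = "G-", group2 = "G+",
                      thresholds = dmc_thresholds(), window_bp = 500,
                      prior_coverage = 100, prior = 0.05) {
  if (any(thresholds$diff <= 0 | thresholds$diff >= 1) ||
      thresholds$p_post <= 0 || thresholds$p_post >= 1)
    stop("thresholds must lie strictly inside (0, 1)")
  s1 <- group_samples(table, group1)
  s2 <- group_samples(table, group2)
  sm1 <- smooth_methylation(table, group1, window_bp)
  sm2 <- smooth_methylation(table, group2, window_bp)
  d1 <- estimate_dispersion(table, group1, prior_coverage = prior_coverage,
                            prior = prior)
  d2 <- estimate_dispersion(table, group2, prior_coverage = prior_coverage,
                            prior = prior)

  group_var <- function(mu, disp, N) {
    # variance of the smoothed group proportion: the estimator pools
    # counts over every (sample, locus) observation in the window, so
    # the beta-binomial variance sums n_j (1 + (n_j - 1) * rho) over the
    # same observations; n(1+(n-1)rho) = n(1-rho) + rho n^2 lets both
    # pieces be computed from windowed sums of N and N^2
    p <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
    wsum <- windowed_sums(table$loci, cbind(rowSums(N), rowSums(N^2)),
                          window_bp)
    W <- wsum[, 1L]
    num <- (1 - disp) * wsum[, 1L] + disp * wsum[, 2L]
    ifelse(W > 0, p * (1 - p) * num / W^2, NA_real_)
  }
  N1 <- table$total[, s1, drop = FALSE]
  N2 <- table$total[, s2, drop = FALSE]
  testable <- rowSums(N1 > 0) >= 1L & rowSums(N2 > 0) >= 1L &
    sm1$testable & sm2$testable
  v <- group_var(sm1$level, d1$dispersion, N1) +
    group_var(sm2$level, d2$dispersion, N2)
  se <- sqrt(pmax(v, 1e-16))
  diff <- sm1$level - sm2$level
  stat <- diff / se
  p_post <- 1 - 2 * stats::pnorm(-abs(stat))
  thr <- thresholds$diff[table$loci$context]
  retained <- testable & !is.na(diff) &
    abs(diff) > ifelse(is.na(thr), Inf, thr) &
    p_post > thresholds$p_post
  out <- table$loci
  out$mu1 <- sm1$level; out$mu2 <- sm2$level
  out$diff <- diff; out$se <- se; out$stat <- stat; out$p_post <- p_post
  out$testable <- testable
  out$retained <- retained & !is.na(retained)
  out$disp1 <- d1$dispersion; out$disp2 <- d2$dispersion
  rownames(out) <- NULL
  if (!any(out$testable)) warning("no testable loci")
  class(out) <- c("dmc_result", "data.frame")
  attr(out, "groups") <- c(group1, group2)
  attr(out, "p_post_threshold") <- thresholds$p_post
  out
}

#' Default DMR segmentation parameters
#'
#' Standard region-calling defaults: minimum length 50 bp, at least 3
#' sites, at least 50 percent of the sites in the region individually
#' significant, adjacent same-sign regions merged when closer than 100 bp.
#' @return named list.
#' @export
dmr_parameters <- function() {
  list(min_len = 50, min_sites = 3, merge_gap = 100, pct_sig = 0.5)
}

#' Call differentially methylated regions from per-locus statistics
#'
#' Works per chromosome and context on the full per-locus result (not only
#' retained DMCs). Significant loci of the same sign are clustered when
#' consecutive significant sites are at most `merge_gap` apart; a cluster
#' becomes a candidate region spanning its first to last significant site.
#' Candidates are kept when the span is at least `min_len` bp, contains at
#' least `min_sites` same-context sites, and at least `pct_sig` of those
#' sites are individually significant. Because smoothing makes the
#' per-site tests of neighbouring loci strongly correlated, each
#' candidate is additionally confirmed with a Wald test on its own raw
#' pooled counts (no smoothing), at the caller's posterior-probability
#' threshold Bonferroni-corrected over all scanned testable loci,
#' whenever `table` and the metadata recorded by [call_dmcs()] are
#' available; unconfirmed candidates are dropped. Surviving
#' same-sign regions closer than `merge_gap` are merged. The region difference is the
#' coverage-weighted mean of the per-site differences, and the score is
#' the sum of the site Wald statistics (an areaStat-like quantity).
#'
#' @param dmcs a `dmc_result` from [call_dmcs()].
#' @param params list as from [dmr_parameters()].
#' @param table optional [cytosine_count_table()] supplying per-site
#'   coverage weights; equal weights are used when absent.
#' @param direction_cutoffs passed to [label_dmr_direction()].
#' @return data.frame of class `dmr_result`: `chrom`, `start`, `end`
#'   (1-based inclusive), `context`, `n_sites`, `n_sig`, `mean_diff`,
#'   `area_stat`, `direction`.
#' @export
call_dmrs <- function(dmcs, params = dmr_parameters(), table = NULL,
                      direction_cutoffs = dmr_direction_cutoffs()) {
  if (params$min_len <= 0 || params$min_sites <= 0 ||
      params$pct_sig <= 0 || params$pct_sig > 1 || params$merge_gap < 0)
    stop("contradictory DMR parameters")
  w <- if (!is.null(table)) rowSums(table$total) else rep(1, nrow(dmcs))
  # region-level confirmation: the smoothed per-site test is spatially
  # correlated (every site in a window shares one estimate), so a single
  # window fluctuation can masquerade as a multi-site region. When the
  # count table and the caller's metadata are available, each candidate
  # is re-tested on its own raw pooled counts (no smoothing, hence no
  # borrowed evidence) against the same posterior-probability threshold.
  grp_attr <- attr(dmcs, "groups")
  pthr <- attr(dmcs, "p_post_threshold")
  confirm <- NULL
  if (!is.null(table) && !is.null(grp_attr) && !is.null(pthr) &&
      !is.null(dmcs$disp1)) {
    cs1 <- group_samples(table, grp_attr[1L])
    cs2 <- group_samples(table, grp_attr[2L])
    confirm <- function(ii_all) {
      side <- function(samps, disp) {
        N <- table$total[ii_all, samps, drop = FALSE]
        W <- sum(N)
        if (W == 0) return(NULL)
        p_raw <- sum(table$meth[ii_all, samps]) / W
        p <- min(max(p_raw, 1e-3), 1 - 1e-3)
        rho <- stats::weighted.mean(disp, rowSums(N) + 1e-9)
        v <- p * (1 - p) * ((1 - rho) * W + rho * sum(N^2)) / W^2
        list(p = p_raw, v = v)
      }
      a <- side(cs1, dmcs$disp1[ii_all])
      b <- side(cs2, dmcs$disp2[ii_all])
      if (is.null(a) || is.null(b)) return(FALSE)
      z <- (a$p - b$p) / sqrt(a$v + b$v)
      # candidates are maxima of a genome-wide scan, so the confirmation
      # is Bonferroni-corrected over all scanned (testable) loci
      2 * stats::pnorm(-abs(z)) < (1 - pthr) / max(1, sum(dmcs$testable))
    }
  }
  empty <- data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), context = character(0L),
                      n_sites = integer(0L), n_sig = integer(0L),
                      mean_diff = numeric(0L), area_stat = numeric(0L),
                      stringsAsFactors = FALSE)
  out <- list()
  grp <- paste(dmcs$chrom, dmcs$context, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    o <- order(dmcs$pos[idx]); idx <- idx[o]
    pos <- dmcs$pos[idx]
    sig <- dmcs$retained[idx]
    sgn <- sign(dmcs$diff[idx])
    si <- which(sig)
    if (length(si) == 0L) next
    # cluster consecutive significant sites: same sign, gap <= merge_gap
    brk <- c(TRUE, diff(pos[si]) > params$merge_gap |
               sgn[si][-1L] != sgn[si][-length(si)])
    cl <- cumsum(brk)
    regions <- lapply(split(si, cl), function(ii) {
      lo <- min(ii); hi <- max(ii)
      span <- which(pos >= pos[lo] & pos <= pos[hi])
      n_sites <- length(span)
      n_sig <- sum(sig[span])
      len <- pos[hi] - pos[lo] + 1L
      if (len < params$min_len || n_sites < params$min_sites ||
          n_sig / n_sites < params$pct_sig) return(NULL)
      ii_all <- idx[span]
      if (!is.null(confirm) && !confirm(ii_all)) return(NULL)
      data.frame(chrom = dmcs$chrom[ii_all[1L]], start = pos[lo], end = pos[hi],
                 context = dmcs$context[ii_all[1L]],
                 n_sites = n_sites, n_sig = n_sig,
                 mean_diff = sum(w[ii_all] * dmcs$diff[ii_all]) /
                   sum(w[ii_all]),
                 area_stat = sum(dmcs$stat[ii_all], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    regions <- do.call(rbind, regions)
    if (is.null(regions) || nrow(regions) == 0L) next
    # merge adjacent surviving regions: same sign, gap <= merge_gap
    regions <- regions[order(regions$start), , drop = FALSE]
    merged <- regions[1L, , drop = FALSE]
    if (nrow(regions) > 1L) {
      for (i in 2L:nrow(regions)) {
        last <- nrow(merged)
        gap <- regions$start[i] - merged$end[last] - 1L
        if (gap <= params$merge_gap &&
            sign(regions$mean_diff[i]) == sign(merged$mean_diff[last])) {
          span <- which(pos >= merged$start[last] & pos <= regions$end[i])
          ii_all <- idx[span]
          merged$end[last] <- regions$end[i]
          merged$n_sites[last] <- length(span)
          merged$n_sig[last] <- sum(sig[span])
          merged$mean_diff[last] <- sum(w[ii_all] * dmcs$diff[ii_all]) /
            sum(w[ii_all])
          merged$area_stat[last] <- sum(dmcs$stat[ii_all], na.rm = TRUE)
        } else merged <- rbind(merged, regions[i, ])
      }
    }
    out[[g]] <- merged
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else empty
  res <- label_dmr_direction(res, direction_cutoffs)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dmr_result", "data.frame")
  res
}

#' Default hyper/hypo direction cutoffs per context
#'
#' Minimum absolute region methylation change to label a DMR hyper- or
#' hypo-methylated: 25 percent in CG and CHG, 10 percent in CHH.
#' @return named numeric vector.
#' @export
dmr_direction_cutoffs <- function() c(CG = 0.25, CHG = 0.25, CHH = 0.10)

#' Label DMR direction (hyper / hypo / weak)
#'
#' A region is `hyper` when its mean difference (treatment minus control)
#' is at least the context cutoff, `hypo` when at most minus the cutoff,
#' and `weak` otherwise. Weak regions are kept but excluded from
#' hyper/hypo tallies.
#'
#' @param dmrs data.frame with `mean_diff` and `context`.
#' @param cutoffs named numeric vector per context (see
#'   [dmr_direction_cutoffs()]).
#' @return `dmrs` with a `direction` column.
#' @export
label_dmr_direction <- function(dmrs, cutoffs = dmr_direction_cutoffs()) {
  cut <- cutoffs[dmrs$context]
  dmrs$direction <- ifelse(dmrs$mean_diff >= cut, "hyper",
                           ifelse(dmrs$mean_diff <= -cut, "hypo", "weak"))
  dmrs
}

#' Export DMRs as BED6+ records
#'
#' Coordinates convert from 1-based inclusive to BED's 0-based half-open;
#' the score is `abs(mean_diff) * 1000` truncated to integer, strand is
#' `.`, and extra columns carry context, site count, mean difference and
#' direction.
#'
#' @param dmrs a `dmr_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("DMR_%s_%d_%s", dmrs$chrom, dmrs$start,
                                   dmrs$context),
                    score = trunc(abs(dmrs$mean_diff) * 1000),
                    strand = ".", context = dmrs$context,
                    n_sites = dmrs$n_sites, mean_diff = dmrs$mean_diff,
                    direction = dmrs$direction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
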