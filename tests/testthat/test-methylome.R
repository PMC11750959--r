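test_that("cytosine count table validates loci and counts", {
  loci <- data.frame(chrom = "chr1", pos = c(10, 20), strand = "+",
                     context = c("CG", "CHH"))
  samples <- data.frame(sample = c("a", "b"), group = c("G-", "G+"))
  meth <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  total <- matrix(5, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_s3_class(cytosine_count_table(loci, meth, total, samples),
                  "cytosine_count_table")
  bad <- meth; bad[1, 1] <- 9   # meth > total
  expect_error(cytosine_count_table(loci, bad, total, samples), "exceed")
  bad_loci <- loci; bad_loci$context[1] <- "XXX"
  expect_error(cytosine_count_table(bad_loci, meth, total, samples), "context")
  bad_loci <- loci; bad_loci$strand[1] <- "x"
  expect_error(cytosine_count_table(bad_loci, meth, total, samples), "strand")
})

write_report <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

test_that("cytosine report loader merges files and fills missing loci", {
  d1 <- data.frame(chrom = "chr1", pos = c(5, 10), strand = "+",
                   meth = c(3, 0), unmeth = c(1, 4),
                   context = c("CG", "CHH"), tri = c("CGA", "CTA"))
  d2 <- data.frame(chrom = "chr1", pos = c(10, 15), strand = c("+", "-"),
                   meth = c(2, 1), unmeth = c(2, 0),
                   context = c("CHH", "CG"), tri = c("CTA", "CGT"))
  p1 <- write_report(withr::local_tempfile(), d1)
  p2 <- write_report(withr::local_tempfile(), d2)
  tab <- load_cytosine_report(c(s1 = p1, s2 = p2),
                              groups = c(s1 = "G-", s2 = "G+"))
  expect_equal(nrow(tab$loci), 3L)
  i5 <- which(tab$loci$pos == 5)
  expect_equal(unname(tab$total[i5, "s2"]), 0L)  # missing locus -> 0
  expect_equal(unname(tab$meth[i5, "s1"]), 3L)
})

test_that("cytosine report loader rejects malformed inputs", {
  base <- data.frame(chrom = "chr1", pos = 5, strand = "+", meth = 1,
                     unmeth = 1, context = "CG", tri = "CGA")
  neg <- base; neg$meth <- -1
  p <- write_report(withr::local_tempfile(), neg)
  expect_error(load_cytosine_report(c(s = p), c(s = "G-")), "negative")
  badctx <- base; badctx$context <- "CGX"
  p <- write_report(withr::local_tempfile(), badctx)
  expect_error(load_cytosine_report(c(s = p), c(s = "G-")), "context")
  dup <- rbind(base, base)
  p <- write_report(withr::local_tempfile(), dup)
  expect_error(load_cytosine_report(c(s = p), c(s = "G-")), "duplicat")
  flip <- base; flip$strand <- "-"
  p1 <- write_report(withr::local_tempfile(), base)
  p2 <- write_report(withr::local_tempfile(), flip)
  expect_error(load_cytosine_report(c(a = p1, b = p2),
                                    c(a = "G-", b = "G+")), "strand")
})

test_that("aggregation identity: pooled report equals per-file pooling", {
  tb4 <- utils::read.csv(system.file("extdata", "bisulfite_report_grapevine.csv",
                                     package = "fluxmeth"))
  per_file <- methylation_count_report(tb4)
  merged <- data.frame(sample = "all",
                       total_analyzed = sum(tb4$total_analyzed),
                       meth_cg = sum(tb4$meth_cg),
                       meth_chg = sum(tb4$meth_chg),
                       meth_chh = sum(tb4$meth_chh),
                       meth_unknown = sum(tb4$meth_unknown))
  pooled <- methylation_count_report(merged)
  by_hand <- 100 * sum(tb4$meth_cg + tb4$meth_chg + tb4$meth_chh +
                         tb4$meth_unknown) / sum(tb4$total_analyzed)
  expect_identical(pooled$percent_mC_overall, by_hand)
  expect_identical(per_file$percent_mC_overall + per_file$conversion_rate,
                   rep(100, nrow(tb4)))
})

test_that("global methylation levels recover designed proportions", {
  tab <- make_flat_table(n = 60, coverage = 50, level = 0.4)
  g <- global_methylation_levels(tab)
  expect_equal(g$percent_cg, rep(40, 4))
  expect_equal(g$percent_mC_overall + g$conversion_rate, rep(100, 4))
  expect_error(global_methylation_levels(structure(
    list(loci = tab$loci[0, ], meth = tab$meth[0, , drop = FALSE],
         total = tab$total[0, , drop = FALSE], samples = tab$samples),
    class = "cytosine_count_table")), "empty")
})

test_that("smoothing pools counts within the window, never across contexts", {
  loci <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 320, 1000),
                     strand = "+", context = c("CG", "CG", "CG", "CHH", "CG"))
  samples <- data.frame(sample = "a", group = "G-")
  meth <- matrix(c(0, 10, 10, 0, 5), ncol = 1, dimnames = list(NULL, "a"))
  total <- matrix(c(10, 10, 10, 10, 10), ncol = 1, dimnames = list(NULL, "a"))
  tab <- cytosine_count_table(loci, meth, total, samples)
  sm <- smooth_methylation(tab, "G-", window_bp = 500)
  # CG locus at 200: window [ -50, 450] pools CG loci 100, 200, 300 only
  i <- which(sm$pos == 200)
  expect_equal(sm$level[i], 20 / 30)
  # isolated CG locus at 1000 pools only itself
  expect_equal(sm$level[sm$pos == 1000], 0.5)
  # CHH locus pools only itself even though CG neighbours are closer
  expect_equal(sm$level[sm$context == "CHH"], 0)
})

test_that("smoothed levels are convex combinations of window proportions", {
  sim <- simulate_methylome(seed = 3, n_loci = 5000)
  sm <- smooth_methylation(sim$table, "G-")
  raw <- rowSums(sim$table$meth[, group_samples(sim$table, "G-")]) /
    pmax(rowSums(sim$table$total[, group_samples(sim$table, "G-")]), 1)
  grp <- paste(sim$table$loci$chrom, sim$table$loci$context)
  for (g in unique(grp)[1:3]) {
    idx <- which(grp == g)
    pos <- sim$table$loci$pos[idx]
    for (i in idx[seq(1, length(idx), by = 97)]) {
      win <- idx[abs(pos - sim$table$loci$pos[i]) <= 250]
      expect_gte(sm$level[i], min(raw[win]) - 1e-12)
      expect_lte(sm$level[i], max(raw[win]) + 1e-12)
    }
  }
})

test_that("dispersion estimator recovers the generating order of magnitude", {
  set.seed(12)
  n <- 2000; cov <- 30; reps <- 3; rho <- 0.1
  loci <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000, strand = "+",
                     context = "CG")
  samples <- data.frame(sample = paste0("s", 1:reps), group = "G-")
  shape <- 1 / rho - 1
  total <- matrix(rpois(n * reps, cov), n, reps,
                  dimnames = list(NULL, samples$sample))
  p <- matrix(rbeta(n * reps, 0.5 * shape, 0.5 * shape), n, reps)
  meth <- matrix(rbinom(n * reps, total, p), n, reps,
                 dimnames = list(NULL, samples$sample))
  tab <- cytosine_count_table(loci, meth, total, samples)
  d <- estimate_dispersion(tab, "G-")
  expect_gte(median(d$dispersion), 0.05)
  expect_lte(median(d$dispersion), 0.2)
  expect_true(all(d$dispersion >= 0 & d$dispersion < 1))
})

test_that("single-replicate dispersion falls back to the prior with a warning", {
  tab <- make_flat_table(n = 10, reps = 1)
  expect_warning(d <- estimate_dispersion(tab, "G-"), "single replicate")
  expect_true(all(d$dispersion == 0.05))
  expect_true(all(d$flagged))
})
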