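test_that("identical count tables produce zero DMCs", {
  tab <- make_flat_table(n = 100, coverage = 30, level = 0.5, reps = 3)
  dmcs <- call_dmcs(tab)
  expect_equal(sum(dmcs$retained), 0L)
  expect_true(all(abs(dmcs$diff) < 1e-12))
})

test_that("a planted strong locus block is retained as hyper DMC", {
  set.seed(21)
  n <- 60
  loci <- data.frame(chrom = "chr1", pos = seq_len(n) * 50, strand = "+",
                     context = "CG")
  samples <- data.frame(sample = paste0("s", 1:6),
                        group = rep(c("G-", "G+"), each = 3))
  total <- matrix(50L, n, 6, dimnames = list(NULL, samples$sample))
  meth <- matrix(0L, n, 6, dimnames = list(NULL, samples$sample))
  block <- 25:35
  for (s in 1:3) meth[, s] <- rbinom(n, 50, ifelse(seq_len(n) %in% block, 0.6, 0.1))
  for (s in 4:6) meth[, s] <- rbinom(n, 50, 0.1)
  tab <- cytosine_count_table(loci, meth, total, samples)
  dmcs <- call_dmcs(tab)
  mid <- which(seq_len(n) %in% 28:32)
  expect_true(all(dmcs$retained[mid]))
  expect_true(all(dmcs$diff[mid] > 0.3))
})

test_that("negating the group labels negates diffs and swaps directions", {
  sim <- simulate_methylome(seed = 13, n_loci = 20000,
                            planted = data.frame(class = "intergenic",
                                                 context = c("CG", "CG"),
                                                 diff = c(0.5, -0.5),
                                                 width = 400L))
  fwd <- call_dmcs(sim$table, group1 = "G-", group2 = "G+")
  rev <- call_dmcs(sim$table, group1 = "G+", group2 = "G-")
  expect_equal(rev$diff, -fwd$diff)
  expect_equal(rev$retained, fwd$retained)
  dfwd <- call_dmrs(fwd, table = sim$table)
  drev <- call_dmrs(rev, table = sim$table)
  expect_equal(drev$mean_diff, -dfwd$mean_diff)
  expect_equal(drev$direction,
               c(hyper = "hypo", hypo = "hyper", weak = "weak")[dfwd$direction],
               ignore_attr = TRUE)
})

test_that("CHH uses the lower retention threshold", {
  thr <- dmc_thresholds()
  expect_equal(thr$diff[["CHH"]], 0.07)
  expect_equal(thr$diff[["CG"]], 0.1)
  expect_equal(thr$p_post, 0.9999)
  expect_error(call_dmcs(make_flat_table(n = 10),
                         thresholds = list(diff = c(CG = 0, CHG = 0.1, CHH = 0.1),
                                           p_post = 0.9999)),
               "threshold")
})

test_that("a planted block yields one DMR spanning it", {
  set.seed(5)
  n <- 60
  loci <- data.frame(chrom = "chr1", pos = seq_len(n) * 25, strand = "+",
                     context = "CG")
  samples <- data.frame(sample = paste0("s", 1:6),
                        group = rep(c("G-", "G+"), each = 3))
  total <- matrix(60L, n, 6, dimnames = list(NULL, samples$sample))
  meth <- matrix(0L, n, 6, dimnames = list(NULL, samples$sample))
  block <- 21:40   # 500 bp, 20 sites
  for (s in 1:3) meth[, s] <- rbinom(n, 60, ifelse(seq_len(n) %in% block, 0.5, 0.1))
  for (s in 4:6) meth[, s] <- rbinom(n, 60, 0.1)
  tab <- cytosine_count_table(loci, meth, total, samples)
  # a narrow smoothing window keeps the block edges crisp (the default
  # 500 bp window bleeds the signal ~250 bp into the null flanks)
  dmrs <- call_dmrs(call_dmcs(tab, window_bp = 50), table = tab)
  expect_equal(nrow(dmrs), 1L)
  expect_lte(abs(dmrs$start - 21 * 25), 50)
  expect_lte(abs(dmrs$end - 40 * 25), 50)
  expect_identical(dmrs$direction, "hyper")
  expect_gte(dmrs$n_sig / dmrs$n_sites, 0.5)
})

test_that("merge gap controls whether nearby clusters fuse", {
  # two significant clusters 120 bp apart: gap 150 merges, gap 80 does not
  mk_dmcs <- function() {
    pos <- c(seq(100, 180, by = 20), seq(300, 380, by = 20))
    data.frame(chrom = "chr1", pos = pos, strand = "+", context = "CG",
               mu1 = 0.6, mu2 = 0.1, diff = 0.5, se = 0.05, stat = 10,
               p_post = 1, testable = TRUE, retained = TRUE)
  }
  p80 <- dmr_parameters(); p80$merge_gap <- 80
  p150 <- dmr_parameters(); p150$merge_gap <- 150
  d80 <- call_dmrs(structure(mk_dmcs(), class = c("dmc_result", "data.frame")),
                   params = p80)
  d150 <- call_dmrs(structure(mk_dmcs(), class = c("dmc_result", "data.frame")),
                    params = p150)
  expect_equal(nrow(d80), 2L)
  expect_equal(nrow(d150), 1L)
  expect_equal(d150$start, 100)
  expect_equal(d150$end, 380)
})

test_that("DMR filters enforce length, site count and significance fraction", {
  base <- data.frame(chrom = "chr1", strand = "+", context = "CG",
                     mu1 = 0.6, mu2 = 0.1, diff = 0.5, se = 0.05,
                     stat = 10, p_post = 1, testable = TRUE, retained = TRUE)
  # two sites only -> below min_sites
  two <- cbind(base[rep(1, 2), ], pos = c(100, 160))
  expect_equal(nrow(call_dmrs(structure(two, class = c("dmc_result", "data.frame")))), 0L)
  # three sites spanning only 40 bp -> below min_len
  short <- cbind(base[rep(1, 3), ], pos = c(100, 120, 140))
  expect_equal(nrow(call_dmrs(structure(short, class = c("dmc_result", "data.frame")))), 0L)
  # significant fraction below 50%: 3 sig + 4 non-sig in the span
  mix <- cbind(base[rep(1, 7), ], pos = c(100, 130, 145, 160, 175, 190, 200))
  mix$retained <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  mix$diff[!mix$retained] <- 0.01
  expect_equal(nrow(call_dmrs(structure(mix, class = c("dmc_result", "data.frame")))), 0L)
  expect_error(call_dmrs(structure(mix, class = c("dmc_result", "data.frame")),
                         params = list(min_len = -1, min_sites = 3,
                                       merge_gap = 100, pct_sig = 0.5)),
               "contradictory")
})

test_that("direction labels use per-context cutoffs and keep weak regions", {
  dmrs <- data.frame(chrom = "chr1", start = c(1, 1, 1), end = c(100, 100, 100),
                     context = c("CG", "CHH", "CG"),
                     n_sites = 5, n_sig = 5,
                     mean_diff = c(0.2, 0.2, -0.3), area_stat = 1)
  lab <- label_dmr_direction(dmrs)
  expect_identical(lab$direction, c("weak", "hyper", "hypo"))
})

test_that("DMR BED export is 0-based half-open", {
  dmrs <- structure(data.frame(chrom = "chr1", start = 101, end = 200,
                               context = "CG", n_sites = 5, n_sig = 5,
                               mean_diff = 0.4, area_stat = 20,
                               direction = "hyper"),
                    class = c("dmr_result", "data.frame"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
  expect_equal(bed$V5, 400)   # trunc(0.4 * 1000)
})

test_that("type-I control: fully null simulations call no DMRs in >= 9 of 10 seeds", {
  zero <- vapply(1:10, function(s) {
    sim <- simulate_methylome(seed = 100 + s, n_loci = 200000, coverage = 30)
    dmcs <- call_dmcs(sim$table)
    expect_lte(mean(dmcs$retained), 1e-3)
    nrow(call_dmrs(dmcs, table = sim$table)) == 0L
  }, logical(1))
  expect_gte(sum(zero), 9L)
})
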