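simple_features <- function() {
  genes <- data.frame(gene_id = c("g1", "g2"),
                      chrom = "chr1",
                      start = c(10001, 30001), end = c(15000, 36000),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("g1", "g1", "g2"),
                      chrom = "chr1",
                      start = c(10001, 14001, 30001),
                      end = c(11000, 15000, 36000))
  tes <- data.frame(chrom = "chr1",
                    start = c(12000, 9000, 50000),
                    end = c(12500, 9400, 51000))
  feature_set(genes, exons, tes, chrom_lengths = c(chr1 = 60000))
}

test_that("introns are the gene body minus exons", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 1001,
                      end = 5000, strand = "+")
  exons <- data.frame(gene_id = "g", chrom = "chr1",
                      start = c(1001, 4001), end = c(2000, 5000))
  fs <- feature_set(genes, exons)
  expect_equal(length(fs$introns), 1L)
  expect_equal(GenomicRanges::start(fs$introns), 2001)
  expect_equal(GenomicRanges::end(fs$introns), 4000)
  # exon outside its gene bounds is rejected
  bad <- exons; bad$end[2] <- 6000
  expect_error(feature_set(genes, bad), "outside")
})

test_that("promoters are 2 kb upstream of the TSS, strand-aware and clipped", {
  genes <- data.frame(gene_id = c("p", "m", "edge"),
                      chrom = "chr1",
                      start = c(5001, 5001, 1201), end = c(6000, 6000, 2000),
                      strand = c("+", "-", "+"))
  pr <- derive_promoters(genes, chrom_lengths = c(chr1 = 6500))
  df <- as.data.frame(pr)
  p <- df[df$gene_id == "p", ]
  expect_equal(c(p$start, p$end), c(3001, 5000))
  m <- df[df$gene_id == "m", ]
  expect_equal(c(m$start, m$end), c(6001, 6500))  # clipped at chrom end
  e <- df[df$gene_id == "edge", ]
  expect_equal(c(e$start, e$end), c(1, 1200))     # clipped at chrom start
})

test_that("DMR category assignment follows the precedence with TE relabels", {
  fs <- simple_features()
  dmrs <- data.frame(
    chrom = "chr1",
    start = c(9300, 10500, 12200, 31000, 50100, 45000, 8200, 14990),
    end = c(9600, 10600, 12300, 31100, 50200, 45100, 8300, 15010))
  got <- assign_dmr_features(dmrs, fs)
  expect_identical(got$category,
                   c("TE-promoter",  # in g1 promoter and on a TE
                     "exon",         # inside g1 first exon
                     "TE-intron",    # in g1 intron overlapping a TE
                     "exon",         # single-exon gene g2
                     "TE",           # extragenic TE
                     "intergenic",
                     "promoter",     # g1 promoter, off the TE
                     "exon"))        # straddles exon end: larger overlap wins
  expect_identical(got$gene_id[1], "g1")
  expect_true(is.na(got$gene_id[5]))
  expect_error(assign_dmr_features(data.frame(chrom = "chrX", start = 1,
                                              end = 10), fs), "unknown")
})

test_that("every DMR gets exactly one category (partition property)", {
  sim <- simulate_methylome(seed = 17, n_loci = 5000)
  set.seed(1)
  dmrs <- data.frame(chrom = sample(names(c(chr1 = 1, chr2 = 1, chr3 = 1)),
                                    200, replace = TRUE),
                     start = sample.int(690000, 200))
  dmrs$end <- dmrs$start + sample(50:2000, 200, replace = TRUE)
  got <- assign_dmr_features(dmrs, sim$features)
  expect_true(all(got$category %in% c("promoter", "TE-promoter", "exon",
                                      "intron", "TE-intron", "TE",
                                      "intergenic")))
  expect_equal(nrow(got), 200L)
  genic <- got$category %in% c("promoter", "TE-promoter", "exon", "intron",
                               "TE-intron")
  expect_true(all(!is.na(got$gene_id[genic])))
})

test_that("GFF3 + BED round-trip through load_annotation", {
  sim <- simulate_methylome(seed = 23, n_loci = 2000,
                            out_dir = withr::local_tempdir())
  fs <- load_annotation(sim$files[["annotation"]], sim$files[["te"]],
                        chrom_lengths = c(chr1 = 7e5, chr2 = 7e5, chr3 = 7e5))
  expect_equal(length(fs$genes), nrow(sim$genes))
  expect_equal(length(fs$exons), nrow(sim$exons))
  expect_equal(length(fs$tes), nrow(sim$tes))
  expect_equal(sort(as.character(S4Vectors::mcols(fs$genes)$gene_id)),
               sort(sim$genes$gene_id))
  # BED is 0-based: starts must come back as the 1-based originals
  expect_setequal(GenomicRanges::start(fs$tes), sim$tes$start)
})

test_that("DEG filter applies all three thresholds jointly", {
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    log2FC = c(2, 2, 2, 0.5, -3, 2),
                    padj = c(0.01, 0.2, 0.01, 0.01, 0.04, 0.01),
                    cpm = c(50, 50, 5, 50, 50, 50))
  got <- filter_degs(tab)
  expect_identical(got$is_deg, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(got$deg_direction[got$is_deg], c("up", "down", "up"))
  expect_equal(attr(got, "tally")[["total"]], 3L)
  expect_error(filter_degs(tab[, -2]), "log2FC")
})

test_that("DMR-DEG linking separates genic DMEGs from promoter promDMEGs", {
  annotated <- data.frame(
    chrom = "chr1", start = c(1, 2, 3, 4, 5, 6), end = c(10, 11, 12, 13, 14, 15),
    context = "CG", mean_diff = c(0.3, -0.3, 0.3, 0.3, 0.3, 0.3),
    category = c("promoter", "promoter", "TE-promoter", "exon", "intron",
                 "intergenic"),
    gene_id = c("g1", "g2", "g3", "g1", "g4", NA))
  degs <- filter_degs(data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                                 log2FC = c(-2, 3, -2, 2),
                                 padj = 0.01, cpm = 100))
  links <- link_dmr_degs(annotated, degs)
  expect_equal(nrow(links$promdmegs), 3L)   # promoter + promoter + TE-promoter
  expect_equal(nrow(links$dmegs), 2L)       # exon + intron
  expect_setequal(links$promdmegs$gene_id, c("g1", "g2", "g3"))
  expect_equal(links$promdmegs$diff_exp[links$promdmegs$gene_id == "g1"], -2)
})

test_that("planted promoter DMRs over DEGs produce exactly the linked count", {
  annotated <- data.frame(
    chrom = "chr1", start = 1:5, end = 11:15, context = "CG",
    mean_diff = 0.3, category = "promoter",
    gene_id = paste0("g", 1:5))
  degs <- filter_degs(data.frame(gene_id = paste0("g", 1:5),
                                 log2FC = c(2, 2, 2, 0, 0),
                                 padj = c(0.01, 0.01, 0.01, 0.9, 0.9),
                                 cpm = 100))
  links <- link_dmr_degs(annotated, degs)
  expect_equal(nrow(links$promdmegs), 3L)
})

test_that("quadrant classification counts correlations and flags zero diffs", {
  df <- data.frame(diff_meth = c(0.3, 0.3, -0.2, -0.2, 0),
                   diff_exp = c(1, -1, 1, -1, 2),
                   context = c("CG", "CHH", "CHG", "CHH", "CG"))
  expect_warning(q <- classify_quadrants(df), "unclassifiable")
  expect_equal(q$summary$classified, 4L)
  expect_equal(unname(q$summary$quadrant_counts[c("Me+/Exp+", "Me+/Exp-",
                                                  "Me-/Exp+", "Me-/Exp-")]),
               rep(1L, 4))
  expect_equal(q$summary$n_negative, 2L)
  expect_equal(q$summary$n_hyper, 2L)
  expect_equal(q$summary$hyper_by_context[["CHH"]], 1L)
})
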