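#' Build a genomic feature set
#'
#' Validates genes, exons and transposable elements, derives introns (gene
#' body minus exons) and promoters (2 kb upstream of the TSS, clipped to
#' the chromosome). All coordinates are 1-based inclusive.
#'
#' @param genes data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons data.frame: `gene_id`, `chrom`, `start`, `end` (may be
#'   NULL, in which case each gene is one exon).
#' @param tes data.frame: `chrom`, `start`, `end`, optional `family`
#'   (may be NULL or empty).
#' @param chrom_lengths optional named vector clipping promoters at
#'   chromosome ends.
#' @param promoter_length promoter length in bp (default 2000).
#' @return object of class `feature_set` with GRanges elements `genes`,
#'   `exons`, `introns`, `tes`, `promoters`.
#' @export
feature_set <- function(genes, exons = NULL, tes = NULL,
                        chrom_lengths = NULL, promoter_length = 2000) {
  genes <- as.data.frame(genes)
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand token in genes: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  exons <- as.data.frame(exons)
  gidx <- match(exons$gene_id, genes$gene_id)
  if (anyNA(gidx)) stop("exon references unknown gene")
  bad <- exons$start < genes$start[gidx] | exons$end > genes$end[gidx]
  if (any(bad))
    stop("exon outside its gene bounds: gene ",
         paste(unique(exons$gene_id[bad]), collapse = ", "))

  gr <- function(df, extra = NULL) {
    g <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = if ("strand" %in% names(df))
                                  df$strand else "*")
    for (col in extra) S4Vectors::mcols(g)[[col]] <- df[[col]]
    g
  }
  genes_gr <- gr(genes, "gene_id")
  exons_gr <- gr(exons, "gene_id")
  # introns: per gene, body minus exons
  intron_list <- lapply(seq_along(genes_gr), function(i) {
    ex <- exons_gr[S4Vectors::mcols(exons_gr)$gene_id ==
                     S4Vectors::mcols(genes_gr)$gene_id[i]]
    intr <- GenomicRanges::setdiff(genes_gr[i], ex, ignore.strand = TRUE)
    S4Vectors::mcols(intr)$gene_id <-
      rep(S4Vectors::mcols(genes_gr)$gene_id[i], length(intr))
    intr
  })
  empty_gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty_gr)$gene_id <- character(0L)
  introns_gr <- do.call(c, c(intron_list, list(empty_gr)))
  tes_gr <- if (is.null(tes) || nrow(as.data.frame(tes)) == 0L)
    GenomicRanges::GRanges() else gr(as.data.frame(tes))
  promoters_gr <- derive_promoters(genes, length = promoter_length,
                                   chrom_lengths = chrom_lengths)
  structure(list(genes = genes_gr, exons = exons_gr, introns = introns_gr,
                 tes = tes_gr, promoters = promoters_gr,
                 chrom_lengths = chrom_lengths),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set:", length(x$genes), "genes,", length(x$exons), "exons,",
      length(x$introns), "introns,", length(x$tes), "TEs,",
      length(x$promoters), "promoters\n")
  invisible(x)
}

#' Load genes/exons from GFF3 and TEs from BED
#'
#' Thin wrapper over rtracklayer import feeding [feature_set()]. Gene
#' records are features of type `gene`; exon records of type `exon` are
#' attached to their gene through the `Parent` (or `gene_id`) attribute.
#'
#' @param gff3 path to a GFF3 file with gene and exon features.
#' @param te_bed optional path to a BED file of transposable elements (an
#'   empty or missing file yields a set in which no TE category can be
#'   assigned).
#' @param chrom_lengths,promoter_length passed to [feature_set()].
#' @return a `feature_set`.
#' @export
load_annotation <- function(gff3, te_bed = NULL, chrom_lengths = NULL,
                            promoter_length = 2000) {
  anno <- rtracklayer::import(gff3, format = "gff3")
  g <- anno[anno$type == "gene"]
  if (length(g) == 0L) stop("no gene features in ", gff3)
  gene_id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$gene_id)
  genes <- data.frame(gene_id = gene_id,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)))
  e <- anno[anno$type == "exon"]
  exons <- if (length(e) > 0L) {
    parent <- if (!is.null(e$Parent) && all(lengths(e$Parent) > 0L))
      vapply(e$Parent, `[[`, character(1L), 1L) else as.character(e$gene_id)
    data.frame(gene_id = sub("^(gene:|mRNA:)", "", parent),
               chrom = as.character(GenomicRanges::seqnames(e)),
               start = GenomicRanges::start(e),
               end = GenomicRanges::end(e))
  } else NULL
  tes <- NULL
  if (!is.null(te_bed) && file.exists(te_bed) &&
      length(readLines(te_bed, n = 1L)) > 0L) {
    t_gr <- rtracklayer::import(te_bed, format = "bed")
    tes <- data.frame(chrom = as.character(GenomicRanges::seqnames(t_gr)),
                      start = GenomicRanges::start(t_gr),
                      end = GenomicRanges::end(t_gr))
  }
  feature_set(genes, exons, tes, chrom_lengths = chrom_lengths,
              promoter_length = promoter_length)
}

#' Derive promoter intervals (2 kb upstream of the TSS)
#'
#' For a plus-strand gene the promoter is the `length` bp ending just
#' before the gene start; for a minus-strand gene, the `length` bp
#' starting just after the gene end. Promoters are clipped at position 1
#' and at the chromosome length when known, so they are at most `length`
#' bp long.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param length promoter length in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return GRanges with a `gene_id` metadata column (genes whose promoter
#'   is fully clipped away are dropped).
#' @export
derive_promoters <- function(genes, length = 2000, chrom_lengths = NULL) {
  genes <- as.data.frame(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - length, genes$end + 1)
  end <- ifelse(plus, genes$start - 1, genes$end + length)
  start <- pmax(start, 1)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  keep <- end >= start
  out <- GenomicRanges::GRanges(genes$chrom[keep],
                                IRanges::IRanges(start[keep], end[keep]),
                                strand = genes$strand[keep])
  S4Vectors::mcols(out)$gene_id <- genes$gene_id[keep]
  out
}

#' Assign each DMR to a genomic feature category
#'
#' Categories form a partition: every DMR receives exactly one of
#' `promoter`, `TE-promoter`, `exon`, `intron`, `TE-intron`, `TE`
#' (extragenic transposable element) or `intergenic`. Precedence is
#' promoter > exon > intron > extragenic TE > intergenic, decided at the
#' highest tier with any overlap (at least 1 bp); ties within a tier go to
#' the feature with the larger overlap, then the leftmost. A
#' promoter-category DMR that also overlaps a TE is relabelled
#' `TE-promoter`, and an intron-category DMR overlapping a TE becomes
#' `TE-intron`.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); typically a `dmr_result`.
#' @param features a [feature_set()].
#' @return `dmrs` with `category` and `gene_id` columns added.
#' @export
assign_dmr_features <- function(dmrs, features) {
  dmrs <- as.data.frame(dmrs)
  known <- unique(c(as.character(GenomicRanges::seqnames(features$genes)),
                    as.character(GenomicRanges::seqnames(features$tes))))
  if (length(known) > 0L && !all(dmrs$chrom %in% known)) {
    # unknown chromosomes are an error only when the annotation is
    # non-empty for every other chromosome mentioned; tolerate none
    bad <- setdiff(unique(dmrs$chrom), known)
    stop("DMR on unknown chromosome: ", paste(bad, collapse = ", "))
  }
  q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  pick <- function(subject) {
    if (length(subject) == 0L)
      return(data.frame(hit = rep(NA_integer_, length(q)),
                        width = rep(0, length(q))))
    hits <- GenomicRanges::findOverlaps(q, subject, ignore.strand = TRUE)
    ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                    subject[S4Vectors::subjectHits(hits)],
                                    ignore.strand = TRUE)
    w <- GenomicRanges::width(ov)
    out <- data.frame(hit = rep(NA_integer_, length(q)),
                      width = rep(0, length(q)))
    if (length(hits) > 0L) {
      df <- data.frame(qh = S4Vectors::queryHits(hits),
                       sh = S4Vectors::subjectHits(hits), w = w,
                       s_start = GenomicRanges::start(subject)[S4Vectors::subjectHits(hits)])
      df <- df[order(df$qh, -df$w, df$s_start, df$sh), ]
      df <- df[!duplicated(df$qh), ]
      out$hit[df$qh] <- df$sh
      out$width[df$qh] <- df$w
    }
    out
  }
  prom <- pick(features$promoters)
  exon <- pick(features$exons)
  intr <- pick(features$introns)
  te <- pick(features$tes)

  n <- length(q)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  has_te <- te$width > 0
  for (i in seq_len(n)) {
    if (prom$width[i] > 0) {
      category[i] <- if (has_te[i]) "TE-promoter" else "promoter"
      gene_id[i] <- S4Vectors::mcols(features$promoters)$gene_id[prom$hit[i]]
    } else if (exon$width[i] > 0) {
      category[i] <- "exon"
      gene_id[i] <- S4Vectors::mcols(features$exons)$gene_id[exon$hit[i]]
    } else if (intr$width[i] > 0) {
      category[i] <- if (has_te[i]) "TE-intron" else "intron"
      gene_id[i] <- S4Vectors::mcols(features$introns)$gene_id[intr$hit[i]]
    } else if (has_te[i]) {
      category[i] <- "TE"
    }
  }
  dmrs$category <- category
  dmrs$gene_id <- gene_id
  dmrs
}

#' Filter a differential-expression table into DEG calls
#'
#' A gene is a DEG when mean CPM > `cpm_min`, adjusted p-value <
#' `padj_max` and `abs(log2FC) > l2fc_min` (all three jointly).
#'
#' @param table data.frame with columns `gene` (or `gene_id`), `log2FC`,
#'   `padj`, `cpm`.
#' @param cpm_min,padj_max,l2fc_min the filter thresholds (defaults 10,
#'   0.05, 1.0).
#' @return the table with `is_deg` and `deg_direction`
#'   (`up`/`down`/`none`) columns; attribute `tally` holds the up/down
#'   totals.
#' @export
filter_degs <- function(table, cpm_min = 10, padj_max = 0.05, l2fc_min = 1.0) {
  table <- as.data.frame(table)
  if ("gene" %in% names(table) && !"gene_id" %in% names(table))
    names(table)[names(table) == "gene"] <- "gene_id"
  need <- c("gene_id", "log2FC", "padj", "cpm")
  if (!all(need %in% names(table)))
    stop("missing column(s): ", paste(setdiff(need, names(table)), collapse = ", "))
  if (any(table$padj < 0 | table$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  table$is_deg <- !is.na(table$padj) & table$cpm > cpm_min &
    table$padj < padj_max & abs(table$log2FC) > l2fc_min
  table$deg_direction <- ifelse(!table$is_deg, "none",
                                ifelse(table$log2FC > 0, "up", "down"))
  attr(table, "tally") <- c(up = sum(table$deg_direction == "up"),
                            down = sum(table$deg_direction == "down"),
                            total = sum(table$is_deg))
  table
}

#' Link annotated DMRs to differentially expressed genes
#'
#' A DMEG is a (genic-category DMR, DEG) pair where genic means the exon,
#' intron or TE-intron categories; a promDMEG is a (promoter-category DMR,
#' DEG) pair where promoter means promoter or TE-promoter. Each
#' (DMR, gene) pair yields one record, so a gene with two promoter DMRs
#' appears twice.
#'
#' @param annotated_dmrs output of [assign_dmr_features()] (needs
#'   `category`, `gene_id`, `mean_diff`, `context`).
#' @param degs output of [filter_degs()].
#' @return list with `dmegs` and `promdmegs` data.frames (`gene_id`,
#'   `chrom`, `start`, `end`, `context`, `diff_meth`, `diff_exp`,
#'   `category`).
#' @export
link_dmr_degs <- function(annotated_dmrs, degs) {
  deg_tab <- degs[degs$is_deg, c("gene_id", "log2FC")]
  join <- function(categories) {
    sel <- annotated_dmrs[annotated_dmrs$category %in% categories &
                            !is.na(annotated_dmrs$gene_id), , drop = FALSE]
    m <- match(sel$gene_id, deg_tab$gene_id)
    sel <- sel[!is.na(m), , drop = FALSE]
    if (nrow(sel) == 0L)
      return(data.frame(gene_id = character(0L), chrom = character(0L),
                        start = integer(0L), end = integer(0L),
                        context = character(0L), diff_meth = numeric(0L),
                        diff_exp = numeric(0L), category = character(0L)))
    data.frame(gene_id = sel$gene_id, chrom = sel$chrom,
               start = sel$start, end = sel$end, context = sel$context,
               diff_meth = sel$mean_diff,
               diff_exp = deg_tab$log2FC[match(sel$gene_id, deg_tab$gene_id)],
               category = sel$category, stringsAsFactors = FALSE)
  }
  list(dmegs = join(c("exon", "intron", "TE-intron")),
       promdmegs = join(c("promoter", "TE-promoter")))
}

#' Classify promoter-DMR / DEG pairs into Me/Exp quadrants
#'
#' Each record gets a methylation state (`+` for hyper, `-` for hypo,
#' from the sign of the promoter methylation difference) and an expression
#' state (sign of the log2 fold change), a quadrant label (`Me+/Exp+`,
#' `Me+/Exp-`, `Me-/Exp+`, `Me-/Exp-`), and a correlation sign (negative
#' when the two states differ). Records with a zero difference on either
#' axis are flagged unclassifiable and excluded from the tallies with a
#' warning.
#'
#' @param promdmegs data.frame with `diff_meth`, `diff_exp`, `context`
#'   (e.g. the `promdmegs` element of [link_dmr_degs()]).
#' @return list with `records` (input plus `me_state`, `exp_state`,
#'   `quadrant`, `correlation_sign`, `classifiable`) and `summary` (counts
#'   per quadrant, correlation tallies, hyper/hypo counts and per-context
#'   counts within each).
#' @export
classify_quadrants <- function(promdmegs) {
  df <- as.data.frame(promdmegs)
  df$classifiable <- df$diff_meth != 0 & df$diff_exp != 0
  if (any(!df$classifiable))
    warning(sum(!df$classifiable),
            " record(s) with zero difference flagged unclassifiable")
  df$me_state <- ifelse(df$diff_meth > 0, "+", "-")
  df$exp_state <- ifelse(df$diff_exp > 0, "+", "-")
  df$me_state[!df$classifiable] <- NA
  df$exp_state[!df$classifiable] <- NA
  df$quadrant <- ifelse(df$classifiable,
                        paste0("Me", df$me_state, "/Exp", df$exp_state), NA)
  df$correlation_sign <- ifelse(!df$classifiable, NA,
                                ifelse(df$me_state == df$exp_state,
                                       "positive", "negative"))
  ok <- df[df$classifiable, , drop = FALSE]
  quadrants <- c("Me+/Exp+", "Me+/Exp-", "Me-/Exp+", "Me-/Exp-")
  qc <- vapply(quadrants, function(q) sum(ok$quadrant == q), integer(1L))
  ctx_within <- function(sel) {
    v <- table(factor(ok$context[sel], levels = c("CG", "CHG", "CHH")))
    stats::setNames(as.integer(v), names(v))
  }
  summary <- list(
    n = nrow(df), classified = nrow(ok),
    unclassifiable = sum(!df$classifiable),
    quadrant_counts = qc,
    n_negative = sum(ok$correlation_sign == "negative"),
    n_positive = sum(ok$correlation_sign == "positive"),
    n_hyper = sum(ok$me_state == "+"),
    n_hypo = sum(ok$me_state == "-"),
    hyper_by_context = ctx_within(ok$me_state == "+"),
    hypo_by_context = ctx_within(ok$me_state == "-"))
  list(records = df, summary = summary)
}
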