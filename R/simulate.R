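#' Build a toy metabolic network with a known feasible flux distribution
#'
#' The network is a miniature heterotrophic cell: glucose uptake feeding
#' glycolysis, branches into protein (amino acid) and cell-wall biomass
#' exports, and a one-carbon loop coupling the folate (THF) cycle to the
#' S-adenosyl-methionine (SAM) cycle: serine donates its one-carbon unit
#' to tetrahydrofolate, methyl-THF remethylates homocysteine to
#' methionine, and methyl transfer from SAM closes the loop. The returned
#' ground-truth flux vector satisfies the internal steady state
#' `S_int %*% v = 0` exactly by construction.
#'
#' @param seed integer seed controlling the ground-truth magnitudes.
#' @param uptake glucose uptake flux (mmol/gDW/day); if NULL drawn
#'   uniformly in (8, 12).
#' @param cellwall_fraction fraction of uptake routed to cell-wall export;
#'   if NULL drawn in (0.2, 0.4).
#' @param cycle_flux SAM-cycle turnover; if NULL drawn in (0.3, 0.8).
#' @return list with `network` (a [reaction_network()]) and `v_true`
#'   (named flux vector).
#' @export
make_toy_network <- function(seed = 1L, uptake = NULL,
                             cellwall_fraction = NULL, cycle_flux = NULL) {
  set.seed(seed)
  u <- uptake %||% stats::runif(1L, 8, 12)
  fw <- cellwall_fraction %||% stats::runif(1L, 0.2, 0.4)
  cyc <- cycle_flux %||% stats::runif(1L, 0.3, 0.8)
  if (u < 0 || cyc < 0 || fw < 0 || fw > 1)
    stop("infeasible specification: all reactions are irreversible, so ",
         "uptake, cycle flux and the cell-wall fraction must be nonnegative")
  cw <- fw * u
  g <- u - cw              # glycolytic flux
  aa <- 2 * g - cyc        # amino acid synthesis (2 pyruvate per glucose)
  if (aa < 0)
    stop("infeasible specification: cycle flux exceeds pyruvate supply")
  mets <- data.frame(id = c("GLC", "PYR", "AA", "SER", "GLY", "THF",
                            "CH2THF", "CH3THF", "MET", "SAM", "SAH", "HCY"),
                     is_internal = TRUE)
  sto <- list(
    upt_glc       = c(GLC = 1),
    glycolysis    = c(GLC = -1, PYR = 2),
    aa_syn        = c(PYR = -1, AA = 1),
    exp_protein   = c(AA = -1),
    exp_cellwall  = c(GLC = -1),
    ser_syn       = c(PYR = -1, SER = 1),
    shmt          = c(SER = -1, THF = -1, GLY = 1, CH2THF = 1),
    exp_gly       = c(GLY = -1),
    mthfr         = c(CH2THF = -1, CH3THF = 1),
    met_synthase  = c(CH3THF = -1, HCY = -1, MET = 1, THF = 1),
    mat           = c(MET = -1, SAM = 1),
    methyltransfer = c(SAM = -1, SAH = 1),
    sahh          = c(SAH = -1, HCY = 1))
  rxns <- data.frame(id = names(sto), reversible = FALSE, lb = 0, ub = 1000)
  net <- reaction_network(mets, rxns, sto)
  v_true <- c(upt_glc = u, glycolysis = g, aa_syn = aa, exp_protein = aa,
              exp_cellwall = cw, ser_syn = cyc, shmt = cyc, exp_gly = cyc,
              mthfr = cyc, met_synthase = cyc, mat = cyc,
              methyltransfer = cyc, sahh = cyc)
  stopifnot(max(abs(s_internal(net) %*% v_true[net$reactions$id])) < 1e-10)
  list(network = net, v_true = v_true)
}

#' Reactions whose flux is observable as a content time course
#' @keywords internal
exchange_reactions <- function(network) {
  internal <- network$metabolites$id[network$metabolites$is_internal]
  vapply(network$reactions$id, function(rid) {
    sto <- network$stoichiometry[[rid]]
    # exchanges touch the boundary: one-sided stoichiometry
    all(sto > 0) || all(sto < 0) ||
      any(!names(sto) %in% internal)
  }, logical(1L))
}

#' Simulate measured concentration time courses from a flux distribution
#'
#' Each exchanged component accumulates (or depletes) linearly:
#' `content(t) = content0 + v_exchange * t`, with the exchange flux
#' piecewise constant in time and scaled per condition. Replicates get
#' multiplicative Gaussian noise of the given coefficient of variation.
#' Components are named after their exchange reaction, so the recovered
#' constraints map straight back onto the network.
#'
#' @param network a [reaction_network()] (e.g. from [make_toy_network()]).
#' @param v_true ground-truth flux vector.
#' @param days vector of sampling days.
#' @param reps replicates per condition.
#' @param noise_cv multiplicative noise CV (0 for noiseless).
#' @param seed integer seed.
#' @param conditions named numeric vector of per-condition scale factors
#'   applied to `v_true` (default `c("G+" = 1, "G-" = 0.15)`, emulating
#'   the collapse of most fluxes under glucose depletion).
#' @param content0 initial content per component (mmol/gDW); must keep
#'   contents nonnegative over the day range.
#' @return list with `series` (data.frame component, condition, replicate,
#'   day, value) and `truth` (data.frame condition, reaction_id, flux).
#' @export
simulate_concentration_timecourse <- function(network, v_true, days = 0:6,
                                              reps = 4L, noise_cv = 0,
                                              seed = 1L,
                                              conditions = c("G+" = 1, "G-" = 0.15),
                                              content0 = 100) {
  set.seed(seed)
  exch <- names(which(exchange_reactions(network)))
  out <- list(); truth <- list()
  for (cond in names(conditions)) {
    v <- v_true[exch] * conditions[[cond]]
    # sign of the content slope: production of boundary material counts
    # positive (accumulation); uptake consumes medium stock, also tracked
    # as a positive cellular content here for simplicity of the inverse map
    for (r in exch) {
      content <- content0 + v[[r]] * days
      if (any(content < 0))
        stop("content of ", r, " becomes negative within the day range; ",
             "increase content0")
      for (rep_i in seq_len(reps)) {
        noise <- if (noise_cv > 0)
          1 + stats::rnorm(length(days), 0, noise_cv) else 1
        out[[length(out) + 1L]] <- data.frame(
          component = r, condition = cond, replicate = rep_i,
          day = days, value = content * noise, stringsAsFactors = FALSE)
      }
    }
    truth[[cond]] <- data.frame(condition = cond, reaction_id = exch,
                                flux = unname(v), stringsAsFactors = FALSE)
  }
  list(series = load_concentration_series(do.call(rbind, out)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Derive per-day flux constraints from a simulated (or measured) series
#'
#' Fits one curve per (component, condition) and evaluates the derivative
#' at each requested day, producing the constraint table consumed by
#' [run_flux_timecourse()].
#'
#' @param series a `concentration_series` whose components are named after
#'   exchange reactions.
#' @param days days at which to take snapshots (must lie inside each
#'   fitted domain).
#' @param method curve-fitting method (see [fit_concentration_curve()]).
#' @return constraint data.frame (reaction_id, kind, value, tolerance,
#'   day, condition).
#' @export
constraints_from_series <- function(series, days, method = "auto") {
  combos <- unique(series[, c("component", "condition")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cv <- fit_concentration_curve(series, combos$component[i],
                                  combos$condition[i], method = method)
    for (d in days) {
      rows[[length(rows) + 1L]] <-
        estimate_exchange_flux(cv, d, series = series)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

rbetabinom <- function(n_draws, size, mu, rho) {
  if (rho <= 0) return(stats::rbinom(n_draws, size, mu))
  shape <- 1 / rho - 1
  p <- stats::rbeta(n_draws, mu * shape, (1 - mu) * shape)
  stats::rbinom(n_draws, size, p)
}

#' Simulate a toy annotated methylome with planted DMRs
#'
#' Generates a small genome annotation (non-overlapping genes with two
#' exons each, transposable elements placed in intergenic space, introns
#' and promoters), cytosine loci with CG/CHG/CHH context labels, and
#' per-sample beta-binomial counts for two groups. Inside planted regions
#' the treatment-group (G-) mean is shifted by the planted difference.
#' Every generator call is a pure function of its arguments and the seed.
#'
#' @param seed integer seed.
#' @param chrom_lengths named vector of chromosome lengths (default 3
#'   chromosomes of 700 kb).
#' @param n_genes,n_tes numbers of genes and TEs.
#' @param n_loci total cytosine loci.
#' @param baseline mean methylation per context (defaults CG 0.48,
#'   CHG 0.32, CHH 0.03, the magnitudes of a glucose-replete grapevine
#'   culture).
#' @param dispersion beta-binomial dispersion among replicates.
#' @param coverage mean Poisson sequencing depth per locus and sample.
#' @param reps named vector of replicate counts per group (default 3 G-,
#'   3 G+).
#' @param context_weights sampling probabilities of the three contexts.
#' @param planted data.frame describing planted DMRs: columns `class`
#'   (promoter/gene/TE/intergenic), `context`, `diff` (treatment minus
#'   control), `width`; or NULL for a null methylome.
#' @param out_dir optional directory; when given, per-sample cytosine
#'   reports (TSV), a GFF3 annotation, a TE BED and the truth table are
#'   written there.
#' @return list with `table` (a [cytosine_count_table()] carrying a
#'   `chrom_lengths` attribute), `features` (a [feature_set()]),
#'   `genes`, `tes` (data.frames), `truth` (planted DMR table with exact
#'   intervals) and `files` (paths, when written).
#' @export
simulate_methylome <- function(seed = 1L,
                               chrom_lengths = c(chr1 = 7e5, chr2 = 7e5, chr3 = 7e5),
                               n_genes = 90L, n_tes = 120L, n_loci = 60000L,
                               baseline = c(CG = 0.48, CHG = 0.32, CHH = 0.03),
                               dispersion = 0.05, coverage = 30,
                               reps = c("G-" = 3L, "G+" = 3L),
                               context_weights = c(CG = 0.25, CHG = 0.25, CHH = 0.5),
                               planted = NULL, out_dir = NULL) {
  set.seed(seed)
  chroms <- names(chrom_lengths)

  # --- annotation: genes tiled with gaps, TEs in the gaps and introns ---
  genes <- list(); tes <- list()
  per_chrom_genes <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1L)))
  for (ci in seq_along(chroms)) {
    L <- chrom_lengths[[ci]]
    ng <- per_chrom_genes[ci]
    if (ng == 0L) next
    slot <- floor(L / ng)
    glen <- pmin(round(stats::runif(ng, 2000, 4000)), slot - 4500)
    gstart <- (seq_len(ng) - 1L) * slot + 2200L +
      round(stats::runif(ng, 0, pmax(slot - glen - 4500, 1)))
    genes[[ci]] <- data.frame(
      gene_id = sprintf("g%s_%03d", chroms[ci], seq_len(ng)),
      chrom = chroms[ci], start = gstart, end = gstart + glen - 1L,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  # two exons per gene leaving one intron in the middle
  third <- floor((genes$end - genes$start + 1L) / 3L)
  exons <- rbind(
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$start + third - 1L),
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$end - third + 1L, end = genes$end))
  # TEs: in intergenic gaps, some inside introns, some inside promoters
  n_te_intron <- round(n_tes * 0.2)
  n_te_prom <- round(n_tes * 0.15)
  n_te_free <- n_tes - n_te_intron - n_te_prom
  pick_genes <- function(k) genes[sample(nrow(genes), k, replace = TRUE), ]
  gi <- pick_genes(n_te_intron)
  te_intron <- data.frame(chrom = gi$chrom,
                          start = gi$start + third[match(gi$gene_id, genes$gene_id)] + 5L,
                          stringsAsFactors = FALSE)
  te_intron$end <- te_intron$start +
    pmax(50L, third[match(gi$gene_id, genes$gene_id)] - 10L) - 1L
  gp <- pick_genes(n_te_prom)
  prom_anchor <- ifelse(gp$strand == "+", gp$start - 900L, gp$end + 300L)
  te_prom <- data.frame(chrom = gp$chrom, start = pmax(1L, prom_anchor),
                        stringsAsFactors = FALSE)
  te_prom$end <- te_prom$start + 599L
  free_start <- round(stats::runif(n_te_free, 1, unname(chrom_lengths[1L]) - 2000))
  te_free <- data.frame(chrom = sample(chroms, n_te_free, replace = TRUE),
                        start = free_start, stringsAsFactors = FALSE)
  te_free$end <- te_free$start + round(stats::runif(n_te_free, 300, 1500))
  tes <- rbind(te_intron, te_prom, te_free)
  # drop free TEs that landed on genes or promoters so "TE" stays extragenic
  fs0 <- feature_set(genes, exons, NULL, chrom_lengths = chrom_lengths)
  te_gr <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start, tes$end))
  is_free <- seq_len(nrow(tes)) > (n_te_intron + n_te_prom)
  hit_gene <- GenomicRanges::countOverlaps(te_gr, fs0$genes) > 0L
  hit_prom <- GenomicRanges::countOverlaps(te_gr, fs0$promoters) > 0L
  tes <- tes[!(is_free & (hit_gene | hit_prom)), , drop = FALSE]
  features <- feature_set(genes, exons, tes, chrom_lengths = chrom_lengths)

  # --- cytosine loci ---
  per_chrom_loci <- diff(round(seq(0, n_loci, length.out = length(chroms) + 1L)))
  loci <- list()
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(chrom_lengths[[ci]], per_chrom_loci[ci]))
    loci[[ci]] <- data.frame(
      chrom = chroms[ci], pos = pos,
      strand = sample(c("+", "-"), length(pos), replace = TRUE),
      context = sample(names(context_weights), length(pos), replace = TRUE,
                       prob = context_weights),
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)

  # locus-level baseline means vary around the context baseline
  conc <- 20
  mu0 <- stats::rbeta(nrow(loci),
                      baseline[loci$context] * conc,
                      (1 - baseline[loci$context]) * conc)
  mu0 <- pmin(pmax(mu0, 1e-3), 1 - 1e-3)
  mu1 <- mu0   # treatment (G-)

  # --- plant DMRs ---
  truth <- data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), context = character(0L),
                      class = character(0L), diff = numeric(0L),
                      n_loci = integer(0L))
  if (!is.null(planted) && nrow(planted) > 0L) {
    anchors <- list(
      promoter = as.data.frame(features$promoters)[, c("seqnames", "start", "end")],
      gene = genes[, c("chrom", "start", "end")],
      TE = tes,
      intergenic = NULL)
    names(anchors$promoter) <- c("chrom", "start", "end")
    used <- GenomicRanges::GRanges()
    for (i in seq_len(nrow(planted))) {
      cls <- planted$class[i]; wid <- planted$width[i]
      placed <- FALSE
      for (try_i in 1:200) {
        if (cls == "intergenic") {
          ch <- sample(chroms, 1L)
          st <- sample.int(chrom_lengths[[ch]] - wid, 1L)
          cand <- data.frame(chrom = ch, start = st, end = st + wid - 1L)
          cand_gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, cand$end))
          # suppressWarnings: single-chromosome queries against multi-
          # chromosome subjects trigger a harmless seqlevel notice
          if (suppressWarnings(
            GenomicRanges::countOverlaps(cand_gr, features$genes) +
            GenomicRanges::countOverlaps(cand_gr, features$promoters) +
            GenomicRanges::countOverlaps(cand_gr, features$tes)) > 0L) next
        } else {
          pool <- anchors[[cls]]
          pool <- pool[pool$end - pool$start + 1L >= wid, , drop = FALSE]
          if (nrow(pool) == 0L) stop("no ", cls, " wide enough for a ",
                                     wid, " bp planted region")
          a <- pool[sample(nrow(pool), 1L), ]
          st <- a$start + sample.int(max(a$end - a$start + 2L - wid, 1L), 1L) - 1L
          cand <- data.frame(chrom = a$chrom, start = st, end = st + wid - 1L)
          cand_gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(st, cand$end))
        }
        if (suppressWarnings(
          GenomicRanges::countOverlaps(cand_gr, used)) > 0L) next
        in_reg <- loci$chrom == cand$chrom & loci$pos >= cand$start &
          loci$pos <= cand$end & loci$context == planted$context[i]
        if (sum(in_reg) < 3L) next
        # re-centre the baseline so the planted shift stays inside [0, 1]
        d <- planted$diff[i]
        base_ok <- stats::runif(sum(in_reg),
                                max(0.02, 0.02 - d), min(0.98, 0.98 - d))
        mu0[in_reg] <- base_ok
        mu1[in_reg] <- base_ok + d
        used <- suppressWarnings(c(used, cand_gr))
        truth <- rbind(truth, data.frame(
          chrom = cand$chrom, start = cand$start, end = cand$end,
          context = planted$context[i], class = cls, diff = d,
          n_loci = sum(in_reg)))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted region ", i,
                        " (class ", cls, ") without overlap")
    }
  }

  # --- counts ---
  sample_names <- unlist(lapply(names(reps), function(g)
    paste0(g, "_", seq_len(reps[[g]]))))
  groups <- stats::setNames(rep(names(reps), reps), sample_names)
  n <- nrow(loci)
  meth <- matrix(0L, n, length(sample_names),
                 dimnames = list(NULL, sample_names))
  total <- meth
  for (s in sample_names) {
    mu <- if (groups[[s]] == names(reps)[1L]) mu1 else mu0
    depth <- stats::rpois(n, coverage)
    total[, s] <- depth
    meth[, s] <- rbetabinom(n, depth, mu, dispersion)
  }
  table <- cytosine_count_table(loci, meth, total,
                                data.frame(sample = sample_names,
                                           group = unname(groups),
                                           stringsAsFactors = FALSE))
  attr(table, "chrom_lengths") <- chrom_lengths

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_methylome_files(table, genes, exons, tes, truth, out_dir)
  }
  list(table = table, features = features, genes = genes, exons = exons,
       tes = tes, truth = truth, files = files)
}

write_methylome_files <- function(table, genes, exons, tes, truth, out_dir) {
  files <- character(0L)
  ord <- order(table$loci$chrom, table$loci$pos)
  for (s in table$samples$sample) {
    p <- file.path(out_dir, paste0("cytosine_report_", gsub("[^A-Za-z0-9_+-]", "", s), ".tsv"))
    df <- data.frame(table$loci$chrom, table$loci$pos, table$loci$strand,
                     table$meth[, s], table$total[, s] - table$meth[, s],
                     table$loci$context,
                     paste0(table$loci$context, "N"))[ord, ]
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[s] <- p
  }
  gff <- file.path(out_dir, "annotation.gff3")
  gene_rows <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$gene_id)
  exon_rows <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       exons$chrom, exons$start, exons$end,
                       genes$strand[match(exons$gene_id, genes$gene_id)],
                       exons$gene_id)
  writeLines(c("##gff-version 3", gene_rows, exon_rows), gff)
  files["annotation"] <- gff
  bed <- file.path(out_dir, "te.bed")
  utils::write.table(data.frame(tes$chrom, tes$start - 1L, tes$end),
                     bed, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  files["te"] <- bed
  tp <- file.path(out_dir, "planted_truth.tsv")
  utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- tp
  files
}

#' Simulate a differential-expression results table
#'
#' Draws negative-binomial counts for two groups of replicates, computes
#' observed log2 fold changes and a two-group Welch test on log2 CPM with
#' Benjamini-Hochberg adjustment, so the DEG filter is exercised
#' end-to-end on realistic p-values rather than fabricated ones. Planted
#' DEGs receive the planted log2 fold change; genes linked to a planted
#' promoter DMR receive the sign opposite to the methylation difference
#' (anticorrelation links).
#'
#' @param genes character vector of gene ids (or a data.frame with a
#'   `gene_id` column).
#' @param frac_deg fraction of genes planted as differentially expressed.
#' @param l2fc planted absolute log2 fold change.
#' @param reps replicates per group.
#' @param libsize sequencing library size.
#' @param dispersion negative-binomial dispersion.
#' @param links optional data.frame with `gene_id` and `diff_meth`; linked
#'   genes are planted with `sign(l2fc) = -sign(diff_meth)`.
#' @param seed integer seed.
#' @return data.frame: `gene_id`, `log2FC` (observed), `padj`, `cpm`,
#'   `true_deg`, `true_l2fc`.
#' @export
simulate_expression_table <- function(genes, frac_deg = 0.1, l2fc = 3,
                                      reps = 3L, libsize = 1e6,
                                      dispersion = 0.05, links = NULL,
                                      seed = 1L) {
  if (frac_deg < 0 || frac_deg > 1) stop("frac_deg must be in [0, 1]")
  set.seed(seed)
  if (is.data.frame(genes)) genes <- genes$gene_id
  ng <- length(genes)
  base_cpm <- stats::rlnorm(ng, meanlog = log(100), sdlog = 0.5)
  true_l2fc <- numeric(ng)
  deg_idx <- sample(ng, round(frac_deg * ng))
  true_l2fc[deg_idx] <- sample(c(-1, 1), length(deg_idx), replace = TRUE) * l2fc
  if (!is.null(links) && nrow(links) > 0L) {
    li <- match(links$gene_id, genes)
    if (anyNA(li)) stop("linked gene absent from the gene list")
    true_l2fc[li] <- -sign(links$diff_meth) * abs(l2fc)
  }
  mu2 <- base_cpm * libsize / 1e6                 # control (G+)
  mu1 <- mu2 * 2^true_l2fc                        # treatment (G-)
  counts1 <- matrix(stats::rnbinom(ng * reps, mu = mu1, size = 1 / dispersion),
                    ng, reps)
  counts2 <- matrix(stats::rnbinom(ng * reps, mu = mu2, size = 1 / dispersion),
                    ng, reps)
  cpm1 <- t(t(counts1) / colSums(counts1)) * 1e6
  cpm2 <- t(t(counts2) / colSums(counts2)) * 1e6
  l1 <- log2(cpm1 + 0.5); l2 <- log2(cpm2 + 0.5)
  pval <- vapply(seq_len(ng), function(i) {
    if (stats::sd(l1[i, ]) == 0 && stats::sd(l2[i, ]) == 0) return(1)
    tryCatch(stats::t.test(l1[i, ], l2[i, ])$p.value, error = function(e) 1)
  }, numeric(1L))
  data.frame(gene_id = genes,
             log2FC = rowMeans(l1) - rowMeans(l2),
             padj = stats::p.adjust(pval, "BH"),
             cpm = rowMeans(cbind(cpm1, cpm2)),
             true_deg = true_l2fc != 0, true_l2fc = true_l2fc,
             stringsAsFactors = FALSE)
}
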