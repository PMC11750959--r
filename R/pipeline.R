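#' Default pipeline configuration
#'
#' Every analysis threshold in one place, at its documented default:
#' DMC retention (difference thresholds per context and posterior
#' probability), smoothing window, dispersion shrinkage prior, DMR
#' segmentation parameters, DMR direction cutoffs, promoter length,
#' metagene geometry, DEG filter, flux-solver tolerances, and simulation
#' sizes for the synthetic run.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    dmc = list(
      diff_threshold = list(CG = 0.1, CHG = 0.1, CHH = 0.07),
      p_post = 0.9999,
      smoothing_window_bp = 500,
      dispersion_prior = 0.05,
      dispersion_prior_coverage = 100),
    dmr = list(
      min_len = 50, min_sites = 3, merge_gap = 100, pct_sig = 0.5,
      direction_cutoff = list(CG = 0.25, CHG = 0.25, CHH = 0.10)),
    annotation = list(
      promoter_length_bp = 2000),
    metagene = list(
      flank_bp = 2000, body_bins = 20, flank_bins = 10),
    deg = list(
      cpm_min = 10, padj_max = 0.05, l2fc_min = 1.0),
    flux = list(
      steady_state_tol = 1e-8, relative_band = 0),
    simulate = list(
      n_loci = 60000, n_genes = 90, n_tes = 120, coverage = 30,
      reps_per_group = 3,
      days = c(0, 1, 2, 3, 4, 5, 6), concentration_reps = 4,
      concentration_noise_cv = 0.05))
}

config_leaves <- function(x, prefix = character(0L)) {
  if (!is.list(x)) return(paste(prefix, collapse = "."))
  unlist(lapply(names(x), function(nm) config_leaves(x[[nm]], c(prefix, nm))))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads the file and validates it against [default_config()]; see
#' [validate_config()].
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Write a configuration to YAML
#' @param config a config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks that every threshold present in [default_config()] is present
#' in `config`; missing entries are reported by their full dotted names
#' in a single error. Basic sanity of the central thresholds is also
#' enforced (probabilities inside (0, 1), positive windows and lengths).
#'
#' @param config a config list (e.g. from [load_config()]).
#' @return the config, invisibly usable, after checks pass.
#' @export
validate_config <- function(config) {
  need <- config_leaves(default_config())
  have <- config_leaves(config)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("config is missing required thresholds: ",
         paste(missing, collapse = ", "))
  with(config$dmc, {
    if (p_post <= 0 || p_post >= 1)
      stop("dmc.p_post must lie strictly inside (0, 1)")
    if (any(unlist(diff_threshold) <= 0 | unlist(diff_threshold) >= 1))
      stop("dmc.diff_threshold values must lie strictly inside (0, 1)")
    if (smoothing_window_bp <= 0) stop("dmc.smoothing_window_bp must be > 0")
  })
  with(config$dmr, {
    if (min_len <= 0 || min_sites <= 0 || merge_gap < 0 ||
        pct_sig <= 0 || pct_sig > 1)
      stop("dmr segmentation parameters are contradictory")
  })
  if (config$annotation$promoter_length_bp <= 0)
    stop("annotation.promoter_length_bp must be > 0")
  if (config$deg$padj_max <= 0 || config$deg$padj_max >= 1)
    stop("deg.padj_max must lie strictly inside (0, 1)")
  config
}

config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  # small stable checksum (polynomial rolling hash), good enough to tell
  # two configs apart in a log line without extra dependencies
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-data pipeline
#'
#' End-to-end driver: simulate a toy network, concentration series,
#' methylome and expression table; solve the daily flux snapshots; call
#' DMCs and DMRs; annotate and integrate with expression; and write an
#' aggregate report. Outputs (DMR BED, DEG/quadrant CSVs, the aggregate
#' report text, and a log recording the seed, the config hash and every
#' assumed parameter) go to `out_dir`.
#'
#' @param config config list (default [default_config()]).
#' @param out_dir output directory (created if absent).
#' @param steps which stages to run; later stages require the earlier
#'   ones in the same call.
#' @return list with the intermediate objects (`simulation`, `fluxes`,
#'   `dmcs`, `dmrs`, `annotated`, `degs`, `quadrants`, `report`) and the
#'   paths written.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run_"),
                         steps = c("simulate", "flux", "methylome",
                                   "integrate", "report")) {
  config <- validate_config(config)
  steps <- match.arg(steps, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pipeline started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("seed: %d", config$seed)
  logf("config hash: %s", config_hash(config))
  logf("assumed parameters:")
  for (leaf in config_leaves(config)) {
    val <- config
    for (k in strsplit(leaf, ".", fixed = TRUE)[[1L]]) val <- val[[k]]
    logf("  %s = %s", leaf, paste(format(val), collapse = ", "))
  }

  res <- list(out_dir = out_dir, log = log_path)
  need <- function(s) s %in% steps

  if (need("simulate")) {
    sim_cfg <- config$simulate
    toy <- make_toy_network(seed = config$seed)
    conc <- simulate_concentration_timecourse(
      toy$network, toy$v_true, days = sim_cfg$days,
      reps = sim_cfg$concentration_reps,
      noise_cv = sim_cfg$concentration_noise_cv, seed = config$seed + 1L)
    meth <- simulate_methylome(
      seed = config$seed + 2L, n_loci = sim_cfg$n_loci,
      n_genes = sim_cfg$n_genes, n_tes = sim_cfg$n_tes,
      coverage = sim_cfg$coverage,
      reps = stats::setNames(rep(sim_cfg$reps_per_group, 2L), c("G-", "G+")),
      planted = data.frame(
        class = rep(c("promoter", "gene", "TE", "intergenic"), each = 5L),
        context = rep(c("CG", "CHG", "CHH", "CG", "CHH"), 4L),
        diff = rep(c(0.4, 0.35, 0.15, -0.4, -0.15), 4L),
        width = 1200L))
    expr <- simulate_expression_table(
      meth$genes, seed = config$seed + 3L,
      links = local({
        tr <- meth$truth[meth$truth$class == "promoter", , drop = FALSE]
        if (nrow(tr) == 0L) return(NULL)
        pr <- as.data.frame(meth$features$promoters)
        gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
        hit <- GenomicRanges::findOverlaps(gr, meth$features$promoters,
                                           select = "first")
        ok <- !is.na(hit)
        data.frame(gene_id = pr$gene_id[hit[ok]], diff_meth = tr$diff[ok])
      }))
    res$simulation <- list(toy = toy, concentration = conc,
                           methylome = meth, expression = expr)
    logf("simulate: %d loci, %d genes, %d planted regions",
         nrow(meth$table$loci), nrow(meth$genes), nrow(meth$truth))
  }

  if (need("flux")) {
    if (is.null(res$simulation)) stop("the flux step needs the simulate step")
    toy <- res$simulation$toy
    constraints <- constraints_from_series(
      res$simulation$concentration$series,
      days = config$simulate$days[c(2L, length(config$simulate$days) - 1L)])
    res$fluxes <- run_flux_timecourse(
      toy$network, constraints, watchlist = "SAM",
      options = list(tol = config$flux$steady_state_tol,
                     relative_band = config$flux$relative_band))
    logf("flux: %d snapshots solved", length(res$fluxes$solutions))
  }

  if (need("methylome")) {
    if (is.null(res$simulation)) stop("the methylome step needs the simulate step")
    meth <- res$simulation$methylome
    thr <- list(diff = unlist(config$dmc$diff_threshold),
                p_post = config$dmc$p_post)
    res$dmcs <- call_dmcs(meth$table, thresholds = thr,
                          window_bp = config$dmc$smoothing_window_bp,
                          prior_coverage = config$dmc$dispersion_prior_coverage,
                          prior = config$dmc$dispersion_prior)
    res$dmrs <- call_dmrs(
      res$dmcs,
      params = config$dmr[c("min_len", "min_sites", "merge_gap", "pct_sig")],
      table = meth$table,
      direction_cutoffs = unlist(config$dmr$direction_cutoff))
    bed <- file.path(out_dir, "dmrs.bed")
    write_dmr_bed(res$dmrs, bed)
    res$files <- c(res$files, dmr_bed = bed)
    logf("methylome: %d DMCs, %d DMRs", sum(res$dmcs$retained),
         nrow(res$dmrs))
  }

  if (need("integrate")) {
    if (is.null(res$dmrs)) stop("the integrate step needs the methylome step")
    meth <- res$simulation$methylome
    res$annotated <- assign_dmr_features(res$dmrs, meth$features)
    res$degs <- filter_degs(res$simulation$expression,
                            cpm_min = config$deg$cpm_min,
                            padj_max = config$deg$padj_max,
                            l2fc_min = config$deg$l2fc_min)
    res$links <- link_dmr_degs(res$annotated, res$degs)
    res$quadrants <- classify_quadrants(res$links$promdmegs)
    deg_csv <- file.path(out_dir, "degs.csv")
    utils::write.csv(res$degs[res$degs$is_deg, ], deg_csv, row.names = FALSE)
    quad_csv <- file.path(out_dir, "promoter_dmr_deg_pairs.csv")
    utils::write.csv(res$quadrants$records, quad_csv, row.names = FALSE)
    res$files <- c(res$files, degs = deg_csv, quadrants = quad_csv)
    logf("integrate: %d DEGs, %d promoter-DMR/DEG pairs",
         sum(res$degs$is_deg), nrow(res$links$promdmegs))
  }

  if (need("report")) {
    res$report <- aggregate_report(
      dmcs = res$dmcs, dmrs = res$dmrs, annotated_dmrs = res$annotated,
      degs = res$degs, quadrants = res$quadrants)
    rp <- file.path(out_dir, "report.txt")
    sink(rp); print(res$report); sink()
    res$files <- c(res$files, report = rp)
    logf("report written")
  }
  logf("pipeline finished %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  res
}
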