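# Shared helpers for the test suite.

# Small hand-built cytosine table: n loci on one chromosome, constant
# spacing, two groups of `reps` samples each with constant coverage.
make_flat_table <- function(n = 50L, spacing = 100L, coverage = 20L,
                            level = 0.5, reps = 2L, context = "CG",
                            chrom_length = NULL) {
  loci <- data.frame(chrom = "chr1", pos = seq_len(n) * spacing,
                     strand = "+", context = context,
                     stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = c(paste0("Gm_", seq_len(reps)), paste0("Gp_", seq_len(reps))),
    group = rep(c("G-", "G+"), each = reps), stringsAsFactors = FALSE)
  total <- matrix(coverage, n, nrow(samples),
                  dimnames = list(NULL, samples$sample))
  meth <- matrix(round(coverage * level), n, nrow(samples),
                 dimnames = list(NULL, samples$sample))
  tab <- cytosine_count_table(loci, meth, total, samples)
  if (!is.null(chrom_length))
    attr(tab, "chrom_lengths") <- c(chr1 = chrom_length)
  tab
}

# 50% reciprocal-overlap recall of truth regions among called regions.
reciprocal_recall <- function(truth, called, frac = 0.5) {
  hit <- 0L
  for (i in seq_len(nrow(truth))) {
    js <- which(called$chrom == truth$chrom[i])
    for (j in js) {
      ov <- min(called$end[j], truth$end[i]) -
        max(called$start[j], truth$start[i]) + 1
      if (ov > 0 &&
          ov >= frac * (truth$end[i] - truth$start[i] + 1) &&
          ov >= frac * (called$end[j] - called$start[j] + 1)) {
        hit <- hit + 1L
        break
      }
    }
  }
  hit / nrow(truth)
}

# Direct KKT solve of min v'v s.t. A v = b: an oracle independent of the
# package's active-set solver.
kkt_oracle <- function(A, b) {
  n <- ncol(A); m <- nrow(A)
  K <- rbind(cbind(2 * diag(n), t(A)), cbind(A, matrix(0, m, m)))
  sol <- qr.solve(K, c(numeric(n), b))
  sol[seq_len(n)]
}
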