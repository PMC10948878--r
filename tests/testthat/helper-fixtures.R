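# in-code fixture builders shared across test files

# one caller's row for a variant; defaults pass every retention rule
call_row <- function(caller, chrom = "1", pos = 100L, ref = "A", alt = "T",
                     variant_class = "SNV", tumor_depth = 100L,
                     tumor_alt_reads = 30L, normal_depth = 100L,
                     normal_alt_reads = 0L, in_dbsnp = FALSE,
                     in_cosmic = FALSE, gene = "GENE1",
                     consequence = "nonsynonymous", sample_id = "S1") {
  data.frame(
    sample_id = sample_id, caller = caller, chrom = chrom, pos = pos,
    ref = ref, alt = alt, variant_class = variant_class,
    tumor_depth = tumor_depth, tumor_alt_reads = tumor_alt_reads,
    normal_depth = normal_depth, normal_alt_reads = normal_alt_reads,
    in_dbsnp = in_dbsnp, in_cosmic = in_cosmic, gene = gene,
    consequence = consequence
  )
}

calls_for <- function(callers, ...) {
  do.call(rbind, lapply(callers, call_row, ...))
}

# flat region track with given log2 values, one region per kb on one chromosome
ratio_track <- function(log2_values, chrom = "1") {
  n <- length(log2_values)
  data.frame(
    chrom = chrom,
    start = seq(0, by = 1000L, length.out = n),
    end = seq(120L, by = 1000L, length.out = n),
    log2_ratio = log2_values
  )
}

# brute-force maximal two-sample |t| over all circular arc splits,
# independent of the segmentation code path
brute_force_best_arc <- function(x, min_width = 2) {
  n <- length(x)
  best <- -Inf
  best_ij <- c(NA, NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      n1 <- j - i
      if (n1 < min_width || n - n1 < min_width) next
      a <- x[(i + 1):j]
      b <- x[-((i + 1):j)]
      sp2 <- ((n1 - 1) * stats::var(a) + (n - n1 - 1) * stats::var(b)) / (n - 2)
      tt <- abs(mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / (n - n1)))
      if (tt > best) {
        best <- tt
        best_ij <- c(i, j)
      }
    }
  }
  list(t = best, i = best_ij[1], j = best_ij[2])
}

# cluster purity: fraction of cells whose cluster's majority truth label
# matches their own
cluster_purity <- function(clusters, truth) {
  tab <- table(clusters, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}
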