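#' Karyotypic chromosome rank
#'
#' Orders chromosomes 1..22, X, Y (with or without a "chr" prefix); any
#' other names are appended in lexical order.
#'
#' @param chrom character vector of chromosome names.
#' @return integer ranks usable with [order()].
#' @export
chrom_rank <- function(chrom) {
  canon <- sub("^chr", "", as.character(chrom))
  levels <- c(as.character(1:22), "X", "Y")
  r <- match(canon, levels)
  extra <- sort(unique(canon[is.na(r)]))
  r[is.na(r)] <- length(levels) + match(canon[is.na(r)], extra)
  r
}

check_regions <- function(regions) {
  req <- c("chrom", "start", "end", "tumor_reads", "normal_reads")
  miss <- setdiff(req, names(regions))
  if (length(miss)) stop("missing region columns: ", paste(miss, collapse = ", "))
  if (any(regions$end <= regions$start)) stop("regions must satisfy end > start")
  if (any(regions$tumor_reads < 0 | regions$normal_reads < 0)) {
    stop("read counts must be nonnegative")
  }
  o <- order(chrom_rank(regions$chrom), regions$start)
  if (!identical(o, seq_len(nrow(regions)))) stop("regions must be sorted")
  by_chr <- split(regions, regions$chrom)
  for (g in by_chr) {
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
      stop("regions must be non-overlapping")
    }
  }
  invisible(regions)
}

#' Remove low-coverage capture regions
#'
#' Capture regions with fewer than `min_reads` reads in both the tumor and
#' the matched control sample are removed. A region below the cutoff in
#' only one of the two samples is retained.
#'
#' @param regions sorted, non-overlapping data.frame with columns `chrom`,
#'   `start`, `end` (0-based half-open), `tumor_reads`, `normal_reads`.
#' @param min_reads coverage cutoff (default 100).
#' @return the retained regions.
#' @export
filter_regions <- function(regions, min_reads = 100) {
  check_regions(regions)
  drop <- regions$tumor_reads < min_reads & regions$normal_reads < min_reads
  regions[!drop, , drop = FALSE]
}

#' Normalized tumor/normal read-count ratios
#'
#' Each sample's region counts are normalized by that sample's total
#' aligned reads; the log2 of the tumor/normal ratio of these normalized
#' counts is the segmentation input. Regions are returned in karyotypic
#' chromosome order sorted by coordinate.
#'
#' @param regions retained regions from [filter_regions()].
#' @param tumor_total,normal_total total aligned reads per sample; default
#'   is the column sum over the retained regions (on-target reads only).
#' @return `regions` with added columns `norm_tumor`, `norm_normal`,
#'   `log2_ratio`. Regions with zero normal reads are dropped with a
#'   warning (the ratio is undefined there).
#' @export
compute_ratios <- function(regions, tumor_total = NULL, normal_total = NULL) {
  if (is.null(tumor_total)) tumor_total <- sum(regions$tumor_reads)
  if (is.null(normal_total)) normal_total <- sum(regions$normal_reads)
  if (tumor_total <= 0 || normal_total <= 0) stop("per-sample totals must be positive")
  zero <- regions$normal_reads == 0
  if (any(zero)) {
    warning(sum(zero), " region(s) with zero normal reads dropped")
    regions <- regions[!zero, , drop = FALSE]
  }
  regions <- regions[order(chrom_rank(regions$chrom), regions$start), , drop = FALSE]
  regions$norm_tumor <- regions$tumor_reads / tumor_total
  regions$norm_normal <- regions$normal_reads / normal_total
  regions$log2_ratio <- log2(regions$norm_tumor / regions$norm_normal)
  rownames(regions) <- NULL
  regions
}

# Recursive circular binary segmentation of one chromosome's ordered
# log2 values. Returns integer breakpoints (end indices of segments).
cbs_chromosome <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < max(4, 2 * min_width) || stats::sd(x) == 0) return(n)
  scan <- .cbs_scan(x, as.integer(min_width), as.integer(n_perm), alpha)
  if (is.na(scan$t) || scan$p >= alpha) return(n)
  i <- scan$i
  j <- scan$j
  cuts <- setdiff(c(i, j), c(0, n))
  if (length(cuts) == 0) return(n)
  bounds <- c(0, sort(cuts), n)
  out <- integer(0)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]
    hi <- bounds[k + 1]
    sub <- cbs_chromosome(x[(lo + 1):hi], alpha, n_perm, min_width)
    out <- c(out, lo + sub)
  }
  out
}

#' Circular binary segmentation of log2 ratios
#'
#' Partitions each chromosome's ordered log2 ratios into segments of
#' constant copy number by recursive circular binary segmentation: the
#' two-sample t statistic between a circular arc and its complement is
#' maximized over all arcs, the split is accepted when its permutation
#' p-value (within-chromosome value shuffles) is below `alpha`, and
#' accepted sub-segments are searched recursively. No post-hoc
#' segment-merging pass is applied.
#'
#' @param ratios output of [compute_ratios()] (needs `chrom`, `start`,
#'   `end`, `log2_ratio`, karyotypically ordered).
#' @param alpha significance level for accepting a split (default 0.01).
#' @param n_perm number of permutations (default 1000; fewer than 100 is
#'   rejected as the p-values become unstable).
#' @param min_width minimum number of regions per segment (default 2).
#' @param seed integer seed for the permutation shuffles.
#' @return data.frame of segments: `chrom`, `start`, `end`,
#'   `member_region_count`, `seg_log2` (mean of member log2 ratios), plus
#'   `first_region`/`last_region` row indices into `ratios`.
#' @export
segment_cbs <- function(ratios, alpha = 0.01, n_perm = 1000, min_width = 2,
                        seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (nrow(ratios) == 0) stop("no regions to segment")
  set.seed(seed)
  ratios <- ratios[order(chrom_rank(ratios$chrom), ratios$start), , drop = FALSE]
  segs <- list()
  offset <- 0
  for (chr in unique(ratios$chrom)) {
    g <- ratios[ratios$chrom == chr, , drop = FALSE]
    ends <- cbs_chromosome(g$log2_ratio, alpha, n_perm, min_width)
    starts <- c(1, utils::head(ends, -1) + 1)
    segs[[chr]] <- data.frame(
      chrom = chr,
      start = g$start[starts],
      end = g$end[ends],
      member_region_count = ends - starts + 1,
      seg_log2 = vapply(
        seq_along(ends),
        function(k) mean(g$log2_ratio[starts[k]:ends[k]]), numeric(1)
      ),
      first_region = offset + starts,
      last_region = offset + ends
    )
    offset <- offset + nrow(g)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Call amplification and deletion on segments
#'
#' A segment is amplified when its mean log2 ratio is strictly greater
#' than `amp_log2` and deleted when strictly less than `del_log2`;
#' otherwise it is neutral.
#'
#' @param segments output of [segment_cbs()].
#' @param amp_log2 amplification threshold (default 1).
#' @param del_log2 deletion threshold (default -0.5).
#' @return segments with a `call` column in
#'   `{amplified, deleted, neutral}`.
#' @export
call_segments <- function(segments, amp_log2 = 1, del_log2 = -0.5) {
  if (any(!is.finite(segments$seg_log2))) stop("seg_log2 must be finite")
  segments$call <- ifelse(segments$seg_log2 > amp_log2, "amplified",
    ifelse(segments$seg_log2 < del_log2, "deleted", "neutral")
  )
  segments
}

#' Gene-level copy-number calls
#'
#' Annotates called segments with the genes whose transcription interval
#' overlaps them. One call is emitted per (gene, overlapping non-neutral
#' segment); genes overlapping only neutral segments get no call. A gene
#' spanning segments with conflicting non-neutral calls yields one call
#' per segment, flagged as a conflict.
#'
#' @param segments called segments from [call_segments()].
#' @param gene_intervals data.frame with `gene`, `chrom`, `start`, `end`
#'   (0-based half-open, same assembly as the regions), or a
#'   `GenomicRanges::GRanges` with a `gene` metadata column.
#' @return data.frame of gene calls: `gene`, `call`, `segment_chrom`,
#'   `segment_start`, `segment_end`, `seg_log2`, `conflict`.
#' @export
annotate_genes <- function(segments, gene_intervals) {
  if (inherits(gene_intervals, "GRanges")) {
    gene_intervals <- data.frame(
      gene = GenomicRanges::mcols(gene_intervals)$gene,
      chrom = as.character(GenomicRanges::seqnames(gene_intervals)),
      start = GenomicRanges::start(gene_intervals) - 1L,
      end = GenomicRanges::end(gene_intervals)
    )
  }
  hot <- segments[segments$call != "neutral", , drop = FALSE]
  empty <- data.frame(
    gene = character(), call = character(), segment_chrom = character(),
    segment_start = integer(), segment_end = integer(),
    seg_log2 = numeric(), conflict = logical()
  )
  if (nrow(hot) == 0 || nrow(gene_intervals) == 0) return(empty)
  unknown <- !gene_intervals$chrom %in% unique(segments$chrom)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " gene(s) on chromosomes absent from segments")
    gene_intervals <- gene_intervals[!unknown, , drop = FALSE]
  }
  if (nrow(gene_intervals) == 0) return(empty)
  seg_gr <- GenomicRanges::GRanges(
    hot$chrom, IRanges::IRanges(hot$start + 1L, hot$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    gene_intervals$chrom,
    IRanges::IRanges(gene_intervals$start + 1L, gene_intervals$end)
  )
  ov <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (length(ov) == 0) return(empty)
  gi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    gene = gene_intervals$gene[gi],
    call = hot$call[si],
    segment_chrom = hot$chrom[si],
    segment_start = hot$start[si],
    segment_end = hot$end[si],
    seg_log2 = hot$seg_log2[si]
  )
  n_calls <- stats::ave(seq_len(nrow(out)), out$gene,
    FUN = function(ix) length(unique(out$call[ix]))
  )
  out$conflict <- n_calls > 1
  rownames(out) <- NULL
  out
}

#' Compare a gene's alteration frequency between two groups
#'
#' Counts samples carrying a given call for a given gene in each group and
#' tests the 2x2 presence/absence table with the two-sided Fisher exact
#' test.
#'
#' @param groupA_calls,groupB_calls named lists mapping sample id to that
#'   sample's gene-call data.frame (as from [annotate_genes()]).
#' @param gene gene symbol.
#' @param call_type `"amplified"` or `"deleted"`.
#' @return list with `countA`, `nA`, `countB`, `nB`, `freqA`, `freqB`
#'   (percent) and `fisher_p`.
#' @export
compare_gene_frequency <- function(groupA_calls, groupB_calls, gene, call_type) {
  if (length(groupA_calls) == 0 || length(groupB_calls) == 0) {
    stop("both groups must be nonempty")
  }
  has_call <- function(df) {
    nrow(df) > 0 && any(df$gene == gene & df$call == call_type)
  }
  cA <- sum(vapply(groupA_calls, has_call, logical(1)))
  cB <- sum(vapply(groupB_calls, has_call, logical(1)))
  nA <- length(groupA_calls)
  nB <- length(groupB_calls)
  ft <- fisher_exact_2x2(cA, nA - cA, cB, nB - cB)
  list(
    countA = cA, nA = nA, countB = cB, nB = nB,
    freqA = 100 * cA / nA, freqB = 100 * cB / nB,
    fisher_p = ft$p_value
  )
}
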