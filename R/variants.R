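SNV_CALLERS <- c("mutect2", "strelka", "varscan", "somaticsniper")
INDEL_CALLERS <- c("strelka", "varscan")
# deterministic preference order when callers disagree on depth (ties on depth)
CALLER_TIE_ORDER <- c("mutect2", "somaticsniper", "strelka", "varscan")

#' Normalize variant alleles
#'
#' Trims bases shared by the reference and alternate alleles so that the
#' same event reported differently by two callers maps to one identity key:
#' the common suffix is removed first, then the common prefix (the position
#' is advanced accordingly). This is the usual left-parsimony convention for
#' indels; SNVs are returned unchanged.
#'
#' @param pos 1-based position vector.
#' @param ref,alt allele strings.
#' @return A data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # trim common suffix, keeping at least one base per allele
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim common prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = pos, ref = ref, alt = alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

check_caller_calls <- function(calls) {
  req <- c(
    "sample_id", "caller", "chrom", "pos", "ref", "alt", "variant_class",
    "tumor_depth", "tumor_alt_reads", "normal_depth", "normal_alt_reads",
    "in_dbsnp", "in_cosmic", "gene", "consequence"
  )
  miss <- setdiff(req, names(calls))
  if (length(miss)) stop("missing call columns: ", paste(miss, collapse = ", "))
  if (any(calls$tumor_alt_reads > calls$tumor_depth) ||
    any(calls$normal_alt_reads > calls$normal_depth)) {
    stop("alt read counts exceed depth")
  }
  bad <- calls$variant_class == "indel" & !(calls$caller %in% INDEL_CALLERS)
  if (any(bad)) stop("indels may only be reported by strelka/varscan")
  invisible(calls)
}

#' Merge per-caller somatic calls into consensus candidates
#'
#' Collapses calls from multiple somatic callers for one tumor/normal pair
#' into one candidate per variant key (chrom, pos, ref, alt after allele
#' normalization). SNVs need support from at least two of the four SNV
#' callers; indels must be reported by both strelka and varscan. Candidates
#' lacking support are annotated `fail_support`, all others start as
#' `candidate` and proceed through [apply_quality_filters()] and
#' [apply_database_filter()].
#'
#' When callers disagree on depths, the read counts of the caller with the
#' highest tumor depth are used (ties broken by a fixed caller order).
#'
#' @param calls data.frame of per-caller calls; one row per (caller,
#'   variant). Required columns: `sample_id`, `caller`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class`, `tumor_depth`, `tumor_alt_reads`,
#'   `normal_depth`, `normal_alt_reads`, `in_dbsnp`, `in_cosmic`, `gene`,
#'   `consequence`.
#' @return data.frame of consensus candidates with `supporting_callers`
#'   (comma-joined), `n_support`, `tumor_vaf`, `normal_vaf` and
#'   `filter_status`.
#' @export
merge_callers <- function(calls) {
  cols <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "variant_class", "key",
    "tumor_depth", "tumor_alt_reads", "normal_depth", "normal_alt_reads",
    "in_dbsnp", "in_cosmic", "gene", "consequence",
    "supporting_callers", "n_support", "tumor_vaf", "normal_vaf",
    "filter_status"
  )
  if (nrow(calls) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  check_caller_calls(calls)
  if (length(unique(calls$sample_id)) > 1) {
    stop("merge_callers expects calls from a single tumor/normal pair")
  }
  norm <- normalize_alleles(calls$pos, calls$ref, calls$alt)
  calls$pos <- norm$pos
  calls$ref <- norm$ref
  calls$alt <- norm$alt
  calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(unique(calls[, c("key", "variant_class")])$key)) {
    stop("inconsistent variant_class for a single variant key")
  }

  split_calls <- split(calls, calls$key)
  rows <- lapply(split_calls, function(g) {
    g <- g[order(-g$tumor_depth, match(g$caller, CALLER_TIE_ORDER)), ]
    rep_row <- g[1, ]
    callers <- sort(unique(g$caller))
    if (rep_row$variant_class == "indel") {
      supported <- all(INDEL_CALLERS %in% callers)
    } else {
      supported <- length(intersect(callers, SNV_CALLERS)) >= 2
    }
    data.frame(
      sample_id = rep_row$sample_id, chrom = rep_row$chrom,
      pos = rep_row$pos, ref = rep_row$ref, alt = rep_row$alt,
      variant_class = rep_row$variant_class, key = rep_row$key,
      tumor_depth = rep_row$tumor_depth,
      tumor_alt_reads = rep_row$tumor_alt_reads,
      normal_depth = rep_row$normal_depth,
      normal_alt_reads = rep_row$normal_alt_reads,
      in_dbsnp = any(g$in_dbsnp), in_cosmic = any(g$in_cosmic),
      gene = rep_row$gene, consequence = rep_row$consequence,
      supporting_callers = paste(callers, collapse = ","),
      n_support = length(callers),
      tumor_vaf = rep_row$tumor_alt_reads / rep_row$tumor_depth,
      normal_vaf = rep_row$normal_alt_reads / rep_row$normal_depth,
      filter_status = if (supported) "candidate" else "fail_support"
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(chrom_rank(out$chrom), out$pos), cols]
}

#' Apply read-depth and allele-frequency filters
#'
#' Retention rules for support-passing candidates, applied in order:
#' both tumor and normal depth must be at least `min_depth` reads
#' (`fail_depth`); tumor VAF must be at least `min_tumor_vaf` with strictly
#' more than `min_tumor_alt` mutated reads (`fail_tumor_vaf`); the matched
#' normal must have VAF at most `max_normal_vaf` or at most
#' `max_normal_alt` mutated reads (`fail_normal_vaf`). Records with zero
#' depth in either sample are rejected with a warning.
#'
#' @param candidates output of [merge_callers()].
#' @param min_depth minimum tumor and normal read depth (default 30).
#' @param min_tumor_vaf minimum tumor variant allele frequency (default 0.10).
#' @param min_tumor_alt tumor mutated-read count must exceed this (default 5).
#' @param max_normal_vaf maximum normal VAF (default 0.01).
#' @param max_normal_alt normal read-count escape clause: a normal with at
#'   most this many mutated reads passes regardless of VAF (default 1).
#' @return candidates with `filter_status` updated.
#' @export
apply_quality_filters <- function(candidates, min_depth = 30,
                                  min_tumor_vaf = 0.10, min_tumor_alt = 5,
                                  max_normal_vaf = 0.01, max_normal_alt = 1) {
  zero <- candidates$tumor_depth == 0 | candidates$normal_depth == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero depth rejected")
    candidates <- candidates[!zero, , drop = FALSE]
  }
  live <- candidates$filter_status %in% c("candidate", "PASS")
  fs <- candidates$filter_status
  fail_depth <- live &
    (candidates$tumor_depth < min_depth | candidates$normal_depth < min_depth)
  fail_tvaf <- live & !fail_depth &
    (candidates$tumor_vaf < min_tumor_vaf |
      candidates$tumor_alt_reads <= min_tumor_alt)
  fail_nvaf <- live & !fail_depth & !fail_tvaf &
    (candidates$normal_vaf > max_normal_vaf &
      candidates$normal_alt_reads > max_normal_alt)
  fs[fail_depth] <- "fail_depth"
  fs[fail_tvaf] <- "fail_tumor_vaf"
  fs[fail_nvaf] <- "fail_normal_vaf"
  candidates$filter_status <- fs
  candidates
}

#' Apply the dbSNP/COSMIC and blocklist filters
#'
#' Known polymorphisms (dbSNP members) are removed unless they are also in
#' COSMIC; variants on a platform artifact blocklist are removed. Survivors
#' of all filters become `PASS`.
#'
#' @param candidates quality-filtered candidates.
#' @param blocklist character vector of variant keys (`chrom:pos:ref:alt`)
#'   known to be recurrent platform artifacts.
#' @return candidates with final `filter_status`.
#' @export
apply_database_filter <- function(candidates, blocklist = character()) {
  live <- candidates$filter_status %in% c("candidate", "PASS")
  fs <- candidates$filter_status
  fail_db <- live & candidates$in_dbsnp & !candidates$in_cosmic
  fail_bl <- live & !fail_db & candidates$key %in% blocklist
  fs[fail_db] <- "fail_dbsnp"
  fs[fail_bl] <- "fail_blocklist"
  fs[live & !fail_db & !fail_bl] <- "PASS"
  candidates$filter_status <- fs
  candidates
}

#' Full consensus variant filtering pipeline
#'
#' Convenience wrapper: [merge_callers()], then [apply_quality_filters()],
#' then [apply_database_filter()].
#'
#' @inheritParams merge_callers
#' @inheritParams apply_database_filter
#' @param ... passed on to [apply_quality_filters()].
#' @return consensus variant data.frame with final `filter_status`.
#' @export
filter_somatic_variants <- function(calls, blocklist = character(), ...) {
  cons <- merge_callers(calls)
  cons <- apply_quality_filters(cons, ...)
  apply_database_filter(cons, blocklist)
}

#' Tumor mutational burden
#'
#' Mutations per megabase: the number of retained somatic variants divided
#' by the number of bases in the coverage space, per million. The high/low
#' status threshold is platform- and disease-specific and must be supplied.
#'
#' @param pass_variants data.frame of PASS variants (or an integer count).
#' @param coverage_bases number of bases in the interrogated coverage space.
#' @param threshold TMB-high cutoff in mutations/Mb (no default: the cutoff
#'   is cohort-calibrated, not universal).
#' @return list with `mutation_count`, `coverage_bases`, `tmb`, `tmb_high`,
#'   `threshold`.
#' @export
compute_tmb <- function(pass_variants, coverage_bases, threshold) {
  if (coverage_bases <= 0) stop("coverage_bases must be positive")
  if (missing(threshold)) stop("a TMB-high threshold must be supplied")
  n <- if (is.data.frame(pass_variants)) {
    sum(pass_variants$filter_status == "PASS")
  } else {
    as.integer(pass_variants)
  }
  tmb <- n / coverage_bases * 1e6
  list(
    mutation_count = n, coverage_bases = coverage_bases,
    tmb = tmb, tmb_high = tmb > threshold, threshold = threshold
  )
}

#' Microsatellite instability score
#'
#' Percentage of evaluated microsatellite sites called somatically unstable.
#' Samples with a score strictly above `cutoff` are MSI-high, otherwise
#' microsatellite stable.
#'
#' @param site_calls character vector (or factor) of per-site calls among
#'   `"stable"`/`"unstable"`.
#' @param cutoff MSI-high threshold on the percentage score (default 3.5).
#' @return list with `n_unstable`, `n_total_sites`, `score`, `status`.
#' @export
compute_msi <- function(site_calls, cutoff = 3.5) {
  site_calls <- as.character(site_calls)
  if (length(site_calls) == 0) stop("empty site table")
  if (!all(site_calls %in% c("stable", "unstable"))) {
    stop("site calls must be 'stable' or 'unstable'")
  }
  n_unstable <- sum(site_calls == "unstable")
  score <- 100 * n_unstable / length(site_calls)
  list(
    n_unstable = n_unstable, n_total_sites = length(site_calls),
    score = score, status = if (score > cutoff) "MSI-H" else "MSS"
  )
}
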