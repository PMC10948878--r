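#' Shared and private mutations for one primary/metastasis pair
#'
#' Intersects the PASS, nonsynonymous variant keys of a matched primary and
#' metastatic sample and expresses shared and private counts as percentages
#' of the union of the two sets.
#'
#' @param primary_pass,met_pass character vectors of variant keys
#'   (`chrom:pos:ref:alt`), or consensus data.frames from
#'   [filter_somatic_variants()] — data.frames are restricted to PASS
#'   nonsynonymous rows automatically.
#' @return list with counts `shared_n`, `primary_private_n`,
#'   `met_private_n` and percentages `shared_pct`, `primary_private_pct`,
#'   `met_private_pct` (the three percentages sum to 100).
#' @export
shared_private_mutations <- function(primary_pass, met_pass) {
  p <- pass_nonsyn_keys(primary_pass)
  m <- pass_nonsyn_keys(met_pass)
  u <- union(p, m)
  if (length(u) == 0) stop("empty union of variant sets")
  shared <- length(intersect(p, m))
  pp <- length(setdiff(p, m))
  mp <- length(setdiff(m, p))
  list(
    shared_n = shared, primary_private_n = pp, met_private_n = mp,
    shared_pct = 100 * shared / length(u),
    primary_private_pct = 100 * pp / length(u),
    met_private_pct = 100 * mp / length(u)
  )
}

pass_nonsyn_keys <- function(x) {
  if (is.data.frame(x)) {
    keep <- x$filter_status == "PASS" & x$consequence == "nonsynonymous"
    unique(x$key[keep])
  } else {
    unique(as.character(x))
  }
}

#' Cohort-level mutation-sharing summary
#'
#' Unweighted mean, minimum and maximum of per-patient shared-mutation
#' percentages, with means stratified by prior-chemotherapy status. A
#' patient with several metastases contributes the mean over their
#' primary-metastasis pairs.
#'
#' @param pairs data.frame with one row per primary-metastasis pair:
#'   `patient_id`, `shared_pct`, `chemo_before_sampling` (logical).
#' @return list with `mean_shared_pct`, `min_shared_pct`,
#'   `max_shared_pct`, `mean_shared_chemo_naive`, `mean_shared_chemo`,
#'   `n_patients`.
#' @export
cohort_sharing_summary <- function(pairs) {
  if (nrow(pairs) == 0) stop("at least one pair is required")
  per_patient <- stats::aggregate(
    shared_pct ~ patient_id, data = pairs, FUN = mean
  )
  chemo <- stats::aggregate(
    chemo_before_sampling ~ patient_id, data = pairs,
    FUN = function(v) any(v)
  )
  per_patient <- merge(per_patient, chemo, by = "patient_id")
  naive <- per_patient$shared_pct[!per_patient$chemo_before_sampling]
  treated <- per_patient$shared_pct[per_patient$chemo_before_sampling]
  list(
    mean_shared_pct = mean(per_patient$shared_pct),
    min_shared_pct = min(per_patient$shared_pct),
    max_shared_pct = max(per_patient$shared_pct),
    mean_shared_chemo_naive = if (length(naive)) mean(naive) else NA_real_,
    mean_shared_chemo = if (length(treated)) mean(treated) else NA_real_,
    n_patients = nrow(per_patient)
  )
}

#' Pathogenic alteration overlap between matched samples
#'
#' Restricts each sample's alterations to those labeled oncogenic or
#' likely oncogenic in a static oncogenicity lookup and reports the shared
#' and metastasis-private pathogenic sets.
#'
#' @param primary_alterations,met_alterations character vectors of
#'   alteration ids of the form `"GENE|class"` (e.g. `"TP53|mutation"`,
#'   `"CDKN2A|deletion"`).
#' @param oncogenicity data.frame with columns `gene`, `alteration`,
#'   `label`; labels `"oncogenic"` and `"likely_oncogenic"` count as
#'   pathogenic.
#' @return list with `shared_pathogenic`, `primary_private_pathogenic`,
#'   `met_private_pathogenic` (character vectors) and `any_shared`.
#' @export
pathogenic_overlap <- function(primary_alterations, met_alterations,
                               oncogenicity) {
  pathogenic <- character(0)
  if (nrow(oncogenicity)) {
    keep <- oncogenicity$label %in% c("oncogenic", "likely_oncogenic")
    pathogenic <- paste(oncogenicity$gene[keep], oncogenicity$alteration[keep],
      sep = "|"
    )
  }
  p <- intersect(unique(primary_alterations), pathogenic)
  m <- intersect(unique(met_alterations), pathogenic)
  shared <- intersect(p, m)
  list(
    shared_pathogenic = shared,
    primary_private_pathogenic = setdiff(p, m),
    met_private_pathogenic = setdiff(m, p),
    any_shared = length(shared) > 0
  )
}

#' Per-gene alteration frequencies by sample group
#'
#' Tabulates, for every gene, the fraction of altered samples among
#' primary and among metastatic samples and tests each gene's 2x2
#' presence/absence table with the two-sided Fisher exact test.
#'
#' @param per_sample_alterations named list mapping sample id to a
#'   character vector of altered gene symbols.
#' @param groups named character vector mapping sample id to `"primary"`
#'   or `"metastatic"`; every sample must be grouped.
#' @return data.frame with `gene`, `count_primary`, `n_primary`,
#'   `count_met`, `n_met`, `freq_primary`, `freq_met` (percent),
#'   `fisher_p`.
#' @export
gene_alteration_frequencies <- function(per_sample_alterations, groups) {
  samples <- names(per_sample_alterations)
  if (!all(samples %in% names(groups))) stop("every sample must be grouped")
  grp <- groups[samples]
  if (!all(grp %in% c("primary", "metastatic"))) {
    stop("groups must be 'primary' or 'metastatic'")
  }
  genes <- sort(unique(unlist(per_sample_alterations)))
  n_p <- sum(grp == "primary")
  n_m <- sum(grp == "metastatic")
  rows <- lapply(genes, function(g) {
    hit <- vapply(per_sample_alterations, function(v) g %in% v, logical(1))
    cp <- sum(hit & grp == "primary")
    cm <- sum(hit & grp == "metastatic")
    data.frame(
      gene = g, count_primary = cp, n_primary = n_p,
      count_met = cm, n_met = n_m,
      freq_primary = 100 * cp / n_p, freq_met = 100 * cm / n_m,
      fisher_p = fisher_exact_2x2(cp, n_p - cp, cm, n_m - cm)$p_value
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(), count_primary = integer(), n_primary = integer(),
      count_met = integer(), n_met = integer(), freq_primary = numeric(),
      freq_met = numeric(), fisher_p = numeric()
    )
  }
  rownames(out) <- NULL
  out
}
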