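#' The six consensus molecular subtype labels
#' @export
CONSENSUS_SUBTYPES <- c("LumP", "LumNS", "LumU", "Stroma-rich", "Ba/Sq", "NE-like")

log_fpkm <- function(x) log2(x + 1)

#' Nearest-centroid consensus molecular subtype classification
#'
#' Correlates each sample's log-transformed expression with each subtype
#' centroid over the genes common to the matrix and the centroid set
#' (Pearson). The label is the centroid with the highest correlation;
#' samples whose best correlation falls below `min_cor` are returned as
#' `"unclassified"`.
#'
#' @param expr genes x samples numeric matrix on the FPKM scale (row names
#'   are gene symbols).
#' @param centroids genes x subtypes numeric matrix of centroid profiles on
#'   the log scale.
#' @param min_cor minimum best Pearson correlation for a confident call
#'   (default 0.15).
#' @param log_transform log2(FPKM + 1)-transform `expr` first (default
#'   TRUE; set FALSE if `expr` is already on the log scale).
#' @return data.frame with `sample`, `label`, `best_correlation`, and one
#'   `cor_<subtype>` column per centroid.
#' @export
classify_subtype <- function(expr, centroids, min_cor = 0.15,
                             log_transform = TRUE) {
  common <- intersect(rownames(expr), rownames(centroids))
  if (length(common) < 2) stop("fewer than 2 classifier genes overlap the matrix")
  x <- expr[common, , drop = FALSE]
  if (log_transform) x <- log_fpkm(x)
  cc <- stats::cor(x, centroids[common, , drop = FALSE], method = "pearson")
  best <- max.col(cc, ties.method = "first")
  best_cor <- cc[cbind(seq_len(nrow(cc)), best)]
  label <- colnames(centroids)[best]
  label[best_cor < min_cor] <- "unclassified"
  out <- data.frame(
    sample = colnames(expr), label = label, best_correlation = best_cor
  )
  cors <- as.data.frame(cc)
  names(cors) <- paste0("cor_", colnames(centroids))
  rownames(out) <- NULL
  cbind(out, cors)
}

#' Within-patient subtype concordance
#'
#' A patient is concordant when all of their classified samples carry the
#' same subtype label. Single-sample patients are concordant by convention
#' and flagged.
#'
#' @param calls data.frame from [classify_subtype()] (needs `sample`,
#'   `label`).
#' @param manifest data.frame with `patient_id` and `sample` columns;
#'   every manifest sample must appear in `calls`.
#' @return data.frame with `patient_id`, `concordant`, `single_sample`,
#'   `labels` (comma-joined in manifest order).
#' @export
subtype_concordance <- function(calls, manifest) {
  missing_s <- setdiff(manifest$sample, calls$sample)
  if (length(missing_s)) {
    stop("unclassified manifest sample(s): ", paste(missing_s, collapse = ", "))
  }
  lab <- calls$label[match(manifest$sample, calls$sample)]
  rows <- lapply(split(seq_len(nrow(manifest)), manifest$patient_id), function(ix) {
    l <- lab[ix]
    data.frame(
      patient_id = manifest$patient_id[ix[1]],
      concordant = length(unique(l)) == 1,
      single_sample = length(l) == 1,
      labels = paste(l, collapse = ",")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partitioning around medoids (k-medoids) clustering
#'
#' Deterministic PAM with Euclidean dissimilarity: the BUILD phase greedily
#' selects k medoids minimizing total dissimilarity, then the SWAP phase
#' exchanges medoid/non-medoid pairs while any swap lowers the objective.
#' All ties break toward the lowest index, so the result is independent of
#' any random state.
#'
#' @param X observations x features numeric matrix.
#' @param k number of clusters, `0 < k < nrow(X)` (k = n is allowed and
#'   returns each point as its own medoid).
#' @return list with `clustering` (integer assignments 1..k), `medoids`
#'   (row indices), `objective` (total within-cluster dissimilarity).
#' @export
pam_cluster <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(!is.finite(X))) stop("X must have no missing values")
  if (k <= 0 || k > n) stop("k must satisfy 0 < k <= n")
  d <- as.matrix(stats::dist(X))
  if (k == n) {
    return(list(clustering = seq_len(n), medoids = seq_len(n), objective = 0))
  }
  # BUILD
  medoids <- which.min(colSums(d))[1]
  while (length(medoids) < k) {
    dn <- apply(d[, medoids, drop = FALSE], 1, min) # current nearest-medoid dist
    gain <- vapply(seq_len(n), function(cand) {
      if (cand %in% medoids) return(-Inf)
      sum(pmax(dn - d[, cand], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain)[1])
  }
  objective <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))
  cost <- objective(medoids)
  # SWAP to local optimum; first strictly improving swap in index order
  repeat {
    improved <- FALSE
    for (mi in seq_along(medoids)) {
      for (cand in seq_len(n)) {
        if (cand %in% medoids) next
        trial <- medoids
        trial[mi] <- cand
        tc <- objective(trial)
        if (tc < cost - 1e-12) {
          medoids <- trial
          cost <- tc
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  medoids <- sort(medoids)
  assign <- apply(d[, medoids, drop = FALSE], 1, which.min)
  list(clustering = as.integer(assign), medoids = medoids, objective = cost)
}

#' T-cell inflamed / depleted immune-contexture classification
#'
#' Restricts the cohort to an immune gene signature, log2(FPKM + 1)
#' transforms and median-centers each gene, optionally appends a reference
#' cohort (e.g. a large bladder-cancer series) for co-clustering, and
#' partitions the samples into two clusters with PAM. The cluster with the
#' higher mean transformed signature expression is labeled "T-cell
#' inflamed", the other "T-cell depleted"; labels are assigned by
#' expression, never by cluster index, so they are invariant to sample
#' order.
#'
#' @param expr genes x samples FPKM matrix for the query cohort.
#' @param signature_genes character vector of signature gene symbols (at
#'   least 2 must be present in `expr`).
#' @param reference_expr optional genes x samples FPKM matrix co-clustered
#'   with the query cohort; calls are returned for query samples only.
#' @return data.frame with `sample`, `label`, `cluster_index`.
#' @export
classify_immune <- function(expr, signature_genes, reference_expr = NULL) {
  genes <- intersect(signature_genes, rownames(expr))
  if (!is.null(reference_expr)) genes <- intersect(genes, rownames(reference_expr))
  if (length(genes) < 2) stop("fewer than 2 signature genes present")
  x <- expr[genes, , drop = FALSE]
  if (!is.null(reference_expr)) {
    x <- cbind(x, reference_expr[genes, , drop = FALSE])
  }
  if (ncol(x) < 2) stop("at least 2 samples are required")
  lx <- log_fpkm(x)
  cx <- lx - apply(lx, 1, stats::median)
  if (nrow(unique(t(cx))) == 1) {
    stop("all samples are identical; two-cluster classification is undefined")
  }
  fit <- pam_cluster(t(cx), k = 2)
  cl_means <- tapply(colMeans(cx), fit$clustering, mean)
  inflamed_cluster <- as.integer(names(cl_means)[which.max(cl_means)])
  label <- ifelse(fit$clustering == inflamed_cluster,
    "T-cell inflamed", "T-cell depleted"
  )
  out <- data.frame(
    sample = colnames(x), label = label, cluster_index = fit$clustering
  )
  out[out$sample %in% colnames(expr), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], character(1))
  sets
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression in decreasing order and
#' a weighted running sum is accumulated: in-set genes add their rank
#' weight (rank from the bottom, raised to `alpha`) normalized by the
#' in-set weight total, out-of-set genes subtract 1/(N - |S|). The
#' enrichment score is the integrated (summed) running sum. Scores are
#' rank-based, hence invariant to monotone transforms of a sample's
#' expression. Each set's scores are then z-standardized across samples.
#'
#' @param expr genes x samples numeric matrix.
#' @param gene_sets named list of gene symbol vectors (e.g. [read_gmt()]).
#' @param alpha rank-weight exponent (default 0.25).
#' @return list with matrices `es` and `z` (gene sets x samples); sets
#'   with no genes in the matrix are omitted with a warning.
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25) {
  n <- nrow(expr)
  keep <- vapply(gene_sets, function(s) any(s %in% rownames(expr)), logical(1))
  if (!all(keep)) {
    warning("omitting ", sum(!keep), " gene set(s) with no genes in the matrix")
    gene_sets <- gene_sets[keep]
  }
  if (length(gene_sets) == 0) stop("no usable gene sets")
  es <- matrix(0, length(gene_sets), ncol(expr),
    dimnames = list(names(gene_sets), colnames(expr))
  )
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE)
    ranked_genes <- rownames(expr)[ord]
    w <- (n:1)^alpha # rank weight in descending-expression order
    for (k in seq_along(gene_sets)) {
      inset <- ranked_genes %in% gene_sets[[k]]
      ns <- sum(inset)
      if (ns == n) {
        es[k, j] <- 0 # every gene in the set: no outside mass to compare to
        next
      }
      step_in <- ifelse(inset, w / sum(w[inset]), 0)
      step_out <- ifelse(inset, 0, 1 / (n - ns))
      es[k, j] <- sum(cumsum(step_in - step_out))
    }
  }
  z <- t(scale(t(es)))
  z[is.nan(z)] <- 0 # constant score across samples
  list(es = es, z = z)
}

#' Compare enrichment scores between sample groups
#'
#' Per gene set, a two-sided rank test between the two groups on the
#' z-standardized enrichment scores: unpaired Mann-Whitney by default, or
#' the Wilcoxon signed-rank test on within-pair differences when
#' `paired = TRUE` (group sizes must then match, in pairing order).
#' P-values are Benjamini-Hochberg adjusted; a set is significant when its
#' q-value is at most `q_threshold`.
#'
#' @param scores result of [ssgsea()].
#' @param groups named character vector mapping sample to `"primary"` or
#'   `"metastatic"` (both groups nonempty).
#' @param paired use the signed-rank test on paired differences.
#' @param q_threshold FDR significance threshold (default 0.25).
#' @return data.frame with `set`, `p`, `q`, `significant`.
#' @export
compare_enrichment <- function(scores, groups, paired = FALSE,
                               q_threshold = 0.25) {
  z <- scores$z
  g <- groups[colnames(z)]
  a <- colnames(z)[g == "primary"]
  b <- colnames(z)[g == "metastatic"]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  p <- vapply(rownames(z), function(s) {
    if (paired) {
      if (length(a) != length(b)) stop("paired test needs equal group sizes")
      d <- z[s, a] - z[s, b]
      if (all(d == 0)) return(1)
      wilcoxon_signed_rank(d)$p_value
    } else {
      if (stats::sd(c(z[s, a], z[s, b])) == 0) return(1)
      mann_whitney_u(z[s, a], z[s, b])$p_value
    }
  }, numeric(1))
  q <- benjamini_hochberg(p)
  data.frame(
    set = rownames(z), p = unname(p), q = q,
    significant = q <= q_threshold, row.names = NULL
  )
}
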