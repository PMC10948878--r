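#' Imaging panel configuration
#'
#' Describes which channels of an imaging mass cytometry panel drive
#' clustering, which are functional readouts excluded from cell-type
#' identification, and which channel pair defines the basal/luminal
#' plasticity ratio.
#'
#' @param clustering_markers channels used for phenotype clustering.
#' @param functional_markers channels recorded but excluded from
#'   clustering (default Ki67, PD1, PDL1, GranzymeB); must be disjoint
#'   from `clustering_markers`.
#' @param plasticity_pair length-2 character vector: the basal and
#'   luminal channel (default KRT5, GATA3).
#' @return list of class `primet_panel`.
#' @export
panel_config <- function(clustering_markers,
                         functional_markers = c("Ki67", "PD1", "PDL1", "GranzymeB"),
                         plasticity_pair = c("KRT5", "GATA3")) {
  if (length(intersect(clustering_markers, functional_markers)) > 0) {
    stop("functional markers must be disjoint from clustering markers")
  }
  if (length(plasticity_pair) != 2) stop("plasticity_pair must name 2 channels")
  structure(
    list(
      clustering_markers = clustering_markers,
      functional_markers = functional_markers,
      plasticity_pair = plasticity_pair
    ),
    class = "primet_panel"
  )
}

#' Default imaging panel
#'
#' The marker panel emitted by [sim_singlecell_cohort()]: tumor markers
#' (panKeratin, KRT5, GATA3, Ecadherin), immune and stromal lineage
#' markers, and the four functional markers excluded from clustering.
#'
#' @return A [panel_config()] object.
#' @export
default_panel <- function() {
  panel_config(
    clustering_markers = c(
      "panKeratin", "KRT5", "GATA3", "Ecadherin", "CD3", "CD4", "CD8a",
      "FOXP3", "CD68", "CD11b", "CD11c", "CD16", "CD31", "aSMA", "Vimentin"
    )
  )
}

MORPHOLOGY_FEATURES <- c(
  "area", "perimeter", "major_axis_length", "eccentricity", "solidity"
)

#' Standardize single-cell marker intensities
#'
#' Quality filtering and standardization of a quantified cell table:
#' cells with solidity exactly 1 (perfectly convex objects, typically
#' segmentation artifacts) are excluded; intensities are log(1 + x)
#' transformed; each marker is z-scored within each image, the signal is
#' capped at -3 and 3, and each marker is then centered and scaled
#' globally. Markers constant within an image (including single-cell
#' images) get z-score 0 there.
#'
#' @param cells data.frame with `sample_id`, `image_id`, `batch_id`, one
#'   column per panel marker, and the morphology columns `area`,
#'   `perimeter`, `major_axis_length`, `eccentricity`, `solidity`.
#' @param panel a [panel_config()].
#' @return list with `features` (kept cells x clustering markers, fully
#'   standardized), `all_markers` (same rows, every panel marker incl.
#'   functional), and `kept` (row indices into `cells`).
#' @export
preprocess_cells <- function(cells, panel) {
  markers <- c(panel$clustering_markers, panel$functional_markers)
  miss <- setdiff(markers, names(cells))
  if (length(miss)) stop("cells table lacks channel(s): ", paste(miss, collapse = ", "))
  kept <- which(cells$solidity != 1)
  x <- log1p(as.matrix(cells[kept, markers, drop = FALSE]))
  image <- cells$image_id[kept]
  single <- names(which(table(image) == 1))
  if (length(single)) {
    warning(length(single), " single-cell image(s): z-scores set to 0 there")
  }
  for (img in unique(image)) {
    rows <- which(image == img)
    mu <- colMeans(x[rows, , drop = FALSE])
    sdv <- apply(x[rows, , drop = FALSE], 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf # constant marker -> z = 0
    x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, mu), 2, sdv, "/")
  }
  x[x > 3] <- 3
  x[x < -3] <- -3
  x <- scale(x)
  x[is.nan(x)] <- 0 # globally constant marker
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(
    features = x[, panel$clustering_markers, drop = FALSE],
    all_markers = x,
    kept = kept
  )
}

#' Empirical-Bayes batch correction
#'
#' Removes per-batch location/scale effects from a feature matrix with the
#' parametric empirical-Bayes adjustment of ComBat, then restores each
#' feature's pre-correction global mean (location re-centering contract).
#' A single-batch input is returned unchanged.
#'
#' @param features cells x features numeric matrix.
#' @param batch_ids batch label per cell; every batch needs at least 2
#'   cells.
#' @return adjusted matrix of the same shape.
#' @export
correct_batch <- function(features, batch_ids) {
  batch_ids <- as.character(batch_ids)
  if (length(batch_ids) != nrow(features)) stop("one batch id per cell required")
  if (any(table(batch_ids) < 2)) stop("every batch needs at least 2 cells")
  if (length(unique(batch_ids)) == 1) return(features)
  pre_mean <- colMeans(features)
  adj <- t(suppressMessages(
    sva::ComBat(dat = t(features), batch = batch_ids)
  ))
  adj <- sweep(adj, 2, colMeans(adj) - pre_mean)
  dimnames(adj) <- dimnames(features)
  adj
}

# exact k nearest neighbors (squared Euclidean) of each query row among
# reference rows, via the compiled brute-force scan; returns neighbor ids
knn_exact <- function(query, ref, k, ref_ids, query_ids) {
  k <- min(k, nrow(ref))
  .knn_brute(query, ref, as.integer(k), as.integer(query_ids),
    as.integer(ref_ids))
}

#' Batch-balanced neighbor graph, Leiden clustering
#'
#' Reduces the corrected feature matrix to `n_pcs` principal components,
#' builds a batch-balanced k-nearest-neighbor graph (each cell takes its
#' `neighbors_within_batch` nearest neighbors from every batch, so batches
#' are forced to mix), and clusters the cells with the Leiden algorithm at
#' the given resolution (modularity objective).
#'
#' @param features cells x features matrix (already batch-corrected).
#' @param batch_ids batch label per cell.
#' @param n_pcs number of principal components (default 30; truncated with
#'   a warning when the matrix has fewer features).
#' @param neighbors_within_batch neighbors drawn from each batch
#'   (default 3).
#' @param resolution Leiden resolution parameter (default 0.5).
#' @param seed integer seed for the Leiden refinement.
#' @return list with `clusters` (integer labels 1..K), `pca` (the score
#'   matrix), and `graph` (the igraph object).
#' @export
embed_and_cluster <- function(features, batch_ids, n_pcs = 30,
                              neighbors_within_batch = 3, resolution = 0.5,
                              seed = 1L) {
  n <- nrow(features)
  if (n_pcs > ncol(features)) {
    warning("n_pcs truncated to the number of features (", ncol(features), ")")
    n_pcs <- ncol(features)
  }
  if (n <= n_pcs) stop("need more cells than principal components")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  batch_ids <- as.character(batch_ids)
  edges <- vector("list", length(unique(batch_ids)))
  cell_idx <- seq_len(n)
  for (bi in seq_along(sort(unique(batch_ids)))) {
    b <- sort(unique(batch_ids))[bi]
    ref_rows <- which(batch_ids == b)
    nb <- knn_exact(
      pc, pc[ref_rows, , drop = FALSE],
      k = neighbors_within_batch,
      ref_ids = ref_rows, query_ids = cell_idx
    )
    edges[[bi]] <- cbind(rep(cell_idx, ncol(nb)), as.vector(nb))
  }
  em <- do.call(rbind, edges)
  em <- em[!is.na(em[, 2]), , drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_edgelist(em, directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_leiden(
    g,
    objective_function = "modularity",
    resolution = resolution, n_iterations = 5
  )
  list(clusters = as.integer(igraph::membership(comm)), pca = pc, graph = g)
}

#' Per-cluster mean marker profiles
#'
#' Average standardized intensity of every panel marker (including the
#' functional markers excluded from clustering) per cluster, with cell
#' counts.
#'
#' @param all_markers standardized cells x markers matrix
#'   (`preprocess_cells()$all_markers`).
#' @param clusters integer cluster label per cell.
#' @return data.frame with `cluster`, `n_cells`, and one `mean_<marker>`
#'   column per marker.
#' @export
cluster_profiles <- function(all_markers, clusters) {
  cl <- sort(unique(clusters))
  prof <- t(vapply(
    cl,
    function(k) colMeans(all_markers[clusters == k, , drop = FALSE]),
    numeric(ncol(all_markers))
  ))
  out <- data.frame(cluster = cl, n_cells = as.integer(table(factor(clusters, levels = cl))))
  means <- as.data.frame(prof)
  names(means) <- paste0("mean_", colnames(all_markers))
  cbind(out, means)
}

#' Default metacluster rule table
#'
#' An ordered marker-logic table aggregating fine-grained clusters into
#' named cell populations (tumor luminal/basal, T-cell subsets,
#' macrophage, immunosuppressive myeloid, fibroblast, endothelial). The
#' table is a reconstruction of a typical urothelial-carcinoma panel
#' ontogeny and is meant to be edited per panel.
#'
#' @return data.frame with `label`, `markers_high`, `markers_low`
#'   (semicolon-separated), `threshold`.
#' @export
default_metacluster_rules <- function() {
  data.frame(
    label = c(
      "Treg", "CD8 T cell", "CD4 T cell",
      "Immunosuppressive myeloid", "Macrophage",
      "Tumor (basal)", "Tumor (luminal)",
      "Fibroblast", "Endothelial"
    ),
    markers_high = c(
      "CD3;FOXP3", "CD3;CD8a", "CD3;CD4",
      "CD11b;CD68;GranzymeB;PDL1", "CD68;CD11b",
      "KRT5", "panKeratin;GATA3",
      "aSMA;Vimentin", "CD31"
    ),
    markers_low = c(
      "", "", "FOXP3",
      "", "GranzymeB",
      "GATA3", "",
      "panKeratin", ""
    ),
    threshold = 0.5
  )
}

#' Assign metacluster labels to cluster profiles
#'
#' Applies an ordered rule table: a cluster matches a rule when its mean
#' standardized intensity is above the rule's threshold for every
#' `markers_high` channel and below it for every `markers_low` channel.
#' The first matching rule wins; clusters matching no rule are labeled
#' `"unassigned"`.
#'
#' @param profiles data.frame from [cluster_profiles()].
#' @param rules rule table as in [default_metacluster_rules()].
#' @return `profiles` with a `metacluster` column.
#' @export
assign_metaclusters <- function(profiles, rules = default_metacluster_rules()) {
  marker_cols <- sub("^mean_", "", grep("^mean_", names(profiles), value = TRUE))
  split_markers <- function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
  }
  cited <- unique(unlist(lapply(
    c(rules$markers_high, rules$markers_low), split_markers
  )))
  bad <- setdiff(cited, marker_cols)
  if (length(bad)) stop("rule cites unknown marker(s): ", paste(bad, collapse = ", "))
  labels <- rep("unassigned", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    for (r in seq_len(nrow(rules))) {
      hi <- split_markers(rules$markers_high[r])
      lo <- split_markers(rules$markers_low[r])
      th <- rules$threshold[r]
      vals_hi <- unlist(profiles[i, paste0("mean_", hi)])
      vals_lo <- unlist(profiles[i, paste0("mean_", lo)])
      if (all(vals_hi > th) && all(vals_lo <= th)) {
        labels[i] <- rules$label[r]
        break
      }
    }
  }
  profiles$metacluster <- labels
  profiles
}

#' Basal/luminal plasticity ratio
#'
#' Per-cell log2 ratio of the basal (KRT5) to the luminal (GATA3) channel
#' on raw intensities, with a pseudocount; 0 means equal expression of the
#' two markers. Returns the per-cell values and a per-sample five-number
#' summary.
#'
#' @param cells quantified cell table (raw intensities).
#' @param panel a [panel_config()]; `plasticity_pair` names the two
#'   channels.
#' @param epsilon pseudocount in raw intensity units (default 0.01).
#' @return list with `per_cell` (data.frame `sample_id`, `image_id`,
#'   `log_ratio`) and `per_sample` (data.frame `sample_id`, `n`, `min`,
#'   `q1`, `median`, `q3`, `max`).
#' @export
plasticity_ratio <- function(cells, panel = default_panel(), epsilon = 0.01) {
  pair <- panel$plasticity_pair
  miss <- setdiff(pair, names(cells))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  lr <- log2((cells[[pair[1]]] + epsilon) / (cells[[pair[2]]] + epsilon))
  per_cell <- data.frame(
    sample_id = cells$sample_id, image_id = cells$image_id, log_ratio = lr
  )
  per_sample <- do.call(rbind, lapply(split(lr, cells$sample_id), function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(n = length(v), min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  per_sample <- cbind(sample_id = rownames(per_sample), per_sample)
  rownames(per_sample) <- NULL
  list(per_cell = per_cell, per_sample = per_sample)
}

#' Median plasticity shift within matched pairs
#'
#' Difference of per-sample median log ratios (metastasis minus primary)
#' for each patient in a pairing manifest.
#'
#' @param per_sample the `per_sample` table from [plasticity_ratio()].
#' @param pairs data.frame with `patient_id`, `primary_sample_id`,
#'   `met_sample_id`.
#' @return data.frame with `patient_id`, `median_primary`, `median_met`,
#'   `delta_median`.
#' @export
plasticity_pair_delta <- function(per_sample, pairs) {
  med <- stats::setNames(per_sample$median, per_sample$sample_id)
  data.frame(
    patient_id = pairs$patient_id,
    median_primary = unname(med[pairs$primary_sample_id]),
    median_met = unname(med[pairs$met_sample_id]),
    delta_median = unname(med[pairs$met_sample_id] - med[pairs$primary_sample_id])
  )
}

#' Metacluster infiltration statistics
#'
#' Counts cells per (image, metacluster) — including zero counts —
#' averages the counts per sample, and compares per-sample means between
#' immune-inflamed and immune-depleted samples with the two-sided
#' Mann-Whitney test, one test per metacluster.
#'
#' @param cell_meta data.frame with `sample_id`, `image_id`,
#'   `metacluster` (one row per clustered cell).
#' @param groups named character vector mapping sample to `"inflamed"` or
#'   `"depleted"`.
#' @return list with `per_image` (counts), `per_sample` (means), and
#'   `tests` (data.frame `metacluster`, `mean_inflamed`, `mean_depleted`,
#'   `p`).
#' @export
infiltration_stats <- function(cell_meta, groups) {
  if (any(is.na(cell_meta$metacluster))) stop("every cell must be metacluster-labeled")
  img_sample <- unique(cell_meta[, c("sample_id", "image_id")])
  metas <- sort(unique(cell_meta$metacluster))
  counts <- as.data.frame(table(
    image_id = factor(cell_meta$image_id, levels = img_sample$image_id),
    metacluster = factor(cell_meta$metacluster, levels = metas)
  ), responseName = "n_cells")
  counts$sample_id <- img_sample$sample_id[
    match(counts$image_id, img_sample$image_id)
  ]
  per_sample <- stats::aggregate(
    n_cells ~ sample_id + metacluster, data = counts, FUN = mean
  )
  names(per_sample)[3] <- "mean_cells_per_image"
  g <- groups[as.character(per_sample$sample_id)]
  tests <- do.call(rbind, lapply(metas, function(m) {
    rows <- per_sample$metacluster == m
    xi <- per_sample$mean_cells_per_image[rows & g == "inflamed"]
    xd <- per_sample$mean_cells_per_image[rows & g == "depleted"]
    p <- if (length(xi) && length(xd)) mann_whitney_u(xi, xd)$p_value else NA_real_
    data.frame(
      metacluster = m,
      mean_inflamed = if (length(xi)) mean(xi) else NA_real_,
      mean_depleted = if (length(xd)) mean(xd) else NA_real_,
      p = p
    )
  }))
  rownames(tests) <- NULL
  list(per_image = counts, per_sample = per_sample, tests = tests)
}

#' Full single-cell phenotyping pipeline
#'
#' [preprocess_cells()], [correct_batch()] with a post-correction global
#' rescale, [embed_and_cluster()], [cluster_profiles()] and
#' [assign_metaclusters()] in one call.
#'
#' @inheritParams preprocess_cells
#' @inheritParams embed_and_cluster
#' @param rules metacluster rule table.
#' @return list with `cells` (kept rows of the input plus `cluster` and
#'   `metacluster`), `profiles`, `features`, `kept`.
#' @export
phenotype_cells <- function(cells, panel = default_panel(),
                            rules = default_metacluster_rules(),
                            n_pcs = 30, neighbors_within_batch = 3,
                            resolution = 0.5, seed = 1L) {
  prep <- preprocess_cells(cells, panel)
  feat <- correct_batch(prep$features, cells$batch_id[prep$kept])
  feat <- scale(feat)
  feat[is.nan(feat)] <- 0
  emb <- embed_and_cluster(
    feat, cells$batch_id[prep$kept],
    n_pcs = min(n_pcs, ncol(feat)),
    neighbors_within_batch = neighbors_within_batch,
    resolution = resolution, seed = seed
  )
  prof <- assign_metaclusters(
    cluster_profiles(prep$all_markers, emb$clusters), rules
  )
  out <- cells[prep$kept, , drop = FALSE]
  out$cluster <- emb$clusters
  out$metacluster <- prof$metacluster[match(emb$clusters, prof$cluster)]
  list(cells = out, profiles = prof, features = feat, kept = prep$kept)
}
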