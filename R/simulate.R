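#' Artifact rate configuration for the variant-call generator
#'
#' Rates (fractions of the true-variant count) of the five decoy classes
#' planted by [sim_variant_calls()]. Each decoy violates exactly one
#' retention rule: tumor/normal depth below 30, tumor VAF/alt-read support
#' below threshold, germline contamination in the matched normal, dbSNP
#' membership without COSMIC membership, or presence on the platform
#' artifact blocklist.
#'
#' @param low_depth,low_vaf,germline,dbsnp_only,blocklist rates in \[0, 1\].
#' @return named list of rates.
#' @export
artifact_config <- function(low_depth = 0, low_vaf = 0, germline = 0,
                            dbsnp_only = 0, blocklist = 0) {
  rates <- c(
    low_depth = low_depth, low_vaf = low_vaf, germline = germline,
    dbsnp_only = dbsnp_only, blocklist = blocklist
  )
  if (any(rates < 0 | rates > 1)) stop("artifact rates must lie in [0, 1]")
  as.list(rates)
}

BASES <- c("A", "C", "G", "T")

# map toy-exome site indices to (chrom, pos); 1-based positions, 22 autosomes
toy_exome_site <- function(site, exome_size, n_chrom = 22) {
  per_chrom <- ceiling(exome_size / n_chrom)
  chrom <- as.character((site - 1) %/% per_chrom + 1)
  pos <- ((site - 1) %% per_chrom) * 150L + 101L
  list(chrom = chrom, pos = pos)
}

#' Simulate per-caller somatic variant calls for a matched pair
#'
#' Generates multi-caller call tables for one primary/metastasis tumor
#' pair with planted shared and private true variants plus decoy records
#' of the named artifact classes. Variant positions are drawn without
#' replacement from a toy exome so variant keys are unique. True somatic
#' SNVs are reported by 2-4 of the four SNV callers, indels by both indel
#' callers; depths are Poisson (mean `depth_mean`, floored so every filter
#' margin holds) and tumor VAFs uniform in \[0.15, 0.6\]. Every decoy
#' violates exactly one retention rule and the truth table records the
#' class of every record.
#'
#' @param n_shared,n_primary_private,n_met_private nonnegative counts of
#'   true variants shared / private to each sample.
#' @param artifacts an [artifact_config()].
#' @param seed integer seed.
#' @param indel_fraction fraction of true variants simulated as indels
#'   (default 0.1).
#' @param depth_mean Poisson depth mean (default 100).
#' @param exome_size number of candidate sites in the toy exome
#'   (default 10000).
#' @param sample_prefix sample-name stem; samples are `<stem>_P` and
#'   `<stem>_M`.
#' @return list with `calls` (per-caller long table over both samples),
#'   `blocklist` (keys of planted blocklist decoys), and `truth`
#'   (data.frame `key`, `sample_id`, `class`; classes `shared`,
#'   `primary_private`, `met_private` or the artifact class), plus
#'   `shared_fraction`.
#' @export
sim_variant_calls <- function(n_shared, n_primary_private, n_met_private,
                              artifacts = artifact_config(), seed = 1L,
                              indel_fraction = 0.1, depth_mean = 100,
                              exome_size = 10000L, sample_prefix = "SIM") {
  counts <- c(n_shared, n_primary_private, n_met_private)
  if (any(counts < 0)) stop("variant counts must be nonnegative")
  set.seed(seed)
  n_true <- sum(counts)
  n_decoy <- vapply(artifacts, function(r) round(r * n_true), numeric(1))
  n_records <- n_true + sum(n_decoy)
  if (n_records > exome_size) stop("toy exome too small for requested counts")
  sites <- sample.int(exome_size, n_records)
  loc <- toy_exome_site(sites, exome_size)

  classes <- c(
    rep("shared", n_shared),
    rep("primary_private", n_primary_private),
    rep("met_private", n_met_private),
    rep(names(n_decoy), n_decoy)
  )
  n_all <- length(classes)
  is_true <- seq_len(n_all) <= n_true
  is_indel <- is_true & stats::runif(n_all) < indel_fraction

  ref <- sample(BASES, n_all, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1)))
  alt[is_indel] <- paste0(ref[is_indel], sample(BASES, sum(is_indel), TRUE))
  vclass <- ifelse(is_indel, "indel", "SNV")
  key <- variant_key(loc$chrom, loc$pos, ref, alt)

  # decoys on alternating samples; shared on both
  primary_id <- paste0(sample_prefix, "_P")
  met_id <- paste0(sample_prefix, "_M")
  owner <- character(n_all)
  owner[classes == "primary_private"] <- primary_id
  owner[classes == "met_private"] <- met_id
  decoy_idx <- which(!is_true)
  owner[decoy_idx] <- rep(c(primary_id, met_id), length.out = length(decoy_idx))

  rdepth <- function(n, floor_at) pmax(stats::rpois(n, depth_mean), floor_at)
  tumor_depth <- rdepth(n_all, 40)
  normal_depth <- rdepth(n_all, 30)
  vaf <- stats::runif(n_all, 0.15, 0.6)
  normal_alt <- stats::rbinom(n_all, 1, 0.1)
  in_dbsnp <- stats::runif(n_all) < 0.10 # known hotspots: also in COSMIC
  in_cosmic <- in_dbsnp

  cls <- classes
  tumor_depth[cls == "low_depth"] <- sample(10:29, sum(cls == "low_depth"), TRUE)
  vaf[cls == "low_vaf"] <- stats::runif(sum(cls == "low_vaf"), 0.02, 0.08)
  in_dbsnp[cls == "dbsnp_only"] <- TRUE
  in_cosmic[cls == "dbsnp_only"] <- FALSE
  germ <- cls == "germline"
  blocklist <- key[cls == "blocklist"]

  build_rows <- function(i, sample_id) {
    callers <- if (is_indel[i]) {
      INDEL_CALLERS
    } else {
      sample(SNV_CALLERS, sample(2:4, 1))
    }
    td <- if (is_true[i]) pmax(stats::rpois(length(callers), tumor_depth[i]), 40) else rep(tumor_depth[i], length(callers))
    ta <- pmax(6, round(vaf[i] * td))
    if (cls[i] == "low_vaf") ta <- pmax(1, round(vaf[i] * td))
    nd <- rep(normal_depth[i], length(callers))
    na_ <- rep(normal_alt[i], length(callers))
    if (germ[i]) na_ <- pmax(2, round(0.05 * nd))
    data.frame(
      sample_id = sample_id, caller = callers,
      chrom = loc$chrom[i], pos = loc$pos[i], ref = ref[i], alt = alt[i],
      variant_class = vclass[i],
      tumor_depth = td, tumor_alt_reads = pmin(ta, td),
      normal_depth = nd, normal_alt_reads = pmin(na_, nd),
      in_dbsnp = in_dbsnp[i], in_cosmic = in_cosmic[i],
      gene = paste0("GENE", sites[i] %% 500), consequence = "nonsynonymous"
    )
  }

  rows <- list()
  truth_rows <- list()
  for (i in seq_len(n_all)) {
    targets <- if (cls[i] == "shared") c(primary_id, met_id) else owner[i]
    for (s in targets) {
      rows[[length(rows) + 1]] <- build_rows(i, s)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        key = key[i], sample_id = s, class = cls[i]
      )
    }
  }
  calls <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  rownames(calls) <- rownames(truth) <- NULL
  list(
    calls = calls, blocklist = blocklist, truth = truth,
    shared_fraction = if (n_true > 0) n_shared / n_true else NA_real_,
    seed = seed
  )
}

#' Simulate tumor/normal capture-region read counts
#'
#' Generates a sorted, non-overlapping capture-region track over 22 toy
#' chromosomes with copy-number segments planted as multiplicative shifts
#' of the tumor expectation: within a planted segment the expected
#' normalized tumor/normal ratio is `2^true_log2`, elsewhere 1. Counts are
#' Poisson draws around the expectation (`noise = "poisson"`) or the
#' expectations themselves (`noise = "none"`). Per-sample totals are
#' returned as fixed library-size constants so normalization is unbiased.
#'
#' @param n_regions_per_chrom regions per chromosome.
#' @param planted_segments data.frame `chrom`, `start`, `end`,
#'   `true_log2`; non-overlapping and sorted within chromosome. May be
#'   empty (flat genome).
#' @param depth_model list with `mean` (expected normal-region reads,
#'   default 100) and `noise` (`"poisson"` or `"none"`).
#' @param seed integer seed.
#' @param n_chrom number of chromosomes (default 22).
#' @return list with `regions` (chrom, start, end, tumor_reads,
#'   normal_reads), `tumor_total`, `normal_total`, and `truth` (the
#'   per-region `true_log2`).
#' @export
sim_capture_counts <- function(n_regions_per_chrom, planted_segments =
                                 data.frame(
                                   chrom = character(), start = integer(),
                                   end = integer(), true_log2 = numeric()
                                 ),
                               depth_model = list(mean = 100, noise = "poisson"),
                               seed = 1L, n_chrom = 22) {
  set.seed(seed)
  spacing <- 1000L
  width <- 120L
  regions <- do.call(rbind, lapply(as.character(seq_len(n_chrom)), function(chr) {
    start <- (seq_len(n_regions_per_chrom) - 1L) * spacing
    data.frame(chrom = chr, start = start, end = start + width)
  }))
  true_log2 <- rep(0, nrow(regions))
  if (nrow(planted_segments)) {
    for (chr in unique(planted_segments$chrom)) {
      ps <- planted_segments[planted_segments$chrom == chr, , drop = FALSE]
      ps <- ps[order(ps$start), , drop = FALSE]
      if (nrow(ps) > 1 && any(ps$start[-1] < ps$end[-nrow(ps)])) {
        stop("planted segments must be non-overlapping")
      }
      mid <- (regions$start + regions$end) / 2
      for (r in seq_len(nrow(ps))) {
        hit <- regions$chrom == chr & mid >= ps$start[r] & mid < ps$end[r]
        true_log2[hit] <- ps$true_log2[r]
      }
    }
  }
  mu_n <- depth_model$mean
  mu_t <- mu_n * 2^true_log2
  if (identical(depth_model$noise, "none")) {
    regions$tumor_reads <- mu_t
    regions$normal_reads <- rep(mu_n, nrow(regions))
  } else {
    regions$tumor_reads <- stats::rpois(nrow(regions), mu_t)
    regions$normal_reads <- stats::rpois(nrow(regions), mu_n)
  }
  list(
    regions = regions,
    tumor_total = mu_n * nrow(regions),
    normal_total = mu_n * nrow(regions),
    truth = data.frame(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      true_log2 = true_log2
    ),
    seed = seed
  )
}

#' Simulate subtype centroid profiles
#'
#' Block-structured centroids on the log2 expression scale: every subtype
#' shares a common baseline and is elevated on its own gene block, giving
#' well-separated but positively correlated centroids, as real
#' transcriptomic subtype centroids are.
#'
#' @param n_genes number of classifier genes (default 300).
#' @param subtypes centroid names (default the six consensus classes).
#' @param shift block elevation in log2 units (default 3).
#' @param seed integer seed.
#' @return genes x subtypes matrix.
#' @export
sim_centroids <- function(n_genes = 300, subtypes = CONSENSUS_SUBTYPES,
                          shift = 3, seed = 1L) {
  set.seed(seed)
  base <- stats::rnorm(n_genes, mean = 5, sd = 1.5)
  k <- length(subtypes)
  block <- cut(seq_len(n_genes), k, labels = FALSE)
  m <- matrix(base, n_genes, k, dimnames = list(
    paste0("G", seq_len(n_genes)), subtypes
  ))
  for (j in seq_len(k)) m[block == j, j] <- m[block == j, j] + shift
  m
}

#' Simulate an FPKM expression cohort with known subtype and immune labels
#'
#' Each sample's log2 expression is its subtype centroid plus Gaussian
#' noise; immune-inflamed samples additionally get `signature_shift` added
#' to a dedicated block of immune signature genes (absent from the
#' centroids). Values are back-transformed to nonnegative FPKM-like units
#' via `2^x - 1`.
#'
#' @param centroids genes x subtypes log2-scale matrix
#'   (e.g. [sim_centroids()]).
#' @param labels character vector of subtype labels, one per sample; each
#'   must name a centroid column.
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.5).
#' @param signature_shift log2 shift added to signature genes of inflamed
#'   samples (default 0: no immune structure).
#' @param immune_labels optional `"inflamed"`/`"depleted"` per sample;
#'   default alternates.
#' @param n_signature number of immune signature genes (default 50).
#' @param seed integer seed.
#' @return list with `fpkm` (genes x samples), `signature_genes`, and
#'   `truth` (data.frame `sample`, `subtype`, `immune`).
#' @export
sim_expression_cohort <- function(centroids, labels, noise_sd = 0.5,
                                  signature_shift = 0, immune_labels = NULL,
                                  n_signature = 50, seed = 1L) {
  if (!all(labels %in% colnames(centroids))) {
    stop("unknown subtype label(s): ",
      paste(setdiff(labels, colnames(centroids)), collapse = ", "))
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  n <- length(labels)
  samples <- sprintf("S%03d", seq_len(n))
  if (is.null(immune_labels)) {
    immune_labels <- rep(c("inflamed", "depleted"), length.out = n)
  }
  sig_genes <- paste0("TCI", seq_len(n_signature))
  sig_base <- stats::setNames(stats::rnorm(n_signature, mean = 3, sd = 1), sig_genes)
  logx <- matrix(0, nrow(centroids) + n_signature, n, dimnames = list(
    c(rownames(centroids), sig_genes), samples
  ))
  for (j in seq_len(n)) {
    e <- c(centroids[, labels[j]], sig_base)
    e[sig_genes] <- e[sig_genes] +
      if (immune_labels[j] == "inflamed") signature_shift else 0
    logx[, j] <- e + stats::rnorm(length(e), sd = noise_sd)
  }
  fpkm <- pmax(2^logx - 1, 0)
  list(
    fpkm = fpkm, signature_genes = sig_genes,
    truth = data.frame(sample = samples, subtype = labels, immune = immune_labels),
    seed = seed
  )
}

#' Default single-cell population profiles
#'
#' Log-normal marker models (meanlog, sdlog per channel) and morphology
#' models for the cell populations of a urothelial tumor microenvironment,
#' matching [default_panel()]. Markers a population expresses sit ~7 sd
#' (log scale) above the background level.
#'
#' @param panel a [panel_config()] naming every channel to model.
#' @return named list of population profiles, each a list with `markers`
#'   (named list of `c(meanlog, sdlog)`) and `morphology`.
#' @export
default_population_profiles <- function(panel = default_panel()) {
  all_markers <- c(panel$clustering_markers, panel$functional_markers)
  hi <- c(3, 0.4)
  mid <- c(1.5, 0.4)
  lo <- c(0, 0.4)
  morpho <- list(
    area = c(log(80), 0.3), perimeter = c(log(35), 0.2),
    major_axis_length = c(log(12), 0.25),
    eccentricity = c(0.2, 0.9), solidity = c(0.85, 0.99)
  )
  make <- function(high = character(), midm = character()) {
    markers <- stats::setNames(rep(list(lo), length(all_markers)), all_markers)
    for (m in high) markers[[m]] <- hi
    for (m in midm) markers[[m]] <- mid
    list(markers = markers, morphology = morpho)
  }
  list(
    tumor_luminal = make(c("panKeratin", "GATA3", "Ecadherin")),
    tumor_basal = make(c("panKeratin", "KRT5"), "Ecadherin"),
    cd8_t = make(c("CD3", "CD8a")),
    cd4_t = make(c("CD3", "CD4")),
    treg = make(c("CD3", "CD4", "FOXP3")),
    macrophage = make(c("CD68", "CD11b", "CD16")),
    myeloid_suppressor = make(c("CD11b", "CD68", "GranzymeB", "PDL1"), "CD11c"),
    fibroblast = make(c("aSMA", "Vimentin")),
    endothelial = make(c("CD31"), "Vimentin")
  )
}

#' Simulate a single-cell imaging cohort with known population labels
#'
#' Draws cells from named population profiles across samples, images and
#' batches. Marker intensities are log-normal with per-batch
#' multiplicative effects; morphology features are simulated directly. A
#' configurable fraction of cells gets solidity exactly 1 to emulate
#' segmentation artifacts.
#'
#' @param population_profiles named list of profiles (see
#'   [default_population_profiles()]); each must model every panel
#'   channel.
#' @param n_cells_per_image cells per image.
#' @param images_per_sample images per sample.
#' @param n_samples number of samples.
#' @param batch_effects named list: batch id -> named numeric vector of
#'   per-marker multiplicative factors (scalars recycle over markers).
#'   Default one batch with factor 1. Samples are assigned to batches
#'   round-robin.
#' @param mixture population sampling probabilities (default uniform).
#' @param solidity_one_rate probability a cell's solidity is exactly 1
#'   (default 0).
#' @param panel a [panel_config()].
#' @param seed integer seed.
#' @return list with `cells` (one row per cell: ids, markers, morphology)
#'   and `truth` (data.frame `cell_id`, `population`).
#' @export
sim_singlecell_cohort <- function(population_profiles = default_population_profiles(),
                                  n_cells_per_image = 200,
                                  images_per_sample = 2, n_samples = 4,
                                  batch_effects = list(B1 = 1),
                                  mixture = NULL, solidity_one_rate = 0,
                                  panel = default_panel(), seed = 1L) {
  set.seed(seed)
  all_markers <- c(panel$clustering_markers, panel$functional_markers)
  for (pn in names(population_profiles)) {
    miss <- setdiff(all_markers, names(population_profiles[[pn]]$markers))
    if (length(miss)) {
      stop("profile '", pn, "' lacks marker(s): ", paste(miss, collapse = ", "))
    }
  }
  pops <- names(population_profiles)
  if (is.null(mixture)) mixture <- rep(1 / length(pops), length(pops))
  batches <- names(batch_effects)
  sample_ids <- sprintf("SMP%02d", seq_len(n_samples))
  sample_batch <- stats::setNames(rep(batches, length.out = n_samples), sample_ids)

  rows <- list()
  for (s in sample_ids) {
    bfac <- batch_effects[[sample_batch[s]]]
    if (length(bfac) == 1) bfac <- stats::setNames(rep(bfac, length(all_markers)), all_markers)
    for (img in seq_len(images_per_sample)) {
      pop <- sample(pops, n_cells_per_image, replace = TRUE, prob = mixture)
      mk <- matrix(0, n_cells_per_image, length(all_markers),
        dimnames = list(NULL, all_markers)
      )
      morpho <- matrix(0, n_cells_per_image, length(MORPHOLOGY_FEATURES),
        dimnames = list(NULL, MORPHOLOGY_FEATURES)
      )
      for (p in pops) {
        ix <- which(pop == p)
        if (!length(ix)) next
        prof <- population_profiles[[p]]
        for (m in all_markers) {
          par <- prof$markers[[m]]
          mk[ix, m] <- stats::rlnorm(length(ix), par[1], par[2]) * bfac[[m]]
        }
        mo <- prof$morphology
        for (f in c("area", "perimeter", "major_axis_length")) {
          morpho[ix, f] <- stats::rlnorm(length(ix), mo[[f]][1], mo[[f]][2])
        }
        morpho[ix, "eccentricity"] <- stats::runif(
          length(ix), mo$eccentricity[1], mo$eccentricity[2]
        )
        morpho[ix, "solidity"] <- stats::runif(
          length(ix), mo$solidity[1], mo$solidity[2]
        )
      }
      artifact <- stats::runif(n_cells_per_image) < solidity_one_rate
      morpho[artifact, "solidity"] <- 1
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, image_id = paste0(s, "_I", img),
        batch_id = sample_batch[[s]],
        as.data.frame(mk), as.data.frame(morpho),
        .population = pop
      )
    }
  }
  cells <- do.call(rbind, rows)
  cells$cell_id <- sprintf("C%06d", seq_len(nrow(cells)))
  truth <- data.frame(cell_id = cells$cell_id, population = cells$.population)
  cells$.population <- NULL
  rownames(cells) <- NULL
  list(cells = cells, truth = truth, seed = seed)
}
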