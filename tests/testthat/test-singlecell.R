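# small 3-population cohort reused across tests
three_pop <- function(seed = 7, n_cells = 150, solidity_one_rate = 0) {
  profs <- default_population_profiles()
  sim_singlecell_cohort(
    profs[c("tumor_luminal", "cd8_t", "macrophage")],
    n_cells_per_image = n_cells, images_per_sample = 2, n_samples = 4,
    batch_effects = list(B1 = 1, B2 = 1.3),
    solidity_one_rate = solidity_one_rate, seed = seed
  )
}

test_that("preprocessing: solidity exclusion, per-image z, cap, global scaling", {
  sc <- three_pop(seed = 3, solidity_one_rate = 0.08)
  panel <- default_panel()
  prep <- preprocess_cells(sc$cells, panel)
  round_cells <- which(sc$cells$solidity == 1)
  expect_gt(length(round_cells), 0)
  expect_length(intersect(prep$kept, round_cells), 0)
  expect_equal(sort(c(prep$kept, round_cells)), seq_len(nrow(sc$cells)))
  expect_false(anyNA(prep$features))
  # capping at +-3 happens before global scaling: per image the z-values
  # are bounded, so after a global affine rescale each marker stays within
  # the rescaled image of [-3, 3]
  x <- log1p(as.matrix(sc$cells[prep$kept, colnames(prep$all_markers)]))
  for (m in colnames(prep$all_markers)) {
    z <- unlist(tapply(
      x[, m], sc$cells$image_id[prep$kept],
      function(v) {
        s <- stats::sd(v)
        if (s == 0) rep(0, length(v)) else pmin(pmax((v - mean(v)) / s, -3), 3)
      }
    ))
    lim <- (3 - mean(z) * c(1, -1)) / stats::sd(z)
    expect_lte(max(prep$all_markers[, m]), max(lim) + 1e-9)
  }
})

test_that("a marker constant within an image gets z-score 0 there", {
  sc <- three_pop(seed = 5, n_cells = 40)
  cells <- sc$cells
  img <- cells$image_id == cells$image_id[1]
  cells$CD3[img] <- 2.5
  prep <- preprocess_cells(cells, default_panel())
  kept_img <- cells$image_id[prep$kept] == cells$image_id[1]
  vals <- prep$all_markers[kept_img, "CD3"]
  expect_equal(length(unique(round(vals, 12))), 1) # one shared post-scale value
})

test_that("single-cell images are kept with zero z-scores and a warning", {
  sc <- three_pop(seed = 9, n_cells = 30)
  cells <- rbind(sc$cells, transform(sc$cells[1, ], image_id = "LONE_I1"))
  expect_warning(prep <- preprocess_cells(cells, default_panel()), "single-cell")
  expect_true(nrow(cells) %in% prep$kept)
})

test_that("panel config enforces disjoint functional markers", {
  expect_error(
    panel_config(c("CD3", "Ki67"), functional_markers = c("Ki67")),
    "disjoint"
  )
  sc <- three_pop(seed = 2, n_cells = 20)
  bad_panel <- panel_config(c(default_panel()$clustering_markers, "NOPE"))
  expect_error(preprocess_cells(sc$cells, bad_panel), "NOPE")
})

test_that("batch correction removes location and scale shifts, keeps global means", {
  set.seed(55)
  n <- 4000
  base <- matrix(rnorm(n * 10), n)
  colnames(base) <- paste0("f", 1:10)
  batch <- rep(c("b1", "b2"), each = n / 2)
  shifted <- base
  shifted[batch == "b2", ] <- shifted[batch == "b2", ] + 2
  adj <- correct_batch(shifted, batch)
  gap <- colMeans(adj[batch == "b1", ]) - colMeans(adj[batch == "b2", ])
  expect_true(all(abs(gap) < 0.05))
  expect_equal(colMeans(adj), colMeans(shifted), tolerance = 1e-6)
  # scale effect
  scaled <- base
  scaled[batch == "b2", ] <- scaled[batch == "b2", ] * 2
  adj2 <- correct_batch(scaled, batch)
  vr <- apply(adj2[batch == "b1", ], 2, stats::var) /
    apply(adj2[batch == "b2", ], 2, stats::var)
  expect_true(all(vr > 0.9 & vr < 1.1))
  # single batch: identity
  expect_equal(correct_batch(base, rep("b1", n)), base)
  expect_error(correct_batch(base, c("solo", rep("b1", n - 1))), "at least 2")
})

test_that("clustering separates well-separated populations at high purity", {
  sc <- three_pop(seed = 11)
  ph <- phenotype_cells(sc$cells, seed = 42)
  truth <- sc$truth$population[ph$kept]
  expect_gte(cluster_purity(ph$cells$cluster, truth), 0.99)
  # metacluster labels match the planted populations
  map <- table(ph$cells$metacluster, truth)
  expect_gte(
    sum(map["Tumor (luminal)", "tumor_luminal"], map["CD8 T cell", "cd8_t"],
      map["Macrophage", "macrophage"]) / sum(map),
    0.99
  )
})

test_that("pipeline is deterministic and near-zero resolution gives one cluster", {
  sc <- three_pop(seed = 13, n_cells = 60)
  ph1 <- phenotype_cells(sc$cells, seed = 5)
  ph2 <- phenotype_cells(sc$cells, seed = 5)
  expect_identical(ph1$cells$cluster, ph2$cells$cluster)
  # limit behavior on a connected graph: one population, resolution -> 0
  one_pop <- sim_singlecell_cohort(
    default_population_profiles()["cd8_t"],
    n_cells_per_image = 80, images_per_sample = 1, n_samples = 2, seed = 19
  )
  prep1 <- preprocess_cells(one_pop$cells, default_panel())
  one <- embed_and_cluster(prep1$features, one_pop$cells$batch_id[prep1$kept],
    n_pcs = 10, resolution = 1e-4, seed = 5
  )
  expect_equal(length(unique(one$clusters)), 1)
})

test_that("duplicated cells land in the same cluster", {
  sc <- three_pop(seed = 17, n_cells = 40)
  prep <- preprocess_cells(sc$cells, default_panel())
  feats <- rbind(prep$features, prep$features)
  batches <- rep(sc$cells$batch_id[prep$kept], 2)
  emb <- embed_and_cluster(feats, batches, n_pcs = 10, seed = 3)
  n <- nrow(prep$features)
  expect_gte(mean(emb$clusters[1:n] == emb$clusters[n + 1:n]), 0.99)
})

test_that("metacluster rules are applied first-match-wins with threshold logic", {
  profiles <- data.frame(
    cluster = 1:3, n_cells = c(10, 10, 10),
    mean_CD3 = c(2, 0, 2), mean_CD8a = c(2, 0, 0), mean_CD4 = c(0, 0, 2),
    mean_FOXP3 = c(0, 0, 0), mean_panKeratin = c(0, 2, 0),
    mean_GATA3 = c(0, 2, 0), mean_KRT5 = c(0, 0, 0),
    mean_Ecadherin = c(0, 2, 0), mean_CD68 = 0, mean_CD11b = 0,
    mean_CD11c = 0, mean_CD16 = 0, mean_CD31 = 0, mean_aSMA = 0,
    mean_Vimentin = 0, mean_Ki67 = 0, mean_PD1 = 0, mean_PDL1 = 0,
    mean_GranzymeB = 0
  )
  lab <- assign_metaclusters(profiles)$metacluster
  expect_equal(lab, c("CD8 T cell", "Tumor (luminal)", "CD4 T cell"))
  none <- profiles
  none[, grep("^mean_", names(none))] <- 0
  expect_equal(assign_metaclusters(none)$metacluster, rep("unassigned", 3))
  bad <- default_metacluster_rules()
  bad$markers_high[1] <- "XYZ"
  expect_error(assign_metaclusters(profiles, bad), "unknown marker")
})

test_that("plasticity ratio: zero at equality, antisymmetric under swap", {
  cells <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    image_id = rep(c("i1", "i2"), each = 3),
    KRT5 = c(4, 4, 8, 1, 2, 3),
    GATA3 = c(4, 1, 2, 1, 2, 3)
  )
  panel <- panel_config(c("KRT5", "GATA3"), functional_markers = character(0))
  r <- plasticity_ratio(cells, panel, epsilon = 0)
  expect_equal(r$per_cell$log_ratio[1], 0)
  expect_equal(r$per_cell$log_ratio[2], 2)
  swapped <- panel_config(c("KRT5", "GATA3"),
    functional_markers = character(0),
    plasticity_pair = c("GATA3", "KRT5")
  )
  r2 <- plasticity_ratio(cells, swapped, epsilon = 0)
  expect_equal(r2$per_cell$log_ratio, -r$per_cell$log_ratio)
  expect_equal(r$per_sample$median[r$per_sample$sample_id == "s2"], 0)
  # matched samples drawn from one population have near-equal medians
  sc <- sim_singlecell_cohort(
    default_population_profiles()["tumor_basal"],
    n_cells_per_image = 1000, images_per_sample = 1, n_samples = 2, seed = 23
  )
  rs <- plasticity_ratio(sc$cells)$per_sample
  delta <- plasticity_pair_delta(
    rs,
    data.frame(
      patient_id = "pt1", primary_sample_id = "SMP01",
      met_sample_id = "SMP02"
    )
  )
  expect_lt(abs(delta$delta_median), 0.2)
})

test_that("infiltration statistics count zeros and detect planted abundance", {
  cell_meta <- data.frame(
    sample_id = rep("s1", 8),
    image_id = rep(c("i1", "i2"), c(3, 5)),
    metacluster = c(rep("CD8 T cell", 3), rep("CD8 T cell", 5))
  )
  groups <- c(s1 = "inflamed")
  r <- infiltration_stats(cell_meta, groups)
  expect_equal(
    r$per_sample$mean_cells_per_image[
      r$per_sample$metacluster == "CD8 T cell"
    ], 4
  )
  # a metacluster absent from one image still contributes a zero count
  cell_meta2 <- rbind(
    cell_meta,
    data.frame(sample_id = "s1", image_id = "i1", metacluster = "Treg")
  )
  r2 <- infiltration_stats(cell_meta2, groups)
  treg <- r2$per_image[r2$per_image$metacluster == "Treg", ]
  expect_equal(sort(treg$n_cells), c(0, 1))
  # planted 3x CD8 abundance separates groups
  set.seed(91)
  imgs <- function(s, lambda) {
    data.frame(
      sample_id = s,
      image_id = rep(paste0(s, "_i", 1:10), stats::rpois(10, lambda) + 1),
      metacluster = "CD8 T cell"
    )
  }
  meta3 <- rbind(
    do.call(rbind, lapply(paste0("inf", 1:5), imgs, lambda = 30)),
    do.call(rbind, lapply(paste0("dep", 1:5), imgs, lambda = 10))
  )
  g3 <- stats::setNames(
    rep(c("inflamed", "depleted"), each = 5),
    c(paste0("inf", 1:5), paste0("dep", 1:5))
  )
  r3 <- infiltration_stats(meta3, g3)
  expect_lt(r3$tests$p[r3$tests$metacluster == "CD8 T cell"], 0.05)
  expect_gt(
    r3$tests$mean_inflamed[r3$tests$metacluster == "CD8 T cell"],
    r3$tests$mean_depleted[r3$tests$metacluster == "CD8 T cell"]
  )
})
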