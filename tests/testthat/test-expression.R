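centroids_fix <- sim_centroids(n_genes = 120, seed = 101)

test_that("nearest-centroid classification: self-match, minCor, recovery", {
  # a sample whose log expression equals a centroid correlates at 1
  fpkm <- matrix(pmax(2^centroids_fix[, "LumP"] - 1, 0),
    ncol = 1,
    dimnames = list(rownames(centroids_fix), "s1")
  )
  call <- classify_subtype(fpkm, centroids_fix)
  expect_equal(call$label, "LumP")
  expect_equal(call$best_correlation, 1, tolerance = 1e-12)
  # uncorrelated noise sample falls below minCor -> unclassified
  set.seed(5)
  noise <- matrix(2^rnorm(120, 5, 2), ncol = 1,
    dimnames = list(rownames(centroids_fix), "n1")
  )
  ncall <- classify_subtype(noise, centroids_fix, min_cor = 0.15)
  if (ncall$best_correlation < 0.15) expect_equal(ncall$label, "unclassified")
  # raising min_cor above the observed best always gives unclassified
  strict <- classify_subtype(noise, centroids_fix,
    min_cor = ncall$best_correlation + 0.01
  )
  expect_equal(strict$label, "unclassified")
  expect_error(
    classify_subtype(fpkm[1, , drop = FALSE], centroids_fix),
    "fewer than 2"
  )
})

test_that("noise-free cohorts classify perfectly; sd 0.5 recovers >= 95%", {
  set.seed(61)
  labels <- sample(colnames(centroids_fix), 120, replace = TRUE)
  coh0 <- sim_expression_cohort(centroids_fix, labels, noise_sd = 0, seed = 8)
  calls0 <- classify_subtype(coh0$fpkm, centroids_fix)
  expect_equal(mean(calls0$label == coh0$truth$subtype), 1)
  coh <- sim_expression_cohort(centroids_fix, labels, noise_sd = 0.5, seed = 9)
  calls <- classify_subtype(coh$fpkm, centroids_fix)
  expect_gte(mean(calls$label == coh$truth$subtype), 0.95)
})

test_that("classifier is invariant to positive affine transforms of log expression", {
  set.seed(12)
  labels <- sample(colnames(centroids_fix), 10, replace = TRUE)
  coh <- sim_expression_cohort(centroids_fix, labels, noise_sd = 0.4, seed = 3)
  lx <- log2(coh$fpkm[rownames(centroids_fix), ] + 1)
  calls <- classify_subtype(coh$fpkm, centroids_fix)
  affine <- classify_subtype(2.5 * lx + 7, centroids_fix, log_transform = FALSE)
  expect_equal(affine$label, calls$label)
  expect_equal(affine$best_correlation, calls$best_correlation, tolerance = 1e-9)
})

test_that("within-patient subtype concordance", {
  calls <- data.frame(
    sample = c("a", "b", "c", "d", "e"),
    label = c("LumP", "LumP", "LumP", "LumU", "Ba/Sq")
  )
  manifest <- data.frame(
    patient_id = c("W1", "W1", "W2", "W2", "W3"),
    sample = c("a", "b", "c", "d", "e")
  )
  r <- subtype_concordance(calls, manifest)
  expect_equal(r$concordant[r$patient_id == "W1"], TRUE)
  expect_equal(r$concordant[r$patient_id == "W2"], FALSE)
  expect_equal(r$labels[r$patient_id == "W2"], "LumP,LumU")
  w3 <- r[r$patient_id == "W3", ]
  expect_true(w3$concordant)
  expect_true(w3$single_sample)
  expect_error(
    subtype_concordance(calls[-1, ], manifest),
    "unclassified manifest sample"
  )
})

test_that("PAM clustering: separation, degenerate k = n, duplicates", {
  set.seed(33)
  X <- rbind(
    matrix(rnorm(60, 0, 1), ncol = 3),
    matrix(rnorm(60, 8, 1), ncol = 3)
  )
  fit <- pam_cluster(X, 2)
  truth <- rep(1:2, each = 20)
  expect_equal(length(unique(fit$clustering[truth == 1])), 1)
  expect_equal(length(unique(fit$clustering[truth == 2])), 1)
  expect_true(fit$clustering[1] != fit$clustering[40])
  # k = n: every point its own medoid at zero cost
  small <- X[1:4, ]
  full <- pam_cluster(small, 4)
  expect_equal(full$objective, 0)
  expect_equal(sort(full$medoids), 1:4)
  # duplicated rows co-cluster
  dup <- rbind(X[1:10, ], X[1:10, ], X[21:30, ])
  dfit <- pam_cluster(dup, 2)
  expect_equal(dfit$clustering[1:10], dfit$clustering[11:20])
  expect_error(pam_cluster(X, 0), "k must")
})

test_that("PAM matches the reference implementation's objective", {
  skip_if_not_installed("cluster")
  set.seed(44)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 4), 40)
    mine <- pam_cluster(X, 3)
    ref <- cluster::pam(stats::dist(X), 3)
    ref_cost <- sum(apply(as.matrix(stats::dist(X))[, ref$id.med], 1, min))
    # both reach a local optimum of the same objective; costs must agree
    expect_equal(mine$objective, ref_cost, tolerance = 1e-8)
  }
})

test_that("immune classification recovers a planted signature shift", {
  set.seed(29)
  labels <- sample(colnames(centroids_fix), 40, replace = TRUE)
  coh <- sim_expression_cohort(centroids_fix, labels,
    noise_sd = 0.3, signature_shift = 2, seed = 15
  )
  calls <- classify_immune(coh$fpkm, coh$signature_genes)
  expected <- ifelse(coh$truth$immune == "inflamed",
    "T-cell inflamed", "T-cell depleted"
  )
  expect_equal(calls$label, expected)
  # sample order must not change labels
  rev_calls <- classify_immune(
    coh$fpkm[, rev(colnames(coh$fpkm))], coh$signature_genes
  )
  expect_equal(
    rev_calls$label[match(calls$sample, rev_calls$sample)],
    calls$label
  )
  # identical samples cannot be split into two clusters
  same <- coh$fpkm[, c(1, 1, 1)]
  colnames(same) <- c("x", "y", "z")
  expect_error(classify_immune(same, coh$signature_genes), "identical")
})

test_that("immune co-clustering with a reference cohort returns query calls only", {
  set.seed(51)
  labels <- sample(colnames(centroids_fix), 12, replace = TRUE)
  coh <- sim_expression_cohort(centroids_fix, labels,
    noise_sd = 0.3, signature_shift = 2, seed = 6
  )
  ref <- sim_expression_cohort(centroids_fix,
    sample(colnames(centroids_fix), 30, replace = TRUE),
    noise_sd = 0.3, signature_shift = 2, seed = 7
  )
  colnames(ref$fpkm) <- paste0("REF_", colnames(ref$fpkm))
  calls <- classify_immune(coh$fpkm, coh$signature_genes,
    reference_expr = ref$fpkm
  )
  expect_setequal(calls$sample, colnames(coh$fpkm))
  expected <- ifelse(coh$truth$immune == "inflamed",
    "T-cell inflamed", "T-cell depleted"
  )
  expect_equal(calls$label, expected)
})

test_that("ssGSEA: top-set maximality, rank invariance, degenerate cohort", {
  set.seed(71)
  expr <- matrix(rexp(10 * 3, 0.2), 10,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:3))
  )
  top3 <- rownames(expr)[order(expr[, 1], decreasing = TRUE)[1:3]]
  sc <- ssgsea(expr, list(top = top3))
  # brute force over all 3-gene sets: the sample's own top genes win
  all_sets <- utils::combn(rownames(expr), 3, simplify = FALSE)
  es_all <- vapply(
    all_sets,
    function(s) ssgsea(expr, list(a = s))$es[1, 1], numeric(1)
  )
  expect_equal(sc$es["top", "s1"], max(es_all))
  # monotone transform of one sample's values leaves its scores unchanged
  expr2 <- expr
  expr2[, 2] <- exp(expr2[, 2] / 3)
  sc2 <- ssgsea(expr2, list(top = top3))
  expect_equal(sc2$es["top", "s2"], sc$es["top", "s2"])
  # shuffling gene order leaves scores unchanged
  perm <- sample(nrow(expr))
  sc3 <- ssgsea(expr[perm, ], list(top = top3))
  expect_equal(sc3$es, sc$es)
  # two identical samples: equal scores, z-scores 0
  twin <- expr[, c(1, 1)]
  colnames(twin) <- c("a", "b")
  sct <- ssgsea(twin, list(top = top3))
  expect_equal(sct$es[1, "a"], sct$es[1, "b"])
  expect_equal(unname(sct$z[1, ]), c(0, 0))
  expect_warning(
    ssgsea(expr, list(top = top3, none = c("zz1", "zz2"))),
    "omitting"
  )
})

test_that("enrichment group comparison flags only truly shifted sets", {
  set.seed(81)
  n_genes <- 60
  genes <- paste0("g", seq_len(n_genes))
  null_expr <- matrix(rnorm(n_genes * 20, 5, 1), n_genes,
    dimnames = list(genes, paste0("s", 1:20))
  )
  groups <- stats::setNames(
    rep(c("primary", "metastatic"), each = 10), colnames(null_expr)
  )
  shifted_set <- genes[1:10]
  sets <- list(up = shifted_set, flat = genes[31:40])
  # no shift anywhere: nothing significant
  cmp_null <- compare_enrichment(ssgsea(null_expr, sets), groups)
  expect_equal(sum(cmp_null$significant), 0)
  # +3-sd shift planted in one set's genes for one group: that set flags
  shifted <- null_expr
  shifted[shifted_set, 11:20] <- shifted[shifted_set, 11:20] + 3
  sc <- ssgsea(shifted, sets)
  cmp <- compare_enrichment(sc, groups)
  expect_true(cmp$significant[cmp$set == "up"])
  expect_true(cmp$q[cmp$set == "up"] <= 0.25)
  # identical group distributions -> p = 1
  same <- null_expr[, c(1:10, 1:10)]
  colnames(same) <- paste0("t", 1:20)
  g2 <- stats::setNames(rep(c("primary", "metastatic"), each = 10), colnames(same))
  cmp2 <- compare_enrichment(ssgsea(same, sets), g2)
  expect_equal(cmp2$p, rep(1, 2), tolerance = 1e-9)
  # paired variant runs and returns one p per set
  cmp3 <- compare_enrichment(sc, groups, paired = TRUE)
  expect_equal(nrow(cmp3), 2)
  expect_error(
    compare_enrichment(
      sc, stats::setNames(rep("primary", 20), colnames(null_expr))
    ),
    "nonempty"
  )
})
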