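test_that("select_templates ranks by similarity with stable ties", {
  fps <- list(a = c(1, 2, 3), b = c(1, 2), c = c(1, 2), d = 7L, e = 9L)
  # candidate {1,2,3}: similarities a=1, b=c=2/3, d=e=0
  lib <- template_library(names(fps), fps)
  top3 <- select_templates(c(1, 2, 3), lib, k = 3)
  # brute-force oracle: recompute similarities, sort by (-sim, id)
  sims <- vapply(fps, function(f) length(intersect(1:3, f)) /
                   length(union(1:3, f)), numeric(1))
  ord <- order(-sims, names(fps))
  expect_identical(top3$template_id, names(fps)[ord][1:3])
  expect_equal(top3$similarity[1], 1)

  # k = library size returns everything; k beyond warns
  expect_equal(nrow(select_templates(c(1, 2, 3), lib, k = 5)), 5)
  expect_warning(all5 <- select_templates(c(1, 2, 3), lib, k = 10), "exceeds")
  expect_equal(nrow(all5), 5)
  expect_error(select_templates(1:3, template_library("t", list(1L))[0, ]),
               class = "dockrf_validation_error")
})

test_that("select_templates rankings are prefix-stable in k", {
  withr::with_seed(11, {
    fps <- lapply(1:12, function(i) sample(166, sample(3:20, 1)))
    lib <- template_library(sprintf("T%02d", 1:12), fps)
    cand <- sample(166, 10)
    full <- select_templates(cand, lib, k = 12)$template_id
    for (k in 1:11)
      expect_identical(select_templates(cand, lib, k = k)$template_id,
                       full[1:k])
  })
})

test_that("cluster_poses partitions by single-linkage RMSD", {
  base <- matrix(rnorm(30), 10, 3)
  same <- replicate(20, base + matrix(rnorm(30, 0, 0.01), 10, 3),
                    simplify = FALSE)
  expect_equal(length(unique(cluster_poses(same, 2))), 1L)

  far <- lapply(same[1:8], function(p) p + 50)  # translated 50 A away
  cl <- cluster_poses(c(same, far), 2)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:20])), 1L)
  expect_equal(length(unique(cl[21:28])), 1L)

  expect_equal(cluster_poses(list(base), 2), 1L)
  expect_error(cluster_poses(list(), 2), class = "dockrf_validation_error")
  expect_error(cluster_poses(list(base, matrix(0, 4, 3)), 2),
               class = "dockrf_validation_error")
})

test_that("lowering the RMSD threshold only refines the partition", {
  withr::with_seed(21, {
    poses <- lapply(1:15, function(i)
      matrix(rnorm(18, sample(c(0, 5, 20), 1), 1), 6, 3))
  })
  thresholds <- c(0.5, 1, 2, 5, 10, 50)
  n_clusters <- vapply(thresholds, function(h)
    length(unique(cluster_poses(poses, h))), integer(1))
  expect_true(all(diff(n_clusters) <= 0))  # fewer clusters as h grows
  # refinement: co-membership at a low threshold implies it at a higher one
  lo <- cluster_poses(poses, 1); hi <- cluster_poses(poses, 5)
  for (i in 1:14) for (j in (i + 1):15)
    if (lo[i] == lo[j]) expect_equal(hi[i], hi[j])
})

test_that("select_best_pose applies the largest-cluster-first rule", {
  expect_equal(select_best_pose(rep(1L, 4), c(5, 9, 7, 2)), 2L)
  # global best score sits in the smaller cluster and must lose
  cl <- c(rep(1L, 12), rep(2L, 8))
  scores <- c(rep(6, 12), rep(5, 7), 99)
  expect_equal(select_best_pose(cl, scores), 1L)
  # equal sizes: higher mean consensus wins
  cl2 <- c(rep(1L, 10), rep(2L, 10))
  scores2 <- c(rep(7.1, 10), rep(6.9, 10))
  expect_equal(select_best_pose(cl2, scores2), 1L)
  expect_error(select_best_pose(rep(1L, 3), c(1, NA, 2)),
               class = "dockrf_missing_error")
})

test_that("aggregation matches direct formula evaluation", {
  tab <- random_pose_table(n_lig = 1, n_pose = 20, seed = 2)
  tab$Plants <- rep(5, 20)
  tab$XScore <- 1:20
  u <- aggregate_metrics(tab)
  expect_equal(u$Plants_Med, 5)
  expect_equal(u$Plants_SD, 0)
  expect_equal(u$XScore_Med, 10.5)          # even count: central midpoint
  expect_equal(u$XScore_SD, sqrt(sum((1:20 - 10.5)^2) / 19))  # = 5.91608...
  expect_equal(u$n_poses, 20)
})

test_that("aggregation is order-invariant and bracketed by min/max", {
  tab <- random_pose_table(n_lig = 6, n_pose = 7, seed = 3)
  u1 <- aggregate_metrics(tab)
  shuffled <- withr::with_seed(4, tab[sample(nrow(tab)), ])
  u2 <- aggregate_metrics(as_pose_table(shuffled))
  expect_equal(u1, u2)
  for (m in metric_schema()$metric) {
    v <- split(tab[[m]], tab$ligand_id)
    med <- u1[[paste0(m, "_Med")]][match(names(v), u1$ligand_id)]
    expect_true(all(med >= vapply(v, min, 1) & med <= vapply(v, max, 1)))
  }
})

test_that("SD is zero iff the pose values are constant", {
  tab <- random_pose_table(n_lig = 4, n_pose = 6, seed = 9)
  tab$DSX <- rep(c(1, 1, 2, 2), each = 6)       # constant per ligand
  u <- aggregate_metrics(tab)
  expect_true(all(u$DSX_SD == 0))
  expect_true(all(u$XScore_SD > 0))             # random draws: never constant
})

test_that("aggregation enforces the minimum pose count", {
  tab <- random_pose_table(n_lig = 2, n_pose = 1, seed = 5)
  expect_error(aggregate_metrics(tab), class = "dockrf_validation_error")
  expect_warning(u <- aggregate_metrics(tab, min_poses = 1), "SD set to 0")
  expect_true(all(u$Plants_SD == 0))
  bad <- random_pose_table(n_lig = 2, n_pose = 3, seed = 6)
  bad$QMean <- as.character(bad$QMean)
  bad$QMean[2] <- "oops"
  expect_error(aggregate_metrics(bad), "QMean",
               class = "dockrf_validation_error")
})

test_that("assemble_features produces the frozen feature sets", {
  tab <- random_pose_table(n_lig = 4, n_pose = 5, seed = 7)
  u <- aggregate_metrics(tab)
  desc <- compute_descriptors(
    molecules(fixture_molecules()[1:4], unique(tab$ligand_id)))
  fp <- maccs_fingerprints(
    molecules(fixture_molecules()[1:4], unique(tab$ligand_id)))

  combined <- assemble_features(u, desc, mode = "combined")
  expect_length(feature_names(combined), 49)
  expect_true(all(grepl("_Med$|_SD$",
                        setdiff(feature_names(combined),
                                c(dockrf:::LIGAND_DESCRIPTORS)))))

  eng <- assemble_features(u, desc, mode = "combined_engineered")
  expect_length(feature_names(eng), 48)
  expect_true("nRotB.nB" %in% names(eng))
  expect_false(any(c("nRotBond", "nBond") %in% names(eng)))

  expect_length(feature_names(assemble_features(u, mode = "structure_only")),
                38)
  expect_length(feature_names(assemble_features(NULL, desc,
                                                mode = "ligand_only")), 11)
  mac <- assemble_features(NULL, desc, mode = "maccs_only", maccs = fp)
  expect_length(feature_names(mac), 166)
  both <- assemble_features(u, desc, mode = "combined_maccs", maccs = fp)
  expect_length(feature_names(both), 215)

  expect_error(assemble_features(u, desc, mode = "everything"),
               class = "dockrf_validation_error")
  expect_error(assemble_features(u, desc[0, ], mode = "combined"),
               class = "dockrf_validation_error")
})

test_that("unified tables round-trip through CSV", {
  u <- aggregate_metrics(random_pose_table(n_lig = 3, n_pose = 4, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_unified_table(u, path)
  back <- read_unified_table(path)
  expect_equal(back$Tanimoto_Med, u$Tanimoto_Med, tolerance = 1e-12)
  expect_identical(names(back), names(u))
})
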