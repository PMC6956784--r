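test_that("p-affinity transforms follow the stated formulas", {
  expect_equal(to_p_affinity("Ki", 1), 9)        # 1 nM -> pKi 9
  expect_equal(to_p_affinity("IC50", 100), 7)
  expect_equal(to_p_affinity("RBA", 100), -6)    # estradiol reference
  expect_equal(to_p_affinity("RBA", 1), -8)
  expect_equal(to_p_affinity("Ki", 1, units = "uM"), 6)
  expect_equal(to_p_affinity("Ki", 1e-9, units = "M"), 9)
  expect_error(to_p_affinity("Ki", 0), class = "dockrf_validation_error")
  expect_error(to_p_affinity("Ki", -2), class = "dockrf_validation_error")
  expect_error(to_p_affinity("EC50", 1))
})

test_that("transforms are strictly monotone", {
  v <- sort(withr::with_seed(1, runif(50, 1e-3, 1e6)))
  expect_true(all(diff(to_p_affinity("Ki", v)) < 0))
  expect_true(all(diff(to_p_affinity("IC50", v)) < 0))
  expect_true(all(diff(to_p_affinity("RBA", v)) > 0))
})

make_tagged <- function(tags, n = 10, seed = 1) {
  study <- generate_study(simulation_config(n, tags = tags, seed = seed))
  per_tag <- lapply(tags, function(tg) {
    u <- aggregate_metrics(study$poses[[tg]])
    build_dataset(assemble_features(u, study$descriptors), study$affinity)
  })
  names(per_tag) <- tags
  per_tag
}

test_that("combine_representations concatenates the stated groupings", {
  tabs <- make_tagged(c("MMFF", "Gast", "BDB", "OB3D", "Frog3D"), n = 6)
  all5 <- combine_representations(tabs, "ALL")
  expect_equal(nrow(all5), 5 * 6)
  expect_identical(attr(all5, "grouping_label"), "ALL")
  dch <- combine_representations(tabs, "dCharge")
  expect_setequal(unique(dch$representation_tag), c("MMFF", "Gast", "BDB"))
  expect_error(combine_representations(tabs[c("MMFF", "BDB")], "dConf"),
               "OB3D", class = "dockrf_validation_error")
  expect_error(combine_representations(tabs, "dCustom"),
               class = "dockrf_validation_error")
})

test_that("stratified hold-out hits exact sizes and stays label-balanced", {
  d <- linear_dataset(n = 281, seed = 2)
  sp <- stratified_holdout(d, 0.2, 5, seed = 17)
  expect_equal(nrow(sp$test), 56)
  expect_equal(nrow(sp$train), 225)
  expect_equal(sort(c(sp$train$ligand_id, sp$test$ligand_id)),
               sort(d$ligand_id))

  d10 <- linear_dataset(n = 10, seed = 3)
  expect_equal(nrow(stratified_holdout(d10, 0.2, 5, seed = 1)$test), 2)

  # two seeds: identical sizes, different membership
  a <- stratified_holdout(d, 0.2, 5, seed = 1)
  b <- stratified_holdout(d, 0.2, 5, seed = 2)
  expect_equal(nrow(a$test), nrow(b$test))
  expect_false(identical(sort(a$test$ligand_id), sort(b$test$ligand_id)))
  # reproducible from one seed
  expect_identical(stratified_holdout(d, 0.2, 5, seed = 1)$test$ligand_id,
                   a$test$ligand_id)

  # per-bin proportions within one record of the global fraction
  units <- dockrf:::ligand_units(d, TRUE)
  bins <- dockrf:::label_bins(units, 5)
  per_bin <- table(bins[match(a$test$ligand_id, units$unit)])
  expect_true(all(abs(per_bin - 0.2 * table(bins)) <= 1))

  expect_error(stratified_holdout(linear_dataset(4), n_bins = 5),
               class = "dockrf_validation_error")
  expect_error(stratified_holdout(d, 1.2), class = "dockrf_validation_error")
})

test_that("ligand grouping keeps representation rows on one side", {
  tabs <- make_tagged(c("BDB", "OB3D", "Frog3D"), n = 30, seed = 5)
  comb <- combine_representations(tabs, "dConf")
  sp <- stratified_holdout(comb, 0.2, 5, seed = 4)
  expect_length(intersect(sp$train$ligand_id, sp$test$ligand_id), 0)
  # every ligand contributes all three representation rows to its side
  expect_true(all(table(sp$test$ligand_id) == 3))
  # ungrouped escape hatch splits at the row level instead
  spu <- stratified_holdout(comb, 0.2, 5, seed = 4, grouped = FALSE)
  expect_equal(nrow(spu$test), floor(0.2 * nrow(comb)))
})

test_that("cv folds partition rows, balance bins and differ across repeats", {
  d <- linear_dataset(n = 100, seed = 6)
  folds <- make_cv_folds(d, k = 10, repeats = 10, seed = 12)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(sort(unique(f)), 1:10)
    expect_true(all(table(f) == 10))       # n=100, k=10: all folds size 10
  }
  # repeats give distinct partitions under one master seed
  keys <- vapply(folds, paste, "", collapse = ",")
  expect_equal(length(unique(keys)), 10)
  # reproducibility
  expect_identical(make_cv_folds(d, k = 10, repeats = 10, seed = 12), folds)
  expect_error(make_cv_folds(linear_dataset(5), k = 10),
               class = "dockrf_validation_error")
})

test_that("cv folds never split a ligand across folds", {
  tabs <- make_tagged(c("MMFF", "Gast", "BDB"), n = 25, seed = 7)
  comb <- combine_representations(tabs, "dCharge")
  folds <- make_cv_folds(comb, k = 5, repeats = 3, seed = 2)
  for (f in folds)
    for (k in unique(f))
      expect_length(intersect(comb$ligand_id[f == k],
                              comb$ligand_id[f != k]), 0)
})

test_that("affinity and dataset tables round-trip through CSV", {
  rec <- affinity_records(c("a", "b", "c"), c("Ki", "IC50", "RBA"),
                          c(10, 200, 50), c("nM", "nM", ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_affinity_table(rec, path)
  back <- read_affinity_table(path)
  expect_equal(back$p_affinity, rec$p_affinity)

  d <- linear_dataset(n = 20, seed = 8)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, p2)
  back2 <- read_dataset(p2)
  expect_equal(back2$p_affinity, d$p_affinity, tolerance = 1e-12)
  expect_identical(feature_names(back2), feature_names(d))
})
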