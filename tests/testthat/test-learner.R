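test_that("training is deterministic given a seed", {
  d <- linear_dataset(n = 120, noise_sd = 0.5, seed = 1)
  probe <- linear_dataset(n = 30, noise_sd = 0.5, seed = 99)
  m1 <- train_rf(d, mtry_grid = 3, n_trees = 50, seed = 7)
  m2 <- train_rf(d, mtry_grid = 3, n_trees = 50, seed = 7)
  expect_identical(predict(m1, probe), predict(m2, probe))
  m3 <- train_rf(d, mtry_grid = 3, n_trees = 50, seed = 8)
  expect_false(identical(predict(m1, probe), predict(m3, probe)))
})

test_that("a noiseless linear target is recovered on held-out data", {
  d <- linear_dataset(n = 500, p_noise = 5, noise_sd = 0, seed = 2)
  sp <- stratified_holdout(d, 0.2, 5, seed = 3)
  m <- train_rf(sp$train, mtry_grid = 4, n_trees = 300, seed = 4)
  rep <- evaluate(predict(m, sp$test), sp$test$p_affinity)
  expect_gte(rep$rP, 0.95)
})

test_that("permuted labels yield no held-out signal (seed-averaged)", {
  rps <- vapply(1:3, function(s) {
    d <- linear_dataset(n = 500, noise_sd = 0, seed = s)
    d$p_affinity <- withr::with_seed(100 + s, sample(d$p_affinity))
    sp <- stratified_holdout(d, 0.2, 5, seed = s)
    m <- train_rf(sp$train, mtry_grid = 4, n_trees = 150, seed = s)
    evaluate(predict(m, sp$test), sp$test$p_affinity)$rP
  }, numeric(1))
  expect_lte(abs(mean(rps)), 0.15)
})

test_that("a single fully-grown, non-bootstrapped tree memorizes", {
  d <- linear_dataset(n = 60, noise_sd = 0.3, seed = 5)
  m <- train_rf(d, mtry_grid = length(feature_names(d)), n_trees = 1,
                min_node = 1, sample_fraction = 1, replace = FALSE, seed = 1)
  expect_equal(predict(m, d), d$p_affinity, tolerance = 1e-12)
})

test_that("predictions are row-order invariant and label-bounded", {
  d <- linear_dataset(n = 200, noise_sd = 0.5, seed = 6)
  m <- train_rf(d, mtry_grid = 3, n_trees = 100, seed = 2)
  probe <- linear_dataset(n = 50, noise_sd = 0.5, seed = 50)
  p1 <- predict(m, probe)
  idx <- withr::with_seed(1, sample(nrow(probe)))
  expect_equal(predict(m, probe[idx, ]), p1[idx])
  # ensemble averages of training labels stay inside the training range
  extreme <- probe
  for (f in feature_names(extreme)) extreme[[f]] <- extreme[[f]] * 100
  expect_true(all(predict(m, extreme) >= m$label_range[1] &
                  predict(m, extreme) <= m$label_range[2]))
})

test_that("schema and label problems are rejected with clear errors", {
  d <- linear_dataset(n = 40, seed = 7)
  m <- train_rf(d, mtry_grid = 3, n_trees = 20, seed = 1)
  probe <- linear_dataset(n = 5, seed = 8)
  probe$bogus <- 1
  expect_error(predict(m, probe), "bogus", class = "dockrf_schema_error")
  probe2 <- linear_dataset(n = 5, seed = 8)
  probe2$f1 <- NULL
  expect_error(predict(m, probe2), "f1", class = "dockrf_schema_error")

  dna <- linear_dataset(n = 40, seed = 9)
  dna$f2[3] <- NA
  expect_error(train_rf(dna, mtry_grid = 3, n_trees = 10), "f2",
               class = "dockrf_validation_error")
  dconst <- linear_dataset(n = 40, seed = 10)
  dconst$p_affinity <- 5
  expect_error(train_rf(dconst, mtry_grid = 3, n_trees = 10),
               class = "dockrf_validation_error")
})

test_that("mtry selection picks the CV-RMSE minimizer", {
  d <- linear_dataset(n = 150, noise_sd = 0.5, seed = 11)
  m <- train_rf(d, k = 5, repeats = 2, mtry_grid = c(1, 3, 6), n_trees = 60,
                cv_trees = 60, seed = 3)
  cv <- m$cv_summary
  expect_equal(nrow(cv), 3)
  expect_equal(m$mtry, cv$mtry[which.min(cv$mean_rmse)])
  expect_true(all(cv$mean_rmse[cv$mtry == m$mtry] <= cv$mean_rmse))
})

test_that("variable importance finds signal and stays calibrated on noise", {
  # one informative feature among nine pure-noise features
  withr::with_seed(13, {
    X <- matrix(rnorm(300 * 10), 300, dimnames = list(NULL, paste0("f", 1:10)))
    d <- data.frame(ligand_id = sprintf("L%03d", 1:300),
                    representation_tag = "BDB",
                    p_affinity = 3 * X[, 4] + rnorm(300, 0, 0.2))
    d <- cbind(d, as.data.frame(X))
  })
  class(d) <- c("dockrf_dataset", "data.frame")
  m <- train_rf(d, mtry_grid = 3, n_trees = 100, seed = 5)
  imp <- variable_importance(m)
  expect_equal(nrow(imp), 10)
  expect_identical(imp$feature[1], "f4")
  expect_equal(imp$importance[1], 100)
  expect_true(all(diff(imp$importance) <= 0))

  # all-noise null: importance should stay flat in nearly all replicates
  flat <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      Xn <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, paste0("g", 1:10)))
      dn <- data.frame(ligand_id = sprintf("L%02d", 1:60),
                       representation_tag = "BDB",
                       p_affinity = rnorm(60))
      dn <- cbind(dn, as.data.frame(Xn))
    })
    class(dn) <- c("dockrf_dataset", "data.frame")
    raw <- variable_importance(train_rf(dn, mtry_grid = 3, n_trees = 60,
                                        seed = s), normalize = FALSE)
    max(raw$importance) <= 3 * median(raw$importance)
  }, logical(1))
  expect_gte(mean(flat), 0.95)
})

test_that("a plug-in engine honoring fit/predict contracts works", {
  lm_engine <- list(
    fit = function(X, y, mtry, seed) stats::lm.fit(cbind(1, X), y),
    predict = function(fit, X) as.numeric(cbind(1, X) %*% fit$coefficients))
  d <- linear_dataset(n = 100, noise_sd = 0, seed = 14)
  m <- train_rf(d, mtry_grid = 3, engine = lm_engine, seed = 1)
  expect_equal(predict(m, d), d$p_affinity, tolerance = 1e-8)
  expect_error(variable_importance(m), class = "dockrf_validation_error")
})

test_that("models round-trip through the versioned archive", {
  d <- linear_dataset(n = 50, seed = 15)
  m <- train_rf(d, mtry_grid = 3, n_trees = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".bin")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, d), predict(m, d))
  saveRDS(list(format = "other/9"), path)
  expect_error(load_model(path), class = "dockrf_io_error")
})
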