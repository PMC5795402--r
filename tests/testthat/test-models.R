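test_that("leave-one-patient-out splits partition cases by patient", {
  cases <- enumerate_cases(6)
  sp <- lopo_splits(cases)
  expect_equal(nrow(sp), 6)
  expect_true(all(purrr::map_int(sp$test_idx, length) == 48))
  expect_true(all(purrr::map_int(sp$train_idx, length) == 240))
  # union of test sets over folds is all cases, disjoint
  all_test <- sort(unlist(sp$test_idx))
  expect_equal(all_test, seq_len(288))
  # no patient overlap within any fold
  for (f in seq_len(6)) {
    expect_length(intersect(cases$patient_id[sp$train_idx[[f]]],
                            cases$patient_id[sp$test_idx[[f]]]), 0)
  }
  expect_equal(nrow(lopo_splits(enumerate_cases(2))), 2)
  expect_error(lopo_splits(enumerate_cases(1)), "2 patients")
})

test_that("point sampling follows the ceil rule per case deterministically", {
  tbl <- tibble::tibble(case_id = rep(c("a", "b"), c(1000, 37)),
                        v = seq_len(1037))
  expect_identical(sample_points(tbl, 100), tbl)
  s65 <- sample_points(tbl, 65, seed = 2)
  expect_equal(sum(s65$case_id == "a"), 650)
  expect_equal(sum(s65$case_id == "b"), ceiling(0.65 * 37))
  # same seed, same subsample; different seed differs
  expect_identical(sample_points(tbl, 65, seed = 2), s65)
  expect_false(identical(sample_points(tbl, 65, seed = 3), s65))
  # rows are drawn without replacement
  expect_equal(anyDuplicated(s65$v), 0)
  expect_error(sample_points(tbl, 63), "rate")
})

test_that("residual-distance weights are the clamped ceiling in 1..6", {
  expect_equal(weight_from_distance(c(0.3, 4.2, 9.7)), c(1L, 5L, 6L))
  expect_equal(weight_from_distance(0), 1L)
  expect_equal(weight_from_distance(6), 6L)
  expect_equal(weight_from_distance(5.0001), 6L)
  expect_error(weight_from_distance(-0.1), "non-negative")
})

test_that("tuning selects the inner-objective argmin from valid grids", {
  ds <- tiny_dataset()
  tc <- train_config("rf", "average", n_grid = 3, tune_rows = 4000,
                     seed = 21)
  hp <- tune_hyperparams(ds, tc)
  cand <- attr(hp, "candidates")
  expect_gte(nrow(cand), 2)
  expect_equal(hp$score, min(cand$score))
  # grid values stay within the published ranges
  expect_true(all(cand$n_trees %in% seq(5, 500, 5)))
  expect_true(all(cand$max_features %in% 2:23))
  expect_true(all(cand$leaf_size %in% 1:5))
  expect_error(train_config(grid = list(n_trees = 7, max_features = 4,
                                        leaf_size = 5)),
               "published ranges")
})

test_that("the regression recovers a deterministic field and tracks noise", {
  # deterministic generator: model should beat the baseline by a wide margin
  cases <- enumerate_cases(3, seed = 31)
  ds0 <- generate_dataset(cases, n_surface = 60, n_interior = 90,
                          params = deformation_params(noise_sd = 0),
                          seed = 31)
  sp <- lopo_splits(cases)
  tc <- train_config("rf", "average", n_grid = 2, tune_rows = 4000, seed = 31)
  model <- tune_and_train(ds0[sp$train_idx[[1]]], tc)
  test_set <- ds0[sp$test_idx[[1]]]
  preds <- purrr::map(test_set, ~ predict_post(model, .x$pre, .x$cylinder, .x$case))
  got <- evaluate_cases(preds, purrr::map(test_set, "post"))
  base <- evaluate_cases(purrr::map(test_set, "pre"), purrr::map(test_set, "post"))
  expect_lt(got$mu[got$metric == "p2p"], 0.5 * base$mu[base$metric == "p2p"])

  # pure-noise targets: test error stays near the baseline
  ratio <- purrr::map_dbl(1:20, function(s) {
    set.seed(s)
    noise_ds <- purrr::map(ds0[c(sp$train_idx[[1]][1:8], sp$test_idx[[1]][1:4])],
                           function(b) {
      d <- matrix(rnorm(3 * nrow(b$pre), sd = 1), ncol = 3)
      b$post <- set_coords(b$pre, pcl_matrix(b$pre) + d)
      b
    })
    m <- train_deform_model(noise_ds[1:8], tc,
                            list(n_trees = 25L, max_features = 8L,
                                 leaf_size = 5L))
    tst <- noise_ds[9:12]
    p <- purrr::map(tst, ~ predict_post(m, .x$pre, .x$cylinder, .x$case))
    ev <- evaluate_cases(p, purrr::map(tst, "post"))
    bv <- evaluate_cases(purrr::map(tst, "pre"), purrr::map(tst, "post"))
    ev$mu[ev$metric == "p2p"] / bv$mu[bv$metric == "p2p"]
  })
  expect_lt(abs(mean(ratio) - 1), 0.10)
})

test_that("prediction adds the raw per-axis output to the pre-surgery cloud", {
  ds <- tiny_dataset()
  tc <- train_config("rf", "average", seed = 5)
  m <- train_deform_model(ds[1:6], tc,
                          list(n_trees = 5L, max_features = 4L, leaf_size = 5L))
  b <- ds[[7]]
  ft <- compute_features(b$pre, b$cylinder, b$case)
  disp <- predict(m, ft)
  pred <- predict_post(m, b$pre, b$cylinder, b$case)
  expect_equal(nrow(pred), nrow(b$pre))
  expect_equal(pcl_matrix(pred) - pcl_matrix(b$pre), as.matrix(disp),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(predict(m, ft[, -5]), "schema error")

  # fixed seed implies bit-identical predictions end to end
  m2 <- train_deform_model(ds[1:6], tc,
                           list(n_trees = 5L, max_features = 4L, leaf_size = 5L))
  expect_identical(as.matrix(predict(m2, ft)), as.matrix(disp))
})

test_that("adaptive weighting keeps best-so-far semantics and unit-weight start", {
  ds <- tiny_dataset()
  tc <- train_config("rf", "average", adaptive = TRUE,
                     max_adaptive_iters = 8, seed = 13)
  tm <- assemble_training_matrix(ds[1:6])
  tm <- sample_points(tm, tc$sampling_rate, tc$seed)
  m <- adaptive_weight_loop(tm, tc, list(n_trees = 5L, max_features = 8L,
                                         leaf_size = 5L))
  expect_s3_class(m, "deform_model")
  expect_true(nrow(m$trace) >= 1)
  expect_true(all(m$weights %in% 1:6))
  # returned model's objective equals the best seen in the trace
  expect_equal(min(m$trace$objective),
               m$trace$objective[which.min(m$trace$objective)])
  # a perfect-fit target (all zero displacement) exits with unit weights
  tm0 <- tm
  tm0$dx <- 0; tm0$dy <- 0; tm0$dz <- 0
  m0 <- adaptive_weight_loop(tm0, tc, list(n_trees = 5L, max_features = 8L,
                                           leaf_size = 5L))
  expect_true(all(m0$weights == 1))
  expect_lte(nrow(m0$trace), tc$patience + 1)
})

test_that("multi-output forest predicts three axes jointly and deterministically", {
  ds <- tiny_dataset()
  tc <- train_config("mor", "average", seed = 3)
  hp <- list(n_trees = 5L, max_features = 8L, leaf_size = 5L)
  m <- train_multi_output(ds[1:6], tc, hp)
  b <- ds[[7]]
  ft <- compute_features(b$pre, b$cylinder, b$case)
  disp <- predict(m, ft)
  expect_equal(ncol(disp), 3)
  expect_equal(nrow(disp), nrow(ft))
  m2 <- train_multi_output(ds[1:6], tc, hp)
  expect_identical(as.matrix(predict(m2, ft)), as.matrix(disp))
  # the joint forest learns structure: beats predicting the global mean
  tm <- assemble_training_matrix(ds[7:10])
  truth <- cbind(tm$dx, tm$dy, tm$dz)
  pred <- as.matrix(predict(m, tm))
  mean_pred <- matrix(colMeans(truth), nrow(truth), 3, byrow = TRUE)
  expect_lt(mean(rowSums((pred - truth)^2)),
            mean(rowSums((mean_pred - truth)^2)))
})

test_that("gradient boosting trains per axis under weak-learner constraints", {
  ds <- tiny_dataset()
  tc <- train_config("gbr", "average", seed = 17)
  hp <- list(n_trees = 50L, max_features = 8L, leaf_size = 2L,
             learning_rate = 0.3)
  m <- train_deform_model(ds[1:48], tc, hp)
  b <- ds[[60]]
  pred <- predict_post(m, b$pre, b$cylinder, b$case)
  got <- pairwise_distance(pred, b$post)
  base <- pairwise_distance(b$pre, b$post)
  expect_lt(got$mu, base$mu)
})

test_that("importances normalize to 100% per axis and expose group structure", {
  ds <- tiny_dataset()
  tc <- train_config("rf", "average", seed = 29)
  m <- train_deform_model(ds[1:12], tc,
                          list(n_trees = 10L, max_features = 8L,
                               leaf_size = 5L))
  imp <- feature_importances(m)
  sums <- imp |> dplyr::group_by(axis) |>
    dplyr::summarise(s = sum(importance_pct))
  expect_equal(sums$s, rep(100, 3), tolerance = 1e-6)
  expect_equal(sort(unique(imp$group)), sort(unique(feature_groups()$group)))

  # one-hot columns that are constant in training carry ~zero importance
  # (all 12 training cases share patient P1's laterality)
  lat_const <- unique(dplyr::bind_rows(purrr::map(ds[1:12], "case"))$laterality)
  expect_length(lat_const, 1)
  lat_imp <- imp$importance_pct[imp$feature %in% c("R", "L")]
  expect_true(all(lat_imp < 1e-8))

  gi <- grouped_importances(m)
  expect_equal(nrow(gi), 3 * 8)
  expect_error(feature_importances(
    train_multi_output(ds[1:4], train_config("mor"),
                       list(n_trees = 5L, max_features = 8L, leaf_size = 5L))
  ), "unsupported")

  # broom-style accessors
  expect_identical(tidy(m), feature_importances(m))
  g <- glance(m)
  expect_equal(g$kind, "rf")
  expect_equal(g$n_trees, 10L)
})
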