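test_that("rating binarisation uses a strict threshold with ties to low", {
  r <- rating_set(cbind(c(1, 5, 5.1, 9), c(2, 4.9, 5.0001, 8)))
  expect_equal(binarize_ratings(r, "valence"), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_ratings(r, "arousal"), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_ratings(r, "valence", threshold = 8), c(0L, 0L, 0L, 1L))
})

test_that("k-fold partitions are disjoint, exhaustive and balanced", {
  for (case in list(c(2400, 10), c(100, 7), c(5, 5), c(17, 4))) {
    n <- case[1]; k <- case[2]
    folds <- kfold_indices(n, k, seed = 13)
    test_sizes <- vapply(folds, function(f) length(f$test), 0L)
    expect_equal(sum(test_sizes), n)
    expect_lte(diff(range(test_sizes)), 1)
    all_test <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_equal(all_test, seq_len(n))
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0)
      expect_equal(sort(c(f$train, f$test)), seq_len(n))
    }
  }
  # the DEAP protocol: 240-sample test folds, 2160-sample training sets
  folds <- kfold_indices(2400, 10, seed = 1)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 240L))
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 2160L))
  # shuffling depends on the seed, partition properties do not
  f2 <- kfold_indices(2400, 10, seed = 2)
  expect_false(identical(folds, f2))
  expect_error(kfold_indices(10, 1), "k")
  expect_error(kfold_indices(10, 11), "k")
})

test_that("leave-one-out is k-fold with k = n", {
  folds <- kfold_indices(5, 5, seed = 3)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 1L))
  cubes <- small_cubes()
  n <- dim(cubes$values)[1]
  both <- c(which(cubes$labels == 0)[1:3], which(cubes$labels == 1)[1:3])
  r <- run_cv(subset_cubes(cubes, both),
              tiny_cae_config(epochs = 1, warmup_epochs = 0, pretrain_epochs = 0),
              scheme = "leave_one_out", seed = 5)
  expect_equal(r$k, 6L)
  expect_length(r$per_fold_accuracy, 6)
})

test_that("cross-validation is deterministic and aggregates fold accuracies", {
  cubes <- small_cubes()
  cc <- tiny_cae_config(epochs = 2, pretrain_epochs = 1)
  r1 <- run_cv(cubes, cc, k = 2, seed = 9)
  r2 <- run_cv(cubes, cc, k = 2, seed = 9)
  expect_identical(r1$per_fold_accuracy, r2$per_fold_accuracy)
  expect_equal(r1$mean_accuracy, mean(r1$per_fold_accuracy))
  expect_equal(r1$fold_status, rep("ok", 2))
})

test_that("single-class training folds are recorded as failed, not fatal", {
  cubes <- small_cubes()
  # force a single-class situation: keep only class-0 cubes plus one class-1
  idx <- c(which(cubes$labels == 0), which(cubes$labels == 1)[1])
  sub <- subset_cubes(cubes, idx)
  r <- run_cv(sub, tiny_cae_config(epochs = 1, warmup_epochs = 0, pretrain_epochs = 0),
              k = length(idx), scheme = "kfold", seed = 2)
  expect_true(any(grepl("single-class", r$fold_status)))
  expect_true(any(is.na(r$per_fold_accuracy)))
})

test_that("trial-grouped splitting keeps a trial's segments together", {
  cubes <- small_cubes()
  expect_message(
    r <- run_cv(cubes, tiny_cae_config(epochs = 1, warmup_epochs = 0,
                                       pretrain_epochs = 0),
                k = 2, seed = 4, group_by_trial = TRUE),
    "trial-grouped")
  expect_equal(r$k, 2L)
})

test_that("the band grid covers the 15 subsets in canonical order", {
  subs <- band_subsets()
  expect_length(subs, 15)
  expect_equal(lengths(subs), c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4))
  expect_equal(subs[[15]], c("theta", "alpha", "beta", "gamma"))
  expect_equal(subs[[10]], c("beta", "gamma"))
})

test_that("band_combination_grid runs end to end per subset and dimension", {
  subj <- small_subject()
  feats <- small_features()
  grid <- band_combination_grid(feats, subj$ratings,
                                config = tiny_cae_config(epochs = 1, warmup_epochs = 0,
                                                         pretrain_epochs = 0),
                                subsets = list("gamma", c("beta", "gamma")),
                                dimensions = c("valence", "arousal"),
                                k = 2, seed = 6)
  expect_equal(nrow(grid$table), 4)
  expect_setequal(unique(grid$table$dimension), c("valence", "arousal"))
  expect_setequal(unique(grid$table$bands), c("gamma", "beta+gamma"))
  expect_equal(grid$table$n_bands, c(1, 2, 1, 2))
  # singleton subsets run with cube depth 1
  expect_true(all(is.finite(grid$table$mean_accuracy)))
})

test_that("subject aggregation averages per-subject means", {
  expect_equal(aggregate_subjects(c(0.8, 0.9))$mean_accuracy, 0.85)
  one <- aggregate_subjects(0.77)
  expect_equal(one$mean_accuracy, 0.77)
  expect_equal(one$sd_accuracy, 0)
  r <- structure(list(mean_accuracy = 0.6), class = "cv_result")
  s <- structure(list(mean_accuracy = 0.8), class = "cv_result")
  agg <- aggregate_subjects(list(r, s))
  expect_equal(agg$mean_accuracy, 0.7)
  expect_equal(agg$n_subjects, 2)
  # order invariance
  expect_equal(aggregate_subjects(list(s, r))$mean_accuracy, 0.7)
  expect_error(aggregate_subjects(list()), "non-empty")
})
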