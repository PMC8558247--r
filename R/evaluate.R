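#' Binarise continuous ratings into low/high classes
#'
#' Ratings strictly above the threshold map to the high class (1), ratings at
#' or below it to the low class (0). The conventional cut on the 1-9 scale is
#' 5; a rating of exactly 5 is low.
#'
#' @param ratings a [rating_set()] or trials x 2 matrix.
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold binarisation cut (default 5).
#' @return integer 0/1 vector, one label per trial.
#' @export
binarize_ratings <- function(ratings, dimension = c("valence", "arousal"),
                             threshold = 5) {
  dimension <- match.arg(dimension)
  ratings <- rating_set(unclass(as.matrix(ratings)))
  as.integer(ratings[, dimension] > threshold)
}

#' Shuffled k-fold partition of sample indices
#'
#' Indices are shuffled by the seed, then split into k folds whose sizes
#' differ by at most one; folds are disjoint and jointly exhaustive.
#' Leave-one-out is the special case `k = n`.
#'
#' @param n_samples number of samples.
#' @param k number of folds, `2 <= k <= n_samples`.
#' @param seed integer seed for the shuffle.
#' @return list of `k` elements, each `list(train = ..., test = ...)`.
#' @export
kfold_indices <- function(n_samples, k, seed = 1) {
  if (!is_count(n_samples)) stopf("`n_samples` must be a positive integer")
  if (!is_count(k) || k < 2 || k > n_samples)
    stopf("`k` must lie in [2, n_samples]; got k = %s, n = %d",
          format(k), n_samples)
  set.seed(seed)
  perm <- sample.int(n_samples)
  # sizes differ by <= 1: first (n mod k) folds get the extra sample
  sizes <- rep(n_samples %/% k, k) + c(rep(1L, n_samples %% k),
                                       rep(0L, k - n_samples %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(perm[starts[i]:ends[i]])
    list(train = sort(setdiff(seq_len(n_samples), test)), test = test)
  })
}

#' Cross-validated accuracy of the classifier on one cube set
#'
#' Trains a fresh model per fold on the training split only and measures
#' accuracy on the held-out fold; nothing fitted on a test fold (including
#' the SAE input standardisation) ever reaches its training. Folds whose
#' training split contains a single class are recorded as failed (accuracy
#' `NA`) with an explicit status.
#'
#' @param cubes a labelled `feature_cube_set`.
#' @param config a [cae_config()]; each fold trains with a derived seed.
#' @param scheme `"kfold"` or `"leave_one_out"`.
#' @param k number of folds for `"kfold"` (default 10).
#' @param seed integer seed for fold shuffling and per-fold training seeds.
#' @param group_by_trial logical; if `TRUE`, folds are drawn over whole
#'   trials so that segments of one trial never straddle the train/test
#'   boundary. The default (`FALSE`) splits at the segment level, which is
#'   optimistic when segments of a trial are correlated; choosing `TRUE`
#'   emits a message noting the protocol change.
#' @param dimension optional tag (`"valence"`/`"arousal"`) carried in the result.
#' @param band_subset optional tag naming the band subset used.
#' @return object of class `cv_result`: scheme, k, `per_fold_accuracy`,
#'   `mean_accuracy`, `fold_status`, seed, tags.
#' @export
run_cv <- function(cubes, config = cae_config(),
                   scheme = c("kfold", "leave_one_out"), k = 10, seed = 1,
                   group_by_trial = FALSE,
                   dimension = NA_character_, band_subset = NA_character_) {
  scheme <- match.arg(scheme)
  if (!inherits(cubes, "feature_cube_set")) stopf("`cubes` must be a feature_cube_set")
  n <- dim(cubes$values)[1L]
  if (group_by_trial) {
    message("trial-grouped splitting: folds respect trial boundaries")
    trials <- sort(unique(cubes$trial))
    if (scheme == "leave_one_out") k <- length(trials)
    tfolds <- kfold_indices(length(trials), k, seed = seed)
    folds <- lapply(tfolds, function(f)
      list(train = which(cubes$trial %in% trials[f$train]),
           test = which(cubes$trial %in% trials[f$test])))
  } else {
    if (scheme == "leave_one_out") k <- n
    folds <- kfold_indices(n, k, seed = seed)
  }
  fold_seeds <- derive_seeds(seed, k)
  acc <- rep(NA_real_, k)
  status <- rep("ok", k)
  for (i in seq_len(k)) {
    tr <- subset_cubes(cubes, folds[[i]]$train)
    te <- subset_cubes(cubes, folds[[i]]$test)
    if (length(unique(tr$labels)) < 2L) {
      status[i] <- "failed: single-class training split"
      next
    }
    cfg <- config
    cfg$seed <- fold_seeds[i]
    model <- train_cae(tr, cfg)
    pred <- predict(model, te)
    acc[i] <- mean(pred$class == te$labels)
  }
  ok <- !is.na(acc)
  structure(list(scheme = scheme, k = as.integer(k),
                 per_fold_accuracy = acc,
                 mean_accuracy = mean(acc[ok]),
                 fold_status = status, seed = as.integer(seed),
                 dimension = dimension, band_subset = band_subset),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s (k = %d)%s: mean accuracy %.4f (folds %s)\n",
              x$scheme, x$k,
              if (is.na(x$dimension)) "" else paste0(", ", x$dimension),
              x$mean_accuracy,
              paste(sprintf("%.2f", x$per_fold_accuracy), collapse = " ")))
  invisible(x)
}

#' The 15 non-empty rhythm subsets, in canonical grid order
#'
#' @return list of character vectors: the four singletons, six pairs, four
#'   triples and the full theta+alpha+beta+gamma set.
#' @export
band_subsets <- function() {
  b <- band_order()
  out <- list()
  for (size in 1:4)
    out <- c(out, utils::combn(b, size, simplify = FALSE))
  out
}

#' Cross-validated accuracy over a grid of band subsets
#'
#' Re-runs the full fuse-and-classify pipeline for every requested band
#' subset and rating dimension: cubes are rebuilt at the subset's depth,
#' a fresh model is cross-validated per cell.
#'
#' @param features a `segmented_de`.
#' @param ratings a [rating_set()].
#' @param config a [cae_config()].
#' @param subsets list of band subsets (default: all 15 non-empty subsets).
#' @param dimensions rating dimensions to evaluate.
#' @param layout a `channel_layout`.
#' @param scheme,k,seed cross-validation scheme (see [run_cv()]).
#' @param threshold rating binarisation cut.
#' @return list with `table` (one row per subset x dimension: bands,
#'   dimension, mean accuracy, k) and `results` (the full `cv_result`s).
#' @export
band_combination_grid <- function(features, ratings, config = cae_config(),
                                  subsets = band_subsets(),
                                  dimensions = c("valence", "arousal"),
                                  layout = default_layout(),
                                  scheme = "kfold", k = 10, seed = 1,
                                  threshold = 5) {
  if (length(subsets) < 1L) stopf("`subsets` must name at least one band subset")
  rows <- list()
  results <- list()
  seeds <- derive_seeds(seed, length(subsets) * length(dimensions))
  i <- 0L
  for (dim_name in dimensions) {
    labels <- binarize_ratings(ratings, dim_name, threshold = threshold)
    for (subset in subsets) {
      i <- i + 1L
      cubes <- build_cubes(features, labels, layout = layout, bands = subset)
      res <- run_cv(cubes, config, scheme = scheme, k = k, seed = seeds[i],
                    dimension = dim_name,
                    band_subset = paste(cubes$bands, collapse = "+"))
      results[[i]] <- res
      rows[[i]] <- data.frame(dimension = dim_name,
                              bands = res$band_subset,
                              n_bands = length(subset),
                              mean_accuracy = res$mean_accuracy,
                              k = res$k, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), results = results)
}

#' Aggregate per-subject cross-validation results
#'
#' Mean and standard deviation of the per-subject mean accuracies — the
#' subject-dependent summary protocol (each model is trained and tested
#' within one subject; subjects are averaged afterwards).
#'
#' @param results non-empty list of `cv_result` objects (or numeric vector of
#'   per-subject mean accuracies).
#' @return list with `mean_accuracy`, `sd_accuracy`, `n_subjects`,
#'   `per_subject`.
#' @export
aggregate_subjects <- function(results) {
  if (length(results) < 1L) stopf("`results` must be non-empty")
  per <- if (is.numeric(results)) as.numeric(results)
         else vapply(results, function(r) {
           if (!inherits(r, "cv_result")) stopf("list elements must be cv_result objects")
           r$mean_accuracy
         }, 0)
  list(mean_accuracy = mean(per),
       sd_accuracy = if (length(per) > 1L) stats::sd(per) else 0,
       n_subjects = length(per),
       per_subject = per)
}
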