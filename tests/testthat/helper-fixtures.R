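# Shared fixtures: small synthetic subjects and cube sets, generated in code.
# Expensive ones are built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

# small but full-width subject: 32 channels, short trials
small_subject <- function(seed = 7, n_trials = 8, trial_seconds = 7, ...) {
  key <- paste0("subj_", seed, "_", n_trials, "_", trial_seconds)
  if (is.null(.fixtures[[key]])) {
    cfg <- synthesis_config(n_trials = n_trials, trial_seconds = trial_seconds,
                            seed = seed, ...)
    .fixtures[[key]] <- generate_subject(cfg)
  }
  .fixtures[[key]]
}

small_features <- function(seed = 7, n_trials = 8, trial_seconds = 7) {
  key <- paste0("feat_", seed, "_", n_trials, "_", trial_seconds)
  if (is.null(.fixtures[[key]])) {
    subj <- small_subject(seed, n_trials, trial_seconds)
    banded <- apply_band_filters(subj$recording)
    .fixtures[[key]] <- extract_features(banded)
  }
  .fixtures[[key]]
}

small_cubes <- function(seed = 7, n_trials = 8, trial_seconds = 7,
                        dimension = "valence") {
  subj <- small_subject(seed, n_trials, trial_seconds)
  feats <- small_features(seed, n_trials, trial_seconds)
  build_cubes(feats, binarize_ratings(subj$ratings, dimension))
}

# a quick-to-train reduced model configuration
tiny_cae_config <- function(...) {
  defaults <- list(conv_layers = list(c(4, 3), c(4, 1)), sae_hidden = c(16, 8),
                   warmup_epochs = 1, pretrain_epochs = 3, epochs = 5,
                   batch_size = 64, seed = 3)
  do.call(cae_config, utils::modifyList(defaults, list(...)))
}

# brute-force convolution stack: direct sliding-window evaluation of the
# convolution sum, independent of the batched gather/matmul implementation
brute_force_encode <- function(params, cube, activation = "relu") {
  g <- params$grid_size
  stack <- cube  # g x g x depth
  for (layer in params$conv) {
    k <- layer$k
    offs <- eegcae:::conv_offsets(k)
    cin <- dim(stack)[3L]
    cout <- length(layer$b)
    out <- array(0, dim = c(g, g, cout))
    for (j in seq_len(cout)) {
      for (x in seq_len(g)) for (y in seq_len(g)) {
        acc <- layer$b[j]
        o <- 0L
        for (dy in offs) for (dx in offs) {
          o <- o + 1L
          sx <- x + dx; sy <- y + dy
          if (sx >= 1L && sx <= g && sy >= 1L && sy <= g)
            acc <- acc + sum(layer$W[[o]][, j] * stack[sx, sy, ])
        }
        out[x, y, j] <- acc
      }
    }
    stack <- if (activation == "relu") pmax(out, 0) else out
  }
  # flatten cell-fastest (row, then column), band-plane last
  as.vector(stack)
}
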