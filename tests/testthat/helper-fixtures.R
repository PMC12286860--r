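# Shared fixtures, built once per test run and memoised. Sizes are chosen so
# that the full suite stays in the minutes range on one CPU: a 16x16 world
# with a (4, 8, 8, 16)-unit extractor gives layer dimensions 256/128/32/16
# and a 128-unit encoding layer.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_extractor <- function() {
  fixture("extractor", function() {
    toy_extractor(seed = 5, input_size = 16, conv_channels = c(4, 8, 8),
                  dense_units = 16)
  })
}

tiny_world <- function() {
  fixture("world", function() {
    make_stimulus_world(seed = 1, n_train = 150, n_test = 40,
                        n_categories = 10, image_size = 16,
                        extractor = tiny_extractor())
  })
}

world_train_features <- function() {
  w <- tiny_world()
  subset_stack(w$features, w$split == "train")
}

world_test_features <- function() {
  w <- tiny_world()
  subset_stack(w$features, w$split == "test")
}

# Noiseless subject at the standard simulation width (96 voxels), used for
# converter training and self-conversion checks.
noiseless_subject <- function() {
  fixture("subject0", function() {
    make_virtual_subject(seed = 11, tiny_world(), n_voxels = 96,
                         noise_sd = 0, sparsity = 0.2)
  })
}

# Recovery subject: 140 voxels >= the 128-unit encoding layer, so the voxel
# pattern determines the encoding features exactly and a vanishing-penalty
# ridge decoder can recover them.
recovery_subject <- function() {
  fixture("subject_rec", function() {
    make_virtual_subject(seed = 12, tiny_world(), n_voxels = 140,
                         noise_sd = 0, sparsity = 0.3)
  })
}

recovery_sessions <- function() {
  fixture("sessions_rec", function() {
    s <- recovery_subject()
    list(train = simulate_session(s, train_set(tiny_world()), 1, seed = 2),
         test = simulate_session(s, test_set(tiny_world()), 2, seed = 3))
  })
}

recovery_decoder <- function() {
  fixture("decoder_rec", function() {
    suppressWarnings(fit_feature_decoder(
      recovery_sessions()$train, world_train_features(),
      n_voxels_select = 500, ridge_penalty = 1e-6))
  })
}

noiseless_sessions <- function() {
  fixture("sessions0", function() {
    s <- noiseless_subject()
    list(train = simulate_session(s, train_set(tiny_world()), 1, seed = 2),
         test = simulate_session(s, test_set(tiny_world()), 2, seed = 3))
  })
}

noiseless_decoder <- function() {
  fixture("decoder0", function() {
    suppressWarnings(fit_feature_decoder(
      noiseless_sessions()$train, world_train_features(),
      n_voxels_select = 500, ridge_penalty = 1e-6))
  })
}

# An independent brute-force Pearson correlation used by oracle tests.
loop_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  num / den
}
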