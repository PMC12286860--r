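# Noise ceilings, conversion accuracy, identification, pairs, bootstrap.

test_that("noise ceilings are exact for degenerate repetition structures", {
  set.seed(51)
  pat <- matrix(rnorm(5 * 8), 5, 8)
  # identical repetitions -> ceilings 1, nothing excluded
  resp <- array(0, dim = c(5, 2, 8))
  resp[, 1, ] <- pat
  resp[, 2, ] <- pat
  nc <- estimate_noise_ceiling(response_dataset(resp, letters[1:5], "s"),
                               n_null = 500, seed = 1)
  expect_equal(nc$pattern, rep(1, 5))
  expect_equal(nc$profile, rep(1, 8))
  expect_length(nc$excluded_stimuli, 0)
  # sign-flipped second repetition -> pattern ceilings -1
  resp[, 2, ] <- -pat
  nc2 <- estimate_noise_ceiling(response_dataset(resp, letters[1:5], "s"),
                                n_null = 500, seed = 1)
  expect_equal(nc2$pattern, rep(-1, 5))
  # single repetition refuses
  expect_error(estimate_noise_ceiling(
    response_dataset(resp[, 1, , drop = FALSE], letters[1:5], "s")),
    "2 repetitions")
})

test_that("profile ceilings track the analytic signal fraction", {
  w <- fixture("snr_world", function() {
    make_stimulus_world(seed = 4, n_train = 200, n_test = 10,
                        n_categories = 8, image_size = 16,
                        extractor = tiny_extractor())
  })
  s <- make_virtual_subject(seed = 22, w, n_voxels = 60, noise_sd = 1,
                            sparsity = 0.2)
  ds <- simulate_session(s, train_set(w), n_repetitions = 2, seed = 6)
  nc <- estimate_noise_ceiling(ds, n_null = 500, seed = 2)
  expect_equal(mean(nc$profile), 0.5, tolerance = 0.05)

  # ceilings rise monotonically as noise shrinks, reaching 1 at zero noise
  ceilings <- vapply(c(1.5, 0.8, 0.3, 0), function(ns) {
    subj <- make_virtual_subject(seed = 22, w, n_voxels = 60, noise_sd = ns,
                                 sparsity = 0.2)
    d <- simulate_session(subj, train_set(w), 2, seed = 6)
    mean(estimate_noise_ceiling(d, n_null = 200, seed = 2)$profile)
  }, numeric(1))
  expect_true(all(diff(ceilings) > 0))
  expect_equal(ceilings[4], 1, tolerance = 1e-12)
})

test_that("conversion accuracy normalizes by ceilings and matches a loop", {
  set.seed(52)
  S <- 5; V <- 6
  meas <- matrix(rnorm(S * V), S, V)
  conv <- meas + matrix(rnorm(S * V, sd = 0.5), S, V)
  resp <- array(0, dim = c(S, 2, V))
  resp[, 1, ] <- meas + matrix(rnorm(S * V, sd = 0.3), S, V)
  resp[, 2, ] <- meas + matrix(rnorm(S * V, sd = 0.3), S, V)
  ds <- response_dataset(resp, letters[1:S], "s")
  nc <- estimate_noise_ceiling(ds, n_null = 300, seed = 3)
  ca <- conversion_accuracy(conv, ds, nc)
  avg <- apply(resp, c(1, 3), mean)
  for (i in 1:S) {
    raw <- loop_pearson(conv[i, ], avg[i, ])
    row <- ca$table[ca$table$metric == "pattern" & ca$table$item == i, ]
    expect_equal(row$raw, raw, tolerance = 1e-12)
    if (row$included) {
      expect_equal(row$normalized, raw / nc$pattern[i], tolerance = 1e-12)
    }
  }
  for (v in 1:V) {
    raw <- loop_pearson(conv[, v], avg[, v])
    row <- ca$table[ca$table$metric == "profile" & ca$table$item == v, ]
    expect_equal(row$raw, raw, tolerance = 1e-12)
  }
  # division contract: raw 0.45 over ceiling 0.9 -> 0.5
  ideal <- estimate_noise_ceiling(ds, n_null = 300, seed = 3)
  ideal$pattern[] <- 0.9
  ideal$excluded_stimuli <- integer(0)
  fake <- conversion_accuracy(conv, ds, ideal)
  prow <- fake$table[fake$table$metric == "pattern", ]
  expect_equal(prow$normalized, prow$raw / 0.9, tolerance = 1e-12)
  # perfect conversion with unit ceilings -> all normalized 1
  ceil1 <- ideal
  ceil1$pattern[] <- 1
  ceil1$profile[] <- 1
  ceil1$excluded_voxels <- integer(0)
  perfect <- conversion_accuracy(avg, ds, ceil1)
  expect_true(all(abs(perfect$table$normalized - 1) < 1e-12))
})

test_that("ceiling normalization gives a perfect converter accuracy ~ 1", {
  # the converted activity equals the true noiseless signal while the
  # measured data are noisy: raw correlations are capped by the ceiling,
  # but normalized accuracy should recover ~1 at any SNR
  w <- fixture("snr_world", function() {
    make_stimulus_world(seed = 4, n_train = 200, n_test = 10,
                        n_categories = 8, image_size = 16,
                        extractor = tiny_extractor())
  })
  # a perfect converter's output is statistically one more measurement of
  # the same signal, so it is compared against a single measurement with
  # the ceiling estimated from that subject's own repetitions
  for (ns in c(0.5, 1)) {
    s <- make_virtual_subject(seed = 23, w, n_voxels = 60, noise_sd = ns,
                              sparsity = 0.2)
    eval_session <- simulate_session(s, train_set(w), 1, seed = 8)
    converted <- response_matrix(simulate_session(s, train_set(w), 1,
                                                  seed = 9))
    ceiling_session <- simulate_session(s, train_set(w), 2, seed = 10)
    nc <- estimate_noise_ceiling(ceiling_session, n_null = 1000, seed = 5)
    ca <- conversion_accuracy(converted, eval_session, nc)
    raw_pattern <- mean(ca$table$raw[ca$table$metric == "pattern"],
                        na.rm = TRUE)
    expect_lt(raw_pattern, 0.95)   # raw accuracy is SNR-limited ...
    expect_equal(                  # ... but normalized accuracy is ~ 1
      ca$summary$mean_normalized[ca$summary$metric == "pattern"], 1,
      tolerance = 0.05)
    expect_equal(
      ca$summary$mean_normalized[ca$summary$metric == "profile"], 1,
      tolerance = 0.05)
  }
})

test_that("identification reproduces printed comparison counts and chance", {
  set.seed(53)
  for (S in c(50, 100)) {
    feats <- matrix(rnorm(S * 20), S, 20)
    res <- pairwise_identification(feats, feats)
    expect_equal(res$n_comparisons, S * (S - 1))
    expect_true(all(res$accuracy == 1))
  }
})

test_that("identification matches brute-force enumeration on a 3-item case", {
  # engineered: candidate 3 correlates better with true 1 than with its own
  tru <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  cand <- rbind(c(1, 0.1, 0, 0), c(0.1, 1, 0, 0), c(0.9, 0.1, 0.3, 0))
  res <- pairwise_identification(cand, tru)
  # brute force over all 6 ordered comparisons
  acc <- numeric(3)
  for (i in 1:3) {
    wins <- 0
    for (j in setdiff(1:3, i)) {
      ri <- loop_pearson(cand[i, ], tru[i, ])
      rj <- loop_pearson(cand[i, ], tru[j, ])
      wins <- wins + (ri > rj) + 0.5 * (ri == rj)
    }
    acc[i] <- wins / 2
  }
  expect_equal(res$accuracy, acc)
  expect_lt(res$accuracy[3], 1)   # the engineered failure

  # common positive affine transforms of candidates leave accuracy unchanged
  res2 <- pairwise_identification(2.7 * cand + 5, tru)
  expect_equal(res2$accuracy, res$accuracy)

  # zero-variance candidate row scores 0.5 everywhere and is flagged
  cand0 <- cand
  cand0[2, ] <- 3
  res3 <- pairwise_identification(cand0, tru)
  expect_equal(res3$accuracy[2], 0.5)
  expect_true(2 %in% res3$flagged)
})

test_that("pair enumeration reproduces the published pair counts", {
  deeprecon <- data.frame(subject_id = sprintf("d%d", 1:5),
                          dataset_id = "deeprecon")
  expect_equal(nrow(enumerate_conversion_pairs(deeprecon, "within_dataset")),
               20)
  roster <- rbind(deeprecon,
                  data.frame(subject_id = sprintf("t%d", 1:3),
                             dataset_id = "things"),
                  data.frame(subject_id = sprintf("n%d", 1:4),
                             dataset_id = "nsd"))
  inter <- enumerate_conversion_pairs(roster, "inter_site")
  expect_equal(nrow(inter), 94)
  expect_true(all(inter$source_dataset != inter$target_dataset))
  all_pairs <- enumerate_conversion_pairs(roster, "all")
  within <- enumerate_conversion_pairs(roster, "within_dataset")
  # |all| = |within| + |inter| for any roster
  expect_equal(nrow(all_pairs), nrow(within) + nrow(inter))
  expect_true(all(all_pairs$source_id != all_pairs$target_id))
  # single subject -> empty grid
  single <- enumerate_conversion_pairs(
    data.frame(subject_id = "a", dataset_id = "x"), "all")
  expect_equal(nrow(single), 0)
})

test_that("dyadic bootstrap excludes self-pairs and is seed-stable", {
  ids <- expand.grid(source_id = letters[1:3], target_id = letters[1:3],
                     stringsAsFactors = FALSE)
  ids <- ids[ids$source_id != ids$target_id, ]
  # constant values -> degenerate CI at the constant
  const <- cbind(ids, value = 0.7)
  ci <- dyadic_bootstrap(const, n_replicates = 200, seed = 1)
  expect_equal(ci$mean, 0.7)
  expect_equal(ci$lower, 0.7)
  expect_equal(ci$upper, 0.7)

  set.seed(54)
  pv <- cbind(ids, value = rnorm(nrow(ids), 0.5, 0.1))
  ci1 <- dyadic_bootstrap(pv, n_replicates = 2000, seed = 11)
  ci2 <- dyadic_bootstrap(pv, n_replicates = 2000, seed = 99)
  expect_lt(abs(ci1$lower - ci2$lower), 0.01)
  expect_lt(abs(ci1$upper - ci2$upper), 0.01)
  expect_lte(ci1$lower, ci1$upper)
  expect_error(dyadic_bootstrap(pv[pv$source_id == "a", ]), "2 distinct")
})

test_that("dyadic bootstrap replicates match a plain-loop oracle", {
  ids <- expand.grid(source_id = letters[1:4], target_id = letters[1:4],
                     stringsAsFactors = FALSE)
  ids <- ids[ids$source_id != ids$target_id, ]
  set.seed(55)
  pv <- cbind(ids, value = runif(nrow(ids)))
  ci <- dyadic_bootstrap(pv, n_replicates = 50, seed = 7)
  # independent re-implementation with the same RNG protocol
  oracle <- local({
    src <- unique(pv$source_id); tgt <- unique(pv$target_id)
    key <- paste(pv$source_id, pv$target_id, sep = "\r")
    lut <- stats::setNames(pv$value, key)
    n0 <- nrow(pv)
    set.seed(7)
    reps <- numeric(50)
    for (b in 1:50) {
      repeat {
        s <- sample(src, length(src), replace = TRUE)
        t <- sample(tgt, length(tgt), replace = TRUE)
        ks <- character(0)
        for (tt in t) for (ss in s) ks <- c(ks, paste(ss, tt, sep = "\r"))
        keep <- character(0)
        for (k in ks) {
          parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
          if (parts[1] != parts[2] && k %in% names(lut)) keep <- c(keep, k)
        }
        if (length(keep) > 0) break
      }
      vals <- unname(lut[keep])
      vals <- sample(vals, length(vals))
      vals <- if (length(vals) >= n0) vals[1:n0] else
        c(vals, sample(vals, n0 - length(vals), replace = TRUE))
      reps[b] <- mean(vals)
    }
    reps
  })
  expect_equal(ci$replicates, oracle, tolerance = 1e-12)
})

test_that("bootstrap CI width shrinks with pair-value dispersion", {
  ids <- expand.grid(source_id = letters[1:4], target_id = letters[1:4],
                     stringsAsFactors = FALSE)
  ids <- ids[ids$source_id != ids$target_id, ]
  set.seed(56)
  wide <- cbind(ids, value = rnorm(nrow(ids), 0.5, 0.2))
  narrow <- ids
  narrow$value <- 0.5 + (wide$value - 0.5) * 0.1
  ciw <- dyadic_bootstrap(wide, n_replicates = 500, seed = 5)
  cin <- dyadic_bootstrap(narrow, n_replicates = 500, seed = 5)
  expect_lt(cin$upper - cin$lower, ciw$upper - ciw$lower)
})
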