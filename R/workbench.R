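## End-to-end experiment runner on virtual subjects.
##
## Reproduces the pipeline shapes of the method: within-individual decoding,
## inter-individual / inter-site conversion with content- and brain-loss
## converters, training-size ladders, and cross-decoder generalization.
## Every stage is seeded from the experiment seed, so a metric table is a
## pure function of (config, seed).

#' Experiment configuration
#'
#' Defaults define the standard simulation conditions: 200 train / 50 test
#' stimuli per site, 96 voxels per subject, repetition noise at a moderate
#' signal-to-noise ratio (noise_sd 0.6), 1 training and 4 test repetitions,
#' decoder ridge penalty 10 (the method's canonical penalty of 100 is tied
#' to trial counts an order of magnitude larger; the penalty scales with
#' training sample count), and 512 content-loss iterations at Adam learning
#' rate 1e-2.
#'
#' @param datasets Named integer vector: subjects per site.
#' @param n_train,n_test,n_categories,image_size,texture_noise World
#'   parameters (see [make_stimulus_world()]).
#' @param n_voxels,noise_sd,sparsity Subject parameters.
#' @param train_reps,test_reps Repetitions per stimulus and split.
#' @param decoder_ridge,n_voxels_select Decoder parameters.
#' @param converter_kinds Subset of `c("content", "brain")` to evaluate
#'   where applicable (brain loss needs shared stimuli, so it is skipped
#'   for inter-site pairs).
#' @param content MLP variant for the content converter.
#' @param iterations,learning_rate Content training schedule.
#' @param nonoverlapping Train content converters on the source half of a
#'   category-disjoint split of the training stimuli while decoders use the
#'   target half (no shared stimuli or categories).
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(datasets = c(siteA = 5L),
                              n_train = 200L, n_test = 50L,
                              n_categories = 10L, image_size = 16L,
                              texture_noise = 0.25,
                              n_voxels = 96L, noise_sd = 0.6, sparsity = 0.2,
                              train_reps = 1L, test_reps = 4L,
                              decoder_ridge = 10, n_voxels_select = 500L,
                              converter_kinds = c("content", "brain"),
                              content = "content_mlp_nonlinear",
                              iterations = 512L, learning_rate = 1e-2,
                              nonoverlapping = FALSE, seed = 1L) {
  stopifnot(length(datasets) >= 1, all(datasets >= 1))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("site", LETTERS[seq_along(datasets)])
  }
  structure(list(datasets = datasets, n_train = n_train, n_test = n_test,
                 n_categories = n_categories, image_size = image_size,
                 texture_noise = texture_noise, n_voxels = n_voxels,
                 noise_sd = noise_sd, sparsity = sparsity,
                 train_reps = train_reps, test_reps = test_reps,
                 decoder_ridge = decoder_ridge,
                 n_voxels_select = n_voxels_select,
                 converter_kinds = converter_kinds, content = content,
                 iterations = iterations, learning_rate = learning_rate,
                 nonoverlapping = nonoverlapping, seed = seed),
            class = "experiment_config")
}

## Build worlds, subjects, sessions and decoders for every site/subject.
## One extractor is shared across sites (the latent content space is
## common); stimuli differ per site, so sites share no stimuli.
build_cohort <- function(config, extractor = NULL) {
  extractor <- extractor %||%
    toy_extractor(seed = derive_seed(config$seed, "extractor"),
                  input_size = config$image_size)
  worlds <- list()
  subjects <- list()
  sessions <- list()
  decoders <- list()
  roster <- data.frame(subject_id = character(0), dataset_id = character(0))
  sub_idx <- 0L
  for (site in names(config$datasets)) {
    world <- make_stimulus_world(
      seed = derive_seed(config$seed, paste0("world_", site)),
      n_train = config$n_train, n_test = config$n_test,
      n_categories = config$n_categories, image_size = config$image_size,
      texture_noise = config$texture_noise, extractor = extractor)
    halves <- if (config$nonoverlapping) {
      split_source_target_nonoverlapping(
        world, derive_seed(config$seed, paste0("split_", site)))
    }
    worlds[[site]] <- world
    for (k in seq_len(config$datasets[[site]])) {
      sub_idx <- sub_idx + 1L
      sid <- sprintf("sub%02d", sub_idx)
      subj <- make_virtual_subject(
        seed = derive_seed(config$seed, paste0("subject_", sid)),
        world = world, n_voxels = config$n_voxels,
        noise_sd = config$noise_sd, dataset_id = site, subject_id = sid,
        sparsity = config$sparsity)
      decoder_stimuli <- if (config$nonoverlapping) halves$target else train_set(world)
      converter_stimuli <- if (config$nonoverlapping) halves$source else train_set(world)
      dec_train <- simulate_session(
        subj, decoder_stimuli, config$train_reps,
        seed = derive_seed(config$seed, paste0("dectrain_", sid)))
      conv_train <- simulate_session(
        subj, converter_stimuli, config$train_reps,
        seed = derive_seed(config$seed, paste0("convtrain_", sid)))
      test <- simulate_session(
        subj, test_set(world), config$test_reps,
        seed = derive_seed(config$seed, paste0("test_", sid)))
      decoders[[sid]] <- suppressWarnings(fit_feature_decoder(
        dec_train, decoder_stimuli$features,
        n_voxels_select = config$n_voxels_select,
        ridge_penalty = config$decoder_ridge))
      subjects[[sid]] <- subj
      sessions[[sid]] <- list(decoder_train = dec_train,
                              converter_train = conv_train,
                              converter_stimuli = converter_stimuli,
                              test = test)
      roster <- rbind(roster, data.frame(subject_id = sid, dataset_id = site))
    }
  }
  list(extractor = extractor, worlds = worlds, subjects = subjects,
       sessions = sessions, decoders = decoders, roster = roster)
}

metric_row <- function(source_id, target_id, layer, metric, value,
                       n_items = NA_integer_, condition = "within") {
  data.frame(source_id = source_id, target_id = target_id, layer = layer,
             metric = metric, value = value, n_items = n_items,
             condition = condition)
}

#' Within-individual decoding benchmark
#'
#' Trains and tests a feature decoder on each subject's own data and emits
#' per-layer pattern/profile decoding accuracies and identification
#' accuracy of the decoded features.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-built cohort (from an internal builder shared
#'   by the experiment runners) to avoid re-simulation.
#' @return A metric table (data frame).
#' @export
run_within_individual <- function(config = experiment_config(),
                                  cohort = NULL) {
  cohort <- cohort %||% build_cohort(config)
  rows <- list()
  for (sid in names(cohort$subjects)) {
    site <- cohort$subjects[[sid]]$dataset_id
    world <- cohort$worlds[[site]]
    true_test <- subset_stack(world$features, world$split == "test")
    decoded <- decode_features(cohort$decoders[[sid]],
                               cohort$sessions[[sid]]$test)
    acc <- decoding_accuracy(decoded, true_test)
    for (nm in decoded$layer_order) {
      rows[[length(rows) + 1L]] <- rbind(
        metric_row(sid, sid, nm, "decoding_pattern",
                   acc$summary$pattern_mean[acc$summary$layer == nm],
                   nrow(decoded$layers[[nm]])),
        metric_row(sid, sid, nm, "decoding_profile",
                   acc$summary$profile_mean[acc$summary$layer == nm],
                   ncol(decoded$layers[[nm]])))
    }
    ident <- pairwise_identification(
      do.call(cbind, decoded$layers), do.call(cbind, true_test$layers))
    rows[[length(rows) + 1L]] <- metric_row(
      sid, sid, "all", "identification", ident$mean_accuracy,
      ident$n_comparisons)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

train_pair_converter <- function(kind, config, cohort, src, tgt) {
  ses <- cohort$sessions[[src]]
  if (kind == "content") {
    train_content_converter(
      ses$converter_train, ses$converter_stimuli$features,
      cohort$decoders[[tgt]],
      content_config(iterations = config$iterations,
                     learning_rate = config$learning_rate,
                     seed = derive_seed(config$seed,
                                        paste0("conv_", src, "_", tgt))),
      kind = config$content)
  } else {
    ## brain loss needs paired (shared-stimulus) data: the two subjects'
    ## responses to the source's training stimuli
    tgt_paired <- simulate_session(
      cohort$subjects[[tgt]], ses$converter_stimuli, config$train_reps,
      seed = derive_seed(config$seed, paste0("paired_", src, "_", tgt)))
    train_brain_loss_converter(response_matrix(ses$converter_train),
                               response_matrix(tgt_paired))
  }
}

#' Inter-individual / inter-site conversion experiment
#'
#' For every ordered pair in scope, trains the requested converters,
#' converts the source's held-out test responses into the target space, and
#' emits noise-ceiling-normalized conversion accuracy (within-site pairs
#' only: inter-site pairs have no measured target responses to the source's
#' stimuli), per-layer decoding accuracy through the target's decoder, and
#' identification accuracy of the decoded features.
#'
#' @param config An [experiment_config()].
#' @param scope Pair scope passed to [enumerate_conversion_pairs()].
#' @param max_pairs Optional cap on the number of pairs (first `n` in
#'   enumeration order), to bound runtime.
#' @param cohort Optional pre-built cohort.
#' @return A metric table (data frame) with one row per (pair, layer,
#'   metric).
#' @export
run_conversion_experiment <- function(config = experiment_config(),
                                      scope = "within_dataset",
                                      max_pairs = NULL, cohort = NULL) {
  cohort <- cohort %||% build_cohort(config)
  pairs <- enumerate_conversion_pairs(cohort$roster, scope)
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs) {
    pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  }
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    src <- pairs$source_id[p]
    tgt <- pairs$target_id[p]
    same_site <- pairs$source_dataset[p] == pairs$target_dataset[p]
    src_world <- cohort$worlds[[pairs$source_dataset[p]]]
    true_test <- subset_stack(src_world$features, src_world$split == "test")
    kinds <- config$converter_kinds
    if (!same_site) kinds <- setdiff(kinds, "brain")
    for (kind in kinds) {
      cond <- paste0(kind, "_loss")
      cv <- train_pair_converter(kind, config, cohort, src, tgt)
      converted <- convert_activity(cv, cohort$sessions[[src]]$test)
      if (same_site) {
        ## measured target responses to the SAME (source-site) test stimuli
        tgt_test <- cohort$sessions[[tgt]]$test
        nc <- estimate_noise_ceiling(
          tgt_test, n_null = 2000,
          seed = derive_seed(config$seed, paste0("null_", tgt)))
        ca <- conversion_accuracy(converted, tgt_test, nc)
        rows[[length(rows) + 1L]] <- rbind(
          metric_row(src, tgt, "voxel", "conversion_pattern",
                     ca$summary$mean_normalized[1], ca$summary$n_items[1],
                     cond),
          metric_row(src, tgt, "voxel", "conversion_profile",
                     ca$summary$mean_normalized[2], ca$summary$n_items[2],
                     cond))
      }
      decoded <- decode_features(cohort$decoders[[tgt]], converted,
                                 stimulus_ids = true_test$stimulus_ids)
      acc <- decoding_accuracy(decoded, true_test)
      for (nm in decoded$layer_order) {
        rows[[length(rows) + 1L]] <- metric_row(
          src, tgt, nm, "decoding_pattern",
          acc$summary$pattern_mean[acc$summary$layer == nm],
          nrow(decoded$layers[[nm]]), cond)
      }
      ident <- pairwise_identification(
        do.call(cbind, decoded$layers), do.call(cbind, true_test$layers))
      rows[[length(rows) + 1L]] <- metric_row(
        src, tgt, "all", "identification", ident$mean_accuracy,
        ident$n_comparisons, cond)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summary of a pair-level metric with dyadic bootstrap CI
#'
#' @param metrics A metric table from [run_conversion_experiment()].
#' @param metric Metric name to summarize.
#' @param layer Layer to summarize (default `"voxel"` / `"all"` rows too).
#' @param condition Converter condition to filter on, or `NULL` for all.
#' @param n_replicates,seed Bootstrap settings.
#' @return A [dyadic_bootstrap()] result.
#' @export
summarize_pairs <- function(metrics, metric, layer = NULL, condition = NULL,
                            n_replicates = 1000L, seed = 1L) {
  rows <- metrics[metrics$metric == metric, , drop = FALSE]
  if (!is.null(layer)) rows <- rows[rows$layer == layer, , drop = FALSE]
  if (!is.null(condition)) {
    rows <- rows[rows$condition == condition, , drop = FALSE]
  }
  dyadic_bootstrap(data.frame(source_id = rows$source_id,
                              target_id = rows$target_id,
                              value = rows$value),
                   n_replicates = n_replicates, seed = seed)
}

#' Converter training-size ladder
#'
#' Trains content-loss converters on nested subsets of the source training
#' samples (against the fixed full-size target decoder) and reports
#' identification accuracy of the decoded features per ladder size.
#'
#' @param config An [experiment_config()].
#' @param sizes Increasing training-set sizes (capped at the available
#'   training samples).
#' @param pair Character vector `c(source_id, target_id)`; defaults to the
#'   first within-site pair.
#' @param cohort Optional pre-built cohort.
#' @return A metric table with one identification row per size.
#' @export
run_training_size_ladder <- function(config = experiment_config(),
                                     sizes = c(25L, 50L, 100L, 200L),
                                     pair = NULL, cohort = NULL) {
  cohort <- cohort %||% build_cohort(config)
  if (is.null(pair)) {
    pairs <- enumerate_conversion_pairs(cohort$roster, "within_dataset")
    if (nrow(pairs) == 0) stop("no within-site pair available")
    pair <- c(pairs$source_id[1], pairs$target_id[1])
  }
  src <- pair[1]; tgt <- pair[2]
  ses <- cohort$sessions[[src]]
  world <- cohort$worlds[[cohort$subjects[[src]]$dataset_id]]
  true_test <- subset_stack(world$features, world$split == "test")
  rows <- list()
  for (sz in sizes) {
    sz <- min(sz, dim(ses$converter_train$responses)[1])
    sub_idx <- seq_len(sz)
    train_sub <- response_dataset(
      ses$converter_train$responses[sub_idx, , , drop = FALSE],
      ses$converter_train$stimulus_ids[sub_idx],
      ses$converter_train$subject_id, ses$converter_train$dataset_id,
      ses$converter_train$split)
    feats_sub <- subset_stack(ses$converter_stimuli$features, sub_idx)
    cv <- train_content_converter(
      train_sub, feats_sub, cohort$decoders[[tgt]],
      content_config(iterations = config$iterations,
                     learning_rate = config$learning_rate,
                     seed = derive_seed(config$seed,
                                        paste0("ladder_", sz))),
      kind = config$content)
    converted <- convert_activity(cv, ses$test)
    decoded <- decode_features(cohort$decoders[[tgt]], converted)
    ident <- pairwise_identification(
      do.call(cbind, decoded$layers), do.call(cbind, true_test$layers))
    rows[[length(rows) + 1L]] <- cbind(
      metric_row(src, tgt, "all", "identification", ident$mean_accuracy,
                 ident$n_comparisons, "content_loss"),
      data.frame(train_size = sz,
                 value_se = stats::sd(ident$accuracy) /
                   sqrt(length(ident$accuracy))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-decoder generalization of converted activity
#'
#' Tests whether converted activity is tailored to the decoder family used
#' during converter training: converters trained against extractor-A
#' (convnet) decoders are evaluated by decoding extractor-B (patchnet)
#' features with a separately trained target decoder, and compared with the
#' target's own within-individual extractor-B decoding. A
#' shuffled-stimulus negative control (converter trained on permuted
#' feature rows) is included when `shuffle_control = TRUE`.
#'
#' @param config An [experiment_config()].
#' @param extractor_b A second extractor defining the alternative feature
#'   space; default [patch_extractor()] at the config's image size.
#' @param pair `c(source_id, target_id)`; defaults to the first within-site
#'   pair.
#' @param shuffle_control Also run the permuted-features control.
#' @param cohort Optional pre-built cohort.
#' @return A metric table with per-layer extractor-B decoding accuracies
#'   under `within`, `cross_decoder`, and optionally `shuffled` conditions.
#' @export
run_cross_decoder_generalization <- function(config = experiment_config(),
                                             extractor_b = NULL, pair = NULL,
                                             shuffle_control = FALSE,
                                             cohort = NULL) {
  cohort <- cohort %||% build_cohort(config)
  extractor_b <- extractor_b %||%
    patch_extractor(seed = derive_seed(config$seed, "extractor_b"),
                    input_size = config$image_size)
  if (is.null(pair)) {
    pairs <- enumerate_conversion_pairs(cohort$roster, "within_dataset")
    if (nrow(pairs) == 0) stop("no within-site pair available")
    pair <- c(pairs$source_id[1], pairs$target_id[1])
  }
  src <- pair[1]; tgt <- pair[2]
  site <- cohort$subjects[[tgt]]$dataset_id
  world <- cohort$worlds[[site]]
  ses_src <- cohort$sessions[[src]]
  feats_b_train <- extract_features(
    extractor_b, world$images[world$split == "train", , , , drop = FALSE],
    stimulus_ids = world$stimulus_ids[world$split == "train"])
  feats_b_test <- extract_features(
    extractor_b, world$images[world$split == "test", , , , drop = FALSE],
    stimulus_ids = world$stimulus_ids[world$split == "test"])
  decoder_b <- suppressWarnings(fit_feature_decoder(
    cohort$sessions[[tgt]]$decoder_train, feats_b_train,
    n_voxels_select = config$n_voxels_select,
    ridge_penalty = config$decoder_ridge))
  rows <- list()
  emit <- function(decoded, cond, src_id) {
    acc <- decoding_accuracy(decoded, feats_b_test)
    for (nm in decoded$layer_order) {
      rows[[length(rows) + 1L]] <<- rbind(
        metric_row(src_id, tgt, nm, "decoding_pattern",
                   acc$summary$pattern_mean[acc$summary$layer == nm],
                   nrow(decoded$layers[[nm]]), cond),
        metric_row(src_id, tgt, nm, "decoding_profile",
                   acc$summary$profile_mean[acc$summary$layer == nm],
                   ncol(decoded$layers[[nm]]), cond))
    }
  }
  ## within: target's own test data through its extractor-B decoder
  emit(decode_features(decoder_b, cohort$sessions[[tgt]]$test), "within", tgt)
  ## cross-decoder: converter trained with extractor-A decoders
  cv <- train_pair_converter("content", config, cohort, src, tgt)
  converted <- convert_activity(cv, ses_src$test)
  emit(decode_features(decoder_b, converted), "cross_decoder", src)
  if (shuffle_control) {
    perm <- with_seed(derive_seed(config$seed, "shuffle"),
                      sample(nrow(ses_src$converter_stimuli$features$layers[[1]])))
    shuffled <- subset_stack(ses_src$converter_stimuli$features, perm)
    cv0 <- train_content_converter(
      ses_src$converter_train, shuffled, cohort$decoders[[tgt]],
      content_config(iterations = config$iterations,
                     learning_rate = config$learning_rate,
                     seed = derive_seed(config$seed, "shuffle_conv")),
      kind = config$content)
    emit(decode_features(decoder_b, convert_activity(cv0, ses_src$test)),
         "shuffled", src)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
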