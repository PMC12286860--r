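## Virtual subjects: simulated voxel encodings over a shared content space.
##
## Every subject reads out from the same latent feature hierarchy (the
## stimulus world's extractor), but through its own idiosyncratic linear
## voxel encoding drawn from a sparse Gaussian ensemble. Voxel signals are
## standardized to unit variance across the world's training stimuli, so a
## subject's `noise_sd` directly sets the per-voxel noise-to-signal ratio
## and the expected profile noise ceiling is 1 / (1 + noise_sd^2).

#' Create a simulated subject
#'
#' Draws a sparse Gaussian linear readout from the designated encoding
#' layer's flattened features to `n_voxels` voxels. Two subjects built from
#' different seeds share the content space but have uncorrelated functional
#' topographies.
#'
#' @param seed Integer seed for the encoding draw.
#' @param world A [make_stimulus_world()] object supplying the content space
#'   and the standardization reference (its training stimuli).
#' @param n_voxels Number of simulated voxels.
#' @param noise_sd Repetition noise standard deviation, in units of the
#'   (unit-variance) voxel signal; `>= 0`.
#' @param dataset_id Site label; subjects from different sites never share
#'   stimuli by construction of their worlds.
#' @param subject_id Identifier; generated from the seed when `NULL`.
#' @param encoding_layer Extractor layer the voxels read out from; defaults
#'   to the middle convolutional layer so that both lower and higher layers
#'   are only partially linearly decodable.
#' @param sparsity Fraction of nonzero entries per voxel readout (1 = dense).
#' @param max_voxels Guard against accidentally huge simulations.
#' @return An object of class `virtual_subject` carrying the encoding matrix
#'   `B` (`[n_voxels x feature_dim]`), bias, and noise level.
#' @export
make_virtual_subject <- function(seed, world, n_voxels = 200L, noise_sd = 0.6,
                                 dataset_id = "siteA", subject_id = NULL,
                                 encoding_layer = NULL, sparsity = 0.05,
                                 max_voxels = 5000L) {
  stopifnot(n_voxels >= 1, noise_sd >= 0)
  if (n_voxels > max_voxels) {
    stop("n_voxels = ", n_voxels, " exceeds the configured maximum ",
         max_voxels)
  }
  if (is.null(encoding_layer)) {
    convs <- world$features$layer_order[
      vapply(world$features$specs, is_spatial_spec, logical(1))]
    encoding_layer <- convs[ceiling(length(convs) / 2)]
  }
  feats <- world$features$layers[[encoding_layer]]
  d <- ncol(feats)
  train_feats <- feats[world$split == "train", , drop = FALSE]
  with_seed(seed, {
    B <- matrix(stats::rnorm(n_voxels * d), n_voxels, d)
    if (sparsity < 1) {
      mask <- matrix(stats::runif(n_voxels * d) < sparsity, n_voxels, d)
      empty <- rowSums(mask) == 0
      if (any(empty)) {
        for (v in which(empty)) mask[v, sample.int(d, 1)] <- TRUE
      }
      B <- B * mask
    }
    signal <- train_feats %*% t(B)
    s <- apply(signal, 2, stats::sd)
    s[s < .Machine$double.eps^0.5] <- 1
    B <- B / s
    bias <- stats::rnorm(n_voxels, 0, 0.1)
    if (n_voxels <= d) {
      if (qr(B)$rank < n_voxels) {
        stop("encoding matrix is rank deficient; increase sparsity or retry ",
             "with another seed")
      }
    }
    structure(list(subject_id = subject_id %||% sprintf("sub_%02d", seed %% 100L),
                   dataset_id = dataset_id, encoding_layer = encoding_layer,
                   B = B, bias = bias, noise_sd = noise_sd,
                   n_voxels = as.integer(n_voxels), seed = seed,
                   extractor_tag = world$extractor$name),
              class = "virtual_subject")
  })
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("<virtual_subject '", x$subject_id, "'> ", x$n_voxels, " voxels, site ",
      x$dataset_id, ", encoding layer ", x$encoding_layer, ", noise_sd ",
      x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Response dataset container
#'
#' @param responses Array `[stimuli x repetitions x voxels]`.
#' @param stimulus_ids Identifiers aligned with the first dimension.
#' @param subject_id,dataset_id Provenance labels.
#' @param split `"train"` or `"test"`.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(responses, stimulus_ids, subject_id,
                             dataset_id = "siteA", split = "train") {
  stopifnot(length(dim(responses)) == 3L,
            dim(responses)[1] == length(stimulus_ids))
  structure(list(responses = responses, stimulus_ids = stimulus_ids,
                 subject_id = subject_id, dataset_id = dataset_id,
                 split = split,
                 n_repetitions = dim(responses)[2]),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  d <- dim(x$responses)
  cat("<response_dataset '", x$subject_id, "'> ", d[1], " stimuli x ", d[2],
      " repetitions x ", d[3], " voxels (", x$split, ")\n", sep = "")
  invisible(x)
}

#' Simulate a measurement session
#'
#' Generates `response[i, r, v] = signal(i, v) + bias(v) + noise`, with the
#' signal the subject's linear readout of the stimulus features and noise
#' i.i.d. Gaussian across repetitions, stimuli and voxels (no temporal
#' autocorrelation: the method operates on trial-level response amplitudes).
#'
#' @param subject A [make_virtual_subject()] object.
#' @param stimuli A `stimulus_set` (e.g. [train_set()] or [test_set()]).
#' @param n_repetitions Repetitions per stimulus (`>= 1`).
#' @param seed Noise seed.
#' @return A [response_dataset()].
#' @export
simulate_session <- function(subject, stimuli, n_repetitions = 1L, seed = 1L) {
  stopifnot(n_repetitions >= 1)
  feats <- stimuli$features$layers[[subject$encoding_layer]]
  if (is.null(feats)) {
    stop("stimulus features lack the subject's encoding layer '",
         subject$encoding_layer, "'")
  }
  if (ncol(feats) != ncol(subject$B)) {
    stop("feature dimension ", ncol(feats), " does not match the subject's ",
         "encoding dimension ", ncol(subject$B))
  }
  n <- nrow(feats)
  signal <- feats %*% t(subject$B)
  signal <- sweep(signal, 2, subject$bias, "+")
  with_seed(seed, {
    resp <- array(0, dim = c(n, n_repetitions, subject$n_voxels))
    for (r in seq_len(n_repetitions)) {
      noise <- if (subject$noise_sd > 0) {
        matrix(stats::rnorm(n * subject$n_voxels, sd = subject$noise_sd),
               n, subject$n_voxels)
      } else 0
      resp[, r, ] <- signal + noise
    }
    split <- unique(stimuli$split)
    response_dataset(resp, stimuli$stimulus_ids, subject$subject_id,
                     subject$dataset_id,
                     if (length(split) == 1) split else "mixed")
  })
}

#' Average a response dataset over repetitions
#'
#' @param dataset A [response_dataset()].
#' @return A `response_dataset` with a single pseudo-repetition holding the
#'   per-stimulus mean; all metadata preserved.
#' @export
average_repetitions <- function(dataset) {
  d <- dim(dataset$responses)
  avg <- apply(dataset$responses, c(1, 3), mean)
  response_dataset(array(avg, dim = c(d[1], 1L, d[3])),
                   dataset$stimulus_ids, dataset$subject_id,
                   dataset$dataset_id, dataset$split)
}

#' Flatten a response dataset to a samples-by-voxels matrix
#'
#' Trial-level flattening interleaves repetitions (stimulus-major order);
#' the returned attribute `stimulus_index` maps rows back to stimuli.
#'
#' @param dataset A [response_dataset()].
#' @param average Average over repetitions first.
#' @return Matrix `[samples x voxels]` with attribute `stimulus_index`.
#' @export
response_matrix <- function(dataset, average = FALSE) {
  if (average) dataset <- average_repetitions(dataset)
  d <- dim(dataset$responses)
  out <- matrix(0, d[1] * d[2], d[3])
  idx <- integer(d[1] * d[2])
  row <- 1L
  for (i in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      out[row, ] <- dataset$responses[i, r, ]
      idx[row] <- i
      row <- row + 1L
    }
  }
  attr(out, "stimulus_index") <- idx
  out
}
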