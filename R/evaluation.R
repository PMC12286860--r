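## Conversion-accuracy metrics, identification analysis, and group statistics.

#' Estimate noise ceilings from repeated responses
#'
#' The pattern ceiling of a stimulus is the mean, over all repetition pairs,
#' of the Pearson correlation between the two repetitions' voxel patterns;
#' the profile ceiling of a voxel is the mean over repetition pairs of the
#' correlation between the voxel's two response sequences across stimuli.
#' The exclusion threshold is the 99th percentile of a random-pair null:
#' for patterns, correlations between repetition responses to MISMATCHED
#' stimuli; for profiles, correlations between mismatched voxels.
#'
#' @param dataset A [response_dataset()] with at least 2 repetitions.
#' @param n_null Seeded draws for each null distribution.
#' @param threshold_quantile Null quantile used as exclusion threshold.
#' @param seed Seed for the null draws.
#' @return An object of class `noise_ceiling` with per-stimulus pattern
#'   ceilings, per-voxel profile ceilings, thresholds, and exclusion sets.
#' @export
estimate_noise_ceiling <- function(dataset, n_null = 10000L,
                                   threshold_quantile = 0.99, seed = 1L) {
  resp <- dataset$responses
  d <- dim(resp)
  if (d[2] < 2) {
    stop("noise ceilings need at least 2 repetitions; with a single ",
         "repetition skip ceiling normalization")
  }
  pairs <- utils::combn(d[2], 2)
  pattern <- vapply(seq_len(d[1]), function(i) {
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      safe_cor(resp[i, pairs[1, p], ], resp[i, pairs[2, p], ])
    }, numeric(1)))
  }, numeric(1))
  profile <- vapply(seq_len(d[3]), function(v) {
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      safe_cor(resp[, pairs[1, p], v], resp[, pairs[2, p], v])
    }, numeric(1)))
  }, numeric(1))
  with_seed(seed, {
    null_pattern <- vapply(seq_len(n_null), function(k) {
      ij <- sample.int(d[1], 2)
      safe_cor(resp[ij[1], sample.int(d[2], 1), ],
               resp[ij[2], sample.int(d[2], 1), ])
    }, numeric(1))
    null_profile <- vapply(seq_len(n_null), function(k) {
      vw <- sample.int(d[3], 2)
      safe_cor(resp[, sample.int(d[2], 1), vw[1]],
               resp[, sample.int(d[2], 1), vw[2]])
    }, numeric(1))
    thr_pattern <- stats::quantile(null_pattern, threshold_quantile,
                                   na.rm = TRUE, names = FALSE)
    thr_profile <- stats::quantile(null_profile, threshold_quantile,
                                   na.rm = TRUE, names = FALSE)
    structure(list(pattern = pattern, profile = profile,
                   pattern_threshold = thr_pattern,
                   profile_threshold = thr_profile,
                   excluded_stimuli = which(is.na(pattern) | pattern < thr_pattern),
                   excluded_voxels = which(is.na(profile) | profile < thr_profile),
                   threshold_quantile = threshold_quantile, n_null = n_null),
              class = "noise_ceiling")
  })
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat("<noise_ceiling> mean pattern ", round(mean(x$pattern, na.rm = TRUE), 3),
      " (", length(x$excluded_stimuli), " stimuli excluded), mean profile ",
      round(mean(x$profile, na.rm = TRUE), 3),
      " (", length(x$excluded_voxels), " voxels excluded)\n", sep = "")
  invisible(x)
}

#' Noise-ceiling-normalized conversion accuracy
#'
#' Raw pattern correlations (converted vs repetition-averaged measured
#' pattern, per test stimulus) and profile correlations (per voxel, across
#' test stimuli) are divided by their respective noise ceilings; items in
#' the ceiling's exclusion sets, and items with non-positive ceilings, are
#' excluded from the means.
#'
#' @param converted Matrix `[stimuli x voxels]` of converted activity.
#' @param measured A [response_dataset()] of the target's measured test
#'   responses (repetition-averaged internally).
#' @param ceiling A [estimate_noise_ceiling()] result computed on the same
#'   measured test set.
#' @return List with `table` (tidy data frame: metric, item, raw, ceiling,
#'   normalized, included) and `summary` (mean normalized pattern and
#'   profile correlations with item counts).
#' @export
conversion_accuracy <- function(converted, measured, ceiling) {
  avg <- response_matrix(measured, average = TRUE)
  if (!all(dim(converted) == dim(avg))) {
    stop("converted (", nrow(converted), "x", ncol(converted),
         ") and measured (", nrow(avg), "x", ncol(avg), ") shapes differ")
  }
  raw_pattern <- rowwise_cor(converted, avg)
  raw_profile <- colwise_cor(converted, avg)
  make_rows <- function(metric, raw, ceil, excluded) {
    ok <- !(seq_along(raw) %in% excluded) & !is.na(ceil) & ceil > 0 & !is.na(raw)
    data.frame(metric = metric, item = seq_along(raw), raw = raw,
               ceiling = ceil, normalized = ifelse(ok, raw / ceil, NA_real_),
               included = ok)
  }
  tab <- rbind(
    make_rows("pattern", raw_pattern, ceiling$pattern, ceiling$excluded_stimuli),
    make_rows("profile", raw_profile, ceiling$profile, ceiling$excluded_voxels))
  summ <- data.frame(
    metric = c("pattern", "profile"),
    mean_normalized = c(
      mean(tab$normalized[tab$metric == "pattern"], na.rm = TRUE),
      mean(tab$normalized[tab$metric == "profile"], na.rm = TRUE)),
    n_items = c(sum(tab$included[tab$metric == "pattern"]),
                sum(tab$included[tab$metric == "profile"])))
  list(table = tab, summary = summ)
}

#' Pairwise identification accuracy
#'
#' For every stimulus, the candidate feature vector (e.g. features of a
#' reconstruction, or decoded features) is compared against the true feature
#' vector of that stimulus and each of the `S - 1` false alternatives drawn
#' from the same test set: an identification is correct when the candidate
#' correlates more with the true vector than with the false one. Exact ties
#' count 0.5 (unbiased under exchangeability); candidate rows with zero
#' variance have undefined correlations and score 0.5 on all their
#' comparisons (flagged).
#'
#' @param candidate Matrix `[S x D]` of candidate feature vectors.
#' @param true Matrix `[S x D]` of true feature vectors, rows aligned.
#' @return List with per-item `accuracy`, `mean_accuracy`, `n_comparisons`
#'   (`S * (S - 1)`), and `flagged` item indices.
#' @export
pairwise_identification <- function(candidate, true) {
  stopifnot(nrow(candidate) >= 2, all(dim(candidate) == dim(true)))
  S <- nrow(candidate)
  C <- matrix(NA_real_, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) C[i, j] <- safe_cor(candidate[i, ], true[j, ])
  }
  flagged <- integer(0)
  acc <- numeric(S)
  for (i in seq_len(S)) {
    if (is.na(C[i, i])) {
      acc[i] <- 0.5
      flagged <- c(flagged, i)
      next
    }
    others <- C[i, -i]
    wins <- ifelse(is.na(others), 0.5,
                   ifelse(C[i, i] > others, 1, ifelse(C[i, i] == others, 0.5, 0)))
    acc[i] <- mean(wins)
  }
  list(accuracy = acc, mean_accuracy = mean(acc),
       n_comparisons = S * (S - 1L), flagged = flagged)
}

#' Enumerate ordered conversion pairs over a subject roster
#'
#' @param subjects Data frame with columns `subject_id` and `dataset_id`.
#' @param scope `"within_dataset"` (both members share a site, source !=
#'   target), `"inter_site"` (sites differ), or `"all"` (their union).
#' @return Data frame of ordered pairs (`source_id`, `target_id`,
#'   `source_dataset`, `target_dataset`, `scope`); zero rows when no pair
#'   qualifies.
#' @export
enumerate_conversion_pairs <- function(subjects,
                                       scope = c("all", "within_dataset",
                                                 "inter_site")) {
  scope <- match.arg(scope)
  stopifnot(nrow(subjects) >= 1)
  g <- expand.grid(src = seq_len(nrow(subjects)), tgt = seq_len(nrow(subjects)))
  g <- g[g$src != g$tgt, , drop = FALSE]
  same_site <- subjects$dataset_id[g$src] == subjects$dataset_id[g$tgt]
  keep <- switch(scope, within_dataset = same_site, inter_site = !same_site,
                 all = rep(TRUE, nrow(g)))
  g <- g[keep, , drop = FALSE]
  out <- data.frame(source_id = subjects$subject_id[g$src],
                    target_id = subjects$subject_id[g$tgt],
                    source_dataset = subjects$dataset_id[g$src],
                    target_dataset = subjects$dataset_id[g$tgt],
                    scope = ifelse(subjects$dataset_id[g$src] ==
                                     subjects$dataset_id[g$tgt],
                                   "within_dataset", "inter_site"))
  rownames(out) <- NULL
  out
}

#' Dyadic bootstrap confidence interval for pair-level values
#'
#' Pair-level accuracies that share a subject are dependent, so ordinary
#' bootstrap resampling of pairs is invalid. Each replicate instead
#' resamples the source IDs and the target IDs with replacement, forms all
#' crossed pairs, drops pairs whose source and target IDs coincide, keeps
#' the pairs observed in the data, and truncates or refills (sampling with
#' replacement from the valid set) to the original sample size before
#' taking the mean. Replicates with zero valid pairs are redrawn (counted).
#'
#' @param pair_values Data frame with columns `source_id`, `target_id`,
#'   `value`.
#' @param n_replicates Bootstrap replicates.
#' @param confidence Confidence level of the percentile interval.
#' @param seed Seed for resampling.
#' @return An object of class `bootstrap_ci` with `mean`, `lower`, `upper`,
#'   `replicates`, and `n_redrawn`.
#' @export
dyadic_bootstrap <- function(pair_values, n_replicates = 1000L,
                             confidence = 0.95, seed = 1L) {
  src_ids <- unique(pair_values$source_id)
  tgt_ids <- unique(pair_values$target_id)
  if (length(src_ids) < 2 || length(tgt_ids) < 2) {
    stop("dyadic bootstrap needs at least 2 distinct source and target IDs")
  }
  key <- paste(pair_values$source_id, pair_values$target_id, sep = "\r")
  lookup <- stats::setNames(pair_values$value, key)
  n0 <- nrow(pair_values)
  with_seed(seed, {
    reps <- numeric(n_replicates)
    n_redrawn <- 0L
    for (b in seq_len(n_replicates)) {
      repeat {
        s <- sample(src_ids, length(src_ids), replace = TRUE)
        t <- sample(tgt_ids, length(tgt_ids), replace = TRUE)
        grid_keys <- paste(rep(s, times = length(t)),
                           rep(t, each = length(s)), sep = "\r")
        valid <- grid_keys[rep(s, times = length(t)) !=
                             rep(t, each = length(s))]
        valid <- valid[valid %in% names(lookup)]
        if (length(valid) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      vals <- unname(lookup[valid])
      vals <- sample(vals, length(vals))
      vals <- if (length(vals) >= n0) vals[seq_len(n0)] else {
        c(vals, sample(vals, n0 - length(vals), replace = TRUE))
      }
      reps[b] <- mean(vals)
    }
    alpha <- (1 - confidence) / 2
    ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
    structure(list(mean = mean(pair_values$value), lower = ci[1],
                   upper = ci[2], confidence = confidence,
                   n_replicates = n_replicates, seed = seed,
                   replicates = reps, n_redrawn = n_redrawn),
              class = "bootstrap_ci")
  })
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> mean %.4f, %d%% CI [%.4f, %.4f] (%d replicates)\n",
              x$mean, round(100 * x$confidence), x$lower, x$upper,
              x$n_replicates))
  invisible(x)
}
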