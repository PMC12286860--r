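## Neural code converters.
##
## The content-loss converter maps a source subject's voxel pattern x into
## the target subject's voxel space so that the target's pre-trained feature
## decoders, applied to the converted pattern, reproduce the true stimulus
## features. Training needs no paired brain data and no shared stimuli: the
## only inputs are the source's own responses, the features of the source's
## own stimuli, and the frozen target decoder. Baselines that DO require
## paired data (brain-loss ridge regression, orthogonal Procrustes) are
## provided for comparison.

#' Content-loss training configuration
#'
#' @param iterations Optimization iterations (one sampled-unit pass over the
#'   full training set and one optimizer step each).
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param weighting `"per_sample"` weighs each (stimulus, layer) term by
#'   `1 / ||v_il||^2` computed on the sampled units; `"per_layer"` uses one
#'   weight per layer (`1 /` mean squared norm), an ablation variant.
#' @param average_repetitions Train on repetition-averaged rather than
#'   trial-level source responses.
#' @param seed Seed for parameter initialization and per-iteration unit
#'   sampling.
#' @return A `content_config` list.
#' @export
content_config <- function(iterations = 1024L, learning_rate = 1e-3,
                           beta1 = 0.9, beta2 = 0.999,
                           weighting = c("per_sample", "per_layer"),
                           average_repetitions = FALSE, seed = 1L) {
  stopifnot(iterations >= 1, learning_rate > 0)
  list(iterations = as.integer(iterations), learning_rate = learning_rate,
       beta1 = beta1, beta2 = beta2, weighting = match.arg(weighting),
       average_repetitions = average_repetitions, seed = seed)
}

#' Content loss between decoded and true feature stacks
#'
#' Computes `sum_i sum_l eta_il || v_il - d_il ||^2` over the included
#' units, with `eta_il = 1 / ||v_il||^2` evaluated on those units (the
#' per-layer variant replaces the per-sample norm with its mean over
#' samples). Layers whose included unit set is empty (or whose true norm is
#' zero) contribute 0.
#'
#' @param decoded,true [feature_stack()]s (or plain named lists of matrices)
#'   with matching layers and stimuli.
#' @param units Optional named list of per-layer unit index vectors (e.g.
#'   from [sample_units_for_iteration()]); `NULL` uses all units.
#' @param weighting `"per_sample"` or `"per_layer"`.
#' @return List with `total` and `per_layer` loss values.
#' @export
content_loss <- function(decoded, true, units = NULL,
                         weighting = c("per_sample", "per_layer")) {
  weighting <- match.arg(weighting)
  dl <- if (inherits(decoded, "feature_stack")) decoded$layers else decoded
  tl <- if (inherits(true, "feature_stack")) true$layers else true
  stopifnot(identical(names(dl), names(tl)))
  per_layer <- numeric(0)
  for (nm in names(dl)) {
    idx <- if (is.null(units)) seq_len(ncol(tl[[nm]])) else units[[nm]]
    if (length(idx) == 0) {
      per_layer[nm] <- 0
      next
    }
    V <- tl[[nm]][, idx, drop = FALSE]
    D <- dl[[nm]][, idx, drop = FALSE]
    norms <- rowSums(V^2)
    eta <- if (weighting == "per_sample") {
      ifelse(norms > 0, 1 / norms, 0)
    } else {
      mn <- mean(norms)
      rep(if (mn > 0) 1 / mn else 0, nrow(V))
    }
    per_layer[nm] <- sum(eta * rowSums((V - D)^2))
  }
  list(total = sum(per_layer), per_layer = per_layer)
}

#' Sample the decoded unit subset for one training iteration
#'
#' Within each convolutional (spatial) layer one feature map (channel) is
#' chosen uniformly at random and all its spatial units are decoded; fully
#' connected layers contribute all their units every iteration.
#'
#' @param specs Named list of [layer_spec()]s.
#' @return Named list of unit index vectors (indices into the flattened
#'   layer, position-fastest within channel).
#' @export
sample_units_for_iteration <- function(specs) {
  out <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (is_spatial_spec(sp)) {
      k <- sample.int(sp$channels, 1)
      pq <- sp$height * sp$width
      out[[nm]] <- ((k - 1L) * pq + 1L):(k * pq)
    } else {
      out[[nm]] <- seq_len(sp$unit_count)
    }
  }
  out
}

#' Train a content-loss neural code converter
#'
#' Optimizes an MLP `Phi` mapping source voxel patterns (`m` voxels) to the
#' target voxel space (`n` voxels) by minimizing
#' `sum_i sum_l eta_il || v_il - (W_l Phi(x_i) + b_l) ||^2` through the
#' frozen target decoder. Each iteration decodes a randomly sampled feature
#' map per convolutional layer (all units of dense layers), evaluates the
#' loss on the full training set, and takes one Adam step. No paired target
#' responses are consumed or accepted.
#'
#' @param source_train A [response_dataset()] of the source subject's
#'   training responses (trial-level by default).
#' @param source_features [feature_stack()] of the TRUE features of the
#'   source's training stimuli (same stimuli, same order).
#' @param target_decoder A frozen [fit_feature_decoder()] for the target.
#' @param config A [content_config()].
#' @param kind MLP variant: nonlinear (default), purely affine, or residual.
#' @return An object of class `converter` with the loss trajectory.
#' @export
train_content_converter <- function(source_train, source_features,
                                    target_decoder,
                                    config = content_config(),
                                    kind = c("content_mlp_nonlinear",
                                             "content_mlp_linear",
                                             "content_mlp_residual")) {
  kind <- match.arg(kind)
  if (!identical(source_features$layer_order, target_decoder$layer_order)) {
    stop("source features and target decoder disagree on the layer set")
  }
  X <- response_matrix(source_train, average = config$average_repetitions)
  si <- attr(X, "stimulus_index")
  m <- ncol(X)
  n <- target_decoder$n_voxels
  specs <- target_decoder$specs
  ## Per-layer affine decoder maps on raw voxel values, full unit set.
  affs <- lapply(target_decoder$layer_order,
                 function(nm) decoder_affine(target_decoder, nm))
  names(affs) <- target_decoder$layer_order
  V_full <- lapply(source_features$layers, function(M) M[si, , drop = FALSE])
  with_seed(config$seed, {
    ops <- build_converter_ops(kind, m, n)
    state <- adam_init(ops)
    trajectory <- numeric(config$iterations)
    for (t in seq_len(config$iterations)) {
      units <- sample_units_for_iteration(specs)
      fwd <- ops_forward(ops, X, cache = TRUE)
      Phi <- fwd$out
      G <- matrix(0, nrow(X), n)
      loss <- 0
      for (nm in target_decoder$layer_order) {
        idx <- units[[nm]]
        aff <- affs[[nm]]
        A <- aff$A[idx, , drop = FALSE]
        a <- aff$a[idx]
        V <- V_full[[nm]][, idx, drop = FALSE]
        D <- Phi[, aff$selected, drop = FALSE] %*% t(A) + rep(a, each = nrow(X))
        E <- V - D
        norms <- rowSums(V^2)
        eta <- if (config$weighting == "per_sample") {
          ifelse(norms > 0, 1 / norms, 0)
        } else {
          mn <- mean(norms)
          rep(if (mn > 0) 1 / mn else 0, nrow(X))
        }
        loss <- loss + sum(eta * rowSums(E^2))
        Gsel <- (-2 * (E * eta)) %*% A
        G[, aff$selected] <- G[, aff$selected] + Gsel
      }
      if (!is.finite(loss)) {
        stop("non-finite content loss at iteration ", t,
             "; reduce the learning rate")
      }
      trajectory[t] <- loss
      bw <- ops_backward(ops, fwd$caches, G)
      upd <- adam_step(ops, bw$grads, state, config$learning_rate,
                       config$beta1, config$beta2, 1e-8, t)
      ops <- upd$ops
      state <- upd$state
    }
    structure(list(kind = kind, m = m, n = n, ops = ops,
                   config = config, trajectory = trajectory,
                   source_id = source_train$subject_id,
                   target_id = target_decoder$subject_id),
              class = "converter")
  })
}

#' Train the brain-loss (ridge) converter baseline
#'
#' Closed-form multivariate ridge regression from paired source and target
#' activity for shared stimuli: minimizes
#' `sum_i || y_i - (M x_i + c) ||^2 + lambda ||M||_F^2` with the bias
#' unpenalized (fit on centered data). When `lambda = NULL` it is chosen by
#' generalized cross-validation over a log grid `10^-2 .. 10^4`.
#'
#' @param paired_source Matrix `[N x m]` of source activity.
#' @param paired_target Matrix `[N x n]` of target activity, row-aligned
#'   (same stimuli).
#' @param ridge_penalty Penalty `lambda`, or `NULL` for GCV.
#' @return A `converter` of kind `brain_ridge` with fields `M` and `c`.
#' @export
train_brain_loss_converter <- function(paired_source, paired_target,
                                       ridge_penalty = NULL) {
  if (nrow(paired_source) != nrow(paired_target)) {
    stop("paired source and target have different sample counts (",
         nrow(paired_source), " vs ", nrow(paired_target), ")")
  }
  N <- nrow(paired_source)
  stopifnot(N >= 2)
  xm <- colMeans(paired_source)
  ym <- colMeans(paired_target)
  Xc <- sweep(paired_source, 2, xm)
  Yc <- sweep(paired_target, 2, ym)
  sv <- svd(Xc)
  gcv_score <- function(lam) {
    shrink <- sv$d / (sv$d^2 + lam)
    B <- sv$v %*% (shrink * crossprod(sv$u, Yc))
    resid <- Yc - Xc %*% B
    df <- sum(sv$d^2 / (sv$d^2 + lam))
    mean(resid^2) / (1 - df / N)^2
  }
  if (is.null(ridge_penalty)) {
    grid <- 10^seq(-2, 4, by = 0.5)
    ridge_penalty <- grid[which.min(vapply(grid, gcv_score, numeric(1)))]
  }
  shrink <- sv$d / (sv$d^2 + ridge_penalty)
  B <- sv$v %*% (shrink * crossprod(sv$u, Yc))     # [m x n]
  M <- t(B)
  c0 <- ym - as.vector(M %*% xm)
  structure(list(kind = "brain_ridge", m = ncol(paired_source),
                 n = ncol(paired_target), M = M, c = c0,
                 ridge_penalty = ridge_penalty),
            class = "converter")
}

#' Train the orthogonal Procrustes converter baseline
#'
#' Finds the orthogonal map (reflections allowed), optional isotropic scale,
#' and translation minimizing the Frobenius error between mapped source and
#' target activity for shared stimuli, via the SVD of the centered
#' cross-covariance.
#'
#' @param paired_source,paired_target Row-aligned activity matrices; the
#'   voxel counts must match unless `pad = TRUE`, in which case the smaller
#'   space is zero-padded.
#' @param scaling Estimate the isotropic scale (otherwise 1).
#' @param pad Zero-pad mismatched voxel spaces.
#' @return A `converter` of kind `procrustes` with orthogonal `R`
#'   (`t(R) %*% R = I`), `scale`, and translation.
#' @export
train_procrustes_converter <- function(paired_source, paired_target,
                                       scaling = TRUE, pad = FALSE) {
  m <- ncol(paired_source)
  n <- ncol(paired_target)
  if (m != n) {
    if (!pad) {
      stop("Procrustes requires matching voxel counts (", m, " vs ", n,
           "); set pad = TRUE to zero-pad the smaller space")
    }
    k <- max(m, n)
    if (m < k) paired_source <- cbind(paired_source,
                                      matrix(0, nrow(paired_source), k - m))
    if (n < k) paired_target <- cbind(paired_target,
                                      matrix(0, nrow(paired_target), k - n))
  }
  xm <- colMeans(paired_source)
  ym <- colMeans(paired_target)
  Xc <- sweep(paired_source, 2, xm)
  Yc <- sweep(paired_target, 2, ym)
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$u %*% t(sv$v)
  s <- if (scaling) sum(sv$d) / sum(Xc^2) else 1
  c0 <- ym - s * as.vector(t(R) %*% xm)
  structure(list(kind = "procrustes", m = m, n = ncol(paired_target),
                 m_original = m, n_original = n, R = R, scale = s, c = c0,
                 padded = m != n),
            class = "converter")
}

#' @export
print.converter <- function(x, ...) {
  cat("<converter [", x$kind, "]> ", x$m, " -> ", x$n, " voxels\n", sep = "")
  invisible(x)
}

#' Apply a converter to source activity patterns
#'
#' Deterministic, batch-order-preserving forward application. MLP variants
#' use per-sample instance-normalization statistics, so a row converts
#' identically alone or inside a batch.
#'
#' @param converter A trained `converter`.
#' @param responses Matrix `[stimuli x m]` or a [response_dataset()]
#'   (repetition-averaged first).
#' @return Matrix `[stimuli x n]` in the target voxel space.
#' @export
convert_activity <- function(converter, responses) {
  if (inherits(responses, "response_dataset")) {
    responses <- response_matrix(responses, average = TRUE)
  }
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != converter$m) {
    stop("voxel dimension ", ncol(responses),
         " does not match converter input ", converter$m)
  }
  switch(converter$kind,
    brain_ridge = responses %*% t(converter$M) +
      rep(converter$c, each = nrow(responses)),
    procrustes = {
      X <- responses
      if (isTRUE(converter$padded) && converter$m_original < nrow(converter$R)) {
        X <- cbind(X, matrix(0, nrow(X), nrow(converter$R) - ncol(X)))
      }
      out <- converter$scale * X %*% converter$R +
        rep(converter$c, each = nrow(X))
      out[, seq_len(converter$n_original), drop = FALSE]
    },
    ops_forward(converter$ops, responses)$out)
}
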