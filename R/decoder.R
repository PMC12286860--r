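## Ridge-regression feature decoders.
##
## Per layer, voxels and feature units are z-scored with training statistics,
## voxels are ranked by their maximum absolute Pearson correlation with any
## of the layer's units, the top `n_voxels_select` are kept, and a
## closed-form ridge solution (penalty on weights only, bias unpenalized and
## implicit in the normalization) maps selected voxels to units. Decoding is
## affine in the input pattern, so the decoder is differentiable with
## respect to the voxel pattern -- the property converter training relies on.

#' Fit per-layer ridge feature decoders
#'
#' @param train_responses A [response_dataset()] (trial-level samples are
#'   used; repetitions are flattened and features repeated accordingly).
#' @param train_features A [feature_stack()] for the same stimuli in the
#'   same order.
#' @param n_voxels_select Voxels retained per layer, ranked by the maximum
#'   `|r|` between the voxel's response sequence and any unit of the layer;
#'   clipped (with a warning) when fewer voxels exist. Constant voxels score
#'   0 and are never selected.
#' @param ridge_penalty Ridge penalty `lambda` applied on normalized data.
#' @return An object of class `feature_decoder`.
#' @export
fit_feature_decoder <- function(train_responses, train_features,
                                n_voxels_select = 500L, ridge_penalty = 100) {
  X0 <- response_matrix(train_responses)
  si <- attr(X0, "stimulus_index")
  if (nrow(train_features$layers[[1]]) != dim(train_responses$responses)[1]) {
    stop("responses and features disagree on the number of stimuli")
  }
  if (!is.null(train_features$stimulus_ids) &&
      !identical(train_features$stimulus_ids, train_responses$stimulus_ids)) {
    stop("responses and features carry different stimulus_ids")
  }
  if (dim(train_responses$responses)[1] < 2) {
    stop("need at least 2 training stimuli")
  }
  vstats <- zscore_fit(X0)
  Xz <- zscore_apply(X0, vstats)
  n_sel <- min(n_voxels_select, ncol(X0))
  if (n_sel < n_voxels_select) {
    warning("n_voxels_select clipped from ", n_voxels_select, " to ",
            n_sel, " available voxels")
  }
  N <- nrow(Xz)
  layers <- list()
  for (nm in train_features$layer_order) {
    Y0 <- train_features$layers[[nm]][si, , drop = FALSE]
    fstats <- zscore_fit(Y0)
    Yz <- zscore_apply(Y0, fstats)
    Yz[, fstats$constant] <- 0
    ## z-scored columns: crossprod / (N - 1) is the Pearson correlation
    C <- crossprod(Xz, Yz) / (N - 1)
    C[vstats$constant, ] <- 0
    score <- apply(abs(C), 1, max)
    sel <- sort(order(score, decreasing = TRUE)[seq_len(n_sel)])
    Xs <- Xz[, sel, drop = FALSE]
    A <- crossprod(Xs)
    diag(A) <- diag(A) + ridge_penalty
    Wt <- solve(A, crossprod(Xs, Yz))       # [n_sel x units]
    Wt[, fstats$constant] <- 0
    layers[[nm]] <- list(W = t(Wt), selected = sel,
                         f_mean = fstats$mean, f_sd = fstats$sd,
                         constant_units = fstats$constant)
  }
  structure(list(layers = layers, layer_order = train_features$layer_order,
                 specs = train_features$specs,
                 v_mean = vstats$mean, v_sd = vstats$sd,
                 n_voxels = ncol(X0), ridge_penalty = ridge_penalty,
                 extractor_tag = attr(train_features, "extractor_tag"),
                 subject_id = train_responses$subject_id),
            class = "feature_decoder")
}

#' @export
print.feature_decoder <- function(x, ...) {
  cat("<feature_decoder> ", x$n_voxels, " voxels (",
      length(x$layers[[1]]$selected), " selected/layer), lambda = ",
      x$ridge_penalty, ", layers: ",
      paste(x$layer_order, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Effective affine map of one decoder layer acting on RAW voxel values of
## the selected voxels: d = A %*% x[selected] + a, in feature units.
decoder_affine <- function(decoder, layer, units = NULL) {
  ly <- decoder$layers[[layer]]
  W <- ly$W
  f_sd <- ly$f_sd
  f_mean <- ly$f_mean
  if (!is.null(units)) {
    W <- W[units, , drop = FALSE]
    f_sd <- f_sd[units]
    f_mean <- f_mean[units]
  }
  A <- (W * f_sd) * rep(1 / decoder$v_sd[ly$selected], each = nrow(W))
  a <- f_mean - as.vector(A %*% decoder$v_mean[ly$selected])
  list(A = A, a = a, selected = ly$selected)
}

#' Decode stimulus features from voxel patterns
#'
#' @param decoder A [fit_feature_decoder()] object.
#' @param responses Matrix `[stimuli x voxels]` (raw values, full voxel
#'   space) or a [response_dataset()], which is repetition-averaged first.
#' @param stimulus_ids Optional identifiers for the output stack.
#' @return A [feature_stack()] of decoded features in original feature
#'   units.
#' @export
decode_features <- function(decoder, responses, stimulus_ids = NULL) {
  if (inherits(responses, "response_dataset")) {
    stimulus_ids <- stimulus_ids %||% responses$stimulus_ids
    responses <- response_matrix(responses, average = TRUE)
  }
  if (ncol(responses) != decoder$n_voxels) {
    stop("voxel count mismatch: decoder expects ", decoder$n_voxels,
         ", got ", ncol(responses))
  }
  out <- list()
  for (nm in decoder$layer_order) {
    aff <- decoder_affine(decoder, nm)
    out[[nm]] <- responses[, aff$selected, drop = FALSE] %*% t(aff$A) +
      rep(aff$a, each = nrow(responses))
  }
  feature_stack(out, decoder$specs, stimulus_ids)
}

#' Pattern and profile decoding accuracy
#'
#' Pattern correlation: Pearson `r` across a layer's units between decoded
#' and true features, one value per test stimulus. Profile correlation:
#' Pearson `r` across test stimuli between decoded and true values, one per
#' unit. Layer means average pattern values over stimuli and profile values
#' over units; correlations with undefined denominators are `NA` and are
#' excluded from means, and profile correlations are only computed with at
#' least 3 stimuli.
#'
#' @param decoded,true [feature_stack()]s with matching layers and stimuli.
#' @return List with `per_layer` (pattern/profile vectors per layer) and
#'   `summary` (data frame of layer means).
#' @export
decoding_accuracy <- function(decoded, true) {
  stopifnot(identical(decoded$layer_order, true$layer_order))
  if (!is.null(decoded$stimulus_ids) && !is.null(true$stimulus_ids) &&
      !identical(decoded$stimulus_ids, true$stimulus_ids)) {
    stop("decoded and true stacks carry different stimulus_ids")
  }
  per_layer <- list()
  rows <- list()
  for (nm in decoded$layer_order) {
    D <- decoded$layers[[nm]]
    Tr <- true$layers[[nm]]
    pattern <- rowwise_cor(D, Tr)
    profile <- if (nrow(D) >= 3) colwise_cor(D, Tr) else rep(NA_real_, ncol(D))
    per_layer[[nm]] <- list(pattern = pattern, profile = profile)
    rows[[nm]] <- data.frame(layer = nm,
                             pattern_mean = mean(pattern, na.rm = TRUE),
                             profile_mean = if (all(is.na(profile))) NA_real_
                                            else mean(profile, na.rm = TRUE),
                             n_stimuli = nrow(D), n_units = ncol(D))
  }
  list(per_layer = per_layer,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
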