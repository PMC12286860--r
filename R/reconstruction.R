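## Feature-inversion image reconstruction.
##
## An image is reconstructed from a decoded feature stack by optimizing a
## generator latent (by default the pixels themselves) under a weighted
## feature MSE plus texture and structure similarity terms built from
## per-channel spatial statistics of convolutional feature maps. All
## gradients are exact: the analytic derivatives of the channel-statistic
## ratios are chained through the extractor's backward pass.

#' Reconstruction configuration
#'
#' @param iterations Gradient iterations (SGD with momentum).
#' @param learning_rate,momentum Optimizer settings.
#' @param lambda_tex,lambda_str Non-negative weights of the texture and
#'   structure terms.
#' @param alpha,beta Per-convolutional-layer weights inside the texture and
#'   structure losses; `NULL` gives `1 / L_conv` to each spatial layer.
#' @param epsilon Small positive stabilizer in the similarity ratios.
#' @param seed Seed for the latent initialization.
#' @return A `reconstruction_config` list.
#' @export
reconstruction_config <- function(iterations = 200L, learning_rate = 0.1,
                                  momentum = 0.9, lambda_tex = 0.1,
                                  lambda_str = 0.1, alpha = NULL, beta = NULL,
                                  epsilon = 1e-6, seed = 1L) {
  stopifnot(iterations >= 1, epsilon > 0, lambda_tex >= 0, lambda_str >= 0)
  list(iterations = as.integer(iterations), learning_rate = learning_rate,
       momentum = momentum, lambda_tex = lambda_tex, lambda_str = lambda_str,
       alpha = alpha, beta = beta, epsilon = epsilon, seed = seed)
}

as_layer_list <- function(x) {
  if (inherits(x, "feature_stack")) {
    lapply(x$layers, function(m) m[1, ])
  } else x
}

stack_specs <- function(x, specs = NULL) {
  if (inherits(x, "feature_stack")) x$specs else specs
}

#' Weighted feature mean-squared-error loss
#'
#' `sum_l gamma_l || predicted_l - target_l ||^2` with
#' `gamma_l = 1 / ||target_l||^2` (layers with zero target norm contribute
#' 0 under this rule).
#'
#' @param predicted,target [feature_stack()]s holding one stimulus, or
#'   plain named lists of per-layer feature vectors.
#' @return List with `total` and `per_layer`.
#' @export
feature_mse_loss <- function(predicted, target) {
  p <- as_layer_list(predicted)
  u <- as_layer_list(target)
  stopifnot(identical(names(p), names(u)))
  per_layer <- vapply(names(u), function(nm) {
    n2 <- sum(u[[nm]]^2)
    if (n2 == 0) 0 else sum((p[[nm]] - u[[nm]])^2) / n2
  }, numeric(1))
  list(total = sum(per_layer), per_layer = per_layer)
}

#' Per-channel spatial statistics of a feature map
#'
#' For a convolutional feature map, the spatial mean `mu_k` and (population)
#' variance `delta_k` of each channel; with a second map, the per-channel
#' spatial cross-covariance.
#'
#' @param u Feature map: `[P, Q, K]` array, `[P*Q, K]` matrix, or a flat
#'   vector with `spec` supplied.
#' @param uhat Optional second map of the same geometry.
#' @param spec A [layer_spec()] when `u` is a flat vector.
#' @return List with `mu`, `delta`, and (when `uhat` is given) `mu_hat`,
#'   `delta_hat`, `cross`.
#' @export
channel_stats <- function(u, uhat = NULL, spec = NULL) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(x)
    if (is.array(x) && length(dim(x)) == 3) {
      return(matrix(x, nrow = dim(x)[1] * dim(x)[2]))
    }
    if (is.null(spec)) stop("flat feature vectors need a layer spec")
    matrix(x, nrow = spec$height * spec$width)
  }
  U <- to_mat(u)
  mu <- colMeans(U)
  delta <- colMeans(U^2) - mu^2
  out <- list(mu = mu, delta = delta)
  if (!is.null(uhat)) {
    Uh <- to_mat(uhat)
    stopifnot(all(dim(Uh) == dim(U)))
    out$mu_hat <- colMeans(Uh)
    out$delta_hat <- colMeans(Uh^2) - out$mu_hat^2
    out$cross <- colMeans(U * Uh) - mu * out$mu_hat
  }
  out
}

spatial_layers <- function(specs) {
  names(specs)[vapply(specs, function(s) is_spatial_spec(s), logical(1))]
}

layer_weights <- function(specs, w) {
  conv <- spatial_layers(specs)
  if (is.null(w)) w <- stats::setNames(rep(1 / length(conv), length(conv)), conv)
  w[conv]
}

#' Texture similarity loss
#'
#' `- sum_l alpha_l (1 / K_l) sum_k (mu_k(u) mu_k(uhat) + eps) /
#' (mu_k(u)^2 + mu_k(uhat)^2 + eps)` over convolutional layers. Symmetric
#' in its two arguments; minimized (at `-sum alpha_l`) when per-channel
#' means coincide, and finite for all-zero maps for any `eps > 0`.
#'
#' @param u,uhat Feature stacks or named lists of per-layer vectors.
#' @param specs Layer specs when plain lists are passed.
#' @param alpha Per-layer weights (`NULL`: `1 / L_conv` each).
#' @param epsilon Stabilizer.
#' @return List with `total` and `per_layer`.
#' @export
texture_loss <- function(u, uhat, specs = NULL, alpha = NULL,
                         epsilon = 1e-6) {
  specs <- stack_specs(u, specs)
  ul <- as_layer_list(u)
  hl <- as_layer_list(uhat)
  alpha <- layer_weights(specs, alpha)
  per_layer <- vapply(names(alpha), function(nm) {
    st <- channel_stats(ul[[nm]], hl[[nm]], spec = specs[[nm]])
    ratio <- (st$mu * st$mu_hat + epsilon) /
      (st$mu^2 + st$mu_hat^2 + epsilon)
    -alpha[[nm]] * mean(ratio)
  }, numeric(1))
  list(total = sum(per_layer), per_layer = per_layer)
}

#' Structure similarity loss
#'
#' `- sum_l beta_l (1 / K_l) sum_k (delta_k(u, uhat) + eps) /
#' (delta_k(u) + delta_k(uhat) + eps)` over convolutional layers, with
#' `delta` the per-channel spatial (co)variance.
#'
#' @inheritParams texture_loss
#' @param beta Per-layer weights (`NULL`: `1 / L_conv` each).
#' @return List with `total` and `per_layer`.
#' @export
structure_loss <- function(u, uhat, specs = NULL, beta = NULL,
                           epsilon = 1e-6) {
  specs <- stack_specs(u, specs)
  ul <- as_layer_list(u)
  hl <- as_layer_list(uhat)
  beta <- layer_weights(specs, beta)
  per_layer <- vapply(names(beta), function(nm) {
    st <- channel_stats(ul[[nm]], hl[[nm]], spec = specs[[nm]])
    ratio <- (st$cross + epsilon) / (st$delta + st$delta_hat + epsilon)
    -beta[[nm]] * mean(ratio)
  }, numeric(1))
  list(total = sum(per_layer), per_layer = per_layer)
}

## Analytic gradients of the similarity terms with respect to the PREDICTED
## map uhat (a [PQ x K] matrix); the target map u is a constant.
texture_grad <- function(U, Uh, alpha_l, eps) {
  PQ <- nrow(U)
  mu <- colMeans(U)
  muh <- colMeans(Uh)
  num <- mu * muh + eps
  den <- mu^2 + muh^2 + eps
  dmuh <- (mu * den - num * 2 * muh) / den^2
  g_per_channel <- -alpha_l / ncol(U) * dmuh / PQ
  matrix(rep(g_per_channel, each = PQ), nrow = PQ)
}

structure_grad <- function(U, Uh, beta_l, eps) {
  PQ <- nrow(U)
  mu <- colMeans(U)
  muh <- colMeans(Uh)
  cross <- colMeans(U * Uh) - mu * muh
  du <- colMeans(U^2) - mu^2
  duh <- colMeans(Uh^2) - muh^2
  num <- cross + eps
  den <- du + duh + eps
  dc <- sweep(U, 2, mu) / PQ                 # d cross / d Uh
  dd <- 2 * sweep(Uh, 2, muh) / PQ           # d den / d Uh
  G <- sweep(dc, 2, den, "*") - sweep(dd, 2, num, "*")
  G <- sweep(G, 2, den^2, "/")
  -beta_l / ncol(U) * G
}

#' Reconstruct an image from a decoded feature stack
#'
#' Minimizes `L_mse + lambda_tex L_tex + lambda_str L_str` over the
#' generator latent by gradient descent with momentum, with seeded random
#' initialization. The texture and structure terms act on convolutional
#' layers only (they need spatial maps); dense layers enter the feature MSE.
#' The returned image/latent is the best iterate encountered, so the final
#' total loss never exceeds the loss at initialization.
#'
#' @param target_features [feature_stack()] (one stimulus) of decoded or
#'   true features; its layers must be a subset of the extractor's.
#' @param extractor The [toy_extractor()] defining the feature functions.
#' @param generator A [pixel_generator()]; `NULL` uses direct pixel
#'   optimization (`identity_pixels`) at the extractor's input geometry.
#' @param config A [reconstruction_config()].
#' @param init Optional initial latent (e.g. a known image's pixels);
#'   `NULL` draws uniform random pixels / standard normal latents.
#' @return An object of class `reconstruction_result`: `image`, `z`,
#'   `trajectory` (data frame: iteration, mse, tex, str, total), `best_iter`.
#' @export
reconstruct_image <- function(target_features, extractor, generator = NULL,
                              config = reconstruction_config(), init = NULL) {
  if (is.null(generator)) {
    generator <- pixel_generator("identity_pixels",
                                 image_size = extractor$input_size,
                                 channels = extractor$input_channels)
  }
  u <- as_layer_list(target_features)
  specs <- stack_specs(target_features)
  missing <- setdiff(names(u), extractor$layer_order)
  if (length(missing)) {
    stop("target features contain layers unknown to the extractor: ",
         paste(missing, collapse = ", "))
  }
  conv_layers <- intersect(spatial_layers(specs), names(u))
  alpha <- layer_weights(specs[conv_layers], config$alpha)
  beta <- layer_weights(specs[conv_layers], config$beta)
  gamma <- lapply(u, function(v) {
    n2 <- sum(v^2)
    if (n2 > 0) 1 / n2 else 0
  })
  eps <- config$epsilon
  z <- if (!is.null(init)) init else with_seed(config$seed, {
    if (generator$mode == "identity_pixels") {
      stats::runif(generator$latent_dim)
    } else stats::rnorm(generator$latent_dim, sd = 0.5)
  })
  vel <- numeric(length(z))
  traj <- data.frame(iteration = seq_len(config$iterations),
                     mse = NA_real_, tex = NA_real_, str = NA_real_,
                     total = NA_real_)
  best <- list(total = Inf, z = z)
  eval_point <- function(z, want_grad = TRUE) {
    gen <- generate_with_cache(generator, z)
    fwd <- extractor_forward(extractor, gen$image, cache = want_grad)
    l_mse <- 0; l_tex <- 0; l_str <- 0
    grads <- list()
    for (nm in names(u)) {
      pred <- as.vector(fwd$pre[[nm]])
      g <- numeric(length(pred))
      l_mse <- l_mse + gamma[[nm]] * sum((pred - u[[nm]])^2)
      if (want_grad) g <- g + 2 * gamma[[nm]] * (pred - u[[nm]])
      if (nm %in% conv_layers && (config$lambda_tex > 0 || config$lambda_str > 0)) {
        sp <- specs[[nm]]
        PQ <- sp$height * sp$width
        U <- matrix(u[[nm]], nrow = PQ)
        Uh <- matrix(pred, nrow = PQ)
        if (config$lambda_tex > 0) {
          mu <- colMeans(U); muh <- colMeans(Uh)
          l_tex <- l_tex - alpha[[nm]] *
            mean((mu * muh + eps) / (mu^2 + muh^2 + eps))
          if (want_grad) {
            g <- g + config$lambda_tex *
              as.vector(texture_grad(U, Uh, alpha[[nm]], eps))
          }
        }
        if (config$lambda_str > 0) {
          st <- channel_stats(U, Uh)
          l_str <- l_str - beta[[nm]] *
            mean((st$cross + eps) / (st$delta + st$delta_hat + eps))
          if (want_grad) {
            g <- g + config$lambda_str *
              as.vector(structure_grad(U, Uh, beta[[nm]], eps))
          }
        }
      }
      if (want_grad) {
        grads[[nm]] <- if (is.matrix(fwd$pre[[nm]])) {
          matrix(g, nrow = nrow(fwd$pre[[nm]]))
        } else g
      }
    }
    total <- l_mse + config$lambda_tex * l_tex + config$lambda_str * l_str
    gz <- NULL
    if (want_grad) {
      g_img <- extractor_backward(extractor, fwd, grads)
      gz <- generator_backward(generator, gen$cache, g_img)
    }
    list(mse = l_mse, tex = l_tex, str = l_str, total = total,
         grad = gz, image = gen$image)
  }
  for (it in seq_len(config$iterations)) {
    ev <- eval_point(z)
    if (!is.finite(ev$total)) {
      stop("non-finite reconstruction loss at iteration ", it,
           " (mse = ", ev$mse, ", tex = ", ev$tex, ", str = ", ev$str, ")")
    }
    traj[it, c("mse", "tex", "str", "total")] <-
      c(ev$mse, ev$tex, ev$str, ev$total)
    if (ev$total < best$total) best <- list(total = ev$total, z = z, iter = it)
    vel <- config$momentum * vel - config$learning_rate * ev$grad
    z <- z + vel
  }
  final <- eval_point(z, want_grad = FALSE)
  if (final$total < best$total) {
    best <- list(total = final$total, z = z, iter = config$iterations + 1L)
  }
  structure(list(image = generate(generator, best$z), z = best$z,
                 trajectory = traj, best_iter = best$iter,
                 best_total = best$total, config = config),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %d iterations, best total loss %.5f (iter %d)\n",
              nrow(x$trajectory), x$best_total, x$best_iter))
  invisible(x)
}
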