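## Toy hierarchical feature extractors and layer-shape arithmetic.
##
## The extractors are small, fixed-weight (random, seeded) stacks of
## convolution-like filter banks with ReLU nonlinearities and a dense readout.
## They provide a differentiable hierarchical content space: per-layer feature
## vectors are taken BEFORE rectification, and gradients of any scalar loss on
## the features with respect to the input pixels are available in closed form.
## They make no claim of equivalence with any pretrained network.

#' Layer geometry descriptor
#'
#' Describes one feature layer: its kind, spatial map size (height `P`,
#' width `Q`, both 1 for fully connected layers), channel count `K`, and the
#' resulting unit count `P * Q * K`.
#'
#' @param name Layer label, unique within an extractor.
#' @param kind One of `"convolutional"`, `"fully_connected"`,
#'   `"patch_embedding"`, `"token_block"`.
#' @param height,width,channels Positive integers describing the feature map.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, height, width, channels) {
  kind <- match.arg(kind, c("convolutional", "fully_connected",
                            "patch_embedding", "token_block"))
  stopifnot(height >= 1, width >= 1, channels >= 1)
  structure(list(name = name, kind = kind,
                 height = as.integer(height), width = as.integer(width),
                 channels = as.integer(channels),
                 unit_count = as.integer(height * width * channels)),
            class = "layer_spec")
}

is_spatial_spec <- function(spec) {
  spec$kind %in% c("convolutional", "patch_embedding") &&
    spec$height >= 1 && spec$width >= 1
}

#' Per-layer feature container
#'
#' Holds one feature matrix per layer (stimuli in rows, flattened units in
#' columns; spatial layers are flattened position-fastest within each
#' channel), the layer geometry, and the stimulus identifiers shared by all
#' layers.
#'
#' @param layers Named list of numeric matrices `[n_stimuli x unit_count]`.
#' @param specs Named list of [layer_spec()] objects, same names and order.
#' @param stimulus_ids Character vector of stimulus identifiers (or `NULL`).
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(layers, specs, stimulus_ids = NULL) {
  stopifnot(identical(names(layers), names(specs)))
  n <- unique(vapply(layers, nrow, integer(1)))
  if (length(n) != 1) stop("layers disagree on the number of stimuli")
  for (nm in names(layers)) {
    if (ncol(layers[[nm]]) != specs[[nm]]$unit_count) {
      stop("layer '", nm, "' has ", ncol(layers[[nm]]),
           " columns but its spec declares ", specs[[nm]]$unit_count, " units")
    }
  }
  if (!is.null(stimulus_ids) && length(stimulus_ids) != n) {
    stop("stimulus_ids length (", length(stimulus_ids),
         ") does not match the stimulus dimension (", n, ")")
  }
  structure(list(layers = layers, specs = specs,
                 layer_order = names(layers), stimulus_ids = stimulus_ids),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("<feature_stack> ", nrow(x$layers[[1]]), " stimuli, layers: ",
      paste(sprintf("%s[%d]", x$layer_order,
                    vapply(x$layers, ncol, integer(1))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Subset a feature stack by stimulus rows
#' @param stack A [feature_stack()].
#' @param idx Row indices (or logical vector) selecting stimuli.
#' @return A `feature_stack` restricted to the selected stimuli.
#' @export
subset_stack <- function(stack, idx) {
  feature_stack(lapply(stack$layers, function(m) m[idx, , drop = FALSE]),
                stack$specs,
                if (!is.null(stack$stimulus_ids)) stack$stimulus_ids[idx])
}

#' Reshape one layer of a feature stack to its spatial array form
#' @param stack A [feature_stack()].
#' @param layer Layer name.
#' @param stimulus Row index of the stimulus to extract.
#' @return Array `[height, width, channels]` for spatial layers, or a plain
#'   unit vector for fully connected layers.
#' @export
feature_map <- function(stack, layer, stimulus = 1L) {
  spec <- stack$specs[[layer]]
  v <- stack$layers[[layer]][stimulus, ]
  if (is_spatial_spec(spec) && (spec$height > 1 || spec$width > 1)) {
    array(v, dim = c(spec$height, spec$width, spec$channels))
  } else v
}

## ----------------------------------------------------------------------
## Toy extractors

#' Build the toy convolutional feature extractor
#'
#' A fixed-weight (seeded He-initialized Gaussian) stack of strided 3x3
#' convolutions with ReLU between stages, followed by one dense readout
#' layer. Per-layer features are the pre-activation values. The default
#' geometry (32x32x3 input; 8, 16, 16 channels at stride 2; 64 dense units)
#' gives four hierarchy levels, enough to exercise multi-layer content
#' losses while remaining seconds-scale to train against.
#'
#' @param seed Integer seed determining the filter banks.
#' @param input_size Input image side length in pixels (square images).
#' @param input_channels Number of image channels (3 for RGB).
#' @param conv_channels Integer vector of channel counts, one per conv stage.
#' @param kernel,stride,pad Convolution geometry shared by all stages.
#' @param dense_units Width of the final dense layer.
#' @param name Extractor tag recorded in decoders and converters.
#' @return An object of class `extractor_model`.
#' @export
toy_extractor <- function(seed = 1L, input_size = 32L, input_channels = 3L,
                          conv_channels = c(8L, 16L, 16L),
                          kernel = 3L, stride = 2L, pad = 1L,
                          dense_units = 64L, name = "convnet") {
  build_extractor(seed, input_size, input_channels,
                  stages = lapply(seq_along(conv_channels), function(i) {
                    list(kind = "convolutional", channels = conv_channels[i],
                         kernel = kernel, stride = stride, pad = pad,
                         name = paste0("conv", i))
                  }),
                  dense_units = dense_units, dense_name =
                    paste0("fc", length(conv_channels) + 1L),
                  name = name)
}

#' Build the toy patch-embedding feature extractor
#'
#' A differently parameterized content space (non-overlapping patch embedding
#' followed by a dense layer), used to test whether converted activity
#' generalizes to a decoder trained on features the converter never saw.
#'
#' @inheritParams toy_extractor
#' @param patch Patch side length; the embedding is a `patch x patch`
#'   convolution at stride `patch` with no padding.
#' @param channels Embedding dimension per patch.
#' @export
patch_extractor <- function(seed = 2L, input_size = 32L, input_channels = 3L,
                            patch = 4L, channels = 12L, dense_units = 32L,
                            name = "patchnet") {
  build_extractor(seed, input_size, input_channels,
                  stages = list(list(kind = "patch_embedding",
                                     channels = channels, kernel = patch,
                                     stride = patch, pad = 0L,
                                     name = "patch1")),
                  dense_units = dense_units, dense_name = "fc2", name = name)
}

build_extractor <- function(seed, input_size, input_channels, stages,
                            dense_units, dense_name, name) {
  with_seed(seed, {
    layers <- list()
    h <- w <- as.integer(input_size)
    ch <- as.integer(input_channels)
    for (st in stages) {
      map <- conv_index_map(h, w, ch, st$kernel, st$stride, st$pad)
      fan_in <- st$kernel^2 * ch
      W <- matrix(stats::rnorm(fan_in * st$channels, sd = sqrt(2 / fan_in)),
                  nrow = fan_in)
      layers[[st$name]] <- list(
        type = "conv", kind = st$kind, map = map, W = W,
        b = rep(0, st$channels),
        spec = layer_spec(st$name, st$kind, map$out_h, map$out_w, st$channels))
      h <- map$out_h; w <- map$out_w; ch <- st$channels
    }
    fan_in <- h * w * ch
    Wd <- matrix(stats::rnorm(fan_in * dense_units, sd = sqrt(2 / fan_in)),
                 nrow = fan_in)
    layers[[dense_name]] <- list(
      type = "dense", W = Wd, b = rep(0, dense_units),
      spec = layer_spec(dense_name, "fully_connected", 1L, 1L, dense_units))
    structure(list(name = name, seed = seed,
                   input_size = as.integer(input_size),
                   input_channels = as.integer(input_channels),
                   layers = layers,
                   layer_order = names(layers)),
              class = "extractor_model")
  })
}

#' @export
print.extractor_model <- function(x, ...) {
  cat("<extractor_model '", x$name, "'> input ", x$input_size, "x",
      x$input_size, "x", x$input_channels, ", layers: ",
      paste(sprintf("%s[%d]", x$layer_order,
                    vapply(x$layers, function(l) l$spec$unit_count,
                           integer(1))), collapse = ", "), "\n", sep = "")
  invisible(x)
}

extractor_specs <- function(model) {
  specs <- lapply(model$layers, function(l) l$spec)
  names(specs) <- model$layer_order
  specs
}

check_image_batch <- function(model, images) {
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, dim = c(1L, d))
    d <- dim(images)
  }
  if (length(d) != 4L) stop("images must be an array [n, height, width, channels]")
  if (d[2] != model$input_size || d[3] != model$input_size) {
    stop("image size ", d[2], "x", d[3], " does not match extractor input ",
         model$input_size, "x", model$input_size)
  }
  if (d[4] != model$input_channels) {
    stop("image channel count ", d[4], " does not match extractor channels ",
         model$input_channels)
  }
  if (min(images) < -1e-8 || max(images) > 1 + 1e-8) {
    stop("pixel values must lie in [0, 1]")
  }
  images
}

## Forward pass for one [h, w, c] image. With cache = TRUE the ReLU masks and
## pre-activations needed by the backward pass are retained.
extractor_forward <- function(model, img, cache = FALSE) {
  pre <- list()
  caches <- list()
  x <- img
  for (nm in model$layer_order) {
    ly <- model$layers[[nm]]
    if (ly$type == "conv") {
      fwd <- conv_forward(x, ly$map, ly$W, ly$b)
      pre[[nm]] <- fwd$pre            # [positions x channels]
      act <- fwd$pre
      act[act < 0] <- 0
      x <- array(act, dim = c(ly$map$out_h, ly$map$out_w, ncol(act)))
      if (cache) caches[[nm]] <- list(mask = fwd$pre > 0)
    } else {
      xv <- as.vector(x)              # pre-dense input, position-fastest
      pre[[nm]] <- as.vector(t(ly$W) %*% xv + ly$b)
      if (cache) caches[[nm]] <- list(in_dim = dim(x))
    }
  }
  list(pre = pre, caches = if (cache) caches)
}

## Backward pass: `grads` is a named list of gradients with respect to each
## layer's PRE-activation features (matrix [positions x channels] for conv
## layers, vector for dense; missing layers contribute zero). Returns the
## gradient with respect to the input image [h, w, c].
extractor_backward <- function(model, fwd, grads) {
  order <- model$layer_order
  upstream <- NULL   # gradient wrt the post-ReLU activation of the layer below
  for (nm in rev(order)) {
    ly <- model$layers[[nm]]
    if (ly$type == "dense") {
      g_pre <- grads[[nm]] %||% numeric(length(ly$b))
      g_in <- as.vector(ly$W %*% g_pre)                   # wrt flattened input
      upstream <- array(g_in, dim = fwd$caches[[nm]]$in_dim)
    } else {
      g_pre <- grads[[nm]] %||% matrix(0, nrow(fwd$pre[[nm]]), ncol(fwd$pre[[nm]]))
      if (!is.null(upstream)) {
        g_act <- matrix(as.vector(upstream), nrow = nrow(fwd$pre[[nm]]))
        g_pre <- g_pre + g_act * fwd$caches[[nm]]$mask
      }
      upstream <- conv_backward_input(g_pre, ly$map, ly$W)
    }
  }
  upstream
}

#' Extract hierarchical features from a batch of images
#'
#' Runs the extractor forward and returns per-layer pre-activation features.
#' The forward pass is deterministic (fixed filter banks) and preserves batch
#' order.
#'
#' @param model An [toy_extractor()] / [patch_extractor()] model.
#' @param images Array `[n, height, width, channels]` (a single
#'   `[height, width, channels]` image is promoted), pixels in `[0, 1]`.
#' @param stimulus_ids Optional identifiers attached to the result.
#' @return A [feature_stack()] with one matrix per layer.
#' @export
extract_features <- function(model, images, stimulus_ids = NULL) {
  images <- check_image_batch(model, images)
  n <- dim(images)[1]
  specs <- extractor_specs(model)
  layers <- lapply(specs, function(s) matrix(0, n, s$unit_count))
  for (i in seq_len(n)) {
    fwd <- extractor_forward(model, array(images[i, , , ],
                                          dim = dim(images)[-1]))
    for (nm in model$layer_order) {
      layers[[nm]][i, ] <- as.vector(fwd$pre[[nm]])
    }
  }
  feature_stack(layers, specs, stimulus_ids)
}

## ----------------------------------------------------------------------
## Published-architecture layer-shape arithmetic

## Chained shape arithmetic for the published architectures. Units are
## P x Q x K from standard convolution / pooling / patch-embedding output
## size formulas; dense layers carry their published widths. AlexNet uses
## the Caffe bvlc_alexnet crop geometry (227 x 227 input), which is the
## geometry under which its first conv layer yields a 55 x 55 map.
architecture_table <- function(architecture, input_size = NULL) {
  conv_out <- function(s, k, st, p) (s + 2L * p - k) %/% st + 1L
  layers <- list()
  add <- function(name, units) layers[[name]] <<- as.integer(units)
  if (architecture == "vgg19") {
    s <- as.integer(input_size %||% 224L)
    blocks <- list(c(2L, 64L), c(2L, 128L), c(4L, 256L), c(4L, 512L), c(4L, 512L))
    for (bi in seq_along(blocks)) {
      for (ci in seq_len(blocks[[bi]][1])) {
        s <- conv_out(s, 3L, 1L, 1L)
        add(sprintf("conv%d_%d", bi, ci), s * s * blocks[[bi]][2])
      }
      s <- conv_out(s, 2L, 2L, 0L)  # max pool
    }
    add("fc6", 4096L); add("fc7", 4096L); add("fc8", 1000L)
  } else if (architecture == "alexnet") {
    s <- as.integer(input_size %||% 227L)
    s <- conv_out(s, 11L, 4L, 0L); add("conv1", s * s * 96L)
    s <- conv_out(s, 3L, 2L, 0L)                       # pool1
    s <- conv_out(s, 5L, 1L, 2L); add("conv2", s * s * 256L)
    s <- conv_out(s, 3L, 2L, 0L)                       # pool2
    s <- conv_out(s, 3L, 1L, 1L); add("conv3", s * s * 384L)
    s <- conv_out(s, 3L, 1L, 1L); add("conv4", s * s * 384L)
    s <- conv_out(s, 3L, 1L, 1L); add("conv5", s * s * 256L)
    add("fc6", 4096L); add("fc7", 4096L); add("fc8", 1000L)
  } else if (architecture == "clip_vit_b32") {
    s <- as.integer(input_size %||% 224L)
    g <- conv_out(s, 32L, 32L, 0L)                     # patch grid
    add("conv1", g * g * 768L)
    tokens <- g * g + 1L                               # + class token
    for (b in 0:11) add(sprintf("block%d", b), tokens * 768L)
    add("ln_post", 768L); add("model_output", 512L)
  } else {
    stop("unknown architecture '", architecture, "'")
  }
  layers
}

#' Unit count of a layer in a published architecture
#'
#' Computes `P x Q x K` for convolutional / patch-embedding layers from the
#' published kernel, stride and padding of the architecture, and returns the
#' published width for dense layers. AlexNet follows the Caffe bvlc_alexnet
#' crop geometry (227-pixel input) rather than 224, since that is the
#' geometry that yields its standard 55 x 55 first-layer map; pass
#' `input_size` explicitly to override any architecture's input resolution.
#'
#' @param architecture `"vgg19"`, `"alexnet"`, or `"clip_vit_b32"`.
#' @param layer_name Layer label, e.g. `"conv1_1"`, `"FC8"`, `"block3"`
#'   (case-insensitive).
#' @param input_size Input resolution in pixels; `NULL` uses the
#'   architecture's standard crop.
#' @return Integer unit count.
#' @export
layer_unit_count <- function(architecture = c("vgg19", "alexnet", "clip_vit_b32"),
                             layer_name, input_size = NULL) {
  architecture <- match.arg(architecture)
  tab <- architecture_table(architecture, input_size)
  key <- tolower(layer_name)
  if (!key %in% names(tab)) {
    stop("unknown layer '", layer_name, "' for ", architecture,
         "; valid layers: ", paste(names(tab), collapse = ", "))
  }
  tab[[key]]
}

## ----------------------------------------------------------------------
## Generators

#' Build a pixel-space generator
#'
#' In `identity_pixels` mode the latent IS the image: `generate()` reshapes
#' `z` to `[height, width, channels]` and clips to `[0, 1]`. In `toy_decoder`
#' mode a fixed random (seeded) dense map followed by a logistic squashing
#' produces the image, giving a smooth differentiable prior-free decoder.
#'
#' @param mode `"identity_pixels"` or `"toy_decoder"`.
#' @param image_size Output image side length.
#' @param channels Output channel count.
#' @param latent_dim Latent dimensionality (`toy_decoder` only; the identity
#'   generator's latent length is `image_size^2 * channels`).
#' @param seed Seed for the toy decoder weights.
#' @return An object of class `generator_model`.
#' @export
pixel_generator <- function(mode = c("identity_pixels", "toy_decoder"),
                            image_size = 32L, channels = 3L,
                            latent_dim = 64L, seed = 1L) {
  mode <- match.arg(mode)
  out_dim <- as.integer(image_size^2 * channels)
  params <- NULL
  if (mode == "toy_decoder") {
    params <- with_seed(seed, list(
      W = matrix(stats::rnorm(latent_dim * out_dim, sd = 1 / sqrt(latent_dim)),
                 nrow = latent_dim),
      b = rep(0, out_dim)))
  } else {
    latent_dim <- out_dim
  }
  structure(list(mode = mode, image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim),
                 params = params, seed = seed),
            class = "generator_model")
}

#' Generate an image from a latent vector
#'
#' @param model A [pixel_generator()].
#' @param z Latent vector of length `model$latent_dim`.
#' @return Image array `[height, width, channels]` with pixels in `[0, 1]`.
#' @export
generate <- function(model, z) {
  generate_with_cache(model, z)$image
}

generate_with_cache <- function(model, z) {
  if (length(z) != model$latent_dim) {
    stop("latent length ", length(z), " does not match generator latent_dim ",
         model$latent_dim)
  }
  d <- c(model$image_size, model$image_size, model$channels)
  if (model$mode == "identity_pixels") {
    img <- pmin(pmax(z, 0), 1)
    list(image = array(img, dim = d), cache = list(inside = z > 0 & z < 1))
  } else {
    lin <- as.vector(t(model$params$W) %*% z + model$params$b)
    img <- stats::plogis(lin)
    list(image = array(img, dim = d), cache = list(img = img))
  }
}

## Gradient with respect to z given the gradient with respect to the image.
generator_backward <- function(model, cache, grad_img) {
  g <- as.vector(grad_img)
  if (model$mode == "identity_pixels") {
    g * cache$inside
  } else {
    gl <- g * cache$img * (1 - cache$img)   # logistic derivative
    as.vector(model$params$W %*% gl)
  }
}
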