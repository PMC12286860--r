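## Procedural stimulus worlds.
##
## Stimuli are colored geometric composites: each category fixes a background
## gradient, a shape type, a shape color and a base position/scale; each
## stimulus jitters those parameters. This gives images whose feature
## representations cluster by category (so category-disjoint splits are
## meaningful) while every image remains unique.

render_stimulus <- function(size, params) {
  xs <- matrix(rep(seq(0, 1, length.out = size), each = size), size, size)
  ys <- matrix(rep(seq(0, 1, length.out = size), times = size), size, size)
  img <- array(0, dim = c(size, size, 3))
  grad <- params$gdir[1] * xs + params$gdir[2] * ys
  grad <- (grad - min(grad)) / max(1e-12, diff(range(grad)))
  for (c in 1:3) img[, , c] <- params$bg[c] * (0.4 + 0.6 * grad)
  dx <- xs - params$cx
  dy <- ys - params$cy
  mask <- switch(params$shape,
    disk   = (dx^2 + dy^2) < params$r^2,
    square = (abs(dx) < params$r) & (abs(dy) < params$r),
    cross  = (abs(dx) < params$r / 3 & abs(dy) < params$r) |
             (abs(dy) < params$r / 3 & abs(dx) < params$r),
    ring   = {
      d2 <- dx^2 + dy^2
      d2 < params$r^2 & d2 > (0.55 * params$r)^2
    },
    stripes = (sin(2 * pi * (dx * params$freq)) > 0) &
              (abs(dx) < 1.5 * params$r) & (abs(dy) < 1.5 * params$r))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[mask] <- params$fg[c]
    img[, , c] <- ch
  }
  pmin(pmax(img, 0), 1)
}

category_params <- function(k) {
  shapes <- c("disk", "square", "cross", "ring", "stripes")
  list(shape = shapes[(k - 1L) %% length(shapes) + 1L],
       bg = stats::runif(3, 0.1, 0.9),
       fg = stats::runif(3, 0, 1),
       gdir = stats::runif(2, -1, 1),
       cx = stats::runif(1, 0.3, 0.7),
       cy = stats::runif(1, 0.3, 0.7),
       r = stats::runif(1, 0.12, 0.3),
       freq = stats::runif(1, 2, 6))
}

jitter_params <- function(p, amount = 0.05) {
  p$cx <- min(0.85, max(0.15, p$cx + stats::rnorm(1, 0, amount)))
  p$cy <- min(0.85, max(0.15, p$cy + stats::rnorm(1, 0, amount)))
  p$r <- max(0.08, p$r * exp(stats::rnorm(1, 0, 0.15)))
  p$fg <- pmin(1, pmax(0, p$fg + stats::rnorm(3, 0, amount)))
  p$bg <- pmin(1, pmax(0, p$bg + stats::rnorm(3, 0, amount)))
  p
}

## Deterministic round-robin allocation of n stimuli to the given categories.
allocate_categories <- function(n, categories) {
  categories[(seq_len(n) - 1L) %% length(categories) + 1L]
}

#' Generate a procedural stimulus world
#'
#' Synthesizes a set of raster stimuli organized by category, attaches
#' ground-truth hierarchical features from a reference extractor, and tags
#' each stimulus with a train/test split. With `category_disjoint = TRUE`
#' the test categories are disjoint from the training categories, emulating
#' category-based generalization splits.
#'
#' @param seed Integer seed; all images and the split are reproducible from
#'   `(seed, arguments)` alone.
#' @param n_train,n_test Stimulus counts per split.
#' @param n_categories Total category count (`>= 2` when
#'   `category_disjoint`).
#' @param image_size Image side length in pixels; must match the extractor.
#' @param category_disjoint Keep test categories disjoint from training
#'   categories.
#' @param texture_noise Weight in `[0, 1)` of an independent random texture
#'   field blended into every image. Geometric composites alone span a
#'   low-dimensional feature manifold; the texture field emulates the
#'   broadband local variability of natural images and keeps the feature
#'   (and hence voxel-signal) covariance well conditioned.
#' @param extractor Reference [toy_extractor()]; built from `seed` when
#'   `NULL`.
#' @return An object of class `stimulus_set` with fields `stimulus_ids`,
#'   `category`, `split`, `images` (`[n, h, w, 3]`), `features`
#'   ([feature_stack()]), and the reference `extractor`.
#' @export
make_stimulus_world <- function(seed, n_train = 200L, n_test = 50L,
                                n_categories = 10L, image_size = 32L,
                                category_disjoint = TRUE, texture_noise = 0.25,
                                extractor = NULL) {
  stopifnot(texture_noise >= 0, texture_noise < 1)
  stopifnot(n_train >= 1, n_test >= 1, n_categories >= 1)
  if (category_disjoint && n_categories < 2) {
    stop("category_disjoint requires at least 2 categories")
  }
  if (is.null(extractor)) {
    extractor <- toy_extractor(seed = derive_seed(seed, "extractor"),
                               input_size = image_size)
  }
  if (extractor$input_size != image_size) {
    stop("extractor input size ", extractor$input_size,
         " does not match image_size ", image_size)
  }
  with_seed(seed, {
    cats <- seq_len(n_categories)
    if (category_disjoint) {
      n_test_cat <- max(1L, min(n_categories - 1L,
                                round(n_categories * n_test / (n_train + n_test))))
      test_cats <- sort(sample(cats, n_test_cat))
      train_cats <- setdiff(cats, test_cats)
    } else {
      train_cats <- test_cats <- cats
    }
    cat_par <- lapply(cats, category_params)
    cat_train <- allocate_categories(n_train, train_cats)
    cat_test <- allocate_categories(n_test, test_cats)
    n <- n_train + n_test
    images <- array(0, dim = c(n, image_size, image_size, 3L))
    category <- c(cat_train, cat_test)
    split <- c(rep("train", n_train), rep("test", n_test))
    for (i in seq_len(n)) {
      img <- render_stimulus(image_size, jitter_params(cat_par[[category[i]]]))
      if (texture_noise > 0) {
        field <- array(stats::runif(length(img)), dim = dim(img))
        img <- (1 - texture_noise) * img + texture_noise * field
      }
      images[i, , , ] <- img
    }
    ids <- sprintf("stim_%04d_%s", seq_len(n), split)
    features <- extract_features(extractor, images, stimulus_ids = ids)
    structure(list(stimulus_ids = ids, category = category, split = split,
                   images = images, features = features,
                   extractor = extractor, seed = seed,
                   category_disjoint = category_disjoint,
                   train_categories = train_cats, test_categories = test_cats),
              class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", sum(x$split == "train"), " train / ",
      sum(x$split == "test"), " test stimuli, ",
      length(unique(x$category)), " categories, ",
      dim(x$images)[2], "x", dim(x$images)[3], " px\n", sep = "")
  invisible(x)
}

## Restrict a stimulus_set to a subset of stimuli.
subset_world <- function(world, idx) {
  out <- world
  out$stimulus_ids <- world$stimulus_ids[idx]
  out$category <- world$category[idx]
  out$split <- world$split[idx]
  out$images <- world$images[idx, , , , drop = FALSE]
  out$features <- subset_stack(world$features, idx)
  out
}

#' Training-set rows of a stimulus world
#' @param world A [make_stimulus_world()] object.
#' @return The `stimulus_set` restricted to its training split.
#' @export
train_set <- function(world) subset_world(world, world$split == "train")

#' Test-set rows of a stimulus world
#' @param world A [make_stimulus_world()] object.
#' @return The `stimulus_set` restricted to its test split.
#' @export
test_set <- function(world) subset_world(world, world$split == "test")

#' Split training stimuli into category-disjoint source and target halves
#'
#' Emulates the non-overlapping condition: the training categories are
#' randomly divided into two halves, and each half's stimuli form one
#' stimulus set, so the source and target converter/decoder trainings share
#' neither stimuli nor categories. The union of the two halves is exactly
#' the original training set; the world's test split is left untouched.
#'
#' @param world A [make_stimulus_world()] object with `>= 2` training
#'   categories.
#' @param seed Seed for the category shuffle.
#' @return List with elements `source` and `target`, each a `stimulus_set`
#'   containing only training stimuli.
#' @export
split_source_target_nonoverlapping <- function(world, seed = 1L) {
  tr_cats <- sort(unique(world$category[world$split == "train"]))
  if (length(tr_cats) < 2) {
    stop("non-overlapping split needs at least 2 training categories")
  }
  with_seed(seed, {
    shuffled <- sample(tr_cats)
    half <- ceiling(length(shuffled) / 2)
    src_cats <- sort(shuffled[seq_len(half)])
    tgt_cats <- sort(shuffled[-seq_len(half)])
    is_train <- world$split == "train"
    list(source = subset_world(world, is_train & world$category %in% src_cats),
         target = subset_world(world, is_train & world$category %in% tgt_cats))
  })
}
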