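## Convolution primitives for the toy feature extractor.
##
## Images are stored as arrays [height, width, channel]; a padded image is
## flattened column-major (rows fastest, then columns, then channels). A
## convolution is expressed as an im2col gather followed by one matrix
## multiply, which keeps both the forward pass and the input-gradient pass
## exact and fast at the image sizes used here (<= 64 x 64).

## Precompute the gather-index matrix for one convolutional layer.
## Returns idx [n_out_positions x (kernel^2 * ch_in)] indexing into the
## flattened padded image; output positions are ordered column-major over
## (row, col) so that flattened feature maps are position-fastest.
conv_index_map <- function(h, w, ch_in, kernel, stride, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  out_h <- (hp - kernel) %/% stride + 1L
  out_w <- (wp - kernel) %/% stride + 1L
  if (out_h < 1L || out_w < 1L) {
    stop("kernel larger than padded input (", hp, "x", wp, ")")
  }
  oi <- rep(seq_len(out_h), times = out_w)
  oj <- rep(seq_len(out_w), each = out_h)
  top <- (oi - 1L) * stride
  left <- (oj - 1L) * stride
  off <- expand.grid(di = seq_len(kernel) - 1L,
                     dj = seq_len(kernel) - 1L,
                     ch = seq_len(ch_in) - 1L)
  idx <- matrix(0L, nrow = out_h * out_w, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    idx[, k] <- (top + off$di[k] + 1L) +
      (left + off$dj[k]) * hp +
      off$ch[k] * (hp * wp)
  }
  list(idx = idx, out_h = out_h, out_w = out_w,
       hp = hp, wp = wp, ch_in = ch_in, pad = pad, h = h, w = w)
}

## Zero-pad an [h, w, c] image and flatten it column-major.
pad_image_vec <- function(img, map) {
  if (map$pad == 0L) return(as.vector(img))
  padded <- array(0, dim = c(map$hp, map$wp, map$ch_in))
  padded[map$pad + seq_len(map$h), map$pad + seq_len(map$w), ] <- img
  as.vector(padded)
}

## Forward convolution: pre-activation matrix [n_out_positions x ch_out].
conv_forward <- function(img, map, W, b) {
  vec <- pad_image_vec(img, map)
  patches <- matrix(vec[map$idx], nrow = nrow(map$idx))
  pre <- patches %*% W
  pre <- sweep(pre, 2, b, "+")
  list(pre = pre, patches = patches)
}

## Gradient of a scalar loss with respect to the layer input image, given the
## gradient with respect to the pre-activations. Within one column of the
## gather index (a fixed patch offset) all target positions are distinct, so
## scatter-add can proceed column by column without collisions.
conv_backward_input <- function(grad_pre, map, W) {
  grad_patches <- grad_pre %*% t(W)
  gpad <- numeric(map$hp * map$wp * map$ch_in)
  for (k in seq_len(ncol(map$idx))) {
    ix <- map$idx[, k]
    gpad[ix] <- gpad[ix] + grad_patches[, k]
  }
  gpad <- array(gpad, dim = c(map$hp, map$wp, map$ch_in))
  if (map$pad > 0L) {
    gpad <- gpad[map$pad + seq_len(map$h), map$pad + seq_len(map$w), , drop = FALSE]
  }
  array(gpad, dim = c(map$h, map$w, map$ch_in))
}
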