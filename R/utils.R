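#' @keywords internal
"_PACKAGE"

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All stochastic operations in the package go
## through this so that (seed, config) fully determine every artifact.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Derive a child seed from a parent seed and a stream label, kept below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

## Column-wise z-scoring with stored statistics; zero-variance columns get
## sd = 1 (and are reported) so downstream algebra stays finite.
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  constant <- !is.finite(sd) | sd < .Machine$double.eps^0.5
  sd[constant] <- 1
  list(mean = mu, sd = sd, constant = constant)
}

zscore_apply <- function(x, stats) {
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

## Pearson correlation of two vectors that returns NA (rather than an error
## or warning) when either side has zero variance.
safe_cor <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

## Row-wise Pearson correlation between matching rows of two matrices.
rowwise_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  vapply(seq_len(nrow(a)), function(i) safe_cor(a[i, ], b[i, ]), numeric(1))
}

## Column-wise Pearson correlation between matching columns of two matrices.
colwise_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  vapply(seq_len(ncol(a)), function(j) safe_cor(a[, j], b[, j]), numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
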