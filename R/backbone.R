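#' Describe a feature-extraction backbone
#'
#' The fusion stage consumes per-backbone feature matrices taken after
#' global average pooling, before any classification head. Three
#' standard architectures are registered by name with their canonical
#' input sizes and pooled feature widths; `surrogate_tiny` is a small
#' two-block convolutional extractor (fixed-seed random filters + global
#' average pooling) that preserves the extract-pool-fuse contract and is
#' the default desk-scale path. The named architectures are likewise
#' served by fixed-seed random-filter networks of the surrogate family
#' at their own input size and width (random-projection convolutional
#' features); loading externally pretrained weights is not supported, so
#' `pretrained = TRUE` is rejected at extraction time.
#'
#' @param name One of `"surrogate_tiny"`, `"resnet18"`, `"densenet201"`,
#'   `"inception_resnet_v2"`.
#' @param input_size Image side length fed to the network. Defaults:
#'   64 (surrogate), 224 (resnet18/densenet201), 299
#'   (inception_resnet_v2). The value 244 sometimes quoted for these
#'   pipelines is accepted here too.
#' @param feature_dim Pooled feature width. Defaults: 32 (surrogate),
#'   512, 1920, 1536 for the named architectures.
#' @param pretrained Must be `FALSE`; kept so configurations carry the
#'   flag explicitly.
#' @param seed Seed for the fixed random filters.
#' @param alias Optional display name used in feature-bundle headers
#'   (defaults to `name`).
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(name = c("surrogate_tiny", "resnet18", "densenet201",
                                   "inception_resnet_v2"),
                          input_size = NULL, feature_dim = NULL,
                          pretrained = FALSE, seed = 1L, alias = NULL) {
  name <- match.arg(name)
  defaults <- list(
    surrogate_tiny = c(size = 64, dim = 32),
    resnet18 = c(size = 224, dim = 512),
    densenet201 = c(size = 224, dim = 1920),
    inception_resnet_v2 = c(size = 299, dim = 1536)
  )[[name]]
  input_size <- as.integer(input_size %||% defaults[["size"]])
  feature_dim <- as.integer(feature_dim %||% defaults[["dim"]])
  if (feature_dim < 1L) abort("`feature_dim` must be positive.")
  if (input_size < 8L) abort("`input_size` must be at least 8 pixels.")
  structure(
    list(name = name, alias = alias %||% name, input_size = input_size,
         feature_dim = feature_dim, pretrained = isTRUE(pretrained),
         seed = as.integer(seed)),
    class = "backbone_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the fixed random filter bank for a spec. Two convolutional
# blocks: 3x3 conv (He-scaled normal filters) + ReLU + 4x4 mean pooling,
# then 3x3 conv + ReLU + global average pooling to `feature_dim`.
surrogate_weights <- function(spec, hidden_channels = 8L) {
  rng <- rng_stream(derive_seed(spec$seed, paste0("backbone_", spec$name)))
  he <- function(k, cin, cout) {
    array(rng$rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  }
  list(
    W1 = he(3L, 1L, hidden_channels),
    b1 = rng$rnorm(hidden_channels, sd = 0.1),
    W2 = he(3L, hidden_channels, spec$feature_dim),
    b2 = rng$rnorm(spec$feature_dim, sd = 0.1)
  )
}

# im2col for 3x3 same-padding convolution: returns (H*W x 9*Cin).
im2col3 <- function(stack) {
  H <- nrow(stack[[1L]]); W <- ncol(stack[[1L]])
  cols <- vector("list", 9L * length(stack))
  k <- 1L
  for (c_in in seq_along(stack)) {
    padded <- matrix(0, H + 2L, W + 2L)
    padded[2:(H + 1L), 2:(W + 1L)] <- stack[[c_in]]
    for (dx in 0:2) {
      for (dy in 0:2) {
        cols[[k]] <- as.vector(padded[(1L + dy):(H + dy), (1L + dx):(W + dx)])
        k <- k + 1L
      }
    }
  }
  matrix(unlist(cols, use.names = FALSE), nrow = H * W)
}

conv3_relu <- function(stack, W, b) {
  H <- nrow(stack[[1L]]); Wd <- ncol(stack[[1L]])
  cin <- dim(W)[3L]; cout <- dim(W)[4L]
  M <- im2col3(stack)
  K <- matrix(W, nrow = 9L * cin, ncol = cout)
  out <- M %*% K
  out <- sweep(out, 2, b, "+")
  out[out < 0] <- 0
  lapply(seq_len(cout), function(j) matrix(out[, j], nrow = H, ncol = Wd))
}

meanpool <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  Hc <- (H %/% f) * f; Wc <- (W %/% f) * f
  m <- m[seq_len(Hc), seq_len(Wc), drop = FALSE]
  blocks <- matrix(0, Hc %/% f, Wc %/% f)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      blocks <- blocks + m[seq(i, Hc, by = f), seq(j, Wc, by = f)]
    }
  }
  blocks / f^2
}

# Forward pass of the surrogate extractor on one grayscale matrix in
# [0, 1]; returns the pooled feature vector.
surrogate_forward <- function(img, weights) {
  s1 <- conv3_relu(list(img), weights$W1, weights$b1)
  s1 <- lapply(s1, meanpool, f = 4L)
  s2 <- conv3_relu(s1, weights$W2, weights$b2)
  vapply(s2, mean, numeric(1))
}

# Normalize heterogeneous image input to a list of grayscale matrices in
# [0, 1]. Accepts a list of matrices / H x W x 3 arrays, or a 3-D array
# stacked along the third dimension.
as_image_list <- function(images) {
  if (is.list(images)) {
    imgs <- images
  } else if (is.array(images) && length(dim(images)) == 3L) {
    imgs <- lapply(seq_len(dim(images)[3L]), function(i) images[, , i])
  } else if (is.matrix(images)) {
    imgs <- list(images)
  } else {
    abort("`images` must be a list of matrices, a matrix, or a 3-D array.")
  }
  if (length(imgs) == 0L) abort("Empty image list.")
  lapply(imgs, function(im) {
    if (is.array(im) && length(dim(im)) == 3L) im <- rowMeans(im, dims = 2L)
    if (!is.matrix(im)) abort("Each image must be a 2-D matrix or H x W x C array.")
    if (any(!is.finite(im))) abort("Images must contain only finite pixel values.")
    if (max(im) > 1) im <- im / 255
    im
  })
}

#' Extract pooled convolutional features from images
#'
#' Images are converted to grayscale, rescaled to \[0, 1\], resized to
#' the backbone's input size (bilinear), and passed through the
#' backbone; the matrix of global-average-pooled activations is
#' returned. Deterministic given the spec (fixed filters).
#'
#' @param images List of matrices (or H x W x 3 arrays), or a 3-D array
#'   of images stacked along the third dimension. Pixels in \[0, 1\]
#'   (or \[0, 255\], rescaled automatically).
#' @param spec A [backbone_spec()].
#' @return Numeric matrix (n_images x feature_dim), column names
#'   `<alias>.<j>`.
#' @export
extract_features <- function(images, spec = backbone_spec()) {
  if (spec$pretrained) {
    abort("Pretrained weights are not available; use `pretrained = FALSE` (fixed random filters).")
  }
  imgs <- as_image_list(images)
  imgs <- lapply(imgs, function(im) {
    if (nrow(im) != spec$input_size || ncol(im) != spec$input_size) {
      im <- EBImage::imageData(EBImage::resize(EBImage::Image(im),
                                               w = spec$input_size,
                                               h = spec$input_size))
    }
    im
  })
  w <- surrogate_weights(spec)
  feats <- t(vapply(imgs, surrogate_forward, numeric(spec$feature_dim), weights = w))
  colnames(feats) <- paste(spec$alias, seq_len(spec$feature_dim), sep = ".")
  feats
}
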