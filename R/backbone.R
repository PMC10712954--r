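# A compact, fixed-weight convolutional feature hierarchy exposing the 13
# named sublayers (conv1, norm1, pool1, conv2, norm2, pool2, conv3, conv4,
# conv5, pool5, fc6, fc7, fc8) at which activations are read out. Weights
# are drawn once from a seeded Gaussian and then frozen; activations are
# recorded before rectification. A pretrained backbone can be plugged in by
# supplying any object with the same contract (`sublayers`, `dims`, and a
# `forward` function).

SUBLAYER_NAMES <- c("conv1", "norm1", "pool1", "conv2", "norm2", "pool2",
                    "conv3", "conv4", "conv5", "pool5", "fc6", "fc7", "fc8")

#' Construct the default synthetic backbone
#'
#' Builds the fixed-weight 13-sublayer feature hierarchy used by the decoding
#' pipeline. The network downsamples the 100x100 input to its native 32x32
#' resolution, applies three blocks of convolution / response-normalisation /
#' max-pooling followed by three stacked convolutions and three fully
#' connected stages, and exposes every stage's activation vector before
#' rectification. Convolution and fully connected stages carry no bias, so an
#' all-zero input produces all-zero activations throughout.
#'
#' @param seed integer seed for the frozen weight draw.
#' @param input_size native input resolution (pixels per side).
#' @return an object of class `backbone`.
#' @export
#' @examples
#' bb <- synthetic_backbone()
#' bb$dims
synthetic_backbone <- function(seed = 171L, input_size = 32L) {
  glorot <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  weights <- with_seed(seed, {
    list(
      conv1 = array(glorot(25, 25 * 8), c(25, 8)),        # 5x5x1 -> 8, stride 2
      conv2 = array(glorot(72, 72 * 16), c(72, 16)),      # 3x3x8 -> 16
      conv3 = array(glorot(144, 144 * 32), c(144, 32)),   # 3x3x16 -> 32
      conv4 = array(glorot(288, 288 * 32), c(288, 32)),   # 3x3x32 -> 32
      conv5 = array(glorot(288, 288 * 16), c(288, 16)),   # 3x3x32 -> 16
      fc6 = matrix(glorot(64, 64 * 128), 128, 64),
      fc7 = matrix(glorot(128, 128 * 64), 64, 128),
      fc8 = matrix(glorot(64, 64 * 32), 32, 64))
  })
  conv_plans <- list(
    conv1 = conv_plan(input_size, k = 5L, stride = 2L, pad = 2L),
    conv2 = conv_plan(8L, k = 3L, stride = 1L, pad = 1L),
    conv3 = conv_plan(4L, k = 3L, stride = 1L, pad = 1L),
    conv4 = conv_plan(4L, k = 3L, stride = 1L, pad = 1L),
    conv5 = conv_plan(4L, k = 3L, stride = 1L, pad = 1L))
  pool_plans <- list(
    pool1 = pool_plan(16L), pool2 = pool_plan(8L), pool5 = pool_plan(4L))
  dims <- c(conv1 = 16L * 16L * 8L, norm1 = 16L * 16L * 8L,
            pool1 = 8L * 8L * 8L, conv2 = 8L * 8L * 16L,
            norm2 = 8L * 8L * 16L, pool2 = 4L * 4L * 16L,
            conv3 = 4L * 4L * 32L, conv4 = 4L * 4L * 32L,
            conv5 = 4L * 4L * 16L, pool5 = 2L * 2L * 16L,
            fc6 = 128L, fc7 = 64L, fc8 = 32L)
  structure(list(sublayers = SUBLAYER_NAMES, dims = dims,
                 input_size = input_size, weights = weights,
                 conv_plans = conv_plans, pool_plans = pool_plans,
                 seed = seed, provenance = "default-synthetic"),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s, %d sublayers, input %dx%d\n", x$provenance,
              length(x$sublayers), x$input_size, x$input_size))
  print(x$dims)
  invisible(x)
}

# Precompute gather indices for an im2col convolution on an n x n input
# (single spatial plan reused across channels). Returns the list of tap
# index columns into the zero-padded (n + 2 pad)^2 plane plus geometry.
conv_plan <- function(n, k, stride, pad) {
  np <- n + 2L * pad
  out <- (n + 2L * pad - k) %/% stride + 1L
  centers_r <- seq(1L, by = stride, length.out = out)
  centers_c <- seq(1L, by = stride, length.out = out)
  pos_r <- rep(centers_r, times = out)
  pos_c <- rep(centers_c, each = out)
  taps <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L))
  idx <- matrix(0L, out * out, k * k)
  for (t in seq_len(k * k)) {
    idx[, t] <- (pos_c + taps$dc[t] - 1L) * np + (pos_r + taps$dr[t])
  }
  list(n = n, np = np, out = out, k = k, pad = pad, idx = idx)
}

pool_plan <- function(n) {
  out <- n %/% 2L
  r <- rep(seq(1L, n, by = 2L), times = out)
  c <- rep(seq(1L, n, by = 2L), each = out)
  base <- (c - 1L) * n + r
  list(out = out, idx = cbind(base, base + 1L, base + n, base + n + 1L))
}

# x: (n*n) x C feature matrix (column-major spatial plane per channel)
conv_forward <- function(x, plan, W) {
  C <- ncol(x)
  k2 <- plan$k^2
  padded <- matrix(0, plan$np * plan$np, C)
  # copy the unpadded plane into the centre of the padded plane
  n <- plan$n; pad <- plan$pad; np <- plan$np
  rows <- rep(seq_len(n) + pad, times = n)
  cols <- rep(seq_len(n) + pad, each = n)
  padded[(cols - 1L) * np + rows, ] <- x
  X <- matrix(0, nrow(plan$idx), k2 * C)
  for (t in seq_len(k2)) {
    X[, ((t - 1L) * C + 1L):(t * C)] <- padded[plan$idx[, t], , drop = FALSE]
  }
  X %*% W
}

pool_forward <- function(x, plan) {
  i <- plan$idx
  pmax(x[i[, 1], , drop = FALSE], x[i[, 2], , drop = FALSE],
       x[i[, 3], , drop = FALSE], x[i[, 4], , drop = FALSE])
}

# cross-channel response normalisation (full channel extent)
lrn_forward <- function(x, alpha = 1, beta = 0.75) {
  s <- rowSums(x^2) / ncol(x)
  x / (1 + alpha * s)^beta
}

relu <- function(x) pmax(x, 0)

# deterministic bilinear resampling of a square matrix to n_out x n_out
resample_bilinear <- function(m, n_out) {
  n <- nrow(m)
  if (n == n_out) return(m)
  # sample at pixel centres of the target grid mapped into source coords
  pos <- (seq_len(n_out) - 0.5) * n / n_out + 0.5 - 0.5  # source positions
  pos <- pmin(pmax(pos, 1), n)
  i0 <- pmin(floor(pos), n - 1L); f <- pos - i0
  a <- m[i0, i0, drop = FALSE]; b <- m[i0 + 1, i0, drop = FALSE]
  c_ <- m[i0, i0 + 1, drop = FALSE]; d <- m[i0 + 1, i0 + 1, drop = FALSE]
  fr <- matrix(f, n_out, n_out); fc <- matrix(f, n_out, n_out, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + c_ * (1 - fr) * fc +
    d * fr * fc
}

#' Extract the 13 sublayer activation vectors of an image
#'
#' Runs one image through the backbone and returns the activation vector of
#' every sublayer, recorded before rectification. The image is resampled to
#' the backbone's native input resolution deterministically (bilinear).
#'
#' @param backbone a [synthetic_backbone()] (or plug-in honouring the same
#'   contract).
#' @param image a `stimulus_image` or a numeric pixel matrix (values need not
#'   be clipped to \[0, 1\]; noisy inputs are allowed).
#' @return named list of 13 numeric vectors whose lengths match
#'   `backbone$dims`.
#' @export
extract_features <- function(backbone, image) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  stopifnot(is.matrix(px), nrow(px) == ncol(px))
  if (!is.null(backbone$forward)) return(backbone$forward(backbone, px))
  x <- resample_bilinear(px, backbone$input_size)
  w <- backbone$weights; cp <- backbone$conv_plans; pp <- backbone$pool_plans

  acts <- vector("list", 13L); names(acts) <- SUBLAYER_NAMES
  a <- conv_forward(matrix(as.vector(x), ncol = 1L), cp$conv1, w$conv1)
  acts$conv1 <- as.vector(a)
  h <- lrn_forward(relu(a));            acts$norm1 <- as.vector(h)
  h <- pool_forward(h, pp$pool1);       acts$pool1 <- as.vector(h)
  a <- conv_forward(h, cp$conv2, w$conv2); acts$conv2 <- as.vector(a)
  h <- lrn_forward(relu(a));            acts$norm2 <- as.vector(h)
  h <- pool_forward(h, pp$pool2);       acts$pool2 <- as.vector(h)
  a <- conv_forward(h, cp$conv3, w$conv3); acts$conv3 <- as.vector(a)
  a2 <- conv_forward(relu(a), cp$conv4, w$conv4); acts$conv4 <- as.vector(a2)
  a3 <- conv_forward(relu(a2), cp$conv5, w$conv5); acts$conv5 <- as.vector(a3)
  h <- pool_forward(relu(a3), pp$pool5); acts$pool5 <- as.vector(h)
  a <- w$fc6 %*% as.vector(h);          acts$fc6 <- as.vector(a)
  a <- w$fc7 %*% relu(a);               acts$fc7 <- as.vector(a)
  a <- w$fc8 %*% relu(a);               acts$fc8 <- as.vector(a)

  bad <- names(acts)[!vapply(acts, function(v) all(is.finite(v)), logical(1))]
  if (length(bad))
    stop("non-finite activations in sublayer ", bad[1], call. = FALSE)
  acts
}

# Activation matrices (n_images x dim) per sublayer for a list of images.
extract_features_set <- function(backbone, images) {
  per <- lapply(images, function(im) extract_features(backbone, im))
  nms <- names(per[[1]])
  lapply(stats::setNames(nms, nms), function(nm)
    do.call(rbind, lapply(per, function(a) a[[nm]])))
}
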