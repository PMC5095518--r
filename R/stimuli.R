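#' Difference-of-Gaussians retinal filter
#'
#' Convolves a grayscale image with the difference of two unit-sum Gaussian
#' kernels (centre minus surround), emulating the centre-surround response of
#' retinal ganglion cells. Kernels are truncated at +/- 4 surround s.d.; the
#' convolution is separable with zero padding, and the output has the same
#' shape as the input. The operator is linear and responds with exactly zero
#' to any uniform image.
#'
#' @param image Numeric matrix (2-D grayscale intensities).
#' @param sigma_center,sigma_surround Gaussian standard deviations in pixels;
#'   `sigma_center < sigma_surround` is required. Defaults are 1 and 2.
#' @return Filtered matrix, same dimensions as `image`.
#' @export
#' @examples
#' img <- generate_synthetic_image(64, seed = 1)
#' f <- dog_filter(img)
#' max(abs(dog_filter(matrix(5, 32, 32))))  # uniform field -> 0
dog_filter <- function(image, sigma_center = 1, sigma_surround = 2) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  if (sigma_center <= 0 || sigma_surround <= 0 || sigma_center >= sigma_surround) {
    stop("require 0 < sigma_center < sigma_surround", call. = FALSE)
  }
  r <- ceiling(4 * sigma_surround)
  gauss1d <- function(sigma) {
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
  }
  conv_sep <- function(img, k) {
    # separable "same" convolution; rows of the band matrix are renormalized
    # where the kernel is truncated at the border so a unit-sum Gaussian blurs
    # a constant image to exactly the same constant
    band <- function(n) {
      m <- matrix(0, n, n)
      for (d in seq(-r, r)) {
        idx <- seq_len(n - abs(d))
        if (d >= 0) m[cbind(idx, idx + d)] <- k[r + 1 + d]
        else m[cbind(idx - d, idx)] <- k[r + 1 + d]
      }
      m / rowSums(m)
    }
    band(nrow(img)) %*% img %*% t(band(ncol(img)))
  }
  conv_sep(image, gauss1d(sigma_center)) - conv_sep(image, gauss1d(sigma_surround))
}

#' Extract a randomly rotated 17x17 patch
#'
#' Samples a square patch from an image at a (by default random, uniform over
#' valid positions) centre, with the patch axes rotated by a (by default
#' uniform in \[0, 360) degrees) angle relative to the image axes. Sampling uses
#' bilinear interpolation of the source image; for angles that are multiples of
#' 90 degrees the sample grid is integer and the crop is exact.
#'
#' @param image Numeric matrix, typically already DoG-filtered.
#' @param size Patch side length in pixels (default 17).
#' @param angle Rotation in degrees; `NULL` (default) draws uniformly in
#'   \[0, 360).
#' @param center Integer vector `c(row, col)`; `NULL` draws uniformly over all
#'   centres for which the rotated sample grid stays inside the image.
#' @return `size` x `size` numeric matrix with attributes `center` and `angle`.
#' @export
extract_patch <- function(image, size = 17L, angle = NULL, center = NULL) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  half <- (size - 1) / 2
  if (is.null(angle)) angle <- stats::runif(1, 0, 360)
  a <- angle * pi / 180
  # axis-aligned half-extent of the rotated sample grid (+1 px for bilinear)
  ext <- half * (abs(cos(a)) + abs(sin(a)))
  exact <- isTRUE(all.equal(angle %% 90, 0)) || isTRUE(all.equal(angle %% 90, 90))
  margin <- if (exact) ceiling(ext - 1e-9) else ceiling(ext) + 1L
  if (is.null(center)) {
    lo <- 1L + margin
    hi_r <- h - margin; hi_c <- w - margin
    if (lo > hi_r || lo > hi_c) {
      need <- 2L * (ceiling(half * sqrt(2)) + 1L) + 1L
      stop("image too small for a rotated ", size, "x", size,
           " patch; need at least ", need, "x", need, " pixels", call. = FALSE)
    }
    center <- c(sample(lo:hi_r, 1L), sample(lo:hi_c, 1L))
  }
  off <- seq(-half, half)
  dx <- outer(off, off, function(i, j) j)   # column offset
  dy <- outer(off, off, function(i, j) i)   # row offset
  sr <- center[1] + dy * cos(a) - dx * sin(a)
  sc <- center[2] + dy * sin(a) + dx * cos(a)
  r0 <- floor(sr); c0 <- floor(sc)
  if (min(r0) < 1 || min(c0) < 1 || max(r0) + 1 > h || max(c0) + 1 > w) {
    # integer grids may touch the border row/col exactly; allow that case
    if (exact && min(sr) >= 1 && max(sr) <= h && min(sc) >= 1 && max(sc) <= w) {
      r0 <- pmin(r0, h - 1L); c0 <- pmin(c0, w - 1L)
    } else {
      stop("patch sample grid falls outside the image for this center/angle",
           call. = FALSE)
    }
  }
  fr <- sr - r0; fc <- sc - c0
  v <- (1 - fr) * (1 - fc) * image[cbind(c(r0), c(c0))] +
       (1 - fr) * fc       * image[cbind(c(r0), c(c0 + 1))] +
       fr       * (1 - fc) * image[cbind(c(r0 + 1), c(c0))] +
       fr       * fc       * image[cbind(c(r0 + 1), c(c0 + 1))]
  out <- matrix(v, size, size)
  attr(out, "center") <- center
  attr(out, "angle") <- angle
  out
}

#' Normalize a patch to zero mean and unit peak amplitude
#'
#' Subtracts the mean and rescales so the largest absolute value is 1,
#' emulating luminance and contrast adaptation. A degenerate (constant) patch
#' maps to all zeros, i.e. null input. Idempotent on non-degenerate patches.
#'
#' @param patch Numeric matrix.
#' @return Matrix of the same shape with `mean = 0` and `max(abs(.)) = 1`
#'   (or all zeros if degenerate).
#' @export
normalize_patch <- function(patch) {
  if (!all(is.finite(patch))) stop("patch contains non-finite values", call. = FALSE)
  p <- patch - mean(patch)
  m <- max(abs(p))
  if (m < 1e-12) return(array(0, dim(patch)))
  p / m
}

#' Split a signed patch into ON- and OFF-centre channels
#'
#' The ON channel is the half-rectified positive part of the patch, the OFF
#' channel the sign-flipped negative part; both are flattened (column-major)
#' and concatenated ON first. The split is lossless: `ON - OFF` reshaped
#' reproduces the patch exactly.
#'
#' @param patch Numeric matrix (typically 17x17 in \[-1, 1\]).
#' @return Non-negative numeric vector of length `2 * length(patch)`.
#' @export
split_on_off <- function(patch) {
  c(pmax(patch, 0), pmax(-patch, 0))
}

#' Recombine an ON/OFF vector into a signed patch
#'
#' Inverse of [split_on_off()].
#'
#' @param on_off Vector of length `2 * size^2` (ON first).
#' @param size Patch side length.
#' @return `size` x `size` signed matrix.
#' @export
combine_on_off <- function(on_off, size = 17L) {
  n <- size * size
  if (length(on_off) != 2L * n) {
    stop("on_off must have length ", 2L * n, call. = FALSE)
  }
  matrix(on_off[seq_len(n)] - on_off[n + seq_len(n)], size, size)
}

#' Randomly shuffle the pixels of a patch
#'
#' Applies a uniformly random permutation to the pixel positions, exactly
#' preserving the multiset of values. Used as the control that destroys the
#' spatial correlations of naturalistic input while keeping its intensity
#' distribution.
#'
#' @param patch Numeric matrix.
#' @return Matrix of the same shape with permuted entries.
#' @export
shuffle_pixels <- function(patch) {
  matrix(sample(as.vector(patch)), nrow(patch), ncol(patch))
}

#' Generate a synthetic naturalistic image
#'
#' Produces a random grayscale image whose radially averaged amplitude
#' spectrum follows a `1/f^exponent` power law (exponent 1 approximates the
#' second-order statistics of natural scenes; exponent 0 gives white noise).
#' Built by shaping white Gaussian noise in the Fourier domain. The output is
#' standardised to zero mean and unit variance.
#'
#' @param size Image side length in pixels (>= 64).
#' @param spectral_exponent Target negative log-log spectral slope (default 1).
#' @param seed Optional integer seed for reproducibility; if `NULL` the current
#'   RNG state is used.
#' @return `size` x `size` numeric matrix.
#' @export
generate_synthetic_image <- function(size = 128L, spectral_exponent = 1,
                                     seed = NULL) {
  if (size < 64) stop("size must be >= 64", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  white <- matrix(stats::rnorm(size * size), size, size)
  spec <- stats::fft(white)
  fr <- c(seq(0, floor(size / 2)), seq(ceiling(size / 2) - 1, 1)) / size
  f2 <- sqrt(outer(fr^2, fr^2, `+`))
  amp <- ifelse(f2 > 0, f2^(-spectral_exponent), 0)
  img <- Re(stats::fft(spec * amp, inverse = TRUE)) / (size * size)
  img <- img - mean(img)
  img / stats::sd(img)
}

#' Convert an ON/OFF stimulus vector to Poisson input rates
#'
#' Input spike trains are Poisson with rates proportional to the ON/OFF
#' intensities: `rate[i] = rate_scale * on_off[i]` (Hz).
#'
#' @param on_off Non-negative stimulus vector.
#' @param rate_scale Hz of input firing per unit intensity (>= 0).
#' @return Non-negative rate vector (Hz), same length.
#' @export
rates_from_stimulus <- function(on_off, rate_scale) {
  if (rate_scale < 0) stop("rate_scale must be non-negative", call. = FALSE)
  if (any(on_off < 0)) stop("on_off must be non-negative", call. = FALSE)
  rate_scale * on_off
}

#' Build a stimulus set of pre-processed patches
#'
#' Runs the full retinal pipeline: take (or generate) grayscale images, DoG
#' filter each once, then repeatedly extract randomly located, randomly
#' rotated patches, normalize them, optionally shuffle their pixels (the
#' randomized-input control), and split them into ON/OFF vectors.
#'
#' @param n Number of patches.
#' @param config A [default_config()] list (stimulus section is used).
#' @param images Optional list of grayscale matrices; if `NULL`, `n_images`
#'   synthetic 1/f images are generated.
#' @param n_images Number of synthetic images when `images` is `NULL`.
#' @param shuffle If `TRUE`, pixel-shuffle every patch (control condition).
#' @param seed Optional seed.
#' @return A `v1net_stimuli` object: list with `on_off` (2*size^2 x n matrix),
#'   `patches` (size x size x n array), `meta` (tibble: image, row, col,
#'   angle), `rate_scale`, and `shuffled` flag.
#' @export
make_stimuli <- function(n, config = default_config(), images = NULL,
                         n_images = 16L, shuffle = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- config$stimuli
  size <- sc$patch_size
  if (is.null(images)) {
    images <- lapply(seq_len(n_images), function(i) {
      generate_synthetic_image(sc$image_size, sc$spectral_exponent)
    })
  }
  filtered <- lapply(images, dog_filter,
                     sigma_center = sc$sigma_center,
                     sigma_surround = sc$sigma_surround)
  on_off <- matrix(0, 2L * size * size, n)
  patches <- array(0, c(size, size, n))
  img_id <- integer(n); rows <- integer(n); cols <- integer(n); angs <- numeric(n)
  for (k in seq_len(n)) {
    i <- sample.int(length(filtered), 1L)
    p <- extract_patch(filtered[[i]], size = size)
    ctr <- attr(p, "center")
    p <- normalize_patch(p)
    if (shuffle) p <- shuffle_pixels(p)
    patches[, , k] <- p
    on_off[, k] <- split_on_off(p)
    img_id[k] <- i; rows[k] <- ctr[1]; cols[k] <- ctr[2]
    angs[k] <- attr(p, "angle") %||% NA_real_
  }
  structure(list(
    on_off = on_off,
    patches = patches,
    meta = tibble::tibble(image = img_id, row = rows, col = cols, angle = angs),
    rate_scale = sc$rate_scale,
    shuffled = shuffle
  ), class = "v1net_stimuli")
}

#' Build a stimulus set from explicit patches
#'
#' Wraps already-prepared signed patches (e.g. mixture-morph stimuli) into the
#' same container [make_stimuli()] produces, so they can be fed to
#' [test_responses()].
#'
#' @param patches List of signed patch matrices, or a 3-D array.
#' @param rate_scale Hz per unit intensity.
#' @return A `v1net_stimuli` object.
#' @export
stimuli_from_patches <- function(patches, rate_scale) {
  if (is.array(patches) && length(dim(patches)) == 3L) {
    patches <- lapply(seq_len(dim(patches)[3]), function(k) patches[, , k])
  }
  size <- nrow(patches[[1]])
  on_off <- vapply(patches, split_on_off, numeric(2L * size * size))
  arr <- array(unlist(patches), c(size, size, length(patches)))
  structure(list(
    on_off = on_off, patches = arr,
    meta = tibble::tibble(image = NA_integer_, row = NA_integer_,
                          col = NA_integer_, angle = NA_real_,
                          .rows = length(patches)),
    rate_scale = rate_scale, shuffled = FALSE
  ), class = "v1net_stimuli")
}

#' @export
print.v1net_stimuli <- function(x, ...) {
  cat("<v1net_stimuli> ", ncol(x$on_off), " patches of ",
      nrow(x$patches), "x", ncol(x$patches),
      if (isTRUE(x$shuffled)) " (pixel-shuffled)", "\n", sep = "")
  invisible(x)
}
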