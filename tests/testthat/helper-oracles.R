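# Independent brute-force oracles used across the test files.

# direct (loop-based) 2-D Gaussian blurs, each renormalized by the in-bounds
# kernel mass at the borders, subtracted to form the DoG response
oracle_dog <- function(img, s1, s2) {
  r <- ceiling(4 * s2)
  blur <- function(s) {
    k1 <- exp(-(-r:r)^2 / (2 * s^2))
    k1 <- k1 / sum(k1)
    h <- nrow(img); w <- ncol(img)
    out <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- 0
      ri <- (-r:r)[i + (-r:r) >= 1 & i + (-r:r) <= h]
      cj <- (-r:r)[j + (-r:r) >= 1 & j + (-r:r) <= w]
      for (di in ri) for (dj in cj) {
        acc <- acc + k1[di + r + 1] * k1[dj + r + 1] * img[i + di, j + dj]
      }
      out[i, j] <- acc / (sum(k1[ri + r + 1]) * sum(k1[cj + r + 1]))
    }
    out
  }
  blur(s1) - blur(s2)
}

# paired-entry Pearson correlation of off-diagonal weights with the transpose
oracle_symmetry <- function(W) {
  n <- nrow(W)
  a <- c(); b <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) { a <- c(a, W[i, j]); b <- c(b, W[j, i]) }
  }
  stats::cor(a, b)
}

# exhaustive pair enumeration for the correlated-pair weight share
oracle_pair_share <- function(resp, W, frac) {
  n <- nrow(resp)
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- suppressWarnings(stats::cor(resp[i, ], resp[j, ]))
    if (!is.finite(r)) r <- 0
    pairs[[length(pairs) + 1]] <- c(i, j, r, W[i, j] + W[j, i])
  }
  m <- do.call(rbind, pairs)
  k <- ceiling(frac * nrow(m))
  sel <- order(m[, 3], decreasing = TRUE)[seq_len(k)]
  tot <- sum(W) - sum(diag(W))
  sum(m[sel, 4]) / tot
}

# closed-form 2x2 normal-equations solve for the mixture regression
oracle_regress <- function(rn, r1, r2) {
  nrm <- function(v) v / sqrt(sum(v^2))
  X <- cbind(nrm(r1), nrm(r2))
  y <- nrm(rn)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# small deterministic test network: tiny populations, no noise by default
tiny_config <- function(n_E = 4L, n_I = 2L, noise_rate = 0, w_noise = 0,
                        stim = 50L, blank = 10L) {
  cfg <- default_config()
  cfg$network$n_E <- n_E
  cfg$network$n_I <- n_I
  cfg$network$noise_rate <- noise_rate
  cfg$network$w_noise <- w_noise
  cfg$protocol$stim_duration <- stim
  cfg$protocol$blank_duration <- blank
  cfg
}

# stimuli object with explicit on/off columns (bypasses image pipeline)
raw_stimuli <- function(on_off, rate_scale = 1000) {
  structure(list(
    on_off = as.matrix(on_off),
    patches = array(0, c(1, 1, ncol(as.matrix(on_off)))),
    meta = tibble::tibble(.rows = ncol(as.matrix(on_off))),
    rate_scale = rate_scale, shuffled = FALSE
  ), class = "v1net_stimuli")
}
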