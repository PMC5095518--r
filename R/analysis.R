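as_counts_matrix <- function(responses) {
  if (inherits(responses, "v1net_responses")) responses$counts
  else as.matrix(responses)
}

#' Reconstruct feedforward receptive fields
#'
#' Each cell's receptive field map is its ON-centre weight vector minus its
#' OFF-centre weight vector, reshaped to the patch grid.
#'
#' @param W_ff A `v1net` network or an `n_cells` x `2*size^2` feedforward
#'   weight matrix (ON columns first).
#' @param size Patch side length (inferred from the column count by default).
#' @return Array `size` x `size` x `n_cells` of signed RF maps.
#' @export
reconstruct_rf <- function(W_ff, size = NULL) {
  if (inherits(W_ff, "v1net")) W_ff <- W_ff$W_ff
  if (is.null(size)) size <- as.integer(sqrt(ncol(W_ff) / 2))
  if (ncol(W_ff) != 2L * size * size) {
    stop("W_ff must have 2*size^2 = ", 2L * size * size, " columns", call. = FALSE)
  }
  n <- size * size
  arr <- array(0, c(size, size, nrow(W_ff)))
  for (i in seq_len(nrow(W_ff))) {
    arr[, , i] <- matrix(W_ff[i, seq_len(n)] - W_ff[i, n + seq_len(n)], size, size)
  }
  arr
}

#' Sort population responses by similarity
#'
#' Hierarchically clusters the population response vectors (columns) using
#' correlation distance (1 - Pearson) and average linkage, and permutes the
#' columns into dendrogram leaf order, which makes the discrete response
#' patterns visible as blocks. Zero-variance columns are assigned correlation
#' 0 by convention and sort last.
#'
#' @param responses A `v1net_responses` object or a cells x presentations
#'   matrix.
#' @param method Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `counts` (column-permuted matrix), `order` (the
#'   permutation), `cor` (presentation-by-presentation Pearson correlation
#'   matrix of the sorted columns), and `hclust` (the tree, over the
#'   non-degenerate columns).
#' @export
cluster_and_sort <- function(responses, method = "average") {
  m <- as_counts_matrix(responses)
  if (ncol(m) < 2) stop("need at least 2 presentations", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  live <- which(sds > 0)
  dead <- which(sds == 0)
  hc <- NULL
  if (length(live) >= 2) {
    cm <- stats::cor(m[, live, drop = FALSE])
    cm[!is.finite(cm)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cm), method = method)
    ord <- c(live[hc$order], dead)
  } else {
    ord <- c(live, dead)
  }
  sorted <- m[, ord, drop = FALSE]
  cmat <- suppressWarnings(stats::cor(sorted))
  cmat[!is.finite(cmat)] <- 0
  diag(cmat) <- 1
  list(counts = sorted, order = ord, cor = cmat, hclust = hc)
}

#' Count response clusters
#'
#' Cuts the similarity tree from [cluster_and_sort()] at a correlation-distance
#' height and reports how many clusters hold at least `min_size` presentations.
#' Used to contrast the multi-cluster structure under naturalistic stimuli with
#' the single block that survives pixel shuffling.
#'
#' @param clustering Result of [cluster_and_sort()].
#' @param h Cut height in correlation distance (default 0.6, i.e. clusters are
#'   merged while their mean correlation exceeds 0.4).
#' @param min_size Minimum number of presentations for a cluster to count
#'   (default 5% of presentations).
#' @return Integer number of clusters.
#' @export
n_response_clusters <- function(clustering, h = 0.6, min_size = NULL) {
  if (is.null(clustering$hclust)) return(if (ncol(clustering$counts) > 0) 1L else 0L)
  ct <- stats::cutree(clustering$hclust, h = h)
  if (is.null(min_size)) min_size <- max(2L, ceiling(0.05 * length(ct)))
  sum(table(ct) >= min_size)
}

#' Bidirectionality of the lateral weight matrix
#'
#' Pearson correlation between the off-diagonal entries of a square weight
#' matrix and the corresponding entries of its transpose; 1 for a perfectly
#' symmetric (fully bidirectional) matrix.
#'
#' @param W Square weight matrix (or a `v1net`, whose `W_lat` is used).
#' @return Correlation coefficient; `NA` (with a warning) if the off-diagonal
#'   entries are constant so the correlation is undefined.
#' @export
weight_symmetry <- function(W) {
  if (inherits(W, "v1net")) W <- W$W_lat
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  off <- upper.tri(W) | lower.tri(W)
  a <- W[off]; b <- t(W)[off]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("off-diagonal weights are constant; symmetry correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Share of total weight in the strongest connections
#'
#' Sorts the connection weights in decreasing order and reports the fraction
#' of the total weight carried by the strongest `top_fraction` of connections.
#' For a square matrix the diagonal (no autapses) is excluded.
#'
#' @param W Non-negative weight matrix or vector (or a `v1net`).
#' @param top_fraction Fraction of connections to include, in (0, 1].
#' @return Share in \[0, 1\]; `NA` (with a warning) if the total weight is 0.
#' @export
weight_concentration <- function(W, top_fraction) {
  if (inherits(W, "v1net")) W <- W$W_lat
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  w <- if (is.matrix(W) && nrow(W) == ncol(W)) W[row(W) != col(W)] else as.vector(W)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  tot <- sum(w)
  if (tot == 0) {
    warning("total weight is zero; concentration undefined")
    return(NA_real_)
  }
  k <- ceiling(top_fraction * length(w))
  sum(sort(w, decreasing = TRUE)[seq_len(k)]) / tot
}

cell_pairs <- function(n) {
  # unordered pairs (i < j)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2])
}

#' Weight share of the most response-correlated cell pairs
#'
#' Ranks all unordered principal-cell pairs by the Pearson correlation of
#' their response time courses, takes the top `top_pair_fraction` of pairs,
#' and reports the fraction of the total lateral weight (both directions
#' summed) carried by those pairs.
#'
#' @param responses A `v1net_responses` object or cells x presentations matrix.
#' @param W_lat Square lateral weight matrix (or a `v1net`).
#' @param top_pair_fraction Fraction of pairs, in (0, 1].
#' @return Share in \[0, 1\]; `NA` (with a warning) if total weight is 0.
#' @export
correlated_pair_weight_share <- function(responses, W_lat,
                                         top_pair_fraction = 0.05) {
  if (inherits(W_lat, "v1net")) W_lat <- W_lat$W_lat
  m <- as_counts_matrix(responses)
  n <- nrow(m)
  if (nrow(W_lat) != n) stop("responses and W_lat disagree on cell count",
                             call. = FALSE)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  pr <- cell_pairs(n)
  pr$cor <- cc[cbind(pr$i, pr$j)]
  pr$w <- W_lat[cbind(pr$i, pr$j)] + W_lat[cbind(pr$j, pr$i)]
  tot <- sum(W_lat[row(W_lat) != col(W_lat)])
  if (tot == 0) {
    warning("total lateral weight is zero; share undefined")
    return(NA_real_)
  }
  k <- ceiling(top_pair_fraction * nrow(pr))
  top <- order(pr$cor, decreasing = TRUE)[seq_len(k)]
  sum(pr$w[top]) / tot
}

#' Receptive-field similarity of strongly connected pairs
#'
#' Ranks unordered principal-cell pairs by summed bidirectional lateral weight
#' and reports the median Pearson correlation between the two reconstructed
#' receptive-field maps within the top `top_weight_fraction` of pairs. Cells
#' with constant (e.g. all-zero) receptive fields contribute correlation 0 by
#' convention.
#'
#' @param W_ff Feedforward weight matrix or a `v1net` (supplies both matrices).
#' @param W_lat Lateral weight matrix (ignored when `W_ff` is a `v1net`).
#' @param top_weight_fraction Fraction of pairs, in (0, 1].
#' @return Median RF correlation over the selected pairs.
#' @export
rf_pair_similarity <- function(W_ff, W_lat = NULL, top_weight_fraction = 0.1) {
  if (inherits(W_ff, "v1net")) {
    W_lat <- W_ff$W_lat
    W_ff <- W_ff$W_ff
  }
  n <- nrow(W_ff)
  rf <- matrix(0, ncol(W_ff) / 2, n)
  half <- ncol(W_ff) / 2
  for (i in seq_len(n)) rf[, i] <- W_ff[i, 1:half] - W_ff[i, half + 1:half]
  pr <- cell_pairs(n)
  pr$w <- W_lat[cbind(pr$i, pr$j)] + W_lat[cbind(pr$j, pr$i)]
  k <- ceiling(top_weight_fraction * nrow(pr))
  if (k < 1) stop("no qualifying pairs", call. = FALSE)
  top <- order(pr$w, decreasing = TRUE)[seq_len(k)]
  cors <- vapply(top, function(p) {
    a <- rf[, pr$i[p]]; b <- rf[, pr$j[p]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
    else stats::cor(a, b)
  }, numeric(1))
  stats::median(cors)
}

#' Extract the most active spontaneous-activity patterns
#'
#' Bins the principal-cell spikes of a spontaneous raster into `bin_ms` time
#' bins, ranks bins by total population spike count (ties broken by earlier
#' time), and keeps the top `top_fraction` of bins as population pattern
#' vectors.
#'
#' @param raster A `v1net_raster` from [record_spontaneous()] (or any tibble
#'   with `time_ms`, `neuron`, and optionally `pop`).
#' @param bin_ms Bin width in ms (default 50).
#' @param top_fraction Fraction of bins to keep (default 0.3).
#' @param n_cells Number of principal cells (taken from the raster attribute
#'   if present).
#' @return Matrix cells x selected bins of spike counts, with attribute
#'   `bin_start_ms` (the selected bins' start times, in rank order).
#' @export
spontaneous_patterns <- function(raster, bin_ms = 50, top_fraction = 0.3,
                                 n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- attr(raster, "n_E") %||% max(raster$neuron, 1L)
  duration <- attr(raster, "duration") %||%
    (if (nrow(raster)) max(raster$time_ms) + 1 else bin_ms)
  if (duration < bin_ms) stop("duration shorter than one bin", call. = FALSE)
  if ("pop" %in% names(raster)) raster <- raster[raster$pop == "E", ]
  raster <- raster[raster$neuron <= n_cells, ]
  n_bins <- floor(duration / bin_ms)
  if (nrow(raster) == 0) {
    out <- matrix(0L, n_cells, 0)
    attr(out, "bin_start_ms") <- numeric(0)
    return(out)
  }
  bin <- pmin(floor(raster$time_ms / bin_ms) + 1L, n_bins)
  counts <- matrix(0L, n_cells, n_bins)
  for (k in seq_len(nrow(raster))) {
    counts[raster$neuron[k], bin[k]] <- counts[raster$neuron[k], bin[k]] + 1L
  }
  tot <- colSums(counts)
  n_keep <- max(1L, ceiling(top_fraction * n_bins))
  ord <- order(-tot, seq_len(n_bins))[seq_len(n_keep)]   # ties -> earlier bin
  out <- counts[, ord, drop = FALSE]
  attr(out, "bin_start_ms") <- (ord - 1L) * bin_ms
  out
}

#' Match spontaneous patterns against evoked clusters
#'
#' Assigns every spontaneous population pattern to the evoked response cluster
#' whose centroid it correlates with best, and summarises how much better the
#' matched-cluster correlation is than the correlation with the other
#' clusters' centroids. A clear positive gap reproduces the observation that
#' the same multi-cell patterns dominate evoked and spontaneous activity.
#'
#' @param spont Pattern matrix from [spontaneous_patterns()].
#' @param responses Evoked `v1net_responses` (or counts matrix).
#' @param k Number of evoked clusters to form (default 4).
#' @return One-row tibble: `within` (mean correlation with the matched
#'   centroid), `between` (mean correlation with non-matched centroids), and
#'   `gap = within - between`.
#' @export
match_patterns <- function(spont, responses, k = 4) {
  m <- as_counts_matrix(responses)
  cl <- cluster_and_sort(m)
  grp <- stats::cutree(cl$hclust, k = k)
  live <- which(apply(m, 2, stats::sd) > 0)
  cents <- vapply(seq_len(k), function(g) {
    rowMeans(m[, live[grp == g], drop = FALSE])
  }, numeric(nrow(m)))
  keep <- which(apply(spont, 2, stats::sd) > 0)
  if (!length(keep)) stop("no non-degenerate spontaneous patterns", call. = FALSE)
  cc <- suppressWarnings(stats::cor(spont[, keep, drop = FALSE], cents))
  cc[!is.finite(cc)] <- 0
  best <- apply(cc, 1, max)
  rest <- (rowSums(cc) - best) / (k - 1)
  tibble::tibble(within = mean(best), between = mean(rest),
                 gap = mean(best) - mean(rest))
}

#' Linear mixtures of two stimuli
#'
#' Generates `n` patches blending two source patches at the normalized-patch
#' stage (before the ON/OFF split), moving linearly from 100% of `s2` at the
#' first element to 100% of `s1` at the last, so the endpoints are exactly the
#' pure stimuli.
#'
#' @param s1,s2 Signed patch matrices of identical shape.
#' @param n Number of mixtures (default 30).
#' @return List of `n` patch matrices.
#' @export
mixture_series <- function(s1, s2, n = 30) {
  if (!all(dim(s1) == dim(s2))) stop("stimulus shapes differ", call. = FALSE)
  lapply(seq_len(n), function(k) {
    lam <- (k - 1) / (n - 1)
    lam * s1 + (1 - lam) * s2
  })
}

#' Intensity ramp of a single stimulus
#'
#' The isolated-stimulus companion of [mixture_series()]: the patch presented
#' alone at the same `n` linearly spaced intensities (increasing or
#' decreasing).
#'
#' @param s Signed patch matrix.
#' @param n Number of steps.
#' @param increasing If `TRUE` intensity runs 0 -> 1 over the series, else
#'   1 -> 0.
#' @return List of `n` patch matrices.
#' @export
intensity_ramp <- function(s, n = 30, increasing = TRUE) {
  lapply(seq_len(n), function(k) {
    lam <- (k - 1) / (n - 1)
    if (!increasing) lam <- 1 - lam
    lam * s
  })
}

#' Decompose a mixture response onto the two pure responses
#'
#' Least-squares regression (no intercept) of the response to a mixed
#' stimulus on the responses to the two component stimuli in isolation, after
#' normalizing all three vectors to unit norm (controlling for overall
#' activity differences).
#'
#' @param r_n Response vector to the mixture.
#' @param r_1,r_2 Responses to the pure stimuli.
#' @return Named numeric vector `c(beta1, beta2)`. A zero-norm `r_n` yields
#'   `c(0, 0)` with a warning.
#' @export
regress_mixture <- function(r_n, r_1, r_2) {
  stopifnot(length(r_n) == length(r_1), length(r_1) == length(r_2))
  nrm <- function(v) {
    s <- sqrt(sum(v^2))
    if (s == 0) v else v / s
  }
  if (sqrt(sum(r_1^2)) == 0 && sqrt(sum(r_2^2)) == 0) {
    stop("both pure-stimulus responses are zero", call. = FALSE)
  }
  if (sqrt(sum(r_n^2)) == 0) {
    warning("zero-norm mixture response; coefficients set to 0")
    return(c(beta1 = 0, beta2 = 0))
  }
  fit <- stats::lm.fit(cbind(nrm(r_1), nrm(r_2)), nrm(r_n))
  b <- fit$coefficients
  b[!is.finite(b)] <- 0
  c(beta1 = unname(b[1]), beta2 = unname(b[2]))
}

#' Regression series over a mixture experiment
#'
#' Applies [regress_mixture()] to every column of a mixture response matrix.
#'
#' @param responses Cells x mixtures response matrix (spike counts or mean
#'   potentials) or a `v1net_responses`.
#' @param r_1,r_2 Pure-stimulus response vectors (conventionally the last and
#'   first column of the series).
#' @return Tibble with columns `mixture`, `beta1`, `beta2`.
#' @export
mixture_betas <- function(responses, r_1, r_2) {
  m <- as_counts_matrix(responses)
  bs <- t(vapply(seq_len(ncol(m)), function(k) {
    suppressWarnings(regress_mixture(m[, k], r_1, r_2))
  }, numeric(2)))
  tibble::tibble(mixture = seq_len(ncol(m)), beta1 = bs[, 1], beta2 = bs[, 2])
}

#' Sharpness of the transition along a mixture series
#'
#' The maximum absolute step between consecutive regression coefficients: 1
#' for an all-or-none switch, `1/(n-1)` for a perfectly linear crossover.
#'
#' @param beta_series Numeric vector (e.g. the `beta1` column from
#'   [mixture_betas()]).
#' @return Maximum absolute consecutive difference.
#' @export
transition_sharpness <- function(beta_series) {
  if (length(beta_series) < 2) stop("series must have length >= 2", call. = FALSE)
  max(abs(diff(beta_series)))
}

#' Firing-rate summary of a frozen-network test run
#'
#' Converts the per-cell, per-presentation spike counts to firing rates over
#' the stimulus window and reports the three headline statistics: the median
#' rate over all (cell, presentation) entries, the absolute maximum rate, and
#' the median over presentations of each presentation's maximal per-cell rate.
#'
#' @param responses A `v1net_responses` object or counts matrix.
#' @param stim_duration Stimulus window in ms (taken from the responses object
#'   if present).
#' @return One-row tibble: `median_rate`, `max_rate`, `median_max_rate` (Hz).
#' @export
rate_stats <- function(responses, stim_duration = NULL) {
  m <- as_counts_matrix(responses)
  if (is.null(stim_duration)) {
    stim_duration <- if (inherits(responses, "v1net_responses"))
      responses$stim_duration else stop("stim_duration required", call. = FALSE)
  }
  rates <- m / stim_duration * 1000
  tibble::tibble(
    median_rate = stats::median(rates),
    max_rate = max(rates),
    median_max_rate = stats::median(apply(rates, 2, max)))
}
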