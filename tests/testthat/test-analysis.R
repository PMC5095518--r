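test_that("receptive-field reconstruction is ON minus OFF", {
  W <- matrix(0, 3, 578)
  expect_equal(reconstruct_rf(W), array(0, c(17, 17, 3)))

  W2 <- matrix(runif(2 * 578), 2, 578)
  W2[2, ] <- W2[1, c(290:578, 1:289)]     # cell 2: ON and OFF swapped
  rf <- reconstruct_rf(W2)
  expect_equal(rf[, , 2], -rf[, , 1], tolerance = 1e-12)

  W3 <- matrix(0, 1, 578)
  W3[1, (5 - 1) * 17 + 3] <- 0.7           # single ON weight at pixel (3, 5)
  rf3 <- reconstruct_rf(W3)
  expect_equal(rf3[3, 5, 1], 0.7)
  expect_equal(sum(rf3 != 0), 1)

  expect_error(reconstruct_rf(matrix(0, 2, 100), size = 17), "columns")
})

test_that("similarity sorting recovers planted response clusters", {
  set.seed(31)
  # two planted patterns + noise, interleaved columns
  a <- c(rep(10, 10), rep(0, 10)); b <- rev(a)
  m <- cbind(sapply(1:15, function(i) a + rnorm(20)),
             sapply(1:15, function(i) b + rnorm(20)))
  m <- m[, sample(30)]
  truth <- apply(m, 2, function(col) mean(col[1:10]) > mean(col[11:20]))
  cl <- cluster_and_sort(m)
  sorted_truth <- truth[cl$order]
  # leaf order separates the two groups into contiguous blocks
  expect_equal(sum(diff(sorted_truth) != 0), 1)
  # within-block correlation exceeds between-block correlation
  w_idx <- which(sorted_truth); b_idx <- which(!sorted_truth)
  expect_gt(mean(cl$cor[w_idx, w_idx]), mean(cl$cor[w_idx, b_idx]) + 0.5)

  # exact duplicates end up adjacent with correlation 1
  m2 <- cbind(a + rnorm(20), b + rnorm(20), 0, 0)
  m2 <- cbind(m2[, 1], m2[, 2], m2[, 1])
  cl2 <- cluster_and_sort(m2)
  dup <- which(cl2$order %in% c(1, 3))
  expect_equal(abs(diff(dup)), 1)
  expect_equal(cl2$cor[dup[1], dup[2]], 1, tolerance = 1e-12)

  # permuting input columns leaves the sorted matrix invariant up to
  # within-cluster order: compare column multisets block-wise
  perm <- sample(30)
  cl3 <- cluster_and_sort(m[, perm])
  expect_equal(sort(colSums(cl3$counts)), sort(colSums(cl$counts)))

  # zero-variance columns sort last with correlation 0 by convention
  mz <- cbind(m[, 1:4], 0)
  clz <- cluster_and_sort(mz)
  expect_equal(clz$order[5], 5)
  expect_equal(clz$cor[5, 1:4], rep(0, 4))
})

test_that("weight symmetry matches the paired-entry oracle and its closed forms", {
  set.seed(32)
  S <- matrix(runif(25), 5); S <- S + t(S); diag(S) <- 0
  expect_equal(weight_symmetry(S), 1.0, tolerance = 1e-12)

  # reciprocal weights anti-ordered: w_ji = M - w_ij gives exactly -1
  A <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    A[i, j] <- runif(1); A[j, i] <- 1 - A[i, j]
  }
  expect_equal(weight_symmetry(A), -1.0, tolerance = 1e-12)

  R <- matrix(runif(25), 5); diag(R) <- 0
  expect_equal(weight_symmetry(R), oracle_symmetry(R), tolerance = 1e-12)
  expect_error(weight_symmetry(matrix(0, 2, 3)), "square")
  expect_warning(weight_symmetry(matrix(1, 3, 3)), "undefined")
})

test_that("weight concentration matches hand computations", {
  expect_equal(weight_concentration(c(9, 1, 0, 0), 0.25), 0.9)
  expect_equal(weight_concentration(rep(2, 50), 0.1), 0.1)
  expect_equal(weight_concentration(runif(40), 1), 1.0)
  W <- matrix(runif(36), 6); diag(W) <- 0
  # matrix form excludes the diagonal
  expect_equal(weight_concentration(W, 0.5),
               weight_concentration(W[row(W) != col(W)], 0.5))
  expect_warning(weight_concentration(matrix(0, 3, 3), 0.1), "undefined")
  expect_error(weight_concentration(c(1, 2), 0), "top_fraction")
})

test_that("correlated-pair weight share matches the exhaustive enumeration oracle", {
  set.seed(33)
  resp <- matrix(rpois(6 * 40, 5), 6, 40)
  W <- matrix(runif(36), 6); diag(W) <- 0
  for (f in c(0.05, 0.2, 0.5)) {
    expect_equal(correlated_pair_weight_share(resp, W, f),
                 oracle_pair_share(resp, W, f), tolerance = 1e-12)
  }

  # all weight on the most correlated pair -> share 1
  resp2 <- matrix(rnorm(5 * 30), 5, 30)
  resp2[2, ] <- resp2[1, ] + rnorm(30, sd = 0.01)
  W2 <- matrix(0, 5, 5); W2[1, 2] <- 3; W2[2, 1] <- 2
  expect_equal(correlated_pair_weight_share(resp2, W2, 0.1), 1.0)

  # weights independent of correlations -> share near the pair fraction
  set.seed(34)
  shares <- replicate(60, {
    r <- matrix(rnorm(20 * 50), 20, 50)
    W3 <- matrix(runif(400), 20); diag(W3) <- 0
    correlated_pair_weight_share(r, W3, 0.25)
  })
  expect_equal(mean(shares), 0.25, tolerance = 0.05)
})

test_that("RF similarity of strong pairs matches direct enumeration on a toy case", {
  # 4 cells: 1 and 2 identical RFs, 3 orthogonal, 4 noise
  base <- as.vector(outer(1:17, 1:17, function(i, j) sin(i / 2)))
  orth <- as.vector(outer(1:17, 1:17, function(i, j) sin(j / 2)))
  W_ff <- rbind(c(pmax(base, 0), pmax(-base, 0)),
                c(pmax(base, 0), pmax(-base, 0)),
                c(pmax(orth, 0), pmax(-orth, 0)),
                runif(578))
  W_lat <- matrix(0.01, 4, 4); diag(W_lat) <- 0
  W_lat[1, 2] <- W_lat[2, 1] <- 5   # strongest pair: identical RFs
  expect_equal(rf_pair_similarity(W_ff, W_lat, 1 / 6), 1.0, tolerance = 1e-9)

  W_lat2 <- matrix(0.01, 4, 4); diag(W_lat2) <- 0
  W_lat2[1, 3] <- W_lat2[3, 1] <- 5 # strongest pair: orthogonal RFs
  expect_equal(rf_pair_similarity(W_ff, W_lat2, 1 / 6), 0, tolerance = 0.1)

  # identical RFs everywhere -> median exactly 1 at any fraction
  W_same <- matrix(rep(W_ff[1, ], 4), 4, byrow = TRUE)
  expect_equal(rf_pair_similarity(W_same, W_lat, 0.5), 1.0, tolerance = 1e-9)
})

test_that("spontaneous pattern extraction ranks bins by population count with deterministic ties", {
  empty <- tibble::tibble(time_ms = integer(0), neuron = integer(0))
  out <- spontaneous_patterns(empty, n_cells = 10)
  expect_equal(ncol(out), 0)

  # one dense epoch dominates
  ras <- tibble::tibble(
    time_ms = c(5L, 60L, 61L, 62L, 63L, 120L),
    neuron = c(1L, 1L, 2L, 3L, 4L, 2L))
  attr(ras, "duration") <- 150
  pat <- spontaneous_patterns(ras, bin_ms = 50, top_fraction = 0.4, n_cells = 4)
  expect_equal(attr(pat, "bin_start_ms")[1], 50)
  expect_equal(sum(pat[, 1]), 4)

  # ties broken by earlier bin time
  ras2 <- tibble::tibble(time_ms = c(10L, 110L), neuron = c(1L, 1L))
  attr(ras2, "duration") <- 150
  pat2 <- spontaneous_patterns(ras2, bin_ms = 50, top_fraction = 0.34,
                               n_cells = 2)
  expect_equal(attr(pat2, "bin_start_ms")[1], 0)
})

test_that("mixture series is a convex path with exact endpoints", {
  set.seed(35)
  s1 <- normalize_patch(matrix(rnorm(289), 17, 17))
  s2 <- normalize_patch(matrix(rnorm(289), 17, 17))
  mix <- mixture_series(s1, s2, n = 30)
  expect_equal(mix[[1]], s2, tolerance = 1e-12)
  expect_equal(mix[[30]], s1, tolerance = 1e-12)
  mid <- mixture_series(s1, s2, n = 3)[[2]]
  expect_equal(mid, (s1 + s2) / 2, tolerance = 1e-12)
  # component intensities move monotonically along the series
  lam1 <- vapply(mix, function(m) sum(m * s1) / sum(s1 * s1), numeric(1))
  expect_true(all(diff(lam1) > 0))
  expect_error(mixture_series(s1, matrix(0, 5, 5)), "shape")

  ramp <- intensity_ramp(s1, n = 5)
  expect_equal(ramp[[1]], 0 * s1)
  expect_equal(ramp[[5]], s1)
})

test_that("mixture regression matches the closed-form normal-equations oracle", {
  set.seed(36)
  r1 <- c(1, 0, 0, 0); r2 <- c(0, 1, 0, 0)
  expect_equal(regress_mixture(r1, r1, r2), c(beta1 = 1, beta2 = 0),
               tolerance = 1e-12)
  expect_equal(regress_mixture(r2, r1, r2), c(beta1 = 0, beta2 = 1),
               tolerance = 1e-12)

  for (k in 1:10) {
    rn <- rpois(30, 4); ra <- rpois(30, 4); rb <- rpois(30, 4)
    got <- regress_mixture(rn, ra, rb)
    want <- oracle_regress(rn, ra, rb)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
  expect_warning(b0 <- regress_mixture(c(0, 0), c(1, 0), c(0, 1)), "zero-norm")
  expect_equal(unname(b0), c(0, 0))
})

test_that("transition sharpness distinguishes ramps from steps", {
  expect_equal(transition_sharpness(seq(0, 1, length.out = 30)), 1 / 29,
               tolerance = 1e-12)
  expect_equal(transition_sharpness(c(rep(0, 15), rep(1, 15))), 1)
  expect_error(transition_sharpness(1), "length")
})

test_that("rate statistics convert counts to Hz and are permutation invariant", {
  z <- matrix(0, 4, 6)
  expect_equal(unlist(rate_stats(z, 300)), c(median_rate = 0, max_rate = 0,
                                             median_max_rate = 0))
  one <- matrix(10, 1, 1)
  expect_equal(unlist(rate_stats(one, 250)),
               c(median_rate = 40, max_rate = 40, median_max_rate = 40))
  set.seed(37)
  m <- matrix(rpois(200, 3), 10, 20)
  expect_equal(rate_stats(m, 300), rate_stats(m[, sample(20)], 300))
})

test_that("tidiers return well-formed tables", {
  cfg <- tiny_config(n_E = 4, n_I = 2)
  net <- build_network(cfg, seed = 38)
  td <- tidy(net)
  expect_equal(nrow(td), 4 * 3)
  expect_true(all(c("pre", "post", "weight", "delay_ms") %in% names(td)))
  g <- suppressWarnings(glance(net))
  expect_equal(g$n_E, 4)

  stim <- raw_stimuli(matrix(0, 578, 2))
  resp <- test_responses(net, stim, seed = 39)
  tr <- tidy(resp)
  expect_equal(nrow(tr), 4 * 2)
  expect_equal(glance(resp)$n_presentations, 2)
})
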