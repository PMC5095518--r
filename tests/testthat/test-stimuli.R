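test_that("DoG filter gives zero response to uniform fields and matches a direct convolution oracle", {
  expect_equal(max(abs(dog_filter(matrix(7, 24, 24)))), 0, tolerance = 1e-12)

  set.seed(41)
  i1 <- matrix(rnorm(32 * 32), 32, 32)
  i2 <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(dog_filter(i1), oracle_dog(i1, 1, 2), tolerance = 1e-10)
  # linearity: dog(a I1 + b I2) = a dog(I1) + b dog(I2)
  expect_equal(dog_filter(2.5 * i1 - 1.3 * i2),
               2.5 * dog_filter(i1) - 1.3 * dog_filter(i2), tolerance = 1e-10)
})

test_that("DoG impulse response is the kernel itself: positive centre, negative surround", {
  imp <- matrix(0, 33, 33)
  imp[17, 17] <- 1
  k <- dog_filter(imp)
  expect_gt(k[17, 17], 0)        # centre dominated by the narrow Gaussian
  expect_lt(k[17, 13], 0)        # 4 px out: surround dominates
  expect_equal(sum(k), 0, tolerance = 1e-10)  # unit-sum Gaussians cancel
})

test_that("DoG filter rejects non-2-D and non-finite input", {
  expect_error(dog_filter(1:10), "matrix")
  expect_error(dog_filter(matrix(c(1, NA, 3, 4), 2)), "finite")
  expect_error(dog_filter(matrix(1, 4, 4), 2, 1), "sigma")
})

test_that("patch extraction is an identity crop at angle 0 and symmetric under 180-degree rotation", {
  img <- matrix(seq_len(17 * 17), 17, 17) * 1.0
  p <- extract_patch(img, angle = 0, center = c(9, 9))
  expect_equal(matrix(p, 17), img, tolerance = 1e-12)

  # radially symmetric pattern is invariant under 180-degree patch rotation
  sym <- outer(-15:15, -15:15, function(i, j) exp(-(i^2 + j^2) / 40))
  p0 <- extract_patch(sym, angle = 0, center = c(16, 16))
  p180 <- extract_patch(sym, angle = 180, center = c(16, 16))
  expect_equal(matrix(p0, 17), matrix(p180, 17), tolerance = 1e-9)
})

test_that("patch locations are uniform over valid positions", {
  set.seed(7)
  img <- matrix(rnorm(64 * 64), 64, 64)
  n <- 10000
  # fixed angle so the valid-centre range (and hence uniformity) is well defined
  centers <- t(replicate(n, attr(extract_patch(img, angle = 45), "center")))
  # coarse 3x3 grid over the valid centre range; chi-square not rejected
  rng <- range(centers)
  cuts <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = 4)
  tab <- table(cut(centers[, 1], cuts), cut(centers[, 2], cuts))
  # bins have slightly unequal integer widths; compare against exact expected
  widths <- diff(round(cuts - 0.5))
  exp_p <- outer(widths, widths) / sum(outer(widths, widths))
  pval <- suppressWarnings(chisq.test(as.vector(tab), p = as.vector(exp_p))$p.value)
  expect_gt(pval, 0.01)
})

test_that("too-small images are rejected with the minimum size in the message", {
  expect_error(extract_patch(matrix(0, 20, 20)), "at least")
})

test_that("patch normalization matches hand arithmetic and handles degenerate input", {
  p <- matrix(c(2, 6, 4, 8), 2, 2)   # [[2,4],[6,8]] row-wise
  expect_equal(normalize_patch(p), matrix(c(-1, 1 / 3, -1 / 3, 1), 2, 2),
               tolerance = 1e-12)
  expect_equal(normalize_patch(matrix(3.7, 5, 5)), matrix(0, 5, 5))
  # postconditions + idempotence on random patches
  set.seed(11)
  for (k in 1:20) {
    q <- normalize_patch(matrix(rnorm(289), 17, 17))
    expect_equal(mean(q), 0, tolerance = 1e-9)
    expect_equal(max(abs(q)), 1, tolerance = 1e-12)
    expect_equal(normalize_patch(q), q, tolerance = 1e-12)
  }
})

test_that("ON/OFF split is a lossless non-negative decomposition", {
  p <- matrix(0, 17, 17); p[3, 5] <- -0.5
  v <- split_on_off(p)
  expect_equal(sum(v[1:289]), 0)             # ON half silent
  expect_equal(sum(v > 0), 1)                # one OFF entry
  expect_equal(v[289 + (5 - 1) * 17 + 3], 0.5)

  all_pos <- matrix(abs(rnorm(289)), 17, 17)
  expect_equal(sum(split_on_off(all_pos)[290:578]), 0)

  set.seed(12)
  for (k in 1:100) {
    q <- normalize_patch(matrix(rnorm(289), 17, 17))
    v <- split_on_off(q)
    expect_true(all(v >= 0))
    expect_equal(combine_on_off(v), q, tolerance = 1e-12)
  }
})

test_that("pixel shuffling preserves the value multiset and visits positions uniformly", {
  set.seed(13)
  p <- matrix(rnorm(289), 17, 17)
  s <- shuffle_pixels(p)
  expect_equal(sort(as.vector(s)), sort(as.vector(p)))
  expect_equal(shuffle_pixels(matrix(2, 17, 17)), matrix(2, 17, 17))

  # marked pixel lands approximately uniformly over all 289 positions
  marked <- matrix(0, 17, 17); marked[1, 1] <- 1
  n <- 5000
  pos <- replicate(n, which(shuffle_pixels(marked) == 1))
  pval <- suppressWarnings(chisq.test(tabulate(pos, 289))$p.value)
  expect_gt(pval, 0.01)
})

test_that("synthetic images have the requested spectral slope and are seed-deterministic", {
  slope_of <- function(img) {
    n <- nrow(img)
    amp <- Mod(stats::fft(img))
    fr <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) / n
    f <- sqrt(outer(fr^2, fr^2, `+`))
    keep <- f > 2 / n & f < 0.4
    bins <- cut(log(f[keep]), 12)
    lx <- tapply(log(f[keep]), bins, mean)
    ly <- tapply(log(amp[keep]), bins, mean)
    unname(coef(lm(ly ~ lx))[2])
  }
  img1 <- generate_synthetic_image(256, spectral_exponent = 1, seed = 5)
  expect_equal(slope_of(img1), -1, tolerance = 0.15)
  img0 <- generate_synthetic_image(256, spectral_exponent = 0, seed = 5)
  expect_equal(slope_of(img0), 0, tolerance = 0.15)

  expect_identical(generate_synthetic_image(64, seed = 3),
                   generate_synthetic_image(64, seed = 3))
  expect_false(identical(generate_synthetic_image(64, seed = 3),
                         generate_synthetic_image(64, seed = 4)))
  expect_error(generate_synthetic_image(32), ">= 64")
})

test_that("stimulus rates are linear in intensity and reject negative scales", {
  expect_equal(rates_from_stimulus(numeric(578), 100), numeric(578))
  v <- numeric(578); v[37] <- 1
  expect_equal(rates_from_stimulus(v, 85)[37], 85)
  expect_error(rates_from_stimulus(v, -1), "non-negative")
})

test_that("make_stimuli produces valid normalized ON/OFF patch sets", {
  cfg <- default_config()
  st <- make_stimuli(25, cfg, n_images = 2, seed = 99)
  expect_equal(dim(st$on_off), c(578, 25))
  expect_true(all(st$on_off >= 0))
  for (k in 1:25) {
    p <- st$patches[, , k]
    expect_equal(mean(p), 0, tolerance = 1e-9)
    expect_equal(max(abs(p)), 1, tolerance = 1e-9)
    expect_equal(combine_on_off(st$on_off[, k]), p, tolerance = 1e-12)
  }
  # shuffled control preserves each patch's value multiset
  st2 <- make_stimuli(5, cfg, n_images = 2, shuffle = TRUE, seed = 99)
  expect_true(all(abs(apply(st2$patches, 3, mean)) < 1e-9))
})
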