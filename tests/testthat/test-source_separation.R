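test_that("preprocessing removes DC and flags gross outlier channels only", {
  x <- matrix(0, 59, 1000)
  x[3, ] <- 17.5                       # constant offset channel
  x[7, ] <- rnorm(1000, sd = 5)
  rec <- quick_recording(x, fs = 1000)
  pp <- preprocess(rec, hp_hz = 0, target_fs_hz = 1000)
  expect_equal(max(abs(pp$data[3, ])), 0)
  # a saturated channel (variance >> others) is excluded and recorded
  set.seed(4)
  y <- matrix(rnorm(59 * 2000, sd = 10), 59)
  y[12, ] <- rnorm(2000, sd = 500)
  pp2 <- preprocess(quick_recording(y), hp_hz = 0, target_fs_hz = 1000)
  expect_equal(pp2$preprocessing$bad_channels, 12L)
  expect_equal(max(abs(pp2$data[12, ])), 0)
  # physiologically plausible variance spread is untouched
  y[12, ] <- rnorm(2000, sd = 25)
  pp3 <- preprocess(quick_recording(y), hp_hz = 0, target_fs_hz = 1000)
  expect_length(pp3$preprocessing$bad_channels, 0)
})

test_that("the notch suppresses a 50 Hz sine by at least 40 dB", {
  t <- seq(0, 4, by = 1 / 1000)[-1]
  x <- matrix(rep(sin(2 * pi * 50 * t), each = 59), 59, byrow = FALSE)
  rec <- quick_recording(x, fs = 1000)
  pp <- preprocess(rec, hp_hz = 0, notch_hz = 50, target_fs_hz = 1000,
                   bad_channel_z = Inf)
  mid <- 1000:3000                     # avoid filter edge transients
  expect_lt(sqrt(mean(pp$data[1, mid]^2)) / sqrt(mean(x[1, mid]^2)), 0.01)
})

test_that("10 kHz -> 1 kHz downsampling preserves a 5 Hz sine", {
  t <- seq(0, 3, by = 1 / 10000)[-1]
  x <- matrix(rep(10 * sin(2 * pi * 5 * t), each = 59), 59, byrow = FALSE)
  rec <- quick_recording(x, fs = 10000)
  pp <- preprocess(rec, hp_hz = 0, target_fs_hz = 1000, bad_channel_z = Inf)
  expect_equal(pp$fs_hz, 1000)
  mid <- 500:2500
  amp <- max(abs(pp$data[1, mid]))
  expect_lt(abs(amp - 10) / 10, 0.01)
  expect_error(preprocess(rec, target_fs_hz = 20000), "configuration error")
})

test_that("a rank-1 noiseless recording gives one IC matching the source", {
  set.seed(6)
  n <- 4000
  s <- spiky_trace(n, 40)
  map <- c(seq(1, 0.2, length.out = 20), rep(0, 39))
  rec <- quick_recording(outer(map, s))
  m <- decompose(rec)
  expect_equal(m$n_ics, 1)
  expect_gte(abs(cor(m$ic_traces[1, ], s)), 0.999)
  expect_gte(abs(sum(m$weights[1, ] * map)) /
               sqrt(sum(m$weights[1, ]^2) * sum(map^2)), 0.999)
  expect_error(decompose(quick_recording(matrix(0, 59, 100))),
               "rank-deficient")
})

test_that("two super-Gaussian sources are unmixed to cosine >= 0.95", {
  set.seed(9)
  n <- 8000
  s1 <- spiky_trace(n, 60); s2 <- spiky_trace(n, 60)
  m1 <- c(rep(0, 10), seq(1, 0.3, length.out = 15), rep(0, 34))
  m2 <- c(rep(0, 40), seq(0.3, 1, length.out = 19))
  X <- outer(m1, s1) + outer(m2, s2) + matrix(rnorm(59 * n, sd = 1), 59)
  m <- decompose(quick_recording(X))
  cos2 <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  best1 <- max(apply(m$weights, 1, cos2, b = m1))
  best2 <- max(apply(m$weights, 1, cos2, b = m2))
  expect_gte(best1, 0.95)
  expect_gte(best2, 0.95)
})

test_that("reconstruction explains at least the variance target", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 2000
    X <- outer(runif(59), spiky_trace(n, 30)) +
      matrix(rnorm(59 * n, sd = 2), 59)
    m <- decompose(quick_recording(X), variance_target = 0.9)
    Xc <- X - rowMeans(X)
    Xhat <- t(m$weights) %*% m$ic_traces
    explained <- 1 - sum((Xc - Xhat)^2) / sum(Xc^2)
    expect_gte(explained, 0.9 - 1e-6)
    expect_gte(m$pca_variance_retained, 0.9)
  }
})

test_that("spatial_map follows its definition and index checks", {
  m <- structure(list(weights = rbind(c(1, 0.5, 0.1, rep(0, 56))),
                      n_ics = 1), class = "source_model")
  expect_equal(spatial_map(m, 1, theta = 0.2), c(1, 2))
  m$weights[1, ] <- c(0.7, rep(0, 58))
  expect_equal(spatial_map(m, 1), 1)
  expect_error(spatial_map(m, 2), "out of range")
  expect_error(spatial_map(m, 1, theta = 1.2), "theta")
})

test_that("electrode relabelling permutes weights; sign flips leave maps", {
  set.seed(13)
  n <- 3000
  s <- spiky_trace(n, 30)
  map <- c(seq(1, 0.25, length.out = 18), rep(0, 41))
  X <- outer(map, s) + matrix(rnorm(59 * n, sd = 0.5), 59)
  perm <- sample(59)
  m_a <- decompose(quick_recording(X))
  m_b <- decompose(quick_recording(X[perm, ]))
  expect_equal(m_b$weights[1, ], m_a$weights[1, perm], tolerance = 1e-6)
  expect_setequal(match(spatial_map(m_a, 1), perm), spatial_map(m_b, 1))
  flipped <- m_a
  flipped$weights <- -flipped$weights
  expect_equal(spatial_map(flipped, 1), spatial_map(m_a, 1))
})

test_that("weight grids place electrodes on the 8 x 8 layout", {
  set.seed(1)
  X <- outer(c(1, rep(0, 58)), spiky_trace(1000, 10)) +
    matrix(rnorm(59000, sd = 0.1), 59)
  m <- decompose(quick_recording(X))
  g <- weight_grid(m, 1)
  expect_equal(dim(g), c(8, 8))
  expect_equal(sum(is.na(g)), 5)       # 4 corners + reference electrode
})
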