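test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(c(1, -1, 0.5), 2), c(0, 0, 0))
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  x <- c(-3, 0, 0.2, 7)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -1), "parameter error")
})

test_that("MAD noise-scale estimator is consistent and homogeneous", {
  expect_identical(estimate_sigma(numeric(16)), 0)
  set.seed(41)
  z <- rnorm(10000)
  expect_gt(estimate_sigma(z), 0.95)
  expect_lt(estimate_sigma(z), 1.05)
  expect_equal(estimate_sigma(-2.5 * z), 2.5 * estimate_sigma(z))
  expect_error(estimate_sigma(numeric(0)), "parameter error")
})

test_that("SURE threshold equals the brute-force risk minimizer", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(2:64, 1)
    coeffs <- rnorm(n, sd = sample(c(0.5, 1, 3), 1))
    sigma <- runif(1, 0.2, 2)
    expect_equal(sure_threshold(coeffs, sigma),
                 brute_force_sure(coeffs, sigma), tolerance = 1e-12)
  }
  expect_identical(sure_threshold(numeric(10), 1), 0)
  expect_error(sure_threshold(rnorm(4), 0), "parameter error")
  expect_error(sure_threshold(numeric(0), 1), "parameter error")
})

test_that("SURE threshold is scale-equivariant and bounded by max |coef|", {
  set.seed(43)
  for (i in 1:20) {
    coeffs <- rnorm(32)
    t1 <- sure_threshold(coeffs, 1)
    expect_equal(sure_threshold(3 * coeffs, 3), 3 * t1, tolerance = 1e-12)
    expect_lte(t1, max(abs(coeffs)))
    expect_gte(t1, 0)
  }
})

test_that("SURE keeps sparse large coefficients while suppressing noise", {
  set.seed(44)
  coeffs <- c(rep(10, 8) * sample(c(-1, 1), 8, TRUE), rnorm(120))
  t <- sure_threshold(coeffs, 1)
  kept <- soft_threshold(coeffs, t)
  big <- abs(coeffs) > 5
  # soft thresholding shrinks spikes by t (~ the noise scale): their support
  # survives intact and most of their energy with it, while the noise floor
  # is largely removed
  expect_true(all(abs(kept[big]) > 8))
  expect_gt(sum(kept[big]^2) / sum(coeffs[big]^2), 0.6)
  expect_lt(sum(kept[!big]^2) / sum(coeffs[!big]^2), 0.4)
  expect_lt(t, 2)
})

test_that("hybrid rule falls back to the universal threshold when sparse", {
  set.seed(45)
  z <- rnorm(64) * 1e-3          # nearly-dead level: SURE unreliable
  t_h <- sure_threshold(z, 1, rule = "hybrid")
  expect_equal(t_h, sqrt(2 * log(64)))
  dense <- c(rnorm(32), rnorm(32, sd = 10))
  expect_lte(sure_threshold(dense, 1, rule = "hybrid"),
             sqrt(2 * log(64)))
})

test_that("epoch denoising preserves length, zeroes zero, shrinks energy", {
  expect_equal(denoise_epoch(numeric(256), "db4"), numeric(256))
  set.seed(46)
  x <- rnorm(256)
  for (mode in c("symmetric", "periodic")) {
    y <- denoise_epoch(x, "sym9", 5, mode)
    expect_length(y, 256L)
  }
  # orthonormal transform + shrinkage: energy never grows (periodic mode)
  for (i in 1:10) {
    x <- rnorm(256) + as.numeric(gen_wavelet_structured("db3", Inf, 256, seed = i))
    y <- denoise_epoch(x, "db3", 5, "periodic")
    expect_lte(sum(y^2), sum(x^2) * (1 + 1e-8))
  }
})

test_that("denoising a sparse broadband signal improves similarity to truth", {
  # signals with a sparse representation are the regime SURE targets
  improved <- 0L
  for (i in 1:10) {
    noisy <- gen_wavelet_structured("db4", snr_db = 10, seed = 400 + i)
    clean <- attr(noisy, "clean")
    y <- denoise_epoch(as.numeric(noisy), "db4", 5)
    improved <- improved +
      (xcorr(y, clean) > xcorr(as.numeric(noisy), clean))
  }
  expect_gte(improved, 8L)
})

test_that("threshold report records one row per level with valid bounds", {
  set.seed(47)
  x <- rnorm(256)
  r <- denoise_epoch(x, "db6", 5, report = TRUE)
  expect_named(r, c("signal", "report"))
  expect_identical(nrow(r$report), 5L)
  expect_true(all(r$report$threshold >= 0))
  expect_true(all(r$report$sigma > 0))
  d <- wavedec(x, "db6", 5)
  expect_true(all(r$report$threshold <=
                    vapply(d$details, function(v) max(abs(v)), 1)))
})

test_that("zeroing D1 removes the finest-band component", {
  set.seed(48)
  x <- rnorm(256)
  y <- denoise_epoch(x, "db4", 5, zero_d1 = TRUE)
  comps <- mra_reconstruct(wavedec(y, "db4", 5))
  expect_lt(sum(comps$D1^2), 1e-3 * sum(x^2))
})

test_that("compiled scoring path matches the reference implementation", {
  set.seed(49)
  for (i in 1:20) {
    x <- rnorm(256) + 3 * as.numeric(gen_wavelet_structured("sym6", Inf, 256, seed = i))
    for (wn in c("db1", "db20", "sym9", "coif5")) {
      w <- wavelet_spec(wn)
      for (mode in c("symmetric", "periodic")) {
        a <- denoise_epoch(x, w, 5, mode)
        b <- mwtselect:::cpp_denoise_epoch(x, w$dec_lo, w$dec_hi, 5L,
                                           mode == "periodic", FALSE, FALSE)
        expect_lt(max(abs(a - b)), 1e-10)
      }
    }
  }
})
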