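test_that("Haar single-level transform matches hand values", {
  s <- dwt_level(c(1, 1, 1, 1), "db1", "periodic")
  expect_equal(s$approx, c(sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(s$detail, c(0, 0), tolerance = 1e-12)
  a <- dwt_level(c(1, -1, 1, -1), "db1", "periodic")
  expect_equal(a$approx, c(0, 0), tolerance = 1e-12)
  expect_equal(sum(a$detail^2), 4, tolerance = 1e-12)
  expect_equal(idwt_level(c(sqrt(2), sqrt(2)), c(0, 0), "db1", "periodic"),
               c(1, 1, 1, 1), tolerance = 1e-12)
})

test_that("single-level round trips are exact in both directions", {
  set.seed(5)
  x <- rnorm(256)
  for (mode in c("symmetric", "periodic")) {
    s <- dwt_level(x, "db7", mode)
    expect_equal(idwt_level(s$approx, s$detail, "db7", mode, out_len = 256),
                 x, tolerance = 1e-10)
  }
  # coefficient-side round trip (periodic transform is orthonormal)
  a <- rnorm(64); d <- rnorm(64)
  y <- idwt_level(a, d, "sym5", "periodic")
  s2 <- dwt_level(y, "sym5", "periodic")
  expect_equal(s2$approx, a, tolerance = 1e-10)
  expect_equal(s2$detail, d, tolerance = 1e-10)
  # zero coefficients reconstruct the zero signal
  expect_equal(idwt_level(numeric(8), numeric(8), "db2", "periodic"),
               numeric(16))
})

test_that("decomposition depth and length mismatches are rejected", {
  expect_error(dwt_level(rnorm(7), "db4", "symmetric"), "decomposition depth")
  expect_error(dwt_level(rnorm(7), "db2", "periodic"), "decomposition depth")
  expect_error(idwt_level(rnorm(4), rnorm(5), "db2"), "length mismatch")
  expect_error(wavedec(rnorm(24), "db1", 5, "periodic"), "decomposition depth")
})

test_that("five-level wavedec of a 256-sample epoch yields six coefficient sets", {
  d <- wavedec(rnorm(256), "sym9", 5)
  expect_identical(d$levels, 5L)
  expect_length(d$details, 5L)
  expect_identical(d$original_length, 256L)
  # constant signal: all details vanish (vanishing moment)
  dc <- wavedec(rep(2.5, 256), "db5", 5, "periodic")
  expect_lt(max(abs(unlist(dc$details))), 1e-10)
})

test_that("wavedec/waverec round trip holds for every bank member", {
  set.seed(11)
  x <- rnorm(256)
  for (w in list_candidate_wavelets()) {
    for (mode in c("symmetric", "periodic")) {
      expect_lt(max(abs(waverec(wavedec(x, w, 5, mode)) - x)), 1e-8)
    }
  }
})

test_that("periodic-mode coefficients conserve energy (Parseval)", {
  set.seed(12)
  x <- rnorm(256)
  for (w in list_candidate_wavelets()) {
    d <- wavedec(x, w, 5, "periodic")
    en <- sum(d$approx^2) + sum(unlist(d$details)^2)
    expect_lt(abs(en - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("db1 and sym1 produce identical decompositions", {
  set.seed(13)
  x <- rnorm(128)
  d1 <- wavedec(x, "db1", 4)
  d2 <- wavedec(x, "sym1", 4)
  expect_identical(d1$details, d2$details)
  expect_identical(d1$approx, d2$approx)
})

test_that("MRA components are additive and band-localized", {
  set.seed(14)
  x <- rnorm(256)
  comps <- mra_reconstruct(wavedec(x, "sym9", 5))
  expect_named(comps, c("D1", "D2", "D3", "D4", "D5", "A5"))
  expect_lt(max(abs(Reduce(`+`, comps) - x)), 1e-8)
  # DC input: all energy in the approximation component
  cd <- mra_reconstruct(wavedec(rep(1, 256), "db4", 5, "periodic"))
  en <- vapply(cd, function(v) sum(v^2), 1)
  expect_identical(names(which.max(en)), "A5")
  expect_gt(en["A5"] / sum(en), 0.999)
  # 48 Hz tone at fs = 256 lands in D2 (32-64 Hz)
  tone <- sin(2 * pi * 48 * (0:255) / 256)
  et <- vapply(mra_reconstruct(wavedec(tone, "db8", 5)), function(v) sum(v^2), 1)
  expect_identical(names(which.max(et)), "D2")
})

test_that("dyadic band map reproduces the canonical EEG band table", {
  m <- dyadic_band_map(256, 5)
  expect_identical(m$component, c("D1", "D2", "D3", "D4", "D5", "A5"))
  expect_equal(m$low_hz, c(64, 32, 16, 8, 4, 0))
  expect_equal(m$high_hz, c(128, 64, 32, 16, 8, 4))
  expect_identical(
    m$eeg_band,
    c("higher gamma and noise", "lower gamma", "beta", "alpha", "theta", "delta")
  )
  # single split at fs = 2
  m2 <- dyadic_band_map(2, 1)
  expect_equal(m2$low_hz, c(0.5, 0))
  expect_equal(m2$high_hz, c(1, 0.5))
  # tiling of [0, fs/2]: contiguous, no gaps or overlaps
  m <- m[order(m$low_hz), ]
  expect_equal(m$low_hz[-1], m$high_hz[-nrow(m)])
  expect_equal(min(m$low_hz), 0)
  expect_equal(max(m$high_hz), 128)
})
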