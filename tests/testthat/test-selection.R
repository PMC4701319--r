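test_that("xcorr is the definitional Pearson correlation", {
  set.seed(61)
  x <- rnorm(100)
  expect_equal(xcorr(x, x), 1)
  expect_equal(xcorr(x, -x), -1)
  # hand-computed via the definitional formula
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 5, 4)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(xcorr(a, b), num / den)
  expect_equal(xcorr(a, b), cor(a, b))
  expect_error(xcorr(c(1, 1), c(2, 2)), "undefined-correlation")
  expect_error(xcorr(1:3, 1:4), "equal length")
  expect_true(is.na(xcorr(c(1, 1), c(1, 2), na_undefined = TRUE)))
})

test_that("score_all covers the full factorial and flags undefined epochs", {
  set.seed(62)
  rec <- noise_recording(seconds = 1, seed = 62)
  rec$data[3, ] <- 0                      # one dead channel
  rec <- eeg_recording(rec$data, rec$fs, rec$labels)
  ep <- segment_epochs(rec, 256)
  bank <- list_candidate_wavelets(c("db1", "db2", "sym1", "sym2"))
  expect_message(sc <- score_all(ep, bank), "undefined-correlation")
  # 19 channels x 1 epoch x 4 wavelets minus 4 dead-channel records
  expect_identical(nrow(sc), 19L * 4L - 4L)
  expect_identical(attr(sc, "n_undefined"), 4L)
  expect_true(all(sc$xcorr >= -1 & sc$xcorr <= 1))
  # db1 and sym1 are the same wavelet: identical score columns
  expect_equal(sc$xcorr[sc$wavelet == "db1"], sc$xcorr[sc$wavelet == "sym1"])
})

test_that("region pooling has the right pool sizes and rejects unmapped channels", {
  rec <- noise_recording(seconds = 2, seed = 63)
  ep <- segment_epochs(rec, 256)
  sc <- score_all(ep, list_candidate_wavelets(c("db2", "sym3")))
  pooled <- aggregate_by_region(sc)
  counts <- table(pooled$region, pooled$wavelet)
  expect_identical(unname(counts["frontal", "db2"]), 7L * 2L)
  expect_identical(unname(counts["occipital", "sym3"]), 2L * 2L)
  expect_identical(sum(counts), nrow(sc))
  bad <- sc
  bad$channel[1] <- "EKG"
  expect_error(aggregate_by_region(bad), "mapping error")
})

test_that("region means are invariant to epoch order", {
  rec <- noise_recording(seconds = 3, seed = 64)
  ep <- segment_epochs(rec, 256)
  sc <- score_all(ep, list_candidate_wavelets(c("db3", "sym4")))
  pooled <- aggregate_by_region(sc)
  m1 <- tapply(pooled$xcorr, list(pooled$region, pooled$wavelet), mean)
  perm <- sample(nrow(pooled))
  m2 <- tapply(pooled$xcorr[perm],
               list(pooled$region[perm], pooled$wavelet[perm]), mean)
  expect_equal(m1, m2)
})

test_that("select_best separates a shifted group and reports equivalences", {
  set.seed(65)
  # null: all wavelet groups drawn from one distribution
  null_pool <- data.frame(
    region = "frontal",
    wavelet = rep(paste0("w", 1:10), each = 30),
    xcorr = rnorm(300)
  )
  fit <- select_best(null_pool)
  expect_s3_class(fit, "mwt_selection")
  expect_gt(length(fit$regions$frontal$equivalent), 0L)
  # one group shifted far above: sole member of the top subset
  shifted <- null_pool
  shifted$xcorr[shifted$wavelet == "w7"] <- rnorm(30) + 10
  fit2 <- select_best(shifted)
  expect_identical(fit2$regions$frontal$winner, "w7")
  expect_length(fit2$regions$frontal$equivalent, 0L)
  # degenerate pools are rejected
  expect_error(
    select_best(data.frame(region = "r", wavelet = "w1", xcorr = c(1, 2))),
    "statistics error"
  )
})

test_that("mwt_select runs end to end with methods and tie-break by name", {
  rec <- gen_recording(synth_config(duration = 2, seed = 66))
  fit <- mwt_select(rec, bank = list_candidate_wavelets(c("db2", "db4", "sym4")),
                    keep_scores = TRUE)
  expect_s3_class(fit, "mwt_selection")
  expect_named(fit$regions,
               c("frontal", "temporal", "parietal", "occipital", "central"))
  for (rg in fit$regions) {
    expect_identical(rg$winner, rg$table$wavelet[1])
    expect_true(all(diff(rg$table$mean) <= 0))
    # lexicographic tie-break within equal means
    expect_false(is.unsorted(rg$table$wavelet[duplicated(rg$table$mean)]))
  }
  expect_output(print(fit), "winner")
  expect_output(summary(fit), "ANOVA")
  cf <- coef(fit)
  expect_length(cf, 5L)
  expect_true(all(cf >= -1 & cf <= 1))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  paths <- write_selection_report(fit, file.path(tempdir(), "selrep"))
  expect_true(all(file.exists(paths)))
})
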