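test_that("KS normality check calibrates on normal and rejects exponential", {
  set.seed(51)
  norm_sample <- rnorm(5000)
  r <- ks_normality(norm_sample)
  expect_gt(r$p.value, 0.05)
  expect_gte(r$statistic, 0)
  expect_lte(r$statistic, 1)
  r2 <- ks_normality(rexp(5000))
  expect_lt(r2$p.value, 0.001)
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("Levene's test detects heteroscedasticity and calibrates under the null", {
  set.seed(52)
  big <- levene_test(list(rnorm(100, sd = 1), rnorm(100, sd = 5)))
  expect_lt(big$p.value, 0.01)
  expect_equal(levene_test(list(c(1, 2, 3), c(4, 5, 6)))$statistic, 0)
  hits <- 0L
  for (i in 1:100) {
    g <- list(rnorm(30), rnorm(30))
    hits <- hits + (levene_test(g)$p.value > 0.05)
  }
  expect_gte(hits, 90L)
})

test_that("Levene's classic form agrees with the mean-centered reference", {
  skip_if_not_installed("car")
  set.seed(53)
  g <- list(a = rnorm(20), b = rnorm(25, sd = 2), c = rnorm(30))
  mine <- levene_test(g)
  v <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), lengths(g)))
  ref <- car::leveneTest(v, f, center = mean)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("one-way ANOVA handles identity, degeneracy, and equals t-squared", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(anova_oneway(list(c(2, 2), c(2, 2))), "zero-variance")
  expect_error(anova_oneway(list(c(1, 2))), ">= 2 groups")
  set.seed(54)
  for (i in 1:100) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    fit <- anova_oneway(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(fit$p.value, tt$p.value, tolerance = 1e-8)
  }
})

test_that("two-way ANOVA recovers additivity and decomposes sums of squares", {
  lev_a <- rep(1:3, each = 8)
  lev_b <- rep(rep(1:4, each = 2), 3)
  v_add <- lev_a + 2 * lev_b
  out <- anova_twoway(v_add, lev_a, lev_b)
  expect_lt(out$sum_sq[out$effect == "A:B"], 1e-16)
  # one factor constant in effect: its F ~ 0
  set.seed(55)
  v2 <- 2 * lev_b + rnorm(24, sd = 0.1)
  out2 <- anova_twoway(v2, sample(lev_a), lev_b, interaction = FALSE)
  expect_gt(out2$p.value[out2$effect == "A"], 0.05)
  # balanced layout: SS_total = SS_A + SS_B + SS_AB + SS_within
  v3 <- rnorm(24)
  out3 <- anova_twoway(v3, lev_a, lev_b)
  ss_total <- sum((v3 - mean(v3))^2)
  expect_equal(sum(out3$sum_sq), ss_total, tolerance = 1e-8)
})

test_that("Duncan critical ranges reproduce published table values", {
  # significant studentized ranges r_p at alpha = 0.05 (classic tables)
  cases <- list(
    list(df = 20, r = c(2.950, 3.097, 3.190)),
    list(df = 10, r = c(3.151, 3.293, 3.376))
  )
  for (cs in cases) {
    d <- duncan_mrt(list(a = 1:2, b = 2:3, c = 3:4, d = 4:5),
                    alpha = 0.05, mse = 1, df_within = cs$df)
    r_p <- unname(d$critical_ranges) / sqrt(1 / 2)  # n_h = 2
    expect_equal(r_p, cs$r, tolerance = 2e-3)
  }
})

test_that("Duncan subsets match a table-driven oracle on a 4-group fixture", {
  # known means, MSE 1, n = 6 per group, df = 20; r_p from published tables
  means <- c(g1 = 10.0, g2 = 9.7, g3 = 8.2, g4 = 8.05)
  groups <- lapply(means, function(m) m + c(-0.1, 0.1, -0.05, 0.05, 0, 0))
  d <- duncan_mrt(groups, alpha = 0.05, mse = 1, df_within = 20)
  se <- sqrt(1 / 6)
  r2 <- 2.950 * se  # 1.204: g1-g2 = 0.3 < r2 together; g3-g4 = 0.15 together
  r3 <- 3.097 * se
  expect_lt(means["g1"] - means["g2"], r2)
  expect_gt(means["g2"] - means["g3"], r2)  # oracle: {g1,g2} vs {g3,g4} split
  tab <- d$table
  expect_identical(tab$letters[tab$group == "g1"], tab$letters[tab$group == "g2"])
  expect_identical(tab$letters[tab$group == "g3"], tab$letters[tab$group == "g4"])
  expect_false(tab$letters[tab$group == "g1"] == tab$letters[tab$group == "g3"])
})

test_that("Duncan letters collapse for equal means and split for huge gaps", {
  same <- duncan_mrt(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                     mse = 1, df_within = 10)
  expect_identical(unique(same$table$letters), "a")
  far <- duncan_mrt(list(a = c(0, 0.1), b = c(100, 100.1)),
                    mse = 0.01, df_within = 10)
  expect_identical(sort(far$table$letters), c("a", "b"))
  d <- duncan_mrt(lapply(1:6, function(i) rnorm(5, i)), alpha = 0.05)
  expect_true(all(diff(d$critical_ranges) >= 0))  # R_p nondecreasing in span
  expect_error(duncan_mrt(list(a = 1:3, b = 2:4), mse = 1, df_within = 0),
               "df_within")
})
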