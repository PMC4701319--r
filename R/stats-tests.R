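# Assumption checks and post-hoc machinery for the region-level comparison of
# wavelet scores: KS normality, Levene homoscedasticity, one-/two-way ANOVA
# and Duncan's multiple range test.

.as_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- as.list(groups)
  if (!is.list(groups)) stop("groups must be a list of numeric vectors")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the sample against a normal distribution with
#' the sample's own mean and standard deviation, with the asymptotic KS
#' p-value.
#'
#' @param sample numeric vector, n >= 5.
#' @return list with `statistic` and `p.value`.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 5L) stop("need at least 5 observations")
  r <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample))
  )
  list(statistic = unname(r$statistic), p.value = r$p.value)
}

#' Levene's test of homogeneity of variances
#'
#' Classic form: a one-way ANOVA on the absolute deviations of each value
#' from its group mean.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `statistic` (F), `df`, and `p.value`.
#' @export
levene_test <- function(groups) {
  groups <- .as_groups(groups)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  dev <- lapply(groups, function(g) abs(g - mean(g)))
  if (stats::var(unlist(dev)) == 0) {
    return(list(statistic = 0, df = c(length(groups) - 1L,
                                      sum(lengths(groups)) - length(groups)),
                p.value = 1))
  }
  a <- anova_oneway(dev)
  list(statistic = a$F, df = c(a$df1, a$df2), p.value = a$p.value)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition over k groups, fit via `stats::lm`.
#' Returns the pieces (within-group mean square, dfs, group means and sizes)
#' that [duncan_mrt()] needs downstream.
#'
#' @param groups list of numeric vectors, or a data.frame of columns.
#' @return object of class `mwt_anova`: list with `F`, `df1`, `df2`,
#'   `p.value`, `mse`, `means`, `sizes`.
#' @export
anova_oneway <- function(groups) {
  groups <- .as_groups(groups)
  if (length(groups) < 2L) stop("need >= 2 groups")
  v <- unlist(groups, use.names = FALSE)
  if (length(v) <= length(groups)) stop("need more values than groups")
  if (stats::var(v) == 0) stop("zero-variance error: all values identical")
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  tab <- stats::anova(stats::lm(v ~ g))
  structure(
    list(
      F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
      p.value = tab$`Pr(>F)`[1], mse = tab$`Mean Sq`[2],
      means = vapply(groups, mean, 1), sizes = lengths(groups)
    ),
    class = "mwt_anova"
  )
}

#' @export
print.mwt_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df1, x$df2, x$F, x$p.value, x$mse))
  invisible(x)
}

#' Two-way ANOVA (Type II sums of squares)
#'
#' Main effects tested by Type II model comparisons (each main effect adjusted
#' for the other), plus the interaction when replicates allow; with a balanced
#' layout this coincides with the sequential decomposition.
#'
#' @param values numeric vector of responses.
#' @param factor_a,factor_b factors (or coercible) of the same length.
#' @param interaction include the A:B interaction term (requires > 1
#'   replicate per cell).
#' @return data.frame with one row per effect: `df`, `sum_sq`, `mean_sq`,
#'   `F`, `p.value`, plus a residual row.
#' @export
anova_twoway <- function(values, factor_a, factor_b, interaction = TRUE) {
  v <- as.numeric(values)
  A <- factor(factor_a)
  B <- factor(factor_b)
  stopifnot(length(A) == length(v), length(B) == length(v))
  if (interaction && !any(table(A, B) > 1L)) interaction <- FALSE
  if (interaction && any(table(A, B) == 0L)) {
    stop("empty cells: interaction term not estimable")
  }
  rss <- function(fml) sum(stats::residuals(stats::lm(fml))^2)
  rss_ab <- rss(v ~ A + B)
  ss_a <- rss(v ~ B) - rss_ab
  ss_b <- rss(v ~ A) - rss_ab
  full <- if (interaction) v ~ A * B else v ~ A + B
  rss_full <- rss(full)
  df_a <- nlevels(A) - 1L
  df_b <- nlevels(B) - 1L
  df_ab <- df_a * df_b
  df_res <- length(v) - df_a - df_b - 1L - if (interaction) df_ab else 0L
  if (df_res <= 0L) stop("no residual degrees of freedom")
  mse <- rss_full / df_res
  eff <- data.frame(
    effect = c("A", "B"), df = c(df_a, df_b), sum_sq = c(ss_a, ss_b),
    stringsAsFactors = FALSE
  )
  if (interaction) {
    eff <- rbind(eff, data.frame(effect = "A:B", df = df_ab,
                                 sum_sq = rss_ab - rss_full))
  }
  eff$mean_sq <- eff$sum_sq / eff$df
  eff$F <- eff$mean_sq / mse
  eff$p.value <- stats::pf(eff$F, eff$df, df_res, lower.tail = FALSE)
  rbind(eff, data.frame(effect = "residual", df = df_res, sum_sq = rss_full,
                        mean_sq = mse, F = NA, p.value = NA))
}

# studentized-range quantile; qtukey's root finder can fail to converge for
# wide spans at low confidence, so fall back to bisection on ptukey
.qtukey_safe <- function(conf, nmeans, df) {
  q <- suppressWarnings(stats::qtukey(conf, nmeans, df))
  if (is.finite(q)) return(q)
  lo <- 0
  hi <- 10
  while (stats::ptukey(hi, nmeans, df) < conf && hi < 1e6) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (stats::ptukey(mid, nmeans, df) < conf) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Duncan's multiple range test
#'
#' Post-hoc grouping of sample means into homogeneous subsets after an ANOVA.
#' Means are sorted in decreasing order; for a stretch spanning p means the
#' critical range is `R_p = q(1 - (1 - alpha)^(p-1); p, df) * sqrt(MSE / n_h)`
#' with `q` the studentized-range quantile (computed numerically via
#' [stats::qtukey()], not table lookup) and `n_h` the harmonic mean group
#' size. A stretch is homogeneous when its range falls below `R_p` or when it
#' is contained in a homogeneous stretch (Duncan's protection rule); letters
#' mark the maximal homogeneous stretches.
#'
#' @param groups list of numeric vectors (the per-group samples).
#' @param alpha significance level of the protected tests.
#' @param mse within-group mean square from the preceding ANOVA; defaults to
#'   computing it from `groups`.
#' @param df_within residual degrees of freedom matching `mse`.
#' @return object of class `duncan_result`: list with `table` (group, mean,
#'   n, letters, ordered by decreasing mean), `critical_ranges` (R_p for
#'   p = 2..k), `alpha`, `mse`, `df_within`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, mse = NULL, df_within = NULL) {
  groups <- .as_groups(groups)
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  if (is.null(mse) || is.null(df_within)) {
    a <- anova_oneway(groups)
    mse <- a$mse
    df_within <- a$df2
  }
  if (df_within <= 0) stop("df_within must be positive")
  means <- vapply(groups, mean, 1)
  sizes <- lengths(groups)
  ord <- order(-means, names(groups))
  m <- means[ord]
  n_h <- k / sum(1 / sizes)
  p <- 2:k
  # protected level for span p: alpha_p = 1 - (1 - alpha)^(p - 1)
  q <- mapply(.qtukey_safe, (1 - alpha)^(p - 1), p,
              MoreArgs = list(df = df_within))
  rp <- q * sqrt(mse / n_h)
  names(rp) <- paste0("p", p)

  # nonsig[i, j]: means ranked i..j are homogeneous (range test + closure)
  nonsig <- diag(TRUE, k)
  for (span in k:2) {
    r_span <- rp[span - 1]
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      raw <- (m[i] - m[j]) < r_span
      contained <- (i > 1L && nonsig[i - 1L, j]) ||
        (j < k && nonsig[i, j + 1L])
      nonsig[i, j] <- raw || contained
    }
  }
  # maximal homogeneous stretches -> letters
  stretches <- list()
  for (i in seq_len(k)) {
    j <- max(which(nonsig[i, i:k])) + i - 1L
    covered <- any(vapply(stretches, function(s) s[1] <= i && s[2] >= j, TRUE))
    if (!covered) stretches[[length(stretches) + 1L]] <- c(i, j)
  }
  lab <- c(letters, as.vector(outer(letters, letters, paste0)))
  letters_ <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]][1]:stretches[[s]][2]
    letters_[rng] <- paste0(letters_[rng], lab[s])
  }
  structure(
    list(
      table = data.frame(
        group = names(groups)[ord], mean = unname(m), n = unname(sizes[ord]),
        letters = letters_, stringsAsFactors = FALSE
      ),
      critical_ranges = rp, alpha = alpha, mse = mse, df_within = df_within
    ),
    class = "duncan_result"
  )
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, df = %d)\n",
              x$alpha, as.integer(x$df_within)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
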