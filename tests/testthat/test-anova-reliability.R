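test_that("two-level rm_anova equals the squared paired t on random fixtures", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n, mean = runif(1, -1, 1))
    d <- tibble::tibble(s = rep(sprintf("s%02d", 1:n), 2),
                        cond = rep(c("a", "b"), each = n),
                        y = c(a, b))
    res <- rm_anova(d, dv = "y", subject = "s", within = "cond")
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$gg_epsilon[1], 1)
    expect_equal(res$p_gg[1], tt$p.value, tolerance = 1e-8)
  }
})

test_that("Greenhouse-Geisser epsilon matches the trace formula", {
  set.seed(202)
  n <- 40; k <- 5
  y <- matrix(rnorm(n * k), n, k) %*% matrix(runif(k * k, -1, 1), k)
  d <- tibble::tibble(s = rep(sprintf("s%02d", 1:n), k),
                      cond = rep(letters[1:k], each = n),
                      y = as.vector(y))
  res <- rm_anova(d, dv = "y", subject = "s", within = "cond")
  # oracle: epsilon from the double-centered covariance of the cells
  S <- cov(y)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps_oracle <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  expect_equal(res$gg_epsilon[1], eps_oracle, tolerance = 1e-8)
  expect_gt(res$gg_epsilon[1], 1 / (k - 1))
  expect_lte(res$gg_epsilon[1], 1)
})

test_that("compound-symmetric data give epsilon near 1", {
  set.seed(303)
  eps <- replicate(30, {
    n <- 30; k <- 4
    subj <- rnorm(n, 0, 1)
    y <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k)
    d <- tibble::tibble(s = rep(1:n, k), cond = rep(1:k, each = n),
                        y = as.vector(y))
    rm_anova(d, dv = "y", subject = "s", within = "cond")$gg_epsilon[1]
  })
  expect_equal(mean(eps), 1, tolerance = 0.12)
})

test_that("multi-factor designs report every main effect and interaction", {
  set.seed(404)
  d <- tidyr::expand_grid(s = sprintf("s%02d", 1:12),
                          hemi = c("L", "R"), site = c("Fp", "O", "P"))
  d$y <- rnorm(nrow(d)) + (d$site == "O") * 0.8
  res <- rm_anova(d, dv = "y", subject = "s", within = c("hemi", "site"))
  expect_setequal(res$effect, c("hemi", "site", "hemi:site"))
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_true(all(res$p_gg >= 0 & res$p_gg <= 1))
  site <- res[res$effect == "site", ]
  expect_equal(site$df1, 2); expect_equal(site$df2, 22)
})

test_that("rm_anova rejects unbalanced data", {
  d <- tibble::tibble(s = c("a", "a", "b"), cond = c("x", "y", "x"),
                      y = rnorm(3))
  expect_error(rm_anova(d, dv = "y", subject = "s", within = "cond"),
               "design error")
})

test_that("Holm adjustment matches the hand-computed step-down triple", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.04, m = 1), 0.04)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  # returned in input order, monotone in sorted order, never below raw p
  set.seed(9)
  p <- runif(12)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_adjust(c(0.5, 1.2)), "domain error")
})

test_that("posthoc_vs_neutral flags degenerate scenarios and adjusts across them", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:10),
                          item_id = sprintf("i%d", 1:3))
  set.seed(11)
  d$x <- ifelse(d$item_id == "i1", 0, rnorm(nrow(d), -1))
  expect_warning(res <- posthoc_vs_neutral(d), "degenerate")
  expect_equal(res$p[res$scenario == "i1"], 1)
  expect_true(all(res$p_holm >= res$p))
})

test_that("valence ANOVA with the neutral reference has df (k, k(n-1))", {
  d <- gen_study1(n_subjects = 60, n_items = 10, seed = 55)
  res <- valence_anova(d)
  expect_equal(res$df1[1], 10)
  expect_equal(res$df2[1], 590)
  # the non-zero mean valence separates every scenario from neutral
  expect_lt(res$p_gg[1], 0.01)
  # cross-check F against the aov error-stratum route
  means <- aggregate(x ~ subject_id + item_id, d, mean)
  names(means) <- c("s", "scen", "v")
  long <- rbind(means, data.frame(s = unique(means$s), scen = ".neutral",
                                  v = 0))
  a <- summary(stats::aov(v ~ scen + Error(s / scen), data = long))
  f_aov <- a[["Error: s:scen"]][[1]]["scen", "F value"]
  expect_equal(res$F[1], f_aov, tolerance = 1e-8)
})

test_that("family-wise error of the neutral post-hocs is controlled under the null", {
  hits <- vapply(1:150, function(s) {
    d <- gen_study1(n_subjects = 15, n_items = 5, x_mean = 0, a1 = 0,
                    seed = 6000 + s)
    any(posthoc_vs_neutral(d)$p_holm < 0.05)
  }, TRUE)
  expect_lt(mean(hits), 0.05 + 3.3 * sqrt(0.05 * 0.95 / 150))
})

test_that("ICC is 1 for shift-identical profiles and invariant to affine maps", {
  base <- matrix(rep(c(1, 3, 2, 5), each = 6), nrow = 6)
  shifted <- base + rnorm(6)  # per-subject additive shifts, no noise
  expect_equal(icc_consistency(shifted), 1, tolerance = 1e-12)
  set.seed(21)
  noisy <- shifted + matrix(rnorm(24, 0, 0.5), 6)
  i1 <- icc_consistency(noisy)
  expect_equal(icc_consistency(noisy + 7), i1, tolerance = 1e-10)
  expect_equal(icc_consistency(noisy * 3 + 1), i1, tolerance = 1e-10)
  expect_lt(i1, 1)
})

test_that("pure-noise matrices give ICC near 0 on average", {
  # the estimator is consistent but negatively biased at small n
  # (E[1 - MS_E/MS_R] < 0 under the null), so probe at a size where the
  # bias term (n-1)/(n-3) - 1 is below the tolerance
  set.seed(31)
  iccs <- replicate(200, icc_consistency(matrix(rnorm(100 * 8), 100, 8)))
  expect_equal(mean(iccs), 0, tolerance = 0.05)
})

test_that("ICC variants order sensibly and degenerate input is flagged", {
  set.seed(41)
  x <- outer(rnorm(12), rep(1, 5)) + outer(rep(1, 12), c(0, 2, 1, 3, 2)) +
    matrix(rnorm(60, 0, 0.7), 12)
  expect_gte(icc_consistency(x, type = "ICC3k"),
             icc_consistency(x, type = "ICC2k"))
  expect_gte(icc_consistency(x, type = "ICC2k"),
             icc_consistency(x, type = "ICC21"))
  expect_warning(icc_consistency(matrix(rep(c(1, 2, 3), 4), nrow = 4,
                                        byrow = TRUE)), "zero between-subject")
})

test_that("PANAS change recovers zero change exactly and built-in shifts on average", {
  rec <- tibble::tibble(subject_id = sprintf("s%02d", 1:10),
                        pa_pre = 30:39, pa_post = 30:39,
                        na_pre = 15:24, na_post = 15:24)
  pc <- panas_change(rec)
  expect_equal(pc$changes$delta, c(0, 0))
  expect_equal(pc$interaction$F, 0)
  # parameter recovery at study scale
  deltas <- vapply(1:100, function(s) {
    b <- gen_study2(n_subjects = 22, pa_shift = -3, na_shift = 3,
                    seed = 7000 + s)
    pc <- panas_change(b$panas)
    pc$changes$delta
  }, numeric(2))
  expect_equal(mean(deltas[1, ]), -3, tolerance = 3 * sd(deltas[1, ]) / 10)
  expect_equal(mean(deltas[2, ]), 3, tolerance = 3 * sd(deltas[2, ]) / 10)
  expect_error(panas_change(rec[1:2, ]), "sample-size")
})

test_that("subject-level correlation is 1 for identical variables and near 0 under independence", {
  d <- gen_study1(n_subjects = 25, seed = 61)
  self <- subject_level_correlation(d, "stress", "stress")
  expect_equal(self$r, 1, tolerance = 1e-12)
  rs <- vapply(1:200, function(s) {
    n <- 20
    tab <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                          a = rnorm(n), b = rnorm(n))
    subject_level_correlation(tab, "a", "b")$r
  }, 1.0)
  expect_equal(mean(rs), 0, tolerance = 0.06)
  # built-in covariate correlation is recovered directionally
  expect_gt(subject_level_correlation(d, "stai", "stress")$r, 0.1)
})
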