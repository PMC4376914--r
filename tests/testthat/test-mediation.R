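test_that("noiseless linear data recover the slope and the grand mean exactly", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:6),
                          item_id = sprintf("i%d", 1:4))
  set.seed(1)
  d$x <- rnorm(nrow(d))
  d$y <- 2 * d$x
  fit <- fit_lmm(d, "y", "x")
  expect_equal(fit$fixed_effects$estimate[2], 2, tolerance = 1e-6)
  expect_equal(fit$fixed_effects$estimate[1], 0, tolerance = 1e-6)

  d$y2 <- 5 + rnorm(nrow(d))
  fit0 <- fit_lmm(d, "y2", character())
  expect_equal(fit0$fixed_effects$estimate[1], mean(d$y2), tolerance = 1e-6)
})

test_that("fixed effects agree with a brute-force GLS oracle on a toy set", {
  set.seed(2)
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:6),
                          item_id = sprintf("i%d", 1:4))
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 0.7 * d$x + rep(rnorm(6, 0, 0.8), each = 4) +
    rep(rnorm(4, 0, 0.5), 6) + rnorm(nrow(d), 0, 0.6)
  fit <- fit_lmm(d, "y", "x")
  vc <- fit$variance_components
  beta_gls <- gls_oracle(d$y, cbind(1, d$x), d$subject_id, d$item_id,
                         vc["subject"], vc["item"], vc["residual"])
  expect_equal(fit$fixed_effects$estimate, as.numeric(beta_gls),
               tolerance = 1e-6)
})

test_that("singular designs and undersized samples are rejected", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:4),
                          item_id = sprintf("i%d", 1:3))
  d$x <- rnorm(nrow(d)); d$x2 <- 2 * d$x; d$y <- rnorm(nrow(d))
  expect_error(fit_lmm(d, "y", c("x", "x2")), "rank error")
  expect_error(fit_lmm(d[d$subject_id == "s01", ], "y", "x"), ">= 2 subjects")
})

test_that("incomplete rows are dropped listwise with a message", {
  d <- gen_study1(n_subjects = 8, n_items = 4, seed = 3)
  d$stress[c(2, 9)] <- NA
  expect_message(fit <- fit_lmm(d, "stress", "x"), "dropping 2")
  expect_equal(fit$n_obs, nrow(d) - 2)
})

test_that("Monte-Carlo indirect CI is reproducible, degenerate-safe and symmetric", {
  # degenerate: zero SEs collapse to the point product
  ci0 <- mc_indirect_ci(2, 3, 0.5, 0, 0, 0, k = 2000, seed = 1)
  expect_equal(ci0$lower, 3); expect_equal(ci0$upper, 3)
  expect_equal(ci0$point, 3)

  # bit-identical under a fixed seed
  a <- mc_indirect_ci(1, 0.5, -0.6, 0.1, 0.05, 0.04, k = 50000, seed = 42)
  b <- mc_indirect_ci(1, 0.5, -0.6, 0.1, 0.05, 0.04, k = 50000, seed = 42)
  expect_identical(a$lower, b$lower)
  expect_identical(a$upper, b$upper)
  expect_true(a$lower <= a$point && a$point <= a$upper)

  # centred normals: symmetric about 0 and covering 0
  s <- mc_indirect_ci(0, 0, 0, 1, 1, 1, k = 1e6, seed = 7)
  expect_equal(s$lower, -s$upper, tolerance = 0.01)
  expect_false(s$significant)

  # width shrinks as SEs shrink
  wide <- mc_indirect_ci(1, 0.5, -0.6, 0.2, 0.2, 0.2, k = 20000, seed = 5)
  narrow <- mc_indirect_ci(1, 0.5, -0.6, 0.02, 0.02, 0.02, k = 20000, seed = 5)
  expect_lt(narrow$upper - narrow$lower, wide$upper - wide$lower)

  expect_error(mc_indirect_ci(1, 1, 1, 0, 0, 0, k = 10, seed = 1),
               "at least 1000")
  expect_error(mc_indirect_ci(1, 1, 1, -0.1, 0, 0, k = 2000, seed = 1),
               "domain error")
})

test_that("an exactly linear outcome recovers c', b1, b2 to numerical precision", {
  # mediators keep their own variation; the outcome carries no noise, so the
  # outcome model is identified and exact
  d <- gen_study1(n_subjects = 10, n_items = 4,
                  a1 = 1, a2 = 0.3, d21 = 0.5, b1 = 0.1, b2 = -0.6,
                  c_prime = -0.15, sd_subject = 0, sd_item = 0,
                  sd_resid = 1, sd_resid_y = 1e-8,
                  gamma_stai = 0, gamma_siri = 0, seed = 8)
  fy <- fit_lmm(d, "risk_taking", c("x", "stress", "risk_perception"))
  est <- setNames(fy$fixed_effects$estimate, fy$fixed_effects$term)
  expect_equal(unname(est["x"]), -0.15, tolerance = 1e-6)
  expect_equal(unname(est["stress"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(est["risk_perception"]), -0.6, tolerance = 1e-6)
})

test_that("serial mediation at study scale recovers the chain within sampling error", {
  d <- gen_study1(n_subjects = 60, n_items = 10, seed = 88)
  m <- serial_mediation(d, "x", "stress", "risk_perception", "risk_taking",
                        covariates_on_y = c("stai", "siri"),
                        k = 5000, seed = 9)
  est <- tidy(m)
  pick <- function(p) est$estimate[est$path == p]
  se <- function(p) est$se[est$path == p]
  expect_lt(abs(pick("a1") - 1.0), 4 * se("a1"))
  expect_lt(abs(pick("d21") - 0.5), 4 * se("d21"))
  expect_lt(abs(pick("b2") - (-0.6)), 4 * se("b2"))
  expect_lt(abs(pick("c_prime") - (-0.15)), 4 * se("c_prime"))
})

test_that("a null a1 path yields a null indirect effect", {
  d <- gen_study1(n_subjects = 10, n_items = 4, a1 = 0, a2 = 0, d21 = 0.5,
                  sd_subject = 0, sd_item = 0, sd_resid = 1,
                  sd_resid_y = 1e-8, gamma_stai = 0, gamma_siri = 0,
                  seed = 10)
  # with a1 = 0, stress is pure noise independent of x
  f1 <- fit_lmm(d, "stress", "x")
  a1_hat <- f1$fixed_effects$estimate[2]
  expect_lt(abs(a1_hat), 4 * f1$fixed_effects$se[2])
})

test_that("indirect effect equals the product of the reported paths exactly", {
  d <- gen_study1(n_subjects = 12, n_items = 5, seed = 12)
  m <- serial_mediation(d, "x", "stress", "risk_perception", "risk_taking",
                        covariates_on_y = c("stai", "siri"), k = 2000, seed = 13)
  est <- with(m$paths, a1["estimate"] * d21["estimate"] * b2["estimate"])
  expect_equal(m$indirect_serial, unname(est), tolerance = 0)
})

test_that("the LRT is zero when mediators are constrained out and df = 2", {
  d <- gen_study1(n_subjects = 12, n_items = 5, seed = 14)
  lrt <- lrt_mediation(d, "x", "stress", "risk_perception", "risk_taking")
  expect_equal(lrt$df, 2L)
  expect_gte(lrt$chi_sq, 0)
  # comparing a model against itself: chi^2 = 0 by construction
  base <- fit_lmm(d, "risk_taking", "x", reml = FALSE)
  expect_equal(2 * (base$log_likelihood - base$log_likelihood), 0)
})

test_that("tidy and glance return the documented shapes", {
  d <- gen_study1(n_subjects = 8, n_items = 4, seed = 15)
  m <- serial_mediation(d, "x", "stress", "risk_perception", "risk_taking",
                        k = 2000, seed = 16)
  td <- tidy(m)
  expect_setequal(td$path, c("a1", "a2", "d21", "c_prime", "b1", "b2"))
  gl <- glance(m)
  expect_true(all(c("indirect_serial", "mc_lower", "mc_upper", "lrt_chi_sq",
                    "lrt_p") %in% names(gl)))
  expect_s3_class(autoplot(m), "ggplot")
})
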